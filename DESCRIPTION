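Package: volnet
Title: Metabolic Network Inference from Volatile-Compound Flux Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-destructive inference of soil metabolic networks from
    multichannel volatile-compound (PTR-TOF-MS) flux time series. Provides
    preprocessing of multiplexed ion-count data (primary-ion normalization,
    gap filling, blank subtraction, replicate averaging, spline smoothing and
    interval aggregation), directed connection inference by lagged mutual
    information partitioned into unique, synergistic and redundant components
    with shuffled-surrogate significance testing, projection of inferred
    connections onto a bipartite metabolite/gene reaction network as shortest
    paths, and extraction of pathway sub-networks supported by at least two
    connections. A synthetic-data module generates pulse-perturbed, lag-coupled
    flux panels with known ground truth for offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    zoo,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
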