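---
title: "Methods: information-partitioning network inference for volatile flux panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-partitioning network inference for volatile flux panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`volnet` infers directed metabolite-to-metabolite connections from
multichannel volatile-compound (mVC) flux time series, and projects them onto
a reaction network. This vignette is the package's account of the science:
the model and its assumptions, the parameters that matter, what the synthetic
benchmark does and does not emulate, and the numerical decisions taken where
the design was genuinely open.

## 1. The measurement model and preprocessing

A flow-through microcosm experiment multiplexes one PTR-TOF-MS instrument
over six chambers (five soil replicates and one blank), each observed for a
10-min slot in a 60-min rotation. Raw data per chamber are ion counts per
m/z channel per timestamp. The preprocessing chain is fixed, in this order:

1. **Primary-ion normalization.** Counts scale with the instrument's primary
   ion supply, so every channel is normalized by the m/z 21 reference
   (hydronium isotopologue): `ncps = count / reference × 500`. A channel
   equal to the reference therefore reads exactly 500 ncps — this worked
   example is a test anchor. Timepoints with a missing or zero reference are
   an error rather than silently dropped: the quantity is undefined there.
2. **Gap filling.** The rotation leaves each chamber with 50-min gaps
   between 10-min observed blocks. Interior missing runs of at most
   `max_gap` (default 50 min) are linearly interpolated; longer runs and
   leading/trailing blocks stay missing. Linear interpolation is the
   minimal-assumption choice; the method is configurable, and the default
   deliberately makes no claim about sub-hour structure inside a gap.
3. **Blank subtraction.** The blank chamber is normalized and gap-filled
   first (so subtraction is defined at all sample timepoints, a choice the
   chain has to make one way or the other), then subtracted entrywise.
   Negative results are clipped to 0 by default — fluxes are non-negative —
   and the clipped-cell count is reported.
4. **Replicate averaging.** Pointwise mean over the five soil replicates,
   ignoring missing cells. Because the rotation staggers the replicates, a
   cell is missing in the average only when no replicate observed (or could
   interpolate) it; in practice that is the blank's unfillable leading block
   and the final rotation slot.
5. **Smoothing and aggregation.** A smoothing spline per channel (strength
   per channel by generalized cross-validation, `stats::smooth.spline`;
   seedless and deterministic; a fixed `spar` is available for exact
   reproducibility across platforms), then means over consecutive 5-min
   windows. Channels with fewer than 10 observations are dropped with a
   warning. The wet-up time is a required configuration value, never
   inferred from the data.

A centered PCA of the resulting timepoint × channel matrix
(`ordination_overview()`) gives the synchronous overview; the information
partitioning below goes beyond it by using temporal ordering.

## 2. Lagged mutual information and its partition

Metabolic transformation chains impose delays, so dependence is probed at
lags: for source `X` and target `Y`,
`LMI(Δτ) = I(X(t − Δτ); Y(t))` over a lag grid of 5–100 min in 5-min steps
(20 lags on a 5-min panel). The best lag is the argmax, with ties broken
toward the smallest lag — the shortest causal delay.

For a target `Y` and two lagged sources `X1`, `X2`, the joint information
`I12 = I(X1, X2; Y)` is decomposed into components that are each
non-negative and sum exactly to `I12`:

* `U1`, `U2` — unique information each source alone contributes,
* `R` — redundant information both carry,
* `S` — synergistic information only the pair carries.

With `I1 = I(X1; Y)`, `I2 = I(X2; Y)`, redundancy is interpolated between
its admissible bounds `R_min = max(0, I1 + I2 − I12)` and
`R_MMI = min(I1, I2)` by the source dependency
`s = I(X1; X2) / min(H(X1), H(X2))`:

`R = R_min + s (R_MMI − R_min)`, then `U_i = I_i − R`, `S = I12 − U1 − U2 − R`.

Any `R` in `[R_min, R_MMI]` keeps all four components non-negative; the
interpolation makes independent sources (s = 0) maximally unique and
duplicate sources (s = 1) maximally redundant. `"minimum"` and `"mmi"` are
selectable for sensitivity analysis. Canonical sanity checks hold exactly on
exhaustive binary tables: XOR gives pure synergy (S = 1 bit), duplicated
sources pure redundancy (R = 1 bit), a copy with an independent distractor
pure uniqueness. A zero-entropy (constant) source is reported with a warning
and contributes no unique information. R is computed but never reported as a
network edge; only U and S connections are.

### Estimator

All information quantities use a plug-in estimator on rank-discretized data:
each series is converted to average ranks and binned into
`B = max(2, floor(n^(1/3)))` equal-occupancy bins. Consequences worth
knowing:

* **Monotone invariance.** Estimates are invariant under monotone transforms
  of each channel (only ranks enter), so units and calibration curves do not
  matter.
* **Ties stay together.** Average ranks keep tied values in one bin: a
  constant series maps to a single symbol (entropy 0, with a warning), and
  discrete-valued series keep their support.
* **Bias.** The plug-in estimate has a positive null bias of roughly
  `(B − 1)² / (2 n ln 2)` bits (about 0.03 bits at n = 10,000). No
  correction is applied by default because the surrogate test absorbs the
  bias under the null; a Miller–Madow correction is available
  (`correct = TRUE`) when the number itself matters. Against the Gaussian
  closed form `−½ log2(1 − ρ²)` the estimator at ρ = 0.6 is within 0.02 bits
  by n = 50,000, and accuracy improves with n.
* **Discretize once, subset per lag.** Channels are discretized on the full
  series and the symbol streams subset for lag alignment. A permuted series
  then has exactly the permuted symbols, which makes the observed
  max-over-lags statistic and its surrogates exactly exchangeable (next
  section). The alternative — re-discretizing each truncated segment —
  breaks that exactness for no estimator benefit at these lags (≤ 20 steps
  of ≥ 300).

## 3. Surrogate significance

Each pair's statistic is its **maximum LMI over the lag grid**. Significance
comes from shuffled surrogates: the source series is randomly permuted
(destroying temporal structure, preserving the marginal), the same
max-over-grid statistic is recomputed, and
`p = (1 + #{surrogate ≥ observed}) / (n + 1)` with n = 2,500 surrogates by
default. Two decisions matter here:

* **The surrogate statistic includes the lag maximization.** Comparing a
  max-selected observation against fixed-lag surrogates would be
  anticonservative; recomputing the max per surrogate makes the test exact
  at level α under the null, which the type-I calibration test confirms
  (rejection fraction within [0.03, 0.07] at α = 0.05 over 1,000
  independent-pair replicates).
* **Per-pair substreams.** All randomness flows from one master seed, with a
  deterministic substream per source-target pair, so results do not depend
  on evaluation order.

Testing is per-connection by default, with no multiple-testing correction —
the per-connection surrogate test is the method's native form. A
Benjamini–Hochberg option (`p_adjust = "BH"`) is provided and is what the
package's own structure-recovery benchmark uses: over the 56 ordered pairs
of an 8-channel panel, uncorrected α = 0.05 testing expects ~2.7 false
positives among 53 null pairs by construction, so a benchmark that demands
near-zero false discoveries is a multiple-testing setting and is treated as
one.

## 4. Network assembly

* Every ordered channel pair is scanned; pairs with (adjusted) p ≤ α are the
  significant connections.
* Unique information is only defined relative to a second source, so each
  retained pair's `U` is taken from one coherent decomposition: the triad
  with its **best synergy partner** — the candidate channel (all channels
  except source and target) maximizing S, each candidate entering at its own
  best pairwise lag to the target. There is no joint lag optimization: the
  combinatorial cost is large and pairwise lags are already stable anchors.
  If no candidate yields S > 0 the triad is omitted (logged) and the pair's
  U falls back to 0.
* The **top 20%** of significant connections by U is retained
  (`floor(fraction · n)`, minimum 1 when nonempty — never more than the
  stated fraction), with deterministic tie-breaks (U descending, then source
  and target label ascending), so the retained set is invariant to input
  order. Ranking by total lagged MI is available as an alternative.
* Dry and wet phases are analysed separately and both networks emitted; the
  wet network is the one usually projected.

## 5. Pathway projection

The reaction graph is a directed bipartite metabolite/gene graph with
pathway-labelled edges (a minimal text stand-in for a KEGG extraction; the
package ships a toy methylotrophy graph). Channels map to metabolite nodes
through a user-supplied annotation table (m/z tolerance 0.005 Th, matching
3-decimal peak labels).

* Each retained connection becomes the **shortest directed path** (BFS, unit
  weights) from source to target metabolite. Ambiguous annotations resolve
  to the globally shortest projection — the benefit of the doubt — with
  equal-length paths tie-broken by lexicographic node-id sequence, so
  projection is deterministic. Connections with no directed path are kept
  and flagged unprojectable; synergy triads project their two sources to the
  shared target independently ("forked" paths). An undirected fallback is
  deliberately off: reactions have direction.
* A pathway whose id labels an edge of at least **two** projected paths is
  extracted as a sub-network (a path crossing several pathways counts once
  for each), with the subgraph induced by its member paths. Shortest-path
  minimality is oracle-tested against exhaustive enumeration on random
  bipartite graphs.
* Exports: GraphML (node attributes `kind` and `detected`, the latter
  flagging metabolites actually measured as channels), flat edge /
  sub-network / unprojectable tables. A user-supplied manual-edge table can
  add known reactions missing from the extraction, under the same
  bipartiteness validation.

## 6. The synthetic benchmark

`coupling_spec()` + `generate_clean_panel()` + `generate_raw_counts()`
emulate the study design statistically: per-channel baselines (optional slow
drift, off by default), a wet-up pulse as a difference of exponentials
(default rise 60 min, decay 600 min — fast spike, slow relaxation, the
qualitative post-wet-up trajectory), directed couplings applied to the
source's deviation from baseline at a lag of ≥ 1 step (linear, quadratic or
threshold — the nonlinear forms exist to verify that mutual information
detects what correlation misses), additive Gaussian channel noise scaled to
baseline (default 5%), and on the instrument side: counts proportional to a
fluctuating m/z 21 reference, a shared blank background, multiplicative
log-normal measurement noise (ion-counting noise is heteroscedastic),
independent across the five simulated jars, and the 10-min/60-min rotation
masking. Generation is stepwise in time, so coupling chains and feedback
loops are well defined; everything is deterministic given the seed.

What it does **not** emulate: chamber mass-balance physics, fragmentation
and isotopes, real soils' unknown coupling structure, and non-stationary
noise. Passing the benchmarks therefore shows the *chain* is correct — it
does not certify performance on real soil data.

Benchmark conditions used by the test suite (chosen once as realistic for
this design, and sized so the whole suite runs in minutes on one CPU):

* **Structure recovery**: 8 channels, 5-min step, 48 h (576 points), three
  linear couplings of gain 3 at lags 15/30/45 min, 5% noise, no pulse (a
  pulse shared across channels is genuine common dependence, not a null),
  2,500 surrogates with BH control. All three edges must be recovered at
  their exact lags with at most one false positive among the 53 null pairs.
* **Round trip**: 4 channels, 1-min step, 24 h, noise off, pulse on all
  channels, full rotation masking. After the complete preprocessing chain
  the 5-min-aggregated clean panel must be recovered with per-channel RMSE
  at most 5% of the channel's range (linear interpolation across a 50-min
  gap on a 60-min-rise pulse leaves ≲ 2% typical error; 5% is honest
  headroom). Only the blank's leading block and the final slot are
  unobservable.
* **Calibration**: 1,000 independent-pair replicates at 500 surrogates each
  (scaled down from the default 2,500 — calibration depends on the p-value
  definition, not the surrogate count).

## 7. Known limitations

* **Shuffled surrogates test temporal structure, not causality.** Channels
  sharing a deterministic trend — e.g. a common wet-up pulse — are genuinely
  dependent and will be flagged even without any metabolic link; permutation
  surrogates are anticonservative for strongly autocorrelated series. The
  wet-phase network should be read with this in mind; phase-restricted
  analysis and the BH option mitigate but do not remove it.
* The redundancy measure is one defensible interpolation between bounds;
  PID is not unique, which is why the bounds themselves are selectable.
* Best-lag-per-source is a heuristic; a target driven through several lags
  reports only the strongest.
* The estimator is binned and univariate-per-source; no transfer entropy,
  no more-than-two-source decompositions, no kernel/KSG estimators.
* Projection inherits the reaction graph's completeness: missing reactions
  make real connections unprojectable (they are reported, not dropped).
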