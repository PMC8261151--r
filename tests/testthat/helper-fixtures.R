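# Shared fixtures and independent oracles, built in code at test time.

# Write a reaction-graph file in the three-section format.
write_graph_file <- function(nodes, edges, pathways,
                             path = tempfile(fileext = ".tsv")) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#nodes", con)
  write.table(nodes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("#edges", con)
  write.table(edges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("#pathways", con)
  write.table(pathways, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A small methylotrophy-flavoured toy reaction graph:
# methanol -mdh-> formaldehyde -fdh-> formate, and
# TMA -tmm-> DMA -dmd-> formaldehyde.
toy_graph_file <- function(path = tempfile(fileext = ".tsv")) {
  nodes <- data.frame(
    id = c("C00132", "C00067", "C00058", "C00565", "C00543",
           "G_mdh", "G_fdh", "G_tmm", "G_dmd"),
    kind = c(rep("metabolite", 5), rep("gene", 4)),
    label = c("methanol", "formaldehyde", "formate", "trimethylamine",
              "dimethylamine", "mdh", "fdh", "tmm", "dmd"))
  edges <- data.frame(
    from = c("C00132", "G_mdh", "C00067", "G_fdh", "C00565", "G_tmm",
             "C00543", "G_dmd"),
    to   = c("G_mdh", "C00067", "G_fdh", "C00058", "G_tmm", "C00543",
             "G_dmd", "C00067"),
    reaction = paste0("R", 1:8),
    pathways = c("P1", "P1", "P1", "P1", "P1,P2", "P2", "P2", "P2"))
  pathways <- data.frame(id = c("P1", "P2"),
                         name = c("Methane metabolism", "Methylamine degradation"))
  write_graph_file(nodes, edges, pathways, path)
}

write_annotation_file <- function(d, path = tempfile(fileext = ".tsv")) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

# Random directed bipartite metabolite/gene graph with pathway labels.
random_bipartite_graph <- function(n_met, n_gene, n_edges, seed) {
  set.seed(seed)
  mets <- paste0("M", seq_len(n_met)); genes <- paste0("G", seq_len(n_gene))
  from <- character(n_edges); to <- character(n_edges)
  for (k in seq_len(n_edges)) {
    if (runif(1) < 0.5) {
      from[k] <- sample(mets, 1); to[k] <- sample(genes, 1)
    } else {
      from[k] <- sample(genes, 1); to[k] <- sample(mets, 1)
    }
  }
  e <- unique(data.frame(from = from, to = to))
  e$reaction <- paste0("R", seq_len(nrow(e)))
  e$pathways <- sample(c("P1", "P2", "P3"), nrow(e), replace = TRUE)
  nodes <- data.frame(id = c(mets, genes),
                      kind = c(rep("metabolite", n_met), rep("gene", n_gene)),
                      label = c(mets, genes))
  pw <- data.frame(id = c("P1", "P2", "P3"), name = c("pw one", "pw two", "pw three"))
  read_reaction_graph(write_graph_file(nodes, e, pw))
}

# Independent shortest-path oracle: exhaustive DFS over all simple directed
# paths (edge list as two character vectors), returning the minimum edge
# count from `from` to `to`, or Inf.
oracle_shortest <- function(edge_from, edge_to, from, to) {
  if (from == to) return(0L)
  best <- Inf
  walk <- function(node, seen, len) {
    if (len >= best) return(invisible())
    nxt <- edge_to[edge_from == node]
    for (v in nxt) {
      if (v == to) { best <<- min(best, len + 1L); next }
      if (!(v %in% seen)) walk(v, c(seen, v), len + 1L)
    }
  }
  walk(from, from, 0L)
  best
}

# Brute-force lag scan by cross-correlation: argmax over lags of
# cor(x(t - lag), y(t)).
oracle_xcorr_lag <- function(x, y, max_lag) {
  n <- length(x)
  cc <- vapply(0:max_lag, function(L)
    abs(cor(x[seq_len(n - L)], y[(L + 1):n])), numeric(1))
  (0:max_lag)[which.max(cc)]
}

# Default benchmark spec for structure recovery: 8 channels, three strong
# linear couplings at distinct lags, 5% channel noise, no pulse.
recovery_spec <- function(seed = 1L) {
  coupling_spec(8, duration = 2880, step = 5,
                edges = data.frame(source = 1:3, target = 4:6,
                                   lag = c(3L, 6L, 9L), gain = 3,
                                   form = "linear"),
                baseline = c(100, 120, 80, 90, 110, 95, 105, 85),
                noise_sd = 0.05, seed = seed)
}
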