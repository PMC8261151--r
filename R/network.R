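#' Build the network of significant directed connections
#'
#' Evaluates lagged mutual information over the lag grid for every ordered
#' channel pair, tests each pair's max-over-grid statistic against shuffled
#' surrogates, and retains pairs with (optionally BH-adjusted) p-value at or
#' below `surr$alpha`. Each retained pair carries its best lag and MI; the
#' unique-information strength `U` is filled in afterwards from the pair's
#' best synergy triad (unique information is only defined relative to a
#' second source in a two-source decomposition).
#'
#' @param panel a [flux_panel] (one phase; see [panel_phase()]).
#' @param grid a [lag_grid].
#' @param surr a [surrogate_config].
#' @return A data frame of retained connections: `source`, `target`,
#'   `best_lag` (min), `best_lag_steps`, `mi`, `p`, plus an attribute
#'   `n_pairs` with the number of pairs evaluated.
#' @export
build_u_network <- function(panel, grid = lag_grid(), surr = surrogate_config()) {
  p <- ncol(panel$values)
  empty <- data.frame(source = character(0), target = character(0),
                      best_lag = numeric(0), best_lag_steps = integer(0),
                      mi = numeric(0), p = numeric(0))
  if (p < 2L) return(structure(empty, n_pairs = 0L))
  pairs <- expand.grid(si = seq_len(p), ti = seq_len(p))
  pairs <- pairs[pairs$si != pairs$ti, ]
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    r <- lagged_mi(panel, pairs$si[k], pairs$ti[k], grid, surr)
    data.frame(source = r$source, target = r$target, best_lag = r$best_lag,
               best_lag_steps = r$best_lag_steps, mi = r$best_mi, p = r$p)
  })
  conn <- do.call(rbind, rows)
  padj <- if (surr$p_adjust == "BH") stats::p.adjust(conn$p, "BH") else conn$p
  keep <- conn[padj <= surr$alpha, , drop = FALSE]
  message("build_u_network: ", nrow(keep), " of ", nrow(conn),
          " ordered pairs significant (alpha ", surr$alpha,
          if (surr$p_adjust == "BH") ", BH-adjusted" else "", ")")
  rownames(keep) <- NULL
  structure(keep, n_pairs = nrow(conn))
}

#' Select the best synergy partner for a significant connection
#'
#' For a retained source-target pair, evaluates every other panel channel as
#' candidate second source: each candidate takes its own best pairwise lag to
#' the target, the triad is decomposed, and the candidate with the highest
#' synergistic information S wins. The winning triad also supplies the pair's
#' unique information `U1`.
#'
#' @param connection one row of a [build_u_network()] result (list or
#'   one-row data frame with `source`, `target`, `best_lag_steps`).
#' @param panel the [flux_panel].
#' @param grid the [lag_grid] used for the candidates' pairwise lag scans.
#' @param redundancy redundancy measure passed to [pid_decompose()].
#' @return A one-row data frame (`source1`, `source2`, `target`, `lag1_steps`,
#'   `lag2_steps`, `U1`, `U2`, `R`, `S`, `n_candidates`), or `NULL` when no
#'   candidate yields S > 0 (logged).
#' @export
best_synergy_partner <- function(connection, panel, grid = lag_grid(),
                                 redundancy = "rescaled") {
  if (ncol(panel$values) < 3L) stop("synergy needs a panel with >= 3 channels")
  src <- channel_index(panel, connection$source)
  tgt <- channel_index(panel, connection$target)
  cand <- setdiff(seq_len(ncol(panel$values)), c(src, tgt))
  steps <- grid_steps(grid, panel)
  best <- NULL
  for (ci in cand) {
    sc <- lmi_scan(panel$values[, ci], panel$values[, tgt], steps)
    clag <- steps[which.max(sc$mi)]
    pid <- suppressWarnings(
      pid_decompose(panel, src, ci, tgt,
                    lag1 = connection$best_lag_steps, lag2 = clag,
                    redundancy = redundancy))
    if (is.null(best) || pid$S > best$S) {
      best <- pid; best$lag2_steps <- clag; best$ci <- ci
    }
  }
  if (is.null(best) || best$S <= 0) {
    message("no candidate with S > 0 for ", connection$source, " -> ",
            connection$target, "; triad omitted")
    return(NULL)
  }
  data.frame(source1 = connection$source,
             source2 = colnames(panel$values)[best$ci],
             target = connection$target,
             lag1_steps = connection$best_lag_steps,
             lag2_steps = best$lag2_steps,
             U1 = best$U1, U2 = best$U2, R = best$R, S = best$S,
             n_candidates = length(cand))
}

#' Keep the top fraction of connections by strength
#'
#' Sorts by the ranking column descending (stable: ties broken by source then
#' target label ascending) and keeps `floor(fraction * n)` rows, at least 1
#' when the input is non-empty — never more than the stated fraction.
#'
#' @param connections data frame of connections.
#' @param fraction fraction to keep, in (0, 1]; default 0.2 (the top 20%).
#' @param by ranking column (default `"U"`; `"mi"` ranks by total lagged MI).
#' @return The filtered, sorted data frame.
#' @export
select_top_fraction <- function(connections, fraction = 0.2, by = "U") {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n <- nrow(connections)
  if (n == 0L) return(connections)
  if (!by %in% names(connections)) stop("no ranking column '", by, "'")
  ord <- order(-connections[[by]], connections$source, connections$target)
  connections[ord, , drop = FALSE][seq_len(max(1L, floor(fraction * n))), ,
                                   drop = FALSE]
}

#' Infer the directed metabolic-connection network of a flux panel
#'
#' The estimation entry point of the package. For each phase of the panel
#' (dry / wet, run separately) it: (1) scans every ordered channel pair with
#' lagged mutual information over the lag grid and keeps surrogate-significant
#' pairs; (2) finds each retained pair's best synergy partner among all other
#' channels, which supplies the pair's unique information `U` and the
#' synergistic triad strength `S`; (3) applies the top-fraction filter on `U`.
#'
#' @param panel a [flux_panel].
#' @param grid a [lag_grid]; default lags 5-100 min in 5-min steps.
#' @param surr a [surrogate_config]; default 2500 shuffles, alpha 0.05.
#' @param fraction top fraction of significant connections retained (0.2).
#' @param rank_by `"U"` (default) or `"mi"`.
#' @param redundancy redundancy measure for the decompositions.
#' @param phases phases to analyse; defaults to those present in the panel.
#' @return An object of class `mvc_network`: list with `connections` (all
#'   significant pairs, with `U` and phase), `top` (after the top-fraction
#'   filter), `triads` (best synergy triad per retained pair), `n_pairs`,
#'   and the configuration. Has `print()`, `summary()` and `plot()` methods.
#' @examples
#' \donttest{
#' spec <- coupling_spec(4, duration = 1500, step = 5,
#'                       edges = data.frame(source = 1, target = 3, lag = 2,
#'                                          gain = 3, form = "linear"),
#'                       noise_sd = 0.05, seed = 11)
#' net <- infer_network(generate_clean_panel(spec),
#'                      surr = surrogate_config(n = 500, seed = 11))
#' net
#' }
#' @export
infer_network <- function(panel, grid = lag_grid(), surr = surrogate_config(),
                          fraction = 0.2, rank_by = c("U", "mi"),
                          redundancy = "rescaled", phases = NULL) {
  stopifnot(inherits(panel, "flux_panel"))
  rank_by <- match.arg(rank_by)
  phases <- phases %||% unique(panel$phase)
  all_conn <- list(); all_triads <- list(); n_pairs <- 0L
  for (ph in phases) {
    sub <- if (length(unique(panel$phase)) == 1L) panel else panel_phase(panel, ph)
    conn <- build_u_network(sub, grid, surr)
    n_pairs <- n_pairs + attr(conn, "n_pairs")
    if (nrow(conn) > 0L && ncol(sub$values) >= 3L) {
      tri <- lapply(seq_len(nrow(conn)), function(k)
        best_synergy_partner(conn[k, ], sub, grid, redundancy))
      U <- vapply(tri, function(t) if (is.null(t)) 0 else t$U1, numeric(1))
      S <- vapply(tri, function(t) if (is.null(t)) NA_real_ else t$S, numeric(1))
      partner <- vapply(tri, function(t) if (is.null(t)) NA_character_ else t$source2,
                        character(1))
      conn$U <- U; conn$S <- S; conn$partner <- partner
      tri <- do.call(rbind, tri[!vapply(tri, is.null, logical(1))])
      if (!is.null(tri) && nrow(tri) > 0L) {
        tri$phase <- ph
        all_triads[[ph]] <- tri
      }
    } else if (nrow(conn) > 0L) {
      conn$U <- conn$mi; conn$S <- NA_real_; conn$partner <- NA_character_
    }
    if (nrow(conn) > 0L) {
      conn$phase <- ph
      all_conn[[ph]] <- conn
    }
  }
  connections <- if (length(all_conn) > 0L) do.call(rbind, all_conn) else
    data.frame(source = character(0), target = character(0),
               best_lag = numeric(0), best_lag_steps = integer(0),
               mi = numeric(0), p = numeric(0), U = numeric(0), S = numeric(0),
               partner = character(0), phase = character(0))
  rownames(connections) <- NULL
  rank_col <- if (rank_by == "U") "U" else "mi"
  top <- do.call(rbind, lapply(split(connections, connections$phase),
                               select_top_fraction, fraction = fraction,
                               by = rank_col))
  top <- top %||% connections
  rownames(top) <- NULL
  triads <- if (length(all_triads) > 0L) do.call(rbind, all_triads) else NULL
  if (!is.null(triads)) rownames(triads) <- NULL
  structure(list(connections = connections, top = top, triads = triads,
                 n_pairs = n_pairs, grid = grid, surr = surr,
                 fraction = fraction, rank_by = rank_by,
                 redundancy = redundancy, phases = phases,
                 call = match.call()),
            class = "mvc_network")
}

#' @export
print.mvc_network <- function(x, ...) {
  cat("Inferred metabolic-connection network\n")
  cat("  ", x$n_pairs, " ordered pairs scanned (lags ", x$grid$min_lag, "-",
      x$grid$max_lag, " min); ", nrow(x$connections),
      " significant (alpha ", x$surr$alpha,
      if (x$surr$p_adjust == "BH") ", BH" else "", ", ", x$surr$n,
      " surrogates)\n", sep = "")
  cat("  top ", x$fraction * 100, "% by ", x$rank_by, ": ", nrow(x$top),
      " connection(s); ",
      if (is.null(x$triads)) 0L else nrow(x$triads), " synergy triad(s)\n",
      sep = "")
  if (nrow(x$top) > 0L) print(utils::head(x$top, 10))
  invisible(x)
}

#' @export
summary.mvc_network <- function(object, ...) {
  s <- list(n_pairs = object$n_pairs,
            n_significant = nrow(object$connections),
            n_top = nrow(object$top),
            n_triads = if (is.null(object$triads)) 0L else nrow(object$triads),
            by_phase = table(object$connections$phase),
            U_range = if (nrow(object$connections)) range(object$connections$U) else NULL)
  class(s) <- "summary.mvc_network"
  s
}

#' @export
print.summary.mvc_network <- function(x, ...) {
  cat("mvc_network summary: ", x$n_significant, "/", x$n_pairs,
      " pairs significant; ", x$n_top, " retained; ", x$n_triads, " triads\n",
      sep = "")
  if (length(x$by_phase)) print(x$by_phase)
  if (!is.null(x$U_range))
    cat(sprintf("  U range: %.4f - %.4f bits\n", x$U_range[1], x$U_range[2]))
  invisible(x)
}

#' Convert inferred connections to an igraph object
#'
#' @param x an `mvc_network`.
#' @param which `"top"` (default) or `"all"` significant connections.
#' @return A directed [igraph::igraph] with edge attributes `U`, `mi`, `p`,
#'   `lag_min`, `phase`.
#' @export
connection_graph <- function(x, which = c("top", "all")) {
  which <- match.arg(which)
  d <- if (which == "top") x$top else x$connections
  if (nrow(d) == 0L) return(igraph::make_empty_graph(directed = TRUE))
  g <- igraph::graph_from_data_frame(d[c("source", "target")], directed = TRUE)
  igraph::E(g)$U <- d$U; igraph::E(g)$mi <- d$mi; igraph::E(g)$p <- d$p
  igraph::E(g)$lag_min <- d$best_lag; igraph::E(g)$phase <- d$phase
  g
}

#' @export
plot.mvc_network <- function(x, which = "top", ...) {
  g <- connection_graph(x, which)
  if (igraph::ecount(g) == 0L) {
    plot.new(); title("no connections"); return(invisible(x))
  }
  w <- igraph::E(g)$U
  plot(g, edge.width = 0.5 + 3 * w / max(w, 1e-12),
       edge.label = paste0(igraph::E(g)$lag_min, "'"),
       vertex.color = "lightsteelblue", ...)
  invisible(x)
}

#' Write connection and triad tables
#'
#' Tab-separated tables with the master seed and configuration recorded in
#' `#` header comments, so a written network is traceable to its run.
#'
#' @param x an `mvc_network`.
#' @param connections_path,triads_path output paths (`NULL` skips).
#' @return Invisibly, the paths written.
#' @export
write_network_tables <- function(x, connections_path, triads_path = NULL) {
  hdr <- paste0("# volnet seed=", x$surr$seed, " n_surrogates=", x$surr$n,
                " alpha=", x$surr$alpha, " p_adjust=", x$surr$p_adjust,
                " fraction=", x$fraction, " rank_by=", x$rank_by,
                " lags=", x$grid$min_lag, "-", x$grid$max_lag)
  wr <- function(d, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  out <- wr(x$top, connections_path)
  if (!is.null(triads_path) && !is.null(x$triads))
    out <- c(out, wr(x$triads, triads_path))
  invisible(out)
}
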