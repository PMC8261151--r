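#' Discretize a series into equal-occupancy symbols
#'
#' Rank-normalizes the series (average ranks, so tied values share a symbol)
#' and bins the ranks into `bins` equal-occupancy bins; by default
#' `bins = max(2, floor(n^(1/3)))`. Rank-based binning makes every downstream
#' information estimate invariant under monotone transforms of the data.
#'
#' @param x numeric vector, missing values already removed.
#' @param bins number of bins; `NULL` for the cube-root rule.
#' @return Integer symbol sequence in `1..bins` with attribute `"bins"`.
#' @examples
#' table(discretize(rnorm(1000)))  # 10 bins of ~100 points
#' @export
discretize <- function(x, bins = NULL) {
  n <- length(x)
  if (n < 1L) stop("empty series")
  if (anyNA(x)) stop("missing values must be removed before discretization")
  B <- as.integer(bins %||% max(2L, floor(n^(1 / 3) + 1e-9)))
  if (max(x) - min(x) < .Machine$double.eps) {
    warning("constant series: single-symbol sequence (entropy 0)")
    return(structure(rep(1L, n), bins = B))
  }
  r <- rank(x, ties.method = "average")
  structure(pmin(B, pmax(1L, as.integer(ceiling(r * B / n)))), bins = B)
}

nbins <- function(x) as.integer(attr(x, "bins") %||% max(x))

entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# joint cell index for up to three symbol vectors
joint_tab <- function(x, y, bx, by) tabulate((x - 1L) * by + y, bx * by)

#' Plug-in mutual information of two discretized sequences (bits)
#'
#' `I = sum p(x,y) log2 p(x,y) / (p(x) p(y))` over the empirical joint
#' distribution; non-negative and symmetric. An optional Miller-Madow bias
#' correction is available (off by default: the surrogate test absorbs
#' estimator bias under the null).
#'
#' @param x,y equal-length integer symbol sequences (from [discretize()]).
#' @param correct apply the Miller-Madow small-sample correction.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, correct = FALSE) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ", length(y))
  n <- length(x)
  if (n < 30L) stop("need n >= 30 observations for the plug-in estimate")
  bx <- nbins(x); by <- nbins(y)
  jj <- joint_tab(x, y, bx, by)
  mi <- entropy_bits(tabulate(x, bx)) + entropy_bits(tabulate(y, by)) -
    entropy_bits(jj)
  if (correct) {
    kx <- sum(tabulate(x, bx) > 0); ky <- sum(tabulate(y, by) > 0)
    kxy <- sum(jj > 0)
    mi <- mi + ((kx - 1) + (ky - 1) - (kxy - 1)) / (2 * n * log(2))
  }
  max(mi, 0)
}

# Fast internal path: precomputed symbols; only the joint entropy changes
# under source permutation, the marginals are permutation-invariant.
mi_symbols <- function(sx, sy, bx, by, hx, hy) {
  hx + hy - entropy_bits(joint_tab(sx, sy, bx, by))
}

#' Surrogate configuration for significance testing
#'
#' @param n number of shuffled surrogates (default 2500).
#' @param alpha per-connection significance level (default 0.05).
#' @param seed master seed; each source-target pair draws its surrogates from
#'   a deterministic substream so results are order-independent.
#' @param p_adjust `"none"` (per-connection testing, the default) or `"BH"`
#'   for Benjamini-Hochberg false-discovery-rate control across pairs.
#' @return A list of class `surrogate_config`.
#' @export
surrogate_config <- function(n = 2500, alpha = 0.05, seed = 1L,
                             p_adjust = c("none", "BH")) {
  if (n < 100) stop("need at least 100 surrogates")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(n = as.integer(n), alpha = alpha, seed = as.integer(seed),
                 p_adjust = match.arg(p_adjust)),
            class = "surrogate_config")
}

#' Shuffled-surrogate significance test
#'
#' Randomly permutes the source series `surr$n` times, recomputing the
#' statistic each time with the target untouched; the permutation destroys
#' temporal structure while preserving the source's marginal distribution.
#' The empirical p-value is `(1 + #\{surrogate >= observed\}) / (n + 1)`.
#'
#' @param x source series; @param y target series.
#' @param statistic function of `(x, y)` returning a scalar; `NULL` (default)
#'   uses plug-in mutual information on discretized series via a fast path.
#' @param surr a [surrogate_config].
#' @param y dependent series, untouched by the shuffling.
#' @return List with `observed`, `p`, and `n_surrogates`.
#' @export
surrogate_test <- function(x, y, statistic = NULL, surr = surrogate_config()) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  local_seed(surr$seed, {
    if (is.null(statistic)) {
      sx <- discretize(x); sy <- discretize(y)
      bx <- nbins(sx); by <- nbins(sy)
      hx <- entropy_bits(tabulate(sx, bx)); hy <- entropy_bits(tabulate(sy, by))
      obs <- mi_symbols(sx, sy, bx, by, hx, hy)
      ge <- 0L
      for (i in seq_len(surr$n))
        if (mi_symbols(sx[sample.int(n)], sy, bx, by, hx, hy) >= obs) ge <- ge + 1L
    } else {
      obs <- statistic(x, y)
      ge <- 0L
      for (i in seq_len(surr$n))
        if (statistic(x[sample.int(n)], y) >= obs) ge <- ge + 1L
    }
    list(observed = obs, p = (1 + ge) / (surr$n + 1), n_surrogates = surr$n)
  })
}

#' Lag grid for lagged mutual information
#'
#' @param min_lag,max_lag,step lag range and increment in minutes; defaults
#'   5 to 100 min in 5-min steps, matching a 5-min panel grid.
#' @return A list of class `lag_grid` with the lag list in minutes.
#' @export
lag_grid <- function(min_lag = 5, max_lag = 100, step = 5) {
  if (min_lag <= 0 || max_lag < min_lag || step <= 0) stop("invalid lag grid")
  structure(list(min_lag = min_lag, max_lag = max_lag, step = step,
                 lags = seq(min_lag, max_lag, by = step)),
            class = "lag_grid")
}

grid_steps <- function(grid, panel) {
  st <- grid$lags / panel$step
  if (any(abs(st - round(st)) > 1e-8))
    stop("lag grid (", grid$step, " min step) is not a multiple of the panel step (",
         panel$step, " min)")
  as.integer(round(st))
}

#' Lagged mutual information between two panel channels
#'
#' For each lag in the grid computes the mutual information between the
#' source shifted back by the lag, `X(t - dt)`, and the unshifted target
#' `Y(t)`. The best lag is the MI argmax (ties broken toward the smallest
#' lag, the shortest causal delay). Significance comes from shuffled
#' surrogates recomputing the same max-over-grid statistic, so the lag
#' selection is accounted for in the null.
#'
#' @param panel a [flux_panel].
#' @param source,target channel identifiers (column name, m/z value, or
#'   index).
#' @param grid a [lag_grid].
#' @param surr a [surrogate_config]; `NULL` skips the significance test.
#' @return A list of class `lagged_mi` with per-lag MI, `best_lag` (minutes),
#'   `best_lag_steps`, `mi` at the best lag, and `p`.
#' @export
lagged_mi <- function(panel, source, target, grid = lag_grid(),
                      surr = surrogate_config()) {
  si <- channel_index(panel, source); ti <- channel_index(panel, target)
  x <- panel$values[, si]; y <- panel$values[, ti]
  steps <- grid_steps(grid, panel)
  scan <- lmi_scan(x, y, steps)
  best <- which.max(scan$mi)          # which.max takes the first (smallest lag) tie
  p <- NA_real_
  if (!is.null(surr)) {
    ps <- pair_seed(surr$seed, si, ti)
    p <- local_seed(ps, lmi_max_pvalue(scan, steps, surr$n, scan$max_mi))
  }
  structure(list(source = colnames(panel$values)[si],
                 target = colnames(panel$values)[ti],
                 lags = grid$lags, mi = scan$mi,
                 best_lag = grid$lags[best], best_lag_steps = steps[best],
                 best_mi = scan$mi[best], p = p),
            class = "lagged_mi")
}

# MI profile over lag steps. Channels are discretized once on the full
# series and the symbol streams subset for lag alignment; this keeps the
# observed statistic and its source-permutation surrogates exactly
# exchangeable (a permuted series has exactly the permuted symbols).
lmi_scan <- function(x, y, steps) {
  n <- length(x)
  sx <- discretize(x); sy <- discretize(y)
  bx <- nbins(sx); by <- nbins(sy)
  mi <- vapply(steps, function(s) {
    if (n - s < 30L)
      stop("insufficient overlap at lag ", s, " steps (n = ", n - s, ")")
    a <- sx[seq_len(n - s)]; b <- sy[(s + 1L):n]
    mi_symbols(a, b, bx, by, entropy_bits(tabulate(a, bx)),
               entropy_bits(tabulate(b, by)))
  }, numeric(1))
  list(mi = mi, max_mi = max(mi), sx = sx, sy = sy, bx = bx, by = by)
}

# Surrogate p-value for the max-over-grid LMI statistic: each surrogate is
# one full-series source permutation, with the same max over the lag grid
# recomputed, so the lag selection is part of the null.
lmi_max_pvalue <- function(scan, steps, n_surr, observed) {
  sx <- scan$sx; sy <- scan$sy; bx <- scan$bx; by <- scan$by
  n <- length(sx)
  pre <- lapply(steps, function(s) {
    b <- sy[(s + 1L):n]
    list(m = n - s, sy = b, hy = entropy_bits(tabulate(b, by)))
  })
  ge <- 0L
  for (k in seq_len(n_surr)) {
    xp <- sx[sample.int(n)]
    mx <- 0
    for (pp in pre) {
      a <- xp[seq_len(pp$m)]
      v <- mi_symbols(a, pp$sy, bx, by, entropy_bits(tabulate(a, bx)), pp$hy)
      if (v > mx) mx <- v
    }
    if (mx >= observed) ge <- ge + 1L
  }
  (1 + ge) / (n_surr + 1)
}

channel_index <- function(panel, ch) {
  if (is.numeric(ch) && length(ch) == 1L && ch == as.integer(ch) &&
      ch >= 1 && ch <= ncol(panel$values) && !any(abs(panel$mz - ch) < 0.5))
    return(as.integer(ch))
  if (is.character(ch)) {
    i <- match(ch, colnames(panel$values))
    if (is.na(i)) stop("channel not in panel: ", ch)
    return(i)
  }
  i <- which(abs(panel$mz - ch) <= 0.005)
  if (length(i) != 1L) stop("channel not in panel (m/z ", ch, ")")
  i
}

#' Two-source partial information decomposition of a lag-aligned triad
#'
#' Decomposes the joint information `I(X1, X2; Y)` that two lagged source
#' channels carry about a target into unique (`U1`, `U2`), redundant (`R`)
#' and synergistic (`S`) components. Redundancy uses rescaled bounds:
#' `R = R_min + s (R_MMI - R_min)` with `R_min = max(0, I1 + I2 - I12)`,
#' `R_MMI = min(I1, I2)`, and source dependency
#' `s = I(X1; X2) / min(H(X1), H(X2))`; any `R` in `[R_min, R_MMI]` keeps all
#' four components non-negative, and `U1 + U2 + R + S = I12` holds by
#' construction.
#'
#' @param panel a [flux_panel].
#' @param source1,source2,target channel identifiers.
#' @param lag1,lag2 source lags in panel steps (each source keeps its own
#'   best pairwise lag; there is no joint lag search).
#' @param redundancy `"rescaled"` (default), `"minimum"` (`R = R_min`) or
#'   `"mmi"` (`R = R_MMI`) for sensitivity analysis.
#' @return A list of class `pid_result` with `I1`, `I2`, `I12`, `U1`, `U2`,
#'   `R`, `S` (bits) and the inputs.
#' @export
pid_decompose <- function(panel, source1, source2, target, lag1, lag2,
                          redundancy = c("rescaled", "minimum", "mmi")) {
  i1 <- channel_index(panel, source1); i2 <- channel_index(panel, source2)
  it <- channel_index(panel, target)
  x1 <- panel$values[, i1]; x2 <- panel$values[, i2]; y <- panel$values[, it]
  n <- length(y); L <- max(lag1, lag2)
  if (n - L < 30L) stop("insufficient overlap for lags ", lag1, ", ", lag2)
  idx <- (L + 1L):n
  res <- pid_triple(x1[idx - lag1], x2[idx - lag2], y[idx],
                    redundancy = match.arg(redundancy))
  res$source1 <- colnames(panel$values)[i1]
  res$source2 <- colnames(panel$values)[i2]
  res$target <- colnames(panel$values)[it]
  res$lag1 <- lag1; res$lag2 <- lag2
  res
}

#' @rdname pid_decompose
#' @param x1,x2,y aligned numeric vectors (already lag-shifted).
#' @export
pid_triple <- function(x1, x2, y, redundancy = c("rescaled", "minimum", "mmi")) {
  redundancy <- match.arg(redundancy)
  # constant inputs are reported below as zero-entropy sources, so the
  # per-series constant warning is redundant here
  s1 <- suppressWarnings(discretize(x1))
  s2 <- suppressWarnings(discretize(x2))
  sy <- suppressWarnings(discretize(y))
  b1 <- nbins(s1); b2 <- nbins(s2); by <- nbins(sy)
  h1 <- entropy_bits(tabulate(s1, b1)); h2 <- entropy_bits(tabulate(s2, b2))
  hy <- entropy_bits(tabulate(sy, by))
  I1 <- h1 + hy - entropy_bits(joint_tab(s1, sy, b1, by))
  I2 <- h2 + hy - entropy_bits(joint_tab(s2, sy, b2, by))
  I1 <- max(I1, 0); I2 <- max(I2, 0)
  s12 <- (s1 - 1L) * b2 + s2         # joint source symbol
  h12 <- entropy_bits(tabulate(s12, b1 * b2))
  I12 <- max(h12 + hy - entropy_bits(joint_tab(s12, sy, b1 * b2, by)), 0)
  I12 <- max(I12, I1, I2)            # chain-rule bound, guards float error
  Isrc <- max(h1 + h2 - h12, 0)      # I(X1; X2)
  if (h1 < 1e-12 || h2 < 1e-12) {
    warning("zero-entropy source: its unique information is 0")
    sdep <- 0
  } else sdep <- min(Isrc / min(h1, h2), 1)
  Rmin <- max(0, I1 + I2 - I12)
  Rmmi <- max(min(I1, I2), Rmin)
  R <- switch(redundancy, rescaled = Rmin + sdep * (Rmmi - Rmin),
              minimum = Rmin, mmi = Rmmi)
  U1 <- max(I1 - R, 0); U2 <- max(I2 - R, 0)
  S <- max(I12 - U1 - U2 - R, 0)
  structure(list(I1 = I1, I2 = I2, I12 = I12, Isources = Isrc,
                 U1 = U1, U2 = U2, R = R, S = S,
                 source_dependency = sdep, redundancy = redundancy),
            class = "pid_result")
}

#' @export
print.pid_result <- function(x, ...) {
  cat("PID (", x$redundancy, " redundancy):",
      if (!is.null(x$source1)) paste0(" {", x$source1, " lag ", x$lag1, ", ",
                                      x$source2, " lag ", x$lag2, "} -> ",
                                      x$target) else "", "\n", sep = "")
  cat(sprintf("  I12 = %.4f bits | U1 = %.4f  U2 = %.4f  R = %.4f  S = %.4f\n",
              x$I12, x$U1, x$U2, x$R, x$S))
  invisible(x)
}

#' @export
print.lagged_mi <- function(x, ...) {
  cat("lagged MI ", x$source, " -> ", x$target, ": best lag ", x$best_lag,
      " min, MI ", sprintf("%.4f", x$best_mi), " bits",
      if (!is.na(x$p)) sprintf(", p = %.4g", x$p), "\n", sep = "")
  invisible(x)
}
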