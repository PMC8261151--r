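#' Preprocessing configuration
#'
#' Parameters of the raw-counts-to-panel chain. The chain order is fixed:
#' primary-ion normalization, gap filling, blank subtraction, replicate
#' averaging, spline smoothing, interval aggregation.
#'
#' @param reference_mz m/z of the primary-ion reference channel (default 21,
#'   the hydronium isotopologue).
#' @param norm_const normalization constant: normalized signal is
#'   `count / reference * norm_const` (default 500).
#' @param max_gap longest missing run that gap filling will interpolate, in
#'   minutes (default 50, the rotation-induced gap between 10-min measurement
#'   slots).
#' @param agg_step aggregation window in minutes (default 5).
#' @param spar smoothing-spline parameter; `NULL` (default) selects the
#'   strength per channel by generalized cross-validation.
#' @param clip_negative clip negative post-subtraction values to 0 (fluxes are
#'   non-negative); default `TRUE`.
#' @param wetup_time wet-up timepoint in minutes used to attach phase labels;
#'   required for phase-resolved inference, `NA` labels everything dry.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(reference_mz = 21, norm_const = 500,
                              max_gap = 50, agg_step = 5, spar = NULL,
                              clip_negative = TRUE, wetup_time = NA_real_) {
  if (norm_const <= 0 || max_gap <= 0 || agg_step <= 0)
    stop("norm_const, max_gap and agg_step must be > 0")
  structure(list(reference_mz = reference_mz, norm_const = norm_const,
                 max_gap = max_gap, agg_step = agg_step, spar = spar,
                 clip_negative = clip_negative, wetup_time = wetup_time),
            class = "preprocess_config")
}

#' Normalize ion counts by the primary-ion reference channel
#'
#' Every non-reference entry becomes `count / reference * norm_const` (ncps),
#' accounting for primary-ion abundance fluctuations; the reference channel is
#' dropped from the output. Timepoints where a channel is observed but the
#' reference is missing or zero are an error (the normalization is undefined
#' there).
#'
#' @param x an [ion_counts] matrix including the reference channel.
#' @param cfg a [preprocess_config].
#' @return An [ion_counts] matrix of normalized signal without the reference
#'   channel.
#' @examples
#' m <- ion_counts(c(0, 30), matrix(c(1234, 1000, 1234, 2000), 2, 2),
#'                 mz = c(21.022, 33.033))
#' normalize_primary_ion(m, preprocess_config())$counts  # 500 at t = 0
#' @export
normalize_primary_ion <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "ion_counts"))
  iref <- which(abs(x$mz - cfg$reference_mz) <= 0.5)
  if (length(iref) != 1L)
    stop("reference channel (m/z ", cfg$reference_mz, ") absent or ambiguous in ",
         x$chamber_id)
  ref <- x$counts[, iref]
  rest <- x$counts[, -iref, drop = FALSE]
  observed <- rowSums(!is.na(rest)) > 0L
  bad <- observed & (is.na(ref) | ref <= 0)
  if (any(bad))
    stop("reference channel missing or zero at observed timestamp ",
         x$time_s[which(bad)[1L]], " s in ", x$chamber_id)
  out <- rest / ref * cfg$norm_const
  ion_counts(x$time_s, out, x$mz[-iref], chamber_id = x$chamber_id)
}

#' Fill rotation-induced gaps by linear interpolation
#'
#' Interior missing runs no longer than `cfg$max_gap` minutes are replaced by
#' linear interpolation between the flanking observed values; longer runs and
#' leading/trailing missing blocks are left missing. Designed for the 50-min
#' gaps the 10-min-per-chamber measurement rotation leaves in each chamber's
#' series.
#'
#' @param x an [ion_counts] matrix on a regular timestamp grid.
#' @param cfg a [preprocess_config].
#' @return The matrix with fillable gaps interpolated; a message reports the
#'   filled / still-missing cell counts.
#' @export
fill_gaps <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "ion_counts"))
  dt <- diff(x$time_s)
  if (length(dt) > 0L && (max(dt) - min(dt)) > 1e-6 * max(dt))
    stop("timestamps not on a regular grid; cannot gap-fill")
  step_min <- if (length(dt) > 0L) dt[1L] / 60 else 1
  maxgap <- max(1L, floor(cfg$max_gap / step_min))
  n_before <- sum(is.na(x$counts))
  filled <- apply(x$counts, 2L, function(col)
    zoo::na.approx(col, x = x$time_s, na.rm = FALSE, maxgap = maxgap))
  filled <- matrix(filled, nrow = nrow(x$counts))
  n_after <- sum(is.na(filled))
  message("fill_gaps [", x$chamber_id, "]: filled ", n_before - n_after,
          " cells, ", n_after, " left missing")
  ion_counts(x$time_s, pmax(filled, 0), x$mz, chamber_id = x$chamber_id)
}

#' Subtract blank-chamber background from a sample matrix
#'
#' Entrywise `sample - blank` on a shared grid and channel set (gap-fill the
#' blank first so the subtraction is defined wherever the sample is observed);
#' negatives are clipped to 0 when `cfg$clip_negative` is on.
#'
#' @param sample,blank [ion_counts] matrices on the same grid with the same
#'   channels.
#' @param cfg a [preprocess_config].
#' @return The background-subtracted sample matrix.
#' @export
subtract_background <- function(sample, blank, cfg = preprocess_config()) {
  stopifnot(inherits(sample, "ion_counts"), inherits(blank, "ion_counts"))
  if (!isTRUE(all.equal(sample$time_s, blank$time_s)))
    stop("sample and blank are not on the same time grid")
  miss <- c(setdiff(colnames(sample$counts), colnames(blank$counts)),
            setdiff(colnames(blank$counts), colnames(sample$counts)))
  if (length(miss) > 0L)
    stop("channel mismatch between sample and blank: ", paste(miss, collapse = ", "))
  out <- sample$counts - blank$counts[, colnames(sample$counts), drop = FALSE]
  if (cfg$clip_negative) {
    nclip <- sum(out < 0, na.rm = TRUE)
    if (nclip > 0L) message("subtract_background: clipped ", nclip,
                            " negative cells to 0")
    out[out < 0] <- 0
  }
  ion_counts(sample$time_s, out, sample$mz, chamber_id = sample$chamber_id,
             allow_negative = !cfg$clip_negative)
}

#' Average replicate chambers pointwise
#'
#' Pointwise mean over replicates at each (time, channel) cell, ignoring
#' missing values: because the rotation observes each replicate in a
#' different slot, a cell is missing in the average only when it is missing
#' in every replicate.
#'
#' @param replicates list of [ion_counts] matrices on a common grid and
#'   channel set.
#' @return An [ion_counts] matrix of replicate means (`chamber_id`
#'   `"averaged"`).
#' @export
average_replicates <- function(replicates) {
  stopifnot(length(replicates) >= 1L)
  if (length(replicates) < 2L) {
    warning("fewer than 2 replicates; passthrough")
    return(replicates[[1L]])
  }
  ref <- replicates[[1L]]
  for (r in replicates[-1L]) {
    if (!isTRUE(all.equal(r$time_s, ref$time_s)) ||
        !identical(colnames(r$counts), colnames(ref$counts)))
      stop("replicates not on a common grid / channel set")
  }
  arr <- vapply(replicates, function(r) r$counts,
                matrix(0, nrow(ref$counts), ncol(ref$counts)))
  s <- apply(arr, c(1, 2), function(v) if (all(is.na(v))) NA_real_ else
    mean(v, na.rm = TRUE))
  ion_counts(ref$time_s, s, ref$mz, chamber_id = "averaged")
}

#' Smooth per channel and aggregate to a coarse regular grid
#'
#' Fits a smoothing spline per channel (strength by generalized
#' cross-validation unless `cfg$spar` fixes it) to reduce measurement noise,
#' then averages the smoothed series within consecutive `cfg$agg_step`-minute
#' windows. Channels with fewer than 10 observed points are dropped with a
#' warning. Phase labels are attached at `cfg$wetup_time`.
#'
#' @param x an averaged, gap-filled [ion_counts] matrix.
#' @param cfg a [preprocess_config].
#' @return A [flux_panel] on the aggregated grid.
#' @export
smooth_and_aggregate <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "ion_counts"))
  t_min <- x$time_s / 60
  keep <- colSums(!is.na(x$counts)) >= 10L
  if (!all(keep))
    warning("dropping channel(s) with <10 observed points: ",
            paste(colnames(x$counts)[!keep], collapse = ", "))
  if (!any(keep)) stop("no channel has enough observations to smooth")
  counts <- x$counts[, keep, drop = FALSE]
  sm <- apply(counts, 2L, function(col) {
    ok <- !is.na(col)
    if (stats::var(col[ok]) < .Machine$double.eps) {
      out <- col
      out[!ok] <- NA_real_
      return(out)                      # constant channel: spline is identity
    }
    fit <- if (is.null(cfg$spar)) stats::smooth.spline(t_min[ok], col[ok]) else
      stats::smooth.spline(t_min[ok], col[ok], spar = cfg$spar)
    out <- rep(NA_real_, length(col))
    out[ok] <- stats::predict(fit, t_min[ok])$y
    out
  })
  sm <- matrix(sm, nrow = nrow(counts))
  win <- floor((t_min - t_min[1L]) / cfg$agg_step)
  agg <- apply(sm, 2L, function(col)
    tapply(col, win, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)))
  agg <- matrix(agg, nrow = length(unique(win)))
  flux_panel(t_min[1L] + unique(win) * cfg$agg_step, agg, x$mz[keep],
             wetup_time = cfg$wetup_time)
}

#' Run the full preprocessing chain
#'
#' Fixed order: normalize each chamber by the primary ion, gap-fill each
#' chamber (blank included), subtract the blank from each soil replicate,
#' average the replicates, smooth and aggregate to the panel grid.
#'
#' @param replicates list of raw [ion_counts] (soil chambers, reference
#'   channel included).
#' @param blank raw [ion_counts] of the blank chamber.
#' @param cfg a [preprocess_config].
#' @return A [flux_panel].
#' @examples
#' spec <- coupling_spec(3, duration = 360, step = 1, noise_sd = 0,
#'                       pulse_onset = 120, pulse_channels = 1:3, seed = 2)
#' raw <- generate_raw_counts(generate_clean_panel(spec), spec,
#'                            rep_noise_sd = 0)
#' panel <- preprocess(raw$replicates, raw$blank,
#'                     preprocess_config(wetup_time = 120))
#' @export
preprocess <- function(replicates, blank, cfg = preprocess_config()) {
  norm <- lapply(replicates, normalize_primary_ion, cfg = cfg)
  blank_n <- fill_gaps(normalize_primary_ion(blank, cfg), cfg)
  filled <- lapply(norm, fill_gaps, cfg = cfg)
  subd <- lapply(filled, subtract_background, blank = blank_n, cfg = cfg)
  avg <- average_replicates(subd)
  smooth_and_aggregate(avg, cfg)
}

#' Principal-component overview of a processed panel
#'
#' Centered (optionally unit-scaled) PCA of the timepoint-by-channel matrix,
#' the standard synchronous overview of which channels co-vary across the
#' wet-up: per-timepoint scores carry the dry/wet phase label, loadings are
#' per channel.
#'
#' @param panel a [flux_panel] with at least 2 channels and no missing cells.
#' @param scale. scale channels to unit variance (default `TRUE`).
#' @return A list with `scores` (data frame incl. `phase`), `loadings`, and
#'   `variance_fraction` (sums to 1).
#' @export
ordination_overview <- function(panel, scale. = TRUE) {
  stopifnot(inherits(panel, "flux_panel"))
  if (ncol(panel$values) < 2L) stop("PCA needs >= 2 channels")
  v <- apply(panel$values, 2L, stats::var)
  if (all(v < .Machine$double.eps)) stop("constant panel: no variance to decompose")
  keep <- if (scale.) v > .Machine$double.eps else rep(TRUE, length(v))
  pc <- stats::prcomp(panel$values[, keep, drop = FALSE], center = TRUE,
                      scale. = scale.)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = data.frame(time = panel$time, phase = panel$phase, pc$x,
                           check.names = FALSE),
       loadings = pc$rotation, variance_fraction = vf)
}
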