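#' Flux panel: regular-grid multichannel volatile-flux time series
#'
#' The central exchange format between all pipeline stages: a matrix of
#' normalized signal (ncps, normalized counts per second) on a regular time
#' grid in minutes, one column per m/z channel, with an optional dry/wet phase
#' label attached at a single wet-up timepoint.
#'
#' @param time numeric vector of timepoints in minutes, regular grid.
#' @param values numeric matrix, `length(time)` rows, one column per channel.
#' @param mz numeric vector of m/z values labelling the channels.
#' @param compound optional character vector of compound annotations.
#' @param wetup_time optional wet-up timepoint (minutes); timepoints at or
#'   after it are labelled `"wet"`, earlier ones `"dry"`. `NA` labels the
#'   whole panel `"dry"`.
#' @return An object of class `flux_panel`: a list with elements `time`,
#'   `step`, `values`, `mz`, `compound`, `phase`, `wetup_time`.
#' @examples
#' p <- flux_panel(seq(0, 55, by = 5), matrix(rnorm(24), 12, 2),
#'                 mz = c(33.033, 45.033), wetup_time = 30)
#' table(p$phase)
#' @export
flux_panel <- function(time, values, mz, compound = NULL, wetup_time = NA_real_) {
  values <- as.matrix(values)
  if (length(time) != nrow(values))
    stop("time length (", length(time), ") != rows of values (", nrow(values), ")")
  if (ncol(values) == 0L) stop("panel has no channels")
  if (length(mz) != ncol(values))
    stop("mz length does not match number of channels")
  if (anyDuplicated(mz)) stop("duplicate m/z channel labels: ",
                              paste(unique(mz[duplicated(mz)]), collapse = ", "))
  steps <- diff(time)
  if (length(steps) > 0L) {
    if (any(steps <= 0)) stop("time grid not strictly increasing")
    if (max(steps) - min(steps) > 1e-8 * max(steps, 1))
      stop("time grid is irregular (step varies)")
    step <- steps[1L]
  } else step <- NA_real_
  phase <- if (is.na(wetup_time)) rep("dry", length(time)) else
    ifelse(time >= wetup_time, "wet", "dry")
  colnames(values) <- format_mz(mz)
  structure(list(time = as.numeric(time), step = step, values = values,
                 mz = as.numeric(mz),
                 compound = if (is.null(compound)) rep(NA_character_, length(mz)) else compound,
                 phase = phase, wetup_time = wetup_time),
            class = "flux_panel")
}

#' @export
print.flux_panel <- function(x, ...) {
  cat("flux_panel: ", length(x$time), " timepoints x ", ncol(x$values),
      " channels, step ", x$step, " min\n", sep = "")
  cat("  time range [", min(x$time), ", ", max(x$time), "] min; phases: ",
      paste(sprintf("%s=%d", names(table(x$phase)), table(x$phase)), collapse = ", "),
      "\n", sep = "")
  cat("  channels: ", paste(utils::head(colnames(x$values), 8), collapse = " "),
      if (ncol(x$values) > 8) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.flux_panel <- function(x) dim(x$values)

#' Subset a flux panel by phase
#'
#' @param panel a [flux_panel].
#' @param phase `"dry"`, `"wet"`, or `"all"`.
#' @return A `flux_panel` restricted to the requested timepoints.
#' @export
panel_phase <- function(panel, phase = c("all", "dry", "wet")) {
  phase <- match.arg(phase)
  if (phase == "all") return(panel)
  keep <- panel$phase == phase
  if (!any(keep)) stop("no timepoints in phase '", phase, "'")
  flux_panel(panel$time[keep], panel$values[keep, , drop = FALSE], panel$mz,
             panel$compound,
             wetup_time = if (phase == "wet") panel$wetup_time else NA_real_)
}

format_mz <- function(mz) sprintf("%.3f", mz)

#' Ion-count matrix from one measurement chamber
#'
#' Raw (or normalized) ion counts: rows are timestamps in seconds since run
#' start, columns are m/z channels. Missing entries (timepoints outside the
#' chamber's slot in the measurement rotation) are `NA`, never zero.
#'
#' @param time_s numeric vector of timestamps (seconds), strictly increasing.
#' @param counts numeric matrix of non-negative counts, `NA` where missing.
#' @param mz numeric m/z channel labels (3-decimal precision by convention).
#' @param chamber_id character label for the chamber/jar.
#' @param allow_negative permit negative values (used for background-subtracted
#'   data when clipping is disabled); raw counts must be non-negative.
#' @return An object of class `ion_counts`.
#' @export
ion_counts <- function(time_s, counts, mz, chamber_id = "chamber",
                       allow_negative = FALSE) {
  counts <- as.matrix(counts)
  if (length(time_s) != nrow(counts)) stop("timestamp/row mismatch")
  if (any(diff(time_s) <= 0)) stop("timestamps not strictly increasing")
  if (length(mz) != ncol(counts)) stop("mz/column mismatch")
  if (anyDuplicated(format_mz(mz)))
    stop("duplicate m/z channel: ",
         paste(unique(format_mz(mz)[duplicated(format_mz(mz))]), collapse = ", "))
  if (!allow_negative) {
    neg <- which(counts < 0, arr.ind = TRUE)
    if (nrow(neg) > 0L)
      stop("negative count at row ", neg[1L, 1L], ", channel ",
           format_mz(mz)[neg[1L, 2L]])
  }
  colnames(counts) <- format_mz(mz)
  structure(list(time_s = as.numeric(time_s), counts = counts,
                 mz = as.numeric(mz), chamber_id = chamber_id),
            class = "ion_counts")
}

#' @export
print.ion_counts <- function(x, ...) {
  cat("ion_counts [", x$chamber_id, "]: ", length(x$time_s), " timepoints x ",
      ncol(x$counts), " channels; ", sum(is.na(x$counts)), " missing cells\n",
      sep = "")
  invisible(x)
}
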