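#' Specification of a synthetic coupled flux panel
#'
#' Describes a ground-truth generative model for benchmark panels: per-channel
#' baselines, a wet-up pulse on selected channels, directed lagged couplings
#' between channels (linear, quadratic or threshold), and additive Gaussian
#' channel noise scaled to the baseline. The generator emulates the dynamics a
#' soil wet-up experiment produces, without claiming to be a soil model.
#'
#' @param n_channels number of channels.
#' @param duration run length in minutes.
#' @param step grid step in minutes.
#' @param edges data frame with columns `source`, `target` (1-based channel
#'   indices), `lag` (in grid steps, >= 1), `gain`, `form` (one of `"linear"`,
#'   `"quadratic"`, `"threshold"`). `NULL` for no couplings.
#' @param baseline per-channel baseline level (ncps); recycled.
#' @param pulse_onset wet-up time in minutes, in `[0, duration)`; `NA` disables
#'   the pulse.
#' @param pulse_channels integer indices of channels receiving the pulse.
#' @param pulse_shape list with `rise`, `decay` (minutes) and `amplitude`
#'   (ncps): a difference-of-exponentials pulse, fast rise and slow decay.
#' @param noise_sd channel noise standard deviation as a fraction of baseline.
#' @param drift per-channel linear drift in ncps per minute (default 0).
#' @param seed integer seed; all generator randomness flows from it.
#' @return An object of class `coupling_spec`.
#' @examples
#' spec <- coupling_spec(4, duration = 720, step = 5,
#'                       edges = data.frame(source = 1, target = 3, lag = 2,
#'                                          gain = 2, form = "linear"),
#'                       seed = 7)
#' panel <- generate_clean_panel(spec)
#' @export
coupling_spec <- function(n_channels, duration, step = 1,
                          edges = NULL,
                          baseline = 100,
                          pulse_onset = NA_real_,
                          pulse_channels = integer(0),
                          pulse_shape = list(rise = 60, decay = 600, amplitude = 50),
                          noise_sd = 0.05,
                          drift = 0,
                          seed = 1L) {
  if (n_channels < 1) stop("invalid spec: n_channels must be >= 1")
  if (duration <= 0 || step <= 0) stop("invalid spec: duration and step must be > 0")
  if (noise_sd < 0) stop("invalid spec: noise_sd must be >= 0")
  if (is.null(edges)) edges <- data.frame(source = integer(0), target = integer(0),
                                          lag = integer(0), gain = numeric(0),
                                          form = character(0))
  edges <- as.data.frame(edges)
  need <- c("source", "target", "lag", "gain", "form")
  if (!all(need %in% names(edges)))
    stop("invalid spec: edges must have columns ", paste(need, collapse = ", "))
  if (nrow(edges) > 0L) {
    if (any(edges$lag < 1)) stop("invalid spec: edges$lag must be >= 1 step")
    if (any(edges$source == edges$target)) stop("invalid spec: self-edge in edges")
    if (any(edges$source < 1 | edges$source > n_channels |
            edges$target < 1 | edges$target > n_channels))
      stop("invalid spec: edges reference channels outside 1..n_channels")
    if (!all(edges$form %in% c("linear", "quadratic", "threshold")))
      stop("invalid spec: edges$form must be linear, quadratic or threshold")
  }
  if (!is.na(pulse_onset) && (pulse_onset < 0 || pulse_onset >= duration))
    stop("invalid spec: pulse_onset must lie in [0, duration)")
  if (length(pulse_channels) > 0L &&
      any(pulse_channels < 1 | pulse_channels > n_channels))
    stop("invalid spec: pulse_channels outside 1..n_channels")
  structure(list(n_channels = as.integer(n_channels), duration = duration,
                 step = step, edges = edges,
                 baseline = rep_len(baseline, n_channels),
                 pulse_onset = pulse_onset,
                 pulse_channels = as.integer(pulse_channels),
                 pulse_shape = pulse_shape, noise_sd = noise_sd,
                 drift = rep_len(drift, n_channels), seed = as.integer(seed)),
            class = "coupling_spec")
}

# Difference-of-exponentials pulse, unit peak, amplitude-scaled.
pulse_profile <- function(t, onset, shape) {
  out <- numeric(length(t))
  s <- t - onset
  on <- s >= 0
  if (!any(on)) return(out)
  raw <- exp(-s[on] / shape$decay) - exp(-s[on] / shape$rise)
  # normalize by analytic peak so amplitude is the realized maximum
  speak <- log(shape$decay / shape$rise) / (1 / shape$rise - 1 / shape$decay)
  peak <- exp(-speak / shape$decay) - exp(-speak / shape$rise)
  out[on] <- shape$amplitude * raw / peak
  out
}

coupling_term <- function(dev, gain, form, scale) {
  switch(form,
         linear    = gain * dev,
         quadratic = gain * dev^2 / scale,
         threshold = gain * scale * (dev > scale),
         stop("unknown coupling form: ", form))
}

#' Generate a clean (pre-instrument) flux panel with known causal structure
#'
#' Each channel is baseline + optional drift + optional wet-up pulse +
#' Gaussian noise; each target channel additionally receives, per incoming
#' edge, a function of the source channel's deviation from its baseline at the
#' edge's lag. Generation proceeds stepwise in time, so coupling chains and
#' feedback loops (lags >= 1 step) are well defined. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [coupling_spec].
#' @return A [flux_panel] at `spec$step` resolution; the wet-up phase label is
#'   attached at `spec$pulse_onset` when a pulse is present.
#' @export
generate_clean_panel <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  tt <- seq(0, spec$duration - spec$step, by = spec$step)
  n <- length(tt); p <- spec$n_channels
  x <- local_seed(spec$seed, {
    noise <- matrix(stats::rnorm(n * p), n, p) %*%
      diag(spec$noise_sd * spec$baseline, p)
    x <- matrix(rep(spec$baseline, each = n), n, p) +
      outer(tt, spec$drift) + noise
    if (!is.na(spec$pulse_onset) && length(spec$pulse_channels) > 0L) {
      pl <- pulse_profile(tt, spec$pulse_onset, spec$pulse_shape)
      for (j in spec$pulse_channels) x[, j] <- x[, j] + pl
    }
    e <- spec$edges
    if (nrow(e) > 0L) {
      # reference scale of each source channel's fluctuations (for the
      # nonlinear forms); falls back to 1 for noise-free channels
      sc <- pmax(spec$noise_sd * spec$baseline, .Machine$double.eps)
      sc[spec$noise_sd == 0] <- 1
      for (t in seq_len(n)) {
        for (k in seq_len(nrow(e))) {
          if (t > e$lag[k]) {
            dev <- x[t - e$lag[k], e$source[k]] - spec$baseline[e$source[k]]
            x[t, e$target[k]] <- x[t, e$target[k]] +
              coupling_term(dev, e$gain[k], e$form[k], sc[e$source[k]])
          }
        }
      }
    }
    x
  })
  mz <- round(30 + seq_len(p) * 2 + 0.033, 3)
  flux_panel(tt, x, mz = mz,
             wetup_time = if (is.na(spec$pulse_onset)) NA_real_ else spec$pulse_onset)
}

#' Simulate raw multiplexed ion counts from a clean panel
#'
#' Emulates the instrument side of a flow-through microcosm experiment: five
#' soil replicates plus one blank chamber measured in a rotation of 10-min
#' slots within a 60-min cycle, counts proportional to a primary-ion reference
#' channel (nominal m/z 21), a shared blank background added to every chamber,
#' and multiplicative log-normal measurement noise per replicate.
#'
#' Counts are `(panel + background) * reference / norm_const`, so primary-ion
#' normalization (division by the measured reference times `norm_const`)
#' recovers `panel + background` exactly, whatever the reference fluctuation.
#'
#' @param panel a [flux_panel] (the clean signal, ncps).
#' @param spec the [coupling_spec] that generated it (supplies the seed).
#' @param background per-channel background level added to all chambers
#'   (ncps); recycled. The blank chamber contains only this background.
#' @param ref_counts nominal primary-ion count rate (counts/s) at m/z 21.
#' @param rep_noise_sd standard deviation of the log-normal multiplicative
#'   measurement noise (0 = noise-free).
#' @param slot_min slot length of the measurement rotation in minutes.
#' @param n_replicates number of soil chambers (the blank takes the next slot).
#' @param mask if `FALSE`, the rotation masking is disabled and every chamber
#'   is observed at every timepoint.
#' @param norm_const normalization constant relating counts to ncps.
#' @return A list with `replicates` (list of [ion_counts], each including the
#'   m/z 21 reference channel), `blank` (an [ion_counts]) and `background`
#'   (the per-channel background used).
#' @export
generate_raw_counts <- function(panel, spec, background = 5, ref_counts = 1e4,
                                rep_noise_sd = 0.02, slot_min = 10,
                                n_replicates = 5, mask = TRUE,
                                norm_const = 500) {
  stopifnot(inherits(panel, "flux_panel"))
  n <- length(panel$time); p <- ncol(panel$values)
  bg <- rep_len(background, p)
  cycle <- slot_min * (n_replicates + 1)
  time_s <- panel$time * 60
  mzs <- c(21.022, panel$mz)
  local_seed(spec$seed + 7919L, {
    reps <- vector("list", n_replicates)
    make_chamber <- function(signal, id, slot) {
      ref <- ref_counts * mult_noise(n, rep_noise_sd)
      counts <- (signal + matrix(rep(bg, each = n), n, p)) * (ref / norm_const)
      counts <- counts * matrix(mult_noise(n * p, rep_noise_sd), n, p)
      m <- cbind(ref, counts)
      if (mask) {
        slot_of <- (panel$time %% cycle) %/% slot_min
        m[slot_of != slot, ] <- NA_real_
      }
      ion_counts(time_s, m, mzs, chamber_id = id)
    }
    for (r in seq_len(n_replicates))
      reps[[r]] <- make_chamber(panel$values, paste0("soil_", r), r - 1L)
    blank <- make_chamber(matrix(0, n, p), "blank", n_replicates)
    list(replicates = reps, blank = blank, background = bg)
  })
}

mult_noise <- function(n, sd) if (sd <= 0) rep(1, n) else
  stats::rlnorm(n, meanlog = -sd^2 / 2, sdlog = sd)

#' Ground truth of a synthetic benchmark
#'
#' @param spec a [coupling_spec].
#' @return A list of class `ground_truth` with `edges` (data frame
#'   source/target/lag in panel steps) and `triads` (data frame
#'   source1/source2/target: every unordered pair of sources converging on a
#'   common target, the configurations expected to carry synergy).
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  e <- spec$edges
  triads <- data.frame(source1 = integer(0), source2 = integer(0), target = integer(0))
  for (tg in unique(e$target)) {
    src <- sort(unique(e$source[e$target == tg]))
    if (length(src) >= 2L) {
      cmb <- utils::combn(src, 2L)
      triads <- rbind(triads, data.frame(source1 = cmb[1L, ], source2 = cmb[2L, ],
                                         target = tg))
    }
  }
  structure(list(edges = e[, c("source", "target", "lag")], triads = triads),
            class = "ground_truth")
}
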