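# Spectral and transition analysis of simulation traces.
#
# The EEG proxy is the population-mean excitatory membrane potential.
# Spectra use Welch's averaged periodogram (Hann windows, 50% overlap,
# per-segment linear detrend).  Band edges follow the standard clinical
# conventions: delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30,
# gamma 30-100 Hz; they partition the analysis range 0.5-100 Hz.

.BANDS <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
               beta = c(13, 30), gamma = c(30, 100))
.F_LO <- 0.5
.F_HI <- 100

.detrend_linear <- function(y) {
  n <- length(y)
  t <- seq_len(n) - (n + 1) / 2
  y - mean(y) - sum(t * y) / sum(t * t) * t
}

#' Welch power spectrum of an EEG-proxy series
#'
#' Averaged periodogram with Hann windows of `window_s` seconds, 50%
#' overlap and linear detrending per segment.  The peak is the maximum of
#' the density in 0.5-100 Hz and its prominence is the ratio of the peak
#' power to the median power over that range.
#'
#' @param x Numeric series (e.g. `trace$mean_V_E_mV`), or a
#'   `trace_record` whose EEG proxy is used.
#' @param sample_rate Sampling rate, Hz (taken from a `trace_record`).
#' @param window_s Welch window length, seconds (default 2).
#' @return A `spectrum_result`: list with `frequencies` (Hz), `power`
#'   (density, signal units^2/Hz), `peak_frequency`, `peak_prominence`,
#'   `band_powers` (delta/theta/alpha/beta/gamma variances), `df`,
#'   `sample_rate` and `n_segments`.
#' @export
power_spectrum <- function(x, sample_rate = NULL, window_s = 2) {
  if (inherits(x, "trace_record")) {
    if (is.null(sample_rate)) sample_rate <- x$sample_rate
    x <- x$trace$mean_V_E_mV
  }
  stopifnot(is.numeric(x), !is.null(sample_rate), sample_rate > 0)
  L <- round(window_s * sample_rate)
  if (length(x) < 2 * L)
    stop("series too short: need at least two windows (",
         2 * L, " samples), got ", length(x))
  hop <- L %/% 2
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1)) # Hann
  wnorm <- sum(w^2)
  nf <- L %/% 2 + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- .detrend_linear(x[s0:(s0 + L - 1L)]) * w
    X <- fft(seg)[seq_len(nf)]
    P <- (Mod(X)^2) / (sample_rate * wnorm)
    P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)] # one-sided
    acc <- acc + P
  }
  power <- acc / length(starts)
  freq <- (seq_len(nf) - 1) * sample_rate / L
  df <- sample_rate / L
  sel <- freq >= .F_LO & freq <= .F_HI
  pk <- which.max(power[sel])
  peak_frequency <- freq[sel][pk]
  peak_prominence <- power[sel][pk] / median(power[sel])
  # fraction of band power concentrated near the peak: ~1 for a spectral
  # line, small for broadband (1/f-like) fluctuations with no rhythm
  half_bw <- max(2, 0.2 * peak_frequency)
  near <- abs(freq[sel] - peak_frequency) <= half_bw
  peak_concentration <- sum(power[sel][near]) / sum(power[sel])
  band_powers <- vapply(.BANDS, function(b) {
    sum(power[freq >= b[1] & freq < b[2]]) * df
  }, numeric(1))
  structure(list(frequencies = freq, power = power,
                 peak_frequency = peak_frequency,
                 peak_prominence = peak_prominence,
                 peak_concentration = peak_concentration,
                 band_powers = band_powers, df = df,
                 sample_rate = sample_rate, n_segments = length(starts)),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf(
    "spectrum_result: peak %.2f Hz (prominence %.1f), %d segments, df = %.3f Hz\n",
    x$peak_frequency, x$peak_prominence, x$n_segments, x$df))
  bp <- x$band_powers
  cat("  band powers:",
      paste(sprintf("%s %.3g", names(bp), bp), collapse = ", "), "\n")
  invisible(x)
}

#' Is a well-defined wave present?
#'
#' Operationalises "the waves disappear".  A wave is declared present when
#' the spectral peak's prominence (peak power over the 0.5-100 Hz median
#' power) reaches `prominence_threshold` *and* the peak is a genuine line:
#' at least `concentration_threshold` of the band power lies within
#' max(2 Hz, 20%) of the peak frequency.  Prominence alone cannot tell a
#' rhythm from the steep broadband low-frequency power of an incoherent
#' high-rate state, which is why the concentration condition is part of
#' the criterion; both thresholds are configurable and reported in every
#' serialized result.
#'
#' @param spec A `spectrum_result`.
#' @param prominence_threshold Default 10.
#' @param concentration_threshold Default 0.4.
#' @return Logical.
#' @export
wave_present <- function(spec, prominence_threshold = 10,
                         concentration_threshold = 0.4) {
  stopifnot(inherits(spec, "spectrum_result"))
  spec$peak_prominence >= prominence_threshold &&
    spec$peak_concentration >= concentration_threshold
}

#' Per-neuron and population-mean firing rates
#'
#' Spike count divided by window length, for every neuron of the chosen
#' population (neurons that never fired count as 0 Hz).
#'
#' @param trace A `trace_record` with a spike raster.
#' @param population `"E"` or `"I"`.
#' @param window Optional time window `c(t0, t1)` in ms (default: the
#'   recorded trace extent).
#' @return List with `per_neuron` (Hz, named by neuron id) and `mean`
#'   (population-mean rate, Hz).
#' @export
firing_rates <- function(trace, population = c("E", "I"), window = NULL) {
  stopifnot(inherits(trace, "trace_record"))
  population <- match.arg(population)
  ras <- trace$raster[trace$raster$population == population, ]
  n <- if (population == "E") trace$n_e else trace$n_i
  offset <- if (population == "E") 0L else trace$n_e
  if (is.null(window)) {
    tt <- trace$trace$time_ms
    if (!length(tt)) return(list(per_neuron = numeric(n), mean = 0))
    window <- c(tt[1] - 1000 / trace$sample_rate, tt[length(tt)])
  }
  len_s <- (window[2] - window[1]) / 1000
  keep <- ras$time_ms > window[1] & ras$time_ms <= window[2]
  counts <- tabulate(ras$neuron_id[keep] - offset, nbins = n)
  per <- counts / len_s
  list(per_neuron = per, mean = mean(per))
}

#' Mean peak-to-trough oscillation amplitude
#'
#' Band-passes the series to 0.5-100 Hz (2nd-order Butterworth, zero-phase)
#' and averages the drop from each local maximum to the following local
#' minimum.  A constant (or extremum-free) series has amplitude 0.
#'
#' @param x Numeric series or `trace_record` (EEG proxy used).
#' @param sample_rate Sampling rate, Hz.
#' @return Amplitude in the series' units (mV for traces).
#' @export
oscillation_amplitude <- function(x, sample_rate = NULL) {
  if (inherits(x, "trace_record")) {
    if (is.null(sample_rate)) sample_rate <- x$sample_rate
    x <- x$trace$mean_V_E_mV
  }
  stopifnot(!is.null(sample_rate))
  if (length(x) < 8 || sd(x) == 0) return(0)
  ny <- sample_rate / 2
  bf <- signal::butter(2, c(.F_LO, min(.F_HI, 0.95 * ny)) / ny, type = "pass")
  y <- signal::filtfilt(bf, x - mean(x))
  dy <- sign(diff(y))
  ext <- which(diff(dy) != 0 & dy[-length(dy)] != 0) + 1L
  if (length(ext) < 2) return(0)
  is_peak <- y[ext] > y[pmax(ext - 1L, 1L)]
  amps <- c()
  for (k in seq_len(length(ext) - 1L))
    if (is_peak[k] && !is_peak[k + 1L])
      amps <- c(amps, y[ext[k]] - y[ext[k + 1L]])
  if (!length(amps)) return(0)
  mean(amps)
}

#' Locate a phase transition in a parameter sweep
#'
#' The transition is placed at the largest absolute jump of the order
#' parameter between consecutive grid points, independently for the
#' forward and backward branches.  If the largest jump is below 3x the
#' median inter-point change the branch is declared transition-free.  The
#' sweep is hysteretic when forward and backward locations differ by more
#' than one grid step.
#'
#' @param sweep A `sweep_result`, or a data frame with columns
#'   `direction`, `value` and the order parameter.
#' @param order_parameter Column name, default `"mean_V_E"`.
#' @return A `transition_estimate`: list with `forward`, `backward`
#'   (parameter values at the transition, NA when absent), `jump`
#'   (forward jump magnitude), `is_hysteretic` and `grid_step`.
#' @export
detect_transition <- function(sweep, order_parameter = "mean_V_E") {
  pts <- if (inherits(sweep, "sweep_result")) sweep$points else sweep
  stopifnot(order_parameter %in% names(pts))
  locate <- function(d) {
    if (nrow(d) < 5) stop("need at least 5 grid points per branch")
    y <- d[[order_parameter]]
    jumps <- abs(diff(y))
    mj <- max(jumps)
    if (mj < 3 * median(jumps) || mj == 0)
      return(list(at = NA_real_, jump = NA_real_))
    k <- which.max(jumps)
    list(at = (d$value[k] + d$value[k + 1]) / 2, jump = mj)
  }
  fw <- pts[pts$direction == "forward", ]
  bw <- pts[pts$direction == "backward", ]
  lf <- locate(fw)
  lb <- if (nrow(bw)) locate(bw) else list(at = NA_real_, jump = NA_real_)
  step <- if (nrow(fw) > 1) median(abs(diff(fw$value))) else NA_real_
  hyst <- !is.na(lf$at) && !is.na(lb$at) && abs(lf$at - lb$at) > step
  structure(list(forward = lf$at, backward = lb$at, jump = lf$jump,
                 is_hysteretic = isTRUE(hyst), grid_step = step,
                 order_parameter = order_parameter),
            class = "transition_estimate")
}

#' @export
print.transition_estimate <- function(x, ...) {
  cat(sprintf(
    "transition_estimate (%s): forward %s, backward %s, hysteretic: %s\n",
    x$order_parameter, format(x$forward), format(x$backward),
    x$is_hysteretic))
  invisible(x)
}

#' Classify the dynamical phase at one parameter point
#'
#' Labels: `A` near-silent (mean E rate < 1 Hz), `B` well-defined rhythm
#' (wave present and I neurons active, >= 1 Hz), `D` high excitation
#' without coherence (I silent, E rate >= 100 Hz, no wave), `C`
#' metastable (forward and backward observables classify differently;
#' takes priority).  `"unclassified"` when nothing applies.
#'
#' @param forward,backward Lists with `rate_E`, `rate_I` (Hz) and
#'   `wave_present` (logical) for the two sweep directions; `backward`
#'   may be `NULL` if only one direction was run.
#' @return Single character label.
#' @export
classify_phase <- function(forward, backward = NULL) {
  one <- function(o) {
    if (o$rate_E < 1) return("A")
    if (isTRUE(o$wave_present) && o$rate_I >= 1) return("B")
    if (o$rate_I < 1 && o$rate_E >= 100 && !isTRUE(o$wave_present))
      return("D")
    "unclassified"
  }
  lf <- one(forward)
  if (is.null(backward)) return(lf)
  lb <- one(backward)
  if (lf != lb) "C" else lf
}

#' Phase diagram over the (mu, tau_rec) plane
#'
#' For each recovery-time row, runs forward and backward adiabatic noise
#' sweeps, classifies every grid cell (see [classify_phase()]) and marks
#' the high-rate (> 100 Hz) sub-regions for E and I.
#'
#' @param mu_grid Monotone grid of noise levels.
#' @param tau_rec_grid Monotone grid of recovery times, ms.
#' @param config Base `sim_config`.
#' @param seed Integer seed.
#' @param dwell,settle_per_point Per-point times, ms (defaults from
#'   `config$sweep`).
#' @return A `phase_diagram`: list with `labels` (tau_rec x mu character
#'   matrix), `high_rate_E`, `high_rate_I` (logical matrices, forward
#'   branch), the grids, per-cell forward/backward observables, and
#'   `boundaries` (data frame of adjacent cell pairs whose labels differ).
#' @export
build_phase_diagram <- function(mu_grid, tau_rec_grid,
                                config = default_config(), seed = NULL,
                                dwell = config$sweep$dwell,
                                settle_per_point = config$sweep$settle_per_point) {
  config <- validate_config(config)
  nm <- length(mu_grid); nt <- length(tau_rec_grid)
  labels <- matrix("unclassified", nt, nm,
                   dimnames = list(tau_rec = tau_rec_grid, mu = mu_grid))
  hiE <- hiI <- matrix(FALSE, nt, nm)
  obs_all <- list()
  for (r in seq_len(nt)) {
    cf <- config
    cf$synapses$tau_rec <- tau_rec_grid[r]
    dirs <- if (nm > 1) c("forward", "backward") else "forward"
    sw <- adiabatic_sweep(cf, "mu", grid = mu_grid, dwell = dwell,
                          settle_per_point = settle_per_point, seed = seed,
                          directions = dirs, keep_traces = TRUE)
    obs_of <- function(i) {
      pt <- sw$points[i, ]
      wp <- wave_present(power_spectrum(sw$traces[[i]], sw$sample_rate,
                                        window_s = min(2, (dwell - settle_per_point) / 2500)))
      list(rate_E = pt$rate_E, rate_I = pt$rate_I, wave_present = wp)
    }
    for (c in seq_len(nm)) {
      fwd <- obs_of(c)
      bwd <- if (nm > 1) obs_of(2 * nm + 1 - c) else NULL
      labels[r, c] <- classify_phase(fwd, bwd)
      hiE[r, c] <- fwd$rate_E > 100
      hiI[r, c] <- fwd$rate_I > 100
      obs_all[[paste(r, c)]] <- list(forward = fwd, backward = bwd)
    }
  }
  # adjacent-cell label changes approximate the transition lines
  bnd <- list()
  for (r in seq_len(nt)) for (c in seq_len(nm - 1))
    if (labels[r, c] != labels[r, c + 1])
      bnd[[length(bnd) + 1L]] <- data.frame(
        tau_rec = tau_rec_grid[r],
        mu = (mu_grid[c] + mu_grid[c + 1]) / 2,
        from = labels[r, c], to = labels[r, c + 1], axis = "mu")
  for (c in seq_len(nm)) for (r in seq_len(nt - 1))
    if (labels[r, c] != labels[r + 1, c])
      bnd[[length(bnd) + 1L]] <- data.frame(
        tau_rec = (tau_rec_grid[r] + tau_rec_grid[r + 1]) / 2,
        mu = mu_grid[c],
        from = labels[r, c], to = labels[r + 1, c], axis = "tau_rec")
  structure(list(labels = labels, high_rate_E = hiE, high_rate_I = hiI,
                 mu_grid = mu_grid, tau_rec_grid = tau_rec_grid,
                 observables = obs_all,
                 boundaries = if (length(bnd)) do.call(rbind, bnd) else NULL,
                 config = config),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("phase_diagram (rows: tau_rec ms, cols: mu):\n")
  print(x$labels, quote = FALSE)
  invisible(x)
}

#' Slow/fast rhythm coexistence (delta-theta vs beta-gamma)
#'
#' Finds the most prominent spectral peak independently in the slow
#' (0.5-8 Hz) and fast (13-100 Hz) ranges; each must exceed 3x the median
#' power of its own range to count.  Also reports the ratio of
#' delta+theta to beta+gamma band power, the modulation-strength summary.
#'
#' @param spec A `spectrum_result`.
#' @return List with `low_peak` (Hz or NA), `high_peak` (Hz or NA) and
#'   `ratio` (delta+theta over beta+gamma power).
#' @export
low_high_coexistence <- function(spec) {
  stopifnot(inherits(spec, "spectrum_result"))
  find_peak <- function(lo, hi) {
    sel <- spec$frequencies >= lo & spec$frequencies <= hi
    p <- spec$power[sel]
    if (!length(p)) return(NA_real_)
    k <- which.max(p)
    if (p[k] >= 3 * median(p)) spec$frequencies[sel][k] else NA_real_
  }
  bp <- spec$band_powers
  list(low_peak = find_peak(0.5, 8), high_peak = find_peak(13, 100),
       ratio = unname((bp["delta"] + bp["theta"]) /
                        (bp["beta"] + bp["gamma"])))
}
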