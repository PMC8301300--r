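# Simulation engine: Poisson external drive, the master stepping loop
# (compiled, see src/engine.cpp), trace recording, and adiabatic
# parameter-sweep protocols.

# flat parameter list handed to the compiled core
.engine_par <- function(config, n_e, n_i, std_static = FALSE) {
  sy <- config$synapses; ne <- config$neurons; no <- config$noise
  list(dt = config$sim$dt,
       tau1 = ne$tau1, tau2_mem = ne$tau2_mem,
       Vth0 = ne$Vth0, Vsat = ne$Vsat, Vmin = ne$Vmin,
       ta = ne$ta, kappa = ne$kappa,
       U = sy$U, tau_rec = sy$tau_rec,
       V0d = sy$V0d, V0h = sy$V0h, tau2 = sy$tau2,
       mu = no$mu, base_rate = no$base_rate, v_ext = no$v_ext,
       noise_to_I = identical(no$targets, "EI"),
       std_static = std_static,
       reset_on_spike = isTRUE(ne$reset_on_spike),
       n_e = as.integer(n_e), n_i = as.integer(n_i))
}

# fresh network state: V = 0, resources fully recovered, no spike history
.engine_state <- function(config, n_e, n_i) {
  n <- n_e + n_i
  wsteps <- max(1L, as.integer(round(config$synapses$t_max / config$sim$dt)))
  list(V = numeric(n), t_last = rep(-Inf, n), x = rep(1, n),
       sq_acc = numeric(n), ipsp_acc = numeric(n_e),
       ring = matrix(0, n, wsteps + 1L), ring_pos = 0L, t = 0)
}

# CSR adjacency (0-based) for the compiled core
.engine_adjacency <- function(conn) {
  n_e <- conn$lattice$n_e
  n_i <- conn$lattice$n_i
  src <- as.integer(t(conn$e_to_i))              # E source of each E->I edge
  cons <- rep(seq_len(n_i), each = ncol(conn$e_to_i)) # its I consumer
  ord <- order(src)                              # stable: file order within E
  counts <- tabulate(src, nbins = n_e)
  list(i2e = as.integer(t(conn$i_to_e)) - 1L,
       e2i_ptr = as.integer(c(0L, cumsum(counts))),
       e2i_idx = as.integer(cons[ord] - 1L))
}

.run_chunk <- function(state, adj, par, n_steps, record_stride,
                       record_trace, record_raster) {
  out <- cpp_run_chunk(state$V, state$t_last, state$x,
                       state$sq_acc, state$ipsp_acc,
                       state$ring, state$ring_pos,
                       adj$i2e, adj$e2i_ptr, adj$e2i_idx,
                       par, state$t, as.integer(n_steps),
                       as.integer(record_stride), record_trace, record_raster)
  state$ring_pos <- out$ring_pos
  state$t <- out$t_end
  list(state = state, out = out)
}

#' Draw external Poisson noise events for one engine step
#'
#' Each targeted neuron independently receives a Poisson number of external
#' depolarizing events with mean `mu * base_rate * dt`; every event injects
#' a square pulse of amplitude `v_ext` and width `t_max` into the neuron's
#' excitatory (gated, depression-free) input.
#'
#' @param n_neurons Number of targeted neurons.
#' @param mu Dimensionless noise level.
#' @param base_rate Events/ms per neuron at `mu = 1`.
#' @param dt Step size, ms.
#' @return Integer vector of per-neuron event counts for this step.
#' @export
sample_noise_events <- function(n_neurons, mu, base_rate, dt) {
  stopifnot(mu >= 0, base_rate >= 0, dt >= 0)
  rpois(n_neurons, mu * base_rate * dt)
}

# connectivity for a config (build + optional small-world rewiring)
.config_connectivity <- function(config) {
  lat <- build_lattice(config$lattice$e_side)
  conn <- build_connectivity(lat)
  if (config$lattice$pr > 0)
    conn <- rewire(conn, config$lattice$pr, config$lattice$rewire_seed)
  conn
}

.assemble_trace <- function(out, config, n_e, n_i) {
  tr <- out$trace
  trace <- data.frame(time_ms = tr[, 1], mean_V_E_mV = tr[, 2],
                      mean_V_I_mV = tr[, 3], mean_Ux_E = tr[, 4],
                      mean_Ux_I = tr[, 5])
  pop <- ifelse(out$raster_id <= n_e, "E", "I")
  raster <- data.frame(neuron_id = out$raster_id, population = pop,
                       time_ms = out$raster_t)
  structure(list(trace = trace, raster = raster,
                 spike_counts = out$spike_counts,
                 n_e = n_e, n_i = n_i,
                 sample_rate = 1000 / (config$sim$dt * config$sim$record_stride),
                 config = config),
            class = "trace_record")
}

#' @export
print.trace_record <- function(x, ...) {
  cat(sprintf(
    "trace_record: %d samples at %.0f Hz, %d E / %d I neurons, %d spikes\n",
    nrow(x$trace), x$sample_rate, x$n_e, x$n_i, nrow(x$raster)))
  invisible(x)
}

#' Run a full simulation
#'
#' Initialises the network at rest (V = 0, resources fully recovered, no
#' spike history), integrates for `sim$duration` ms at `sim$dt` and records
#' the population traces (EEG proxy = mean E membrane potential) and spike
#' raster after discarding the first `sim$settle` ms.  Fully reproducible
#' given the seed.
#'
#' @param config A `sim_config` (see [default_config()], [load_config()]).
#' @param seed Integer seed; overrides `config$sim$seed` when given.
#' @param conn Optional pre-built `connectivity_map` (built from the config
#'   when omitted).
#' @param record_raster Keep the full spike raster (default `TRUE`).
#' @param std_static Hard-wire the depression factor to its static value
#'   `U` (diagnostic; the `tau_rec = 0` dynamic path must match this
#'   bit-for-bit).
#' @return A `trace_record`: list with `trace` (data frame `time_ms`,
#'   `mean_V_E_mV`, `mean_V_I_mV`, `mean_Ux_E`, `mean_Ux_I`), `raster`
#'   (`neuron_id`, `population`, `time_ms`), per-neuron `spike_counts` for
#'   the recorded window, population sizes and the config.
#' @export
run_simulation <- function(config = default_config(), seed = NULL,
                           conn = NULL, record_raster = TRUE,
                           std_static = FALSE) {
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$sim$seed
  if (!is.null(seed)) set.seed(seed)
  if (is.null(conn)) conn <- .config_connectivity(config)
  n_e <- conn$lattice$n_e; n_i <- conn$lattice$n_i
  adj <- .engine_adjacency(conn)
  par <- .engine_par(config, n_e, n_i, std_static)
  state <- .engine_state(config, n_e, n_i)
  dt <- config$sim$dt; stride <- config$sim$record_stride
  n_settle <- round(config$sim$settle / dt)
  n_main <- round((config$sim$duration - config$sim$settle) / dt)
  n_main <- (n_main %/% stride) * stride
  if (n_settle > 0) {
    res <- .run_chunk(state, adj, par, n_settle, stride, FALSE, FALSE)
    state <- res$state
  }
  if (n_main > 0) {
    res <- .run_chunk(state, adj, par, n_main, stride, TRUE, record_raster)
    out <- res$out
  } else {
    out <- list(trace = matrix(0, 0, 5), spike_counts = integer(n_e + n_i),
                raster_id = integer(0), raster_t = numeric(0))
  }
  .assemble_trace(out, config, n_e, n_i)
}

#' Adiabatic parameter sweep with state continuity
#'
#' Steps a control parameter (`mu` or `tau_rec`) along a grid, forward and
#' then backward, carrying the full dynamical state (membrane potentials,
#' resources, spike history, RNG stream) between grid points so the system
#' tracks its current attractor.  At each point the first
#' `settle_per_point` ms of the `dwell` are discarded and observables are
#' averaged over the remainder.
#'
#' @param config A `sim_config`.
#' @param param `"mu"` or `"tau_rec"`.
#' @param grid Monotone numeric grid of parameter values.
#' @param dwell Time spent at each grid point, ms.
#' @param settle_per_point Initial part of each dwell discarded from the
#'   observables, ms (`< dwell`).
#' @param seed Integer seed.
#' @param directions Subset of `c("forward", "backward")`; the backward
#'   branch continues from the forward end state (reversed grid).
#' @param keep_traces Keep the recorded EEG-proxy series of every point
#'   (needed for per-point spectra).
#' @return A `sweep_result`: list with `points` (data frame: `direction`,
#'   `value`, `mean_V_E`, `mean_V_I`, `rate_E`, `rate_I`, `mean_Ux_E`,
#'   `mean_Ux_I`), optional `traces`, the grids and the config.
#' @export
adiabatic_sweep <- function(config = default_config(),
                            param = c("mu", "tau_rec"), grid,
                            dwell = config$sweep$dwell,
                            settle_per_point = config$sweep$settle_per_point,
                            seed = NULL,
                            directions = c("forward", "backward"),
                            keep_traces = FALSE) {
  config <- validate_config(config)
  param <- match.arg(param)
  stopifnot(length(grid) >= 1, dwell > settle_per_point)
  directions <- match.arg(directions, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  conn <- .config_connectivity(config)
  n_e <- conn$lattice$n_e; n_i <- conn$lattice$n_i
  adj <- .engine_adjacency(conn)
  state <- .engine_state(config, n_e, n_i)
  dt <- config$sim$dt; stride <- config$sim$record_stride
  n_settle <- round(settle_per_point / dt)
  n_meas <- ((round((dwell - settle_per_point) / dt)) %/% stride) * stride
  meas_ms <- n_meas * dt

  set_param <- function(cf, v) {
    if (param == "mu") cf$noise$mu <- v else cf$synapses$tau_rec <- v
    cf
  }
  rows <- list(); traces <- list(); k <- 0L
  for (dir in directions) {
    g <- if (dir == "forward") grid else rev(grid)
    for (v in g) {
      par <- .engine_par(set_param(config, v), n_e, n_i)
      if (n_settle > 0) {
        res <- .run_chunk(state, adj, par, n_settle, stride, FALSE, FALSE)
        state <- res$state
      }
      res <- .run_chunk(state, adj, par, n_meas, stride, TRUE, FALSE)
      state <- res$state
      out <- res$out
      k <- k + 1L
      rows[[k]] <- data.frame(
        direction = dir, value = v,
        mean_V_E = mean(out$trace[, 2]), mean_V_I = mean(out$trace[, 3]),
        rate_E = sum(out$spike_counts[seq_len(n_e)]) / n_e / meas_ms * 1000,
        rate_I = sum(out$spike_counts[n_e + seq_len(n_i)]) / n_i / meas_ms * 1000,
        mean_Ux_E = mean(out$trace[, 4]), mean_Ux_I = mean(out$trace[, 5]))
      if (keep_traces) traces[[k]] <- out$trace[, 2]
    }
  }
  points <- do.call(rbind, rows)
  structure(list(points = points, param = param, grid = grid,
                 traces = if (keep_traces) traces else NULL,
                 sample_rate = 1000 / (dt * stride),
                 dwell = dwell, settle_per_point = settle_per_point,
                 config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result over %s: %d points (%s)\n", x$param,
              nrow(x$points), paste(unique(x$points$direction), collapse = "+")))
  invisible(x)
}

#' Calibrate the external-noise constants
#'
#' The reference parameter set leaves two constants open: the Poisson base
#' rate (events/ms per neuron at `mu = 1`) and the excitatory square-pulse
#' width `t_max`.  This routine anchors them to two printed observables:
#' (a) the silent-to-oscillatory onset sits at `mu = target_onset_mu` and
#' (b) the no-depression (`tau_rec = 0`) spectrum at `mu = 0.8` peaks near
#' `target_alpha_hz`.  Because the drive enters only through the product
#' `mu * base_rate`, the onset found at any reference rate rescales
#' exactly: `base_rate = onset_rate / target_onset_mu`.  The rescaled rate
#' is then verified (and, if needed, re-rescaled) on a fine onset scan
#' around the target, so a coarse first scan cannot silently censor the
#' onset.  Because the two anchors pull the rate in opposite directions, a
#' final joint stage scans small upward rate scalings (which move the onset
#' below target by a known factor while raising the peak frequency) and
#' picks, over all pulse-width candidates, the pair minimising the worst
#' tolerance-weighted deviation from the two anchors — subject to the
#' reference-model constraint that well-defined waves persist at higher
#' drive (`mu` = 1 and 3 without depression), which rejects calibrations
#' whose rhythm collapses just past the onset.
#'
#' @param target_alpha_hz Desired no-depression peak frequency at
#'   `mu = 0.8` (default 10 Hz).
#' @param target_onset_mu Desired onset noise level (default 0.5).
#' @param t_max_grid Candidate pulse widths, ms.
#' @param config Base configuration.
#' @param seed Integer seed.
#' @param dwell Per-point simulated time for the scans, ms.
#' @return List with the calibrated `base_rate` and `t_max`, the achieved
#'   `peak_hz` and `onset_mu`, and the per-candidate search table.
#' @export
calibrate_noise <- function(target_alpha_hz = 10, target_onset_mu = 0.5,
                            t_max_grid = c(0.5, 1, 2, 4, 8),
                            config = default_config(), seed = 1,
                            dwell = 5000) {
  config <- validate_config(config)
  config$synapses$tau_rec <- 0
  settle <- min(2000, dwell - 2000)
  win_s <- min(2, (dwell - settle) / 2500)
  # smallest grid mu with a sustained wave (>= 1 Hz E rate + spectral
  # line), NA when the scanned range contains no onset
  measure_onset <- function(cf, grid) {
    sw <- adiabatic_sweep(cf, "mu", grid = grid, dwell = dwell,
                          settle_per_point = settle, seed = seed,
                          directions = "forward", keep_traces = TRUE)
    osc <- vapply(seq_along(sw$traces), function(i) {
      sw$points$rate_E[i] >= 1 &&
        wave_present(power_spectrum(sw$traces[[i]], sw$sample_rate,
                                    window_s = win_s))
    }, logical(1))
    if (!any(osc)) NA_real_ else sw$points$value[which(osc)[1]]
  }
  cand <- list()
  for (tm in t_max_grid) {
    cf <- config
    cf$synapses$t_max <- tm
    # coarse bracketing scan at the reference rate, then iterate the exact
    # scaling law base_rate ~ onset_rate / target_onset_mu until the onset
    # verifies on a fine grid around the target (guards against the coarse
    # grid censoring an onset below its first point)
    onset <- measure_onset(cf, seq(0.1, 1.6, by = 0.1))
    if (is.na(onset)) next
    base_rate <- onset * cf$noise$base_rate / target_onset_mu
    achieved <- NA_real_
    for (it in 1:3) {
      cf$noise$base_rate <- base_rate
      achieved <- measure_onset(cf, target_onset_mu * seq(0.2, 1.6, by = 0.05))
      if (is.na(achieved)) break
      if (abs(achieved - target_onset_mu) <= 0.05 * target_onset_mu) break
      base_rate <- base_rate * achieved / target_onset_mu
    }
    if (is.na(achieved)) next
    # joint stage: scaling the rate by s moves the onset to target/s exactly
    # (scaling law), while the mu = 0.8 peak frequency rises with drive, so
    # a small upward scaling can buy alpha accuracy with a bounded onset
    # error.  Pick the scaling minimising the worst relative deviation,
    # onset weighted by the 15% transition-location tolerance and the peak
    # by the 20% frequency tolerance.
    spectrum_at <- function(mu, sd) {
      cf$noise$mu <- mu
      cf$sim$duration <- 14000
      cf$sim$settle <- 2000
      rec <- run_simulation(cf, seed = sd, record_raster = FALSE)
      power_spectrum(rec$trace$mean_V_E_mV, rec$sample_rate, window_s = 2)
    }
    for (s in c(1, 1.05, 1.1, 1.15, 1.2, 1.25, 1.3)) {
      cf$noise$base_rate <- base_rate * s
      # seed-median alpha peak: the mu = 0.8 point can sit near a regime
      # boundary where a single realization is not representative
      sps <- lapply(seed + 0:2, function(sd) spectrum_at(0.8, sd))
      pk <- median(vapply(sps, `[[`, numeric(1), "peak_frequency"))
      cand[[length(cand) + 1L]] <- data.frame(
        t_max = tm, base_rate = base_rate * s,
        peak_hz = pk, onset_mu = achieved / s)
    }
  }
  if (!length(cand))
    stop("calibration failed: no candidate pulse width produced sustained oscillations")
  tab <- do.call(rbind, cand)
  tab$score <- pmax(abs(tab$onset_mu - target_onset_mu) /
                      (0.15 * target_onset_mu),
                    abs(tab$peak_hz - target_alpha_hz) /
                      (0.20 * target_alpha_hz))
  # constraint from the reference (no-depression) model: well-defined waves
  # must persist as the drive grows past the alpha point, so candidates
  # whose rhythm has already collapsed at mu = 1 or mu = 3 are rejected
  # however well they score on the two point anchors
  tab$persistent <- NA
  for (k in order(tab$score)) {
    cf <- config
    cf$synapses$t_max <- tab$t_max[k]
    cf$noise$base_rate <- tab$base_rate[k]
    spectrum_at <- function(mu, sd) {
      cf$noise$mu <- mu
      cf$sim$duration <- 9000
      cf$sim$settle <- 2000
      rec <- run_simulation(cf, seed = sd, record_raster = FALSE)
      power_spectrum(rec$trace$mean_V_E_mV, rec$sample_rate, window_s = 2)
    }
    tab$persistent[k] <- wave_present(spectrum_at(1, seed)) &&
      wave_present(spectrum_at(3, seed))
    if (tab$persistent[k]) break # candidates are scanned best-first
  }
  ok <- which(tab$persistent)
  if (!length(ok))
    stop("calibration failed: no candidate keeps waves alive past the onset")
  best <- ok[which.min(tab$score[ok])]
  if (tab$score[best] > 1)
    warning("calibration: no persistent candidate meets both anchors within ",
            "tolerance; best has onset mu = ", round(tab$onset_mu[best], 3),
            " and peak = ", round(tab$peak_hz[best], 1), " Hz")
  list(base_rate = tab$base_rate[best], t_max = tab$t_max[best],
       peak_hz = tab$peak_hz[best], onset_mu = tab$onset_mu[best],
       search = tab)
}
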