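# Model configuration: defaults, merging, validation.
#
# All units are mV / ms / Hz throughout.  Defaults are the printed values of
# the reference parameter set: tau1 = 16 ms, tau2 = 26 ms, U = 0.5,
# V0d = 8 mV, V0h = -4*V0d, Vsat = 90 mV, Vmin = -20 mV, Vth0 = 6 mV,
# ta = 4 ms, kappa^-1 = 0.5 ms, external pulse amplitude 5.48 mV, 196 E /
# 49 I module.  The two constants the reference set leaves open — the
# external Poisson base rate (events/ms per neuron at mu = 1) and the
# excitatory square-pulse width t_max — are fixed by calibrate_noise() so
# that mu = 0.8 without depression gives the ~10 Hz alpha peak and the
# silent-to-oscillatory onset sits near mu = 0.5.

#' Default simulation configuration
#'
#' Nested list of all model parameters with their default values.  Blocks:
#' `lattice` (`e_side`, `pr`, `rewire_seed`), `synapses` (`U`, `tau_rec`,
#' `V0d`, `V0h`, `t_max`, `tau2`), `neurons` (`tau1`, `tau2_mem`, `Vth0`,
#' `Vsat`, `Vmin`, `ta`, `kappa`, `reset_on_spike`), `noise` (`mu`, `v_ext`,
#' `base_rate`, `targets`), `sim` (`dt`, `duration`, `settle`,
#' `record_stride`, `seed`) and `sweep` (`dwell`, `settle_per_point`).
#'
#' @return A list of class `sim_config`.
#' @export
default_config <- function() {
  structure(list(
    lattice = list(e_side = 14L, pr = 0, rewire_seed = 1L),
    synapses = list(U = 0.5, tau_rec = 0, V0d = 8, V0h = -32,
                    t_max = 4, tau2 = 26),
    neurons = list(tau1 = 16, tau2_mem = 26, Vth0 = 6, Vsat = 90,
                   Vmin = -20, ta = 4, kappa = 2, reset_on_spike = FALSE),
    noise = list(mu = 1, v_ext = 5.48, base_rate = 0.302588, targets = "E"),
    sim = list(dt = 0.04, duration = 10000, settle = 2000,
               record_stride = 25L, seed = NULL),
    sweep = list(dwell = 5000, settle_per_point = 2000)
  ), class = "sim_config")
}

# recursive merge of override into base (named lists only)
.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

.check <- function(ok, path, msg) {
  if (!isTRUE(ok)) stop(sprintf("config field %s: %s", path, msg), call. = FALSE)
}

#' Validate a simulation configuration
#'
#' Checks every parameter invariant (ranges, signs, orderings) and reports
#' violations with the offending field path.
#'
#' @param config A `sim_config` list (see [default_config()]).
#' @return The validated config, invisibly classed `sim_config`.
#' @export
validate_config <- function(config) {
  cf <- config
  la <- cf$lattice; sy <- cf$synapses; ne <- cf$neurons
  no <- cf$noise; si <- cf$sim; sw <- cf$sweep
  .check(la$e_side >= 6 && la$e_side %% 2 == 0, "lattice.e_side",
         "must be an even integer >= 6")
  .check(la$pr >= 0 && la$pr <= 1, "lattice.pr", "must lie in [0, 1]")
  .check(sy$U > 0 && sy$U <= 1, "synapses.U", "must lie in (0, 1]")
  .check(sy$tau_rec >= 0, "synapses.tau_rec", "must be >= 0 ms")
  .check(sy$V0d > 0, "synapses.V0d", "must be > 0 mV")
  .check(sy$V0h < 0, "synapses.V0h", "must be < 0 mV")
  .check(sy$t_max > 0, "synapses.t_max", "must be > 0 ms")
  .check(sy$tau2 > 0, "synapses.tau2", "must be > 0 ms")
  .check(ne$tau1 > 0, "neurons.tau1", "must be > 0 ms")
  .check(ne$tau2_mem > 0, "neurons.tau2_mem", "must be > 0 ms")
  .check(ne$ta > 0, "neurons.ta", "must be > 0 ms")
  .check(ne$kappa > 0, "neurons.kappa", "must be > 0 /ms")
  .check(ne$Vmin < 0 && 0 < ne$Vth0 && ne$Vth0 < ne$Vsat,
         "neurons.Vmin/Vth0/Vsat", "need Vmin < Vrest(0) < Vth0 < Vsat")
  .check(no$mu >= 0, "noise.mu", "must be >= 0")
  .check(no$v_ext > 0, "noise.v_ext", "must be > 0 mV")
  .check(no$base_rate > 0, "noise.base_rate", "must be > 0 events/ms")
  .check(no$targets %in% c("E", "EI"), "noise.targets",
         'must be "E" or "EI"')
  .check(si$dt > 0, "sim.dt", "must be > 0 ms")
  .check(si$settle >= 0 && si$duration >= si$settle, "sim.duration",
         "need duration >= settle >= 0")
  .check(si$record_stride >= 1, "sim.record_stride", "must be >= 1")
  .check(sw$dwell > sw$settle_per_point && sw$settle_per_point >= 0,
         "sweep.dwell", "need dwell > settle_per_point >= 0")
  class(cf) <- "sim_config"
  invisible(cf)
}

#' Load a configuration file, merged with defaults
#'
#' Reads a YAML (or JSON, by extension) configuration file, merges it over
#' [default_config()], applies the balance convention `V0h = -4 * V0d`
#' whenever `V0d` is given without `V0h`, and validates all invariants.
#' An empty file yields the pure defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file, or `NULL`
#'   for pure defaults.
#' @return A validated `sim_config` list.
#' @export
load_config <- function(path = NULL) {
  cf <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    else
      yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.null(user$synapses$V0d) && is.null(user$synapses$V0h))
      user$synapses$V0h <- -4 * user$synapses$V0d
    cf <- .merge_config(cf, user)
  }
  cf <- validate_config(cf)
  cf
}

#' @export
print.sim_config <- function(x, ...) {
  cat("stdwaves simulation configuration\n")
  str(x, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' @importFrom utils str
NULL
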