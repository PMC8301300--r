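# Result serialization, run manifests and test-fixture spike trains.
# All files are plain text; units are mV / ms / Hz, stated in the headers.

#' Write / read a trace record as CSV
#'
#' The population trace goes to `path` (columns `time_ms`, `mean_V_E_mV`,
#' `mean_V_I_mV`, `mean_Ux_E`, `mean_Ux_I`) and, when a raster is present,
#' the spike raster to `<path>.spikes.csv` (columns `neuron_id`,
#' `population`, `time_ms`).  Reading round-trips both plus the metadata
#' needed by the analysis layer (population sizes, sample rate).
#'
#' @param trace A `trace_record`.
#' @param path Output CSV path.
#' @return `write_trace` returns `path` invisibly; `read_trace` the
#'   reconstructed `trace_record`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_record"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- list(n_e = trace$n_e, n_i = trace$n_i,
              sample_rate = trace$sample_rate, units = "mV/ms/Hz")
  writeLines(paste0("# ", jsonlite::toJSON(hdr, auto_unbox = TRUE)), con)
  write.csv(trace$trace, con, row.names = FALSE, quote = FALSE)
  if (!is.null(trace$raster) && nrow(trace$raster))
    write.csv(trace$raster, paste0(path, ".spikes.csv"),
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# ")) stop("missing JSON header line in ", path)
  hdr <- jsonlite::fromJSON(sub("^# ", "", first))
  tr <- read.csv(path, skip = 1L)
  need <- c("time_ms", "mean_V_E_mV", "mean_V_I_mV", "mean_Ux_E", "mean_Ux_I")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("trace file lacks column(s): ",
                         paste(miss, collapse = ", "))
  spk_path <- paste0(path, ".spikes.csv")
  raster <- if (file.exists(spk_path)) read.csv(spk_path)
  else data.frame(neuron_id = integer(0), population = character(0),
                  time_ms = numeric(0))
  structure(list(trace = tr, raster = raster, spike_counts = NULL,
                 n_e = hdr$n_e, n_i = hdr$n_i,
                 sample_rate = hdr$sample_rate, config = NULL),
            class = "trace_record")
}

#' Read an external EEG-like series
#'
#' Accepts a two-column time/value text file (comma, tab or whitespace
#' separated, optional header) for use with the spectral tools; time in ms.
#'
#' @param path Input file.
#' @return List with `values`, `times_ms` and the inferred `sample_rate`
#'   (Hz).
#' @export
read_eeg_series <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "",
                         comment.char = "#", fill = TRUE)
  if (ncol(d) == 1)
    d <- utils::read.csv(path, header = FALSE, comment.char = "#")
  if (is.character(d[[1]][1]) || is.na(suppressWarnings(as.numeric(d[[1]][1]))))
    d <- d[-1, , drop = FALSE] # header row
  tms <- as.numeric(d[[1]]); val <- as.numeric(d[[2]])
  if (anyNA(tms) || anyNA(val)) stop("non-numeric entries in EEG series file")
  list(times_ms = tms, values = val,
       sample_rate = 1000 / median(diff(tms)))
}

#' Write an analysis result as a JSON summary
#'
#' Serialises the scalar summary of a `spectrum_result`,
#' `transition_estimate`, `sweep_result` (its points table) or
#' `phase_diagram` (its labels) to JSON.
#'
#' @param result One of the analysis result objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  out <- if (inherits(result, "spectrum_result")) {
    list(type = "spectrum", peak_frequency_hz = result$peak_frequency,
         peak_prominence = result$peak_prominence,
         peak_concentration = result$peak_concentration,
         band_powers = as.list(result$band_powers), df_hz = result$df)
  } else if (inherits(result, "transition_estimate")) {
    list(type = "transition", forward = result$forward,
         backward = result$backward, jump = result$jump,
         is_hysteretic = result$is_hysteretic, grid_step = result$grid_step)
  } else if (inherits(result, "sweep_result")) {
    list(type = "sweep", param = result$param, points = result$points)
  } else if (inherits(result, "phase_diagram")) {
    list(type = "phase_diagram", mu_grid = result$mu_grid,
         tau_rec_grid = result$tau_rec_grid,
         labels = apply(result$labels, 1, as.list))
  } else stop("unsupported result type: ", paste(class(result), collapse = "/"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, package version and output
#' inventory of a run so it can be reproduced bit-identically.
#'
#' @param dir Output directory (one manifest per directory).
#' @param config The `sim_config` used.
#' @param seed The seed used.
#' @param files Character vector of produced files.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed, files = character(0)) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(package = "stdwaves",
         version = as.character(packageVersion("stdwaves")),
         seed = seed, config = unclass(config), files = files,
         written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(dir) {
  jsonlite::fromJSON(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}

#' Deterministic fixture spike trains
#'
#' Generates spike-time sequences for driving single-synapse and
#' single-neuron kernels in tests: `periodic` (interval `T` ms over
#' `duration`), `poisson` (rate `rate_hz` over `duration`), or `burst`
#' (`n` spikes spaced `T` ms starting at `t0`).
#'
#' @param kind `"periodic"`, `"poisson"` or `"burst"`.
#' @param params List of kind-specific parameters (see Details above):
#'   periodic needs `T`, `duration`; poisson needs `rate_hz`, `duration`;
#'   burst needs `n`, `T` and optionally `t0` (default 0).
#' @param seed Integer seed (used by `poisson`).
#' @return Increasing numeric vector of spike times, ms.
#' @export
make_fixture_spiketrain <- function(kind = c("periodic", "poisson", "burst"),
                                    params, seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    periodic = seq(params$T, params$duration, by = params$T),
    poisson = .with_seed(seed, {
      n <- rpois(1, params$rate_hz * params$duration / 1000)
      sort(runif(n, 0, params$duration))
    }),
    burst = {
      t0 <- if (is.null(params$t0)) 0 else params$t0
      t0 + params$T * (seq_len(params$n) - 1)
    })
}
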