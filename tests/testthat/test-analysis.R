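make_sine <- function(freq, fs = 1000, dur_s = 10, a = 1, noise = 0) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  a * sin(2 * pi * freq * t) + rnorm(length(t), sd = noise)
}

test_that("spectrum recovers a known sinusoid's frequency", {
  set.seed(1)
  sp <- power_spectrum(make_sine(10, noise = 0.01), 1000, window_s = 2)
  expect_equal(sp$peak_frequency, 10, tolerance = sp$df / 10 + 1e-9)
  expect_gt(sp$peak_prominence, 100)
  expect_gt(sp$peak_concentration, 0.9)
  expect_true(wave_present(sp))
})

test_that("white noise shows no prominent wave", {
  set.seed(2)
  sp <- power_spectrum(rnorm(20000), 1000, window_s = 2)
  expect_lt(sp$peak_prominence, 8)
  expect_lt(sp$peak_concentration, 0.2)
  expect_false(wave_present(sp))
})

test_that("band powers satisfy Parseval's identity for band-limited mixtures", {
  set.seed(3)
  x <- make_sine(6, a = 2) + make_sine(40, a = 1)
  sp <- power_spectrum(x, 1000, window_s = 2)
  # variance of the two components: a^2/2 each
  expect_equal(sum(sp$band_powers), 2^2 / 2 + 1^2 / 2, tolerance = 0.05)
  expect_gt(sp$band_powers[["theta"]], 1.8)  # 6 Hz line
  expect_gt(sp$band_powers[["gamma"]], 0.4)  # 40 Hz line
  expect_lt(sp$band_powers[["alpha"]], 0.1)
})

test_that("band edges partition the analysis range without overlap", {
  bands <- stdwaves:::.BANDS
  edges <- unlist(bands)
  expect_equal(unname(edges[seq(2, 10, 2)][-5]), # upper edge k = lower k+1
               unname(edges[seq(1, 9, 2)][-1]))
  expect_equal(bands$delta[1], 0.5)
  expect_equal(bands$gamma[2], 100)
})

test_that("spectral peak is invariant to the recording stride", {
  cf <- small_config(mu = 2, duration = 6000, settle = 1000)
  cf$sim$record_stride <- 25L # 1 kHz
  a <- power_spectrum(run_simulation(cf, seed = 7, record_raster = FALSE))
  cf$sim$record_stride <- 13L # ~1.9 kHz
  b <- power_spectrum(run_simulation(cf, seed = 7, record_raster = FALSE))
  expect_equal(a$peak_frequency, b$peak_frequency, tolerance = 0.15)
})

test_that("wave declaration is monotone in the prominence threshold", {
  set.seed(4)
  sp <- power_spectrum(make_sine(12, noise = 1), 1000, window_s = 2)
  flags <- vapply(c(1, 5, 20, 100, 1000),
                  function(th) wave_present(sp, prominence_threshold = th),
                  logical(1))
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("firing rates count spikes over the window per neuron", {
  tr <- structure(list(
    trace = data.frame(time_ms = seq(1, 1000)),
    raster = data.frame(neuron_id = rep(1L, 100), population = "E",
                        time_ms = seq(10, 1000, by = 10)),
    n_e = 4, n_i = 2, sample_rate = 1000), class = "trace_record")
  fr <- firing_rates(tr, "E", window = c(0, 1000))
  expect_equal(fr$per_neuron, c(100, 0, 0, 0))
  expect_equal(fr$mean, 25)
  empty <- firing_rates(tr, "I", window = c(0, 1000))
  expect_equal(empty$mean, 0)
})

test_that("oscillation amplitude recovers peak-to-trough of a sinusoid", {
  x <- make_sine(8, a = 3, dur_s = 5)
  expect_equal(oscillation_amplitude(x, 1000), 6, tolerance = 0.1)
  expect_equal(oscillation_amplitude(rep(2, 5000), 1000), 0)
  # RMS identity for a pure tone: amplitude ~ 2 sqrt(2) RMS
  expect_equal(oscillation_amplitude(x, 1000),
               2 * sqrt(2) * sqrt(mean((x - mean(x))^2)), tolerance = 0.1)
})

test_that("transition detector recovers a planted step exactly", {
  v <- seq(1, 20)
  pts <- data.frame(direction = rep(c("forward", "backward"),
                                    each = length(v)),
                    value = c(v, rev(v)),
                    mean_V_E = c(ifelse(v < 10.5, 1, 8) + 0.01 * v,
                                 ifelse(rev(v) < 10.5, 1, 8) + 0.01 * rev(v)))
  tr <- detect_transition(pts)
  expect_equal(tr$forward, 10.5)
  expect_equal(tr$backward, 10.5)
  expect_false(tr$is_hysteretic)
})

test_that("transition detector recovers a planted hysteresis loop", {
  v <- seq(1, 20)
  fwd <- ifelse(v < 10.5, 1, 8)          # jumps between 10 and 11
  bwd <- ifelse(rev(v) < 8.5, 1, 8)      # returns between 9 and 8
  pts <- data.frame(direction = rep(c("forward", "backward"), each = 20),
                    value = c(v, rev(v)), mean_V_E = c(fwd, bwd))
  tr <- detect_transition(pts)
  expect_equal(tr$forward, 10.5)
  expect_equal(tr$backward, 8.5)
  expect_true(tr$is_hysteretic)
})

test_that("a gentle monotone ramp yields no transition", {
  v <- seq(1, 30)
  pts <- data.frame(direction = "forward", value = v,
                    mean_V_E = 0.3 * v + sin(v) * 0.05)
  tr <- detect_transition(pts)
  expect_true(is.na(tr$forward))
  expect_false(tr$is_hysteretic)
})

test_that("canonical observable bundles map to phases A, B, D, C", {
  silent <- list(rate_E = 0.2, rate_I = 0, wave_present = FALSE)
  rhythmic <- list(rate_E = 30, rate_I = 15, wave_present = TRUE)
  saturated <- list(rate_E = 180, rate_I = 0.1, wave_present = FALSE)
  expect_equal(classify_phase(silent, silent), "A")
  expect_equal(classify_phase(rhythmic, rhythmic), "B")
  expect_equal(classify_phase(saturated, saturated), "D")
  expect_equal(classify_phase(rhythmic, saturated), "C") # branch mismatch
  odd <- list(rate_E = 50, rate_I = 0.5, wave_present = FALSE)
  expect_equal(classify_phase(odd, odd), "unclassified")
})

test_that("slow/fast coexistence finds both components of a mixture", {
  set.seed(5)
  lone <- power_spectrum(make_sine(40, noise = 0.2), 1000, window_s = 2)
  co <- low_high_coexistence(lone)
  expect_true(is.na(co$low_peak))
  expect_equal(co$high_peak, 40, tolerance = 0.6)
  both <- power_spectrum(make_sine(5, a = 1.5, noise = 0.05) +
                           make_sine(40, noise = 0), 1000, window_s = 2)
  cb <- low_high_coexistence(both)
  expect_equal(cb$low_peak, 5, tolerance = 0.6)
  expect_equal(cb$high_peak, 40, tolerance = 0.6)
  expect_gt(cb$ratio, 1) # slow component carries more variance
})

test_that("phase diagram labels a minimal grid and flags no C at tau_rec = 0", {
  cf <- default_config()
  cf$sweep$dwell <- 4000
  cf$sweep$settle_per_point <- 1500
  pd <- build_phase_diagram(mu_grid = c(0.1, 1), tau_rec_grid = 0,
                            config = cf, seed = 9)
  expect_equal(dim(pd$labels), c(1, 2))
  expect_equal(pd$labels[1, 1], "A") # mu = 0.1: near-silent
  expect_equal(pd$labels[1, 2], "B") # mu = 1: rhythmic
  expect_false(any(pd$labels == "C")) # no STD, no metastability
})
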