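test_that("identical seeds give bit-identical runs, different seeds differ", {
  cf <- small_config(duration = 1500, settle = 200)
  a <- run_simulation(cf, seed = 11)
  b <- run_simulation(cf, seed = 11)
  c <- run_simulation(cf, seed = 12)
  expect_identical(a$trace, b$trace)
  expect_identical(a$raster, b$raster)
  expect_false(identical(a$trace$mean_V_E_mV, c$trace$mean_V_E_mV))
})

test_that("tau_rec = 0 runs are bit-identical to the static-depression build", {
  cf <- small_config(mu = 1.5, tau_rec = 0, duration = 2000, settle = 200)
  dyn <- run_simulation(cf, seed = 5)
  stat <- run_simulation(cf, seed = 5, std_static = TRUE)
  expect_identical(dyn$trace, stat$trace)
  expect_identical(dyn$raster, stat$raster)
  # and the static path genuinely differs once depression is on
  cf$synapses$tau_rec <- 300
  dyn2 <- run_simulation(cf, seed = 5)
  expect_false(identical(dyn2$trace$mean_V_E_mV, dyn$trace$mean_V_E_mV))
})

test_that("a noiseless network started at rest stays exactly silent", {
  cf <- small_config(mu = 0, duration = 1000, settle = 0)
  rec <- run_simulation(cf, seed = 1)
  expect_true(all(rec$trace$mean_V_E_mV == 0))
  expect_true(all(rec$trace$mean_V_I_mV == 0))
  expect_equal(nrow(rec$raster), 0)
})

test_that("with no noise the membrane relaxes to silence from any state", {
  cf <- small_config(mu = 0)
  conn <- stdwaves:::.config_connectivity(cf)
  adj <- stdwaves:::.engine_adjacency(conn)
  par <- stdwaves:::.engine_par(cf, conn$lattice$n_e, conn$lattice$n_i)
  state <- stdwaves:::.engine_state(cf, conn$lattice$n_e, conn$lattice$n_i)
  set.seed(2)
  state$V[] <- runif(length(state$V), -20, 90) # arbitrary initial voltages
  prev <- mean(abs(state$V))
  for (k in 1:8) {
    res <- stdwaves:::.run_chunk(state, adj, par, 2500, 25, TRUE, FALSE)
    state <- res$state
    cur <- mean(abs(state$V))
    expect_lt(cur, prev + 1e-12)
    prev <- cur
  }
  expect_lt(prev, 1e-3) # 800 ms >> every relaxation constant
})

test_that("a single suprathreshold E neuron excites exactly its I consumers", {
  cf <- small_config(mu = 0)
  conn <- stdwaves:::.config_connectivity(cf)
  n_e <- conn$lattice$n_e; n_i <- conn$lattice$n_i
  adj <- stdwaves:::.engine_adjacency(conn)
  par <- stdwaves:::.engine_par(cf, n_e, n_i)
  state <- stdwaves:::.engine_state(cf, n_e, n_i)
  state$V[1] <- 50 # force one E spike; everything else at rest
  res <- stdwaves:::.run_chunk(state, adj, par, 250, 250, TRUE, TRUE)
  consumers <- n_e + which(apply(conn$e_to_i == 1, 1, any))
  expect_equal(res$out$raster_id[1], 1)
  expect_equal(res$out$raster_t[1], cf$sim$dt) # spikes at the first step
  v_end <- res$state$V
  expect_true(all(v_end[consumers] > 0.3))
  silent_i <- setdiff(n_e + seq_len(n_i), consumers)
  expect_true(all(v_end[silent_i] == 0))
  expect_true(all(v_end[2:n_e] <= 0)) # other E's see no input (no E-E edges)
})

test_that("EPSP pulse delivered by the engine matches the waveform kernel", {
  # one forced E spike; a consumer I's excitatory accumulator must equal
  # V0d * U * x for exactly t_max and drive the membrane accordingly
  cf <- small_config(mu = 0)
  conn <- stdwaves:::.config_connectivity(cf)
  n_e <- conn$lattice$n_e
  adj <- stdwaves:::.engine_adjacency(conn)
  par <- stdwaves:::.engine_par(cf, n_e, conn$lattice$n_i)
  state <- stdwaves:::.engine_state(cf, n_e, conn$lattice$n_i)
  state$V[1] <- 50
  tgt <- n_e + which(apply(conn$e_to_i == 1, 1, any))[1]
  dt <- cf$sim$dt
  amp <- epsp_contribution(0, 0.5, cf$synapses$V0d, cf$synapses$t_max)
  # replicate the gated Euler update of the target I neuron step by step
  v_ref <- 0
  p <- c(cf$neurons, cf$synapses)
  nstep_on <- round(cf$synapses$t_max / dt)
  for (s in 1:nstep_on)
    v_ref <- membrane_step(v_ref, gated_input(v_ref, amp, 0, 0, p), dt, p)
  res <- stdwaves:::.run_chunk(state, adj, par, nstep_on + 1L, 1, TRUE, FALSE)
  # pulse active from the step after the spike for t_max: compare potential
  expect_equal(res$state$V[tgt], v_ref, tolerance = 1e-12)
})

test_that("external events are Poisson with mean mu * base_rate * dt", {
  set.seed(9)
  n <- 200000
  mu <- 1.3; base_rate <- 0.44; dt <- 0.04
  k <- sample_noise_events(n, mu, base_rate, dt)
  lam <- mu * base_rate * dt
  expect_equal(mean(k), lam, tolerance = 0.03)
  expect_equal(var(k), lam, tolerance = 0.05)
  expect_true(all(sample_noise_events(1000, 0, base_rate, dt) == 0))
})

test_that("no neuron can exceed the refractory rate ceiling", {
  cf <- small_config(mu = 200, duration = 2000, settle = 500)
  rec <- run_simulation(cf, seed = 4)
  rates_e <- firing_rates(rec, "E")$per_neuron
  rates_i <- firing_rates(rec, "I")$per_neuron
  expect_true(all(c(rates_e, rates_i) <= 1000 / cf$neurons$ta + 1e-9))
  expect_gt(max(rates_e), 100) # the drive really was saturating
  # inter-spike intervals respect the absolute refractory period
  for (id in unique(rec$raster$neuron_id[seq_len(min(2000, nrow(rec$raster)))])) {
    isi <- diff(rec$raster$time_ms[rec$raster$neuron_id == id])
    if (length(isi)) expect_gt(min(isi), cf$neurons$ta - 1e-9)
  }
})

test_that("raster times are multiples of dt and trace is on the stride grid", {
  cf <- small_config(mu = 2, duration = 1200, settle = 400)
  rec <- run_simulation(cf, seed = 6)
  dt <- cf$sim$dt
  expect_true(all(abs(rec$raster$time_ms / dt -
                        round(rec$raster$time_ms / dt)) < 1e-9))
  dtr <- diff(rec$trace$time_ms)
  expect_true(all(abs(dtr - dt * cf$sim$record_stride) < 1e-9))
  expect_equal(rec$sample_rate, 1000)
})

test_that("a one-point sweep reduces to a plain run", {
  cf <- small_config(mu = 1.2, duration = 1500, settle = 500)
  sw <- adiabatic_sweep(cf, "mu", grid = 1.2, dwell = 1500,
                        settle_per_point = 500, seed = 13,
                        directions = "forward")
  cf$noise$mu <- 1.2
  rec <- run_simulation(cf, seed = 13, record_raster = FALSE)
  expect_equal(sw$points$mean_V_E, mean(rec$trace$mean_V_E_mV))
  expect_equal(sw$points$rate_E,
               sum(rec$spike_counts[seq_len(rec$n_e)]) / rec$n_e /
                 (1500 - 500) * 1000)
})

test_that("sweep runs the grid forward then backward with state carried", {
  cf <- small_config(duration = 1000, settle = 0)
  g <- seq(0.5, 1.5, by = 0.5)
  sw <- adiabatic_sweep(cf, "mu", grid = g, dwell = 600,
                        settle_per_point = 200, seed = 3)
  expect_equal(sw$points$value, c(g, rev(g)))
  expect_equal(sw$points$direction, rep(c("forward", "backward"), each = 3))
})

test_that("duration equal to settle yields an empty record without error", {
  cf <- small_config(duration = 800, settle = 800)
  rec <- run_simulation(cf, seed = 1)
  expect_equal(nrow(rec$trace), 0)
  expect_equal(nrow(rec$raster), 0)
})
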