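# Small, fast configurations used throughout the suite.

# the dynamical-anchor checks are allowed to fail collectively without
# cutting the rest of the suite short
options(testthat.progress.max_fails = 100)

small_config <- function(mu = 1, tau_rec = 0, duration = 3000, settle = 500,
                         e_side = 8) {
  cf <- default_config()
  cf$lattice$e_side <- e_side
  cf$noise$mu <- mu
  cf$synapses$tau_rec <- tau_rec
  cf$sim$duration <- duration
  cf$sim$settle <- settle
  cf
}

default_params <- function() {
  cf <- default_config()
  c(cf$synapses, cf$neurons)
}

# brute-force distances from an I plaquette center to every E site under
# periodic wraparound (independent oracle for the neighborhood cutoffs)
periodic_d2 <- function(lattice, i_index) {
  ci <- lattice$positions_i[i_index, ]
  L <- lattice$e_side
  dx <- abs(lattice$positions_e[, 1] - ci[1])
  dy <- abs(lattice$positions_e[, 2] - ci[2])
  dx <- pmin(dx, L - dx)
  dy <- pmin(dy, L - dy)
  dx^2 + dy^2
}
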