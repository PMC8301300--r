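# Example stdwaves configuration (all units mV / ms / Hz).
# Only the fields you want to change need to appear; everything else takes
# the package defaults (see ?default_config).  Giving V0d without V0h
# applies the balance convention V0h = -4 * V0d.
synapses:
  tau_rec: 200      # recovery time constant of synaptic resources (ms)
  V0d: 8            # EPSP peak amplitude (mV); V0h auto-set to -32
noise:
  mu: 1             # external drive level (dimensionless)
sim:
  duration: 12000   # total simulated time (ms)
  settle: 2000      # discarded before recording (ms)
  seed: 1
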