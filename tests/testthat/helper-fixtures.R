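# Shared fixtures: the two reference lipid parameter sets and a
# reduced-sample-rate protocol that keeps simulated traces small in tests.

eps0 <- electrobend::vacuum_permittivity

# DOPC on a 0.9 mm aperture: d0 = 2.69 nm, E = 1.757e7 Pa -> k_c = 1.9e-20 J
dopc_params <- function(...) {
  simulation_params(...)
}

# DOPG: d0 = 2.84 nm, E = 6.29e6 Pa -> k_c = 0.8e-20 J
dopg_params <- function(young_modulus = 6.29e6, ...) {
  simulation_params(
    zero_field_thickness = 2.84e-9,
    young_modulus = young_modulus,
    lipid = "DOPG",
    ...
  )
}

# Standard square-wave schedule sampled at a test-friendly rate.
fast_protocol <- function(sample_rate = 200, ...) {
  build_protocol(sample_rate = sample_rate, ...)
}

no_boot <- list(bootstrap_replicates = 0)

# k_c implied by a simulation parameter set (thin-plate chain at its Poisson
# ratio) -- the generator truth for round-trip tests.
params_kc <- function(params) {
  params$young_modulus * params$zero_field_thickness^3 /
    (24 * (1 - params$poisson_ratio) * (1 + params$poisson_ratio))
}
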