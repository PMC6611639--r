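# shared fixtures and independent oracles used across test files

ref_strains <- qs_strains()
ref_weights <- qs_weights()

strain_row <- function(id) ref_strains[ref_strains$strain == id, , drop = FALSE]

# brute-force weight extraction: enumerate the scan grid and compare whole
# landscapes directly (independent of the bisection path in extract_weight)
brute_extract <- function(observed, tester, env = qs_env(),
                          scan = seq(-3, 3, by = 0.05)) {
  ok <- vapply(scan, function(w) {
    sim <- simulate_landscape(tester, w, env,
                              cognate_volumes = observed$cognate_volumes,
                              interactor_volumes = observed$interactor_volumes)
    landscape_mismatch(sim, observed) == 0
  }, logical(1))
  scan[ok]
}

# closed-form steady state of the reporter ODE at constant density and
# constant effective concentration
lacz_exact <- function(t_min, params, n, c_eff) {
  A <- params$f * hill_activation(c_eff, params$theta, params$m) + 1
  params$rho_L * n * A / params$gamma_L * (1 - exp(-params$gamma_L * t_min))
}
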