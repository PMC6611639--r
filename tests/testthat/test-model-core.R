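test_that("effective concentration is a clamped weighted sum", {
  expect_equal(effective_concentration(1, 2.0), 2.0)
  expect_equal(effective_concentration(c(1, -1), c(1.0, 2.0)), 0.0)
  expect_equal(effective_concentration(c(1, 0.445), c(1.0, 1.0)), 1.445)
  expect_error(effective_concentration(c(1, 1), 1), "same length")
  expect_error(effective_concentration(1, -1), ">= 0")
})

test_that("Hill activation has the right limits and is monotone", {
  expect_equal(hill_activation(0, 1.4, 2), 0)
  expect_equal(hill_activation(1.4, 1.4, 2), 0.5)
  expect_lt(abs(hill_activation(1e4 * 1.4, 1.4, 2) - 1), 1e-6)
  cs <- seq(0, 10, by = 0.1)
  expect_true(all(diff(hill_activation(cs, 1.4, 2)) >= 0))
  expect_error(hill_activation(1, 0, 2), "theta")
})

test_that("without signal or production the reporter stays at baseline", {
  p <- strain_row("A")
  p$rho_c <- 0
  sim <- qs_simulate(p, env = qs_env(), init_c = 0, tester = "A")
  expect_true(all(sim$c == 0))
  ref <- qs_simulate(p, env = qs_env(), init_c = 0, tester = "A")
  expect_equal(fold_change(sim, ref), 1.0)
})

test_that("reporter matches the exact linear-ODE solution at constant coefficients", {
  p <- strain_row("C")
  p$mu <- 0
  env <- qs_env(duration_h = 17, n0 = 1e8) # > 10 / gamma_L minutes
  for (ce in c(0, p$theta, 10)) {
    sim <- qs_simulate(p, env = env, init_c = ce, tester = "C")
    # pointwise from 5 / gamma_L on
    sel <- sim$times >= 5 / p$gamma_L
    exact <- lacz_exact(sim$times[sel], p, 1e8, ce)
    expect_lt(max(abs(sim$L[sel] - exact) / exact), 0.01)
    # final value within 1% of the steady state rho_L * n * (f H + 1) / gamma_L
    A <- p$f * hill_activation(ce, p$theta, p$m) + 1
    expect_equal(tail(sim$L, 1), p$rho_L * 1e8 * A / p$gamma_L,
                 tolerance = 0.01)
  }
})

test_that("logistic growth matches the closed form and converges with dt", {
  p <- strain_row("A")
  p$rho_L <- 0; p$rho_c <- 0
  closed <- function(t_min, n0, s, mu_h) {
    s / (1 + (s / n0 - 1) * exp(-mu_h / 60 * t_min))
  }
  errs <- vapply(c(1, 0.25, 0.05), function(dt) {
    env <- qs_env(duration_h = 10, n0 = 1e6, dt_min = dt)
    sim <- qs_simulate(p, env = env)
    exact <- closed(sim$times, 1e6, env$capacity, p$mu)
    final <- abs(tail(sim$n[, 1], 1) - tail(exact, 1)) / tail(exact, 1)
    expect_lt(final, 0.001)
    max(abs(sim$n[, 1] - exact) / exact)
  }, numeric(1))
  # first-order error: refining dt 20x shrinks the worst pointwise error ~20x
  expect_lt(errs[3], errs[1] / 10)
  expect_lt(errs[3], 0.005)
})

test_that("fold change equals the steady-state prediction f*H + 1", {
  p <- strain_row("C")
  env <- qs_env()
  sat <- qs_simulate(p, env = env, init_c = 30, tester = "C")
  ref <- qs_simulate(p, env = env, init_c = 0, tester = "C")
  expect_equal(fold_change(sat, ref), p$f + 1, tolerance = 0.02)
  half <- qs_simulate(p, env = env, init_c = p$theta, tester = "C")
  expect_equal(fold_change(half, ref), p$f / 2 + 1, tolerance = 0.02)
  expect_equal(fold_change(ref, ref), 1.0)
})

test_that("state variables are non-negative and respect the carrying capacity", {
  for (seed in 1:5) {
    fx <- gen_community_fixture(4, w_range = c(-2, 2), seed = seed)
    set.seed(seed)
    init_c <- runif(4, 0, 20)
    env <- qs_env(duration_h = 10, n0 = runif(4, 1e5, 1e8))
    sim <- qs_simulate(fx$strains, fx$weights, env, init_c = init_c,
                       produce_signal = TRUE, tester = 1)
    expect_true(all(sim$n >= 0))
    expect_true(all(sim$c >= 0))
    expect_true(all(sim$L >= 0))
    expect_true(all(rowSums(sim$n) <= env$capacity * (1 + 1e-9)))
    expect_equal(diff(sim$times), rep(env$dt_min, length(sim$times) - 1))
  }
})

test_that("halving the time step changes final states by less than 0.5%", {
  AB <- ref_strains[ref_strains$strain %in% c("A", "B"), ]
  W <- ref_weights[c("A", "B"), c("A", "B")]
  final <- function(dt) {
    sim <- simulate_coculture(AB, W, n0 = c(5e5, 5e5),
                              env = coculture_env(dt_min = dt))
    c(sim$n[nrow(sim$n), ], sim$c[nrow(sim$c), ])
  }
  a <- final(1); b <- final(0.5)
  expect_lt(max(abs(a - b) / a), 0.005)
  tester_final <- function(dt) {
    env <- qs_env(dt_min = dt)
    tail(qs_simulate(strain_row("C"), env = env, init_c = 2, tester = "C")$L, 1)
  }
  expect_lt(abs(tester_final(1) - tester_final(0.5)) / tester_final(1), 0.005)
})

test_that("negative weighted sums clamp to zero signal and unit fold change", {
  p <- strain_row("C")
  W <- weight_matrix(rbind(c(1, -2), c(0, 1)), c("C", "D"))
  expect_equal(effective_concentration(W[1, ], c(1, 2)), 0)
  st <- predict_state(rbind(p, strain_row("D")), W,
                      signal_mixture(C = 5, D = 25), qs_env())
  expect_equal(unname(attr(st, "fold")["C"]), 1.0)
  expect_false(st$bits[1])
})

test_that("with non-negative weights the fold change is monotone in every signal", {
  p <- strain_row("B")
  env <- qs_env()
  set.seed(42)
  for (rep in 1:5) {
    w <- c(1, runif(2, 0, 2))
    conc <- runif(3, 0, 3)
    base <- fold_const(p, effective_concentration(w, conc), env)
    for (j in 1:3) {
      up <- conc; up[j] <- up[j] + 1
      expect_gte(fold_const(p, effective_concentration(w, up), env) + 1e-12,
                 base)
    }
  }
})

test_that("dimension and validity errors are raised", {
  p <- strain_row("A")
  expect_error(qs_simulate(p, W = diag(2)), "match|square|dimension")
  expect_error(qs_env(dt_min = 0), "dt_min")
  expect_error(qs_env(n0 = 2e9), "carrying capacity")
  expect_error(strain_params("X", f = -1, theta = 1), "f must be")
  expect_error(weight_matrix(matrix(c(2, 0, 0, 1), 2)), "diagonal")
  p0 <- p
  p0$rho_L <- 0 # no reporter production: the no-signal baseline is zero
  expect_error(activation_threshold(p0), "degenerate baseline")
  sim1 <- qs_simulate(p0, env = qs_env(duration_h = 1), init_c = 1, tester = "A")
  expect_error(fold_change(sim1, sim1), "degenerate baseline")
})
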