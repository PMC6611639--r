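test_that("plate-reader emulation is a deterministic transform at zero noise", {
  p <- strain_row("C")
  sim <- qs_simulate(p, env = qs_env(), init_c = 5, tester = "C")
  tr <- emulate_plate_reader(sim, gain = 50, noise_sd = 0)
  ti <- match("C", sim$strain_order)
  expect_equal(tr$fluor_per_cell,
               50 * cumsum(sim$L) * sim$env$dt_min / sim$n[, ti])
  expect_equal(tr$od, sim$n[, ti] / sim$env$capacity)
  # zero gain leaves zero-mean noise
  tr0 <- emulate_plate_reader(sim, gain = 0, noise_sd = 1, seed = 3)
  expect_lt(abs(mean(tr0$fluor_per_cell)), 0.2)
  # seeded noise reproduces bit for bit
  expect_equal(emulate_plate_reader(sim, 50, 2, seed = 9)$fluor_per_cell,
               emulate_plate_reader(sim, 50, 2, seed = 9)$fluor_per_cell)
})

test_that("the 0-5 h fluorescence slope reproduces the endpoint fold change", {
  p <- strain_row("C")
  env <- qs_env()
  sim_sig <- qs_simulate(p, env = env, init_c = 30, tester = "C")
  sim_ref <- qs_simulate(p, env = env, init_c = 0, tester = "C")
  r_sig <- lacz_rate(emulate_plate_reader(sim_sig, noise_sd = 0))
  r_ref <- lacz_rate(emulate_plate_reader(sim_ref, noise_sd = 0))
  expect_equal(r_sig / r_ref, fold_change(sim_sig, sim_ref), tolerance = 0.05)
})

test_that("lacz_rate is the least-squares slope over the window", {
  tt <- seq(0, 600, by = 1)
  mk <- function(y) structure(list(times = tt, fluor_per_cell = y,
                                   od = rep(1, length(tt))),
                              class = "fluorescence_trace")
  expect_equal(lacz_rate(mk(3 + 0.25 * tt)), 0.25)
  expect_equal(lacz_rate(mk(rep(7, length(tt)))), 0)
  set.seed(5)
  noisy <- 3 + 0.25 * tt + rnorm(length(tt), 0, 2)
  fitted <- lacz_rate(mk(noisy))
  se <- summary(lm(noisy[tt <= 300] ~ tt[tt <= 300]))$coefficients[2, 2]
  expect_lt(abs(fitted - 0.25), 3 * se)
  expect_error(lacz_rate(mk(tt), window_h = c(0, 0.01)), "at least 3")
})

test_that("synthetic dose-response data are seed-reproducible and refittable", {
  truth <- strain_row("E")
  clean <- gen_dose_response(truth, noise_sd = 0)
  expect_equal(clean$fold_changes,
               simulate_dose_response(truth)$fold_changes)
  a <- gen_dose_response(truth, noise_sd = 0.5, seed = 42)
  b <- gen_dose_response(truth, noise_sd = 0.5, seed = 42)
  expect_identical(a$fold_changes, b$fold_changes)
  expect_gt(max(abs(a$fold_changes - clean$fold_changes)), 0)
  fit <- fit_dose_response(clean, truth)
  expect_lt(abs(fit$f_hat - 6.951) / 6.951, 0.01)
  expect_lt(abs(fit$theta_hat - 1.815) / 1.815, 0.01)
})

test_that("synthetic landscapes flip bits at the requested rate", {
  p <- strain_row("C")
  truth <- simulate_landscape(p, 0.445)
  expect_equal(landscape_mismatch(gen_landscape(p, 0.445, flip_prob = 0),
                                  truth), 0)
  mism <- vapply(1:200, function(s)
    landscape_mismatch(gen_landscape(p, 0.445, flip_prob = 0.4, seed = s),
                       truth), numeric(1))
  n <- length(truth$on)
  se <- sqrt(n * 0.4 * 0.6 / 200)
  expect_lt(abs(mean(mism) - 0.4 * n), 4 * se)
  # flip-free landscapes invert to the generating weight
  est <- extract_weight(gen_landscape(p, 0.445, flip_prob = 0), p)
  expect_lte(est$w_lo, 0.445)
  expect_gte(est$w_hi, 0.445)
  expect_error(gen_landscape(p, 0.445, flip_prob = 0.6), "flip_prob")
})

test_that("community fixtures are seeded, valid and reduce correctly at zero crosstalk", {
  fx1 <- gen_community_fixture(5, seed = 1)
  fx2 <- gen_community_fixture(5, seed = 1)
  expect_identical(fx1$weights, fx2$weights)
  for (s in 1:50) {
    fx <- gen_community_fixture(sample(2:7, 1), w_range = c(-2, 2), seed = s)
    expect_equal(unname(diag(fx$weights)), rep(1, nrow(fx$weights)))
    expect_silent(validate_strains(fx$strains))
    expect_equal(rownames(fx$weights), fx$strains$strain)
  }
  # zero weights: community prediction reduces to independent thresholds
  fx0 <- gen_community_fixture(5, w_range = c(0, 0), seed = 2)
  vols <- setNames(c(25, 0, 25, 0, 25), fx0$strains$strain)
  st <- predict_state(fx0$strains, fx0$weights, signal_mixture(vols))
  conc <- volume_to_concentration(vols)
  expect_equal(st$bits, unname(conc >= fx0$strains$theta))
})

test_that("the synthetic pipeline closes end to end with exact recovery at zero noise", {
  truth <- strain_row("B")
  w_true <- -0.7
  dr <- gen_dose_response(truth, noise_sd = 0, seed = 1)
  fit <- fit_dose_response(dr, truth)
  expect_lt(abs(fit$f_hat - truth$f) / truth$f, 0.01)
  expect_lt(abs(fit$theta_hat - truth$theta) / truth$theta, 0.01)
  refit <- truth
  refit$f <- fit$f_hat; refit$theta <- fit$theta_hat
  expect_equal(activation_threshold(refit), fit$threshold_fold)
  ls <- gen_landscape(refit, w_true, flip_prob = 0, seed = 1)
  est <- extract_weight(ls, refit)
  expect_lte(est$w_lo - est$scan_step, w_true)
  expect_gte(est$w_hi + est$scan_step, w_true)
  W <- weight_matrix(rbind(c(1, est$w_mean), c(0, 1)), c("B", "X"))
  pair <- rbind(refit, strain_params("X", f = 5, theta = 1.5))
  st <- predict_state(pair, W, signal_mixture(B = 15, X = 0))
  expect_true(st$bits[1]) # 2.25 nM cognate signal exceeds theta_B
})
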