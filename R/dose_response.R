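#' Convert a supernatant volume to a signal concentration
#'
#' Stationary-phase supernatant is assumed to carry `stock_conc` (30 nM) of
#' signal; loading `x` uL into a `total_volume` (200) uL well gives
#' `stock_conc * x / total_volume` nM.
#'
#' @param x supernatant volume in uL (vectorised).
#' @param total_volume assay volume in uL.
#' @param stock_conc signal concentration of undiluted supernatant, nM.
#' @return Signal concentration(s) in nM.
#' @examples
#' volume_to_concentration(200) # 30 nM at full strength
#' volume_to_concentration(25)  # 3.75 nM
#' @export
volume_to_concentration <- function(x, total_volume = 200, stock_conc = 30) {
  if (any(x < 0) || any(x > total_volume))
    stop("volumes must lie in [0, total_volume]")
  stock_conc * x / total_volume
}

#' Simulate a single-signal dose-response curve
#'
#' Simulates the LacZ fold change of a tester strain exposed to a range of
#' volumes of its cognate supernatant (constant exogenous signal), one forward
#' run per volume plus a shared no-signal baseline.
#'
#' @param params one-row strain parameter table for the tester.
#' @param env simulation environment, see [qs_env()].
#' @param volumes supernatant volumes in uL.
#' @inheritParams volume_to_concentration
#' @return An object of class `dose_response`: a list with `strain_id`,
#'   `volumes`, `fold_changes`, `noise_sd` (0) and `seed` (`NA`).
#' @export
simulate_dose_response <- function(params, env = qs_env(),
                                   volumes = seq(0, 25, by = 1),
                                   total_volume = 200, stock_conc = 30) {
  params <- validate_strains(params)
  stopifnot(nrow(params) == 1L)
  conc <- volume_to_concentration(volumes, total_volume, stock_conc)
  fc <- fold_const(params, conc, env)
  structure(list(strain_id = params$strain, volumes = volumes,
                 fold_changes = fc, noise_sd = 0, seed = NA_integer_,
                 total_volume = total_volume, stock_conc = stock_conc),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response of strain %s: %d volumes in [%g, %g] uL%s\n",
              x$strain_id, length(x$volumes), min(x$volumes), max(x$volumes),
              if (x$noise_sd > 0) sprintf(", noise sd %g", x$noise_sd) else ""))
  print(data.frame(volume_ul = x$volumes, fold_change = signif(x$fold_changes, 5)))
  invisible(x)
}

#' Fit fold-change and half-max parameters to dose-response data
#'
#' Estimates `f` and `theta` by minimising the root-mean-squared error between
#' observed fold changes and the simulated dose-response curve. The optimiser
#' is Nelder-Mead on log-parameters, restarted from a 5 x 5 log-spaced grid of
#' initial values, with box constraints `f` in (0, 100] and `theta` in
#' (0, 30] nM enforced by penalty. All other strain parameters are held fixed.
#'
#' @param data a `dose_response` object (or list with `volumes` and
#'   `fold_changes`).
#' @param fixed a one-row strain table supplying all parameters except `f` and
#'   `theta` (its `f`/`theta` entries are ignored).
#' @param env simulation environment used for the fit.
#' @param f_max,theta_max upper bounds of the search box.
#' @param n_starts number of log-spaced initial values per parameter.
#' @return An object of class `qs_fit` with `f_hat`, `theta_hat`, `rmse` and
#'   `threshold_fold` (the activation threshold implied by the fit).
#' @export
fit_dose_response <- function(data, fixed = NULL, env = qs_env(),
                              f_max = 100, theta_max = 30, n_starts = 5) {
  vols <- data$volumes
  obs <- data$fold_changes
  if (length(vols) != length(obs)) stop("volumes and fold_changes differ in length")
  if (length(vols) < 4) stop("need at least 4 dose-response points")
  if (diff(range(obs)) < 1e-6)
    stop("non-identifiable: fold changes show no dose dependence")
  if (is.null(fixed)) {
    fixed <- strain_params(if (!is.null(data$strain_id)) data$strain_id else "X",
                           f = 1, theta = 1)
  }
  fixed <- validate_strains(fixed)
  stopifnot(nrow(fixed) == 1L)
  tv <- if (!is.null(data$total_volume)) data$total_volume else 200
  sc <- if (!is.null(data$stock_conc)) data$stock_conc else 30
  conc <- volume_to_concentration(vols, tv, sc)

  objective <- function(par) {
    f <- exp(par[1]); theta <- exp(par[2])
    if (f > f_max || theta > theta_max)
      return(1e6 + max(f - f_max, theta - theta_max))
    p <- fixed
    p$f <- f; p$theta <- theta
    sim <- fold_const(p, conc, env)
    sqrt(mean((sim - obs)^2))
  }
  f0 <- exp(seq(log(0.5), log(80), length.out = n_starts))
  t0 <- exp(seq(log(0.05), log(20), length.out = n_starts))
  best <- NULL
  for (fs in f0) for (ts in t0) {
    fit <- stats::optim(c(log(fs), log(ts)), objective, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  f_hat <- exp(best$par[1]); theta_hat <- exp(best$par[2])
  p <- fixed; p$f <- f_hat; p$theta <- theta_hat
  structure(list(f_hat = f_hat, theta_hat = theta_hat, rmse = best$value,
                 threshold_fold = activation_threshold(p, env),
                 strain_id = fixed$strain, convergence = best$convergence),
            class = "qs_fit")
}

#' @export
print.qs_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit (strain %s): f = %.4g, theta = %.4g nM\n",
              x$strain_id, x$f_hat, x$theta_hat))
  cat(sprintf("  RMSE = %.3g, activation threshold (fold change) = %.4g\n",
              x$rmse, x$threshold_fold))
  invisible(x)
}

#' Activation threshold of a strain
#'
#' The simulated LacZ fold change of a tester held at a cognate signal
#' concentration equal to its half-max `theta`. A fold change at or above this
#' value counts as QS ON (ties activate). Because `f` and `theta` differ
#' between strains, each strain has a distinct threshold.
#'
#' @param params one-row strain parameter table.
#' @param env simulation environment.
#' @return The threshold fold change (> 1 whenever `f > 0`).
#' @export
activation_threshold <- function(params, env = qs_env()) {
  params <- validate_strains(params)
  stopifnot(nrow(params) == 1L)
  fold_const(params, params$theta, env)
}
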