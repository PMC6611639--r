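with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Emulate a plate-reader fluorescence trace of the LacZ assay
#'
#' Converts a simulated LacZ trajectory into the fluorescence-per-cell signal
#' of a fluorogenic beta-galactosidase assay: the fluorescent product
#' accumulates at a rate proportional to the enzyme amount, so
#' `fluor_per_cell(t) = gain * integral of L / n(t)` plus seeded additive
#' Gaussian noise. An optical-density proxy (`n / capacity`) accompanies the
#' trace.
#'
#' @param sim a `qs_sim` carrying a tester LacZ trajectory.
#' @param gain fluorescence units per unit of accumulated LacZ activity.
#' @param noise_sd standard deviation of the additive measurement noise, in
#'   fluorescence units.
#' @param seed integer seed for the noise (or `NULL`).
#' @return An object of class `fluorescence_trace`: `times` (min),
#'   `fluor_per_cell`, `od`.
#' @export
emulate_plate_reader <- function(sim, gain = 50, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(sim, "qs_sim"))
  if (is.null(sim$L)) stop("simulation carries no tester LacZ trajectory")
  ti <- match(sim$tester, sim$strain_order)
  n <- sim$n[, ti]
  dt <- sim$env$dt_min
  cum <- cumsum(sim$L) * dt
  fl <- gain * cum / pmax(n, .Machine$double.eps)
  fl <- fl + with_seed(seed, stats::rnorm(length(fl), 0, noise_sd))
  structure(list(times = sim$times, fluor_per_cell = fl,
                 od = n / sim$env$capacity),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace: %d points over %g min, final %g AU/cell\n",
              length(x$times), max(x$times),
              signif(x$fluor_per_cell[length(x$times)], 4)))
  invisible(x)
}

#' LacZ expression level from a fluorescence trace
#'
#' The rate of fluorescence increase: the least-squares slope of
#' fluorescence-per-cell against time over a window (the linear region of the
#' assay, 0-5 h by default).
#'
#' @param trace a `fluorescence_trace`.
#' @param window_h two-element interval in hours.
#' @return The slope, fluorescence units per minute.
#' @export
lacz_rate <- function(trace, window_h = c(0, 5)) {
  stopifnot(inherits(trace, "fluorescence_trace"), length(window_h) == 2)
  sel <- trace$times >= window_h[1] * 60 & trace$times <= window_h[2] * 60
  if (sum(sel) < 3) stop("need at least 3 points inside the window")
  unname(stats::coef(stats::lm(trace$fluor_per_cell[sel] ~ trace$times[sel]))[2])
}

#' Generate a (noisy) synthetic dose-response dataset
#'
#' [simulate_dose_response()] with seeded additive Gaussian noise on the fold
#' changes, floored at a small positive value.
#'
#' @param truth one-row strain table used as ground truth.
#' @param volumes supernatant volumes in uL.
#' @param noise_sd standard deviation of the additive noise on fold changes.
#' @param seed integer seed (or `NULL`).
#' @param env simulation environment.
#' @return A `dose_response` object, see [simulate_dose_response()].
#' @export
gen_dose_response <- function(truth, volumes = seq(0, 25, by = 1),
                              noise_sd = 0, seed = NULL, env = qs_env()) {
  out <- simulate_dose_response(truth, env, volumes)
  if (noise_sd > 0) {
    out$fold_changes <- pmax(
      0.01, out$fold_changes +
        with_seed(seed, stats::rnorm(length(volumes), 0, noise_sd)))
  }
  out$noise_sd <- noise_sd
  out$seed <- if (is.null(seed)) NA_integer_ else seed
  out
}

#' Generate a (noisy) synthetic activation landscape
#'
#' [simulate_landscape()] with seeded independent Bernoulli bit flips.
#'
#' @param truth one-row strain table of the tester (ground truth).
#' @param true_w generating crosstalk weight of the interacting signal.
#' @param flip_prob per-cell flip probability, in `[0, 0.5)`.
#' @param seed integer seed (or `NULL`).
#' @param env simulation environment.
#' @inheritParams simulate_landscape
#' @return A `qs_landscape`.
#' @export
gen_landscape <- function(truth, true_w, flip_prob = 0, seed = NULL,
                          env = qs_env(),
                          cognate_volumes = seq(0, 25, by = 5),
                          interactor_volumes = seq(0, 25, by = 5)) {
  if (flip_prob < 0 || flip_prob >= 0.5)
    stop("flip_prob must lie in [0, 0.5)")
  ls <- simulate_landscape(truth, true_w, env, cognate_volumes,
                           interactor_volumes)
  if (flip_prob > 0) {
    flips <- with_seed(seed, stats::runif(length(ls$on)) < flip_prob)
    ls$on <- xor(ls$on, matrix(flips, nrow = nrow(ls$on)))
  }
  ls
}

#' Generate a random community fixture with known ground truth
#'
#' Builds a strain table (reference `f`/`theta` values reused cyclically) and
#' a random crosstalk weight matrix with unit diagonal and off-diagonal
#' entries drawn uniformly from `w_range` (use `c(0, 0)` for a crosstalk-free
#' community).
#'
#' @param n_strains number of strains (>= 2).
#' @param w_range two-element range of the uniform off-diagonal weight law.
#' @param seed integer seed (or `NULL`).
#' @return A list with elements `strains` and `weights`.
#' @export
gen_community_fixture <- function(n_strains, w_range = c(-1, 1), seed = NULL) {
  if (n_strains < 2) stop("n_strains must be >= 2")
  ref <- qs_strains()
  idx <- ((seq_len(n_strains) - 1) %% nrow(ref)) + 1
  ids <- make.unique(ref$strain[idx], sep = "")
  strains <- strain_params(ids, f = ref$f[idx], theta = ref$theta[idx])
  w <- with_seed(seed, matrix(stats::runif(n_strains^2, w_range[1], w_range[2]),
                              n_strains))
  diag(w) <- 1
  list(strains = strains, weights = weight_matrix(w, ids))
}
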