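#' Effective signal concentration under crosstalk
#'
#' The neural-network integration step: each strain senses the weighted sum of
#' all signal concentrations, clamped at zero from below, so that inhibitory
#' crosstalk can cancel but never invert activation.
#'
#' @param weights_row numeric vector, one crosstalk weight per signal (the
#'   strain's row of the weight matrix; the self-weight should be 1).
#' @param conc numeric vector of signal concentrations in nM (>= 0).
#' @return `max(0, sum(weights_row * conc))`, a scalar in nM.
#' @examples
#' effective_concentration(c(1, -1), c(1, 2)) # clamped to 0
#' @export
effective_concentration <- function(weights_row, conc) {
  if (length(weights_row) != length(conc))
    stop("weights_row and conc must have the same length")
  if (any(conc < 0)) stop("signal concentrations must be >= 0")
  max(0, sum(weights_row * conc))
}

#' Hill activation function
#'
#' Fraction of maximal QS activation at an effective signal concentration
#' `c_eff`: `c_eff^m / (c_eff^m + theta^m)`.
#'
#' @param c_eff effective signal concentration, nM (>= 0); vectorised.
#' @param theta half-max concentration, nM (> 0).
#' @param m Hill coefficient (> 0).
#' @return Activation fraction in `[0, 1]`.
#' @export
hill_activation <- function(c_eff, theta, m) {
  if (any(c_eff < 0)) stop("c_eff must be >= 0")
  if (theta <= 0) stop("theta must be > 0")
  if (m <= 0) stop("m must be > 0")
  ifelse(c_eff == 0, 0, c_eff^m / (c_eff^m + theta^m))
}

#' Forward simulation of growth, signaling and reporter expression
#'
#' Integrates the coupled model with an explicit forward-Euler scheme at the
#' environment's time step (1 min by default): logistic growth of every strain
#' under a shared carrying capacity; QS-regulated signal production for strains
#' flagged as producers; and Hill-regulated LacZ expression for an optional
#' tester strain. Signals held by non-producers (exogenous supernatant boluses)
#' are constant by default, or decay at `gamma_c` when `tester_decay = TRUE`.
#' All state variables are clamped at zero from below.
#'
#' @param strains strain parameter table, see [strain_params()].
#' @param W crosstalk weight matrix over the same strains ([weight_matrix()]).
#' @param env simulation environment, see [qs_env()].
#' @param init_c initial signal concentrations in nM (recycled).
#' @param produce_signal logical per strain; `TRUE` for producers.
#' @param tester optional strain label (or index) whose LacZ trajectory is
#'   integrated.
#' @param tester_decay should exogenous (non-producer) signals decay at
#'   `gamma_c`? Defaults to `FALSE`: a supernatant bolus is held constant.
#' @param perturbations optional list of [perturbation()] objects; each adds an
#'   instantaneous concentration increment to one strain's signal at its time.
#' @return An object of class `qs_sim` with elements `times` (min), `n`
#'   (cells/mL, one column per strain), `c` (nM), `L` (LacZ units, `NULL` when
#'   no tester was given), `strain_order`, and the environment used.
#' @export
qs_simulate <- function(strains, W = NULL, env = qs_env(), init_c = 0,
                        produce_signal = FALSE, tester = NULL,
                        tester_decay = FALSE, perturbations = NULL) {
  strains <- validate_strains(strains)
  k <- nrow(strains)
  if (is.null(W)) W <- weight_matrix(diag(k), strains$strain)
  W <- weight_matrix(W)
  if (nrow(W) != k)
    stop("weight matrix dimensions do not match the number of strains")
  if (!identical(rownames(W), strains$strain))
    W <- W[strains$strain, strains$strain, drop = FALSE]
  init_c <- rep_len(init_c, k)
  if (any(init_c < 0)) stop("init_c must be >= 0")
  produce_signal <- rep_len(produce_signal, k)
  n0 <- rep_len(env$n0, k)
  if (sum(n0) > env$capacity)
    stop("total initial density exceeds the carrying capacity")
  tester_idx <- -1L
  if (!is.null(tester)) {
    if (is.character(tester)) tester_idx <- match(tester, strains$strain) - 1L
    else tester_idx <- as.integer(tester) - 1L
    if (is.na(tester_idx) || tester_idx < 0L || tester_idx >= k)
      stop("tester not found among the strains")
  }
  nsteps <- as.integer(round(env$duration_h * 60 / env$dt_min))
  pert_step <- integer(0); pert_strain <- integer(0); pert_dc <- numeric(0)
  for (p in perturbations) {
    stopifnot(inherits(p, "qs_perturbation"))
    if (p$time_h > env$duration_h)
      stop("perturbation time lies beyond the simulated duration")
    idx <- match(p$source_strain, strains$strain)
    if (is.na(idx)) stop("perturbation source strain not found: ", p$source_strain)
    pert_step <- c(pert_step, as.integer(round(p$time_h * 60 / env$dt_min)))
    pert_strain <- c(pert_strain, idx - 1L)
    pert_dc <- c(pert_dc, perturbation_increment(p, env$volume_ml))
  }
  res <- cpp_simulate(strains$f, strains$theta, strains$m, strains$rho_L,
                      strains$gamma_L, strains$rho_c, strains$gamma_c,
                      strains$mu / 60, W, env$capacity, env$dt_min, nsteps,
                      n0, init_c, produce_signal, tester_idx, tester_decay,
                      pert_step, pert_strain, pert_dc)
  colnames(res$n) <- colnames(res$c) <- strains$strain
  structure(list(times = res$times, n = res$n, c = res$c,
                 L = if (tester_idx >= 0) res$L else NULL,
                 tester = if (tester_idx >= 0) strains$strain[tester_idx + 1] else NULL,
                 strain_order = strains$strain, strains = strains, env = env),
            class = "qs_sim")
}

#' @export
print.qs_sim <- function(x, ...) {
  k <- ncol(x$n)
  cat(sprintf("QS simulation: %d strain(s) (%s), %d steps of %g min\n",
              k, paste(x$strain_order, collapse = ", "),
              length(x$times) - 1L, x$env$dt_min))
  fin <- function(m) signif(m[nrow(m), ], 4)
  cat("  final densities (cells/mL):", paste(fin(x$n), collapse = ", "), "\n")
  cat("  final signals (nM):       ", paste(fin(x$c), collapse = ", "), "\n")
  if (!is.null(x$L))
    cat(sprintf("  tester %s final LacZ: %s\n", x$tester,
                signif(x$L[length(x$L)], 4)))
  invisible(x)
}

#' Tidy data frame of a simulation
#'
#' @param x a `qs_sim` object.
#' @param ... unused.
#' @return Long-format data.frame with columns
#'   `time_min, variable, strain, value`, where `variable` is one of
#'   `"density"`, `"signal"`, `"lacz"`.
#' @export
as.data.frame.qs_sim <- function(x, ...) {
  k <- ncol(x$n)
  out <- rbind(
    data.frame(time_min = rep(x$times, k),
               variable = "density",
               strain = rep(x$strain_order, each = length(x$times)),
               value = as.vector(x$n)),
    data.frame(time_min = rep(x$times, k),
               variable = "signal",
               strain = rep(x$strain_order, each = length(x$times)),
               value = as.vector(x$c)))
  if (!is.null(x$L))
    out <- rbind(out, data.frame(time_min = x$times, variable = "lacz",
                                 strain = x$tester, value = x$L))
  out
}

#' LacZ fold change between two simulations
#'
#' Ratio of the tester's LacZ readout in the presence and absence of signal.
#' The readout is the LacZ value at the final simulated time.
#'
#' @param L_signal `qs_sim` of the tester exposed to the signal mixture.
#' @param L_nosignal `qs_sim` of the same tester with no signal.
#' @return The dimensionless fold change (>= 0).
#' @export
fold_change <- function(L_signal, L_nosignal) {
  stopifnot(inherits(L_signal, "qs_sim"), inherits(L_nosignal, "qs_sim"))
  if (is.null(L_signal$L) || is.null(L_nosignal$L))
    stop("both simulations must carry a tester LacZ trajectory")
  if (!isTRUE(all.equal(L_signal$times, L_nosignal$times)))
    stop("the two runs must share the same time grid")
  denom <- L_nosignal$L[length(L_nosignal$L)]
  if (denom <= 0) stop("degenerate baseline: no-signal LacZ is zero")
  L_signal$L[length(L_signal$L)] / denom
}

# Batched fold changes of one tester at constant effective concentrations.
# Integrates the reporter equation for every c_eff plus the shared no-signal
# baseline in a single Euler pass (all runs share the growth trajectory).
fold_const <- function(params, c_eff, env = qs_env()) {
  stopifnot(nrow(params) == 1L)
  nsteps <- as.integer(round(env$duration_h * 60 / env$dt_min))
  cpp_fold_const(params$f, params$theta, params$m, params$rho_L,
                 params$gamma_L, params$mu / 60, env$n0[1], env$capacity,
                 env$dt_min, nsteps, pmax(0, c_eff))
}
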