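#' A timed signal perturbation
#'
#' An instantaneous addition of producer supernatant to a growing co-culture.
#' Added to a culture of volume `V` mL, a bolus of `volume` uL at
#' `supernatant_conc` nM raises the source strain's signal concentration by
#' `supernatant_conc * volume / (V * 1000 + volume)` nM.
#'
#' @param source_strain label of the strain whose signal is added.
#' @param volume supernatant volume in uL (>= 0).
#' @param time_h time of addition, hours after inoculation (>= 0).
#' @param supernatant_conc signal concentration of the supernatant, nM.
#' @return An object of class `qs_perturbation`.
#' @export
perturbation <- function(source_strain, volume, time_h, supernatant_conc = 30) {
  if (volume < 0) stop("volume must be >= 0")
  if (time_h < 0) stop("time_h must be >= 0")
  structure(list(source_strain = source_strain, volume = volume,
                 time_h = time_h, supernatant_conc = supernatant_conc),
            class = "qs_perturbation")
}

perturbation_increment <- function(p, culture_volume_ml) {
  p$supernatant_conc * p$volume / (culture_volume_ml * 1000 + p$volume)
}

#' Default environment for growing co-cultures
#'
#' 3 mL of competence medium inoculated at a total density of 1e6 cells/mL,
#' grown for 10 h.
#'
#' @inheritParams qs_env
#' @export
coculture_env <- function(volume_ml = 3, capacity = 1e9, dt_min = 1,
                          duration_h = 10, n0 = 1e6) {
  qs_env(volume_ml = volume_ml, capacity = capacity, dt_min = dt_min,
         duration_h = duration_h, n0 = n0)
}

#' Simulate a growing producer co-culture
#'
#' All strains grow logistically under a shared carrying capacity and produce
#' their own signal at a QS-regulated rate; crosstalk couples the strains
#' through each strain's effective signal concentration. Optional
#' perturbations add signal boluses at specified times.
#'
#' @param strains strain parameter table of the producers.
#' @param W crosstalk weight matrix.
#' @param n0 initial densities, cells/mL (recycled; overrides `env$n0`).
#' @param env simulation environment (see [coculture_env()]).
#' @param perturbations list of [perturbation()] objects.
#' @return A `qs_sim` object, see [qs_simulate()].
#' @export
simulate_coculture <- function(strains, W = NULL, n0 = NULL,
                               env = coculture_env(), perturbations = NULL) {
  if (!is.null(n0)) env$n0 <- n0
  qs_simulate(strains, W, env, init_c = 0,
              produce_signal = TRUE, tester = NULL,
              perturbations = perturbations)
}

#' Tester supernatant assay of a finished co-culture
#'
#' Emulates harvesting the co-culture supernatant and applying it to tester
#' strains: the final signal concentrations are diluted by the assay fraction
#' (150 uL of supernatant in a 200 uL well by default), each tester's fold
#' change is simulated under its clamped weighted signal sum, and normalised
#' by its activation threshold.
#'
#' @param coculture a finished `qs_sim` from [simulate_coculture()].
#' @param testers strain parameter table of the testers (defaults to the
#'   co-culture strains).
#' @param W crosstalk weight matrix covering the testers and the co-culture
#'   signals.
#' @param env assay environment for the tester wells (see [qs_env()]).
#' @param dilution fraction of the assay volume that is co-culture supernatant.
#' @return An object of class `coculture_outcome`: `final_c` (nM, undiluted),
#'   `tester_fold` (fold change / threshold) and `active` per tester.
#' @export
supernatant_assay <- function(coculture, testers = NULL, W = NULL,
                              env = qs_env(), dilution = 150 / 200) {
  stopifnot(inherits(coculture, "qs_sim"))
  final_c <- coculture$c[nrow(coculture$c), ]
  if (is.null(testers)) testers <- coculture$strains
  testers <- validate_strains(testers)
  k <- nrow(testers)
  if (is.null(W)) W <- weight_matrix(diag(length(final_c)),
                                     coculture$strain_order)
  W <- weight_matrix(W)
  c_assay <- dilution * final_c
  norm_fold <- numeric(k)
  for (i in seq_len(k)) {
    row <- W[testers$strain[i], names(final_c)]
    ceff <- effective_concentration(row, c_assay)
    p <- testers[i, , drop = FALSE]
    norm_fold[i] <- fold_const(p, ceff, env) / activation_threshold(p, env)
  }
  structure(list(final_c = final_c,
                 tester_fold = setNames(norm_fold, testers$strain),
                 active = setNames(norm_fold >= 1, testers$strain)),
            class = "coculture_outcome")
}

#' @export
print.coculture_outcome <- function(x, ...) {
  cat("Co-culture outcome (tester assay):\n")
  print(data.frame(strain = names(x$tester_fold),
                   final_c_nM = signif(x$final_c[names(x$tester_fold)], 4),
                   normalized_fold = signif(x$tester_fold, 4),
                   active = x$active))
  if (!is.null(attr(x, "ratio")))
    cat(sprintf("  inoculation ratio: %g\n", attr(x, "ratio")))
  invisible(x)
}

run_pair_outcome <- function(paramsA, paramsB, W, ratio, env, assay_env,
                             n0_total, perturbations = NULL) {
  n0 <- n0_total * c(ratio, 1) / (ratio + 1)
  strains <- rbind(paramsA, paramsB)
  cc <- simulate_coculture(strains, W[strains$strain, strains$strain],
                           n0 = n0, env = env, perturbations = perturbations)
  out <- supernatant_assay(cc, strains, W[strains$strain, strains$strain],
                          env = assay_env)
  attr(out, "ratio") <- ratio
  out
}

#' Sweep the inoculation ratio of a two-producer co-culture
#'
#' Runs co-cultures of two producers at a series of inoculation ratios (A:B,
#' total inoculum held constant), assays the supernatant with both testers,
#' and refines the critical ratio at which the second strain stops activating
#' QS by bisection between the bracketing swept ratios (on a log scale).
#'
#' @param paramsA,paramsB one-row strain tables of the two producers.
#' @param W crosstalk weight matrix covering both strains.
#' @param ratios numeric vector of inoculation ratios (> 0), A:B.
#' @param env co-culture environment.
#' @param assay_env tester-well environment for the supernatant assay.
#' @param n0_total total initial density, cells/mL.
#' @param refine_tol relative tolerance of the bisection refinement.
#' @return A list of `coculture_outcome` objects (one per ratio) with
#'   attribute `"critical_ratio"`: the refined smallest ratio at which strain B
#'   is inactive (`NA` when the sweep does not bracket a change).
#' @export
ratio_sweep <- function(paramsA, paramsB, W, ratios = c(1, 2, 5, 10, 100, 1000),
                        env = coculture_env(), assay_env = qs_env(),
                        n0_total = 1e6, refine_tol = 0.01) {
  if (any(ratios <= 0)) stop("ratios must be > 0")
  ratios <- sort(ratios)
  outcomes <- lapply(ratios, function(r)
    run_pair_outcome(paramsA, paramsB, W, r, env, assay_env, n0_total))
  b_active <- vapply(outcomes, function(o) o$active[2], logical(1))
  crit <- NA_real_
  flip <- which(b_active[-length(b_active)] & !b_active[-1])
  if (length(flip)) {
    lo <- ratios[flip[1]]; hi <- ratios[flip[1] + 1]
    while (hi / lo > 1 + refine_tol) {
      mid <- sqrt(lo * hi)
      o <- run_pair_outcome(paramsA, paramsB, W, mid, env, assay_env, n0_total)
      if (o$active[2]) lo <- mid else hi <- mid
    }
    crit <- hi
  }
  structure(outcomes, critical_ratio = crit, ratios = ratios,
            class = "ratio_sweep")
}

#' @export
print.ratio_sweep <- function(x, ...) {
  tab <- data.frame(
    ratio = attr(x, "ratios"),
    A_fold = vapply(x, function(o) o$tester_fold[1], numeric(1)),
    B_fold = vapply(x, function(o) o$tester_fold[2], numeric(1)))
  tab$A_active <- tab$A_fold >= 1
  tab$B_active <- tab$B_fold >= 1
  cat("Inoculation-ratio sweep (normalized tester fold changes):\n")
  print(tab, row.names = FALSE)
  cat(sprintf("  critical ratio (B inactivates): %s\n",
              format(attr(x, "critical_ratio"))))
  invisible(x)
}

#' Scan the timing of a signal perturbation
#'
#' Repeats a two-producer co-culture, introducing the same signal perturbation
#' at a series of times, and assays the final supernatant with both testers.
#'
#' @param strains strain parameter table of the producers (two or more rows).
#' @param W crosstalk weight matrix covering producers and the perturbing
#'   signal.
#' @param n0 initial densities of the producers, cells/mL.
#' @param pert a [perturbation()] template; its `time_h` is replaced by each
#'   entry of `times_h`.
#' @param times_h perturbation times in hours.
#' @param env co-culture environment.
#' @param assay_env tester-well environment.
#' @return An object of class `perturbation_scan`: for each time, the
#'   normalised tester folds and activation flags.
#' @export
perturbation_timing_scan <- function(strains, W, n0, pert,
                                     times_h = 0:7, env = coculture_env(),
                                     assay_env = qs_env()) {
  stopifnot(inherits(pert, "qs_perturbation"))
  strains <- validate_strains(strains)
  W <- weight_matrix(W)
  sig_order <- rownames(W)
  outcomes <- lapply(times_h, function(tp) {
    p <- pert; p$time_h <- tp
    # the perturbing signal may come from a strain absent from the co-culture:
    # carry it as a non-growing, non-producing signal channel
    extra <- setdiff(p$source_strain, strains$strain)
    sim_strains <- strains
    n0_full <- rep_len(n0, nrow(strains))
    if (length(extra)) {
      sim_strains <- rbind(strains, qs_strains(extra))
      n0_full <- c(n0_full, 0)
    }
    Wsub <- W[sim_strains$strain, sim_strains$strain]
    cc <- simulate_coculture(sim_strains, Wsub, n0 = n0_full, env = env,
                             perturbations = list(p))
    supernatant_assay(cc, strains, Wsub, env = assay_env)
  })
  folds <- t(vapply(outcomes, function(o) o$tester_fold,
                    numeric(nrow(strains))))
  structure(list(times_h = times_h, outcomes = outcomes,
                 tester_fold = folds,
                 active = folds >= 1),
            class = "perturbation_scan")
}

#' @export
print.perturbation_scan <- function(x, ...) {
  cat("Perturbation-timing scan (normalized tester fold changes):\n")
  tab <- data.frame(time_h = x$times_h, signif(x$tester_fold, 4),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}
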