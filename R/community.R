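#' Community-level binary signaling state
#'
#' @param bits logical (or 0/1) vector of per-strain QS activation.
#' @param strain_order character vector of strain labels.
#' @return An object of class `community_state`.
#' @export
community_state <- function(bits, strain_order) {
  bits <- as.logical(bits)
  if (length(bits) != length(strain_order))
    stop("bits and strain_order must have the same length")
  structure(list(strain_order = strain_order, bits = bits),
            class = "community_state")
}

#' @export
format.community_state <- function(x, ...) {
  paste0("(", paste(as.integer(x$bits), collapse = ","), ")")
}

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf("Community state [%s]: %s\n",
              paste(x$strain_order, collapse = ","), format(x)))
  invisible(x)
}

#' @export
`==.community_state` <- function(e1, e2) {
  identical(e1$strain_order, e2$strain_order) && identical(e1$bits, e2$bits)
}

#' Predict the community-level signaling state for a signal mixture
#'
#' For each strain, the tester's LacZ fold change is simulated under the
#' effective concentration `sum_j w[i, j] * c_j` (clamped at 0) of the full
#' signal mixture, and compared with that strain's activation threshold. Each
#' bit is computed from an independent tester run, mirroring the parallel
#' single-tester experiments. The model is a fully connected single-layer
#' network: bits interact only through the weighted sum of signal inputs.
#'
#' @param strains strain parameter table (one row per community member).
#' @param W crosstalk weight matrix over the same strains.
#' @param mixture a [signal_mixture()] of supernatant volumes.
#' @param env simulation environment.
#' @return A [community_state()]; its `"fold"` and `"threshold"` attributes
#'   carry the per-strain fold changes and thresholds.
#' @export
predict_state <- function(strains, W, mixture, env = qs_env()) {
  strains <- validate_strains(strains)
  W <- weight_matrix(W)
  if (nrow(W) != nrow(strains))
    stop("weight matrix dimensions do not match the number of strains")
  if (!identical(rownames(W), strains$strain))
    W <- W[strains$strain, strains$strain, drop = FALSE]
  conc <- mixture_concentrations(mixture, strains$strain)
  k <- nrow(strains)
  fold <- thr <- numeric(k)
  for (i in seq_len(k)) {
    ceff <- effective_concentration(W[i, ], conc)
    fold[i] <- fold_const(strains[i, , drop = FALSE], ceff, env)
    thr[i] <- activation_threshold(strains[i, , drop = FALSE], env)
  }
  out <- community_state(fold >= thr, strains$strain)
  attr(out, "fold") <- setNames(fold, strains$strain)
  attr(out, "threshold") <- setNames(thr, strains$strain)
  out
}

#' Scan community states along a one-signal ramp
#'
#' Holds all but one supernatant volume fixed and evaluates the predicted
#' community state at each level of the varied signal, counting how many times
#' the state changes between adjacent levels.
#'
#' @param strains,W,env as in [predict_state()].
#' @param base_mixture the [signal_mixture()] of fixed volumes.
#' @param varied label of the strain whose supernatant volume is ramped.
#' @param levels volumes (uL) of the varied supernatant.
#' @return An object of class `transition_scan`: `levels`, the list of
#'   `states`, their string forms and `n_transitions`.
#' @export
transition_scan <- function(strains, W, base_mixture, varied,
                            levels = seq(0, 25, by = 5), env = qs_env()) {
  stopifnot(inherits(base_mixture, "signal_mixture"))
  other <- base_mixture$volumes[setdiff(names(base_mixture$volumes), varied)]
  if (any(levels < 0) || any(sum(other) + levels > base_mixture$total_volume))
    stop("levels must keep the total volume within the assay volume")
  states <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    vols <- c(other, setNames(levels[i], varied))
    mix <- signal_mixture(vols, total_volume = base_mixture$total_volume,
                          stock_conc = base_mixture$stock_conc)
    states[[i]] <- predict_state(strains, W, mix, env)
  }
  strings <- vapply(states, format, character(1))
  structure(list(levels = levels, states = states, strings = strings,
                 varied = varied,
                 n_transitions = sum(strings[-1] != strings[-length(strings)])),
            class = "transition_scan")
}

#' @export
print.transition_scan <- function(x, ...) {
  cat(sprintf("Community-state scan over %s (%d transitions):\n",
              x$varied, x$n_transitions))
  print(data.frame(volume_ul = x$levels, state = x$strings))
  invisible(x)
}
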