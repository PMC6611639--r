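#' Default kinetic and regulatory constants
#'
#' Rate constants shared by all strains unless overridden. `f` and `theta` are
#' strain specific and have no global default. Values are calibrated so that a
#' lone producer inoculated at 1e6 cells/mL accumulates roughly 30 nM of
#' signal after 10 h of growth, the working concentration of ComX in
#' stationary-phase supernatant, and so that basal LacZ expression is
#' detectable; see the package vignette for the calibration.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{m}{Hill coefficient (dimensionless).}
#'   \item{rho_L}{basal LacZ production rate, LacZ-units·mL·cell^-1·min^-1.}
#'   \item{gamma_L}{LacZ degradation rate, min^-1.}
#'   \item{rho_c}{basal signal production rate, nM·mL·cell^-1·min^-1.}
#'   \item{gamma_c}{signal degradation rate, min^-1.}
#'   \item{mu}{growth rate, h^-1.}
#' }
#' @export
qs_defaults <- function() {
  list(m = 2, rho_L = 1e-9, gamma_L = 0.01,
       rho_c = 2.6e-11, gamma_c = 0.005, mu = 2)
}

#' Construct a strain parameter table
#'
#' One row per strain. `f` is the fold increase in LacZ (and signal) production
#' upon full QS activation; `theta` is the effective signal concentration of
#' half-maximal activation in nM.
#'
#' @param strain character vector of strain labels.
#' @param f QS fold-change multiplier (> 0), recycled.
#' @param theta half-max effective signal concentration in nM (> 0), recycled.
#' @param m Hill coefficient.
#' @param rho_L basal LacZ production rate per cell per minute.
#' @param gamma_L LacZ degradation rate, min^-1.
#' @param rho_c basal signal production rate per cell per minute (nM scale).
#' @param gamma_c signal degradation rate, min^-1.
#' @param mu growth rate, h^-1.
#' @return A `data.frame` with columns
#'   `strain,f,theta,m,rho_L,gamma_L,rho_c,gamma_c,mu`.
#' @export
strain_params <- function(strain, f, theta,
                          m = qs_defaults()$m,
                          rho_L = qs_defaults()$rho_L,
                          gamma_L = qs_defaults()$gamma_L,
                          rho_c = qs_defaults()$rho_c,
                          gamma_c = qs_defaults()$gamma_c,
                          mu = qs_defaults()$mu) {
  out <- data.frame(strain = as.character(strain), f = f, theta = theta,
                    m = m, rho_L = rho_L, gamma_L = gamma_L,
                    rho_c = rho_c, gamma_c = gamma_c, mu = mu,
                    stringsAsFactors = FALSE)
  validate_strains(out)
}

#' Validate a strain parameter table
#'
#' @param strains a data.frame as returned by [strain_params()].
#' @return The validated table (invisibly unchanged).
#' @export
validate_strains <- function(strains) {
  req <- c("strain", "f", "theta", "m", "rho_L", "gamma_L",
           "rho_c", "gamma_c", "mu")
  missing <- setdiff(req, names(strains))
  if (length(missing))
    stop("strain table is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(strains$strain))
    stop("duplicated strain labels in strain table")
  with(strains, {
    if (any(f < 0)) stop("f must be >= 0")
    if (any(theta <= 0)) stop("theta must be > 0")
    if (any(m <= 0)) stop("m must be > 0")
    if (any(c(rho_L, gamma_L, rho_c, gamma_c) < 0)) stop("rates must be >= 0")
    if (any(mu < 0)) stop("mu must be >= 0")
  })
  strains
}

#' Reference parameter set for the five ComX-variant strains
#'
#' The five near-isogenic \emph{Bacillus subtilis} strains A-E, each producing
#' and sensing a distinct chemical variant of the ComX quorum-sensing peptide.
#' `f` and `theta` are the best-fit dose-response parameters of each tester
#' strain (fold change of LacZ at saturation minus one, and half-max signal
#' concentration); the rate constants are the package defaults.
#'
#' @param ids optional subset of strain labels to return.
#' @return A strain parameter table, see [strain_params()].
#' @examples
#' qs_strains()
#' qs_strains("C")
#' @export
qs_strains <- function(ids = NULL) {
  tab <- strain_params(strain = c("A", "B", "C", "D", "E"),
                       f = c(5.955, 4.083, 24.839, 8.345, 6.951),
                       theta = c(1.393, 1.633, 1.364, 1.394, 1.815))
  if (!is.null(ids)) {
    if (!all(ids %in% tab$strain))
      stop("unknown strain id(s): ", paste(setdiff(ids, tab$strain), collapse = ", "))
    tab <- tab[match(ids, tab$strain), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Construct and validate a crosstalk weight matrix
#'
#' Entry `w[i, j]` is the signed weight with which the signal of strain `j`
#' contributes to the effective signal concentration sensed by strain `i`.
#' Self-weights (the diagonal) are always 1; off-diagonal weights may take any
#' sign, positive for excitatory and negative for inhibitory crosstalk.
#'
#' @param w a square numeric matrix with unit diagonal.
#' @param strain_order optional character vector of labels for rows/columns;
#'   defaults to existing dimnames.
#' @return The validated matrix with dimnames set.
#' @export
weight_matrix <- function(w, strain_order = NULL) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (is.null(strain_order)) strain_order <- rownames(w)
  if (is.null(strain_order)) strain_order <- LETTERS[seq_len(nrow(w))]
  if (length(strain_order) != nrow(w))
    stop("strain_order length does not match weight matrix dimension")
  if (any(abs(diag(w) - 1) > 1e-12))
    stop("self-weights (the diagonal) must all be exactly 1")
  storage.mode(w) <- "double"
  dimnames(w) <- list(strain_order, strain_order)
  w
}

#' Curated crosstalk weight matrix for the five-strain ComX community
#'
#' An example weight matrix for strains A-E whose sign structure follows the
#' crosstalk network measured for the five ComX variants: strain C is activated
#' by signal from A (w = 0.445) and itself, strongly inhibited by signal from B
#' and D, and responds only weakly (and negatively) to signal from E; strain E
#' responds to no signal but its own; signal A inhibits QS in strain B while
#' signal B activates QS in strain A; and signal C inhibits strain B but
#' promotes strain A. Off-diagonal magnitudes other than w[C,A] are
#' package-chosen representative values consistent with those qualitative
#' constraints, not measured quantities.
#'
#' @return A 5 x 5 weight matrix, see [weight_matrix()].
#' @export
qs_weights <- function() {
  w <- rbind(
    A = c(1.000,  0.300, 0.400, -0.200,  0.100),
    B = c(-0.120, 1.000, -1.000, -0.300, 1.050),
    C = c(0.445, -1.500, 1.000, -2.000, -0.200),
    D = c(0.200, -0.400, 0.300,  1.000, -0.200),
    E = c(0.000,  0.000, 0.000,  0.000,  1.000))
  weight_matrix(w, c("A", "B", "C", "D", "E"))
}

#' Simulation environment parameters
#'
#' @param volume_ml culture volume in mL (a 200 uL plate well by default).
#' @param capacity carrying capacity `s`, cells/mL.
#' @param dt_min integration time step in minutes.
#' @param duration_h simulated time span in hours.
#' @param n0 initial cell density per strain, cells/mL (recycled across
#'   strains where needed).
#' @return An object of class `qs_env`.
#' @export
qs_env <- function(volume_ml = 0.2, capacity = 1e9, dt_min = 1,
                   duration_h = 10, n0 = 1e8) {
  if (volume_ml <= 0) stop("volume_ml must be > 0")
  if (capacity <= 0) stop("capacity must be > 0")
  if (dt_min <= 0) stop("dt_min must be > 0")
  if (duration_h <= 0) stop("duration_h must be > 0")
  if (any(n0 < 0)) stop("n0 must be >= 0")
  if (sum(n0) > capacity) stop("total initial density exceeds the carrying capacity")
  structure(list(volume_ml = volume_ml, capacity = capacity, dt_min = dt_min,
                 duration_h = duration_h, n0 = n0),
            class = "qs_env")
}

#' @export
print.qs_env <- function(x, ...) {
  cat("QS simulation environment\n")
  cat(sprintf("  volume: %g mL, capacity: %g cells/mL\n", x$volume_ml, x$capacity))
  cat(sprintf("  dt: %g min, duration: %g h, n0: %s cells/mL\n",
              x$dt_min, x$duration_h, paste(format(x$n0), collapse = ", ")))
  invisible(x)
}

#' A supernatant signal mixture
#'
#' Volumes of producer-strain supernatant loaded into an assay well. The
#' supernatant of a stationary-phase producer culture is assumed to carry
#' `stock_conc` (30 nM by default) of its ComX variant, so a volume `x` uL
#' diluted into a `total_volume` uL well contributes
#' `stock_conc * x / total_volume` nM of that signal.
#'
#' @param ... named per-strain volumes in uL, e.g. `A = 10, B = 4`, or a single
#'   named numeric vector.
#' @param total_volume total assay volume in uL.
#' @param stock_conc signal concentration of undiluted supernatant, nM.
#' @return An object of class `signal_mixture`.
#' @examples
#' signal_mixture(A = 10, B = 4)
#' @export
signal_mixture <- function(..., total_volume = 200, stock_conc = 30) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]])))
    volumes <- unlist(args[[1]])
  else
    volumes <- unlist(args)
  if (is.null(names(volumes)) || any(!nzchar(names(volumes))))
    stop("mixture volumes must be named by strain")
  if (any(volumes < 0)) stop("volumes must be >= 0")
  if (sum(volumes) > total_volume)
    stop("total supernatant volume exceeds the assay volume")
  if (stock_conc <= 0) stop("stock_conc must be > 0")
  structure(list(volumes = volumes, total_volume = total_volume,
                 stock_conc = stock_conc),
            class = "signal_mixture")
}

#' Parse a mixture given as a compact string
#'
#' @param x a string such as `"A=10,B=4,C=15"` (volumes in uL).
#' @inheritParams signal_mixture
#' @return A [signal_mixture()].
#' @export
parse_mixture <- function(x, total_volume = 200, stock_conc = 30) {
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  kv <- strsplit(trimws(parts), "=", fixed = TRUE)
  vols <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  names(vols) <- vapply(kv, function(p) trimws(p[1]), character(1))
  signal_mixture(vols, total_volume = total_volume, stock_conc = stock_conc)
}

#' @export
print.signal_mixture <- function(x, ...) {
  cat("Signal mixture (uL of supernatant in a", x$total_volume, "uL well):\n ")
  cat(paste(sprintf("%s=%g", names(x$volumes), x$volumes), collapse = ", "), "\n")
  invisible(x)
}

#' Concentrations contributed by a mixture, per strain
#'
#' @param mixture a [signal_mixture()].
#' @param strain_order strain labels defining the output order; strains absent
#'   from the mixture contribute 0 nM.
#' @return Named numeric vector of concentrations in nM.
#' @export
mixture_concentrations <- function(mixture, strain_order) {
  stopifnot(inherits(mixture, "signal_mixture"))
  unknown <- setdiff(names(mixture$volumes), strain_order)
  if (length(unknown))
    stop("mixture names not in strain order: ", paste(unknown, collapse = ", "))
  vols <- setNames(numeric(length(strain_order)), strain_order)
  vols[names(mixture$volumes)] <- mixture$volumes
  volume_to_concentration(vols, total_volume = mixture$total_volume,
                          stock_conc = mixture$stock_conc)
}
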