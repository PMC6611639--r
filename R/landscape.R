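#' Simulate a binary activation landscape for a signal pair
#'
#' For every combination of cognate and interacting supernatant volume, the
#' tester's LacZ fold change is simulated with effective concentration
#' `c_eff = c_cognate + w_int * c_interactor` (clamped at 0) and compared with
#' the tester's activation threshold; a cell is ON when the fold change meets
#' the threshold (ties activate).
#'
#' @param tester one-row strain parameter table of the tester.
#' @param w_int crosstalk weight of the interacting signal on the tester.
#' @param env simulation environment.
#' @param cognate_volumes,interactor_volumes grid axes in uL (strictly
#'   increasing; the default is the 6 x 6 grid of 0-25 uL in 5 uL steps).
#' @param interactor_id optional label of the interacting strain.
#' @inheritParams volume_to_concentration
#' @return An object of class `qs_landscape`: `tester_id`, `interactor_id`,
#'   the two volume axes and the logical ON matrix (rows = cognate volumes,
#'   columns = interactor volumes).
#' @export
simulate_landscape <- function(tester, w_int, env = qs_env(),
                               cognate_volumes = seq(0, 25, by = 5),
                               interactor_volumes = seq(0, 25, by = 5),
                               interactor_id = NA_character_,
                               total_volume = 200, stock_conc = 30) {
  tester <- validate_strains(tester)
  stopifnot(nrow(tester) == 1L)
  check_axis <- function(v, what) {
    if (any(diff(v) <= 0)) stop(what, " volumes must be strictly increasing")
    if (any(v < 0) || any(v > 25)) stop(what, " volumes must lie in [0, 25] uL")
  }
  check_axis(cognate_volumes, "cognate")
  check_axis(interactor_volumes, "interactor")
  c_cog <- volume_to_concentration(cognate_volumes, total_volume, stock_conc)
  c_int <- volume_to_concentration(interactor_volumes, total_volume, stock_conc)
  ceff <- pmax(0, outer(c_cog, c_int, function(a, b) a + w_int * b))
  fc <- fold_const(tester, as.vector(ceff), env)
  thr <- activation_threshold(tester, env)
  on <- matrix(fc >= thr, nrow = length(c_cog), ncol = length(c_int))
  structure(list(tester_id = tester$strain, interactor_id = interactor_id,
                 cognate_volumes = cognate_volumes,
                 interactor_volumes = interactor_volumes, on = on,
                 total_volume = total_volume, stock_conc = stock_conc),
            class = "qs_landscape")
}

#' @export
print.qs_landscape <- function(x, ...) {
  cat(sprintf("Activation landscape of tester %s vs interactor %s (1 = QS ON)\n",
              x$tester_id, x$interactor_id))
  m <- matrix(as.integer(x$on), nrow = nrow(x$on),
              dimnames = list(cognate_ul = x$cognate_volumes,
                              interactor_ul = x$interactor_volumes))
  print(m)
  invisible(x)
}

#' Count differing cells between two activation landscapes
#'
#' @param a,b `qs_landscape` objects on identical axes.
#' @return Integer number of grid cells whose ON/OFF value differs.
#' @export
landscape_mismatch <- function(a, b) {
  stopifnot(inherits(a, "qs_landscape"), inherits(b, "qs_landscape"))
  if (!isTRUE(all.equal(a$cognate_volumes, b$cognate_volumes)) ||
      !isTRUE(all.equal(a$interactor_volumes, b$interactor_volumes)))
    stop("landscape axes do not match")
  sum(xor(a$on, b$on))
}

#' Invert an observed activation landscape into a crosstalk-weight interval
#'
#' Scans a grid of candidate weights and returns the set of weights whose
#' simulated landscape reproduces the observed one (exactly by default, or up
#' to `tol_mismatch` differing cells). Because the weight enters the effective
#' concentration linearly and the simulated fold change is monotone in it, each
#' grid cell switches ON at a single critical weight; the critical weight of
#' every cell is located by bisection over the scan grid with the same
#' simulator used by [simulate_landscape()], and the compatible set is then
#' read off cell-interval intersections. The result is identical to brute-force
#' scanning every candidate weight.
#'
#' @param observed a `qs_landscape` (e.g. measured, or from [gen_landscape()]).
#' @param tester one-row strain parameter table of the tester.
#' @param env simulation environment.
#' @param scan_lo,scan_hi,scan_step the scanned weight grid
#'   `seq(scan_lo, scan_hi, by = scan_step)`.
#' @param tol_mismatch number of cells allowed to differ (0 = exact equality).
#' @return An object of class `weight_estimate`: `w_mean`, `w_lo`, `w_hi`,
#'   `compatible_count`, plus the scan settings.
#' @export
extract_weight <- function(observed, tester, env = qs_env(),
                           scan_lo = -3, scan_hi = 3, scan_step = 0.001,
                           tol_mismatch = 0) {
  stopifnot(inherits(observed, "qs_landscape"))
  tester <- validate_strains(tester)
  stopifnot(nrow(tester) == 1L)
  if (scan_lo >= scan_hi) stop("scan_lo must be < scan_hi")
  if (scan_step <= 0) stop("scan_step must be > 0")
  grid <- seq(scan_lo, scan_hi, by = scan_step)
  M <- length(grid)
  c_cog <- volume_to_concentration(observed$cognate_volumes,
                                   observed$total_volume, observed$stock_conc)
  c_int <- volume_to_concentration(observed$interactor_volumes,
                                   observed$total_volume, observed$stock_conc)
  thr <- activation_threshold(tester, env)
  cells <- expand.grid(ci = seq_along(c_cog), cj = seq_along(c_int))
  cc <- c_cog[cells$ci]
  ii <- c_int[cells$cj]
  obs <- as.vector(observed$on)

  ncell <- length(cc)
  on_at <- function(idx, w) { # batched: cells idx at per-cell weights w
    fold_const(tester, pmax(0, cc[idx] + w * ii[idx]), env) >= thr
  }
  # cells with c_int = 0 never depend on w
  fixed <- ii == 0
  on_fixed <- rep(NA, ncell)
  if (any(fixed)) on_fixed[fixed] <- on_at(which(fixed), 0)

  # first_on[k]: smallest scan index at which cell k is ON (M + 1 = never);
  # ON is a non-decreasing step in w, located by vectorised bisection with
  # one batched simulator call per round
  first_on <- rep(NA_integer_, ncell)
  free <- which(!fixed)
  on_first <- on_at(free, grid[1])
  on_last <- on_at(free, grid[M])
  first_on[free[on_first]] <- 1L
  first_on[free[!on_last]] <- M + 1L
  active <- free[!on_first & on_last]
  lo <- rep(2L, ncell); hi <- rep(M, ncell)
  while (length(active)) {
    mid <- (lo[active] + hi[active]) %/% 2L
    on_mid <- on_at(active, grid[mid])
    hi[active[on_mid]] <- mid[on_mid]
    lo[active[!on_mid]] <- mid[!on_mid] + 1L
    done <- lo[active] >= hi[active]
    first_on[active[done]] <- lo[active[done]]
    active <- active[!done]
  }

  # mismatch count per scanned weight, accumulated as a difference array
  dmis <- integer(M + 1L)
  add_range <- function(l, r) { # mismatch on scan indices l..r
    if (l > r) return()
    dmis[l] <<- dmis[l] + 1L
    dmis[r + 1L] <<- dmis[r + 1L] - 1L
  }
  for (k in seq_len(ncell)) {
    if (fixed[k]) {
      if (xor(on_fixed[k], obs[k])) add_range(1L, M)
    } else if (obs[k]) {
      add_range(1L, first_on[k] - 1L) # simulated OFF below first_on
    } else {
      add_range(min(first_on[k], M + 1L), M) # simulated ON from first_on up
    }
  }
  mismatches <- cumsum(dmis[seq_len(M)])
  compatible <- which(mismatches <= tol_mismatch)
  if (!length(compatible))
    stop("no compatible weight: the observed landscape cannot be produced ",
         "by any scanned weight")
  w_vals <- grid[compatible]
  structure(list(w_lo = min(w_vals), w_hi = max(w_vals),
                 w_mean = (min(w_vals) + max(w_vals)) / 2,
                 compatible_count = length(compatible),
                 contiguous = all(diff(compatible) == 1L),
                 scan_lo = scan_lo, scan_hi = scan_hi, scan_step = scan_step,
                 tol_mismatch = tol_mismatch),
            class = "weight_estimate")
}

#' @export
print.weight_estimate <- function(x, ...) {
  cat(sprintf("Crosstalk weight estimate: %.3f (range %.3f to %.3f, %d compatible values)\n",
              x$w_mean, x$w_lo, x$w_hi, x$compatible_count))
  if (!x$contiguous) cat("  note: the compatible set is not contiguous\n")
  invisible(x)
}

#' Write / read an activation landscape as CSV
#'
#' The CSV has the interactor volumes as the header row, the cognate volumes
#' as the first column, and cells in {0, 1}.
#'
#' @param x a `qs_landscape`.
#' @param path file path.
#' @return `write_landscape` returns `path` invisibly; `read_landscape`
#'   returns a `qs_landscape`.
#' @export
write_landscape <- function(x, path) {
  stopifnot(inherits(x, "qs_landscape"))
  m <- matrix(as.integer(x$on), nrow = nrow(x$on))
  df <- data.frame(cognate_ul = x$cognate_volumes, m)
  names(df) <- c("cognate_ul", x$interactor_volumes)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @param tester_id,interactor_id strain labels to attach on reading.
#' @export
read_landscape <- function(path, tester_id = NA_character_,
                           interactor_id = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  cog <- df[[1]]
  int <- as.numeric(names(df)[-1])
  on <- as.matrix(df[, -1, drop = FALSE]) != 0
  dimnames(on) <- NULL
  structure(list(tester_id = tester_id, interactor_id = interactor_id,
                 cognate_volumes = cog, interactor_volumes = int, on = on,
                 total_volume = 200, stock_conc = 30),
            class = "qs_landscape")
}
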