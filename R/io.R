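#' Read / write strain parameter tables as CSV
#'
#' The CSV has the header `strain,f,theta,m,rho_L,gamma_L,rho_c,gamma_c,mu`.
#'
#' @param path file path.
#' @return `read_strains` returns a validated strain table; `write_strains`
#'   returns `path` invisibly.
#' @export
read_strains <- function(path) {
  validate_strains(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_strains
#' @param strains a strain parameter table.
#' @export
write_strains <- function(strains, path) {
  utils::write.csv(validate_strains(strains), path, row.names = FALSE)
  invisible(path)
}

#' Read / write crosstalk weight matrices as CSV
#'
#' First row and first column carry the strain labels; the diagonal must be 1.
#'
#' @param path file path.
#' @return `read_weights` returns a validated [weight_matrix()];
#'   `write_weights` returns `path` invisibly.
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  weight_matrix(as.matrix(df), rownames(df))
}

#' @rdname read_weights
#' @param W a weight matrix.
#' @export
write_weights <- function(W, path) {
  W <- weight_matrix(W)
  utils::write.csv(as.data.frame(W), path, row.names = TRUE)
  invisible(path)
}

#' Write a simulation as tidy CSV
#'
#' Long format with columns `time_min, variable, strain, value`.
#'
#' @param sim a `qs_sim`.
#' @param path file path.
#' @export
write_sim <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}
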