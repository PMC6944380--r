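#' Spectral norm of a matrix
#'
#' Largest singular value, the matrix analogue of the vector L2 norm used
#' throughout the error metrics (reaching error over a movement window,
#' inverse-model error, forward-model error).
#'
#' @param x A numeric matrix (or a vector, treated as a single column).
#' @return A single non-negative number.
#' @examples
#' spectral_norm(diag(c(3, 1)))  # 3
#' @export
spectral_norm <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  stopifnot(is.numeric(x))
  if (!all(is.finite(x))) stop("spectral_norm(): non-finite entries", call. = FALSE)
  if (all(x == 0)) return(0)
  svd(x, nu = 0, nv = 0)$d[1]
}

# Derive a child seed from a master seed; stays within 32-bit integer range.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 7919) %% 2147483647)
}

# internal: assert a numeric matrix with given dims
check_matrix <- function(x, nrow = NULL, ncol = NULL, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` has non-finite entries", name), call. = FALSE)
  if (!is.null(nrow) && nrow(x) != nrow)
    stop(sprintf("`%s` must have %d rows", name, nrow), call. = FALSE)
  if (!is.null(ncol) && ncol(x) != ncol)
    stop(sprintf("`%s` must have %d columns", name, ncol), call. = FALSE)
  invisible(x)
}
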