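#' Calibration set of body-signal samples
#'
#' Wraps an S x M matrix of body-signal samples recorded while the user moves
#' freely ("motor babbling"), the raw material from which the interface map is
#' calibrated. Rows are signal channels, columns are time samples.
#'
#' @param signals Numeric S x M matrix, M > S.
#' @param sample_rate Sampling rate in samples per second.
#' @return An object of class `bomi_calibration`.
#' @export
calibration_set <- function(signals, sample_rate = 75) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("`signals` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(signals))) stop("`signals` has non-finite values", call. = FALSE)
  if (ncol(signals) <= nrow(signals))
    stop("need more samples than channels (M > S)", call. = FALSE)
  if (nrow(signals) < 1L) stop("need at least one channel", call. = FALSE)
  stopifnot(is.numeric(sample_rate), sample_rate > 0)
  structure(list(signals = signals, sample_rate = sample_rate),
            class = "bomi_calibration")
}

#' @export
print.bomi_calibration <- function(x, ...) {
  cat(sprintf("<bomi_calibration> %d channels x %d samples @ %g Hz\n",
              nrow(x$signals), ncol(x$signals), x$sample_rate))
  invisible(x)
}

new_interface_map <- function(H, origin, variance_share, eigenvalues = NULL) {
  structure(list(H = H, origin = origin, variance_share = variance_share,
                 eigenvalues = eigenvalues),
            class = "bomi_map")
}

#' Build the body-to-cursor interface map by principal component analysis
#'
#' The interface is a fixed linear map p = H q + origin from the S-dimensional
#' body-signal vector q to the K-dimensional cursor position p. The rows of H
#' are the K leading eigenvectors of the covariance of the calibration
#' signals, so the cursor responds to the user's dominant movement
#' combinations. The signal mean is folded into the origin, so the average
#' babbling posture maps to the workspace center.
#'
#' Eigenvector sign is fixed by flipping each row so its largest-magnitude
#' component is positive (PCA sign is otherwise arbitrary).
#'
#' @param cal A [calibration_set()].
#' @param K Number of retained components (cursor dimensions), K < S.
#' @return A `bomi_map` with elements `H` (K x S), `origin` (length K; maps
#'   the mean posture to zero), `variance_share` (fraction of total variance
#'   captured by the K retained components) and `eigenvalues` (all S).
#' @export
build_map_pca <- function(cal, K = 2) {
  stopifnot(inherits(cal, "bomi_calibration"))
  S <- nrow(cal$signals)
  if (K >= S) stop("K must be smaller than the number of channels", call. = FALSE)
  X <- cal$signals
  mu <- rowMeans(X)
  Xc <- X - mu
  covm <- tcrossprod(Xc) / (ncol(X) - 1)
  total <- sum(diag(covm))
  if (total <= 0 || !all(is.finite(covm)))
    stop("degenerate calibration: zero total variance", call. = FALSE)
  eg <- eigen(covm, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  H <- t(eg$vectors[, seq_len(K), drop = FALSE])
  # deterministic sign: largest-magnitude component of each row positive
  for (k in seq_len(K)) {
    j <- which.max(abs(H[k, ]))
    if (H[k, j] < 0) H[k, ] <- -H[k, ]
  }
  new_interface_map(H, origin = as.numeric(-H %*% mu),
                    variance_share = sum(vals[seq_len(K)]) / sum(vals),
                    eigenvalues = vals)
}

#' Adjust workspace origin, orientation and scaling of an interface map
#'
#' Emulates the customization step in which the task frame is matched to the
#' display: the map is rotated, scaled, and given a new origin. The cursor
#' position is p = H q + origin.
#'
#' @param map A `bomi_map`.
#' @param rotation Rotation angle in radians (counterclockwise, K = 2 only).
#' @param scale Positive scale factor applied to H.
#' @param origin New origin (length-K, cm); defaults to the map's current one.
#' @return The adjusted `bomi_map`.
#' @export
adjust_map <- function(map, rotation = 0, scale = 1, origin = NULL) {
  stopifnot(inherits(map, "bomi_map"), scale > 0)
  H <- map$H
  if (rotation != 0) {
    if (nrow(H) != 2) stop("rotation is defined for K = 2 maps", call. = FALSE)
    R <- rbind(c(cos(rotation), -sin(rotation)),
               c(sin(rotation),  cos(rotation)))
    H <- R %*% H
  }
  H <- scale * H
  map$H <- H
  if (!is.null(origin)) {
    stopifnot(length(origin) == nrow(H))
    map$origin <- as.numeric(origin)
  }
  map
}

#' Rescale an interface map to a target spectral norm
#'
#' The workspace gain ‖H‖ sets the body-signal excursion needed to cross the
#' workspace and thereby the effective per-trial rate of inverse-model
#' learning. The default, ‖H‖ = sqrt(2)/5 cm per signal unit, makes the
#' fitted exponential decay rate of the reaching error equal to the
#' inverse-model learning rate eta for targets 5 cm from the origin with
#' K = 2 (see the methods vignette for the derivation).
#'
#' @param map A `bomi_map`.
#' @param target_norm Desired spectral norm of H (cm per signal unit).
#' @return The rescaled `bomi_map`.
#' @export
normalize_workspace <- function(map, target_norm = sqrt(2) / 5) {
  stopifnot(inherits(map, "bomi_map"), target_norm > 0)
  nrm <- spectral_norm(map$H)
  if (nrm == 0) stop("cannot normalize a zero map", call. = FALSE)
  map$H <- map$H * (target_norm / nrm)
  map
}

#' @export
print.bomi_map <- function(x, ...) {
  cat(sprintf("<bomi_map> K=%d x S=%d, ||H|| = %.4g, variance share = %.3f\n",
              nrow(x$H), ncol(x$H), spectral_norm(x$H), x$variance_share))
  invisible(x)
}

#' Serialize / restore an interface map as JSON
#'
#' @param map A `bomi_map`.
#' @param path File path.
#' @return `write_map_json()` returns `path` invisibly; `read_map_json()`
#'   returns the `bomi_map`.
#' @export
write_map_json <- function(map, path) {
  stopifnot(inherits(map, "bomi_map"))
  obj <- list(K = nrow(map$H), S = ncol(map$H),
              H = as.numeric(t(map$H)),  # row-major
              origin = map$origin,
              variance_share = map$variance_share,
              eigenvalues = map$eigenvalues)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map_json
#' @export
read_map_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- matrix(obj$H, nrow = obj$K, byrow = TRUE)
  new_interface_map(H, origin = obj$origin,
                    variance_share = obj$variance_share,
                    eigenvalues = obj$eigenvalues)
}

#' Read/write a calibration set as CSV (+ JSON sidecar for the sample rate)
#'
#' One row per sample, one column per channel (`q1`, `q2`, ...).
#'
#' @param cal A [calibration_set()].
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `write_calibration_csv()` returns `path` invisibly;
#'   `read_calibration_csv()` returns the [calibration_set()].
#' @export
write_calibration_csv <- function(cal, path) {
  stopifnot(inherits(cal, "bomi_calibration"))
  df <- as.data.frame(t(cal$signals))
  names(df) <- paste0("q", seq_len(nrow(cal$signals)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(sample_rate = cal$sample_rate),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  calibration_set(t(as.matrix(df)), sample_rate = meta$sample_rate)
}
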