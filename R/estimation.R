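#' Least-squares estimation of the inverse model from a movement window
#'
#' Solves Q ~ G U in the least-squares sense: G = Q U^T (U U^T)^-1, where Q
#' (S x r) collects the body vectors and U (K x r) the targets of the r
#' trials in a movement set. If U U^T is numerically rank deficient
#' (condition number above `cond_tol`) the solve either errors or, with
#' `fallback = TRUE`, falls back to the Moore-Penrose pseudo-inverse with a
#' warning.
#'
#' @param Q S x r matrix of body vectors (columns are trials).
#' @param U K x r matrix of targets (columns aligned with Q).
#' @param cond_tol Condition-number threshold for U U^T.
#' @param fallback Use the pseudo-inverse instead of erroring on
#'   rank-deficient windows.
#' @return The estimated S x K inverse model.
#' @export
estimate_inverse <- function(Q, U, cond_tol = 1e12, fallback = FALSE) {
  stopifnot(is.matrix(Q), is.matrix(U), ncol(Q) == ncol(U))
  UUt <- U %*% t(U)
  d <- svd(UUt, nu = 0, nv = 0)$d
  if (d[length(d)] <= 0 || d[1] / d[length(d)] > cond_tol) {
    if (!fallback)
      stop(sprintf("rank-deficient target window (condition number %.3g)",
                   if (d[length(d)] > 0) d[1] / d[length(d)] else Inf),
           call. = FALSE)
    warning("rank-deficient target window; using pseudo-inverse", call. = FALSE)
    sv <- svd(U)
    keep <- sv$d > sv$d[1] * 1e-12
    Uplus <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
    return(Q %*% Uplus)
  }
  Q %*% t(U) %*% solve(UUt)
}

#' Windowed reaching error
#'
#' The movement-set reaching error is the spectral norm of
#' E = H Q - U, the K x r matrix whose columns are the per-trial reaching
#' errors of the window.
#'
#' @param map A `bomi_map`.
#' @param Q,U Window matrices as in [estimate_inverse()].
#' @return Non-negative scalar (cm).
#' @export
reaching_error <- function(map, Q, U) {
  stopifnot(inherits(map, "bomi_map"))
  spectral_norm(map$H %*% Q - U)
}

#' Inverse model error
#'
#' IME = ‖H G - I_K‖ (spectral norm): how far G is from a right inverse of
#' the interface map. 0 for an exact right inverse; 1 for G = 0.
#'
#' @param map A `bomi_map`.
#' @param G S x K inverse model.
#' @return Non-negative scalar (unitless).
#' @export
inverse_model_error <- function(map, G) {
  stopifnot(inherits(map, "bomi_map"))
  spectral_norm(map$H %*% G - diag(nrow(map$H)))
}

#' Relative change between consecutive inverse-model estimates
#'
#' ‖G_n - G_prev‖ / ‖G_prev‖ (spectral norms). The `denominator` flag
#' switches the normalization to the current estimate ‖G_n‖.
#'
#' @param G_n,G_prev Consecutive S x K estimates.
#' @param denominator `"prev"` (default) or `"current"`.
#' @return Non-negative scalar.
#' @export
delta_G <- function(G_n, G_prev, denominator = c("prev", "current")) {
  denominator <- match.arg(denominator)
  stopifnot(all(dim(G_n) == dim(G_prev)))
  den <- spectral_norm(if (denominator == "prev") G_prev else G_n)
  if (den == 0) stop("delta_G(): zero denominator norm", call. = FALSE)
  spectral_norm(G_n - G_prev) / den
}

#' Forward model error
#'
#' FME = ‖H - H_hat‖ / ‖H‖ (spectral norms): the normalized distance of the
#' learner's forward estimate from the true interface map.
#'
#' @param map A `bomi_map`.
#' @param H_hat K x S forward estimate.
#' @return Non-negative scalar (unitless).
#' @export
forward_model_error <- function(map, H_hat) {
  stopifnot(inherits(map, "bomi_map"))
  nH <- spectral_norm(map$H)
  if (nH == 0) stop("forward_model_error(): zero interface map", call. = FALSE)
  spectral_norm(map$H - H_hat) / nH
}

#' Prediction error
#'
#' PE = ‖p - H_hat q‖: distance between the observed cursor position and the
#' position predicted by the forward estimate from the executed body vector.
#'
#' @param p Observed cursor position (length K).
#' @param H_hat K x S forward estimate.
#' @param q Executed body vector (length S).
#' @return Non-negative scalar (cm).
#' @export
prediction_error <- function(p, H_hat, q) {
  sqrt(sum((p - as.numeric(H_hat %*% q))^2))
}

#' Learning curves from a session
#'
#' Computes the windowed, data-derived curves (what an experimenter can
#' extract from a trial log) and, when state snapshots are available, the
#' model-truth curves:
#' \describe{
#'   \item{re}{windowed reaching error; spectral norm of H Q - U by default
#'     (`re_variant = "windowed-spectral"`), or the window mean of the
#'     per-trial L2 error norms (`"per-trial-l2"`).}
#'   \item{ime}{spectral norm of H G_est - I with G_est the moving-window
#'     least-squares estimate of the inverse model.}
#'   \item{dg}{relative change of consecutive G_est (see [delta_G()]).}
#'   \item{ime_model, fme, pe}{from the recorded learner state: inverse
#'     model error of the internal G, forward model error of H_hat, and the
#'     per-trial prediction error.}
#' }
#'
#' @param session A `bomi_session` (or a trial-log tibble plus `map`).
#' @param map Required if `session` is a bare log tibble.
#' @param r Window length (trials).
#' @param re_variant Reaching-error definition for `re`.
#' @param dg_denominator Normalization for `dg`, see [delta_G()].
#' @return A `bomi_curves` tibble with one row per window end `n >= r`.
#' @export
learning_curves <- function(session, map = NULL, r = 12,
                            re_variant = c("windowed-spectral", "per-trial-l2"),
                            dg_denominator = c("prev", "current")) {
  re_variant <- match.arg(re_variant)
  dg_denominator <- match.arg(dg_denominator)
  if (inherits(session, "bomi_session")) {
    log <- session$log
    map <- session$map
    states <- session$states
    if ("phase" %in% names(log)) {
      keep <- log$phase == 2
      log <- log[keep, , drop = FALSE]
      if (!is.null(states))
        states <- list(H_hat = states$H_hat[, , keep, drop = FALSE],
                       G = states$G[, , keep, drop = FALSE])
    }
  } else {
    log <- session
    states <- NULL
    if (is.null(map)) stop("`map` is required with a bare trial log", call. = FALSE)
  }
  S <- sum(grepl("^q[0-9]+$", names(log)))
  Qall <- t(as.matrix(log[, paste0("q", seq_len(S))]))
  Uall <- t(as.matrix(log[, c("u_x", "u_y")]))
  ntr <- nrow(log)
  if (ntr < r) stop("fewer trials than the window length", call. = FALSE)
  ends <- r:ntr
  re <- ime <- dg <- rep(NA_real_, length(ends))
  G_prev <- NULL
  for (i in seq_along(ends)) {
    idx <- (ends[i] - r + 1):ends[i]
    Q <- Qall[, idx, drop = FALSE]; U <- Uall[, idx, drop = FALSE]
    re[i] <- if (re_variant == "windowed-spectral") reaching_error(map, Q, U)
             else mean(log$e_norm[idx])
    G_est <- estimate_inverse(Q, U, fallback = TRUE)
    ime[i] <- inverse_model_error(map, G_est)
    if (!is.null(G_prev)) dg[i] <- delta_G(G_est, G_prev, dg_denominator)
    G_prev <- G_est
  }
  out <- tibble::tibble(n = log$n[ends], re = re, ime = ime, dg = dg)
  if (!is.null(states)) {
    out$ime_model <- vapply(ends, function(n)
      inverse_model_error(map, states$G[, , n]), 0)
    out$fme <- vapply(ends, function(n)
      forward_model_error(map, states$H_hat[, , n]), 0)
    out$pe <- log$pe[ends]
  }
  class(out) <- c("bomi_curves", class(out))
  attr(out, "r") <- r
  attr(out, "re_variant") <- re_variant
  out
}

#' Coefficient of determination
#'
#' R^2 = 1 - SSres/SStot with SStot the total sum of squares of `y` about
#' its mean and SSres the residual sum of squares against `y_hat`. Can be
#' negative when the prediction is worse than the mean.
#'
#' @param y Observed series.
#' @param y_hat Predicted series (same length).
#' @return A scalar, at most 1.
#' @export
r_squared <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop("r_squared(): constant observed series", call. = FALSE)
  1 - sum((y - y_hat)^2) / sstot
}

#' Fit an exponential learning curve
#'
#' Fits y(n) = a exp(-lambda n) + c by bounded nonlinear least squares
#' (a, lambda, c >= 0). The decay rate lambda (1/trial) is the learning
#' rate read off a reaching-error or inverse-model-error curve. Start
#' values: a0 = y[1] - y[end], c0 = y[end], lambda0 = 2/N.
#'
#' @param y Non-negative series (e.g. a windowed error curve).
#' @param n Trial indices (defaults to `seq_along(y)`; pass the curve's `n`
#'   column so rates are per trial).
#' @return A `bomi_expfit` with elements `a`, `lambda`, `c`, `r2`, `se`
#'   (named standard errors) and the underlying `fit`. `tidy()` and
#'   `glance()` methods are provided.
#' @export
fit_exponential <- function(y, n = seq_along(y)) {
  stopifnot(length(y) >= 10, all(is.finite(y)), all(y >= -1e-12))
  if (max(y) - min(y) < 1e-12) {
    # constant series: amplitude degenerate, lambda unidentifiable
    out <- structure(list(a = 0, lambda = NA_real_, c = mean(y), r2 = NA_real_,
                          se = c(a = NA, lambda = NA, c = NA),
                          degenerate = TRUE, fit = NULL),
                     class = "bomi_expfit")
    return(out)
  }
  df <- data.frame(n = n, y = y)
  start <- list(a = max(y[1] - y[length(y)], 1e-3),
                lambda = 2 / length(y),
                c = max(y[length(y)], 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-lambda * n) + c, data = df, start = start,
                      lower = c(0, 0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("exponential fit failed to converge: ", conditionMessage(e),
           call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(a = NA, lambda = NA, c = NA))
  structure(list(a = unname(cf["a"]), lambda = unname(cf["lambda"]),
                 c = unname(cf["c"]),
                 r2 = r_squared(y, stats::fitted(fit)),
                 se = se, degenerate = unname(cf["a"]) < 1e-10, fit = fit,
                 data = df),
            class = "bomi_expfit")
}

#' @export
print.bomi_expfit <- function(x, ...) {
  cat(sprintf("<bomi_expfit> y = a exp(-lambda n) + c: a=%.4g lambda=%.4g c=%.4g R2=%.3f%s\n",
              x$a, x$lambda, x$c, x$r2,
              if (isTRUE(x$degenerate)) " [degenerate amplitude]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.bomi_expfit <- function(x, ...) {
  tibble::tibble(term = c("a", "lambda", "c"),
                 estimate = c(x$a, x$lambda, x$c),
                 std.error = as.numeric(x$se[c("a", "lambda", "c")]))
}

#' @importFrom generics glance
#' @export
glance.bomi_expfit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, lambda = x$lambda,
                 degenerate = isTRUE(x$degenerate),
                 nobs = if (is.null(x$data)) NA_integer_ else nrow(x$data))
}

#' Select (epsilon, sigma) by minimizing the summed forward-model error
#'
#' Given a subject's interface map, target sequence and inverse learning
#' rate eta, searches the (epsilon, sigma) box for the pair minimizing the
#' cost C = sum_n ‖H - H_hat(n)‖ / ‖H‖, where H_hat(n) is produced by
#' free-running simulations of the learning dynamics on the same target
#' sequence. C is averaged over a fixed set of noise seeds to tame
#' stochasticity, and minimized by Nelder-Mead restarted from a coarse grid
#' of starting points (candidates are clamped to the box).
#'
#' Note that C is a performance functional of the model: it measures how
#' well the forward model can be learned under candidate parameters, and
#' its minimizer need not coincide with the parameters that generated a
#' particular trial log (see the identifiability discussion in the methods
#' vignette).
#'
#' @param map A `bomi_map`.
#' @param targets Target tibble (the subject's training sequence).
#' @param eta_fixed Inverse-model rate held fixed (e.g. the fitted
#'   lambda of the reaching-error curve).
#' @param box Named list with `epsilon` and `sigma` ranges.
#' @param eval_seeds Integer seeds over which C is averaged.
#' @param n_trials Trials per evaluation (defaults to the full sequence).
#' @param forward_init Forward-model initialization for the evaluation runs.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A `bomi_paramfit`: `epsilon`, `sigma`, `C`, `eval_seeds`, and
#'   the per-start `trace`. `tidy()`/`glance()` methods are provided.
#' @export
fit_model_params <- function(map, targets, eta_fixed,
                             box = list(epsilon = c(0.01, 0.5),
                                        sigma = c(0.1, 1.5)),
                             eval_seeds = 101:105,
                             n_trials = nrow(targets),
                             forward_init = "zero",
                             maxit = 80) {
  stopifnot(eta_fixed >= 0, length(eval_seeds) >= 1)
  clamp <- function(x, rng) min(max(x, rng[1]), rng[2])
  cost <- function(par) {
    eps <- clamp(par[1], box$epsilon); sig <- clamp(par[2], box$sigma)
    vals <- vapply(eval_seeds, function(sd) {
      ses <- tryCatch(
        run_session(map, targets, learner_params(eta_fixed, eps, sig, seed = sd),
                    forward_init = forward_init, n_trials = n_trials,
                    record_states = TRUE),
        error = function(e) NULL)
      if (is.null(ses)) return(NA_real_)
      mean(vapply(seq_len(n_trials), function(n)
        forward_model_error(map, ses$states$H_hat[, , n]), 0))
    }, 0)
    if (any(is.na(vals))) return(1e6)  # diverged candidate
    mean(vals)
  }
  starts <- expand.grid(
    epsilon = box$epsilon[1] + c(0.25, 0.75) * diff(box$epsilon),
    sigma = box$sigma[1] + c(0.25, 0.75) * diff(box$sigma))
  trace <- purrr::pmap_dfr(starts, function(epsilon, sigma) {
    opt <- stats::optim(c(epsilon, sigma), cost, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-4))
    tibble::tibble(start_epsilon = epsilon, start_sigma = sigma,
                   epsilon = clamp(opt$par[1], box$epsilon),
                   sigma = clamp(opt$par[2], box$sigma),
                   C = opt$value, convergence = opt$convergence)
  })
  if (all(trace$C >= 1e6))
    stop("fit_model_params(): all candidate evaluations diverged; best-so-far trace attached",
         call. = FALSE)
  best <- trace[which.min(trace$C), ]
  structure(list(epsilon = best$epsilon, sigma = best$sigma, C = best$C,
                 eta = eta_fixed, eval_seeds = eval_seeds, trace = trace,
                 n_trials = n_trials),
            class = "bomi_paramfit")
}

#' @export
print.bomi_paramfit <- function(x, ...) {
  cat(sprintf("<bomi_paramfit> epsilon=%.4g sigma=%.4g (eta fixed at %.4g), C=%.4g over %d seeds\n",
              x$epsilon, x$sigma, x$eta, x$C, length(x$eval_seeds)))
  invisible(x)
}

#' @export
tidy.bomi_paramfit <- function(x, ...) {
  tibble::tibble(term = c("epsilon", "sigma"), estimate = c(x$epsilon, x$sigma))
}

#' @export
glance.bomi_paramfit <- function(x, ...) {
  tibble::tibble(C = x$C, eta = x$eta, n_seeds = length(x$eval_seeds),
                 n_trials = x$n_trials)
}
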