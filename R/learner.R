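#' Learner parameters
#'
#' The three scalar parameters of the coupled learning dynamics:
#' `eta` is the inverse-model learning rate (per trial), `epsilon` the
#' forward-model learning rate, and `sigma` the standard deviation (body
#' signal units) of the isotropic Gaussian exploration noise added to each
#' planned body vector.
#'
#' `eta` and `epsilon` are dimensionless fractional rates. For the inverse
#' model this holds by construction of the default workspace normalization
#' (see [normalize_workspace()]); for the forward model the raw gradient step
#' applied per trial is `epsilon / q_ref^2`, where `q_ref` is the body-signal
#' scale of reaching (mean target distance divided by the workspace gain
#' ‖H‖). This makes `epsilon` invariant to the arbitrary units in which body
#' signals are expressed; the per-trial fractional reduction of the
#' prediction error along the executed movement direction is `epsilon`. If
#' `q_ref` is `NULL` it is resolved by the session driver.
#'
#' @param eta Inverse-model learning rate (>= 0).
#' @param epsilon Forward-model learning rate (>= 0, fractional).
#' @param sigma Exploration-noise SD (body units, >= 0).
#' @param seed RNG seed for the noise stream.
#' @param q_ref Optional reference body-signal scale.
#' @return A `bomi_params` list.
#' @export
learner_params <- function(eta, epsilon, sigma, seed = 1L, q_ref = NULL) {
  stopifnot(eta >= 0, epsilon >= 0, sigma >= 0)
  structure(list(eta = eta, epsilon = epsilon, sigma = sigma,
                 seed = as.integer(seed), q_ref = q_ref),
            class = "bomi_params")
}

#' Learner state
#'
#' The state of learning: the forward estimate `H_hat` (K x S) and the
#' inverse model `G` (S x K), together 2*K*S numbers (32 dimensions for
#' S = 8, K = 2), plus the trial counter.
#'
#' @param H_hat K x S forward-model estimate.
#' @param G S x K inverse model.
#' @param n Trial index (completed trials).
#' @return A `bomi_state` list.
#' @export
learner_state <- function(H_hat, G, n = 0L) {
  check_matrix(H_hat, name = "H_hat")
  check_matrix(G, nrow = ncol(H_hat), ncol = nrow(H_hat), name = "G")
  structure(list(H_hat = H_hat, G = G, n = as.integer(n)), class = "bomi_state")
}

#' Dimension of the combined learning state
#' @param state A `bomi_state`.
#' @return Number of scalar state variables (elements of H_hat plus G).
#' @export
state_dim <- function(state) {
  stopifnot(inherits(state, "bomi_state"))
  length(state$H_hat) + length(state$G)
}

#' Draw a naive initial inverse model
#'
#' Initial conditions emulate a naive but not empty motor repertoire. The
#' inverse model is `(Gmin + N) (I + D)`, where `Gmin` is the minimum-norm
#' right inverse of H; `N` is a random null-space contamination sized so that
#' the non-potent share of the initial movement variance matches the
#' babbling statistic (27% outside the two leading components, the
#' complement of the 73% captured by the interface); and `D` is a random
#' task-space distortion (a mixture of a conformal rotation-plus-gain error
#' and a general linear distortion) scaled so that the mean initial reaching
#' error equals the target distance. See the methods vignette.
#'
#' @param map A `bomi_map`.
#' @param radius Target distance (cm); sets the initial error scale.
#' @param seed RNG seed.
#' @param null_frac Amplitude of the null-space contamination relative to
#'   the potent part (Frobenius); default `sqrt(0.27/0.73)`.
#' @param w_general Mixture weight of the general (possibly ill-conditioned)
#'   distortion component versus the conformal one.
#' @return An S x K matrix.
#' @export
initial_inverse <- function(map, radius = 5, seed = 1L,
                            null_frac = sqrt(0.27 / 0.73), w_general = 0.65) {
  stopifnot(inherits(map, "bomi_map"))
  H <- map$H
  K <- nrow(H); S <- ncol(H)
  withr_seed(derive_seed(seed, 211L), {
    Gmin <- t(H) %*% solve(H %*% t(H))
    NS <- svd(H, nv = S)$v[, (K + 1):S, drop = FALSE]
    Nn <- NS %*% matrix(stats::rnorm((S - K) * K), S - K, K)
    Nn <- Nn * (null_frac * norm(Gmin, "F") / norm(Nn, "F"))
    th <- stats::runif(1, 0, 2 * pi)
    C <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    if (K != 2) C <- diag(K)  # conformal part defined for planar tasks
    Z <- matrix(stats::rnorm(K * K), K, K)
    Z <- Z * sqrt(K) / norm(Z, "F")
    D <- (1 - w_general) * C + w_general * Z
    ang <- 2 * pi * (seq_len(max(6, 2 * K)) - 1) / max(6, 2 * K)
    U <- rbind(cos(ang), sin(ang))[seq_len(K), , drop = FALSE] * radius
    D <- D * (radius / mean(sqrt(colSums((D %*% U)^2))))
    (Gmin + Nn) %*% (diag(K) + D)
  })
}

#' Initialize a learner for a session
#'
#' @param map A `bomi_map`.
#' @param targets A target tibble from [generate_targets()].
#' @param params A [learner_params()].
#' @param forward `"zero"` starts the forward estimate at 0 (a fully naive
#'   learner); `"estimated"` initializes it by least squares of cursor on
#'   body signals over a 12-trial pre-session window driven by the naive
#'   inverse model, emulating initial conditions inferred from early
#'   performance.
#' @param G0,H_hat0 Optional explicit initial matrices (override the drawn
#'   ones).
#' @return A `bomi_state`.
#' @export
initial_state <- function(map, targets, params, forward = c("zero", "estimated"),
                          G0 = NULL, H_hat0 = NULL) {
  forward <- match.arg(forward)
  H <- map$H
  K <- nrow(H); S <- ncol(H)
  radius <- mean(sqrt(targets$u_x^2 + targets$u_y^2))
  if (is.null(G0)) G0 <- initial_inverse(map, radius = radius, seed = params$seed)
  if (is.null(H_hat0)) {
    if (forward == "zero") {
      H_hat0 <- matrix(0, K, S)
    } else {
      npre <- min(12L, nrow(targets))
      H_hat0 <- withr_seed(derive_seed(params$seed, 613L), {
        U <- t(as.matrix(targets[seq_len(npre), c("u_x", "u_y")]))
        Q <- G0 %*% U + matrix(stats::rnorm(S * npre, 0, params$sigma), S, npre)
        P <- H %*% Q
        t(solve(Q %*% t(Q), Q %*% t(P)))
      })
    }
  }
  learner_state(H_hat0, G0, n = 0L)
}

#' Plan a body action for a target
#'
#' The planned body vector is the inverse model applied to the target plus
#' fresh isotropic Gaussian exploration noise: q = G u + xi, with each
#' component of xi drawn i.i.d. from N(0, sigma^2). Draws come from the
#' current RNG stream.
#'
#' @param state A `bomi_state`.
#' @param u Target position (length K).
#' @param params A [learner_params()].
#' @return A list with `q` (length S) and `xi` (length S).
#' @export
plan_action <- function(state, u, params) {
  stopifnot(inherits(state, "bomi_state"))
  xi <- stats::rnorm(nrow(state$G), 0, params$sigma)
  list(q = as.numeric(state$G %*% u) + xi, xi = xi)
}

#' One gradient step of the forward model
#'
#' H_hat' = H_hat + epsilon (p - H_hat q) q^T, the (negative) gradient step
#' on the squared prediction error (1/2)‖p - H_hat q‖^2. `epsilon` here is
#' the raw step size; the session driver passes `epsilon / q_ref^2`.
#'
#' @param H_hat K x S forward estimate.
#' @param q Executed body vector (length S).
#' @param p Observed cursor position (length K).
#' @param epsilon Raw learning rate.
#' @return Updated K x S matrix.
#' @export
update_forward <- function(H_hat, q, p, epsilon) {
  if (!all(is.finite(H_hat)) || !all(is.finite(q)) || !all(is.finite(p)) ||
      !is.finite(epsilon))
    stop("update_forward(): non-finite inputs", call. = FALSE)
  H_hat + epsilon * (p - as.numeric(H_hat %*% q)) %o% q
}

#' One gradient step of the inverse model
#'
#' G' = G - eta H_hat^T e u^T. When H_hat equals the true map H this is
#' gradient descent on the squared reaching error (1/2)‖(H G - I) u‖^2.
#' The pre-update forward estimate is used (both updates within a trial see
#' the same H_hat).
#'
#' @param G S x K inverse model.
#' @param H_hat K x S forward estimate (pre-update).
#' @param e Reaching error p - u (length K).
#' @param u Target (length K).
#' @param eta Learning rate.
#' @return Updated S x K matrix.
#' @export
update_inverse <- function(G, H_hat, e, u, eta) {
  if (!all(is.finite(G)) || !all(is.finite(H_hat)) || !all(is.finite(e)) ||
      !all(is.finite(u)) || !is.finite(eta))
    stop("update_inverse(): non-finite inputs", call. = FALSE)
  G - eta * t(H_hat) %*% (e %o% u)
}

#' Execute one reaching trial and update the learner
#'
#' Order of evaluation within a trial: (1) plan q = G u + xi with the current
#' inverse model; (2) the interface maps q to the cursor endpoint
#' p = H q + origin; (3) the reaching error e = p - u is observed; (4) the
#' forward estimate is updated from the prediction error; (5) the inverse
#' model is updated using the pre-update forward estimate. Noise is drawn
#' from the current RNG stream (seed the stream for reproducibility).
#'
#' @param state A `bomi_state`.
#' @param map A `bomi_map`.
#' @param u Target (length K).
#' @param params A [learner_params()]; `q_ref` must be set (or it defaults
#'   to ‖u‖ / ‖H‖ for this trial).
#' @return A list with the updated `state` and a one-row tibble `record`
#'   (target, noise, body vector, cursor, prediction, errors).
#' @export
step_trial <- function(state, map, u, params) {
  stopifnot(inherits(state, "bomi_state"), inherits(map, "bomi_map"))
  H <- map$H
  q_ref <- params$q_ref
  if (is.null(q_ref)) q_ref <- sqrt(sum(u^2)) / spectral_norm(H)
  act <- plan_action(state, u, params)
  q <- act$q
  p <- as.numeric(H %*% q) + if (is.null(map$origin)) 0 else map$origin
  e <- p - u
  p_pred <- as.numeric(state$H_hat %*% q)
  H_hat_new <- update_forward(state$H_hat, q, p, params$epsilon / q_ref^2)
  G_new <- update_inverse(state$G, state$H_hat, e, u, params$eta)
  rec <- tibble::tibble(
    n = state$n + 1L,
    u_x = u[1], u_y = u[2],
    p_x = p[1], p_y = p[2],
    e_norm = sqrt(sum(e^2)),
    pe = sqrt(sum((p - p_pred)^2))
  )
  rec$q <- list(q); rec$xi <- list(act$xi)
  list(state = learner_state(H_hat_new, G_new, state$n + 1L), record = rec)
}
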