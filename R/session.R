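#' Run a full learning session
#'
#' Iterates [step_trial()] over a target sequence, recording the complete
#' trial log and (optionally) the state trajectory. A divergence guard
#' aborts with a diagnostic if the state norm exceeds
#' `divergence_factor` times its initial scale (user-supplied learning
#' rates can be unstable).
#'
#' @param map A `bomi_map`.
#' @param targets Target tibble from [generate_targets()].
#' @param params A [learner_params()].
#' @param init Optional `bomi_state`; by default drawn by [initial_state()].
#' @param forward_init Passed to [initial_state()] when `init` is NULL:
#'   `"zero"` (naive) or `"estimated"` (pre-session least squares).
#' @param n_trials Number of trials to run (at most `nrow(targets)`).
#' @param stop_rule `"fixed"` runs all trials; `"criterion"` stops once the
#'   trailing `r`-trial mean of the reaching-error norm falls below
#'   `target_radius` (the performance plateau).
#' @param r Window length for the stopping criterion.
#' @param target_radius Success radius (cm); defaults to the protocol's.
#' @param record_states Keep per-trial snapshots of H_hat and G.
#' @param divergence_factor Abort threshold multiplier.
#' @return A `bomi_session`: list with `log` (tibble: `n`, `block`,
#'   `target_id`, `u_x`, `u_y`, `q1..qS`, `xi1..xiS`, `p_x`, `p_y`,
#'   `e_norm`, `pe`), `states` (arrays `H_hat` K x S x n and `G` S x K x n),
#'   `map`, `params`, `init`, `trials_to_criterion` (first trial whose
#'   trailing window meets the criterion, or NA), `r`, `target_radius`.
#' @export
run_session <- function(map, targets, params, init = NULL,
                        forward_init = c("zero", "estimated"),
                        n_trials = nrow(targets),
                        stop_rule = c("fixed", "criterion"),
                        r = 12, target_radius = NULL,
                        record_states = TRUE, divergence_factor = 1e6) {
  forward_init <- match.arg(forward_init)
  stop_rule <- match.arg(stop_rule)
  stopifnot(inherits(map, "bomi_map"), inherits(params, "bomi_params"))
  if (n_trials > nrow(targets))
    stop("n_trials exceeds the target sequence; generate a longer protocol",
         call. = FALSE)
  proto <- attr(targets, "protocol")
  if (is.null(target_radius))
    target_radius <- if (!is.null(proto)) proto$target_radius else 1
  H <- map$H
  K <- nrow(H); S <- ncol(H)
  origin <- if (is.null(map$origin)) rep(0, K) else map$origin
  if (is.null(init))
    init <- initial_state(map, targets, params, forward = forward_init)
  if (is.null(params$q_ref))
    params$q_ref <- mean(sqrt(targets$u_x^2 + targets$u_y^2)) / spectral_norm(H)
  eps_raw <- params$epsilon / params$q_ref^2
  Hh <- init$H_hat; G <- init$G
  guard <- divergence_factor * max(1, norm(G, "F"), norm(H, "F"))

  Umat <- t(as.matrix(targets[seq_len(n_trials), c("u_x", "u_y")]))
  qs <- matrix(NA_real_, n_trials, S)
  xis <- matrix(NA_real_, n_trials, S)
  ps <- matrix(NA_real_, n_trials, K)
  e_norm <- pe <- numeric(n_trials)
  if (record_states) {
    Hh_tr <- array(NA_real_, c(K, S, n_trials))
    G_tr <- array(NA_real_, c(S, K, n_trials))
  }
  run_sum <- 0; used <- n_trials; ttc <- NA_integer_
  withr_seed(params$seed, {
    for (n in seq_len(n_trials)) {
      u <- Umat[, n]
      xi <- stats::rnorm(S, 0, params$sigma)
      q <- as.numeric(G %*% u) + xi
      p <- as.numeric(H %*% q) + origin
      e <- p - u
      p_pred <- as.numeric(Hh %*% q)
      Hh_new <- Hh + eps_raw * (p - p_pred) %o% q
      G <- G - params$eta * t(Hh) %*% (e %o% u)
      Hh <- Hh_new
      if (!all(is.finite(G)) || !all(is.finite(Hh)) ||
          norm(G, "F") > guard || norm(Hh, "F") > guard)
        stop(sprintf("learning dynamics diverged at trial %d (||G||_F = %.3g); reduce eta/epsilon",
                     n, norm(G, "F")), call. = FALSE)
      qs[n, ] <- q; xis[n, ] <- xi; ps[n, ] <- p
      e_norm[n] <- sqrt(sum(e^2))
      pe[n] <- sqrt(sum((p - p_pred)^2))
      if (record_states) { Hh_tr[, , n] <- Hh; G_tr[, , n] <- G }
      run_sum <- run_sum + e_norm[n]
      if (n > r) run_sum <- run_sum - e_norm[n - r]
      if (n >= r && is.na(ttc) && run_sum / r < target_radius) ttc <- n
      if (stop_rule == "criterion" && !is.na(ttc)) { used <- n; break }
    }
  })
  idx <- seq_len(used)
  log <- tibble::tibble(
    n = targets$n[idx], block = targets$block[idx],
    target_id = targets$target_id[idx],
    u_x = targets$u_x[idx], u_y = targets$u_y[idx])
  qdf <- tibble::as_tibble(qs[idx, , drop = FALSE], .name_repair = "minimal")
  names(qdf) <- paste0("q", seq_len(S))
  xdf <- tibble::as_tibble(xis[idx, , drop = FALSE], .name_repair = "minimal")
  names(xdf) <- paste0("xi", seq_len(S))
  log <- dplyr::bind_cols(log, qdf, xdf)
  log$p_x <- ps[idx, 1]; log$p_y <- ps[idx, 2]
  log$e_norm <- e_norm[idx]; log$pe <- pe[idx]
  structure(list(
    log = log,
    states = if (record_states)
      list(H_hat = Hh_tr[, , idx, drop = FALSE], G = G_tr[, , idx, drop = FALSE])
    else NULL,
    map = map, params = params, init = init,
    trials_to_criterion = ttc, r = r, target_radius = target_radius),
    class = "bomi_session")
}

#' @export
print.bomi_session <- function(x, ...) {
  cat(sprintf("<bomi_session> %d trials; eta=%.4g eps=%.4g sigma=%.4g; trials to criterion: %s\n",
              nrow(x$log), x$params$eta, x$params$epsilon, x$params$sigma,
              ifelse(is.na(x$trials_to_criterion), "not reached",
                     x$trials_to_criterion)))
  invisible(x)
}

#' Run a two-phase (sequential) learning session
#'
#' The sequential alternative to concurrent learning: first a motor-babbling
#' phase in which aimless body vectors q ~ N(0, babble_sd^2 I) drive only
#' the forward-model update (the inverse model is untouched); then a
#' reaching phase in which only the inverse model is updated, using the
#' phase-1 forward estimate held fixed.
#'
#' @inheritParams run_session
#' @param babble_trials Number of babbling trials (phase 1).
#' @param babble_sd Per-channel SD of babbling movements; defaults to
#'   `q_ref / sqrt(S)` so that aimless exploration spans the same
#'   body-signal range used for reaching.
#' @return A `bomi_session` whose log has a `phase` column (1 = babbling,
#'   2 = reaching). Phase-1 rows have `NA` targets and reaching errors.
#' @export
run_two_phase <- function(map, targets, params, init = NULL,
                          babble_trials = 200, babble_sd = NULL,
                          n_trials = nrow(targets), r = 12,
                          target_radius = NULL, record_states = TRUE) {
  stopifnot(babble_trials >= 1)
  H <- map$H
  K <- nrow(H); S <- ncol(H)
  origin <- if (is.null(map$origin)) rep(0, K) else map$origin
  proto <- attr(targets, "protocol")
  if (is.null(target_radius))
    target_radius <- if (!is.null(proto)) proto$target_radius else 1
  if (is.null(init)) init <- initial_state(map, targets, params, forward = "zero")
  if (is.null(params$q_ref))
    params$q_ref <- mean(sqrt(targets$u_x^2 + targets$u_y^2)) / spectral_norm(H)
  if (is.null(babble_sd)) babble_sd <- params$q_ref / sqrt(S)
  eps_raw <- params$epsilon / params$q_ref^2
  Hh <- init$H_hat; G <- init$G
  ntot <- babble_trials + n_trials
  qs <- matrix(NA_real_, ntot, S); ps <- matrix(NA_real_, ntot, K)
  e_norm <- pe <- rep(NA_real_, ntot)
  if (record_states) {
    Hh_tr <- array(NA_real_, c(K, S, ntot)); G_tr <- array(NA_real_, c(S, K, ntot))
  }
  withr_seed(params$seed, {
    for (n in seq_len(babble_trials)) {
      q <- stats::rnorm(S, 0, babble_sd)
      p <- as.numeric(H %*% q) + origin
      p_pred <- as.numeric(Hh %*% q)
      Hh <- Hh + eps_raw * (p - p_pred) %o% q
      qs[n, ] <- q; ps[n, ] <- p; pe[n] <- sqrt(sum((p - p_pred)^2))
      if (record_states) { Hh_tr[, , n] <- Hh; G_tr[, , n] <- G }
    }
    for (i in seq_len(n_trials)) {
      n <- babble_trials + i
      u <- c(targets$u_x[i], targets$u_y[i])
      xi <- stats::rnorm(S, 0, params$sigma)
      q <- as.numeric(G %*% u) + xi
      p <- as.numeric(H %*% q) + origin
      e <- p - u
      G <- G - params$eta * t(Hh) %*% (e %o% u)
      qs[n, ] <- q; ps[n, ] <- p
      e_norm[n] <- sqrt(sum(e^2))
      pe[n] <- sqrt(sum((p - as.numeric(Hh %*% q))^2))
      if (record_states) { Hh_tr[, , n] <- Hh; G_tr[, , n] <- G }
    }
  })
  log <- tibble::tibble(
    n = seq_len(ntot),
    phase = rep(1:2, c(babble_trials, n_trials)),
    block = c(rep(NA_integer_, babble_trials), targets$block[seq_len(n_trials)]),
    target_id = c(rep(NA_integer_, babble_trials), targets$target_id[seq_len(n_trials)]),
    u_x = c(rep(NA_real_, babble_trials), targets$u_x[seq_len(n_trials)]),
    u_y = c(rep(NA_real_, babble_trials), targets$u_y[seq_len(n_trials)]))
  qdf <- tibble::as_tibble(qs, .name_repair = "minimal")
  names(qdf) <- paste0("q", seq_len(S))
  log <- dplyr::bind_cols(log, qdf)
  log$p_x <- ps[, 1]; log$p_y <- ps[, 2]
  log$e_norm <- e_norm; log$pe <- pe
  re2 <- e_norm[(babble_trials + 1):ntot]
  w <- if (length(re2) >= r)
    vapply(r:length(re2), function(i) mean(re2[(i - r + 1):i]), 0) else numeric(0)
  ttc <- if (any(w < target_radius)) which(w < target_radius)[1] + r - 1L else NA_integer_
  structure(list(
    log = log,
    states = if (record_states) list(H_hat = Hh_tr, G = G_tr) else NULL,
    map = map, params = params, init = init, babble_trials = babble_trials,
    trials_to_criterion = ttc, r = r, target_radius = target_radius),
    class = c("bomi_two_phase", "bomi_session"))
}
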