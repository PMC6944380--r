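#' Specification of a synthetic subject
#'
#' Bundles everything needed to generate one synthetic subject: the learner
#' parameters (drawn within the study's subject-specific ranges when not
#' supplied), the babbling covariance spectrum used for calibration, and an
#' optional sensor measurement noise applied to logged body signals only
#' (never inside the learning loop: the model's exploration noise xi is part
#' of the action, not of the measurement).
#'
#' Default parameter ranges: sigma in [0.65, 0.83], epsilon in [0.15, 0.25],
#' eta in [0.006, 0.036]. The default babbling spectrum is proportional to
#' (45, 28, 8, 7, 5, 3, 2, 2), so the two leading components carry 73% of
#' the variance.
#'
#' @param params Optional [learner_params()]; drawn from the ranges if NULL.
#' @param babble_spectrum Positive, descending eigenvalue profile (length S).
#' @param measurement_noise_sd SD of Gaussian noise added to logged q.
#' @param seed Subject seed (drives parameter draw, calibration, session).
#' @return A `bomi_subject_spec`.
#' @export
subject_spec <- function(params = NULL,
                         babble_spectrum = c(45, 28, 8, 7, 5, 3, 2, 2),
                         measurement_noise_sd = 0, seed = 1L) {
  stopifnot(all(babble_spectrum > 0), !is.unsorted(rev(babble_spectrum)),
            measurement_noise_sd >= 0)
  if (is.null(params)) {
    params <- withr_seed(derive_seed(seed, 17L), {
      learner_params(eta = stats::runif(1, 0.006, 0.036),
                     epsilon = stats::runif(1, 0.15, 0.25),
                     sigma = stats::runif(1, 0.65, 0.83),
                     seed = derive_seed(seed, 29L))
    })
  }
  stopifnot(inherits(params, "bomi_params"))
  structure(list(params = params, babble_spectrum = babble_spectrum,
                 measurement_noise_sd = measurement_noise_sd,
                 seed = as.integer(seed)),
            class = "bomi_subject_spec")
}

#' Generate a motor-babbling calibration set
#'
#' Samples an S-channel "free dance": a temporally smoothed Gaussian process
#' whose covariance has eigenvalues proportional to the subject's babbling
#' spectrum in a random orthonormal frame. Smoothing is a first-order
#' low-pass (cutoff ~1 Hz at the default 75 samples/s) so the trajectories
#' are physically plausible; the filter output is rescaled to unit variance
#' so the covariance spectrum is unchanged. Total variance is normalized to
#' S (unit variance per channel on average), which fixes the body-signal
#' scale referenced by the noise amplitude sigma.
#'
#' @param spec A [subject_spec()].
#' @param S Number of channels.
#' @param M Number of samples.
#' @param rate Sample rate (samples/s).
#' @param cutoff Low-pass cutoff (Hz).
#' @return A [calibration_set()].
#' @export
generate_calibration <- function(spec, S = 8, M = 5000, rate = 75, cutoff = 1) {
  stopifnot(inherits(spec, "bomi_subject_spec"), M > S)
  lam <- spec$babble_spectrum
  stopifnot(length(lam) == S)
  lam <- lam / sum(lam) * S
  withr_seed(derive_seed(spec$seed, 101L), {
    V <- qr.Q(qr(matrix(stats::rnorm(S * S), S, S)))
    a <- exp(-2 * pi * cutoff / rate)
    burn <- 200L
    Z <- matrix(stats::rnorm(S * (M + burn)), S, M + burn)
    for (t in 2:(M + burn)) Z[, t] <- a * Z[, t - 1] + sqrt(1 - a^2) * Z[, t]
    Z <- Z[, (burn + 1):(burn + M), drop = FALSE]
    X <- V %*% (sqrt(lam) * Z)
    calibration_set(X, sample_rate = rate)
  })
}

#' Generate a complete synthetic subject
#'
#' Composes the full pipeline the study applied per subject: calibrate
#' ([generate_calibration()] + [build_map_pca()]), normalize the workspace
#' ([normalize_workspace()], origin at the screen center), then run a
#' training session of the learning dynamics ([run_session()]). If
#' `measurement_noise_sd > 0`, i.i.d. Gaussian noise is added to the logged
#' body signals (columns `q1..qS`) after the fact; the dynamics never see it.
#'
#' @param spec A [subject_spec()].
#' @param cfg A [protocol_config()]; its seed is re-derived from the
#'   subject seed so subjects get distinct target orders.
#' @param ... Passed to [run_session()] (e.g. `forward_init`, `stop_rule`).
#' @return A `bomi_subject`: list with `spec`, `calibration`, `map`,
#'   `session` (ground-truth trajectory in `session$states`), and `log`
#'   (the measurement-noise-corrupted trial log an experimenter would see).
#' @export
generate_subject <- function(spec, cfg = protocol_config(), ...) {
  stopifnot(inherits(spec, "bomi_subject_spec"), inherits(cfg, "bomi_protocol"))
  cal <- generate_calibration(spec)
  map <- build_map_pca(cal, K = 2)
  map <- normalize_workspace(map)
  map <- adjust_map(map, origin = c(0, 0))
  cfg$seed <- derive_seed(spec$seed, 401L)
  targets <- generate_targets(cfg)
  session <- run_session(map, targets, spec$params, ...)
  log <- session$log
  if (spec$measurement_noise_sd > 0) {
    S <- sum(grepl("^q[0-9]+$", names(log)))
    noise <- withr_seed(derive_seed(spec$seed, 499L), {
      matrix(stats::rnorm(nrow(log) * S, 0, spec$measurement_noise_sd),
             nrow(log), S)
    })
    log[paste0("q", seq_len(S))] <- log[paste0("q", seq_len(S))] + noise
  }
  structure(list(spec = spec, calibration = cal, map = map,
                 session = session, log = log),
            class = "bomi_subject")
}

#' @export
print.bomi_subject <- function(x, ...) {
  cat(sprintf("<bomi_subject> seed=%d eta=%.4g eps=%.4g sigma=%.4g; %d trials, ttc=%s\n",
              x$spec$seed, x$spec$params$eta, x$spec$params$epsilon,
              x$spec$params$sigma, nrow(x$log),
              ifelse(is.na(x$session$trials_to_criterion), "NA",
                     x$session$trials_to_criterion)))
  invisible(x)
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject seeds are derived deterministically from `master_seed`;
#' parameters are sampled within the declared ranges unless `specs` is
#' given.
#'
#' @param n_subjects Number of subjects.
#' @param master_seed Master seed.
#' @param cfg Protocol configuration shared by the cohort.
#' @param specs Optional list of [subject_spec()]s (overrides sampling).
#' @param ... Passed to [generate_subject()].
#' @return A list of `bomi_subject`s.
#' @export
make_cohort <- function(n_subjects, master_seed = 1L, cfg = protocol_config(),
                        specs = NULL, ...) {
  stopifnot(n_subjects >= 1)
  if (is.null(specs))
    specs <- lapply(seq_len(n_subjects), function(i)
      subject_spec(seed = derive_seed(master_seed, i)))
  stopifnot(length(specs) == n_subjects)
  lapply(specs, generate_subject, cfg = cfg, ...)
}
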