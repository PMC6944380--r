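test_that("least squares recovers a known inverse model exactly", {
  # hand-checkable normal equations
  Gstar <- rbind(c(1, 0), c(0, 2))
  U <- rbind(c(1, 0, 1), c(0, 1, 1))
  Q <- Gstar %*% U
  expect_equal(estimate_inverse(Q, U), Gstar, tolerance = 1e-12)
  # exact linear recovery at S = 8
  set.seed(4)
  Gstar <- matrix(rnorm(16), 8, 2)
  U <- matrix(rnorm(2 * 12), 2, 12)
  expect_equal(estimate_inverse(Gstar %*% U, U), Gstar, tolerance = 1e-10)
})

test_that("the inverse estimate converges as window noise vanishes", {
  set.seed(5)
  Gstar <- matrix(rnorm(16), 8, 2)
  U <- matrix(rnorm(2 * 24), 2, 24)
  err <- vapply(c(1, 0.1, 0.01, 0.001), function(s) {
    mean(replicate(20, {
      Q <- Gstar %*% U + matrix(rnorm(8 * 24, 0, s), 8, 24)
      spectral_norm(estimate_inverse(Q, U) - Gstar)
    }))
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[4], 1e-2)
})

test_that("rank-deficient windows error or fall back with a warning", {
  U <- rbind(c(1, 2, 3), c(2, 4, 6))  # rank 1
  Q <- matrix(rnorm(24), 8, 3)
  expect_error(estimate_inverse(Q, U), "rank-deficient")
  expect_warning(G <- estimate_inverse(Q, U, fallback = TRUE), "pseudo-inverse")
  expect_equal(dim(G), c(8, 2))
})

test_that("windowed reaching error is the top singular value of H Q - U", {
  map <- random_rowortho_map(norm = 0.25, seed = 6)
  # window chosen to land exactly on target: zero error
  U <- matrix(rnorm(2 * 12), 2, 12)
  Q <- t(map$H) %*% solve(map$H %*% t(map$H)) %*% U
  expect_equal(reaching_error(map, Q, U), 0, tolerance = 1e-12)
  # diagonal case
  m1 <- map; m1$H <- rbind(c(1, 0, 0), c(0, 1, 0))
  Q1 <- rbind(c(3, 0, 0), c(0, 1, 0), 0)
  expect_equal(reaching_error(m1, Q1, matrix(0, 2, 3)), 3)
  # independent power-iteration oracle
  set.seed(7)
  for (i in 1:20) {
    E <- matrix(rnorm(2 * 12), 2, 12)
    expect_equal(spectral_norm(E), power_norm(E), tolerance = 1e-6)
  }
})

test_that("inverse and forward model errors have their defining values", {
  map <- random_rowortho_map(norm = 1, seed = 8)
  expect_equal(inverse_model_error(map, t(map$H)), 0, tolerance = 1e-12)
  expect_equal(inverse_model_error(map, matrix(0, 8, 2)), 1)
  m <- random_rowortho_map(norm = 0.4, seed = 9)
  pinv <- t(m$H) %*% solve(m$H %*% t(m$H))
  expect_lt(inverse_model_error(m, pinv), 1e-10)
  expect_equal(forward_model_error(m, m$H), 0)
  expect_equal(forward_model_error(m, m$H * 0), 1)
  q <- rnorm(8)
  expect_equal(prediction_error(as.numeric(m$H %*% q), m$H, q), 0)
  # IME is invariant to reciprocal rescaling of H and G
  expect_equal(inverse_model_error(m, pinv * 2),
               inverse_model_error(adjust_map(m, scale = 2), pinv),
               tolerance = 1e-12)
})

test_that("delta_G measures relative change with the chosen denominator", {
  G <- matrix(rnorm(16), 8, 2)
  expect_equal(delta_G(G, G), 0)
  expect_equal(delta_G(2 * G, G), 1)
  expect_equal(delta_G(2 * G, G, denominator = "current"), 0.5)
  expect_error(delta_G(G, G * 0), "zero denominator")
})

test_that("R squared follows the general residual definition", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(3, 2, 1)), -3)
  expect_error(r_squared(c(2, 2, 2), y), "constant")
})

test_that("exponential fit recovers noiseless parameters and flags degeneracy", {
  n <- 1:300
  y <- 2 * exp(-0.05 * n) + 1
  f <- fit_exponential(y, n)
  expect_equal(c(f$a, f$lambda, f$c), c(2, 0.05, 1), tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_equal(tidy(f)$estimate, c(f$a, f$lambda, f$c))
  g <- fit_exponential(rep(3, 50))
  expect_true(g$degenerate)
  expect_equal(g$a, 0)
})

test_that("learning curves decay and the window estimator tracks the learner's G", {
  spec <- subject_spec(params = learner_params(0.029, 0.19, 0.78, seed = 2), seed = 2)
  sub <- generate_subject(spec)
  cv <- learning_curves(sub$session)
  expect_true(all(c("re", "ime", "dg", "ime_model", "fme", "pe") %in% names(cv)))
  expect_true(all(stats::na.omit(unlist(cv[-1])) >= 0))
  # monotone-in-trend decay to plateau for the windowed errors
  expect_lt(mean(tail(cv$re, 20)), 0.2 * mean(head(cv$re, 5)))
  expect_lt(mean(tail(cv$ime, 20)), 0.3 * mean(head(cv$ime, 5)))
  # estimator consistency: data-estimated IME matches the internal G's IME
  # once learning has settled
  expect_lt(abs(mean(tail(cv$ime, 30)) - mean(tail(cv$ime_model, 30))), 0.05)
  # asymptotic relative change of G settles near the 0.1 scale
  expect_lt(median(tail(cv$dg, 50)), 0.15)
})

test_that("long concurrent learning drives FME and PE to near zero", {
  ok <- sapply(1:10, function(sd) {
    spec <- subject_spec(seed = sd)  # rates sampled within the study ranges
    sub <- generate_subject(spec, protocol_config(n_blocks = 186, seed = sd))
    st <- sub$session$states
    fme <- forward_model_error(sub$map, st$H_hat[, , 10000])
    pe0 <- mean(sub$session$log$pe[1:5])
    pe1 <- mean(sub$session$log$pe[9981:10000])
    c(fme < 0.1, pe1 < 0.1 * pe0)
  })
  expect_gte(sum(ok[1, ]), 8)
  expect_gte(sum(ok[2, ]), 8)
})
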