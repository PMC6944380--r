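test_that("action planning reduces to the inverse model without noise", {
  map <- random_rowortho_map(seed = 1)
  G <- t(map$H) * 10
  st <- learner_state(map$H, G)
  p0 <- learner_params(0.1, 0.1, 0)
  act <- plan_action(st, c(3, -4), p0)
  expect_equal(act$q, as.numeric(G %*% c(3, -4)))
  expect_equal(act$xi, rep(0, 8))
  expect_equal(plan_action(st, c(0, 0), p0)$q, rep(0, 8))
})

test_that("exploration noise has the declared per-component scale", {
  st <- learner_state(matrix(0, 2, 8), matrix(0, 8, 2))
  p <- learner_params(0, 0, sigma = 0.7)
  set.seed(99)
  draws <- replicate(10000, plan_action(st, c(1, 0), p)$q)
  expect_true(all(abs(apply(draws, 1, sd) / 0.7 - 1) < 0.03))
})

test_that("single-step updates match hand arithmetic and element-wise oracles", {
  # worked 2x2 examples
  Hh <- matrix(0, 2, 2)
  out <- update_forward(Hh, q = c(1, 0), p = c(2, 0), epsilon = 0.1)
  expect_equal(out, rbind(c(0.2, 0), c(0, 0)))
  G <- matrix(0, 2, 2)
  out2 <- update_inverse(G, H_hat = diag(2), e = c(-1, 0), u = c(1, 0), eta = 0.5)
  expect_equal(out2, rbind(c(0.5, 0), c(0, 0)))
  # true map as forward estimate and consistent observation: no update
  map <- random_rowortho_map(seed = 5)
  q <- rnorm(8)
  expect_equal(update_forward(map$H, q, as.numeric(map$H %*% q), 0.3), map$H)
  expect_equal(update_inverse(t(map$H), map$H, c(0, 0), c(1, 2), 0.3), t(map$H))
  # random instances against independently coded element-wise updates
  set.seed(2)
  for (i in 1:100) {
    K <- sample(1:3, 1); S <- K + sample(1:4, 1)
    Hh <- matrix(rnorm(K * S), K, S); G <- matrix(rnorm(S * K), S, K)
    q <- rnorm(S); p <- rnorm(K); e <- rnorm(K); u <- rnorm(K)
    expect_equal(update_forward(Hh, q, p, 0.07), oracle_forward(Hh, q, p, 0.07),
                 tolerance = 1e-12)
    expect_equal(update_inverse(G, Hh, e, u, 0.05), oracle_inverse(G, Hh, e, u, 0.05),
                 tolerance = 1e-12)
  }
})

test_that("updates descend the finite-difference gradients of their losses", {
  set.seed(3)
  for (i in 1:20) {
    K <- 2; S <- 5
    H <- matrix(rnorm(K * S), K, S)
    Hh <- matrix(rnorm(K * S), K, S)
    q <- rnorm(S); p <- rnorm(K)
    g_fd <- fd_grad(function(X) 0.5 * sum((p - X %*% q)^2), Hh)
    step <- update_forward(Hh, q, p, 1) - Hh   # = -gradient
    expect_equal(step, -g_fd, tolerance = 1e-6)
    G <- matrix(rnorm(S * K), S, K); u <- rnorm(K)
    e <- as.numeric((H %*% G - diag(K)) %*% u)
    g_fd2 <- fd_grad(function(X) 0.5 * sum(((H %*% X - diag(K)) %*% u)^2), G)
    step2 <- update_inverse(G, H, e, u, 1) - G
    expect_equal(step2, -g_fd2, tolerance = 1e-6)
  }
})

test_that("a converged noiseless learner is a fixed point of the trial step", {
  map <- random_rowortho_map(norm = 0.3, seed = 8)
  G <- t(map$H) / 0.3^2            # exact right inverse
  st <- learner_state(map$H, G)
  out <- step_trial(st, map, c(5, 0), learner_params(0.1, 0.2, 0))
  expect_equal(out$state$H_hat, st$H_hat)
  expect_equal(out$state$G, st$G)
  expect_equal(out$record$e_norm, 0)
})

test_that("seeded sessions are bit-for-bit reproducible", {
  map <- random_rowortho_map(seed = 13)
  tg <- generate_targets(protocol_config(n_blocks = 1, seed = 13))
  pr <- learner_params(0.03, 0.2, 0.7, seed = 77)
  s1 <- run_session(map, tg, pr)
  s2 <- run_session(map, tg, pr)
  expect_identical(s1$log, s2$log)
  expect_identical(s1$states, s2$states)
})

test_that("noiseless error contracts geometrically at rate eta", {
  # row-orthonormal H scaled to ||H|| = 1, repeated unit-norm target,
  # forward model frozen at the truth: ||e_n|| = (1 - eta)^n ||e_0||
  map <- random_rowortho_map(norm = 1, seed = 21)
  eta <- 0.05
  tg <- repeat_target(c(1, 0), 101)
  init <- learner_state(map$H, matrix(0, 8, 2))
  ses <- run_session(map, tg, learner_params(eta, 0, 0), init = init,
                     target_radius = 1e-9)
  e <- ses$log$e_norm
  expect_equal(e[2:101], e[1] * (1 - eta)^(1:100), tolerance = 1e-10)
})

test_that("a frozen learner leaves state and errors constant", {
  map <- random_rowortho_map(seed = 31)
  tg <- generate_targets(protocol_config(n_blocks = 1, seed = 31))
  ses <- run_session(map, tg, learner_params(0, 0, 0))
  expect_equal(ses$states$G[, , 1], ses$states$G[, , 54])
  expect_equal(ses$states$H_hat[, , 1], ses$states$H_hat[, , 54])
  per_target <- split(ses$log$e_norm, ses$log$target_id)
  expect_true(all(vapply(per_target, function(x) diff(range(x)) < 1e-12, TRUE)))
})

test_that("the divergence guard reports the offending trial", {
  map <- random_rowortho_map(seed = 41)
  tg <- generate_targets(protocol_config(seed = 41))
  expect_error(
    run_session(map, tg, learner_params(eta = 50, epsilon = 50, sigma = 0.5)),
    "diverged at trial")
})

test_that("two-phase learning freezes the inverse model during babbling", {
  map <- random_rowortho_map(seed = 51)
  tg <- generate_targets(protocol_config(n_blocks = 2, seed = 51))
  ses <- run_two_phase(map, tg, learner_params(0.03, 0.2, 0.7, seed = 4),
                       babble_trials = 100)
  expect_identical(ses$states$G[, , 1], ses$states$G[, , 100])
  expect_identical(ses$states$G[, , 50], ses$init$G)
  # forward estimate is frozen during reaching
  expect_identical(ses$states$H_hat[, , 101], ses$states$H_hat[, , 150])
  expect_equal(ses$log$phase, rep(1:2, c(100, 108)))
})

test_that("babbling drives the forward error down in trend", {
  fmes <- sapply(1:5, function(sd) {
    map <- random_rowortho_map(seed = sd)
    tg <- generate_targets(protocol_config(n_blocks = 1, seed = sd))
    ses <- run_two_phase(map, tg, learner_params(0.02, 0.2, 0.7, seed = sd),
                         babble_trials = 200)
    vapply(c(1, 50, 100, 200), function(n)
      forward_model_error(map, ses$states$H_hat[, , n]), 0)
  })
  med <- apply(fmes, 1, median)
  expect_true(all(diff(med) < 0))
  expect_lt(med[4], 0.1 * med[1])
})
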