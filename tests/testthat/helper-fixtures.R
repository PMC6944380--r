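# shared fixtures: small maps, toy target sequences, reference oracles

# random K x S map with orthonormal rows scaled to `norm`
random_rowortho_map <- function(S = 8, K = 2, norm = sqrt(2) / 5, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(S * K), S, K)))
  m <- bomilearn:::new_interface_map(t(Q) * norm, origin = rep(0, K),
                                     variance_share = NA_real_)
  m
}

# a target tibble that repeats one target (for closed-form decay checks)
repeat_target <- function(u, n) {
  tg <- tibble::tibble(n = seq_len(n), block = 1L, cycle = 1L, target_id = 1L,
                       u_x = u[1], u_y = u[2])
  attr(tg, "protocol") <- protocol_config()
  tg
}

# independent spectral-norm oracle: power iteration on t(X) X
power_norm <- function(X, iters = 500) {
  A <- crossprod(X)
  v <- rep(1, ncol(A)) / sqrt(ncol(A))
  for (i in seq_len(iters)) {
    w <- A %*% v
    v <- w / sqrt(sum(w^2))
  }
  sqrt(as.numeric(t(v) %*% A %*% v))
}

# independent element-wise oracles for the two gradient updates
oracle_forward <- function(H_hat, q, p, eps) {
  K <- nrow(H_hat); S <- ncol(H_hat)
  out <- H_hat
  pred <- numeric(K)
  for (k in 1:K) for (s in 1:S) pred[k] <- pred[k] + H_hat[k, s] * q[s]
  for (k in 1:K) for (s in 1:S) out[k, s] <- H_hat[k, s] + eps * (p[k] - pred[k]) * q[s]
  out
}
oracle_inverse <- function(G, H_hat, e, u, eta) {
  S <- nrow(G); K <- ncol(G)
  out <- G
  for (s in 1:S) for (k in 1:K) {
    acc <- 0
    for (j in 1:K) acc <- acc + H_hat[j, s] * e[j]
    out[s, k] <- G[s, k] - eta * acc * u[k]
  }
  out
}

# central finite differences of a scalar function of a matrix
fd_grad <- function(f, X, h = 1e-6) {
  g <- X * 0
  for (i in seq_along(X)) {
    Xp <- X; Xm <- X
    Xp[i] <- Xp[i] + h; Xm[i] <- Xm[i] - h
    g[i] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  g
}

# table of the study's six subject-specific parameter sets
subject_table <- data.frame(
  sigma = c(0.7335, 0.6587, 0.7395, 0.7241, 0.8278, 0.7794),
  epsilon = c(0.1774, 0.2463, 0.1924, 0.2178, 0.1540, 0.1937),
  eta = c(0.036, 0.010, 0.015, 0.016, 0.021, 0.029))

# windowed trailing mean
wmean <- function(x, r = 12) {
  vapply(r:length(x), function(i) mean(x[(i - r + 1):i]), numeric(1))
}
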