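# Independent oracles used across the suite. These are deliberately written
# against the literal update formulas (dense algebra, explicit loops) and
# share no code path with the package solver.

# dense linear-algebra oracle for tridiagonal systems
dense_tridiag_solve <- function(sub, d, sup, rhs) {
  n <- length(d)
  A <- diag(d, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      A[i + 1, i] <- sub[i]
      A[i, i + 1] <- sup[i]
    }
  }
  as.numeric(solve(A, rhs))
}

# independently coded classical implicit solver (backward Euler in time,
# central differences in space, killing term lagged), dense solve per step
backward_euler_oracle <- function(ic, k_fun, bc_left, bc_right, L, T, dt, dx) {
  M <- round(L / dx)
  N <- round(T / dt)
  x <- (0:M) * dx
  lam <- dt / dx^2
  A <- diag(1 + 2 * lam, M - 1)
  if (M > 2) {
    for (i in 1:(M - 2)) {
      A[i, i + 1] <- -lam
      A[i + 1, i] <- -lam
    }
  }
  U <- matrix(0, N + 1, M + 1)
  U[1, ] <- ic(x)
  for (n in 0:(N - 1)) {
    tn <- n * dt
    b <- (1 - dt * k_fun(x[2:M], tn)) * U[n + 1, 2:M]
    bl <- bc_left((n + 1) * dt)
    br <- bc_right((n + 1) * dt)
    b[1] <- b[1] + lam * bl
    b[M - 1] <- b[M - 1] + lam * br
    U[n + 2, 2:M] <- as.numeric(solve(A, b))
    U[n + 2, 1] <- bl
    U[n + 2, M + 1] <- br
  }
  U
}

# literal term-by-term evaluation of the implicit-step right-hand side:
# (1 - kf_i) u_i^n - sum_{j=1}^{n} b_j (u_i^{n+1-j} - u_i^{n-j}) + tau * bc
rhs_literal_oracle <- function(history, alpha, killing_factor, tau, bl, br) {
  n <- nrow(history) - 1
  m_int <- ncol(history) - 2
  bj <- function(j) (j + 1)^(1 - alpha) - j^(1 - alpha)
  kf <- rep_len(killing_factor, m_int)
  out <- numeric(m_int)
  for (i in seq_len(m_int)) {
    acc <- (1 - kf[i]) * history[n + 1, i + 1]
    if (n >= 1) {
      for (j in 1:n) {
        acc <- acc - bj(j) * (history[n + 2 - j, i + 1] - history[n + 1 - j, i + 1])
      }
    }
    out[i] <- acc
  }
  out[1] <- out[1] + tau * bl
  out[m_int] <- out[m_int] + tau * br
  out
}

# literal iteration of the von Neumann amplification recursion, coded
# directly from the printed update (independent of the package routine)
amplification_literal_oracle <- function(theta, tau, alpha, kf, n_steps) {
  bj <- function(j) (j + 1)^(1 - alpha) - j^(1 - alpha)
  if (alpha == 1) bj <- function(j) 0 * j
  denom <- 1 + 4 * tau * sin(theta / 2)^2
  lam <- 1
  for (n in 0:(n_steps - 1)) {
    cur <- lam[n + 1]
    if (n == 0) {
      num <- (1 - kf) * cur
    } else {
      num <- (1 - kf - bj(1)) * cur + bj(n) * lam[1]
      if (n >= 2) {
        for (j in 1:(n - 1)) num <- num - (bj(j + 1) - bj(j)) * lam[n + 1 - j]
      }
    }
    lam <- c(lam, num / denom)
  }
  abs(lam)
}

# residual of the implicit update relation at time level n+1 (rows of a
# computed solution substituted back into the literal scheme)
scheme_residual <- function(U, alpha, dt, dx, k_fun) {
  N <- nrow(U) - 1
  M <- ncol(U) - 1
  tau <- gamma(2 - alpha) * dt^alpha / dx^2
  x_int <- (1:(M - 1)) * dx
  worst <- 0
  for (n in 0:(N - 1)) {
    kf <- gamma(2 - alpha) * dt^alpha * k_fun(x_int, n * dt)
    lhs <- -tau * (U[n + 2, 3:(M + 1)] + U[n + 2, 1:(M - 1)]) +
      (1 + 2 * tau) * U[n + 2, 2:M]
    rhs <- rhs_literal_oracle(U[1:(n + 1), , drop = FALSE], alpha, kf, 0, 0, 0)
    worst <- max(worst, max(abs(lhs - rhs)))
  }
  worst
}

table1_reference <- function() {
  tibble::tribble(
    ~r, ~alpha, ~lower_value, ~lower_error, ~upper_value, ~upper_error,
    0,   0.2, 0.02070978, 1.11503e-2, 0.03451629, 1.85838e-2,
    0,   0.4, 0.01806187, 2.13199e-3, 0.0301031,  3.55332e-3,
    0,   0.6, 0.01592767, 7.40335e-4, 0.02654611, 1.23389e-3,
    0,   0.8, 0.01487763, 2.84872e-4, 0.02479604, 4.74786e-4,
    0,   1.0, 0.01437086, 7.01618e-5, 0.0239514,  1.16936e-4,
    0.3, 0.2, 0.02347108, 1.1575e-2,  0.03244532, 1.74688e-2,
    0.3, 0.4, 0.01986805, 2.34519e-3, 0.0282969,  3.34012e-3,
    0.3, 0.6, 0.01752043, 8.14369e-4, 0.02495335, 1.15986e-3,
    0.3, 0.8, 0.01636539, 3.13359e-4, 0.02330828, 4.46299e-4,
    0.3, 1.0, 0.01580795, 7.7178e-5,  0.02251435, 1.0992e-4,
    0.7, 0.2, 0.02554206, 1.3752e-2,  0.02968401, 1.59821e-2,
    0.7, 0.4, 0.02227630, 2.62946e-3, 0.02588868, 3.05585e-3,
    0.7, 0.6, 0.019644127, 9.1308e-4, 0.02282966, 1.06115e-3,
    0.7, 0.8, 0.01834907, 3.51342e-4, 0.02132460, 4.08316e-4,
    0.7, 1.0, 0.01772406, 8.65329e-5, 0.02059824, 1.00565e-4
  )
}
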