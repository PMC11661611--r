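test_that("tridiagonal assembly has the implicit-update coefficients", {
  sys <- assemble_tridiagonal(0.04, 3)
  expect_equal(sys$diag, rep(1.08, 3))
  expect_equal(sys$sub, rep(-0.04, 2))
  expect_equal(sys$super, rep(-0.04, 2))
  # dominance margin is exactly 1 at interior rows, for any tau
  for (tau in c(1e-8, 0.04, 3, 1e6)) {
    sys <- assemble_tridiagonal(tau, 5)
    margin <- sys$diag[3] - abs(sys$sub[2]) - abs(sys$super[3])
    expect_equal(margin, 1)
  }
})

test_that("thomas_solve matches hand elimination and the identity system", {
  expect_equal(thomas_solve(c(0, 0), c(1, 1, 1), c(0, 0), c(3, -1, 2)),
               c(3, -1, 2))
  expect_equal(thomas_solve(-1, c(2, 2), -1, c(1, 1)), c(1, 1))
})

test_that("thomas_solve matches a dense solve on random dominant systems", {
  set.seed(11)
  for (case in 1:50) {
    n <- sample(2:50, 1)
    sub <- runif(n - 1, -1, 1)
    sup <- runif(n - 1, -1, 1)
    d <- abs(c(0, sub)) + abs(c(sup, 0)) + runif(n, 0.5, 2)
    rhs <- rnorm(n)
    got <- thomas_solve(sub, d, sup, rhs)
    want <- dense_tridiag_solve(sub, d, sup, rhs)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-12)
  }
})

test_that("build_rhs reduces correctly at n = 0 and in the classical limit", {
  u0 <- matrix(c(0.1, 0.5, 0.9, 0.4, 0.2), nrow = 1)
  w <- caputo_weights(0.5, 0)
  rhs <- build_rhs(u0, w, killing_factor = 0, tau = 0.3, bc_left = 2, bc_right = 5)
  expect_equal(rhs, c(0.5 + 0.3 * 2, 0.9, 0.4 + 0.3 * 5))
  # alpha = 1: all weights vanish; any history length gives backward Euler
  hist3 <- rbind(u0, u0 * 1.1, u0 * 1.3)
  kf <- c(0.02, 0.05, 0.01)
  rhs1 <- build_rhs(hist3, caputo_weights(1, 2), kf, tau = 0.1, 1, 1)
  expect_equal(rhs1, (1 - kf) * hist3[3, 2:4] + c(0.1, 0, 0.1))
})

test_that("build_rhs matches the literal term-by-term summation oracle", {
  set.seed(3)
  for (alpha in c(0.3, 0.5, 0.8)) {
    history <- matrix(rnorm(4 * 5), nrow = 4)  # n = 3 completed steps, 3 interior
    kf <- runif(3, 0, 0.1)
    w <- caputo_weights(alpha, 3)
    got <- build_rhs(history, w, kf, tau = 0.7, bc_left = 1.5, bc_right = -2)
    want <- rhs_literal_oracle(history, alpha, kf, tau = 0.7, 1.5, -2)
    expect_equal(got, want, tolerance = 1e-14)
  }
  expect_error(build_rhs(matrix(rnorm(15), 3), caputo_weights(0.5, 1), 0, 0.1, 0, 0),
               "weights")
})

test_that("constants are stationary under pure diffusion", {
  prob <- tumor_problem(
    length_L = 2, t_final = 0.5,
    ic_shape = function(x) rep(3, length(x)),
    ic_coefficient = fuzzy_crisp(1),
    bc_left = function(t, r) c(3, 3), bc_right = function(t, r) c(3, 3)
  )
  sol <- solve_fuzzy(prob, 0.5, scheme_params(0.6, 0.1, 0.25, 2, 0.5))
  expect_equal(max(abs(sol$lower - 3)), 0, tolerance = 1e-13)
  expect_equal(max(abs(sol$upper - 3)), 0, tolerance = 1e-13)
})

test_that("the scheme is linear: scaling IC and BCs scales the solution", {
  base <- benchmark_problem(alpha = 0.5)
  br <- defuzzify_problem(base$problem, r = 0)$lower
  scaled <- br
  scaled$ic <- function(x) 2 * br$ic(x)
  scaled$bc_left <- function(t) 2 * br$bc_left(t)
  scaled$bc_right <- function(t) 2 * br$bc_right(t)
  u1 <- solve_branch(br, base$scheme)
  u2 <- solve_branch(scaled, base$scheme)
  expect_equal(u2, 2 * u1, tolerance = 1e-13, ignore_attr = TRUE)
})

test_that("computed levels satisfy the implicit update relation to 1e-10", {
  for (alpha in c(0.4, 1)) {
    bp <- benchmark_problem(alpha = alpha)
    br <- defuzzify_problem(bp$problem, r = 0.3)$upper
    U <- solve_branch(br, bp$scheme)
    res <- scheme_residual(U, alpha, bp$scheme$dt, bp$scheme$dx,
                           k_fun = function(x, t) 0 * x + t^2)
    expect_lt(res, 1e-10)
  }
})

test_that("at alpha = 1 the solver equals an independent backward-Euler code", {
  bp <- benchmark_problem(alpha = 1)
  for (r in c(0, 0.7)) {
    brs <- defuzzify_problem(bp$problem, r)
    for (side in c("lower", "upper")) {
      br <- brs[[side]]
      got <- solve_branch(br, bp$scheme)
      want <- backward_euler_oracle(br$ic, br$k, br$bc_left, br$bc_right,
                                    L = 5, T = 0.05, dt = 0.01, dx = 0.5)
      expect_lt(max(abs(got - want)), 1e-12)
    }
  }
})

test_that("non-commensurate meshes fail fast with a suggestion", {
  expect_error(scheme_params(0.5, 0.013, 0.5, 5, 0.05), "commensurate")
  expect_error(scheme_params(0.5, 0.01, 0.4, 5, 0.05), "commensurate")
})

test_that("fuzzy solves keep the envelope and respond monotonically to r", {
  bp <- benchmark_problem(alpha = 0.6)
  sols <- lapply(c(0, 0.3, 0.7, 1), function(r) solve_fuzzy(bp$problem, r, bp$scheme))
  for (s in sols) {
    expect_true(s$envelope_ok)
    expect_true(all(s$lower <= s$upper + 1e-12))
  }
  at <- function(s, br) grid_value(s, 4, 0.05)[[br]]
  lows <- vapply(sols, at, numeric(1), br = "lower")
  ups <- vapply(sols, at, numeric(1), br = "upper")
  expect_true(all(diff(lows) > 0))   # lower branch nondecreasing in r
  expect_true(all(diff(ups) < 0))    # upper branch nonincreasing in r
  # degenerate cut: branches coincide
  expect_equal(sols[[4]]$lower, sols[[4]]$upper, tolerance = 1e-13)
})

test_that("large mesh ratios stay bounded (unconditional stability smoke)", {
  bp <- benchmark_problem(alpha = 0.5, dt = 0.5, dx = 0.1, t_final = 1)
  expect_gt(bp$scheme$tau, 40)
  sol <- solve_fuzzy(bp$problem, 0, bp$scheme)
  bound <- max(abs(sol$upper[1, ]), abs(sol$upper[, 1]), abs(sol$upper[, ncol(sol$upper)]))
  expect_lt(max(abs(sol$upper)), 3 * bound)
  expect_false(any(!is.finite(sol$lower)))
})

test_that("tidy/glance expose the grid as tabular data", {
  bp <- benchmark_problem()
  sol <- solve_fuzzy(bp$problem, 0.3, bp$scheme)
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(sol$x) * length(sol$t))
  expect_named(td, c("x", "t", "r", "alpha", "lower", "upper"))
  row <- td[td$x == 4 & td$t == 0.05, ]
  expect_equal(c(row$lower, row$upper), unname(grid_value(sol, 4, 0.05)))
  g <- glance(sol)
  expect_equal(nrow(g), 1L)
  expect_true(g$envelope_ok)
  p <- ggplot2::autoplot(sol)
  expect_s3_class(p, "ggplot")
})
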