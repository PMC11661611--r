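#' Tridiagonal coefficients of the implicit update
#'
#' The implicit step couples the new time level through
#' `-tau u_{i-1} + (1 + 2 tau) u_i - tau u_{i+1}` at every interior node,
#' so the system matrix has constant diagonal `1 + 2 tau` and off-diagonals
#' `-tau`. It is strictly diagonally dominant with margin exactly 1 at
#' interior rows, for every mesh ratio — the algebraic root of the scheme's
#' unconditional stability.
#'
#' @param tau mesh ratio, > 0 (see [mesh_ratio()]).
#' @param n_interior number of interior nodes, >= 1.
#' @return list with numeric vectors `sub`, `diag`, `super` (lengths
#'   `n_interior - 1`, `n_interior`, `n_interior - 1`).
#' @export
assemble_tridiagonal <- function(tau, n_interior) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0,
            n_interior >= 1, n_interior == round(n_interior))
  list(sub = rep(-tau, n_interior - 1),
       diag = rep(1 + 2 * tau, n_interior),
       super = rep(-tau, n_interior - 1))
}

#' Thomas algorithm for tridiagonal systems
#'
#' O(n) Gaussian elimination without pivoting, valid for the strictly
#' diagonally dominant systems the implicit assembly produces.
#'
#' @param sub,diag,super sub-, main- and super-diagonal coefficient vectors.
#' @param rhs right-hand side, same length as `diag`.
#' @return solution vector `x` with `T x = rhs`.
#' @export
thomas_solve <- function(sub, diag, super, rhs) {
  n <- length(diag)
  stopifnot(length(rhs) == n, length(sub) == n - 1 || n == 1,
            length(super) == n - 1 || n == 1)
  cp <- numeric(max(n - 1, 0))
  dp <- numeric(n)
  piv <- diag[1]
  if (piv == 0) stop("zero pivot in tridiagonal elimination", call. = FALSE)
  if (n > 1) cp[1] <- super[1] / piv
  dp[1] <- rhs[1] / piv
  if (n > 1) {
    for (i in 2:n) {
      piv <- diag[i] - sub[i - 1] * cp[i - 1]
      if (piv == 0) stop("zero pivot in tridiagonal elimination", call. = FALSE)
      if (i < n) cp[i] <- super[i] / piv
      dp[i] <- (rhs[i] - sub[i - 1] * dp[i - 1]) / piv
    }
    for (i in (n - 1):1) dp[i] <- dp[i] - cp[i] * dp[i + 1]
  }
  dp
}

#' Right-hand side of the implicit step
#'
#' Builds the interior-node RHS of the update at time level `n + 1`:
#' `(1 - kf_i) u_i^n - sum_{j=1}^{n} b_j (u_i^{n+1-j} - u_i^{n-j})`
#' where `kf_i = gamma(2 - alpha) dt^alpha k(x_i, t_n)` is the (lagged)
#' killing factor, plus the Dirichlet contributions `tau * bc` at the first
#' and last interior entries. At `n = 0` the memory sum is empty; at
#' `alpha = 1` all weights vanish and the RHS is the classical backward-Euler
#' one.
#'
#' @param history numeric matrix of the `n + 1` completed time levels (rows
#'   `u^0 .. u^n`) over all nodes, boundaries included.
#' @param weights Caputo weights `b_1 .. b_n` from [caputo_weights()]
#'   (length >= n).
#' @param killing_factor numeric vector over interior nodes:
#'   `gamma(2 - alpha) dt^alpha k(x_i, t_n)`.
#' @param tau mesh ratio.
#' @param bc_left,bc_right Dirichlet values at the new level `n + 1`.
#' @return numeric RHS vector over the interior nodes.
#' @export
build_rhs <- function(history, weights, killing_factor, tau, bc_left, bc_right) {
  stopifnot(is.matrix(history), nrow(history) >= 1)
  n <- nrow(history) - 1L
  m_int <- ncol(history) - 2L
  stopifnot(m_int >= 1, length(killing_factor) %in% c(1L, m_int))
  if (length(weights) < n) {
    stop(sprintf("need %d Caputo weights, got %d", n, length(weights)), call. = FALSE)
  }
  int <- 2:(m_int + 1L)
  rhs <- (1 - killing_factor) * history[n + 1L, int]
  if (n >= 1L) {
    for (j in seq_len(n)) {
      rhs <- rhs - weights[j] * (history[n + 2L - j, int] - history[n + 1L - j, int])
    }
  }
  rhs[1L] <- rhs[1L] + tau * bc_left
  rhs[m_int] <- rhs[m_int] + tau * bc_right
  rhs
}

#' March one crisp branch of the model
#'
#' Time-marches the implicit Caputo L1 / central-difference scheme for a
#' crisp branch problem: at each step the full solution history enters the
#' memory term, the killing term is lagged at level `n`, and one strictly
#' diagonally dominant tridiagonal system is solved by [thomas_solve()].
#'
#' @param problem a `crisp_branch_problem` (one element of
#'   [defuzzify_problem()]'s result).
#' @param scheme a [scheme_params()]. Its mesh must tile the problem domain.
#' @return numeric matrix of size `(n_steps + 1) x (n_nodes + 1)`: rows are
#'   time levels `t_n = n dt`, columns are nodes `x_i = i dx`. Row 1 is the
#'   initial condition; first and last columns are the boundary values.
#' @export
solve_branch <- function(problem, scheme) {
  stopifnot(inherits(problem, "crisp_branch_problem"),
            inherits(scheme, "scheme_params"))
  if (abs(scheme$n_steps * scheme$dt - problem$t_final) > 1e-9 * max(1, problem$t_final) ||
      abs(scheme$n_nodes * scheme$dx - problem$length_L) > 1e-9 * max(1, problem$length_L)) {
    stop("scheme mesh does not tile the problem domain", call. = FALSE)
  }
  M <- scheme$n_nodes
  N <- scheme$n_steps
  x <- (0:M) * scheme$dx
  x_int <- x[2:M]
  coeff <- gamma(2 - scheme$alpha) * scheme$dt^scheme$alpha
  weights <- caputo_weights(scheme$alpha, N)
  sys <- assemble_tridiagonal(scheme$tau, M - 1L)

  U <- matrix(0, N + 1L, M + 1L)
  U[1L, ] <- problem$ic(x)
  for (n in 0:(N - 1L)) {
    t_n <- n * scheme$dt
    t_new <- (n + 1L) * scheme$dt
    kf <- coeff * problem$k(x_int, t_n)
    bl <- problem$bc_left(t_new)
    br <- problem$bc_right(t_new)
    rhs <- build_rhs(U[seq_len(n + 1L), , drop = FALSE], weights, kf,
                     scheme$tau, bl, br)
    U[n + 2L, 2:M] <- thomas_solve(sys$sub, sys$diag, sys$super, rhs)
    U[n + 2L, 1L] <- bl
    U[n + 2L, M + 1L] <- br
  }
  dimnames(U) <- list(t = format((0:N) * scheme$dt), x = format(x))
  U
}

#' Solve the fuzzy model at one membership level
#'
#' Runs [solve_branch()] on the lower and upper branch problems obtained by
#' [defuzzify_problem()] and bundles the two solution surfaces. The envelope
#' property (`lower <= upper` at every node) is checked after the solve;
#' because the branches are solved independently a violation is possible in
#' principle, so it raises a warning and sets `envelope_ok = FALSE` rather
#' than an error.
#'
#' @inheritParams defuzzify_problem
#' @param scheme a [scheme_params()].
#' @return a `fuzzy_solution_grid`: list with `x`, `t`, `lower`, `upper`
#'   (matrices, time level by node), `r`, `alpha`, `tau`, `scheme`,
#'   `envelope_ok`.
#' @examples
#' bp <- benchmark_problem()
#' sol <- solve_fuzzy(bp$problem, r = 0, bp$scheme)
#' glance(sol)
#' @export
solve_fuzzy <- function(spec, r, scheme) {
  branches <- defuzzify_problem(spec, r)
  lower <- solve_branch(branches$lower, scheme)
  upper <- solve_branch(branches$upper, scheme)
  envelope_ok <- all(lower <= upper + 1e-12)
  if (!envelope_ok) {
    warning("fuzzy envelope violated: lower branch exceeds upper branch at some node",
            call. = FALSE)
  }
  structure(
    list(x = (0:scheme$n_nodes) * scheme$dx,
         t = (0:scheme$n_steps) * scheme$dt,
         lower = lower, upper = upper,
         r = r, alpha = scheme$alpha, tau = scheme$tau,
         scheme = scheme, envelope_ok = envelope_ok),
    class = "fuzzy_solution_grid"
  )
}

#' Read a fuzzy solution grid at a space-time point
#'
#' @param sol a `fuzzy_solution_grid`.
#' @param x,t node position and time level; must coincide with grid points.
#' @return named numeric vector `c(lower, upper)`.
#' @export
grid_value <- function(sol, x, t) {
  stopifnot(inherits(sol, "fuzzy_solution_grid"))
  i <- which(abs(sol$x - x) <= 1e-9 * max(1, abs(x)))
  n <- which(abs(sol$t - t) <= 1e-9 * max(1, abs(t)))
  if (length(i) != 1L || length(n) != 1L) {
    stop("requested point is not on the solution grid", call. = FALSE)
  }
  c(lower = sol$lower[n, i], upper = sol$upper[n, i])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fuzzy solution grid into a long tibble
#'
#' @param x a `fuzzy_solution_grid`.
#' @param ... unused.
#' @return a tibble with columns `x`, `t`, `r`, `alpha`, `lower`, `upper`,
#'   ordered t-major then x.
#' @method tidy fuzzy_solution_grid
#' @export
tidy.fuzzy_solution_grid <- function(x, ...) {
  sol <- x
  grid <- tidyr::expand_grid(t = sol$t, x_pos = sol$x)
  tibble::tibble(
    x = grid$x_pos, t = grid$t, r = sol$r, alpha = sol$alpha,
    lower = as.vector(t(sol$lower)), upper = as.vector(t(sol$upper))
  )
}

#' One-row summary of a fuzzy solution grid
#'
#' @param x a `fuzzy_solution_grid`.
#' @param ... unused.
#' @return a one-row tibble: `alpha`, `r`, `tau`, `n_steps`, `n_nodes`,
#'   `envelope_ok`, `min_lower`, `max_upper`.
#' @method glance fuzzy_solution_grid
#' @export
glance.fuzzy_solution_grid <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, r = x$r, tau = x$tau,
    n_steps = x$scheme$n_steps, n_nodes = x$scheme$n_nodes,
    envelope_ok = x$envelope_ok,
    min_lower = min(x$lower), max_upper = max(x$upper)
  )
}

#' @export
print.fuzzy_solution_grid <- function(x, ...) {
  cat(sprintf(
    "fuzzy solution grid: alpha = %g, r = %g, tau = %.4g, %d time steps x %d nodes%s\n",
    x$alpha, x$r, x$tau, x$scheme$n_steps, x$scheme$n_nodes,
    if (x$envelope_ok) "" else " [envelope violated]"
  ))
  invisible(x)
}

#' Plot the fuzzy solution envelope at selected times
#'
#' Draws the lower/upper branch envelope of the tumor-cell concentration as a
#' ribbon over `x`, faceted by time level.
#'
#' @param object a `fuzzy_solution_grid`.
#' @param times time levels to show; defaults to first, middle and final.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fuzzy_solution_grid
#' @export
autoplot.fuzzy_solution_grid <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    times <- unique(object$t[c(1L, ceiling(length(object$t) / 2), length(object$t))])
  }
  dat <- tidy(object)
  dat <- dplyr::filter(dat, .data$t %in% times)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), colour = "steelblue4") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), colour = "steelblue4") +
    ggplot2::facet_wrap(~t, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "x", y = "tumor-cell concentration",
      title = sprintf("Fuzzy envelope at r = %g, alpha = %g", object$r, object$alpha)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
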