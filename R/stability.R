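#' Von Neumann amplification recursion
#'
#' Iterates the Fourier-mode amplification recursion of the implicit scheme
#' from `lambda^0 = 1`:
#'
#' `lambda^{n+1} = [ (1 - kf - b_1) lambda^n
#'                  - sum_{j=1}^{n-1} (b_{j+1} - b_j) lambda^{n-j}
#'                  + b_n lambda^0 ] / (1 + 4 tau sin^2(theta / 2))`
#'
#' (at `n = 0` the numerator is `(1 - kf) lambda^0`), where `theta` is the
#' Fourier phase, `tau` the mesh ratio and `kf` the killing factor
#' `gamma(2 - alpha) dt^alpha k` (equivalently `tau dx^2 k`). Because the
#' weights decrease and the denominator is `>= 1` for every `tau`, the
#' magnitudes never exceed the initial one — the scheme is unconditionally
#' stable, and this function makes that claim machine-checkable.
#'
#' @param theta Fourier phase in `(0, pi]` (0 allowed; gives the constant
#'   mode).
#' @param tau mesh ratio, > 0.
#' @param alpha fractional order in (0, 1].
#' @param killing_factor the nonnegative factor `gamma(2-alpha) dt^alpha k`;
#'   conservatively, its worst case (max) over the time window.
#' @param n_steps number of iterations, >= 1.
#' @return numeric vector of the magnitudes `|lambda^n / lambda^0|`,
#'   `n = 0 .. n_steps`.
#' @export
amplification_factors <- function(theta, tau, alpha, killing_factor = 0,
                                  n_steps = 50) {
  check_alpha(alpha)
  stopifnot(is.numeric(theta), length(theta) == 1L,
            is.numeric(tau), length(tau) == 1L, tau > 0,
            killing_factor >= 0, n_steps >= 1)
  b <- caputo_weights(alpha, n_steps)
  denom <- 1 + 4 * tau * sin(theta / 2)^2
  lam <- numeric(n_steps + 1L)
  lam[1L] <- 1
  for (n in 0:(n_steps - 1L)) {
    if (n == 0L) {
      num <- (1 - killing_factor) * lam[1L]
    } else {
      num <- (1 - killing_factor - b[1L]) * lam[n + 1L] + b[n] * lam[1L]
      if (n >= 2L) {
        j <- seq_len(n - 1L)
        num <- num - sum((b[j + 1L] - b[j]) * lam[n + 1L - j])
      }
    }
    lam[n + 2L] <- num / denom
  }
  abs(lam)
}

#' Sweep the amplification factor over a parameter grid
#'
#' Convenience grid sweep of [amplification_factors()]; the supremum column
#' is the quantity the unconditional-stability claim bounds by 1.
#'
#' @param theta_grid Fourier phases.
#' @param tau_grid mesh ratios.
#' @param alpha_grid fractional orders.
#' @param killing_factor,n_steps passed to [amplification_factors()].
#' @return a tibble with columns `theta`, `tau`, `alpha`, `max_magnitude`.
#' @export
amplification_sweep <- function(theta_grid = seq(pi / 50, pi, length.out = 50),
                                tau_grid = c(0.01, 0.354, 1, 100),
                                alpha_grid = c(0.2, 0.5, 0.8, 1),
                                killing_factor = 0, n_steps = 100) {
  grid <- tidyr::expand_grid(theta = theta_grid, tau = tau_grid, alpha = alpha_grid)
  grid$max_magnitude <- purrr::pmap_dbl(grid, function(theta, tau, alpha) {
    max(amplification_factors(theta, tau, alpha, killing_factor, n_steps))
  })
  grid
}

#' Discrete fuzzy error norm
#'
#' The weighted l2 norm over interior nodes,
#' `||e||_2 = sqrt( sum_i h |e_i|^2 )`, used to measure perturbation growth.
#'
#' @param e numeric vector of interior-node errors.
#' @param h space step.
#' @return nonnegative scalar.
#' @export
fuzzy_error_norm <- function(e, h) {
  stopifnot(h > 0)
  sqrt(sum(h * abs(e)^2))
}

#' Initial-condition perturbation experiment
#'
#' Empirical counterpart of the stability theorem: solves a fuzzy problem
#' twice, once with the stated initial condition and once with the initial
#' condition perturbed by `delta(x)`, and tracks the discrete error norm of
#' the difference over time, per branch. For the implicit scheme the norm
#' sequence must not grow above its initial value, on any mesh.
#'
#' @inheritParams solve_fuzzy
#' @param delta perturbation sampler `delta(x)`; if `NULL`, a reproducible
#'   random perturbation `amp * runif(-1, 1)` on interior nodes is drawn
#'   using `seed`.
#' @param amp amplitude of the random perturbation (default 1e-3).
#' @param seed integer seed for the random perturbation.
#' @return a `perturbation_experiment`: list with a tibble `norms` (columns
#'   `step`, `t`, `branch`, `norm`, `ratio`), `max_ratio`, and the two runs.
#' @export
perturbation_experiment <- function(spec, scheme, r = 0, delta = NULL,
                                    amp = 1e-3, seed = 1L) {
  stopifnot(inherits(spec, "tumor_problem"))
  M <- scheme$n_nodes
  if (is.null(delta)) {
    set.seed(seed)
    bump <- stats::runif(M - 1L, -amp, amp)
    xs_int <- (1:(M - 1L)) * scheme$dx
    delta <- function(x) {
      out <- numeric(length(x))
      idx <- match(round(x / scheme$dx), round(xs_int / scheme$dx))
      hit <- !is.na(idx)
      out[hit] <- bump[idx[hit]]
      out
    }
  }
  perturbed <- spec
  base_ic <- spec$ic_shape
  # perturb the crisp shape; boundary nodes keep the unperturbed BC values
  perturbed$ic_shape <- function(x) base_ic(x) + delta(x)
  base_run <- solve_fuzzy(spec, r, scheme)
  pert_run <- solve_fuzzy(perturbed, r, scheme)
  int <- 2:M
  norms <- dplyr::bind_rows(lapply(c("lower", "upper"), function(br) {
    eps <- pert_run[[br]][, int, drop = FALSE] - base_run[[br]][, int, drop = FALSE]
    nrm <- apply(eps, 1L, fuzzy_error_norm, h = scheme$dx)
    tibble::tibble(step = 0:scheme$n_steps, t = base_run$t, branch = br,
                   norm = nrm,
                   ratio = if (nrm[1L] > 0) nrm / nrm[1L] else nrm)
  }))
  structure(
    list(norms = norms,
         max_ratio = max(norms$ratio),
         base = base_run, perturbed = pert_run, r = r, scheme = scheme),
    class = "perturbation_experiment"
  )
}

#' @export
print.perturbation_experiment <- function(x, ...) {
  cat(sprintf(
    "perturbation experiment: alpha = %g, r = %g, tau = %.4g, max norm ratio = %.6g\n",
    x$scheme$alpha, x$r, x$scheme$tau, x$max_ratio
  ))
  invisible(x)
}

#' Plot perturbation norm histories
#'
#' @param object a [perturbation_experiment()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot perturbation_experiment
#' @export
autoplot.perturbation_experiment <- function(object, ...) {
  ggplot2::ggplot(object$norms,
                  ggplot2::aes(x = .data$t, y = .data$ratio,
                               colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "t", y = expression("||" * epsilon^n * "|| / ||" * epsilon^0 * "||"),
                  title = "Perturbation norm growth (implicit scheme)")
}

#' Explicit-scheme reference (internal comparator)
#'
#' A minimal explicit counterpart of [solve_branch()] — same Caputo memory
#' term and lagged killing, but the spatial stencil taken at the old time
#' level, so no linear solve. It is conditionally stable and diverges for
#' large mesh ratios; it exists to contrast with the implicit scheme in
#' stability demonstrations, not as a production solver.
#'
#' @inheritParams solve_branch
#' @return solution matrix as in [solve_branch()].
#' @keywords internal
#' @export
solve_branch_explicit <- function(problem, scheme) {
  stopifnot(inherits(problem, "crisp_branch_problem"),
            inherits(scheme, "scheme_params"))
  M <- scheme$n_nodes
  N <- scheme$n_steps
  x <- (0:M) * scheme$dx
  x_int <- x[2:M]
  coeff <- gamma(2 - scheme$alpha) * scheme$dt^scheme$alpha
  weights <- caputo_weights(scheme$alpha, N)
  U <- matrix(0, N + 1L, M + 1L)
  U[1L, ] <- problem$ic(x)
  for (n in 0:(N - 1L)) {
    t_n <- n * scheme$dt
    kf <- coeff * problem$k(x_int, t_n)
    lap <- U[n + 1L, 3:(M + 1L)] - 2 * U[n + 1L, 2:M] + U[n + 1L, 1:(M - 1L)]
    new <- (1 - kf) * U[n + 1L, 2:M] + scheme$tau * lap
    if (n >= 1L) {
      for (j in seq_len(n)) {
        new <- new - weights[j] * (U[n + 2L - j, 2:M] - U[n + 1L - j, 2:M])
      }
    }
    U[n + 2L, 2:M] <- new
    U[n + 2L, 1L] <- problem$bc_left((n + 1L) * scheme$dt)
    U[n + 2L, M + 1L] <- problem$bc_right((n + 1L) * scheme$dt)
  }
  U
}
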