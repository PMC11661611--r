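#' Fuzzy tumor-model problem specification
#'
#' Defines an instance of the one-dimensional fuzzy time-fractional tumor
#' model on `[0, L] x [0, T]`:
#' `d^alpha u / dt^alpha = d^2 u / dx^2 - k(x, t) u`, with fuzzy
#' initial-condition and killing-rate coefficients carried in r-cut form.
#' The killing rate factorises as `killing_coefficient * killing_shape(x, t)`
#' and the initial condition as `ic_coefficient * ic_shape(x)`; Dirichlet
#' boundary values are fuzzy-valued samplers of `(t, r)`.
#'
#' @param length_L spatial domain length, > 0.
#' @param t_final final time, > 0.
#' @param ic_shape function `s2(x)`, the crisp spatial profile of the initial
#'   condition; vectorised over `x`.
#' @param ic_coefficient a [fuzzy_number()]: the fuzzy factor multiplying
#'   `ic_shape`.
#' @param killing_shape function `s1(x, t)`, the crisp net cell-killing rate
#'   profile (units: inverse time); vectorised over `x`.
#' @param killing_coefficient a [fuzzy_number()] multiplying `killing_shape`;
#'   defaults to the crisp value 1.
#' @param bc_left,bc_right fuzzy Dirichlet samplers: functions of `(t, r)`
#'   returning `c(lower, upper)` boundary values at `x = 0` and `x = L`.
#' @return a `tumor_problem` object.
#' @seealso [defuzzify_problem()], [solve_fuzzy()], [benchmark_problem()]
#' @export
tumor_problem <- function(length_L, t_final, ic_shape, ic_coefficient,
                          killing_shape = function(x, t) 0 * x,
                          killing_coefficient = fuzzy_crisp(1),
                          bc_left, bc_right) {
  stopifnot(is.numeric(length_L), length_L > 0, is.numeric(t_final), t_final > 0,
            is.function(ic_shape), is.function(killing_shape),
            inherits(ic_coefficient, "fuzzy_number"),
            inherits(killing_coefficient, "fuzzy_number"),
            is.function(bc_left), is.function(bc_right))
  structure(
    list(length_L = length_L, t_final = t_final,
         ic_shape = ic_shape, ic_coefficient = ic_coefficient,
         killing_shape = killing_shape, killing_coefficient = killing_coefficient,
         bc_left = bc_left, bc_right = bc_right),
    class = "tumor_problem"
  )
}

#' Discretization parameters for the implicit scheme
#'
#' Collects the mesh (`dt`, `dx`), the fractional order, the derived mesh
#' ratio `tau = gamma(2 - alpha) dt^alpha / dx^2`, and the grid counts. The
#' mesh must tile the domain: `dt` must divide `t_final` and `dx` must divide
#' `length_L` to within 1e-9 relative, otherwise the constructor fails fast
#' with a suggested commensurate step rather than silently re-meshing.
#'
#' @inheritParams mesh_ratio
#' @param length_L,t_final domain extents the mesh must tile.
#' @return a `scheme_params` object with fields `alpha`, `dt`, `dx`, `tau`,
#'   `n_steps`, `n_nodes`.
#' @export
scheme_params <- function(alpha, dt, dx, length_L, t_final) {
  tau <- mesh_ratio(alpha, dt, dx)  # validates alpha, dt, dx
  n_steps <- commensurate_count(t_final, dt, "dt", "t_final")
  n_nodes <- commensurate_count(length_L, dx, "dx", "length_L")
  if (n_nodes < 2) stop("mesh must have at least one interior node", call. = FALSE)
  structure(
    list(alpha = alpha, dt = dt, dx = dx, tau = tau,
         n_steps = n_steps, n_nodes = n_nodes),
    class = "scheme_params"
  )
}

commensurate_count <- function(total, step, step_name, total_name) {
  n <- total / step
  if (abs(n - round(n)) > 1e-9 * max(1, abs(n))) {
    stop(sprintf(
      "%s = %g does not divide %s = %g; nearest commensurate %s is %g",
      step_name, step, total_name, total, step_name, total / round(n)
    ), call. = FALSE)
  }
  as.integer(round(n))
}

#' Defuzzify a fuzzy problem into crisp lower/upper branch problems
#'
#' At membership level `r` the fuzzy model decomposes into two decoupled
#' crisp initial-boundary-value problems of the form
#' `d^alpha u / dt^alpha = u_xx - k(x, t) u`: the lower branch takes the
#' lower r-cut endpoints of the fuzzy coefficients and boundary values, the
#' upper branch the upper endpoints. For a degenerate (crisp) specification
#' the two branches coincide at every `r`.
#'
#' Corner consistency (`ic(0) == bc(0)` at both ends, per branch) is checked
#' and violations beyond `corner_tol` raise a warning.
#'
#' @param spec a [tumor_problem()].
#' @param r membership level in \[0, 1\].
#' @param corner_tol tolerance for the IC/BC corner-compatibility warning.
#' @return a list with elements `lower` and `upper`, each a
#'   `crisp_branch_problem`: a list with `ic(x)`, `k(x, t)`, `bc_left(t)`,
#'   `bc_right(t)`, `length_L`, `t_final`, `branch`, `r`.
#' @export
defuzzify_problem <- function(spec, r, corner_tol = 1e-8) {
  stopifnot(inherits(spec, "tumor_problem"))
  check_r(r)
  branches <- lapply(c(lower = 1L, upper = 2L), function(side) {
    tau2 <- unname(r_cut(spec$ic_coefficient, r)[side])
    tau1 <- unname(r_cut(spec$killing_coefficient, r)[side])
    branch_name <- c("lower", "upper")[side]
    force(tau2); force(tau1)
    prob <- structure(
      list(
        ic = function(x) tau2 * spec$ic_shape(x),
        k = function(x, t) tau1 * spec$killing_shape(x, t),
        bc_left = function(t) unname(spec$bc_left(t, r)[side]),
        bc_right = function(t) unname(spec$bc_right(t, r)[side]),
        length_L = spec$length_L, t_final = spec$t_final,
        branch = branch_name, r = r
      ),
      class = "crisp_branch_problem"
    )
    corners <- c(prob$ic(0) - prob$bc_left(0), prob$ic(spec$length_L) - prob$bc_right(0))
    if (any(abs(corners) > corner_tol)) {
      warning(sprintf(
        "%s branch: initial and boundary conditions disagree at a corner (max |gap| = %.3g)",
        branch_name, max(abs(corners))
      ), call. = FALSE)
    }
    prob
  })
  branches
}
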