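#' Run configuration
#'
#' A serializable description of a benchmark-family run: the fuzzy
#' initial-condition coefficient as a triangular 3-tuple, the spatial profile
#' exponent, mesh, domain, and the alpha/r evaluation grids. The defaults
#' reproduce the benchmark study exactly (time-dependent killing rate `t^2`,
#' `dt = 0.01`, `dx = 0.5`, domain `[0, 5]`, `t = 0.05`, alpha grid
#' `0.2 .. 1`, r grid `0, 0.3, 0.7`). Round-trips losslessly through
#' [write_run_config()] / [read_run_config()].
#'
#' @param alpha_grid fractional orders, each in (0, 1].
#' @param r_grid membership levels, each in \[0, 1\].
#' @param dt,dx mesh sizes, > 0.
#' @param length_L,t_final domain extents, > 0.
#' @param k_exp spatial profile exponent.
#' @param ic_coefficient numeric 3-tuple `(left, peak, right)` of the
#'   triangular initial-condition coefficient.
#' @param x_report,t_report report point.
#' @param seed integer seed recorded for any randomised downstream step.
#' @param log_level one of `"quiet"`, `"info"`.
#' @return a `run_config` object (named list).
#' @export
run_config <- function(alpha_grid = c(0.2, 0.4, 0.6, 0.8, 1),
                       r_grid = c(0, 0.3, 0.7),
                       dt = 0.01, dx = 0.5,
                       length_L = 5, t_final = 0.05,
                       k_exp = -1,
                       ic_coefficient = c(0.75, 1, 1.25),
                       x_report = 4, t_report = 0.05,
                       seed = 1L,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (any(alpha_grid <= 0 | alpha_grid > 1)) {
    stop("alpha_grid values must lie in (0, 1]", call. = FALSE)
  }
  if (any(r_grid < 0 | r_grid > 1)) {
    stop("r_grid values must lie in [0, 1]", call. = FALSE)
  }
  if (dt <= 0 || dx <= 0 || length_L <= 0 || t_final <= 0) {
    stop("mesh sizes and domain extents must be positive", call. = FALSE)
  }
  if (length(ic_coefficient) != 3L || is.unsorted(ic_coefficient)) {
    stop("ic_coefficient must be a nondecreasing (left, peak, right) triple",
         call. = FALSE)
  }
  structure(
    list(alpha_grid = as.numeric(alpha_grid), r_grid = as.numeric(r_grid),
         dt = dt, dx = dx, length_L = length_L, t_final = t_final,
         k_exp = k_exp, ic_coefficient = as.numeric(ic_coefficient),
         x_report = x_report, t_report = t_report,
         seed = as.integer(seed), log_level = log_level),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Missing keys take the benchmark defaults; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a validated [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, raw)
}

#' Write a run configuration to a YAML file
#'
#' @param config a [run_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' Instantiate the problem and schemes described by a configuration
#'
#' @param config a [run_config()].
#' @param alpha fractional order to build the scheme for (must come from the
#'   configured grid unless `strict = FALSE`).
#' @param strict require `alpha` to be in `config$alpha_grid`.
#' @return list with `problem` and `scheme`, as [benchmark_problem()].
#' @export
config_problem <- function(config, alpha, strict = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (strict && !any(abs(config$alpha_grid - alpha) < 1e-12)) {
    stop("alpha not in the configured grid", call. = FALSE)
  }
  ic <- config$ic_coefficient
  bp <- benchmark_problem(alpha = alpha, dt = config$dt, dx = config$dx,
                          length_L = config$length_L, t_final = config$t_final,
                          k_exp = config$k_exp)
  if (!isTRUE(all.equal(ic, c(0.75, 1, 1.25)))) {
    s_coef <- fuzzy_triangular(ic[1], ic[2], ic[3])
    bc_at <- function(x0) function(t, r) c(
      lower = exact_solution(x0, t, alpha, r, "lower", config$k_exp, s_coef),
      upper = exact_solution(x0, t, alpha, r, "upper", config$k_exp, s_coef)
    )
    bp$problem <- tumor_problem(
      length_L = config$length_L, t_final = config$t_final,
      ic_shape = function(x) exp(config$k_exp * x),
      ic_coefficient = s_coef,
      killing_shape = function(x, t) 0 * x + t^2,
      bc_left = bc_at(0), bc_right = bc_at(config$length_L)
    )
  }
  bp
}

fmt17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a fuzzy solution grid (or tidy table) to CSV
#'
#' Long format with header `x,t,r,alpha,lower,upper`, rows ordered t-major
#' then x. Floats are written with 17 significant digits so a read-back
#' reproduces the grid bit-for-bit.
#'
#' @param x a `fuzzy_solution_grid` or a data frame with the long-format
#'   columns (an empty one yields a header-only file).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(x, path) {
  if (inherits(x, "fuzzy_solution_grid")) x <- tidy(x)
  cols <- c("x", "t", "r", "alpha", "lower", "upper")
  stopifnot(all(cols %in% names(x)))
  x <- x[order(x$t, x$x), cols]
  lines <- paste(cols, collapse = ",")
  if (nrow(x) > 0) {
    body <- do.call(paste, c(lapply(x, fmt17), sep = ","))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format solution CSV
#'
#' @param path file written by [write_solution_csv()].
#' @return a tibble with columns `x`, `t`, `r`, `alpha`, `lower`, `upper`.
#' @export
read_solution_csv <- function(path) {
  dat <- utils::read.csv(path, colClasses = "numeric")
  tibble::as_tibble(dat)
}

#' Export a solution as a self-describing JSON bundle
#'
#' @param sol a `fuzzy_solution_grid`.
#' @param path output file path.
#' @param config optional [run_config()] to embed.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(sol, path, config = NULL) {
  stopifnot(inherits(sol, "fuzzy_solution_grid"))
  bundle <- list(
    alpha = sol$alpha, r = sol$r, tau = sol$tau,
    dt = sol$scheme$dt, dx = sol$scheme$dx,
    envelope_ok = sol$envelope_ok,
    x = sol$x, t = sol$t,
    lower = unname(sol$lower),
    upper = unname(sol$upper)
  )
  if (!is.null(config)) bundle$config <- unclass(config)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
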