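#' Caputo L1 memory weights
#'
#' The L1 discretization of the Caputo derivative of order `alpha` writes the
#' memory term as a weighted sum over all previous time levels with weights
#' `b_j = (j + 1)^(1 - alpha) - j^(1 - alpha)`, `j = 1, 2, ...`. For
#' `0 < alpha < 1` the weights lie in (0, 1], decrease strictly in `j`, and
#' telescope: `sum_{j=1}^{n-1} (b_{j+1} - b_j) = b_n - b_1`. At `alpha = 1`
#' every weight is exactly zero and the scheme reduces to classical backward
#' Euler; that case is short-circuited to avoid floating-point noise.
#'
#' Weights are cached per `alpha` so each time step reuses the prefix already
#' computed.
#'
#' @param alpha fractional order, in (0, 1].
#' @param n number of completed time steps (weights `b_1 .. b_n`); `n = 0`
#'   yields an empty vector.
#' @return numeric vector of length `n`, with attribute `alpha`.
#' @examples
#' caputo_weights(0.5, 2)  # c(sqrt(2) - 1, sqrt(3) - sqrt(2))
#' caputo_weights(1, 5)    # exact zeros
#' @export
caputo_weights <- function(alpha, n) {
  check_alpha(alpha)
  stopifnot(length(n) == 1L, is.finite(n), n >= 0, n == round(n))
  n <- as.integer(n)
  if (n == 0L) {
    return(structure(numeric(0), alpha = alpha))
  }
  if (alpha == 1) {
    return(structure(rep(0, n), alpha = alpha))
  }
  key <- format(alpha, digits = 17)
  cached <- .weight_cache[[key]]
  if (is.null(cached) || length(cached) < n) {
    j <- seq_len(n)
    cached <- (j + 1)^(1 - alpha) - j^(1 - alpha)
    .weight_cache[[key]] <- cached
  }
  structure(cached[seq_len(n)], alpha = alpha)
}

.weight_cache <- new.env(parent = emptyenv())

#' Mesh ratio of the implicit scheme
#'
#' The dimensionless coupling `tau = gamma(2 - alpha) * dt^alpha / dx^2`
#' multiplying the spatial stencil in the implicit update. At `alpha = 1` it
#' reduces to the classical parabolic mesh ratio `dt / dx^2`.
#'
#' @inheritParams caputo_weights
#' @param dt time step, > 0.
#' @param dx space step, > 0.
#' @return positive numeric scalar.
#' @examples
#' mesh_ratio(1, 0.01, 0.5)    # 0.04
#' mesh_ratio(0.5, 0.01, 0.5)  # gamma(1.5) * 0.1 / 0.25
#' @export
mesh_ratio <- function(alpha, dt, dx) {
  check_alpha(alpha)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive number", call. = FALSE)
  }
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0) {
    stop("dx must be a positive number", call. = FALSE)
  }
  gamma(2 - alpha) * dt^alpha / dx^2
}

#' Caputo weight property check
#'
#' Verifies, for a given `alpha` in (0, 1) strictly and horizon `n`, the
#' three L1-weight properties the stability argument rests on: positivity and
#' boundedness (`0 < b_j <= 1`), strict monotone decrease, and the
#' telescoping identity `sum_{j=1}^{n-1} (b_{j+1} - b_j) = b_n - b_1` to
#' machine precision. (`alpha = 1` is excluded: all weights vanish there and
#' strict positivity fails trivially.)
#'
#' @param alpha fractional order, strictly inside (0, 1).
#' @param n horizon (number of weights), >= 2.
#' @param tol tolerance for the telescoping identity.
#' @return a list with `pass` (logical) and `counterexample` (`NULL`, or a
#'   named list describing the first violated property).
#' @export
caputo_weight_check <- function(alpha, n, tol = 1e-12) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  }
  stopifnot(n >= 2)
  b <- caputo_weights(alpha, n)
  fail <- function(what, detail) list(pass = FALSE, counterexample = c(list(property = what), detail))
  if (any(b <= 0) || any(b > 1)) {
    j <- which(b <= 0 | b > 1)[1]
    return(fail("0 < b_j <= 1", list(j = j, b_j = b[j])))
  }
  if (any(diff(b) >= 0)) {
    j <- which(diff(b) >= 0)[1]
    return(fail("b_j strictly decreasing", list(j = j, b_j = b[j], b_j1 = b[j + 1])))
  }
  lhs <- sum(diff(b))
  rhs <- b[n] - b[1]
  if (abs(lhs - rhs) > tol) {
    return(fail("telescoping sum(b_{j+1} - b_j) == b_n - b_1",
                list(lhs = lhs, rhs = rhs)))
  }
  list(pass = TRUE, counterexample = NULL)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("fractional order alpha must lie in (0, 1]", call. = FALSE)
  }
  invisible(alpha)
}
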