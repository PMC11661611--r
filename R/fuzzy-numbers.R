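#' Parametric (r-cut) fuzzy numbers
#'
#' A fuzzy number is carried through its r-cut endpoint functions
#' `lower(r)` and `upper(r)`, r in \[0, 1\] (single-parametric form). The
#' endpoints must satisfy fuzzy convexity: `lower` nondecreasing, `upper`
#' nonincreasing, `lower(r) <= upper(r)` everywhere, and the two coincide at
#' the core `r = 1`.
#'
#' @param lower,upper functions of a single argument `r` in \[0, 1\],
#'   vectorised over `r`.
#' @return an object of class `fuzzy_number`.
#' @seealso [fuzzy_triangular()] for the triangular special case,
#'   [r_cut()] to evaluate the interval at a membership level.
#' @examples
#' fz <- fuzzy_number(function(r) r - 1, function(r) 1 - r)
#' r_cut(fz, 0.5)
#' @export
fuzzy_number <- function(lower, upper) {
  stopifnot(is.function(lower), is.function(upper))
  structure(list(lower = lower, upper = upper), class = "fuzzy_number")
}

#' Triangular fuzzy number
#'
#' The default fuzzy-number family: piecewise-linear membership determined by
#' `(left, peak, right)`. Its r-cut is the interval
#' `[left + (peak - left) r, right - (right - peak) r]`, which collapses to
#' `peak` at `r = 1`. A degenerate (crisp) number has
#' `left == peak == right`.
#'
#' @param left,peak,right numeric scalars with `left <= peak <= right`.
#' @return a `fuzzy_triangular` object (also a `fuzzy_number`).
#' @examples
#' s <- fuzzy_triangular(0.75, 1, 1.25)
#' r_cut(s, 0)    # c(0.75, 1.25)
#' r_cut(s, 1)    # c(1, 1)
#' @export
fuzzy_triangular <- function(left, peak, right) {
  stopifnot(is.numeric(left), is.numeric(peak), is.numeric(right),
            length(left) == 1L, length(peak) == 1L, length(right) == 1L,
            is.finite(left), is.finite(peak), is.finite(right))
  if (!(left <= peak && peak <= right)) {
    stop("triangular fuzzy number requires left <= peak <= right", call. = FALSE)
  }
  fz <- fuzzy_number(
    lower = function(r) left + (peak - left) * r,
    upper = function(r) right - (right - peak) * r
  )
  fz$left <- left
  fz$peak <- peak
  fz$right <- right
  class(fz) <- c("fuzzy_triangular", class(fz))
  fz
}

#' Crisp (degenerate) fuzzy number
#'
#' Convenience wrapper for a triangular number whose support is a single
#' point, so both r-cut endpoints equal `value` at every r.
#'
#' @param value numeric scalar.
#' @return a `fuzzy_triangular` object.
#' @export
fuzzy_crisp <- function(value) fuzzy_triangular(value, value, value)

#' Evaluate the r-cut interval of a fuzzy number
#'
#' @param fz a [fuzzy_number()] or [fuzzy_triangular()].
#' @param r membership level in \[0, 1\].
#' @return numeric vector `c(lower, upper)` of the interval endpoints.
#' @examples
#' r_cut(fuzzy_triangular(0.75, 1, 1.25), 0.3)  # c(0.825, 1.175)
#' @export
r_cut <- function(fz, r) {
  check_r(r)
  stopifnot(inherits(fz, "fuzzy_number"))
  lo <- fz$lower(r)
  up <- fz$upper(r)
  if (!all(is.finite(lo)) || !all(is.finite(up))) {
    stop("r-cut endpoints must be finite", call. = FALSE)
  }
  if (any(lo > up + 1e-12)) {
    stop("r-cut lower endpoint exceeds upper endpoint", call. = FALSE)
  }
  c(lower = lo, upper = up)
}

#' One endpoint of an r-cut
#'
#' @inheritParams r_cut
#' @param branch `"lower"` or `"upper"`.
#' @return numeric scalar endpoint.
#' @export
r_cut_branch <- function(fz, r, branch = c("lower", "upper")) {
  branch <- match.arg(branch)
  unname(r_cut(fz, r)[[branch]])
}

check_r <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0) || any(r > 1)) {
    stop("membership level r must lie in [0, 1]", call. = FALSE)
  }
  invisible(r)
}

#' @export
print.fuzzy_triangular <- function(x, ...) {
  cat(sprintf("triangular fuzzy number (%g, %g, %g)\n", x$left, x$peak, x$right))
  invisible(x)
}

#' @export
print.fuzzy_number <- function(x, ...) {
  core <- r_cut(x, 1)
  supp <- r_cut(x, 0)
  cat(sprintf("parametric fuzzy number: support [%g, %g], core [%g, %g]\n",
              supp[1], supp[2], core[1], core[2]))
  invisible(x)
}
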