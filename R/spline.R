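#' B-spline basis over age for time-varying effects
#'
#' Builds the clamped B-spline basis used to expand haplotype effects as
#' smooth functions of age, \eqn{\beta_h(t) = \sum_l \beta_{hl} B_l(t)}.
#' With `L` interior knots and order `k` (cubic: `k = 4`) the basis has
#' `L + k` functions; the defaults — interior knots (40, 60), boundary
#' knots (20, 100), cubic — give 6 basis functions covering adult ages.
#' The knot vector is clamped (each boundary knot repeated `k` times), so
#' the basis is a partition of unity on the boundary interval and the end
#' basis functions interpolate at the boundaries.
#'
#' @param interior_knots Numeric vector of interior knots (default `c(40, 60)`).
#' @param boundary_knots Length-2 numeric vector strictly containing the
#'   interior knots (default `c(20, 100)`).
#' @param order Spline order (polynomial degree + 1); default 4 (cubic).
#' @return A list of class `"lbl_spline_basis"`: `order`,
#'   `interior_knots`, `boundary_knots`, `knots` (full clamped vector),
#'   `n_basis`.
#' @seealso [evaluate_basis()], [evaluate_effect()]
#' @export
spline_basis <- function(interior_knots = c(40, 60),
                         boundary_knots = c(20, 100),
                         order = 4L) {
  order <- as.integer(order)
  stopifnot(order >= 1L, length(boundary_knots) == 2L,
            boundary_knots[1L] < boundary_knots[2L])
  interior_knots <- sort(as.numeric(interior_knots))
  if (length(interior_knots) &&
      (min(interior_knots) <= boundary_knots[1L] ||
       max(interior_knots) >= boundary_knots[2L]))
    .stopf("boundary knots must strictly contain the interior knots")
  knots <- c(rep(boundary_knots[1L], order), interior_knots,
             rep(boundary_knots[2L], order))
  structure(
    list(order = order, interior_knots = interior_knots,
         boundary_knots = as.numeric(boundary_knots), knots = knots,
         n_basis = length(interior_knots) + order),
    class = "lbl_spline_basis")
}

#' @export
print.lbl_spline_basis <- function(x, ...) {
  cat(sprintf(
    "lbl_spline_basis: order %d, interior knots (%s), boundary (%g, %g), %d basis functions\n",
    x$order, paste(x$interior_knots, collapse = ", "),
    x$boundary_knots[1L], x$boundary_knots[2L], x$n_basis))
  invisible(x)
}

#' Evaluate the B-spline basis at ages
#'
#' Returns the matrix of basis function values (Cox-de Boor / de Boor
#' evaluation via [splines::splineDesign()]). Values at the right boundary
#' are defined by continuity from the left so the basis still sums to 1
#' there. Ages outside the boundary knots are invalid inputs and raise an
#' error.
#'
#' @param basis An `"lbl_spline_basis"`.
#' @param t Numeric vector of ages.
#' @return A `length(t)` x `n_basis` matrix; each row is nonnegative and
#'   sums to 1.
#' @export
evaluate_basis <- function(basis, t) {
  stopifnot(inherits(basis, "lbl_spline_basis"), is.numeric(t))
  lo <- basis$boundary_knots[1L]; hi <- basis$boundary_knots[2L]
  if (any(t < lo | t > hi))
    .stopf("age(s) outside the boundary knots [%g, %g]: %s", lo, hi,
           paste(utils::head(t[t < lo | t > hi], 3L), collapse = ", "))
  splines::splineDesign(basis$knots, x = t, ord = basis$order,
                        outer.ok = FALSE)
}

#' Evaluate a spline-expanded effect at ages
#'
#' Computes \eqn{\sum_l c_l B_l(t)} — e.g. a haplotype's log-odds-ratio
#' curve at age `t` from its spline coefficients.
#'
#' @param basis An `"lbl_spline_basis"`.
#' @param coeffs Numeric vector of length `n_basis`.
#' @param t Numeric vector of ages.
#' @return Numeric vector `length(t)` of effect values.
#' @export
evaluate_effect <- function(basis, coeffs, t) {
  stopifnot(inherits(basis, "lbl_spline_basis"))
  if (length(coeffs) != basis$n_basis)
    .stopf("coeffs has length %d; basis has %d functions",
           length(coeffs), basis$n_basis)
  drop(evaluate_basis(basis, t) %*% coeffs)
}
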