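#' Trapezoidal fuzzy numbers
#'
#' A trapezoidal fuzzy number is the 4-tuple `(a, b, c, d)` with
#' `a <= b <= c <= d`: membership rises linearly on `[a, b]`, is 1 on the
#' plateau `[b, c]`, and falls linearly on `[c, d]`. `b == c` degenerates to a
#' triangular number and `a == b, c == d` to a plain interval; both are
#' permitted. All fuzzy quantities in this package are carried in this form.
#'
#' @param a Either the lower support bound, or a numeric vector of length 4
#'   giving all four components.
#' @param b,c,d Remaining components when `a` is scalar.
#' @return An object of class `"trapezoid"`: a named numeric vector
#'   `(a, b, c, d)`.
#' @examples
#' trapezoid(0, 0.25, 0.75, 1)
#' trapezoid(c(0.2, 0.4, 0.6, 0.8))
#' @seealso [defuzzify()], [tfn_membership()], [tfn_add()]
#' @export
trapezoid <- function(a, b = NULL, c = NULL, d = NULL) {
  v <- if (is.null(b)) as.numeric(a) else as.numeric(c(a, b, c, d))
  if (length(v) != 4L || !all(is.finite(v)))
    stop("a trapezoid needs four finite components", call. = FALSE)
  if (is.unsorted(v))
    stop("trapezoid components must satisfy a <= b <= c <= d; got (",
         paste(format(v), collapse = ", "), ")", call. = FALSE)
  structure(v, names = c("a", "b", "c", "d"), class = "trapezoid")
}

#' Signed component tuple
#'
#' The formal componentwise result of fuzzy subtraction or division. The
#' printed algebra for those operations does not preserve the
#' `a <= b <= c <= d` ordering, so the result is returned as a
#' `"signed_tuple"` carrying an `ordered` flag instead of being silently
#' re-sorted.
#'
#' @param v Numeric vector of length 4.
#' @return A `"signed_tuple"` with attribute `ordered` (`TRUE` iff the
#'   components are non-decreasing).
#' @seealso [is_ordered()], [tfn_subtract()], [tfn_divide()]
#' @export
signed_tuple <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 4L || !all(is.finite(v)))
    stop("a signed tuple needs four finite components", call. = FALSE)
  structure(v, names = c("a", "b", "c", "d"), class = "signed_tuple",
            ordered = !is.unsorted(v))
}

#' @rdname signed_tuple
#' @param x A `"signed_tuple"` or `"trapezoid"`.
#' @export
is_ordered <- function(x) {
  if (inherits(x, "trapezoid")) return(TRUE)
  isTRUE(attr(x, "ordered"))
}

#' @export
print.trapezoid <- function(x, digits = 4, ...) {
  cat("<trapezoid> (", paste(format(unclass(x), digits = digits),
                             collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
print.signed_tuple <- function(x, digits = 4, ...) {
  cat("<signed tuple> (", paste(format(unclass(x), digits = digits),
                                collapse = ", "), ")",
      if (is_ordered(x)) " [ordered]" else " [NOT ordered]", "\n", sep = "")
  invisible(x)
}

# Coerce trapezoid / signed_tuple / bare numeric to a plain length-4 vector.
tfn_components <- function(x) {
  v <- as.numeric(unclass(x))
  if (length(v) != 4L || !all(is.finite(v)))
    stop("expected a fuzzy number with four finite components", call. = FALSE)
  v
}

# Coerce a list of tuples or an n x 4 matrix to an n x 4 matrix.
tfn_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 4L) stop("expected a matrix with 4 columns", call. = FALSE)
    m <- x
  } else if (is.list(x)) {
    m <- do.call(rbind, lapply(x, tfn_components))
  } else {
    m <- matrix(tfn_components(x), nrow = 1L)
  }
  if (!all(is.finite(m))) stop("non-finite components", call. = FALSE)
  colnames(m) <- c("a", "b", "c", "d")
  m
}

#' Membership function of a trapezoidal fuzzy number
#'
#' Piecewise-linear membership: 0 outside the support `[a, d]`, 1 on the
#' plateau `[b, c]`, linear ramps in between. A degenerate ramp (`a == b` or
#' `c == d`) is treated as a step with membership 1 at the plateau edge.
#'
#' @param A A [trapezoid()].
#' @param x Numeric vector of evaluation points.
#' @return Membership values in `[0, 1]`, one per element of `x`.
#' @examples
#' A <- trapezoid(0, 0.25, 0.75, 1)
#' tfn_membership(A, c(0.125, 0.5, 2))  # 0.5, 1, 0
#' @export
tfn_membership <- function(A, x) {
  v <- tfn_components(A)
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("evaluation points must be finite numbers", call. = FALSE)
  vapply(x, function(xi) {
    if (xi < v[1] || xi > v[4]) return(0)
    if (xi >= v[2] && xi <= v[3]) return(1)
    if (xi < v[2]) (xi - v[1]) / (v[2] - v[1]) else (xi - v[4]) / (v[3] - v[4])
  }, numeric(1))
}

#' Trapezoidal fuzzy arithmetic
#'
#' Componentwise arithmetic on positive trapezoidal fuzzy numbers: addition,
#' subtraction, multiplication, componentwise division, and non-negative
#' scalar multiplication. Addition, multiplication (of positive operands) and
#' scaling preserve the trapezoid ordering; subtraction and division in
#' general do not, and therefore return a [signed_tuple()] whose `ordered`
#' flag records whether the result is still a valid trapezoid.
#'
#' Componentwise division is kept for fidelity with the linguistic
#' weighted-average construction it serves; it is not the extension-principle
#' quotient, and its result need not be a trapezoid.
#'
#' @param A1,A2 Fuzzy numbers ([trapezoid()] or bare length-4 numerics).
#' @param lambda Non-negative scalar.
#' @return `tfn_add`, `tfn_multiply`, `tfn_scale`: a [trapezoid()];
#'   `tfn_subtract`, `tfn_divide`: a [signed_tuple()].
#' @examples
#' tfn_add(trapezoid(1, 2, 3, 4), trapezoid(1, 1, 1, 1))   # (2,3,4,5)
#' tfn_scale(0.5, trapezoid(0.2, 0.4, 0.6, 0.8))           # (0.1,0.2,0.3,0.4)
#' tfn_subtract(trapezoid(0, 0.5, 0.5, 1), trapezoid(0, 0, 1, 1))
#' @export
tfn_add <- function(A1, A2) {
  trapezoid(tfn_components(A1) + tfn_components(A2))
}

#' @rdname tfn_add
#' @export
tfn_subtract <- function(A1, A2) {
  signed_tuple(tfn_components(A1) - tfn_components(A2))
}

#' @rdname tfn_add
#' @export
tfn_multiply <- function(A1, A2) {
  v1 <- tfn_components(A1); v2 <- tfn_components(A2)
  if (any(v1 < 0) || any(v2 < 0))
    stop("componentwise multiplication is defined for positive operands",
         call. = FALSE)
  trapezoid(v1 * v2)
}

#' @rdname tfn_add
#' @export
tfn_divide <- function(A1, A2) {
  v1 <- tfn_components(A1); v2 <- tfn_components(A2)
  if (any(v2 == 0))
    stop("division by a tuple with a zero component", call. = FALSE)
  if (any(v2 < 0))
    stop("componentwise division is defined for positive divisors",
         call. = FALSE)
  signed_tuple(v1 / v2)
}

#' @rdname tfn_add
#' @export
tfn_scale <- function(lambda, A1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop("lambda must be a single non-negative number", call. = FALSE)
  trapezoid(lambda * tfn_components(A1))
}

#' Componentwise mean of trapezoidal fuzzy numbers
#'
#' The arithmetic mean of each component across a collection. The mean of
#' ordered tuples is ordered, so the result is a valid [trapezoid()].
#'
#' @param x A list of fuzzy numbers or an `n x 4` matrix (rows = tuples).
#' @return A [trapezoid()].
#' @examples
#' tfn_mean(list(trapezoid(0, 0, 0, 0), trapezoid(1, 1, 1, 1)))
#' @export
tfn_mean <- function(x) {
  if ((is.list(x) && length(x) == 0L) || (is.matrix(x) && nrow(x) == 0L))
    stop("cannot average an empty collection", call. = FALSE)
  trapezoid(colMeans(tfn_matrix(x)))
}

#' Segmentation-integral defuzzification
#'
#' Maps a fuzzy number to the crisp value `(a + 2b + 2c + d) / 6`, the
#' y-weighted average of the left and right inverse membership ramps. The
#' formula is linear in the components and does not require ordering, so it
#' also accepts [signed_tuple()]s and matrices of tuples.
#'
#' @param A A [trapezoid()], [signed_tuple()], length-4 numeric, or `n x 4`
#'   matrix.
#' @return A numeric scalar (or vector, for a matrix input) at full
#'   precision; see [round_half_up()] for report rounding.
#' @examples
#' defuzzify(trapezoid(0.643, 0.720, 0.797, 0.874))  # 0.7585
#' @export
defuzzify <- function(A) {
  if (is.matrix(A)) {
    m <- tfn_matrix(A)
    return(as.numeric(m %*% c(1, 2, 2, 1)) / 6)
  }
  v <- tfn_components(A)
  (v[1] + 2 * v[2] + 2 * v[3] + v[4]) / 6
}

#' Round half away from zero
#'
#' Report-layer rounding. Base R's `round()` rounds half to even;
#' the published tables round halves away from zero (e.g. an unrounded value
#' of 0.7225 is reported as 0.723, and a gap of -0.0255 as -0.026), which
#' this helper reproduces. Internal computation is always at full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' A tolerance of `1e-9` is applied at the half-way boundary so that values
#' that are exactly on it mathematically, but land a few ulps below it in
#' binary floating point (e.g. `0.675 - 0.7055`), still round up.
#'
#' @examples
#' round_half_up(0.7225, 3)   # 0.723
#' round_half_up(-0.0255, 3)  # -0.026
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
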