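#' Linguistic term sets
#'
#' An ordered verbal rating scale `S = {S_0, ..., S_T}` with granularity
#' `T + 1`. The scale supports negation (`Neg(S_t) = S_{T-t}`), max and min.
#' An optional extended bound `extended_T >= T` admits out-of-scale
#' judgements (indices in `(T, extended_T]`) so that extreme answers are
#' representable without data loss.
#'
#' @param id Short identifier used by survey files to reference the set.
#' @param labels Character vector of term names, ordered from worst to best;
#'   granularity is `length(labels)`.
#' @param extended_T Optional integer `>= T` bounding the extended scale.
#' @return An object of class `"linguistic_termset"` with fields `id`,
#'   `labels`, `T`, `extended_T`.
#' @examples
#' s7 <- linguistic_termset("seven", c("very poor", "poor", "slightly poor",
#'                                     "fair", "slightly good", "good",
#'                                     "very good"))
#' s7$T  # 6
#' @seealso [default_termsets()], [linguistic_value()], [encode()]
#' @export
linguistic_termset <- function(id, labels, extended_T = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  labels <- as.character(labels)
  if (length(labels) < 2L || anyDuplicated(labels))
    stop("a term set needs at least two distinct labels", call. = FALSE)
  T <- length(labels) - 1L
  if (!is.null(extended_T)) {
    extended_T <- as.integer(extended_T)
    if (extended_T < T) stop("extended_T must be >= T", call. = FALSE)
  }
  structure(list(id = id, labels = labels, T = T, extended_T = extended_T),
            class = "linguistic_termset")
}

#' @export
print.linguistic_termset <- function(x, ...) {
  cat("<linguistic term set '", x$id, "'> granularity ", x$T + 1L,
      if (!is.null(x$extended_T)) paste0(" (extended to index ", x$extended_T, ")"),
      "\n  S_0..S_", x$T, ": ", paste(x$labels, collapse = " < "), "\n",
      sep = "")
  invisible(x)
}

# Maximum admissible index for a set.
termset_max_index <- function(set) {
  if (is.null(set$extended_T)) set$T else set$extended_T
}

#' Uncertain linguistic value
#'
#' A point term `S_m` or a hesitant interval `[S_m, S_n]` of consecutive
#' terms on a given term set. `m == n` expresses a point answer.
#'
#' @param set A [linguistic_termset()].
#' @param m,n Lower and upper term indices, `0 <= m <= n`, bounded by the
#'   set's `T` (or `extended_T` when configured).
#' @param clamp If `TRUE`, out-of-range indices are snapped into `[0, T]`
#'   instead of raising an error.
#' @return An object of class `"linguistic_value"`.
#' @examples
#' s <- default_termsets()$seven
#' linguistic_value(s, 4)       # point term S_4
#' linguistic_value(s, 4, 5)    # hesitant interval [S_4, S_5]
#' @export
linguistic_value <- function(set, m, n = m, clamp = FALSE) {
  stopifnot(inherits(set, "linguistic_termset"))
  m <- as.integer(m); n <- as.integer(n)
  if (clamp) {
    m <- min(max(m, 0L), set$T)
    n <- min(max(n, 0L), set$T)
  }
  top <- termset_max_index(set)
  if (is.na(m) || is.na(n) || m < 0L || m > n || n > top)
    stop("invalid term indices [", m, ", ", n, "] for set '", set$id,
         "' (admissible 0..", top, ")", call. = FALSE)
  structure(list(set = set, m = m, n = n), class = "linguistic_value")
}

#' @export
print.linguistic_value <- function(x, ...) {
  lab <- function(i) if (i <= x$set$T) x$set$labels[i + 1L] else paste0("S", i)
  if (x$m == x$n) {
    cat("<linguistic value> S_", x$m, " ('", lab(x$m), "') on '",
        x$set$id, "'\n", sep = "")
  } else {
    cat("<linguistic value> [S_", x$m, ", S_", x$n, "] ('", lab(x$m),
        "'..'", lab(x$n), "') on '", x$set$id, "'\n", sep = "")
  }
  invisible(x)
}

#' Term negation, maximum and minimum
#'
#' Scale operators of a linguistic term set: `negate_term()` reflects an
#' index about the scale midpoint (`T - t`); `term_max()` and `term_min()`
#' pick the larger/smaller index.
#'
#' @param t,t1,t2 Term indices in `0..T`.
#' @param set A [linguistic_termset()] (only its `T` is used).
#' @return An integer term index.
#' @examples
#' s <- default_termsets()$seven
#' negate_term(0, s)  # 6
#' term_max(2, 5)     # 5
#' @export
negate_term <- function(t, set) {
  T <- if (inherits(set, "linguistic_termset")) set$T else as.integer(set)
  t <- as.integer(t)
  if (any(t < 0L | t > T)) stop("term index out of range", call. = FALSE)
  T - t
}

#' @rdname negate_term
#' @export
term_max <- function(t1, t2) pmax(as.integer(t1), as.integer(t2))

#' @rdname negate_term
#' @export
term_min <- function(t1, t2) pmin(as.integer(t1), as.integer(t2))

# Vectorized index-interval encoding onto [0,1]; rows = values.
# For indices <= T this is exactly the printed conversion
#   ( max{(2m-1)/(2T+1), 0}, 2m/(2T+1), (2n+1)/(2T+1), min{(2n+2)/(2T+1), 1} );
# extended indices (> T) additionally clamp the inner components at 1 so the
# result stays a normalized trapezoid.
encode_indices <- function(m, n, T) {
  den <- 2 * T + 1
  a <- pmax((2 * m - 1) / den, 0)
  b <- 2 * m / den
  cc <- (2 * n + 1) / den
  d <- pmin((2 * n + 2) / den, 1)
  cbind(a = pmin(a, 1), b = pmin(b, 1), c = pmin(cc, 1), d = d)
}

#' Encode a linguistic value as a trapezoidal fuzzy number
#'
#' Converts a point term `S_m` or hesitant interval `[S_m, S_n]` on a
#' granularity-`(T+1)` scale into a normalized trapezoid on `[0, 1]`:
#' `( max{(2m-1)/(2T+1), 0}, 2m/(2T+1), (2n+1)/(2T+1), min{(2n+2)/(2T+1), 1} )`.
#' Each value is encoded with its own set's `T`, which is what makes ratings
#' from scales of different granularity commensurable: after encoding, all
#' arithmetic mixes freely on `[0, 1]`.
#'
#' @param value A [linguistic_value()].
#' @return A [trapezoid()] with `0 <= a <= b <= c <= d <= 1`.
#' @examples
#' s <- default_termsets()$seven
#' encode(linguistic_value(s, 2))     # (3/13, 4/13, 5/13, 6/13)
#' encode(linguistic_value(s, 4, 5))  # (7/13, 8/13, 11/13, 12/13)
#' @export
encode <- function(value) {
  stopifnot(inherits(value, "linguistic_value"))
  trapezoid(encode_indices(value$m, value$n, value$set$T)[1L, ])
}

#' Reference encodings of a term set
#'
#' Encodes every point term `S_0..S_T` of a set, yielding the reference
#' trapezoids against which aggregated ratings are compared during
#' indicator screening.
#'
#' @param set A [linguistic_termset()].
#' @return A `(T+1) x 4` matrix; row `theta + 1` is the encoding of
#'   `S_theta`, rownames `"S0".."ST"`.
#' @examples
#' reference_encodings(default_termsets()$seven)
#' @seealso [similarity_profile()]
#' @export
reference_encodings <- function(set) {
  stopifnot(inherits(set, "linguistic_termset"))
  th <- 0:set$T
  m <- encode_indices(th, th, set$T)
  rownames(m) <- paste0("S", th)
  m
}

#' Built-in term sets
#'
#' The 5-term performance scale ("fail".."excellent"), the 7-term
#' performance scale ("very poor".."very good") and its 7-term importance
#' reading ("very unimportant".."very important"), as shipped in
#' `inst/extdata/termsets.json`.
#'
#' @return A named list of [linguistic_termset()] objects with names
#'   `five`, `seven`, `seven_importance`.
#' @examples
#' default_termsets()$five
#' @export
default_termsets <- function() {
  path <- system.file("extdata", "termsets.json", package = "mgliqual",
                      mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(raw, function(ts)
    linguistic_termset(ts$id, ts$labels,
                       extended_T = if (!is.null(ts$extended_T)) ts$extended_T))
}
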