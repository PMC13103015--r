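#' Natural cubic spline basis specification for visit time
#'
#' Defines the time basis used in both the fixed and the random parts of the
#' trajectory models: a natural cubic spline (piecewise cubic, C2-continuous,
#' linear beyond the boundary knots) with boundary knots at the minimum and
#' maximum observed measurement times of a variable and interior knots at
#' quantiles of all its observation times (the median for the default
#' `df = 2`).  The basis excludes the intercept, which is a separate design
#' column.
#'
#' @param times numeric vector of observed measurement times (months), with
#'   multiplicity; quantiles are taken over all values, not unique times.
#' @param df positive integer; number of basis columns (default 2: one
#'   interior knot at the median).
#' @return An object of class `SplineBasisSpec`: a list with elements `df`,
#'   `boundary` (length-2 numeric) and `interior` (length `df - 1`).
#' @examples
#' makeSplineSpec(c(1, 1, 3, 3, 12, 12))   # boundary (1, 12), interior 3
#' @export
makeSplineSpec <- function(times, df = 2L) {
  stopifnot(is.numeric(times), length(df) == 1L, df >= 2)
  times <- times[is.finite(times)]
  if (length(unique(times)) < df + 1L)
    stop("identifiability: need at least ", df + 1L,
         " distinct times for a df=", df, " natural spline basis")
  bnd <- range(times)
  probs <- seq_len(df - 1L) / df
  interior <- unname(quantile(times, probs = probs, type = 7))
  if (any(interior <= bnd[1]) || any(interior >= bnd[2]))
    stop("identifiability: interior knot coincides with a boundary knot")
  if (anyDuplicated(interior))
    stop("identifiability: duplicated interior knots")
  structure(list(df = as.integer(df), boundary = bnd, interior = interior),
            class = "SplineBasisSpec")
}

#' Evaluate a natural spline basis
#'
#' Returns the `df` natural-cubic-spline basis values at the requested times.
#' Inside the boundary knots the basis is C2; at and beyond the boundary
#' knots the second derivative is zero, so extrapolation is linear.
#'
#' @param spec a `SplineBasisSpec` from [makeSplineSpec()].
#' @param t numeric vector of times (extrapolation beyond the boundary is
#'   allowed and linear).
#' @return numeric matrix, `length(t)` rows by `spec$df` columns.
#' @export
evaluateBasis <- function(spec, t) {
  stopifnot(inherits(spec, "SplineBasisSpec"), is.numeric(t), all(is.finite(t)))
  b <- splines::ns(t, knots = spec$interior, Boundary.knots = spec$boundary,
                   intercept = FALSE)
  m <- matrix(as.numeric(b), nrow = length(t), ncol = spec$df)
  colnames(m) <- paste0("ns", seq_len(spec$df))
  m
}

#' @export
print.SplineBasisSpec <- function(x, ...) {
  cat(sprintf(
    "SplineBasisSpec: df=%d, boundary knots (%g, %g), interior knot(s) %s\n",
    x$df, x$boundary[1], x$boundary[2], paste(signif(x$interior, 6),
                                              collapse = ", ")))
  invisible(x)
}
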