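#' Triangular membership function
#'
#' A triangular fuzzy membership function with support `[a, c]` and peak at
#' `b`.  Degenerate sides (`a == b` or `b == c`) give a vertical edge, which
#' is how the shouldered end sets of a bounded universe are represented: the
#' set is at full membership exactly at the universe edge and the edge is
#' made effective by input clamping (see [fuzzify()]).
#'
#' @param a,b,c Breakpoints in universe units, `a <= b <= c`; peak at `b`.
#' @return An object of class `lw_mf`.
#' @seealso [mf_trapezoidal()], [membership()]
#' @export
#' @examples
#' membership(mf_triangular(-1, 0, 1), c(-1, 0, 0.5, 3))
mf_triangular <- function(a, b, c) {
  bp <- c(a, b, c)
  if (!all(is.finite(bp))) lw_stop("breakpoints must be finite", "lw_invalid_config")
  if (is.unsorted(bp)) lw_stop("breakpoints must be non-decreasing (a <= b <= c)", "lw_invalid_config")
  if (a == c) lw_stop("triangular support must have positive width", "lw_invalid_config")
  structure(list(shape_kind = "triangular", breakpoints = bp), class = "lw_mf")
}

#' Trapezoidal membership function
#'
#' @param a,b,c,d Breakpoints, `a <= b <= c <= d`; membership is 1 on the
#'   plateau `[b, c]` and 0 outside `[a, d]`.
#' @return An object of class `lw_mf`.
#' @export
mf_trapezoidal <- function(a, b, c, d) {
  bp <- c(a, b, c, d)
  if (!all(is.finite(bp))) lw_stop("breakpoints must be finite", "lw_invalid_config")
  if (is.unsorted(bp)) lw_stop("breakpoints must be non-decreasing (a <= b <= c <= d)", "lw_invalid_config")
  if (a == d) lw_stop("trapezoidal support must have positive width", "lw_invalid_config")
  structure(list(shape_kind = "trapezoidal", breakpoints = bp), class = "lw_mf")
}

#' Evaluate a membership function
#'
#' Piecewise-linear evaluation of a triangular or trapezoidal membership
#' function.  Vectorised over `x`.
#'
#' @param mf An `lw_mf` object.
#' @param x Numeric vector of crisp values in universe units.
#' @return Membership degrees in `[0, 1]`, same length as `x`.
#' @export
membership <- function(mf, x) {
  if (!inherits(mf, "lw_mf")) lw_stop("mf must be an lw_mf object", "lw_invalid_input")
  if (!all(is.finite(x))) lw_stop("x must be finite", "lw_invalid_input")
  bp <- mf$breakpoints
  if (mf$shape_kind == "triangular") {
    a <- bp[1]; b <- bp[2]; cc <- bp[3]
    up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
    dn <- if (cc > b) (cc - x) / (cc - b) else as.numeric(x <= b)
  } else {
    a <- bp[1]; b <- bp[2]; cc <- bp[3]; d <- bp[4]
    up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
    dn <- if (d > cc) (d - x) / (d - cc) else as.numeric(x <= cc)
  }
  pmax(0, pmin(up, dn, 1))
}

#' Fuzzy partition of a bounded universe
#'
#' @param lo,hi Universe bounds, `lo < hi`.
#' @param labels Ordered character vector of set names.
#' @param functions List of `lw_mf` objects, one per label.
#' @return An object of class `fuzzy_partition`.
#' @export
fuzzy_partition <- function(lo, hi, labels, functions) {
  if (!is.numeric(lo) || !is.numeric(hi) || !is.finite(lo) || !is.finite(hi) || lo >= hi)
    lw_stop("universe bounds must be finite with lo < hi", "lw_invalid_config")
  if (length(labels) != length(functions))
    lw_stop("one membership function per label is required", "lw_invalid_config")
  if (anyDuplicated(labels)) lw_stop("labels must be unique", "lw_invalid_config")
  if (!all(vapply(functions, inherits, logical(1), "lw_mf")))
    lw_stop("functions must all be lw_mf objects", "lw_invalid_config")
  p <- structure(
    list(universe_lo = lo, universe_hi = hi, labels = as.character(labels),
         functions = stats::setNames(functions, labels)),
    class = "fuzzy_partition"
  )
  # coverage: every point of the universe belongs to at least one set
  xs <- seq(lo, hi, length.out = 201)
  if (any(apply(fuzzify(p, xs), 1, max) <= 0))
    lw_stop("partition does not cover the universe (a point has zero total membership)",
            "lw_invalid_config")
  p
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition> %d sets on [%g, %g]: %s\n",
              length(x$labels), x$universe_lo, x$universe_hi,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Build a Ruspini partition with evenly spaced triangular sets
#'
#' Constructs the default family of membership functions used for both
#' inputs (lateral position, lateral drift) and the judgment output:
#' triangular sets with peaks evenly spaced from `lo` to `hi`, adjacent sets
#' crossing at degree 0.5, and shouldered end sets whose peaks sit on the
#' universe edges.  Membership degrees sum to exactly 1 everywhere on
#' `[lo, hi]` (a Ruspini partition), so every crisp input activates at most
#' two sets.
#'
#' @param lo,hi Universe bounds, `lo < hi`.
#' @param labels Ordered set names, at least 2.
#' @return A `fuzzy_partition`.
#' @export
#' @examples
#' lp <- make_ruspini_partition(-2, 2, c("Sx+", "Sx", "C", "Dx", "Dx+"))
#' fuzzify(lp, 0.5)  # crossover between C and Dx
make_ruspini_partition <- function(lo, hi, labels) {
  if (length(labels) < 2) lw_stop("at least 2 labels are required", "lw_invalid_config")
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    lw_stop("universe bounds must be finite with lo < hi", "lw_invalid_config")
  n <- length(labels)
  peaks <- seq(lo, hi, length.out = n)
  fns <- vector("list", n)
  for (i in seq_len(n)) {
    a <- if (i == 1L) peaks[1] else peaks[i - 1]
    cc <- if (i == n) peaks[n] else peaks[i + 1]
    fns[[i]] <- mf_triangular(a, peaks[i], cc)
  }
  fuzzy_partition(lo, hi, labels, fns)
}

#' Fuzzify a crisp value against a partition
#'
#' Evaluates every set of the partition at `x`.  Values outside the universe
#' are clamped to the nearest bound before evaluation, so a vehicle beyond
#' the +/-2 m range is scored as maximally off-centre rather than rejected:
#' the detector must keep scoring, not halt.
#'
#' @param p A `fuzzy_partition`.
#' @param x Numeric vector of crisp values.
#' @return For a single value, a named numeric vector of membership degrees;
#'   for a vector, a numeric matrix with one row per value and one column
#'   per label.
#' @export
fuzzify <- function(p, x) {
  if (!inherits(p, "fuzzy_partition")) lw_stop("p must be a fuzzy_partition", "lw_invalid_config")
  if (length(x) == 0 || !all(is.finite(x))) lw_stop("x must be finite", "lw_invalid_input")
  xc <- pmin(pmax(x, p$universe_lo), p$universe_hi)
  m <- vapply(p$functions, membership, numeric(length(xc)), x = xc)
  if (length(x) == 1L) {
    out <- as.numeric(m)
    names(out) <- p$labels
    out
  } else {
    dimnames(m) <- list(NULL, p$labels)
    m
  }
}
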