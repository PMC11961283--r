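#' Natural cubic spline basis with analytic derivative
#'
#' Evaluates the natural cubic regression spline basis used for the SITAR mean
#' curve, together with its exact first derivative. The basis agrees
#' column-for-column with [splines::ns()] (no intercept column), so natural
#' splines contain all linear functions and are linear beyond the boundary
#' knots; evaluation outside the boundary knots uses that linear extension.
#'
#' @param x numeric vector of evaluation points (ages, years).
#' @param knots strictly increasing interior knots.
#' @param boundary length-2 boundary knots; the curve is linear outside them.
#' @param deriv 0 for basis values, 1 or 2 for derivative bases (the second
#'   derivative is zero at and beyond the boundary knots).
#' @return numeric matrix, `length(x)` rows and `length(knots) + 1` columns.
#' @examples
#' B <- natural_spline_basis(seq(8, 19, 0.5), knots = c(11, 14), boundary = c(8, 19))
#' @export
natural_spline_basis <- function(x, knots, boundary, deriv = 0) {
  if (length(boundary) != 2L || diff(boundary) <= 0)
    stop("'boundary' must be two increasing values", call. = FALSE)
  if (length(knots) && (any(diff(c(boundary[1], sort(knots), boundary[2])) <= 0) ||
                        is.unsorted(knots, strictly = TRUE)))
    stop("interior knots must be strictly increasing and inside the boundary knots",
         call. = FALSE)
  if (!deriv %in% c(0, 1, 2)) stop("'deriv' must be 0, 1 or 2", call. = FALSE)
  ak <- sort(c(rep(boundary, 4L), knots))
  ## natural constraint: zero second derivative at both boundary knots;
  ## same construction (and column drop) as splines::ns(intercept = FALSE)
  con <- splines::splineDesign(ak, boundary, 4L, derivs = c(2L, 2L))[, -1L, drop = FALSE]
  qrc <- qr(t(con))
  proj <- function(m) as.matrix(t(qr.qty(qrc, t(m)))[, -(1:2), drop = FALSE])
  evalb <- function(xx, dv)
    proj(splines::splineDesign(ak, xx, 4L, derivs = rep(dv, length(xx)))[, -1L, drop = FALSE])
  xc <- pmin(pmax(x, boundary[1]), boundary[2])
  lo <- x < boundary[1]
  hi <- x > boundary[2]
  if (deriv == 0) {
    B <- evalb(xc, 0L)
    if (any(lo)) B[lo, ] <- B[lo, , drop = FALSE] +
        (x[lo] - boundary[1]) * rep(evalb(boundary[1], 1L), each = sum(lo))
    if (any(hi)) B[hi, ] <- B[hi, , drop = FALSE] +
        (x[hi] - boundary[2]) * rep(evalb(boundary[2], 1L), each = sum(hi))
  } else if (deriv == 1) {
    B <- evalb(xc, 1L)
    if (any(lo)) B[lo, ] <- rep(evalb(boundary[1], 1L), each = sum(lo))
    if (any(hi)) B[hi, ] <- rep(evalb(boundary[2], 1L), each = sum(hi))
  } else {
    B <- evalb(xc, 2L)
    if (any(lo)) B[lo, ] <- 0
    if (any(hi)) B[hi, ] <- 0
  }
  dimnames(B) <- list(NULL, paste0("s", seq_len(ncol(B))))
  B
}

## hot-path worker: basis plus first and second derivative in one pass.
## Row-for-row identical to three natural_spline_basis() calls (same knot
## vector, same constraint QR, same Householder applications per column),
## but with one stacked splineDesign evaluation and one projection.
ns_basis_pre <- function(knots, boundary) {
  ak <- sort(c(rep(boundary, 4L), knots))
  con <- splines::splineDesign(ak, boundary, 4L, derivs = c(2L, 2L))[, -1L, drop = FALSE]
  qrc <- qr(t(con))
  proj <- function(m) as.matrix(t(qr.qty(qrc, t(m)))[, -(1:2), drop = FALSE])
  list(ak = ak, qrc = qrc, proj = proj,
       dlo = proj(splines::splineDesign(ak, boundary[1], 4L, derivs = 1L)[, -1L, drop = FALSE]),
       dhi = proj(splines::splineDesign(ak, boundary[2], 4L, derivs = 1L)[, -1L, drop = FALSE]))
}

ns_basis_all <- function(x, knots, boundary, pre = NULL) {
  if (is.null(pre)) pre <- ns_basis_pre(knots, boundary)
  n <- length(x)
  xc <- pmin(pmax(x, boundary[1]), boundary[2])
  des <- splines::splineDesign(pre$ak, c(xc, xc, xc), 4L,
                               derivs = rep(0:2, each = n))[, -1L, drop = FALSE]
  P <- pre$proj(des)
  B0 <- P[seq_len(n), , drop = FALSE]
  B1 <- P[n + seq_len(n), , drop = FALSE]
  B2 <- P[2L * n + seq_len(n), , drop = FALSE]
  lo <- x < boundary[1]
  hi <- x > boundary[2]
  if (any(lo) || any(hi)) {
    dlo <- pre$dlo
    dhi <- pre$dhi
    if (any(lo)) {
      B0[lo, ] <- B0[lo, , drop = FALSE] +
        (x[lo] - boundary[1]) * rep(dlo, each = sum(lo))
      B1[lo, ] <- rep(dlo, each = sum(lo))
      B2[lo, ] <- 0
    }
    if (any(hi)) {
      B0[hi, ] <- B0[hi, , drop = FALSE] +
        (x[hi] - boundary[2]) * rep(dhi, each = sum(hi))
      B1[hi, ] <- rep(dhi, each = sum(hi))
      B2[hi, ] <- 0
    }
  }
  cn <- paste0("s", seq_len(ncol(B0)))
  dimnames(B0) <- dimnames(B1) <- dimnames(B2) <- list(NULL, cn)
  list(B0 = B0, B1 = B1, B2 = B2)
}

#' Spline curve object
#'
#' Lightweight container for a fitted natural-spline mean curve: interior and
#' boundary knots, an intercept, basis coefficients, and the age offset used to
#' centre ages before basis construction.
#'
#' @param knots interior knots (centred-age scale).
#' @param boundary boundary knots (centred-age scale).
#' @param intercept curve intercept (cm).
#' @param coef basis coefficients, one per basis column.
#' @param xoffset age offset (years) subtracted from age before evaluation.
#' @return an object of class `spline_curve`.
#' @export
spline_curve <- function(knots, boundary, intercept, coef, xoffset = 0) {
  stopifnot(length(coef) == length(knots) + 1L)
  structure(list(knots = as.numeric(knots), boundary = as.numeric(boundary),
                 intercept = as.numeric(intercept), coef = as.numeric(coef),
                 xoffset = as.numeric(xoffset)),
            class = "spline_curve")
}

#' Evaluate a spline curve or its velocity
#'
#' @param curve a [spline_curve()].
#' @param age ages in years (observed scale).
#' @param deriv 0 for height (cm), 1 for velocity (cm/year).
#' @return numeric vector.
#' @export
eval_curve <- function(curve, age, deriv = 0) {
  x <- age - curve$xoffset
  B <- natural_spline_basis(x, curve$knots, curve$boundary, deriv = deriv)
  drop(B %*% curve$coef) + if (deriv == 0) curve$intercept else 0
}

#' @export
print.spline_curve <- function(x, ...) {
  cat("Natural cubic spline curve\n")
  cat("  interior knots (age):", format(round(x$knots + x$xoffset, 2)), "\n")
  cat("  boundary knots (age):", format(round(x$boundary + x$xoffset, 2)), "\n")
  cat("  coefficients:", format(round(x$coef, 3)), "\n")
  invisible(x)
}

## least-squares fit of a spline_curve to (x, y) pairs
fit_spline_curve <- function(age, y, df, xoffset = mean(age),
                             boundary = NULL, knots = NULL) {
  x <- age - xoffset
  if (is.null(boundary)) boundary <- range(x)
  if (is.null(knots))
    knots <- seq(boundary[1], boundary[2], length.out = df + 1L)[2:df]
  B <- natural_spline_basis(x, knots, boundary)
  co <- stats::lm.fit(cbind(1, B), y)$coefficients
  spline_curve(knots, boundary, co[1], co[-1], xoffset)
}
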