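#' Remove the non-linear age effect from every variable
#'
#' For each column independently, fits ordinary least squares on an
#' intercept plus a natural cubic spline basis of age (knots at age
#' quantiles) and returns the residuals.  This is the pre-processing step
#' behind the age-deflated ("model 2") factor analysis: after deflation no
#' latent factor can be driven by the shared, possibly non-linear, age
#' trend.
#'
#' Deflation is a linear projection, so it is idempotent, and residuals are
#' orthogonal to the fitted basis to numerical precision.
#'
#' @param x complete samples x variables matrix (impute first).
#' @param age per-sample age in years.
#' @param df spline degrees of freedom (default 4).
#' @return residual matrix of the same shape (attribute `basis` holds the
#'   design used).
#' @export
deflate_age <- function(x, age, df = 4L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("deflate_age requires a complete matrix")
  if (length(age) != nrow(x)) stop("one age per sample required")
  if (df < 2L) stop("df must be >= 2")
  if (length(unique(age)) < df + 2L)
    stop("degenerate ages: need more distinct ages than spline df + 1")
  basis <- cbind(1, splines::ns(age, df = df))
  qrb <- qr(basis)
  res <- x - basis %*% qr.coef(qrb, x)
  dimnames(res) <- dimnames(x)
  attr(res, "basis") <- basis
  res
}
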