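#' @include AllClasses.R angles.R
NULL

#' Fit a fixed-period sinusoid to an angular deviation versus psi
#'
#' Ordinary least squares on the basis {sin(k psi), cos(k psi), 1} with
#' k = 360 / period (k = 3 for the default 120-degree period, i.e. extrema
#' every 60 degrees of psi). The fitted curve is reported as
#' amplitude * sin(k (psi - phase)) + offset with amplitude >= 0 and phase in
#' [0, period). Treating the y values as plain reals is valid because the
#' deviations surveyed here are confined to a few degrees; inputs with
#' |y| >= 90 are rejected.
#'
#' @param psi psi angles, degrees.
#' @param y angular deviations (delta-omega or theta-C), degrees, |y| < 90.
#' @param period fixed period in degrees; must divide 360. Default 120.
#' @return a \linkS4class{HarmonicFit}.
#' @export
fitHarmonic <- function(psi, y, period = 120) {
  ok <- is.finite(psi) & is.finite(y)
  psi <- psi[ok]; y <- y[ok]
  n <- length(y)
  if (n < 4L) stop("fitHarmonic: need at least 4 observations")
  if (360 %% period != 0) stop("fitHarmonic: period must divide 360")
  if (any(abs(y) >= 90))
    stop("fitHarmonic: |y| >= 90 degrees; linear treatment of angles invalid")
  k <- 360 / period
  s <- sin(.deg2rad(k * psi))
  c_ <- cos(.deg2rad(k * psi))
  fit <- stats::lm(y ~ s + c_)
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("fitHarmonic: rank-deficient design (psi values do not span the period)")
  a <- unname(cf["s"]); b <- unname(cf["c_"]); off <- unname(cf["(Intercept)"])
  A <- sqrt(a^2 + b^2)
  ## a sin(k psi) + b cos(k psi) = A sin(k (psi - phase))
  ## with a = A cos(k phase), b = -A sin(k phase)
  ph <- if (A > 0) (.rad2deg(atan2(-b, a)) / k) %% period else 0
  sst <- sum((y - mean(y))^2)
  ssr <- sum(stats::residuals(fit)^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - ssr / sst)) else 1
  new("HarmonicFit", amplitude = A, phase = ph, offset = off,
      period = period, rSquared = r2, n = n)
}

#' Linear regression between two angular deviations
#'
#' Ordinary least squares of y on x with Pearson correlation, treating the
#' wrapped degree values as reals (valid for small deviations). Used for the
#' theta-C versus delta-omega coupling.
#'
#' @param x,y numeric vectors, degrees.
#' @return a \linkS4class{LinearFit}.
#' @export
fitLinear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fitLinear: need at least 3 observations")
  if (stats::sd(x) == 0) stop("fitLinear: degenerate regressor (x constant)")
  constantY <- stats::sd(y) == 0
  if (constantY) {
    warning("fitLinear: y constant; correlation reported as 0")
    return(new("LinearFit", slope = 0, intercept = mean(y), r = 0,
               n = n, constantY = TRUE))
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  new("LinearFit", slope = unname(cf[2L]), intercept = unname(cf[1L]),
      r = stats::cor(x, y), n = n, constantY = FALSE)
}

#' Zeros of a fitted harmonic in [0, 360)
#'
#' Roots of amplitude * sin(k (psi - phase)) + offset = 0. For a centered fit
#' (offset 0) these are the psi values at which the deviation vanishes --
#' planar peptide bonds -- spaced period/2 (60 degrees by default) apart.
#'
#' @param fit a \linkS4class{HarmonicFit}.
#' @return sorted numeric vector of psi roots in [0, 360); empty when
#'   |offset| > amplitude. An amplitude of exactly 0 returns an empty vector
#'   carrying attribute \code{everywhereZero = TRUE} when the offset is also 0
#'   (the model vanishes identically).
#' @export
zeroCrossings <- function(fit) {
  stopifnot(is(fit, "HarmonicFit"))
  A <- fit@amplitude; off <- fit@offset; k <- 360 / fit@period
  if (A == 0) {
    out <- numeric(0)
    if (off == 0) attr(out, "everywhereZero") <- TRUE
    return(out)
  }
  if (abs(off) > A) return(numeric(0))
  alpha <- .rad2deg(asin(-off / A))
  roots <- c(outer(c(alpha, 180 - alpha), 360 * (-2:4), "+")) / k + fit@phase
  roots <- sort(unique(round(roots %% 360, 9)))
  roots[!duplicated(round(roots, 6))]
}
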