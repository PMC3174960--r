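#' Wrap an angle into (-180, 180]
#'
#' All angular quantities in pepgeom (phi, psi, omega, omega3, delta-omega,
#' theta-C, theta-N) live on the half-open interval (-180, 180] degrees, the
#' crystallographic convention under which an ideal trans peptide bond sits at
#' omega = +180 rather than -180.
#'
#' @param x numeric vector of angles in degrees; must be finite.
#' @return numeric vector congruent to \code{x} modulo 360, in (-180, 180].
#' @examples
#' wrapAngle(c(360, -181, 180, 539))
#' @export
wrapAngle <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("wrapAngle: input must be finite numeric")
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Signed torsion angle of four points
#'
#' IUPAC-IUB signed dihedral: looking from atom 2 towards atom 3, a clockwise
#' rotation of the far bond relative to the near bond is positive. Computed as
#' \code{atan2(((b1 x b2) x (b2 x b3)) . b2hat, (b1 x b2) . (b2 x b3))} with
#' bond vectors \code{b_k = p_{k+1} - p_k}, then wrapped into (-180, 180].
#'
#' Degenerate geometry (coincident consecutive points or a collinear atom
#' triple) raises an error rather than returning NaN, because silent NaNs
#' corrupt downstream circular means.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @param labels optional character vector of four atom labels used in
#'   degenerate-geometry error messages.
#' @return torsion angle in degrees, in (-180, 180].
#' @examples
#' dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)) # +90
#' @export
dihedralAngle <- function(p1, p2, p3, p4, labels = c("p1", "p2", "p3", "p4")) {
  stopifnot(length(p1) == 3L, length(p2) == 3L, length(p3) == 3L, length(p4) == 3L)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  scale <- max(sqrt(sum(b1^2)), sqrt(sum(b2^2)), sqrt(sum(b3^2)))
  eps <- 1e-10 * max(scale^2, 1)
  if (sqrt(sum(n1^2)) < eps)
    stop(sprintf("dihedralAngle: degenerate geometry, atoms %s-%s-%s are collinear or coincident",
                 labels[1L], labels[2L], labels[3L]))
  if (sqrt(sum(n2^2)) < eps)
    stop(sprintf("dihedralAngle: degenerate geometry, atoms %s-%s-%s are collinear or coincident",
                 labels[2L], labels[3L], labels[4L]))
  b2hat <- b2 / sqrt(sum(b2^2))
  y <- sum(.cross3(n1, n2) * b2hat)
  x <- sum(n1 * n2)
  wrapAngle(.rad2deg(atan2(y, x)))
}

#' Signed deviation of omega from its ideal isomer value
#'
#' For a trans bond the ideal omega is 180 degrees, for cis it is 0; the
#' deviation is wrapped so that omega = -178 (trans) gives +2, not -358.
#'
#' @param omega omega torsion(s), degrees.
#' @param isomer character, \code{"trans"} or \code{"cis"} (recycled).
#' @return signed deviation in degrees, in (-180, 180].
#' @export
deltaOmega <- function(omega, isomer = c("trans", "cis")) {
  isomer <- match.arg(isomer, several.ok = TRUE)
  isomer <- rep_len(isomer, length(omega))
  ifelse(isomer == "trans", wrapAngle(omega - 180), wrapAngle(omega))
}

#' Carbonyl-carbon pyramidalization angle
#'
#' theta-C = (omega - omega3 + 180) mod 360, wrapped into (-180, 180], where
#' omega is the CA(i)-C(i)-N(i+1)-CA(i+1) torsion and omega3 the
#' O(i)-C(i)-N(i+1)-CA(i+1) torsion. Zero for a planar carbonyl carbon.
#'
#' @param omega,omega3 torsions in degrees (vectors recycled).
#' @return theta-C in degrees.
#' @export
thetaC <- function(omega, omega3) wrapAngle(omega - omega3 + 180)

#' Amide-nitrogen pyramidalization angle
#'
#' Mirrors the theta-C construction on the nitrogen side:
#' theta-N = (omegaH - omega + 180) mod 360, with
#' omegaH = CA(i)-C(i)-N(i+1)-H(i+1). Zero for a planar nitrogen. Measurable
#' only when the amide hydrogen position is known; with \code{omegaH = NA}
#' the result is NA (an undefined-result marker, not an error).
#'
#' @param omegaH CA-C-N-H torsion(s), degrees, or NA when H is absent.
#' @param omega omega torsion(s), degrees.
#' @return theta-N in degrees, NA where omegaH is NA.
#' @export
thetaN <- function(omegaH, omega) {
  out <- rep(NA_real_, max(length(omegaH), length(omega)))
  omegaH <- rep_len(omegaH, length(out))
  omega <- rep_len(omega, length(out))
  ok <- !is.na(omegaH) & !is.na(omega)
  out[ok] <- wrapAngle(omegaH[ok] - omega[ok] + 180)
  out
}

#' Classify a peptide bond as cis or trans
#'
#' trans iff |wrap(omega - 180)| <= 90; the boundary at exactly 90 is assigned
#' to trans. Only near-planar bonds survive the survey filters, so the tie
#' rule is inert in practice.
#'
#' @param omega omega torsion(s), degrees.
#' @return character vector, \code{"cis"} or \code{"trans"}.
#' @export
classifyIsomer <- function(omega) {
  ifelse(abs(wrapAngle(omega - 180)) <= 90, "trans", "cis")
}

#' Circular mean of angles
#'
#' atan2 of the mean sine and cosine, wrapped into (-180, 180]. The resultant
#' length R in [0, 1] is returned as a dispersion diagnostic (1 = all angles
#' identical, 0 = uniform). A vanishing resultant leaves the mean undefined
#' and returns NA with a warning.
#'
#' @param angles numeric vector of angles in degrees; must be non-empty.
#' @return list with components \code{mean} (degrees, NA if undefined) and
#'   \code{R} (resultant length).
#' @examples
#' circularMean(c(179, -179))$mean # 180, not 0
#' @export
circularMean <- function(angles) {
  if (length(angles) == 0L) stop("circularMean: empty input")
  if (any(!is.finite(angles))) stop("circularMean: non-finite input")
  rad <- .deg2rad(angles)
  s <- mean(sin(rad))
  c_ <- mean(cos(rad))
  R <- sqrt(s^2 + c_^2)
  if (R < 1e-12) {
    warning("circularMean: zero resultant, mean undefined")
    return(list(mean = NA_real_, R = R))
  }
  list(mean = wrapAngle(.rad2deg(atan2(s, c_))), R = R)
}
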