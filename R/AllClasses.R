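#' @import methods
NULL

.ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "element",
                "x", "y", "z", "b", "occ", "alt", "partialOcc")

#' StructureModel: an atomic coordinate model
#'
#' Holds one model's atoms (chains -> residues -> atoms) as a flat table plus
#' the entry-level metadata the survey filters use. Atom rows are ordered by
#' chain, then residue number and insertion code. One row per atom after
#' alternate-location resolution; \code{partialOcc} marks atoms whose residue
#' carries any backbone atom with occupancy below 1.
#'
#' @slot entryId character entry identifier.
#' @slot atoms data.frame with columns chain, resno, insert, resid, elety,
#'   element, x, y, z, b, occ, alt, partialOcc.
#' @slot resolution numeric, Angstrom (NA if not recorded in the header).
#' @slot rFactor numeric, fraction (NA if not recorded).
#' @exportClass StructureModel
setClass("StructureModel",
  representation(entryId = "character", atoms = "data.frame",
                 resolution = "numeric", rFactor = "numeric"),
  prototype(entryId = "", atoms = data.frame(),
            resolution = NA_real_, rFactor = NA_real_))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msgs <- character()
  if (nrow(a) > 0L) {
    missing <- setdiff(.ATOM_COLS, names(a))
    if (length(missing))
      msgs <- c(msgs, paste("atoms table missing columns:",
                            paste(missing, collapse = ", ")))
    else {
      if (any(!is.finite(a$x)) || any(!is.finite(a$y)) || any(!is.finite(a$z)))
        msgs <- c(msgs, "non-finite coordinates")
      if (any(a$occ < 0 | a$occ > 1, na.rm = TRUE))
        msgs <- c(msgs, "occupancy outside [0, 1]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StructureModel
#'
#' @param atoms atom table (see \linkS4class{StructureModel}).
#' @param entryId entry identifier.
#' @param resolution resolution in Angstrom, or NA.
#' @param rFactor crystallographic R-factor as a fraction, or NA.
#' @return a \linkS4class{StructureModel}.
#' @export
StructureModel <- function(atoms, entryId = "", resolution = NA_real_,
                           rFactor = NA_real_) {
  if (!"partialOcc" %in% names(atoms)) atoms$partialOcc <- FALSE
  if (!"element" %in% names(atoms)) atoms$element <- ""
  if (!"alt" %in% names(atoms)) atoms$alt <- ""
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  rownames(atoms) <- NULL
  new("StructureModel", entryId = as.character(entryId),
      atoms = atoms[, .ATOM_COLS],
      resolution = as.numeric(resolution), rFactor = as.numeric(rFactor))
}

#' FilterConfig: residue- and entry-level survey filters
#'
#' Defaults encode the survey protocol: entries at resolution 1.6 Angstrom or
#' better with R-factor below 0.20; residues excluded when Gly/Pro, when any
#' backbone atom is partially occupied, when the residue main-chain B-factor
#' exceeds 1.3 times the main-chain average of the entire protein (all chains
#' pooled), or when the following peptide bond is cis. Chain breaks are
#' geometric: C(i)-N(i+1) distance above \code{chainBreakDistance}.
#'
#' @slot bFactorRatio numeric, default 1.3.
#' @slot minResolution numeric Angstrom, default 1.6.
#' @slot maxRFactor numeric fraction, default 0.20.
#' @slot excludeResidues character, default GLY and PRO.
#' @slot transOnly logical, default TRUE.
#' @slot chainBreakDistance numeric Angstrom, default 1.8 (a bonded C-N is
#'   about 1.33).
#' @slot gateSource character, "header" to gate entries on header-derived
#'   resolution/R-factor, "none" to assume the selection was done upstream
#'   (PISCES-style); default "none".
#' @exportClass FilterConfig
setClass("FilterConfig",
  representation(bFactorRatio = "numeric", minResolution = "numeric",
                 maxRFactor = "numeric", excludeResidues = "character",
                 transOnly = "logical", chainBreakDistance = "numeric",
                 gateSource = "character"),
  prototype(bFactorRatio = 1.3, minResolution = 1.6, maxRFactor = 0.20,
            excludeResidues = c("GLY", "PRO"), transOnly = TRUE,
            chainBreakDistance = 1.8, gateSource = "none"))

setValidity("FilterConfig", function(object) {
  msgs <- character()
  if (object@bFactorRatio <= 0) msgs <- c(msgs, "bFactorRatio must be > 0")
  if (object@chainBreakDistance <= 0)
    msgs <- c(msgs, "chainBreakDistance must be > 0")
  if (!object@gateSource %in% c("none", "header"))
    msgs <- c(msgs, "gateSource must be 'none' or 'header'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FilterConfig
#'
#' @param bFactorRatio residue-to-protein main-chain B-factor ratio threshold.
#' @param minResolution entry resolution gate, Angstrom.
#' @param maxRFactor entry R-factor gate, fraction.
#' @param excludeResidues residue names excluded outright.
#' @param transOnly keep only trans peptide bonds.
#' @param chainBreakDistance C-N distance (Angstrom) beyond which the chain is
#'   considered broken.
#' @param gateSource "none" or "header" (see \linkS4class{FilterConfig}).
#' @return a \linkS4class{FilterConfig}.
#' @export
FilterConfig <- function(bFactorRatio = 1.3, minResolution = 1.6,
                         maxRFactor = 0.20,
                         excludeResidues = c("GLY", "PRO"),
                         transOnly = TRUE, chainBreakDistance = 1.8,
                         gateSource = "none") {
  new("FilterConfig", bFactorRatio = bFactorRatio,
      minResolution = minResolution, maxRFactor = maxRFactor,
      excludeResidues = toupper(excludeResidues), transOnly = transOnly,
      chainBreakDistance = chainBreakDistance, gateSource = gateSource)
}

#' InternalCoordinates: a backbone chain as (length, angle, torsion) triplets
#'
#' The first three atoms (N1, CA1, C1) are anchored by their Cartesian
#' coordinates; every later backbone atom (N, CA, C, O interleaved in build
#' order) is defined by a bond length to its parent, a bond angle, and a
#' torsion against three already-placed anchor atoms. Rebuilding with
#' \code{\link{buildBackbone}} is the exact inverse of
#' \code{\link{extractInternal}}. The omega torsion of peptide bond i sits on
#' the CA(i+1) placement row; the carbonyl oxygen of residue i is placed by
#' the omega3 torsion about the C(i)-N(i+1) axis, which makes theta-C directly
#' controllable.
#'
#' @slot anchor 3x3 numeric matrix, rows = Cartesian coordinates of N1, CA1, C1.
#' @slot ic data.frame with columns resno, atom, length, angle, torsion and
#'   one row per non-anchor atom in build order.
#' @slot nres integer number of residues.
#' @exportClass InternalCoordinates
setClass("InternalCoordinates",
  representation(anchor = "matrix", ic = "data.frame", nres = "integer"))

setValidity("InternalCoordinates", function(object) {
  msgs <- character()
  if (!identical(dim(object@anchor), c(3L, 3L)))
    msgs <- c(msgs, "anchor must be a 3x3 matrix")
  ic <- object@ic
  if (nrow(ic) > 0L) {
    need <- c("resno", "atom", "length", "angle", "torsion")
    if (!all(need %in% names(ic)))
      msgs <- c(msgs, "ic table missing columns")
    else {
      if (any(ic$length <= 0)) msgs <- c(msgs, "bond lengths must be > 0")
      if (any(ic$angle <= 0 | ic$angle >= 180))
        msgs <- c(msgs, "bond angles must lie in (0, 180)")
    }
  }
  if (object@nres < 1L) msgs <- c(msgs, "nres must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' EnsembleSpec: parameters of the synthetic backbone generator
#'
#' The generator draws per-residue (phi, psi) from a basin mixture (or a fixed
#' point), then couples the peptide-bond geometry to psi with the survey's
#' statistical structure: delta-omega = A sin(3 (psi - phase)) + noise, and
#' theta-C = slope * delta-omega + intercept + noise, from which omega and
#' omega3 follow.
#'
#' @slot nChains integer number of chains.
#' @slot chainLength integer residues per chain (>= 4).
#' @slot sampler list: either \code{list(type = "fixed", phi =, psi =)} or
#'   \code{list(type = "basins", basins = data.frame(phi, psi, sd, weight))}.
#' @slot amplitude numeric degrees, sinusoid amplitude A.
#' @slot phase numeric degrees, sinusoid phase.
#' @slot noiseOmegaSd numeric degrees, Gaussian noise on delta-omega.
#' @slot thetaCSlope numeric, linear coupling of theta-C to delta-omega.
#' @slot thetaCIntercept numeric degrees.
#' @slot noiseThetaCSd numeric degrees, Gaussian noise on theta-C.
#' @slot seed integer RNG seed.
#' @exportClass EnsembleSpec
setClass("EnsembleSpec",
  representation(nChains = "integer", chainLength = "integer",
                 sampler = "list", amplitude = "numeric", phase = "numeric",
                 noiseOmegaSd = "numeric", thetaCSlope = "numeric",
                 thetaCIntercept = "numeric", noiseThetaCSd = "numeric",
                 seed = "integer"))

setValidity("EnsembleSpec", function(object) {
  msgs <- character()
  if (object@chainLength < 4L) msgs <- c(msgs, "chainLength must be >= 4")
  if (object@nChains < 1L) msgs <- c(msgs, "nChains must be >= 1")
  if (object@noiseOmegaSd < 0 || object@noiseThetaCSd < 0)
    msgs <- c(msgs, "noise standard deviations must be >= 0")
  s <- object@sampler
  if (is.null(s$type) || !s$type %in% c("fixed", "basins"))
    msgs <- c(msgs, "sampler$type must be 'fixed' or 'basins'")
  else if (s$type == "basins") {
    b <- s$basins
    if (!is.data.frame(b) || !all(c("phi", "psi", "sd", "weight") %in% names(b)))
      msgs <- c(msgs, "basins must be a data.frame with phi, psi, sd, weight")
    else if (any(b$weight < 0) || sum(b$weight) <= 0)
      msgs <- c(msgs, "basin weights must be nonnegative with positive sum")
  } else if (is.null(s$phi) || is.null(s$psi)) {
    msgs <- c(msgs, "fixed sampler needs phi and psi")
  }
  if (length(msgs)) msgs else TRUE
})

#' Default Ramachandran basin mixture used by the generator
#'
#' Four populated regions (beta, polyproline-II, right- and left-handed
#' alpha) with isotropic Gaussian spread, weighted roughly as in folded
#' proteins. The psi centers span the 120-degree period of the
#' delta-omega(psi) sinusoid so its amplitude and phase are identifiable
#' from a synthetic survey.
#'
#' @return data.frame with columns phi, psi, sd (degrees), weight.
#' @export
defaultBasins <- function() {
  data.frame(
    phi = c(-120, -75, -63, 57),
    psi = c(135, 150, -43, 47),
    sd = c(25, 20, 15, 15),
    weight = c(0.35, 0.15, 0.40, 0.10)
  )
}

#' Construct an EnsembleSpec
#'
#' Defaults mirror the conformational dependence observed in high-resolution
#' surveys: a 2-degree sinusoid amplitude with 1-degree angular noise on
#' delta-omega, and theta-C coupled to delta-omega with slope 0.6 (the
#' protein-side regression slope is about 0.59) plus 0.5-degree noise.
#'
#' @param nChains number of chains.
#' @param chainLength residues per chain.
#' @param sampler (phi, psi) sampler; see \linkS4class{EnsembleSpec}.
#' @param amplitude sinusoid amplitude A, degrees.
#' @param phase sinusoid phase, degrees.
#' @param noiseOmegaSd Gaussian sd of delta-omega noise, degrees.
#' @param thetaCSlope theta-C vs delta-omega slope.
#' @param thetaCIntercept theta-C intercept, degrees.
#' @param noiseThetaCSd Gaussian sd of theta-C noise, degrees.
#' @param seed integer RNG seed.
#' @return an \linkS4class{EnsembleSpec}.
#' @export
EnsembleSpec <- function(nChains = 50L, chainLength = 42L,
                         sampler = list(type = "basins", basins = defaultBasins()),
                         amplitude = 2, phase = 0, noiseOmegaSd = 1,
                         thetaCSlope = 0.6, thetaCIntercept = 0,
                         noiseThetaCSd = 0.5, seed = 1L) {
  new("EnsembleSpec", nChains = as.integer(nChains),
      chainLength = as.integer(chainLength), sampler = sampler,
      amplitude = amplitude, phase = phase, noiseOmegaSd = noiseOmegaSd,
      thetaCSlope = thetaCSlope, thetaCIntercept = thetaCIntercept,
      noiseThetaCSd = noiseThetaCSd, seed = as.integer(seed))
}

#' HarmonicFit: a fixed-period sinusoid fitted to angular deviations
#'
#' Model value at psi is \code{amplitude * sin(k (psi - phase)) + offset} with
#' k = 360 / period; the default period of 120 degrees puts extrema every 60
#' degrees of psi.
#'
#' @slot amplitude numeric degrees, >= 0.
#' @slot phase numeric degrees in [0, period).
#' @slot offset numeric degrees.
#' @slot period numeric degrees (fixed at fit time, default 120).
#' @slot rSquared numeric in [0, 1].
#' @slot n integer number of observations.
#' @exportClass HarmonicFit
setClass("HarmonicFit",
  representation(amplitude = "numeric", phase = "numeric", offset = "numeric",
                 period = "numeric", rSquared = "numeric", n = "integer"))

#' LinearFit: ordinary least squares on wrapped degree values
#'
#' @slot slope numeric.
#' @slot intercept numeric degrees.
#' @slot r numeric Pearson correlation in [-1, 1] (0 with
#'   \code{constantY = TRUE} when y has no variance).
#' @slot n integer.
#' @slot constantY logical.
#' @exportClass LinearFit
setClass("LinearFit",
  representation(slope = "numeric", intercept = "numeric", r = "numeric",
                 n = "integer", constantY = "logical"))

#' DistortionReport: C-alpha trace drift after omega idealization
#'
#' Carries every candidate drift metric so any reading of "trace difference"
#' can be checked: per-residue C-alpha displacements in the common anchored
#' frame (no superposition), their mean and maximum, and the RMSD after
#' optimal Kabsch superposition (always <= the unsuperposed RMS).
#'
#' @slot perResidueDisplacement numeric vector, Angstrom.
#' @slot meanDisplacement numeric Angstrom.
#' @slot maxDisplacement numeric Angstrom.
#' @slot kabschRmsd numeric Angstrom.
#' @slot nAtoms integer number of C-alpha atoms compared.
#' @exportClass DistortionReport
setClass("DistortionReport",
  representation(perResidueDisplacement = "numeric",
                 meanDisplacement = "numeric", maxDisplacement = "numeric",
                 kabschRmsd = "numeric", nAtoms = "integer"))

setValidity("DistortionReport", function(object) {
  msgs <- character()
  if (any(object@perResidueDisplacement < 0))
    msgs <- c(msgs, "displacements must be >= 0")
  rms <- sqrt(mean(object@perResidueDisplacement^2))
  if (object@kabschRmsd > rms + 1e-8)
    msgs <- c(msgs, "kabschRmsd cannot exceed unsuperposed RMS displacement")
  if (length(msgs)) msgs else TRUE
})
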