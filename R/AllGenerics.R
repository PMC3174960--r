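#' @include AllClasses.R
NULL

#' Accessors for pepgeom S4 objects
#'
#' @param object a pepgeom S4 object.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("entryId", function(object) standardGeneric("entryId"))
#' @rdname accessors
#' @export
setMethod("entryId", "StructureModel", function(object) object@entryId)

#' @rdname accessors
#' @export
setGeneric("atomData", function(object) standardGeneric("atomData"))
#' @rdname accessors
#' @export
setMethod("atomData", "StructureModel", function(object) object@atoms)

#' @rdname accessors
#' @export
setGeneric("resolutionOf", function(object) standardGeneric("resolutionOf"))
#' @rdname accessors
#' @export
setMethod("resolutionOf", "StructureModel", function(object) object@resolution)

#' @rdname accessors
#' @export
setGeneric("rFactorOf", function(object) standardGeneric("rFactorOf"))
#' @rdname accessors
#' @export
setMethod("rFactorOf", "StructureModel", function(object) object@rFactor)

#' @rdname accessors
#' @export
setGeneric("chainIds", function(object) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setMethod("chainIds", "StructureModel", function(object)
  unique(object@atoms$chain))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(object) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setMethod("nResidues", "StructureModel", function(object) {
  a <- object@atoms
  if (nrow(a) == 0L) return(0L)
  nrow(unique(a[, c("chain", "resno", "insert")]))
})
#' @rdname accessors
#' @export
setMethod("nResidues", "InternalCoordinates", function(object) object@nres)

#' @rdname accessors
#' @export
setGeneric("icTable", function(object) standardGeneric("icTable"))
#' @rdname accessors
#' @export
setMethod("icTable", "InternalCoordinates", function(object) object@ic)

#' @rdname accessors
#' @export
setGeneric("anchorCoords", function(object) standardGeneric("anchorCoords"))
#' @rdname accessors
#' @export
setMethod("anchorCoords", "InternalCoordinates", function(object) object@anchor)

#' @rdname accessors
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))
#' @rdname accessors
#' @export
setMethod("amplitude", "HarmonicFit", function(object) object@amplitude)

#' @rdname accessors
#' @export
setGeneric("phase", function(object) standardGeneric("phase"))
#' @rdname accessors
#' @export
setMethod("phase", "HarmonicFit", function(object) object@phase)

#' @rdname accessors
#' @export
setGeneric("offsetOf", function(object) standardGeneric("offsetOf"))
#' @rdname accessors
#' @export
setMethod("offsetOf", "HarmonicFit", function(object) object@offset)

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setMethod("rSquared", "HarmonicFit", function(object) object@rSquared)

#' @rdname accessors
#' @export
setGeneric("slopeOf", function(object) standardGeneric("slopeOf"))
#' @rdname accessors
#' @export
setMethod("slopeOf", "LinearFit", function(object) object@slope)

#' @rdname accessors
#' @export
setGeneric("interceptOf", function(object) standardGeneric("interceptOf"))
#' @rdname accessors
#' @export
setMethod("interceptOf", "LinearFit", function(object) object@intercept)

#' @rdname accessors
#' @export
setGeneric("pearsonR", function(object) standardGeneric("pearsonR"))
#' @rdname accessors
#' @export
setMethod("pearsonR", "LinearFit", function(object) object@r)

#' @rdname accessors
#' @export
setGeneric("caDisplacements", function(object) standardGeneric("caDisplacements"))
#' @rdname accessors
#' @export
setMethod("caDisplacements", "DistortionReport",
          function(object) object@perResidueDisplacement)

#' @rdname accessors
#' @export
setGeneric("meanDisplacement", function(object) standardGeneric("meanDisplacement"))
#' @rdname accessors
#' @export
setMethod("meanDisplacement", "DistortionReport",
          function(object) object@meanDisplacement)

#' @rdname accessors
#' @export
setGeneric("maxDisplacement", function(object) standardGeneric("maxDisplacement"))
#' @rdname accessors
#' @export
setMethod("maxDisplacement", "DistortionReport",
          function(object) object@maxDisplacement)

#' @rdname accessors
#' @export
setGeneric("kabschRmsd", function(object) standardGeneric("kabschRmsd"))
#' @rdname accessors
#' @export
setMethod("kabschRmsd", "DistortionReport", function(object) object@kabschRmsd)

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel", if (nzchar(object@entryId)) object@entryId else "<unnamed>",
      "\n  chains:", paste(chainIds(object), collapse = " "),
      "\n  residues:", nResidues(object),
      " atoms:", nrow(object@atoms), "\n")
  if (!is.na(object@resolution))
    cat("  resolution:", object@resolution, "A")
  if (!is.na(object@rFactor))
    cat("  R-factor:", object@rFactor)
  if (!is.na(object@resolution) || !is.na(object@rFactor)) cat("\n")
})

setMethod("show", "InternalCoordinates", function(object) {
  cat("InternalCoordinates:", object@nres, "residues,",
      nrow(object@ic) + 3L, "backbone atoms (3 anchored)\n")
})

setMethod("show", "HarmonicFit", function(object) {
  cat(sprintf(
    "HarmonicFit: %.3f deg * sin(%g deg period; phase %.2f deg) + %.3f deg\n  R^2 = %.4f, n = %d\n",
    object@amplitude, object@period, object@phase, object@offset,
    object@rSquared, object@n))
})

setMethod("show", "LinearFit", function(object) {
  cat(sprintf("LinearFit: y = %.4f + %.4f x, R = %.4f, n = %d\n",
              object@intercept, object@slope, object@r, object@n))
})

setMethod("show", "DistortionReport", function(object) {
  cat(sprintf(
    "DistortionReport over %d C-alpha atoms\n  mean displacement %.3f A, max %.3f A (anchored frame)\n  Kabsch RMSD %.3f A\n",
    object@nAtoms, object@meanDisplacement, object@maxDisplacement,
    object@kabschRmsd))
})

setMethod("show", "EnsembleSpec", function(object) {
  cat(sprintf(
    "EnsembleSpec: %d chains x %d residues, A = %g deg (phase %g), sd(omega-noise) = %g\n  theta-C = %g * d-omega + %g, sd = %g; sampler: %s; seed %d\n",
    object@nChains, object@chainLength, object@amplitude, object@phase,
    object@noiseOmegaSd, object@thetaCSlope, object@thetaCIntercept,
    object@noiseThetaCSd, object@sampler$type, object@seed))
})
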