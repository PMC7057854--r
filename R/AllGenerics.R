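#' Accessors for macrodissect objects
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param x a macrodissect object.
#' @return `nFrames` and `nAtoms` return integers; `ligandId` a string;
#'   `frames` a list of coordinate matrices; `atomData` the atom
#'   data.frame; `masks` a named list of atom-index vectors;
#'   `rmsdValues` the numeric RMSD vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("ligandId", function(x) standardGeneric("ligandId"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname accessors
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname accessors
#' @export
setGeneric("rmsdValues", function(x) standardGeneric("rmsdValues"))

#' @rdname accessors
#' @export
setMethod("nFrames", "ConformerEnsemble", function(x) length(x@frames))

#' @rdname accessors
#' @export
setMethod("nAtoms", "ConformerEnsemble", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setMethod("nAtoms", "ReferenceStructure", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setMethod("ligandId", "ConformerEnsemble", function(x) x@ligandId)

#' @rdname accessors
#' @export
setMethod("ligandId", "RmsdSeries", function(x) x@ligandId)

#' @rdname accessors
#' @export
setMethod("ligandId", "PopulationEstimate", function(x) x@ligandId)

#' @rdname accessors
#' @export
setMethod("ligandId", "SurfaceAreas", function(x) x@ligandId)

#' @rdname accessors
#' @export
setMethod("frames", "ConformerEnsemble", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("atomData", "ConformerEnsemble", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("atomData", "ReferenceStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("masks", "ReferenceStructure", function(x) x@masks)

#' @rdname accessors
#' @export
setMethod("rmsdValues", "RmsdSeries", function(x) x@values)

setMethod("show", "ConformerEnsemble", function(object) {
  cat("ConformerEnsemble '", object@ligandId, "': ",
      length(object@frames), " frames x ", nrow(object@atoms), " atoms, ",
      nrow(object@bonds), " bonds\n", sep = "")
})

setMethod("show", "ReferenceStructure", function(object) {
  cat("ReferenceStructure: ", nrow(object@atoms), " atoms; masks: ",
      paste(names(object@masks), collapse = ", "), "\n", sep = "")
})

setMethod("show", "RmsdSeries", function(object) {
  cat("RmsdSeries '", object@ligandId, "' vs '", object@referenceId, "' (",
      object@selectionName, "): ", length(object@values),
      " frames, range [", sprintf("%.2f", min(object@values)), ", ",
      sprintf("%.2f", max(object@values)), "] A\n", sep = "")
})

setMethod("show", "PopulationEstimate", function(object) {
  cat(sprintf(
    "PopulationEstimate '%s': p1 = %.3f +/- %s (threshold %.2f A, %d blocks)\n",
    object@ligandId, object@p1,
    if (is.na(object@sigmaP1)) "NA" else sprintf("%.3f", object@sigmaP1),
    object@threshold, object@nBlocks))
})

setMethod("show", "FepNetwork", function(object) {
  cat("FepNetwork: ", length(object@nodes), " ligands, ",
      nrow(object@edges), " binding edges; reference '",
      object@reference, "'\n", sep = "")
})

setMethod("show", "SurfaceAreas", function(object) {
  cat(sprintf(
    "SurfaceAreas '%s': %d frames; <PSA> = %.1f +/- %.1f, <NPSA> = %.1f +/- %.1f A^2\n",
    object@ligandId, nrow(object@perFrame),
    object@meanPsa, object@sigmaPsa, object@meanNpsa, object@sigmaNpsa))
})

setMethod("show", "LipoModel", function(object) {
  cat(sprintf(
    "LipoModel: logD = %.3f*NPSA %+.3f*PSA %+.3f  (n = %d, r_fit = %s)\n",
    object@coefNpsa, object@coefPsa, object@intercept, object@n,
    if (is.na(object@pearsonRFit)) "NA" else sprintf("%.3f", object@pearsonRFit)))
  cat("  descriptor scale: ", object@descriptorScale, "\n", sep = "")
})
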