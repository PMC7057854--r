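## Central S4 containers. Coordinates are Angstrom throughout; atom and frame
## indices are 1-based.

#' ConformerEnsemble: a multi-frame coordinate set for one ligand
#'
#' Holds the conformer ensemble of a single ligand, i.e. what an
#' enhanced-sampling molecular dynamics run of the free ligand produces:
#' a fixed atom table plus one coordinate set per frame.
#'
#' @slot ligandId single string identifying the ligand (e.g. "7_HH").
#' @slot atoms data.frame with columns `name`, `element`, `resid`
#'   (residue index), one row per atom; row order is the atom order of
#'   every frame.
#' @slot bonds two-column integer matrix of 1-based atom indices.
#' @slot frames list of numeric matrices, each `nAtoms x 3`, Angstrom.
#' @slot frameTimes optional numeric vector of frame times in ns
#'   (length 0 when absent).
#'
#' @seealso [readEnsemble()], [sliceBlocks()], [makeBimodalEnsemble()]
#' @exportClass ConformerEnsemble
setClass("ConformerEnsemble",
  representation(
    ligandId   = "character",
    atoms      = "data.frame",
    bonds      = "matrix",
    frames     = "list",
    frameTimes = "numeric"
  )
)

setValidity("ConformerEnsemble", function(object) {
  msg <- character()
  na <- nrow(object@atoms)
  if (length(object@ligandId) != 1L) msg <- c(msg, "ligandId must be a single string")
  if (!all(c("name", "element", "resid") %in% names(object@atoms)))
    msg <- c(msg, "atoms must have columns name, element, resid")
  if (length(object@frames) < 1L) msg <- c(msg, "ensemble must have at least 1 frame")
  bad <- which(!vapply(object@frames, function(f)
    is.matrix(f) && nrow(f) == na && ncol(f) == 3L && is.numeric(f), logical(1)))
  if (length(bad))
    msg <- c(msg, sprintf("frame %d does not have %d x 3 numeric coordinates", bad[1], na))
  if (nrow(object@bonds)) {
    if (ncol(object@bonds) != 2L) msg <- c(msg, "bonds must have two columns")
    else {
      if (any(object@bonds < 1L | object@bonds > na))
        msg <- c(msg, "bond indices out of atom range")
      if (any(object@bonds[, 1] == object@bonds[, 2]))
        msg <- c(msg, "self-bonds are not allowed")
    }
  }
  if (length(object@frameTimes) &&
      length(object@frameTimes) != length(object@frames))
    msg <- c(msg, "frameTimes must match the number of frames")
  if (length(msg)) msg else TRUE
})

#' ReferenceStructure: a single bound-state coordinate set with atom masks
#'
#' The reference against which free-ligand conformers are measured,
#' typically the ligand conformation extracted from a ligand/protein
#' co-crystal structure. Named selection masks (e.g. "backbone",
#' "crosslink") define the atom sets used for superposition and RMSD.
#'
#' @slot atoms data.frame as in [ConformerEnsemble-class].
#' @slot coords numeric matrix `nAtoms x 3`, Angstrom.
#' @slot masks named list of 1-based integer atom-index vectors.
#' @slot bonds two-column integer matrix of 1-based atom indices.
#'
#' @exportClass ReferenceStructure
setClass("ReferenceStructure",
  representation(
    atoms  = "data.frame",
    coords = "matrix",
    masks  = "list",
    bonds  = "matrix"
  )
)

setValidity("ReferenceStructure", function(object) {
  msg <- character()
  na <- nrow(object@atoms)
  if (!is.numeric(object@coords) || nrow(object@coords) != na ||
      ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be an nAtoms x 3 numeric matrix")
  if (length(object@masks)) {
    if (is.null(names(object@masks)) || any(!nzchar(names(object@masks))))
      msg <- c(msg, "masks must be named")
    for (nm in names(object@masks)) {
      ix <- object@masks[[nm]]
      if (!length(ix)) msg <- c(msg, sprintf("mask '%s' is empty", nm))
      else if (any(ix < 1L | ix > na))
        msg <- c(msg, sprintf("mask '%s' has indices outside 1..%d", nm, na))
    }
  }
  if (length(msg)) msg else TRUE
})

#' AtomClassTable: polar/nonpolar class and vdW radius per atom
#'
#' @slot atomClass character vector, each entry "polar" or "nonpolar".
#' @slot radius numeric vector of positive van der Waals radii (Angstrom),
#'   parallel to `atomClass`.
#'
#' @seealso [assignAtomClasses()]
#' @exportClass AtomClassTable
setClass("AtomClassTable",
  representation(atomClass = "character", radius = "numeric")
)

setValidity("AtomClassTable", function(object) {
  msg <- character()
  if (length(object@atomClass) != length(object@radius))
    msg <- c(msg, "class and radius must have equal length")
  if (!all(object@atomClass %in% c("polar", "nonpolar")))
    msg <- c(msg, "classes must be 'polar' or 'nonpolar'")
  if (any(!is.finite(object@radius) | object@radius <= 0))
    msg <- c(msg, "all radii must be positive")
  if (length(msg)) msg else TRUE
})

#' RmsdSeries: per-frame RMSD of an ensemble against a reference
#'
#' @slot ligandId ligand identifier.
#' @slot values numeric vector of RMSD values (Angstrom), one per frame.
#' @slot selectionName name of the mask the RMSD was measured over.
#' @slot referenceId identifier of the reference structure.
#'
#' @seealso [rmsdSeries()], [classifyPopulations()]
#' @exportClass RmsdSeries
setClass("RmsdSeries",
  representation(
    ligandId      = "character",
    values        = "numeric",
    selectionName = "character",
    referenceId   = "character"
  )
)

setValidity("RmsdSeries", function(object) {
  msg <- character()
  if (!length(object@values)) msg <- c(msg, "empty RMSD series")
  if (any(object@values < 0, na.rm = TRUE)) msg <- c(msg, "RMSD values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PopulationEstimate: occupancy of the bioactive population with block error
#'
#' Occupancy of population 1 (frames with RMSD at or below the threshold,
#' i.e. conformers resembling the bound state) with a 1-sigma statistical
#' uncertainty estimated from contiguous trajectory blocks.
#'
#' @slot ligandId ligand identifier.
#' @slot p1 fraction of frames in population 1.
#' @slot p2 fraction in population 2 (`1 - p1`).
#' @slot sigmaP1 sample standard deviation (ddof = 1) of the per-block p1
#'   values; `NA` when fewer than 2 blocks were used.
#' @slot threshold RMSD threshold (Angstrom) separating the populations.
#' @slot nBlocks number of contiguous blocks.
#' @slot perBlockP1 numeric vector of per-block p1 values.
#'
#' @exportClass PopulationEstimate
setClass("PopulationEstimate",
  representation(
    ligandId   = "character",
    p1         = "numeric",
    p2         = "numeric",
    sigmaP1    = "numeric",
    threshold  = "numeric",
    nBlocks    = "integer",
    perBlockP1 = "numeric"
  )
)

setValidity("PopulationEstimate", function(object) {
  msg <- character()
  if (abs(object@p1 + object@p2 - 1) > 1e-12) msg <- c(msg, "p1 + p2 must equal 1")
  if (object@p1 < 0 || object@p1 > 1) msg <- c(msg, "p1 must lie in [0, 1]")
  if (!is.na(object@sigmaP1) && object@sigmaP1 < 0) msg <- c(msg, "sigmaP1 must be >= 0")
  if (length(object@perBlockP1) != object@nBlocks)
    msg <- c(msg, "perBlockP1 must have one entry per block")
  if (length(msg)) msg else TRUE
})

#' FepNetwork: relative binding free energy differences on a ligand graph
#'
#' Nodes are ligands; each edge carries a binding free energy difference
#' `ddG = ddG(complex leg) - ddG(solvent leg)` in kcal/mol for the
#' alchemical transformation `from -> to`, optionally annotated with the
#' restraint force constant it was computed under.
#'
#' @slot nodes character vector of ligand ids.
#' @slot edges data.frame with columns `from`, `to`, `ddG` and optionally
#'   `forceConstant`; one row per binding edge.
#' @slot reference ligand id anchoring relative pKd estimates at 0.
#'
#' @seealso [fepNetwork()], [cycleClosure()], [relativeDpkd()]
#' @exportClass FepNetwork
setClass("FepNetwork",
  representation(
    nodes     = "character",
    edges     = "data.frame",
    reference = "character"
  )
)

setValidity("FepNetwork", function(object) {
  msg <- character()
  if (!all(c("from", "to", "ddG") %in% names(object@edges)))
    msg <- c(msg, "edges must have columns from, to, ddG")
  else {
    if (any(object@edges$from == object@edges$to))
      msg <- c(msg, "self-edges are not allowed")
    if (!all(c(object@edges$from, object@edges$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed in nodes")
  }
  if (length(object@reference) != 1L || !(object@reference %in% object@nodes))
    msg <- c(msg, "reference must be one of the nodes")
  if (length(msg)) msg else TRUE
})

#' SurfaceAreas: per-frame and ensemble-averaged SASA partition
#'
#' Total solvent accessible surface area of each frame, partitioned into
#' polar (PSA) and nonpolar (NPSA) atom contributions, with ensemble means
#' and 1-sigma uncertainties.
#'
#' @slot ligandId ligand identifier.
#' @slot perFrame data.frame with columns `total`, `psa`, `npsa`
#'   (Angstrom^2), one row per frame.
#' @slot meanPsa,meanNpsa ensemble means (Angstrom^2).
#' @slot sigmaPsa,sigmaNpsa 1-sigma uncertainties (over frames, or over
#'   blocks when computed block-wise).
#'
#' @seealso [ensembleSurface()]
#' @exportClass SurfaceAreas
setClass("SurfaceAreas",
  representation(
    ligandId  = "character",
    perFrame  = "data.frame",
    meanPsa   = "numeric",
    meanNpsa  = "numeric",
    sigmaPsa  = "numeric",
    sigmaNpsa = "numeric"
  )
)

setValidity("SurfaceAreas", function(object) {
  msg <- character()
  pf <- object@perFrame
  if (!all(c("total", "psa", "npsa") %in% names(pf)))
    msg <- c(msg, "perFrame must have columns total, psa, npsa")
  else {
    if (any(pf$total < 0 | pf$psa < 0 | pf$npsa < 0))
      msg <- c(msg, "areas must be >= 0")
    if (any(abs(pf$total - pf$psa - pf$npsa) > 1e-6))
      msg <- c(msg, "per-frame total must equal psa + npsa")
  }
  if (length(msg)) msg else TRUE
})

#' LipoModel: linear lipophilicity model logD ~ NPSA + PSA
#'
#' Ordinary least squares fit of measured logD on ensemble-averaged
#' nonpolar and polar surface-area descriptors. The descriptor scale is
#' whatever the caller supplied; it is recorded, never rescaled.
#'
#' @slot coefNpsa,coefPsa slopes in logD units per descriptor unit.
#' @slot intercept intercept in logD units.
#' @slot pearsonRFit Pearson correlation of fitted vs. measured logD
#'   (`NA` when undefined, e.g. constant response).
#' @slot n number of observations used in the fit.
#' @slot descriptorScale free-text note recording the descriptor units.
#' @slot fit the underlying `lm` object (or `NULL`).
#'
#' @seealso [fitLogdModel()], [predictLogd()]
#' @exportClass LipoModel
setClass("LipoModel",
  representation(
    coefNpsa        = "numeric",
    coefPsa         = "numeric",
    intercept       = "numeric",
    pearsonRFit     = "numeric",
    n               = "integer",
    descriptorScale = "character",
    fit             = "ANY"
  )
)

setValidity("LipoModel", function(object) {
  msg <- character()
  if (!is.na(object@pearsonRFit) && abs(object@pearsonRFit) > 1 + 1e-12)
    msg <- c(msg, "|pearsonRFit| must be <= 1")
  if (object@n < 3L) msg <- c(msg, "a fit needs at least 3 observations")
  if (length(msg)) msg else TRUE
})
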