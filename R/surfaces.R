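## Shrake-Rupley solvent accessible surface area with a polar/nonpolar
## partition, and ensemble-averaged (dynamic) PSA/NPSA.

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice). Seed-free: the same nPoints always gives the same lattice.
.spherePoints <- function(nPoints) {
  i <- seq_len(nPoints) - 0.5
  z <- 1 - 2 * i / nPoints
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley per-atom solvent accessible surface area
#'
#' Each atom's sphere of radius `r_i + probe` is sampled with a
#' deterministic golden-spiral lattice of `nPoints` points; a point is
#' accessible iff it lies strictly outside every other atom's expanded
#' sphere, and the atom's SASA is the accessible fraction times
#' `4 pi (r_i + probe)^2`. With the strict-inequality rule, coincident
#' atoms of equal radius each keep their shared surface points.
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param radii per-atom vdW radii (Angstrom), positive.
#' @param probeRadius solvent probe radius (Angstrom, default 1.4 =
#'   water).
#' @param nPoints sphere sample points per atom (default 960).
#' @return numeric vector of per-atom SASA (Angstrom^2).
#' @export
#' @examples
#' shrakeRupley(matrix(0, 1, 3), 1.6)  # isolated sphere: 4*pi*3^2
shrakeRupley <- function(coords, radii, probeRadius = 1.4, nPoints = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) == 1L) radii <- rep(radii, n)
  if (length(radii) != n) stop("need one radius per atom")
  if (any(radii <= 0)) stop("radii must be positive")
  if (nPoints < 1L) stop("nPoints must be >= 1")
  pts <- .spherePoints(nPoints)
  expanded <- radii + probeRadius
  # neighbor lists: only atoms whose expanded spheres can overlap matter
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    nb <- which(d < expanded[i] + expanded & seq_len(n) != i)
    if (!length(nb)) { out[i] <- 4 * pi * expanded[i]^2; next }
    P <- pts * expanded[i]
    P <- sweep(P, 2, coords[i, ], `+`)
    buried <- rep(FALSE, nPoints)
    for (j in nb) {
      dj2 <- (P[, 1] - coords[j, 1])^2 + (P[, 2] - coords[j, 2])^2 +
        (P[, 3] - coords[j, 3])^2
      # strict-inequality exclusion with a margin above FP noise, so
      # points exactly on a neighbor's surface stay accessible
      buried <- buried | (dj2 < expanded[j]^2 - 1e-9)
      if (all(buried)) break
    }
    out[i] <- mean(!buried) * 4 * pi * expanded[i]^2
  }
  out
}

#' Partition per-atom SASA into polar and nonpolar surface area
#'
#' @param perAtomSasa per-atom SASA vector (Angstrom^2), e.g. from
#'   [shrakeRupley()].
#' @param classes an [AtomClassTable-class] parallel to the atoms.
#' @return named numeric vector `c(psa = ..., npsa = ...)`.
#' @export
partitionSasa <- function(perAtomSasa, classes) {
  stopifnot(is(classes, "AtomClassTable"))
  if (length(perAtomSasa) != length(classes@atomClass))
    stop("every atom needs a class: lengths differ")
  c(psa = sum(perAtomSasa[classes@atomClass == "polar"]),
    npsa = sum(perAtomSasa[classes@atomClass == "nonpolar"]))
}

#' Ensemble-averaged (dynamic) surface areas
#'
#' Computes per-frame total SASA, PSA and NPSA across a conformer
#' ensemble and the ensemble means with 1-sigma uncertainties — the
#' "dynamic" surface areas of a flexible ligand. Uncertainties are over
#' frames by default, or over contiguous block means when `nBlocks` is
#' at least 2.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param classes an [AtomClassTable-class]; default
#'   `assignAtomClasses(ensemble)`.
#' @param probeRadius probe radius (Angstrom, default 1.4).
#' @param nPoints sphere sample points per atom (default 960).
#' @param nBlocks when >= 2, sigma is the sd of block means over this
#'   many contiguous blocks.
#' @param framesSubset optional frame indices to restrict the average to
#'   (e.g. population-1 frames only).
#' @return a [SurfaceAreas-class].
#' @export
ensembleSurface <- function(ensemble, classes = assignAtomClasses(ensemble),
                            probeRadius = 1.4, nPoints = 960L,
                            nBlocks = NULL, framesSubset = NULL) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  frames <- ensemble@frames
  if (!is.null(framesSubset)) frames <- frames[framesSubset]
  pf <- t(vapply(frames, function(f) {
    sa <- shrakeRupley(f, classes@radius, probeRadius, nPoints)
    p <- partitionSasa(sa, classes)
    c(total = sum(sa), p)
  }, numeric(3)))
  pf <- as.data.frame(pf)
  sigma <- function(v) {
    if (!is.null(nBlocks) && nBlocks >= 2L && length(v) >= nBlocks) {
      bm <- vapply(.blockIndices(length(v), as.integer(nBlocks)),
                   function(ix) mean(v[ix]), numeric(1))
      sd(bm)
    } else if (length(v) >= 2L) sd(v) else 0
  }
  new("SurfaceAreas", ligandId = ensemble@ligandId, perFrame = pf,
      meanPsa = mean(pf$psa), meanNpsa = mean(pf$npsa),
      sigmaPsa = sigma(pf$psa), sigmaNpsa = sigma(pf$npsa))
}
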