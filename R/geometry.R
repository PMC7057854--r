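## Rigid-body superposition (Kabsch), RMSD series and torsions.

#' Kabsch least-squares rigid-body superposition
#'
#' Computes the proper rotation and translation that superposes `mobile`
#' onto `reference` in the least-squares sense over a selection of atoms,
#' via SVD of the covariance matrix with the standard sign correction so
#' reflections are never returned (det(R) = +1).
#'
#' @param mobile,reference `n x 3` coordinate matrices (Angstrom) with
#'   identical atom order.
#' @param selection 1-based atom indices used both for the fit and the
#'   returned RMSD; default all atoms. Needs at least 3 non-collinear
#'   atoms.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3;
#'   the transform is `x %*% rotation + translation`), and `rmsd`
#'   (Angstrom, over the selection, after transforming `mobile`).
#' @export
#' @examples
#' ref <- matrix(rnorm(12), 4, 3)
#' kabschSuperpose(ref + 5, ref)$rmsd  # ~0: translation removed
kabschSuperpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L)
    stop("superposition needs at least 3 selected atoms")
  if (any(selection > nrow(mobile)) || any(selection > nrow(reference)))
    stop("selection index out of range")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity check: rank of the centered selection must be >= 2
  if (sum(svd(A0)$d > 1e-8 * max(1, max(abs(A0)))) < 2L)
    stop("selected atoms are collinear; superposition is ill-defined")
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)   # so that A0 %*% t(R) ~ B0
  rot <- t(R)
  trans <- cb - as.vector(ca %*% rot)
  fitted <- A %*% rot + matrix(trans, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

# RMSD between two aligned coordinate blocks (no fitting).
.rawRmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD of an ensemble against a reference structure
#'
#' For each frame: superpose on the atoms of `fitSelection`, then measure
#' RMSD over the atoms of `measureSelection`. Both selections are named
#' masks of the reference (see [ReferenceStructure()]); the same indices
#' are applied to the ensemble, so ensemble and reference must share the
#' atom order over the selected atoms. For free-ligand ensembles the fit
#' is on the ligand itself.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param reference a [ReferenceStructure-class].
#' @param fitSelection mask name used for superposition (default
#'   "backbone").
#' @param measureSelection mask name the RMSD is measured over; defaults
#'   to `fitSelection`.
#' @return an [RmsdSeries-class] of length `nFrames(ensemble)`.
#' @export
#' @examples
#' ref <- makeToyMacrocycle(8)
#' ens <- makeBimodalEnsemble(EnsembleSpec("x", nFrames = 50, seed = 1), ref)
#' summary(rmsdValues(rmsdSeries(ens, ref)))
rmsdSeries <- function(ensemble, reference, fitSelection = "backbone",
                       measureSelection = fitSelection) {
  stopifnot(is(ensemble, "ConformerEnsemble"),
            is(reference, "ReferenceStructure"))
  for (nm in unique(c(fitSelection, measureSelection)))
    if (!nm %in% names(reference@masks))
      stop("mask '", nm, "' is not defined on the reference")
  fitIx <- reference@masks[[fitSelection]]
  meaIx <- reference@masks[[measureSelection]]
  if (max(c(fitIx, meaIx)) > nAtoms(ensemble))
    stop("mask indices exceed the ensemble atom count (mask mismatch)")
  refC <- reference@coords
  vals <- vapply(ensemble@frames, function(f) {
    fit <- kabschSuperpose(f, refC, fitIx)
    moved <- f %*% fit$rotation +
      matrix(fit$translation, nrow(f), 3, byrow = TRUE)
    .rawRmsd(moved[meaIx, , drop = FALSE], refC[meaIx, , drop = FALSE])
  }, numeric(1))
  new("RmsdSeries", ligandId = ensemble@ligandId, values = vals,
      selectionName = measureSelection, referenceId = "reference")
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking down the p2->p3 bond, a clockwise
#' rotation of the p3-p4 bond relative to p1-p2 is positive. Returns
#' degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
#' @examples
#' dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # 180
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) < 1e-20 || sum(b2^2) < 1e-20 || sum(b3^2) < 1e-20)
    stop("degenerate geometry: consecutive points coincide")
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate geometry: collinear points")
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion profile of one bond across an ensemble
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param atomQuad ordered 1-based indices of the four atoms defining the
#'   dihedral.
#' @return list with `bond` (the quad), `angles` (degrees, one per frame)
#'   and `histogram` (10-degree bins over (-180, 180]).
#' @export
torsionProfile <- function(ensemble, atomQuad) {
  stopifnot(length(atomQuad) == 4L, all(atomQuad <= nAtoms(ensemble)))
  ang <- vapply(ensemble@frames, function(f)
    dihedralAngle(f[atomQuad[1], ], f[atomQuad[2], ],
                  f[atomQuad[3], ], f[atomQuad[4], ]), numeric(1))
  h <- hist(ang, breaks = seq(-180, 180, by = 10), plot = FALSE,
            right = TRUE)
  list(bond = as.integer(atomQuad), angles = ang,
       histogram = data.frame(mid = h$mids, count = h$counts))
}
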