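## Seeded synthetic-data generators. These emulate the statistical
## structure of enhanced-sampling MD output — bimodal free-ligand RMSD
## ensembles with a known bioactive fraction, FEP networks with additive
## node free energies plus Gaussian edge noise, and linear PSA/NPSA->logD
## data — so the full pipeline can run and be validated without any MD
## engine. Every generator consumes an explicit integer seed and is
## bit-reproducible for a fixed spec + seed.

#' Specification of a synthetic bimodal conformer ensemble
#'
#' @param ligandId ligand identifier.
#' @param nFrames number of frames.
#' @param pBioactive probability that a frame is drawn from the native
#'   (bioactive, population-1) mode; in [0, 1]. Default 0.30, the
#'   mid-range occupancy of the study ligands (observed range 0.06-0.40).
#' @param nativeJitterSigma per-coordinate Gaussian jitter of native
#'   frames (Angstrom, default 0.25; puts the native RMSD mode well
#'   below the 2.6 Angstrom threshold).
#' @param decoySegmentAngle rotation (degrees, default 120) of the
#'   crosslink-bearing half of the ring in decoy frames; mimics the
#'   crosslink swinging away from its bound-state position.
#' @param decoyDisplacement extra rigid displacement (Angstrom, default
#'   2) of the rotated segment, pushing the decoy RMSD mode well above
#'   the threshold.
#' @param seed integer RNG seed.
#' @return a list of class "EnsembleSpec".
#' @export
EnsembleSpec <- function(ligandId, nFrames = 1000L, pBioactive = 0.30,
                         nativeJitterSigma = 0.25, decoySegmentAngle = 120,
                         decoyDisplacement = 2, seed = 1L) {
  if (pBioactive < 0 || pBioactive > 1) stop("pBioactive must be in [0, 1]")
  if (nativeJitterSigma <= 0 || decoyDisplacement < 0)
    stop("jitter sigma must be positive, displacement non-negative")
  structure(list(ligandId = as.character(ligandId),
                 nFrames = as.integer(nFrames),
                 pBioactive = pBioactive,
                 nativeJitterSigma = nativeJitterSigma,
                 decoySegmentAngle = decoySegmentAngle,
                 decoyDisplacement = decoyDisplacement,
                 seed = as.integer(seed)),
            class = "EnsembleSpec")
}

#' Toy macrocycle reference structure
#'
#' Builds a closed ring of pseudo-residues (backbone atoms N, CA, C, O
#' each) with CA-CA spacing ~3.8 Angstrom, plus a two-carbon crosslink
#' chord bridging two ring positions — a geometric stand-in for a
#' crosslinked macrocyclic peptide. Masks "backbone" (ring N/CA/C/O),
#' "crosslink" (chord carbons) and "all" are populated; bonds cover the
#' ring and the chord.
#'
#' @param nResidues number of ring residues (>= 4, default 8).
#' @return a [ReferenceStructure-class].
#' @export
#' @examples
#' nAtoms(makeToyMacrocycle(8))  # 34: 8*4 backbone + 2 crosslink
makeToyMacrocycle <- function(nResidues = 8L) {
  nResidues <- as.integer(nResidues)
  if (nResidues < 4L) stop("need at least 4 residues to close a ring")
  R <- 3.8 / (2 * sin(pi / nResidues))
  theta <- 2 * pi * (seq_len(nResidues) - 1) / nResidues
  dtheta <- 2 * pi / nResidues
  atoms <- list(); coords <- list(); bonds <- list()
  idx <- function(res, k) (res - 1L) * 4L + k  # N=1, CA=2, C=3, O=4
  for (r in seq_len(nResidues)) {
    t0 <- theta[r]
    ca <- c(R * cos(t0), R * sin(t0), 0)
    nn <- c(R * cos(t0 - 0.35 * dtheta), R * sin(t0 - 0.35 * dtheta), 0.35)
    cc <- c(R * cos(t0 + 0.35 * dtheta), R * sin(t0 + 0.35 * dtheta), -0.35)
    oo <- cc + c(1.23 * cos(t0), 1.23 * sin(t0), -0.55)
    atoms[[r]] <- data.frame(
      name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      resid = r, stringsAsFactors = FALSE)
    coords[[r]] <- rbind(nn, ca, cc, oo)
    bonds[[r]] <- rbind(c(idx(r, 1), idx(r, 2)), c(idx(r, 2), idx(r, 3)),
                        c(idx(r, 3), idx(r, 4)),
                        c(idx(r, 3), idx(r %% nResidues + 1L, 1)))
  }
  atoms <- do.call(rbind, atoms)
  coords <- do.call(rbind, coords)
  # crosslink chord between residues 2 and 2 + nResidues/2 (cf. ring
  # positions 3 and 6 of an 8-residue macrocycle), lifted out of plane
  r1 <- 2L; r2 <- 2L + nResidues %/% 2L
  ca1 <- coords[idx(r1, 2), ]; ca2 <- coords[idx(r2, 2), ]
  x1 <- ca1 + (ca2 - ca1) / 3 + c(0, 0, 1.6)
  x2 <- ca1 + 2 * (ca2 - ca1) / 3 + c(0, 0, 1.6)
  atoms <- rbind(atoms, data.frame(
    name = c("CX1", "CX2"), element = c("C", "C"),
    resid = c(r1, r2), stringsAsFactors = FALSE))
  nb <- nrow(coords)
  coords <- rbind(coords, rbind(x1, x2))
  bonds <- rbind(do.call(rbind, bonds),
                 c(idx(r1, 2), nb + 1L), c(nb + 1L, nb + 2L),
                 c(nb + 2L, idx(r2, 2)))
  rownames(atoms) <- NULL; dimnames(coords) <- NULL
  ReferenceStructure(
    atoms, coords,
    masks = list(backbone = seq_len(nb),
                 crosslink = c(nb + 1L, nb + 2L),
                 all = seq_len(nb + 2L)),
    bonds = bonds)
}

# Rotate points about the axis through `origin` with unit direction
# `axis` by `angleDeg` degrees (Rodrigues).
.rotateAbout <- function(points, origin, axis, angleDeg) {
  a <- angleDeg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  p <- sweep(points, 2, origin)
  kx <- .cross3Mat(p, k)
  rot <- p * cos(a) + kx * sin(a) +
    outer(as.vector(p %*% k), k) * (1 - cos(a))
  sweep(rot, 2, origin, `+`)
}

.cross3Mat <- function(p, k) {
  cbind(k[2] * p[, 3] - k[3] * p[, 2],
        k[3] * p[, 1] - k[1] * p[, 3],
        k[1] * p[, 2] - k[2] * p[, 1])
}

#' Generate a bimodal conformer ensemble with known ground truth
#'
#' Each frame is, with probability `pBioactive`, the reference perturbed
#' by isotropic Gaussian jitter (the native, population-1 mode), and
#' otherwise a decoy built by rotating the crosslink-bearing half of the
#' ring about the hinge axis and displacing it — mimicking the crosslink
#' leaving its bound-state position — plus the same jitter. Ground-truth
#' labels are returned so recovery can be tested without the RMSD
#' classifier. The generator warns when the two RMSD modes are closer
#' than 4 pooled standard deviations (modes merged, classification
#' unreliable).
#'
#' @param spec an [EnsembleSpec()].
#' @param reference a [ReferenceStructure-class] with "backbone" and
#'   "crosslink" masks, e.g. [makeToyMacrocycle()].
#' @return list with `ensemble` (a [ConformerEnsemble-class]), `labels`
#'   (character, "native"/"decoy" per frame) and `seed`.
#' @export
#' @examples
#' ref <- makeToyMacrocycle(8)
#' out <- makeBimodalEnsemble(EnsembleSpec("5_MeMe", 200, 0.3, seed = 7), ref)
#' mean(out$labels == "native")
makeBimodalEnsemble <- function(spec, reference) {
  stopifnot(inherits(spec, "EnsembleSpec"),
            is(reference, "ReferenceStructure"))
  set.seed(spec$seed)
  na <- nAtoms(reference)
  ref <- reference@coords
  # segment to move in decoys: atoms of the ring half between the two
  # crosslink anchor residues, plus the crosslink itself
  anchors <- sort(unique(reference@atoms$resid[reference@masks$crosslink]))
  if (length(anchors) < 2L) anchors <- c(anchors, anchors + 3L)
  segRes <- seq(anchors[1], anchors[2])
  seg <- which(reference@atoms$resid %in% segRes |
                 seq_len(na) %in% reference@masks$crosslink)
  hinge1 <- which(reference@atoms$resid == anchors[1] &
                    reference@atoms$name == "CA")[1]
  hinge2 <- which(reference@atoms$resid == anchors[2] &
                    reference@atoms$name == "CA")[1]
  axis <- ref[hinge2, ] - ref[hinge1, ]
  labels <- ifelse(stats::runif(spec$nFrames) < spec$pBioactive,
                   "native", "decoy")
  frames <- vector("list", spec$nFrames)
  for (i in seq_len(spec$nFrames)) {
    f <- ref
    if (labels[i] == "decoy") {
      f[seg, ] <- .rotateAbout(f[seg, , drop = FALSE], ref[hinge1, ],
                               axis, spec$decoySegmentAngle)
      f[seg, 3] <- f[seg, 3] + spec$decoyDisplacement
    }
    f <- f + matrix(rnorm(3 * na, sd = spec$nativeJitterSigma), na, 3)
    frames[[i]] <- f
  }
  ens <- ConformerEnsemble(spec$ligandId, reference@atoms, frames,
                           bonds = reference@bonds)
  # mode-separation check on the actual RMSD series
  rs <- rmsdValues(rmsdSeries(ens, reference))
  if (all(c("native", "decoy") %in% labels)) {
    mN <- mean(rs[labels == "native"]); mD <- mean(rs[labels == "decoy"])
    sN <- sd(rs[labels == "native"]); sD <- sd(rs[labels == "decoy"])
    pooled <- sqrt(mean(c(sN^2, sD^2), na.rm = TRUE))
    if (is.finite(pooled) && abs(mD - mN) < 4 * pooled)
      warning("native and decoy RMSD modes are separated by less than ",
              "4 pooled sigma; populations may merge")
  }
  list(ensemble = ens, labels = labels, seed = spec$seed)
}

#' Specification of a synthetic FEP network
#'
#' @param nodeDdg named numeric vector of true relative binding free
#'   energies (kcal/mol) per ligand.
#' @param edges data.frame with columns `from`, `to` (ligand ids among
#'   `names(nodeDdg)`).
#' @param noiseSigma per-leg Gaussian noise sd (kcal/mol).
#' @param seed integer RNG seed.
#' @return list of class "NetworkSpec".
#' @export
NetworkSpec <- function(nodeDdg, edges, noiseSigma = 0.2, seed = 1L) {
  edges <- as.data.frame(edges)
  if (!all(c(edges$from, edges$to) %in% names(nodeDdg)))
    stop("edge endpoints must be named in nodeDdg")
  structure(list(nodeDdg = nodeDdg, edges = edges,
                 noiseSigma = noiseSigma, seed = as.integer(seed)),
            class = "NetworkSpec")
}

#' Generate a synthetic FEP edge table
#'
#' Per edge and leg, the forward free energy difference is the additive
#' node difference plus `N(0, sigma)` noise; the backward value is minus
#' the forward truth plus independent noise, so hysteresis is exactly 0
#' at `sigma = 0` and has sd `sigma * sqrt(2)` otherwise. Solvent-leg
#' node values are drawn once per ligand so that the binding combination
#' (complex minus solvent) recovers `nodeDdg` differences.
#'
#' @param spec a [NetworkSpec()].
#' @param forceConstant restraint force constant label attached to every
#'   row (kcal/mol/Angstrom^2, default 1).
#' @return data.frame in the edge-table layout of [readFepEdges()]:
#'   `ligand_from`, `ligand_to`, `leg`, `ddG_kcal_mol`,
#'   `ddG_reverse_kcal_mol`, `force_constant`.
#' @export
makeFepNetwork <- function(spec, forceConstant = 1) {
  stopifnot(inherits(spec, "NetworkSpec"))
  set.seed(spec$seed)
  solvent <- setNames(rnorm(length(spec$nodeDdg)), names(spec$nodeDdg))
  complexG <- spec$nodeDdg + solvent
  rows <- list()
  for (i in seq_len(nrow(spec$edges))) {
    a <- spec$edges$from[i]; b <- spec$edges$to[i]
    for (leg in c("complex", "solvent")) {
      truth <- if (leg == "complex") complexG[[b]] - complexG[[a]] else
        solvent[[b]] - solvent[[a]]
      fwd <- truth + rnorm(1, sd = spec$noiseSigma)
      bwd <- -truth + rnorm(1, sd = spec$noiseSigma)
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_from = a, ligand_to = b, leg = leg,
        ddG_kcal_mol = fwd, ddG_reverse_kcal_mol = bwd,
        force_constant = forceConstant, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic PSA/NPSA -> logD dataset
#'
#' Descriptors are uniform draws (NPSA ~ U(6, 9), PSA ~ U(3.5, 5), in
#' units of 100 Angstrom^2) and logD follows the linear model plus
#' Gaussian noise. With the default coefficients the generated logD
#' values fall in the experimentally typical 0.5-1.5 range for
#' macrocyclic peptides.
#'
#' @param coefNpsa,coefPsa,intercept generating coefficients (defaults
#'   0.27, -0.82, 2.22).
#' @param noiseSigma sd of additive logD noise (default 0.05).
#' @param n number of compounds (>= 4, default 12).
#' @param seed integer RNG seed.
#' @param npsaRange,psaRange descriptor ranges (units of 100 Angstrom^2).
#' @return data.frame with columns `psa`, `npsa`, `logd`.
#' @export
#' @examples
#' d <- makeLipoDataset(n = 10, noiseSigma = 0, seed = 3)
#' fitLogdModel(d$psa, d$npsa, d$logd)
makeLipoDataset <- function(coefNpsa = 0.27, coefPsa = -0.82,
                            intercept = 2.22, noiseSigma = 0.05, n = 12L,
                            seed = 1L, npsaRange = c(6, 9),
                            psaRange = c(3.5, 5)) {
  if (n < 4L) stop("need n >= 4")
  set.seed(as.integer(seed))
  npsa <- runif(n, npsaRange[1], npsaRange[2])
  psa <- runif(n, psaRange[1], psaRange[2])
  logd <- coefNpsa * npsa + coefPsa * psa + intercept +
    rnorm(n, sd = noiseSigma)
  data.frame(psa = psa, npsa = npsa, logd = logd)
}

#' Generate the four-ligand synthetic population study
#'
#' Builds one bimodal ensemble per ligand at the bioactive occupancies
#' reported for the substitution series (H/H 6%, Me/H 16%, Me/Me 30%,
#' Et/Me 40%), all against one toy-macrocycle reference.
#'
#' @param nFrames frames per ligand (default 5000).
#' @param seed integer base seed; ligand i uses `seed * 1000 + i`.
#' @param pValues named occupancy vector; the default is the study
#'   series.
#' @return list with `reference`, `ensembles` (named list of
#'   [ConformerEnsemble-class]), `labels` (named list) and `pTrue`.
#' @export
makeStudy <- function(nFrames = 5000L, seed = 1L,
                      pValues = c("7_HH" = 0.06, "9_MeH" = 0.16,
                                  "5_MeMe" = 0.30, "11_EtMe" = 0.40)) {
  reference <- makeToyMacrocycle(8L)
  out <- list(reference = reference, ensembles = list(), labels = list(),
              pTrue = pValues)
  for (i in seq_along(pValues)) {
    id <- names(pValues)[i]
    spec <- EnsembleSpec(id, nFrames = nFrames, pBioactive = pValues[[i]],
                         seed = (as.integer(seed) %% 2000000L) * 1000L + i)
    gen <- makeBimodalEnsemble(spec, reference)
    out$ensembles[[id]] <- gen$ensemble
    out$labels[[id]] <- gen$labels
  }
  out
}
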