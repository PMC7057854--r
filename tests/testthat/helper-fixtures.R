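# Shared fixtures, built in code at test time.

toyRef <- makeToyMacrocycle(8L)

# minimal multi-model PDB text: nModels frames of nAtoms carbon atoms
writeTinyPdb <- function(path, nModels = 3L, nAtoms = 10L,
                         dropAtomInModel = NULL) {
  lines <- character()
  for (m in seq_len(nModels)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    na <- if (!is.null(dropAtomInModel) && m == dropAtomInModel)
      nAtoms - 1L else nAtoms
    for (i in seq_len(na)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  C%-2d LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, i * 1.5, m * 0.1, 0))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# random proper rotation matrix, seeded
randomRotation <- function(seed) {
  set.seed(seed)
  qr <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# analytic accessible area of two equal spheres of expanded radius R at
# center distance d (each loses a spherical cap of height R - d/2)
twoSphereExact <- function(r, probe, d) {
  R <- r + probe
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}
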