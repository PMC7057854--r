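## Ensemble input/output and atom classification.
##
## Multi-model PDB goes through bio3d; a preliminary line scan of
## MODEL/ENDMDL blocks produces frame-level error messages (which frame has
## a deviating atom count) that a generic parser would not give. XYZ is
## parsed directly: the format is a bare frame count + comment + element
## lines, repeated.

# Bondi van der Waals radii (Angstrom), the default radius set.
.bondiRadii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98
)

#' Default van der Waals radii (Bondi set)
#'
#' @return named numeric vector of radii in Angstrom, indexed by element
#'   symbol.
#' @export
#' @examples
#' vdwRadii()[["C"]]
vdwRadii <- function() .bondiRadii

#' Construct a ConformerEnsemble
#'
#' @param ligandId single string identifying the ligand.
#' @param atoms data.frame with columns `name`, `element`, `resid`.
#' @param frames list of `nAtoms x 3` coordinate matrices (Angstrom).
#' @param bonds optional two-column matrix of 1-based atom indices.
#' @param frameTimes optional numeric vector of frame times (ns).
#' @return a validated [ConformerEnsemble-class] object.
#' @export
ConformerEnsemble <- function(ligandId, atoms, frames, bonds = NULL,
                              frameTimes = numeric()) {
  if (is.null(bonds)) bonds <- matrix(integer(), ncol = 2)
  storage.mode(bonds) <- "integer"
  new("ConformerEnsemble", ligandId = as.character(ligandId),
      atoms = atoms, bonds = bonds,
      frames = lapply(frames, function(f) {
        f <- as.matrix(f); dimnames(f) <- NULL; f
      }),
      frameTimes = as.numeric(frameTimes))
}

#' Construct a ReferenceStructure
#'
#' @param atoms data.frame with columns `name`, `element`, `resid`.
#' @param coords `nAtoms x 3` coordinate matrix (Angstrom).
#' @param masks named list of 1-based atom-index vectors; masks select the
#'   atoms used for superposition and RMSD measurement.
#' @param bonds optional two-column matrix of 1-based atom indices.
#' @return a validated [ReferenceStructure-class] object.
#' @export
ReferenceStructure <- function(atoms, coords, masks = list(), bonds = NULL) {
  if (is.null(bonds)) bonds <- matrix(integer(), ncol = 2)
  storage.mode(bonds) <- "integer"
  coords <- as.matrix(coords); dimnames(coords) <- NULL
  new("ReferenceStructure", atoms = atoms, coords = coords,
      masks = lapply(masks, as.integer), bonds = bonds)
}

# Infer an element symbol from a PDB atom name when the element column is
# blank: strip digits/primes, prefer two-letter halogens, else first letter.
.elementFromName <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[0-9' ]", "", nm)
    if (!nzchar(s)) stop("cannot infer element from atom name '", nm, "'")
    two <- toupper(substr(s, 1, 2))
    if (two %in% c("CL", "BR")) {
      paste0(substr(two, 1, 1), tolower(substr(two, 2, 2)))
    } else {
      toupper(substr(s, 1, 1))
    }
  }, character(1), USE.NAMES = FALSE)
}

# Count ATOM/HETATM records per MODEL block, so parse errors can name the
# offending frame.
.scanPdbModels <- function(lines) {
  modelStarts <- grep("^MODEL", lines)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  if (!length(modelStarts)) return(if (any(isAtom)) sum(isAtom) else integer())
  modelEnds <- grep("^ENDMDL", lines)
  if (length(modelEnds) != length(modelStarts))
    stop("unbalanced MODEL/ENDMDL records")
  mapply(function(s, e) sum(isAtom[s:e]), modelStarts, modelEnds)
}

#' Read a conformer ensemble from file
#'
#' Reads a multi-model PDB (MODEL/ENDMDL blocks) or a multi-frame XYZ file
#' into a [ConformerEnsemble-class]. Frames keep file order; the atom order
#' must be identical across frames. Elements come from PDB columns 77-78
#' when present, otherwise from atom-name heuristics.
#'
#' @param path path to the file.
#' @param format "pdb" or "xyz"; default guesses from the file extension.
#' @param ligandId ligand identifier; default is the file base name.
#' @return a [ConformerEnsemble-class].
#' @export
#' @examples
#' ref <- makeToyMacrocycle(6)
#' ens <- makeBimodalEnsemble(EnsembleSpec("x", nFrames = 3, seed = 1), ref)
#' f <- tempfile(fileext = ".pdb")
#' writeEnsemble(ens, f)
#' nFrames(readEnsemble(f))
readEnsemble <- function(path, format = c("auto", "pdb", "xyz"),
                         ligandId = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xyz")) "xyz" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(ligandId)) ligandId <- tools::file_path_sans_ext(basename(path))
  if (format == "pdb") .readEnsemblePdb(path, ligandId) else
    .readEnsembleXyz(path, ligandId)
}

.readEnsemblePdb <- function(path, ligandId) {
  lines <- readLines(path, warn = FALSE)
  counts <- .scanPdbModels(lines)
  if (!length(counts) || all(counts == 0)) stop("no atoms found in ", path)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("MODEL %d has %d atoms, expected %d", bad, counts[bad],
                 counts[1]))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  elesy <- trimws(pdb$atom$elesy)
  element <- ifelse(nzchar(elesy) & !is.na(elesy), elesy,
                    .elementFromName(trimws(pdb$atom$elety)))
  atoms <- data.frame(name = trimws(pdb$atom$elety), element = element,
                      resid = pdb$atom$resno, stringsAsFactors = FALSE)
  nf <- nrow(pdb$xyz)
  framelist <- lapply(seq_len(nf), function(i)
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE))
  ConformerEnsemble(ligandId, atoms, framelist)
}

.readEnsembleXyz <- function(path, ligandId) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (!length(lines)) stop("empty XYZ file: ", path)
  framelist <- list(); atoms <- NULL; i <- 1L; frame <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    frame <- frame + 1L
    if (is.na(n) || n < 1L)
      stop(sprintf("XYZ frame %d: invalid atom count line", frame))
    if (i + 1L + n > length(lines))
      stop(sprintf("XYZ frame %d: truncated (%d atoms declared)", frame, n))
    body <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(tok) < 4L))
      stop(sprintf("XYZ frame %d: malformed coordinate line", frame))
    el <- vapply(tok, `[[`, character(1), 1L)
    xyz <- t(vapply(tok, function(t)
      as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz)) stop(sprintf("XYZ frame %d: non-numeric coordinates", frame))
    if (is.null(atoms)) {
      atoms <- data.frame(name = el, element = el, resid = 1L,
                          stringsAsFactors = FALSE)
    } else if (n != nrow(atoms)) {
      stop(sprintf("XYZ frame %d has %d atoms, expected %d", frame, n,
                   nrow(atoms)))
    }
    framelist[[frame]] <- xyz
    i <- i + 2L + n
  }
  ConformerEnsemble(ligandId, atoms, framelist)
}

#' Write a conformer ensemble to file
#'
#' Writes multi-model PDB (3-decimal coordinates) or multi-frame XYZ
#' (6-decimal coordinates).
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param path output path.
#' @param format "pdb" or "xyz"; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
writeEnsemble <- function(ensemble, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz") "xyz" else "pdb"
  }
  stopifnot(is(ensemble, "ConformerEnsemble"))
  if (format == "pdb") {
    xyz <- do.call(rbind, lapply(ensemble@frames, function(f) as.vector(t(f))))
    bio3d::write.pdb(
      file = path, xyz = xyz,
      resno = ensemble@atoms$resid,
      resid = rep("LIG", nAtoms(ensemble)),
      eleno = seq_len(nAtoms(ensemble)),
      elety = ensemble@atoms$name,
      elesy = ensemble@atoms$element,
      chain = rep("A", nAtoms(ensemble)))
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (f in ensemble@frames) {
      writeLines(c(as.character(nAtoms(ensemble)), ensemble@ligandId), con)
      writeLines(sprintf("%-3s %14.6f %14.6f %14.6f",
                         ensemble@atoms$element, f[, 1], f[, 2], f[, 3]), con)
    }
  }
  invisible(path)
}

#' Classify atoms as polar or nonpolar and assign vdW radii
#'
#' Default ruleset: N, O and S atoms are polar, as is any hydrogen bonded
#' to one of them; C, P and hydrogens on carbon are nonpolar. A hydrogen
#' without bond information is attached to its nearest heavy atom in the
#' first frame. Radii default to the Bondi set and can be overridden or
#' extended per element.
#'
#' @param ensemble a [ConformerEnsemble-class] (or
#'   [ReferenceStructure-class]).
#' @param polarElements elements considered intrinsically polar.
#' @param radii named vector of per-element radii (Angstrom); merged over
#'   the Bondi defaults.
#' @return an [AtomClassTable-class] parallel to the atom table.
#' @export
#' @examples
#' ref <- makeToyMacrocycle(6)
#' ens <- makeBimodalEnsemble(EnsembleSpec("x", nFrames = 1, seed = 1), ref)
#' table(assignAtomClasses(ens)@atomClass)
assignAtomClasses <- function(ensemble, polarElements = c("N", "O", "S"),
                              radii = NULL) {
  atoms <- atomData(ensemble)
  allRadii <- .bondiRadii
  if (!is.null(radii)) allRadii[names(radii)] <- radii
  el <- atoms$element
  unknown <- setdiff(unique(el), names(allRadii))
  if (length(unknown)) {
    bad <- which(el %in% unknown)
    stop("no vdW radius for element(s) ", paste(unknown, collapse = ", "),
         " (atom ", paste(head(bad, 5), collapse = ", "),
         "); supply one via `radii`")
  }
  cls <- ifelse(el %in% polarElements, "polar", "nonpolar")
  isH <- el == "H"
  if (any(isH)) {
    bonds <- if (is(ensemble, "ConformerEnsemble")) ensemble@bonds else
      ensemble@bonds
    coords <- if (is(ensemble, "ConformerEnsemble")) ensemble@frames[[1]] else
      ensemble@coords
    for (i in which(isH)) {
      nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
      if (!length(nb)) {
        heavy <- which(!isH)
        if (!length(heavy)) next
        d2 <- rowSums(sweep(coords[heavy, , drop = FALSE], 2,
                            coords[i, ])^2)
        nb <- heavy[which.min(d2)]
      }
      cls[i] <- if (any(el[nb] %in% polarElements)) "polar" else "nonpolar"
    }
  }
  new("AtomClassTable", atomClass = cls, radius = unname(allRadii[el]))
}

#' Split an ensemble into contiguous blocks
#'
#' Partitions the frame sequence into `nBlocks` contiguous,
#' order-preserving blocks whose sizes differ by at most one (earlier
#' blocks take the extra frame). Block averaging over such partitions is
#' the standard way to attach statistical uncertainties to trajectory
#' averages.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param nBlocks number of blocks, between 1 and `nFrames(ensemble)`.
#' @return list of [ConformerEnsemble-class] objects.
#' @export
#' @examples
#' ref <- makeToyMacrocycle(6)
#' ens <- makeBimodalEnsemble(EnsembleSpec("x", nFrames = 7, seed = 1), ref)
#' sapply(sliceBlocks(ens, 3), nFrames)  # 3 2 2
sliceBlocks <- function(ensemble, nBlocks) {
  nf <- nFrames(ensemble)
  nBlocks <- as.integer(nBlocks)
  if (nBlocks < 1L) stop("nBlocks must be >= 1")
  if (nBlocks > nf)
    stop("nBlocks (", nBlocks, ") exceeds the number of frames (", nf, ")")
  sizes <- rep(nf %/% nBlocks, nBlocks) +
    c(rep(1L, nf %% nBlocks), rep(0L, nBlocks - nf %% nBlocks))
  ends <- cumsum(sizes); starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(nBlocks), function(b) {
    ix <- starts[b]:ends[b]
    ConformerEnsemble(
      ensemble@ligandId, ensemble@atoms, ensemble@frames[ix],
      bonds = ensemble@bonds,
      frameTimes = if (length(ensemble@frameTimes))
        ensemble@frameTimes[ix] else numeric())
  })
}

# Split a plain vector into the same contiguous blocks sliceBlocks uses.
.blockIndices <- function(n, nBlocks) {
  sizes <- rep(n %/% nBlocks, nBlocks) +
    c(rep(1L, n %% nBlocks), rep(0L, nBlocks - n %% nBlocks))
  ends <- cumsum(sizes); starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(nBlocks), function(b) starts[b]:ends[b])
}
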