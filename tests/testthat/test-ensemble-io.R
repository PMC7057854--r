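test_that("multi-model PDB files read into ensembles with file structure intact", {
  f <- writeTinyPdb(tempfile(fileext = ".pdb"), nModels = 3, nAtoms = 10)
  ens <- readEnsemble(f)
  expect_s4_class(ens, "ConformerEnsemble")
  expect_equal(nFrames(ens), 3)
  expect_equal(nAtoms(ens), 10)
  expect_true(all(atomData(ens)$element == "C"))
  # frames keep file order: x of atom 1 is constant, y encodes the model
  expect_equal(sapply(frames(ens), function(fr) fr[1, 2]),
               c(0.1, 0.2, 0.3))
})

test_that("single-frame XYZ files read correctly", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("5", "comment",
               sprintf("%s %.3f %.3f %.3f", c("C", "N", "O", "C", "H"),
                       1:5, 0, 0)), f)
  ens <- readEnsemble(f)
  expect_equal(nFrames(ens), 1)
  expect_equal(nAtoms(ens), 5)
  expect_equal(atomData(ens)$element, c("C", "N", "O", "C", "H"))
  expect_equal(frames(ens)[[1]][, 1], as.numeric(1:5))
})

test_that("a frame with a deviating atom count is an error naming the frame", {
  f <- writeTinyPdb(tempfile(fileext = ".pdb"), nModels = 3, nAtoms = 10,
                    dropAtomInModel = 2)
  expect_error(readEnsemble(f), "MODEL 2")
  f2 <- tempfile(fileext = ".pdb")
  writeLines("END", f2)
  expect_error(readEnsemble(f2), "no atoms")
  f3 <- tempfile(fileext = ".xyz")
  writeLines(c("3", "c", "C 0 0 0", "C 1 0 0", "C 2 0 0",
               "3", "c", "C 0 0 0", "C 1 0 0"), f3)
  expect_error(readEnsemble(f3), "frame 2")
})

test_that("write/read round-trips preserve coordinates to printed precision", {
  gen <- makeBimodalEnsemble(EnsembleSpec("rt", nFrames = 4, seed = 5), toyRef)
  ens <- gen$ensemble
  fp <- tempfile(fileext = ".pdb")
  writeEnsemble(ens, fp)
  back <- readEnsemble(fp)
  expect_equal(nFrames(back), nFrames(ens))
  for (i in seq_len(nFrames(ens)))
    expect_lt(max(abs(frames(back)[[i]] - frames(ens)[[i]])), 5.01e-4)
  expect_equal(atomData(back)$element, atomData(ens)$element)
  fx <- tempfile(fileext = ".xyz")
  writeEnsemble(ens, fx)
  backx <- readEnsemble(fx)
  for (i in seq_len(nFrames(ens)))
    expect_lt(max(abs(frames(backx)[[i]] - frames(ens)[[i]])), 1e-6)
})

test_that("sliceBlocks partitions contiguously with near-equal sizes", {
  mk <- function(n) ConformerEnsemble(
    "b", data.frame(name = "C", element = "C", resid = 1L),
    lapply(seq_len(n), function(i) matrix(c(i, 0, 0), 1, 3)))
  expect_equal(sapply(sliceBlocks(mk(2500), 5), nFrames), rep(500L, 5))
  expect_equal(sapply(sliceBlocks(mk(7), 3), nFrames), c(3L, 2L, 2L))
  one <- sliceBlocks(mk(10), 1)
  expect_length(one, 1)
  expect_equal(nFrames(one[[1]]), 10)
  # concatenating the blocks restores the original frame sequence
  blocks <- sliceBlocks(mk(11), 4)
  xs <- unlist(lapply(blocks, function(b)
    sapply(frames(b), function(f) f[1, 1])))
  expect_identical(xs, as.numeric(1:11))
  expect_error(sliceBlocks(mk(3), 4), "exceeds")
  expect_error(sliceBlocks(mk(3), 0), ">= 1")
})

test_that("atom classification follows the N/O/S + attached-H rule", {
  atoms <- data.frame(name = c("N", "CA", "C", "O", "H", "HA"),
                      element = c("N", "C", "C", "O", "H", "H"),
                      resid = 1L)
  co <- matrix(c(0, 0, 0,  1.5, 0, 0,  3, 0, 0,  3.5, 1, 0,
                 -1, 0, 0,  1.5, 1.1, 0), 6, 3, byrow = TRUE)
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(5, 1), c(6, 2))
  ens <- ConformerEnsemble("cls", atoms, list(co), bonds = bonds)
  ct <- assignAtomClasses(ens)
  expect_equal(ct@atomClass,
               c("polar", "nonpolar", "nonpolar", "polar",
                 "polar", "nonpolar"))  # H on N polar, H on CA nonpolar
  expect_equal(ct@radius[1], vdwRadii()[["N"]])
  # hydrogens without bond records fall back to the nearest heavy atom
  ens2 <- ConformerEnsemble("cls2", atoms, list(co))
  expect_equal(assignAtomClasses(ens2)@atomClass[5], "polar")
})

test_that("unknown elements without a radius are an error; overrides work", {
  atoms <- data.frame(name = c("C", "XX"), element = c("C", "Xx"),
                      resid = 1L)
  ens <- ConformerEnsemble("u", atoms,
                           list(matrix(c(0, 0, 0, 5, 0, 0), 2, 3,
                                       byrow = TRUE)))
  expect_error(assignAtomClasses(ens), "Xx")
  ct <- assignAtomClasses(ens, radii = c(Xx = 2.0))
  expect_equal(ct@radius[2], 2.0)
  # per-element radius override replaces the Bondi default
  ct2 <- assignAtomClasses(ens, radii = c(C = 1.9, Xx = 2.0))
  expect_equal(ct2@radius[1], 1.9)
})

test_that("ensemble validity rejects malformed objects", {
  atoms <- data.frame(name = "C", element = "C", resid = 1L)
  expect_error(ConformerEnsemble("x", atoms, list()), "at least 1 frame")
  expect_error(ConformerEnsemble("x", atoms, list(matrix(0, 2, 3))),
               "coordinates")
  expect_error(ConformerEnsemble("x", atoms, list(matrix(0, 1, 3)),
                                 bonds = rbind(c(1, 1))), "self-bonds")
  expect_error(ReferenceStructure(atoms, matrix(0, 1, 3),
                                  masks = list(bad = 2L)), "outside")
})
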