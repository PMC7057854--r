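test_that("isolated and non-overlapping spheres give exact areas", {
  # isolated sphere: accessible fraction is 1 at any lattice size
  expect_equal(shrakeRupley(matrix(0, 1, 3), 1.6, 1.4, 96),
               4 * pi * 3.0^2, tolerance = 1e-9)
  far <- shrakeRupley(rbind(c(0, 0, 0), c(100, 0, 0)), c(1.6, 1.2), 1.4, 96)
  expect_equal(far, 4 * pi * c(3.0^2, 2.6^2), tolerance = 1e-9)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  co <- rbind(c(0, 0, 0), c(3, 0, 0))
  exact <- twoSphereExact(1.7, 1.4, 3)
  got960 <- sum(shrakeRupley(co, 1.7, 1.4, 960))
  expect_lt(abs(got960 - exact) / exact, 0.02)
  got10k <- sum(shrakeRupley(co, 1.7, 1.4, 10000))
  expect_lt(abs(got10k - exact) / exact, 0.005)
  # deterministic lattice: error shrinks monotonically over the ladder
  errs <- sapply(c(96, 960, 9600), function(np)
    abs(sum(shrakeRupley(co, 1.7, 1.4, np)) - exact) / exact)
  expect_true(all(diff(errs) < 0))
})

test_that("occlusion only ever removes area and distant atoms change nothing", {
  set.seed(55)
  co <- matrix(runif(30, 0, 6), 10, 3)
  base <- shrakeRupley(co, 1.7)
  # appending a far-away atom leaves every existing atom untouched
  plus <- shrakeRupley(rbind(co, c(500, 0, 0)), c(rep(1.7, 10), 1.7))
  expect_equal(plus[1:10], base, tolerance = 1e-9)
  # appending any overlapping atom never increases another atom's SASA
  for (s in 1:5) {
    set.seed(60 + s)
    extra <- co[sample(10, 1), ] + rnorm(3, sd = 1)
    withx <- shrakeRupley(rbind(co, extra), rep(1.7, 11))
    expect_true(all(withx[1:10] <= base + 1e-9))
  }
})

test_that("SASA agrees with an independent reference implementation", {
  # expected totals computed with the Shrake-Rupley implementation in the
  # biotite structure library (probe 1.4 A, 5000 points per atom) on the
  # same seeded fixtures
  referenceTotals <- c(530.5814, 648.8408, 616.5997, 670.6981, 632.6477,
                       681.1360, 627.9101, 583.9346, 582.3330, 718.2272)
  radset <- c(1.2, 1.52, 1.55, 1.7, 1.8)
  for (k in 1:10) {
    set.seed(2000 + k)
    co <- matrix(runif(60, 0, 8), 20, 3)
    got <- sum(shrakeRupley(co, rep(radset, length.out = 20), 1.4, 960))
    expect_lt(abs(got - referenceTotals[k]) / referenceTotals[k], 0.02)
  }
})

test_that("partitioning conserves the total and respects classes", {
  ct <- function(cls) new("AtomClassTable", atomClass = cls,
                          radius = rep(1.7, length(cls)))
  sa <- c(10, 20, 30)
  expect_equal(partitionSasa(sa, ct(rep("polar", 3)))[["npsa"]], 0)
  expect_equal(partitionSasa(sa, ct(rep("nonpolar", 3)))[["psa"]], 0)
  mixed <- partitionSasa(sa, ct(c("polar", "nonpolar", "polar")))
  expect_equal(unname(sum(mixed)), sum(sa))
  expect_equal(mixed[["psa"]], 40)
  expect_error(partitionSasa(c(1, 2), ct(rep("polar", 3))), "lengths")
})

test_that("ensemble surfaces average per-frame partitions", {
  gen <- makeBimodalEnsemble(EnsembleSpec("s", nFrames = 3, seed = 13), toyRef)
  ens <- gen$ensemble
  # identical frames: zero sigma, mean equals the single-frame value
  same <- ConformerEnsemble("same", ens@atoms,
                            replicate(4, frames(ens)[[1]],
                                      simplify = FALSE))
  ss <- ensembleSurface(same, nPoints = 240)
  expect_equal(ss@sigmaPsa, 0, tolerance = 1e-9)
  cls <- assignAtomClasses(same)
  single <- partitionSasa(shrakeRupley(frames(ens)[[1]], cls@radius,
                                       1.4, 240), cls)
  expect_equal(ss@meanPsa, single[["psa"]], tolerance = 1e-9)
  expect_true(all(abs(ss@perFrame$total - ss@perFrame$psa -
                        ss@perFrame$npsa) < 1e-6))
  # two frames: mean is the midpoint
  two <- ConformerEnsemble("two", ens@atoms, frames(ens)[1:2])
  st <- ensembleSurface(two, nPoints = 240)
  expect_equal(st@meanPsa, mean(st@perFrame$psa))
})

test_that("mixing compact and extended conformers brackets the mean SASA", {
  atoms <- data.frame(name = rep("C", 6), element = "C", resid = 1L)
  compact <- cbind(seq(0, 5 * 1.5, by = 1.5), 0, 0)     # tight chain
  extended <- cbind(seq(0, 5 * 4.0, by = 4.0), 0, 0)    # stretched chain
  mixEns <- ConformerEnsemble("mix", atoms,
                              list(compact, compact, extended, extended))
  cls <- assignAtomClasses(mixEns)
  tot <- function(co) sum(shrakeRupley(co, cls@radius, 1.4, 240))
  mixed <- ensembleSurface(mixEns, nPoints = 240)
  meanTotal <- mean(mixed@perFrame$total)
  expect_gt(meanTotal, tot(compact))
  expect_lt(meanTotal, tot(extended))
})

test_that("degenerate and invalid SASA inputs are handled", {
  # coincident equal-radius atoms: strict-inequality exclusion keeps the
  # shared surface for both atoms
  co <- rbind(c(0, 0, 0), c(0, 0, 0))
  sa <- shrakeRupley(co, 1.7, 1.4, 960)
  expect_equal(sa[1], sa[2])
  expect_equal(sum(sa), 2 * 4 * pi * 3.1^2, tolerance = 1e-9)
  expect_error(shrakeRupley(matrix(0, 1, 3), -1), "positive")
  expect_error(shrakeRupley(matrix(0, 2, 3), c(1, 1, 1)), "one radius")
})
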