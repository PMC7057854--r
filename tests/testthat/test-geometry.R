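# brute-force quaternion oracle: minimal RMSD over rotations found by
# multi-start Nelder-Mead on quaternion parameters (centers aligned first)
quaternionOracle <- function(mobile, reference, nStarts = 40) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  rotFromQ <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) sqrt(mean(rowSums((A %*% t(rotFromQ(q)) - B)^2)))
  best <- Inf
  set.seed(99)
  for (s in seq_len(nStarts)) {
    q0 <- rnorm(4)
    fit <- optim(q0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}

test_that("superposition removes rigid-body motion exactly", {
  set.seed(4)
  ref <- matrix(rnorm(30), 10, 3)
  out <- kabschSuperpose(ref, ref)
  expect_equal(out$rmsd, 0, tolerance = 1e-12)
  expect_equal(out$rotation, diag(3), tolerance = 1e-8)
  shifted <- ref + matrix(c(5, 0, 0), 10, 3, byrow = TRUE)
  expect_lt(kabschSuperpose(shifted, ref)$rmsd, 1e-12)
  expect_equal(det(kabschSuperpose(shifted, ref)$rotation), 1,
               tolerance = 1e-10)
})

test_that("superposition errors on degenerate selections", {
  ref <- matrix(rnorm(12), 4, 3)
  expect_error(kabschSuperpose(ref, ref, selection = 1:2), "at least 3")
  line <- cbind(1:4, 0, 0)
  expect_error(kabschSuperpose(line, line), "collinear")
})

test_that("Kabsch RMSD matches an exhaustive quaternion-search oracle", {
  # tetrahedron rotated 90 degrees about z with one vertex displaced 0.5 A
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  mob <- tet %*% t(Rz)
  mob[1, ] <- mob[1, ] + c(0.5, 0, 0)
  got <- kabschSuperpose(mob, tet)$rmsd
  expect_equal(got, quaternionOracle(mob, tet), tolerance = 1e-4)
})

test_that("RMSD is invariant under rigid-body transforms of the mobile set", {
  for (s in 1:20) {
    set.seed(300 + s)
    ref <- matrix(rnorm(45), 15, 3)
    mob <- ref + matrix(rnorm(45, sd = 0.4), 15, 3)
    base <- kabschSuperpose(mob, ref)$rmsd
    R <- randomRotation(500 + s)
    moved <- mob %*% R + matrix(rnorm(3), 15, 3, byrow = TRUE)
    expect_equal(kabschSuperpose(moved, ref)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("rmsdSeries equals per-frame superposition and handles closed forms", {
  gen <- makeBimodalEnsemble(EnsembleSpec("g", nFrames = 10, seed = 2), toyRef)
  rs <- rmsdSeries(gen$ensemble, toyRef)
  expect_length(rmsdValues(rs), 10)
  manual <- vapply(frames(gen$ensemble), function(f)
    kabschSuperpose(f, toyRef@coords,
                    masks(toyRef)$backbone)$rmsd, numeric(1))
  expect_equal(rmsdValues(rs), manual, tolerance = 1e-12)

  # ensemble of N copies of the reference: all-zero series
  copies <- ConformerEnsemble("c", toyRef@atoms,
                              replicate(4, toyRef@coords, simplify = FALSE))
  expect_equal(rmsdValues(rmsdSeries(copies, toyRef)), rep(0, 4),
               tolerance = 1e-10)

  # one measured atom moved 1 A, fit mask untouched -> RMSD = 1/sqrt(k)
  co <- toyRef@coords
  cx <- masks(toyRef)$crosslink
  co[cx[1], ] <- co[cx[1], ] + c(0, 0, 1)
  one <- ConformerEnsemble("m", toyRef@atoms, list(co))
  rs1 <- rmsdSeries(one, toyRef, fitSelection = "backbone",
                    measureSelection = "crosslink")
  expect_equal(rmsdValues(rs1), 1 / sqrt(length(cx)), tolerance = 1e-10)

  expect_error(rmsdSeries(gen$ensemble, toyRef, fitSelection = "nope"),
               "mask")
})

test_that("dihedral angles follow the standard sign convention", {
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, -1, 0)), 180)
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 1, 0)), 0)
  expect_equal(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                             c(1, 1, 1)), 90)
  # independent oracle: direct atan2 triple-product formula
  oracle <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    atan2(sqrt(sum(b2^2)) * sum(b1 * cr(b2, b3)),
          sum(cr(b1, b2) * cr(b2, b3))) * 180 / pi
  }
  set.seed(7)
  for (i in 1:25) {
    p <- lapply(1:4, function(.) rnorm(3))
    got <- dihedralAngle(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(got, oracle(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-10)
    # torsion is invariant under atom-order reversal ...
    expect_equal(dihedralAngle(p[[4]], p[[3]], p[[2]], p[[1]]), got,
                 tolerance = 1e-10)
    # ... and antisymmetric under mirror reflection
    m <- lapply(p, function(v) v * c(1, 1, -1))
    expect_equal(dihedralAngle(m[[1]], m[[2]], m[[3]], m[[4]]), -got,
                 tolerance = 1e-10)
  }
  expect_error(dihedralAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 1, 0)), "degenerate")
})

test_that("torsion profiles stay in (-180, 180] and histogram the frames", {
  gen <- makeBimodalEnsemble(EnsembleSpec("t", nFrames = 30, seed = 8), toyRef)
  tp <- torsionProfile(gen$ensemble, c(1, 2, 3, 5))
  expect_length(tp$angles, 30)
  expect_true(all(tp$angles > -180 & tp$angles <= 180))
  expect_equal(sum(tp$histogram$count), 30)
})
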