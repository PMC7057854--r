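test_that("leg combination is the thermodynamic-cycle difference", {
  expect_equal(combineLegs(5.0, 3.0), 2.0)
  expect_equal(combineLegs(1.7, 1.7), 0)
  expect_equal(combineLegs(-1.2, -0.8), -combineLegs(1.2, 0.8))
  expect_error(combineLegs(1, NA), "missing leg")
  expect_error(combineLegs(c(1, 2), 1), "one-to-one")
})

test_that("hysteresis is the forward+backward sum, zero when converged", {
  expect_equal(edgeHysteresis(1.2, -1.2), 0)
  expect_equal(edgeHysteresis(1.2, -1.0), 0.2)
  expect_equal(edgeHysteresis(-1.2, 1.0, convention = "absdiff"), 0.2)
  expect_true(is.na(edgeHysteresis(1.2, NA)))
})

test_that("cycle closure sums signed ddG around basis cycles", {
  net0 <- fepNetwork(data.frame(from = c("A", "B", "C"),
                                to = c("B", "C", "A"),
                                ddG = c(1.0, -0.4, -0.6)), reference = "A")
  cc0 <- cycleClosure(net0)
  expect_equal(nrow(cc0$cycles), 1)
  expect_equal(cc0$cycles$closure, 0, tolerance = 1e-12)
  expect_equal(cc0$cycles$length, 3)
  net1 <- fepNetwork(data.frame(from = c("A", "B", "C"),
                                to = c("B", "C", "A"),
                                ddG = c(1.0, -0.4, -0.5)), reference = "A")
  expect_equal(abs(cycleClosure(net1)$cycles$closure), 0.1,
               tolerance = 1e-12)
  expect_equal(cycleClosure(net1)$rms, 0.1, tolerance = 1e-12)
  # acyclic network: empty result, not an error
  tree <- fepNetwork(data.frame(from = c("A", "B"), to = c("B", "C"),
                                ddG = c(1, 2)), reference = "A")
  expect_equal(nrow(cycleClosure(tree)$cycles), 0)
})

test_that("networks from additive node values close exactly without noise", {
  nodes <- c(A = 0, B = 1.2, C = -0.7, D = 2.5)
  edges <- data.frame(from = c("A", "B", "C", "A", "B"),
                      to = c("B", "C", "D", "C", "D"))
  tab <- makeFepNetwork(NetworkSpec(nodes, edges, noiseSigma = 0, seed = 3))
  expect_equal(edgeHysteresis(tab$ddG_kcal_mol, tab$ddG_reverse_kcal_mol),
               rep(0, nrow(tab)), tolerance = 1e-12)
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  nets <- readFepEdges(f, reference = "A")
  cc <- cycleClosure(nets[[1]])
  expect_true(all(abs(cc$cycles$closure) < 1e-12))
  # node recovery is exact: binding edges are consistent
  est <- relativeDpkd(nets[[1]])
  expect_equal(setNames(est$ddG, est$ligand)[names(nodes)],
               nodes, tolerance = 1e-10)
})

test_that("a two-node network converts its single edge through ln(10)RT", {
  net <- fepNetwork(data.frame(from = "REF", to = "X", ddG = 1.3642),
                    reference = "REF")
  est <- relativeDpkd(net, temperature = 298.15)
  expect_equal(est$dpkd[est$ligand == "X"], -1.0000, tolerance = 1e-4)
  expect_equal(est$dpkd[est$ligand == "X"], ddgToDpkd(1.3642))
  expect_equal(est$dpkd[est$ligand == "REF"], 0)
})

test_that("node estimates are invariant under edge reversal and re-rooting", {
  set.seed(15)
  nodes <- c(R = 0, B = 0.8, C = -1.1, D = 0.4)
  edges <- data.frame(from = c("R", "B", "C", "R"),
                      to = c("B", "C", "D", "C"))
  tab <- makeFepNetwork(NetworkSpec(nodes, edges, noiseSigma = 0.3, seed = 21))
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  net <- readFepEdges(f, reference = "R")[[1]]
  base <- relativeDpkd(net)
  flipped <- net@edges
  flipped[, c("from", "to")] <- flipped[, c("to", "from")]
  flipped$ddG <- -flipped$ddG
  netF <- fepNetwork(flipped, reference = "R")
  got <- relativeDpkd(netF)
  expect_equal(setNames(got$ddG, got$ligand)[base$ligand],
               setNames(base$ddG, base$ligand)[base$ligand],
               tolerance = 1e-10)
})

test_that("nodes disconnected from the reference are dropped with a warning", {
  net <- fepNetwork(data.frame(from = c("A", "X"), to = c("B", "Y"),
                               ddG = c(1, 2)), reference = "A",
                    nodes = c("A", "B", "X", "Y"))
  expect_warning(est <- relativeDpkd(net), "not connected")
  expect_setequal(est$ligand, c("A", "B"))
})

test_that("restraint sensitivity flags ligands with level-dependent estimates", {
  t1 <- data.frame(ligand = c("a", "b", "c"), dpkd = c(0.1, 1.0, -0.5))
  rs0 <- restraintSensitivity(list(t1, t1, t1))
  expect_equal(rs0$spread, rep(0, 3))
  expect_false(any(rs0$flagged))
  t2 <- t1; t2$dpkd[2] <- 1.5
  rs <- restraintSensitivity(list(soft = t1, medium = t2, hard = t1))
  expect_equal(rs$spread[rs$ligand == "b"], 0.5)
  expect_false(rs$flagged[rs$ligand == "b"])  # threshold is exclusive
  rs2 <- restraintSensitivity(list(t1, t2), flagThreshold = 0.4)
  expect_true(rs2$flagged[rs2$ligand == "b"])
  expect_error(restraintSensitivity(list(t1)), "at least 2")
})

test_that("mean spread grows with per-level jitter", {
  meanSpread <- function(sigma) {
    sp <- numeric(50)
    for (s in 1:50) {
      set.seed(1000 + s)
      tabs <- lapply(1:3, function(l)
        data.frame(ligand = letters[1:5],
                   dpkd = 1:5 / 2 + rnorm(5, sd = sigma)))
      sp[s] <- mean(restraintSensitivity(tabs)$spread)
    }
    mean(sp)
  }
  spreads <- sapply(c(0.05, 0.2, 0.8), meanSpread)
  expect_true(all(diff(spreads) > 0))
})

test_that("edge tables round-trip through files and export to GraphML", {
  nodes <- c(A = 0, B = 1)
  tab <- makeFepNetwork(NetworkSpec(nodes, data.frame(from = "A", to = "B"),
                                    noiseSigma = 0, seed = 1),
                        forceConstant = 10)
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  nets <- readFepEdges(f, reference = "A")
  expect_named(nets, "10")
  expect_equal(nets[["10"]]@edges$ddG, 1, tolerance = 1e-12)
  g <- tempfile(fileext = ".graphml")
  writeGraphML(nets[["10"]], g)
  expect_true(file.exists(g) && file.size(g) > 0)
  # a missing solvent leg is an error naming the pair
  bad <- tab[tab$leg == "complex", ]
  fb <- tempfile(fileext = ".tsv")
  write.table(bad, fb, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readFepEdges(fb, reference = "A"), "solvent")
})
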