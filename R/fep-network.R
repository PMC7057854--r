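## Relative-FEP network bookkeeping: leg combination, hysteresis, cycle
## closure, least-squares node free energies, restraint sensitivity.

#' Construct a FepNetwork
#'
#' @param edges data.frame with columns `from`, `to`, `ddG` (binding
#'   free energy differences, kcal/mol, complex minus solvent leg) and
#'   optionally `forceConstant`.
#' @param reference ligand id anchoring relative estimates at 0.
#' @param nodes optional explicit node set; defaults to all ids on edges
#'   plus the reference.
#' @return a [FepNetwork-class].
#' @export
fepNetwork <- function(edges, reference, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (is.null(nodes))
    nodes <- unique(c(reference, edges$from, edges$to))
  new("FepNetwork", nodes = as.character(nodes), edges = edges,
      reference = as.character(reference))
}

#' Combine complex and solvent FEP legs into a binding ddG
#'
#' `ddG_bind = ddG_complex - ddG_solvent` for the same alchemical
#' transformation: the standard thermodynamic-cycle combination of the
#' two simulation legs.
#'
#' @param complexDdg,solventDdg leg free energy differences (kcal/mol).
#' @return binding ddG (kcal/mol).
#' @export
#' @examples
#' combineLegs(5, 3)  # 2
combineLegs <- function(complexDdg, solventDdg) {
  if (length(complexDdg) != length(solventDdg))
    stop("complex and solvent legs must pair up one-to-one")
  if (anyNA(complexDdg) || anyNA(solventDdg))
    stop("missing leg value: both legs are required for each edge")
  complexDdg - solventDdg
}

#' Read FEP edge tables and assemble binding networks
#'
#' Reads a TSV/CSV with columns `ligand_from`, `ligand_to`, `leg`
#' ("complex"/"solvent"), `ddG_kcal_mol`, optional
#' `ddG_reverse_kcal_mol` and `force_constant`, pairs the two legs of
#' each transformation (per restraint level) via [combineLegs()], and
#' returns one [FepNetwork-class] per restraint level.
#'
#' @param path path to the edge table.
#' @param reference reference ligand id.
#' @param sep field separator (default tab).
#' @return named list of [FepNetwork-class], one per force-constant
#'   level (name = the level, "NA" when absent).
#' @export
readFepEdges <- function(path, reference, sep = "\t") {
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  assembleFepNetworks(tab, reference)
}

#' Assemble binding networks from an in-memory two-leg edge table
#'
#' Same pairing as [readFepEdges()], starting from a data.frame (e.g.
#' the output of [makeFepNetwork()]).
#'
#' @param tab data.frame in the edge-table layout of [readFepEdges()].
#' @param reference reference ligand id.
#' @return named list of [FepNetwork-class], one per force-constant
#'   level.
#' @export
assembleFepNetworks <- function(tab, reference) {
  need <- c("ligand_from", "ligand_to", "leg", "ddG_kcal_mol")
  if (!all(need %in% names(tab)))
    stop("edge table needs columns ", paste(need, collapse = ", "))
  if (!"force_constant" %in% names(tab)) tab$force_constant <- NA
  nets <- list()
  for (fc in unique(tab$force_constant)) {
    sub <- tab[if (is.na(fc)) is.na(tab$force_constant) else
      !is.na(tab$force_constant) & tab$force_constant == fc, ]
    pairKey <- paste(sub$ligand_from, sub$ligand_to)
    edges <- do.call(rbind, lapply(unique(pairKey), function(k) {
      rows <- sub[pairKey == k, ]
      cpx <- rows$ddG_kcal_mol[rows$leg == "complex"]
      slv <- rows$ddG_kcal_mol[rows$leg == "solvent"]
      if (length(cpx) != 1L || length(slv) != 1L)
        stop("edge ", k, " (force constant ", fc,
             "): need exactly one complex and one solvent leg")
      data.frame(from = rows$ligand_from[1], to = rows$ligand_to[1],
                 ddG = combineLegs(cpx, slv), forceConstant = fc,
                 stringsAsFactors = FALSE)
    }))
    nets[[as.character(fc)]] <- fepNetwork(edges, reference)
  }
  nets
}

#' Forward/backward hysteresis of FEP edges
#'
#' For a transformation run both forward and backward, the sum
#' `ddG_forward + ddG_reverse` is 0 for perfectly converged estimates;
#' its magnitude diagnoses non-convergence. The alternative
#' `"absdiff"` convention reports `|ddG_forward - (-ddG_reverse)|`,
#' which is the same number in absolute value.
#'
#' @param ddG forward free energy differences (kcal/mol).
#' @param ddGReverse backward differences (kcal/mol); `NA` entries give
#'   `NA` hysteresis.
#' @param convention "sum" (default, signed) or "absdiff".
#' @return hysteresis per edge (kcal/mol).
#' @export
#' @examples
#' edgeHysteresis(1.2, -1.0)  # 0.2
edgeHysteresis <- function(ddG, ddGReverse, convention = c("sum", "absdiff")) {
  convention <- match.arg(convention)
  h <- ddG + ddGReverse
  if (convention == "absdiff") abs(h) else h
}

.asIgraph <- function(network) {
  igraph::graph_from_data_frame(
    network@edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = network@nodes))
}

#' Cycle-closure errors of a FEP network
#'
#' Finds a cycle basis of the undirected network (the chords of a
#' spanning tree) and reports the signed sum of binding ddG values
#' around each basis cycle. Consistent, converged networks close to 0;
#' the RMS over cycles summarizes the network.
#'
#' @param network a [FepNetwork-class].
#' @return list with `cycles` (data.frame: one row per basis cycle,
#'   columns `length` and `closure` in kcal/mol; zero rows when the
#'   network is acyclic) and `rms`.
#' @export
cycleClosure <- function(network) {
  edges <- network@edges
  ne <- nrow(edges)
  empty <- data.frame(length = integer(), closure = numeric())
  if (ne == 0L) return(list(cycles = empty, rms = NA_real_))
  # BFS spanning forest with node potentials: pot[to] - pot[from] = ddG
  # along tree edges. For every chord, the basis-cycle closure is
  # ddG_chord - (pot[to] - pot[from]); cycle length = chord + tree path.
  nodes <- network@nodes
  pot <- setNames(rep(NA_real_, length(nodes)), nodes)
  depth <- setNames(rep(NA_integer_, length(nodes)), nodes)
  parent <- setNames(rep(NA_character_, length(nodes)), nodes)
  inTree <- rep(FALSE, ne)
  for (root in nodes) {
    if (!is.na(pot[root])) next
    pot[root] <- 0; depth[root] <- 0L
    queue <- root
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      touching <- which((edges$from == u | edges$to == u) & !inTree)
      for (i in touching) {
        v <- if (edges$from[i] == u) edges$to[i] else edges$from[i]
        if (!is.na(pot[v])) next
        inTree[i] <- TRUE
        pot[v] <- pot[u] + if (edges$from[i] == u) edges$ddG[i] else
          -edges$ddG[i]
        depth[v] <- depth[u] + 1L
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  chords <- which(!inTree)
  if (!length(chords)) return(list(cycles = empty, rms = NA_real_))
  treePathLen <- function(a, b) {
    da <- depth[a]; db <- depth[b]; len <- 0L
    while (da > db) { a <- parent[a]; da <- da - 1L; len <- len + 1L }
    while (db > da) { b <- parent[b]; db <- db - 1L; len <- len + 1L }
    while (a != b) { a <- parent[a]; b <- parent[b]; len <- len + 2L }
    len
  }
  cyc <- data.frame(
    length = vapply(chords, function(i)
      treePathLen(edges$from[i], edges$to[i]) + 1L, integer(1)),
    closure = vapply(chords, function(i)
      edges$ddG[i] - (pot[edges$to[i]] - pot[edges$from[i]]), numeric(1)))
  list(cycles = cyc, rms = sqrt(mean(cyc$closure^2)))
}

#' Relative pKd of every ligand versus the reference
#'
#' Solves for per-node binding free energies by ordinary least squares
#' over all binding edges (`ddG_edge ~ g_to - g_from`), with the
#' reference node pinned at 0, then converts to pKd differences via
#' [ddgToDpkd()]. On a tree this reduces to exact path sums; on
#' redundant networks the least-squares estimate averages over paths
#' (and has lower variance than any single path).
#'
#' @param network a [FepNetwork-class]; must be connected from the
#'   reference. Nodes not connected to the reference are dropped with a
#'   warning.
#' @param temperature K (default 298.15).
#' @return data.frame with columns `ligand`, `ddG` (kcal/mol vs.
#'   reference) and `dpkd` (pKd units vs. reference, positive = tighter
#'   binder), including the reference row at 0.
#' @export
relativeDpkd <- function(network, temperature = 298.15) {
  g <- .asIgraph(network)
  comp <- igraph::components(g)
  refComp <- comp$membership[[network@reference]]
  keep <- names(comp$membership)[comp$membership == refComp]
  dropped <- setdiff(network@nodes, keep)
  if (length(dropped))
    warning("dropping node(s) not connected to the reference: ",
            paste(dropped, collapse = ", "))
  edges <- network@edges[network@edges$from %in% keep &
                           network@edges$to %in% keep, ]
  free <- setdiff(keep, network@reference)
  gvals <- setNames(numeric(length(keep)), keep)
  if (length(free)) {
    X <- matrix(0, nrow(edges), length(free),
                dimnames = list(NULL, free))
    for (i in seq_len(nrow(edges))) {
      if (edges$to[i] %in% free) X[i, edges$to[i]] <- 1
      if (edges$from[i] %in% free) X[i, edges$from[i]] <- -1
    }
    fit <- lsfit(X, edges$ddG, intercept = FALSE)
    gvals[free] <- fit$coefficients
  }
  data.frame(ligand = keep, ddG = unname(gvals[keep]),
             dpkd = ddgToDpkd(unname(gvals[keep]), temperature),
             stringsAsFactors = FALSE)
}

#' Sensitivity of relative pKd estimates to the restraint level
#'
#' Restrained FEP introduces an arbitrary force constant; if estimates
#' are insensitive to it, the restraint bias affects all ligands
#' similarly. Given per-level ΔpKd tables, reports each ligand's
#' max-minus-min spread and standard deviation across levels and flags
#' ligands whose spread exceeds a threshold.
#'
#' @param tables named list of data.frames with columns `ligand` and
#'   `dpkd` (e.g. from [relativeDpkd()]), one per restraint level; at
#'   least 2 levels sharing a ligand set.
#' @param flagThreshold spread (pKd units) above which a ligand is
#'   flagged (default 0.5).
#' @return data.frame with columns `ligand`, `spread`, `sdAcrossLevels`,
#'   `flagged`.
#' @export
restraintSensitivity <- function(tables, flagThreshold = 0.5) {
  if (length(tables) < 2L) stop("need at least 2 restraint levels")
  ligands <- Reduce(intersect, lapply(tables, function(t) t$ligand))
  if (!length(ligands)) stop("restraint tables share no ligands")
  vals <- sapply(tables, function(t) t$dpkd[match(ligands, t$ligand)])
  vals <- matrix(vals, nrow = length(ligands))
  spread <- apply(vals, 1, function(v) max(v) - min(v))
  sds <- apply(vals, 1, sd)
  data.frame(ligand = ligands, spread = spread, sdAcrossLevels = sds,
             flagged = spread > flagThreshold, stringsAsFactors = FALSE)
}

#' Export a FEP network to GraphML
#'
#' @param network a [FepNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network@edges, directed = TRUE,
    vertices = data.frame(name = network@nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
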