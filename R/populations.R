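## Population analysis of bimodal RMSD distributions: occupancy of the
## bioactive population (population 1) with block-averaged uncertainties.

#' Histogram of an RMSD series
#'
#' Left-closed, right-open bins of fixed width starting at 0.
#'
#' @param series an [RmsdSeries-class] or a numeric vector of RMSD values.
#' @param binWidth bin width in Angstrom (default 0.1).
#' @return data.frame with columns `lower`, `upper`, `count`, `density`
#'   (density integrates to 1).
#' @export
#' @examples
#' rmsdHistogram(c(0.05, 0.15, 0.15), binWidth = 0.1)$count  # 1 2
rmsdHistogram <- function(series, binWidth = 0.1) {
  x <- if (is(series, "RmsdSeries")) series@values else as.numeric(series)
  if (!length(x)) stop("empty RMSD series")
  if (binWidth <= 0) stop("binWidth must be > 0")
  nb <- max(1L, as.integer(floor(max(x) / binWidth)) + 1L)
  lower <- (seq_len(nb) - 1L) * binWidth
  bin <- pmin(as.integer(floor(x / binWidth)) + 1L, nb)
  counts <- tabulate(bin, nbins = nb)
  data.frame(lower = lower, upper = lower + binWidth, count = counts,
             density = counts / (length(x) * binWidth))
}

#' Classify frames into bioactive and non-bioactive populations
#'
#' Population 1 (the bioactive, bound-state-like population) is the set
#' of frames with RMSD at or below `threshold`; population 2 is the rest.
#' The 1-sigma uncertainty of the occupancy is the sample standard
#' deviation (ddof = 1) of per-block occupancies over `nBlocks`
#' contiguous blocks.
#'
#' @param series an [RmsdSeries-class] or numeric RMSD vector.
#' @param threshold RMSD threshold in Angstrom (default 2.6); frames
#'   exactly at the threshold count as population 1.
#' @param nBlocks number of contiguous blocks (default 5). With fewer
#'   than 2 blocks the uncertainty is undefined and reported as `NA`.
#' @param ligandId ligand id for the result; taken from the series when
#'   available.
#' @return a [PopulationEstimate-class].
#' @export
#' @examples
#' classifyPopulations(c(1, 2, 3, 4), threshold = 2.6, nBlocks = 2)
classifyPopulations <- function(series, threshold = 2.6, nBlocks = 5L,
                                ligandId = NULL) {
  x <- if (is(series, "RmsdSeries")) series@values else as.numeric(series)
  if (is.null(ligandId))
    ligandId <- if (is(series, "RmsdSeries")) series@ligandId else "ligand"
  nBlocks <- as.integer(nBlocks)
  if (nBlocks < 1L) stop("nBlocks must be >= 1")
  if (length(x) < nBlocks)
    stop("series length (", length(x), ") is below nBlocks (", nBlocks, ")")
  inP1 <- x <= threshold
  p1 <- mean(inP1)
  blocks <- .blockIndices(length(x), nBlocks)
  perBlock <- vapply(blocks, function(ix) mean(inP1[ix]), numeric(1))
  sigma <- if (nBlocks >= 2L) sd(perBlock) else NA_real_
  new("PopulationEstimate", ligandId = as.character(ligandId),
      p1 = p1, p2 = 1 - p1, sigmaP1 = sigma, threshold = threshold,
      nBlocks = nBlocks, perBlockP1 = perBlock)
}

#' Block-to-block convergence of an RMSD distribution
#'
#' Splits the series into contiguous blocks, histograms each block on
#' shared bins, and reports the L1 distance between normalized block
#' densities for every block pair. Similar distributions across blocks
#' indicate consistent sampling; the maximum pairwise distance serves as
#' a single convergence score (0 = identical, 2 = disjoint).
#'
#' @param series an [RmsdSeries-class] or numeric RMSD vector.
#' @param nBlocks number of contiguous blocks (default 5).
#' @param binWidth histogram bin width in Angstrom (default 0.1).
#' @return list with `pairwise` (data.frame: blockA, blockB, l1),
#'   `perBlockMean` (mean distance of each block to the others) and
#'   `maxDistance`.
#' @export
blockConvergence <- function(series, nBlocks = 5L, binWidth = 0.1) {
  x <- if (is(series, "RmsdSeries")) series@values else as.numeric(series)
  nBlocks <- as.integer(nBlocks)
  if (length(x) < nBlocks)
    stop("series length is below nBlocks")
  blocks <- .blockIndices(length(x), nBlocks)
  nb <- as.integer(floor(max(x) / binWidth)) + 1L
  dens <- lapply(blocks, function(ix) {
    xi <- x[ix]
    bin <- pmin(as.integer(floor(xi / binWidth)) + 1L, nb)
    tabulate(bin, nbins = nb) / length(xi)
  })
  pairs <- utils::combn(nBlocks, 2)
  l1 <- apply(pairs, 2, function(p) sum(abs(dens[[p[1]]] - dens[[p[2]]])))
  pw <- data.frame(blockA = pairs[1, ], blockB = pairs[2, ], l1 = l1)
  perBlock <- vapply(seq_len(nBlocks), function(b)
    mean(pw$l1[pw$blockA == b | pw$blockB == b]), numeric(1))
  list(pairwise = pw, perBlockMean = perBlock,
       maxDistance = if (length(l1)) max(l1) else 0)
}

#' Locate the histogram minimum between two modes
#'
#' Helper for choosing a population threshold: finds the bin with the
#' lowest count inside a search window of a (presumed bimodal) RMSD
#' histogram. Never applied automatically; the classification threshold
#' stays an explicit argument.
#'
#' @param series RMSD series or numeric vector.
#' @param window numeric length-2 search window in Angstrom.
#' @param binWidth histogram bin width (default 0.1).
#' @return midpoint (Angstrom) of the lowest-count bin in the window.
#' @export
findHistogramMinimum <- function(series, window, binWidth = 0.1) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  h <- rmsdHistogram(series, binWidth)
  mid <- (h$lower + h$upper) / 2
  inWin <- mid >= window[1] & mid <= window[2]
  if (!any(inWin)) stop("search window contains no histogram bins")
  mid[inWin][which.min(h$count[inWin])]
}
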