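#' Population-level bin edges for MeC/DAPI joint histograms
#'
#' All nuclei of a stack are binned on shared edges spanning the pooled
#' within-ROI intensity range of each channel, so their codistributions are
#' directly comparable. 64 bins per axis by default.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param rois list of \linkS4class{NucleusROI}; when \code{NULL} the whole
#'   stack is pooled.
#' @param nBins bins per axis.
#' @return list with numeric edge vectors \code{dapi} and \code{mec}
#'   (length \code{nBins + 1}).
#' @export
makeBinEdges <- function(stack, rois = NULL, nBins = 64L) {
  dapi <- getChannel(stack, "DAPI")
  mec <- getChannel(stack, "MeC")
  if (!is.null(rois)) {
    idx <- unlist(lapply(rois, roiPixels))
    dapi <- dapi[idx]
    mec <- mec[idx]
  }
  edge <- function(v) {
    r <- range(v)
    if (r[1L] == r[2L]) r[2L] <- r[1L] + 1
    seq(r[1L], r[2L] + 1e-9 * diff(r) + 1e-9, length.out = nBins + 1L)
  }
  list(dapi = edge(dapi), mec = edge(mec))
}

#' MeC/DAPI joint histogram of one nucleus
#'
#' Counts (DAPI, MeC) intensity pairs over the ROI pixels on the shared
#' population bin edges and normalises to a probability table. Intensities
#' outside the edge range are clamped into the end bins.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param roi a \linkS4class{NucleusROI}.
#' @param binEdges edges from [makeBinEdges()].
#' @return A \linkS4class{Codistribution}; the attribute \code{"counts"} on
#'   its histogram holds the total pixel count before normalisation.
#' @export
jointHistogram <- function(stack, roi, binEdges) {
  idx <- roiPixels(roi)
  if (length(idx) == 0L) stop("empty ROI")
  .jointHist(getChannel(stack, "DAPI")[idx], getChannel(stack, "MeC")[idx],
             binEdges)
}

# core histogram on per-pixel intensity vectors
.jointHist <- function(d, m, binEdges) {
  nB <- c(length(binEdges$dapi) - 1L, length(binEdges$mec) - 1L)
  bd <- pmin(pmax(findInterval(d, binEdges$dapi, rightmost.closed = TRUE),
                  1L), nB[1L])
  bm <- pmin(pmax(findInterval(m, binEdges$mec, rightmost.closed = TRUE),
                  1L), nB[2L])
  counts <- tabulate((bm - 1L) * nB[1L] + bd, nbins = nB[1L] * nB[2L])
  h <- matrix(counts / length(d), nrow = nB[1L], ncol = nB[2L])
  attr(h, "counts") <- length(d)
  new("Codistribution", hist = h, binEdges = binEdges, kld = NA_real_)
}

#' Kullback-Leibler divergence between two codistributions
#'
#' Computes \eqn{D(p \| q) = \sum_b p'_b \log_2(p'_b / q'_b)} in bits,
#' where \eqn{p', q'} are the epsilon-smoothed, re-normalised tables
#' (\eqn{p' = (p + \epsilon) / (1 + B\epsilon)} over \eqn{B} bins). The
#' pseudocount makes the divergence finite on empty reference bins; the
#' default 1e-6 per bin is far below one pixel's probability mass for any
#' realistic ROI, so it leaves the divergence scale intact (a large
#' per-bin pseudocount such as \eqn{1/B} mixes substantial uniform mass
#' into both tables and compresses the divergence well below the 4.5-bit
#' dissimilarity scale).
#'
#' @param p,q \linkS4class{Codistribution} objects on identical bin edges,
#'   or plain non-negative tables of equal shape.
#' @param epsilon positive smoothing pseudocount per bin.
#' @return Non-negative divergence in bits (>= 0 up to 1e-12).
#' @export
klDivergence <- function(p, q, epsilon = 1e-6) {
  if (is(p, "Codistribution") && is(q, "Codistribution")) {
    if (!isTRUE(all.equal(p@binEdges, q@binEdges)))
      stop("mismatched bin edges")
    ph <- p@hist
    qh <- q@hist
  } else {
    ph <- as.numeric(p)
    qh <- as.numeric(q)
    if (length(ph) != length(qh)) stop("mismatched binning")
  }
  stopifnot(epsilon > 0)
  ps <- (ph + epsilon)
  ps <- ps / sum(ps)
  qs <- (qh + epsilon)
  qs <- qs / sum(qs)
  sum(ps * log2(ps / qs))
}

#' Population reference codistribution
#'
#' Element-wise mean of the nucleus histograms, re-normalised: the
#' "typical" MeC/DAPI codistribution every nucleus is scored against.
#'
#' @param cods list of \linkS4class{Codistribution} (>= 2, shared edges).
#' @return A \linkS4class{Codistribution}.
#' @export
populationReference <- function(cods) {
  if (length(cods) < 2L)
    stop("need at least 2 nuclei to form a population reference")
  edges <- cods[[1L]]@binEdges
  for (cd in cods[-1L])
    if (!isTRUE(all.equal(cd@binEdges, edges)))
      stop("mismatched bin edges across nuclei")
  m <- Reduce(`+`, lapply(cods, function(cd) cd@hist)) / length(cods)
  m <- m / sum(m)
  new("Codistribution", hist = m, binEdges = edges, kld = NA_real_)
}

#' Score nuclei against the population reference
#'
#' Sets each nucleus's K-L divergence (bits) against the population mean
#' codistribution. By default the reference for nucleus \eqn{i} is the
#' leave-one-out mean over the other nuclei; this equals the plain
#' population mean up to O(1/n) but removes the self-masking bound
#' \eqn{D \le \log_2 n} that a self-inclusive mean imposes on small
#' populations (at the >1000-cell populations the assay is designed for
#' the two are indistinguishable).
#'
#' @param cods list of \linkS4class{Codistribution}.
#' @param epsilon smoothing pseudocount per bin (see [klDivergence()]).
#' @param leaveOneOut score each nucleus against the mean of the others?
#' @return The input list with \code{kld} set on every element.
#' @export
scoreKLD <- function(cods, epsilon = 1e-6, leaveOneOut = TRUE) {
  n <- length(cods)
  if (n < 2L) stop("need at least 2 nuclei to score")
  total <- Reduce(`+`, lapply(cods, function(cd) cd@hist))
  edges <- cods[[1L]]@binEdges
  for (i in seq_len(n)) {
    ref <- if (leaveOneOut) (total - cods[[i]]@hist) / (n - 1L) else total / n
    cods[[i]]@kld <- klDivergence(cods[[i]]@hist, ref, epsilon = epsilon)
  }
  cods
}

#' Flag dissimilar (outlier) nuclei by K-L divergence
#'
#' A nucleus is "dissimilar" iff its divergence from the population
#' reference exceeds the threshold (default 4.5 bits). M-phase-like nuclei
#' (compact, uniformly bright) land far from the interphase reference and
#' are flagged by the same cut. The threshold's scale depends on the
#' histogram binning, so it is exposed rather than hard-coded.
#'
#' @param cods list of scored \linkS4class{Codistribution} (see
#'   [scoreKLD()]).
#' @param threshold divergence cut in bits.
#' @return list with integer index vectors \code{kept} and
#'   \code{dissimilar}, plus \code{fraction} of nuclei flagged.
#' @export
flagOutliers <- function(cods, threshold = 4.5) {
  kld <- vapply(cods, codKLD, numeric(1))
  if (anyNA(kld)) stop("all nuclei must be scored before flagging")
  dis <- which(kld > threshold)
  list(kept = setdiff(seq_along(cods), dis), dissimilar = dis,
       fraction = length(dis) / length(cods))
}

#' Export a per-pixel (DAPI, MeC) scatter sample for one nucleus
#'
#' Writes up to \code{maxPoints} ROI pixels as a two-column CSV for
#' codistribution scatter plots.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param roi a \linkS4class{NucleusROI}.
#' @param path output CSV path.
#' @param maxPoints subsample cap (deterministic: evenly spaced).
#' @return \code{path}, invisibly.
#' @export
writeScatterSample <- function(stack, roi, path, maxPoints = 5000L) {
  idx <- roiPixels(roi)
  if (length(idx) > maxPoints)
    idx <- idx[round(seq(1L, length(idx), length.out = maxPoints))]
  df <- data.frame(dapi = getChannel(stack, "DAPI")[idx],
                   mec = getChannel(stack, "MeC")[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
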