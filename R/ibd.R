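#' Detect pairwise IBD segments by seed-and-extend haplotype matching
#'
#' GERMLINE-style detector: markers are partitioned into consecutive slices
#' of \code{sliceMarkers} markers; haplotypes identical over a slice form an
#' exact-match seed for each pair in the group. Seeds of the same haplotype
#' pair are merged across slices while the mismatches accumulated inside
#' the merged span stay within the per-segment allowances -- a mismatching
#' marker at which both individuals are homozygous counts against
#' \code{maxHomMismatch}, any other mismatch against \code{maxHetMismatch}.
#' Each merged match is finally extended marker-by-marker beyond its slice
#' boundaries to the first mismatching marker. Segments at least
#' \code{minCm} long (genetic distance between first and last matched
#' marker) are reported.
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}}.
#' @param gmap a \code{\linkS4class{GeneticMap}}.
#' @param sliceMarkers markers per hash slice (default 64).
#' @param maxHomMismatch allowed homozygous-context mismatches per segment
#'   (default 1).
#' @param maxHetMismatch allowed heterozygous-context mismatches per
#'   segment (default 1).
#' @param minCm minimum reported genetic length in cM (default 2).
#' @return data.frame with \code{hap_i}, \code{hap_j} (1-based haplotype
#'   indices, \code{hap_i < hap_j}), \code{start_bp}, \code{end_bp},
#'   \code{length_cM}, \code{n_markers}.
#' @export
detectIBD <- function(panel, gmap, sliceMarkers = 64, maxHomMismatch = 1,
                      maxHetMismatch = 1, minCm = 2) {
  a <- alleles(panel)
  m <- ncol(a)
  if (m < sliceMarkers)
    stop("slice larger than marker count (", sliceMarkers, " > ", m, ")")
  nHap <- nrow(a)
  cm <- interpolateCM(gmap, positions(panel))
  geno <- genotypeMatrix(panel)
  nSlices <- m %/% sliceMarkers
  sliceEnd <- seq_len(nSlices) * sliceMarkers
  sliceStart <- sliceEnd - sliceMarkers + 1L

  # candidate pairs: share at least one exact-match slice
  pairKeys <- new.env(hash = TRUE)
  for (s in seq_len(nSlices)) {
    key <- apply(a[, sliceStart[s]:sliceEnd[s], drop = FALSE], 1L,
                 paste, collapse = "")
    grp <- split(seq_len(nHap), key)
    for (g in grp) {
      if (length(g) < 2) next
      for (u in seq_len(length(g) - 1L))
        for (v in (u + 1L):length(g))
          assign(paste0(g[u], "_", g[v]), TRUE, envir = pairKeys)
    }
  }
  pairs <- ls(pairKeys)
  out <- vector("list", length(pairs))
  for (pi in seq_along(pairs)) {
    ij <- as.integer(strsplit(pairs[pi], "_", fixed = TRUE)[[1]])
    i <- ij[1]; j <- ij[2]
    mism <- which(a[i, ] != a[j, ])
    # slices containing no mismatch are matched seeds for this pair
    matched <- rep(TRUE, nSlices)
    if (length(mism)) {
      s <- (mism - 1L) %/% sliceMarkers + 1L
      matched[unique(s[s <= nSlices])] <- FALSE
    }
    if (!any(matched)) next
    indI <- (i + 1L) %/% 2L
    indJ <- (j + 1L) %/% 2L
    homCtx <- geno[indI, ] %in% c(0L, 2L) & geno[indJ, ] %in% c(0L, 2L)

    r <- rle(matched)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runS <- starts[r$values]           # slice indices of seed runs
    runE <- ends[r$values]
    segs <- list()
    curS <- runS[1]; curE <- runE[1]; hom <- 0L; het <- 0L
    if (length(runS) > 1) {
      for (k in 2:length(runS)) {
        gapMarkers <- (sliceEnd[curE] + 1L):(sliceStart[runS[k]] - 1L)
        gm <- mism[mism %in% gapMarkers]
        nh <- sum(homCtx[gm]); nt <- length(gm) - nh
        if (hom + nh <= maxHomMismatch && het + nt <= maxHetMismatch) {
          curE <- runE[k]; hom <- hom + nh; het <- het + nt
        } else {
          segs[[length(segs) + 1L]] <- c(curS, curE)
          curS <- runS[k]; curE <- runE[k]; hom <- 0L; het <- 0L
        }
      }
    }
    segs[[length(segs) + 1L]] <- c(curS, curE)

    res <- lapply(segs, function(se) {
      lo <- sliceStart[se[1]]; hi <- sliceEnd[se[2]]
      before <- mism[mism < lo]
      after <- mism[mism > hi]
      lo <- if (length(before)) max(before) + 1L else 1L
      hi <- if (length(after)) min(after) - 1L else m
      lenCm <- cm[hi] - cm[lo]
      if (lenCm < minCm) return(NULL)
      data.frame(hap_i = i, hap_j = j,
                 start_bp = positions(panel)[lo],
                 end_bp = positions(panel)[hi],
                 length_cM = lenCm, n_markers = hi - lo + 1L)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (length(res)) out[[pi]] <- do.call(rbind, res)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(hap_i = integer(), hap_j = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      length_cM = numeric(), n_markers = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$hap_i, res$hap_j, res$start_bp), , drop = FALSE]
}

#' Normalised IBD sharing score
#'
#' Total genetic length of IBD segments whose length lies in
#' \code{[loCm, hiCm]} (3-20 cM by default; segments outside the band are
#' excluded entirely), divided by the number of between-haplotype pairs
#' C(2n, 2) - n for n diploid individuals (within-individual haplotype
#' pairs do not count). Elevated scores indicate founder effects and recent
#' bottlenecks.
#'
#' @param segments data.frame from \code{\link{detectIBD}}.
#' @param nIndividuals number of diploid individuals n (>= 2).
#' @param loCm,hiCm length band in cM (defaults 3 and 20).
#' @return List with \code{score} (cM per haplotype pair),
#'   \code{norm_constant}, \code{total_cM}, \code{n_segments} (in band).
#' @export
ibdScore <- function(segments, nIndividuals, loCm = 3, hiCm = 20) {
  if (nIndividuals < 2) stop("need at least 2 individuals")
  norm <- choose(2 * nIndividuals, 2) - nIndividuals
  inBand <- segments$length_cM >= loCm & segments$length_cM <= hiCm
  total <- sum(segments$length_cM[inBand])
  list(score = total / norm, norm_constant = norm, total_cM = total,
       n_segments = sum(inBand))
}

#' Weighted block-jackknife confidence interval for the IBD score
#'
#' The chromosome is cut into consecutive blocks of \code{blockMb};
#' segments are assigned to the block containing their midpoint, and the
#' delete-one-block weighted jackknife (weights proportional to block bp
#' length) gives the standard error. The 95% interval is
#' score +/- 1.96 se.
#'
#' @param segments data.frame from \code{\link{detectIBD}}.
#' @param nIndividuals number of diploid individuals.
#' @param extent numeric (start_bp, end_bp) covered by the panel.
#' @param blockMb jackknife block size in Mb (default 10).
#' @param loCm,hiCm score band in cM.
#' @return List with \code{score}, \code{se}, \code{ci} (length 2),
#'   \code{n_blocks}, \code{norm_constant}, \code{n_individuals}.
#' @export
ibdJackknife <- function(segments, nIndividuals, extent, blockMb = 10,
                         loCm = 3, hiCm = 20) {
  span <- extent[2] - extent[1] + 1
  nBlocks <- ceiling(span / (blockMb * 1e6))
  if (nBlocks < 2) stop("insufficient blocks: extent spans only ", nBlocks)
  full <- ibdScore(segments, nIndividuals, loCm, hiCm)
  mid <- (segments$start_bp + segments$end_bp) / 2
  blk <- pmin(floor((mid - extent[1]) / (blockMb * 1e6)) + 1, nBlocks)
  w <- rep(blockMb * 1e6, nBlocks)
  w[nBlocks] <- span - (nBlocks - 1) * blockMb * 1e6
  loo <- vapply(seq_len(nBlocks), function(b) {
    ibdScore(segments[blk != b, , drop = FALSE], nIndividuals,
             loCm, hiCm)$score
  }, numeric(1))
  n <- sum(w)
  h <- n / w
  pseudo <- h * full$score - (h - 1) * loo
  thetaJ <- nBlocks * full$score - sum((1 - w / n) * loo)
  v <- sum((pseudo - thetaJ)^2 / (h - 1)) / nBlocks
  se <- sqrt(v)
  list(score = full$score, se = se,
       ci = c(full$score - 1.96 * se, full$score + 1.96 * se),
       n_blocks = nBlocks, norm_constant = full$norm_constant,
       n_individuals = nIndividuals)
}
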