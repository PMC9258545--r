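#' Extended haplotype homozygosity around a core marker
#'
#' EHH at distance x from the core is the probability that two randomly
#' chosen haplotypes carrying the core allele are identical at every marker
#' between the core and x: \code{sum C(c_h, 2) / C(n_c, 2)} over the counts
#' \code{c_h} of distinct extended haplotypes among the \code{n_c} carriers.
#' EHH equals 1 at the core and is non-increasing outward on each side;
#' curves are evaluated at marker positions.
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}}.
#' @param gmap a \code{\linkS4class{GeneticMap}}.
#' @param coreIndex marker index of the core SNP.
#' @param allele \code{"derived"} or \code{"ancestral"}: which core allele's
#'   carriers to follow.
#' @param stopAt stop walking once EHH falls below this value (0 walks the
#'   full chromosome).
#' @return A list with \code{coreIndex}, \code{allele}, \code{nCarriers},
#'   \code{skipped} (TRUE when fewer than 2 carriers), and per-side
#'   data.frames \code{left}/\code{right} with columns \code{idx},
#'   \code{bp}, \code{cm} and \code{ehh} (the core point, EHH = 1, is
#'   included first in each).
#' @export
computeEHH <- function(panel, gmap, coreIndex,
                       allele = c("derived", "ancestral"), stopAt = 0) {
  allele <- match.arg(allele)
  a <- alleles(panel)
  cm <- interpolateCM(gmap, positions(panel))
  res <- .ehh_curve(a, as.integer(coreIndex) - 1L,
                    if (allele == "derived") 1L else 0L, stopAt)
  corePt <- data.frame(idx = coreIndex, bp = positions(panel)[coreIndex],
                       cm = cm[coreIndex], ehh = 1)
  side <- function(idx, ehh) {
    idx <- idx + 1L
    rbind(corePt,
          data.frame(idx = idx, bp = positions(panel)[idx],
                     cm = cm[idx], ehh = ehh))
  }
  list(coreIndex = coreIndex, allele = allele,
       nCarriers = res$n_carriers,
       skipped = res$n_carriers < 2,
       left = if (res$n_carriers < 2) NULL
              else side(res$left_idx, res$left_ehh),
       right = if (res$n_carriers < 2) NULL
               else side(res$right_idx, res$right_ehh))
}

.skipReasons <- c("0" = "", "1" = "maf", "2" = "no_cutoff_crossing",
                  "3" = "too_few_carriers")

#' iHS scan over all markers of a panel
#'
#' For each core marker with derived allele frequency in
#' \code{[minMaf, 1 - minMaf]}, the EHH curves of the ancestral and derived
#' alleles are integrated over genetic distance (trapezoid rule, with a
#' linearly interpolated final point where EHH crosses \code{cutoff}) on
#' both sides of the core, truncating at \code{maxExtendBp}. Cores whose
#' EHH fails to reach the cutoff before a chromosome end are skipped. The unstandardised score is
#' \code{uihs = ln(iHH_derived / iHH_ancestral)}, so that positive
#' standardised values flag unusually long haplotypes around the derived
#' allele (the selscan sign convention in which iHS > 2 suggests selection
#' on the derived allele).
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}}.
#' @param gmap a \code{\linkS4class{GeneticMap}}.
#' @param cutoff EHH integration cutoff (default 0.05).
#' @param minMaf frequency filter for core markers (default 0.05).
#' @param maxGapBp warn when any adjacent-marker gap exceeds this (default
#'   200 kb; long gaps make linear interpolation of EHH coarse).
#' @param maxExtendBp physical bound on the EHH walk on each side of the
#'   core (default 1 Mb, selscan's --max-extend): integration is truncated
#'   there when EHH is still above \code{cutoff}. Only failing to reach
#'   the cutoff at a chromosome end skips a core. Set to 0 to remove the
#'   bound (cost grows quadratically on high-LD panels).
#' @return data.frame with one row per marker: \code{marker_id},
#'   \code{core}, \code{daf}, \code{ihh_a}, \code{ihh_d}, \code{uihs},
#'   \code{skipped}, \code{reason}.
#' @export
ihsScan <- function(panel, gmap, cutoff = 0.05, minMaf = 0.05,
                    maxGapBp = 2e5, maxExtendBp = 1e6) {
  if (nMarkers(panel) < 2) stop("need at least 2 markers")
  gaps <- diff(positions(panel))
  if (length(gaps) && max(gaps) > maxGapBp)
    warning(sum(gaps > maxGapBp), " inter-marker gap(s) exceed ",
            maxGapBp / 1000, " kb")
  cm <- interpolateCM(gmap, positions(panel))
  df <- .ihs_cores(alleles(panel), cm, positions(panel),
                   seq_len(nMarkers(panel)) - 1L, minMaf, cutoff,
                   maxExtendBp)
  data.frame(marker_id = markerIds(panel), core = df$core, daf = df$daf,
             ihh_a = df$ihh_a, ihh_d = df$ihh_d, uihs = df$uihs,
             skipped = df$skip != 0L,
             reason = unname(.skipReasons[as.character(df$skip)]),
             stringsAsFactors = FALSE)
}

#' Unstandardised iHS at a single core marker
#'
#' @inheritParams ihsScan
#' @param coreIndex marker index of the core SNP.
#' @return One-row data.frame as in \code{\link{ihsScan}}.
#' @export
computeIHS <- function(panel, gmap, coreIndex, cutoff = 0.05,
                       minMaf = 0.05, maxExtendBp = 1e6) {
  cm <- interpolateCM(gmap, positions(panel))
  df <- .ihs_cores(alleles(panel), cm, positions(panel),
                   as.integer(coreIndex) - 1L, minMaf, cutoff, maxExtendBp)
  data.frame(marker_id = markerIds(panel)[coreIndex], core = df$core,
             daf = df$daf, ihh_a = df$ihh_a, ihh_d = df$ihh_d,
             uihs = df$uihs, skipped = df$skip != 0L,
             reason = unname(.skipReasons[as.character(df$skip)]),
             stringsAsFactors = FALSE)
}

#' Standardise iHS within derived-allele-frequency bins
#'
#' Within each DAF bin of width \code{binWidth}, the standardised score is
#' (uihs - bin mean) / bin SD, with the SD using denominator n, so every
#' occupied bin has mean 0 and variance 1 by construction. Bins holding
#' fewer than 2 unskipped records leave \code{sihs} undefined with a
#' warning.
#'
#' @param records data.frame from \code{\link{ihsScan}}.
#' @param binWidth DAF bin width (default 0.02).
#' @return The input with an added \code{sihs} column.
#' @export
standardizeIHS <- function(records, binWidth = 0.02) {
  if (!nrow(records)) stop("no iHS records to standardise")
  records$sihs <- NA_real_
  use <- !records$skipped & is.finite(records$uihs)
  if (!any(use)) {
    warning("no unskipped records; nothing standardised")
    return(records)
  }
  bin <- floor(records$daf[use] / binWidth)
  bin[bin >= 1 / binWidth] <- 1 / binWidth - 1   # daf == 1 edge
  u <- records$uihs[use]
  sihs <- rep(NA_real_, length(u))
  thin <- 0L
  for (b in unique(bin)) {
    sel <- bin == b
    if (sum(sel) < 2L) {
      thin <- thin + 1L
      next
    }
    mu <- mean(u[sel])
    sdN <- sqrt(mean((u[sel] - mu)^2))
    if (sdN == 0) {
      thin <- thin + 1L
      next
    }
    sihs[sel] <- (u[sel] - mu) / sdN
  }
  if (thin > 0)
    warning(thin, " DAF bin(s) with < 2 records (or zero spread); ",
            "their sihs left undefined")
  records$sihs[use] <- sihs
  records
}

#' LD decay profile: mean r-squared in distance bins
#'
#' Squared Pearson correlation of derived-allele dosage (0/1/2) vectors for
#' every marker pair within \code{windowKb}, averaged within distance bins
#' of \code{binKb}. Pairs where either marker has zero dosage variance are
#' excluded rather than counted as zero.
#'
#' @param x a \code{\linkS4class{HaplotypePanel}} or an individuals x
#'   markers dosage matrix.
#' @param pos marker bp positions (taken from the panel when \code{x} is
#'   one).
#' @param windowKb maximum pair distance in kb (default 100).
#' @param binKb bin width in kb (default 1).
#' @return data.frame with \code{lo_kb}, \code{hi_kb} (bin (lo, hi]),
#'   \code{mean_r2} (NA for empty bins) and \code{n_pairs}.
#' @export
ldDecay <- function(x, pos = NULL, windowKb = 100, binKb = 1) {
  if (is(x, "HaplotypePanel")) {
    pos <- positions(x)
    x <- genotypeMatrix(x)
  }
  if (is.null(pos)) stop("marker positions required")
  m <- ncol(x)
  if (m < 2) stop("need at least 2 markers")
  nBins <- ceiling(windowKb / binKb)
  sumR2 <- numeric(nBins)
  nPair <- integer(nBins)
  z <- scale(x)                      # columns with zero variance become NaN
  okCol <- !is.na(colSums(z))
  n <- nrow(x)
  maxBp <- windowKb * 1000
  for (lag in seq_len(m - 1)) {
    d <- pos[(1 + lag):m] - pos[1:(m - lag)]
    inWin <- which(d <= maxBp & d > 0)
    if (!length(inWin)) {
      if (min(d) > maxBp) break
      next
    }
    j <- inWin
    ok <- okCol[j] & okCol[j + lag]
    j <- j[ok]
    if (!length(j)) next
    r <- colSums(z[, j, drop = FALSE] * z[, j + lag, drop = FALSE]) / (n - 1)
    b <- ceiling(d[j] / (binKb * 1000))
    for (bb in unique(b)) {
      sel <- b == bb
      sumR2[bb] <- sumR2[bb] + sum(r[sel]^2)
      nPair[bb] <- nPair[bb] + sum(sel)
    }
  }
  data.frame(lo_kb = (seq_len(nBins) - 1) * binKb,
             hi_kb = seq_len(nBins) * binKb,
             mean_r2 = ifelse(nPair > 0, sumR2 / pmax(nPair, 1L), NA_real_),
             n_pairs = nPair)
}

#' Nei haplotype diversity in marker windows
#'
#' For each non-overlapping window of \code{windowMarkers} consecutive
#' markers, the unbiased haplotype diversity is
#' \code{H = n/(n-1) * (1 - sum p_i^2)} over the frequencies \code{p_i} of
#' the distinct window haplotypes among the \code{n} haplotypes. A trailing
#' partial window is dropped.
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}} with at least
#'   \code{windowMarkers} markers and 2 haplotypes.
#' @param windowMarkers markers per window (default 10).
#' @return List with \code{windows} (data.frame: window, start_bp, end_bp,
#'   hap_div) and \code{mean_hap_div}.
#' @export
haplotypeDiversity <- function(panel, windowMarkers = 10) {
  n <- nHaplotypes(panel)
  if (n < 2) stop("need at least 2 haplotypes")
  m <- nMarkers(panel)
  if (m < windowMarkers) stop("fewer markers than the window size")
  a <- alleles(panel)
  nWin <- m %/% windowMarkers
  H <- numeric(nWin)
  startBp <- endBp <- numeric(nWin)
  for (w in seq_len(nWin)) {
    idx <- ((w - 1) * windowMarkers + 1):(w * windowMarkers)
    key <- apply(a[, idx, drop = FALSE], 1L, paste, collapse = "")
    p <- table(key) / n
    H[w] <- n / (n - 1) * (1 - sum(p^2))
    startBp[w] <- positions(panel)[idx[1]]
    endBp[w] <- positions(panel)[idx[length(idx)]]
  }
  list(windows = data.frame(window = seq_len(nWin), start_bp = startBp,
                            end_bp = endBp, hap_div = H),
       mean_hap_div = mean(H))
}

#' Expected heterozygosity per site
#'
#' He = 2 p (1 - p) with p the derived allele frequency.
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}} with >= 1 marker.
#' @return List with \code{per_site} (numeric vector) and
#'   \code{mean_exp_het}.
#' @export
expectedHeterozygosity <- function(panel) {
  if (nMarkers(panel) < 1) stop("need at least 1 marker")
  p <- derivedFreq(panel)
  he <- 2 * p * (1 - p)
  list(per_site = he, mean_exp_het = mean(he))
}

#' Combined diversity summary
#'
#' @inheritParams haplotypeDiversity
#' @return List with \code{window_hap_div}, \code{mean_hap_div} and
#'   \code{mean_exp_het}.
#' @export
diversitySummary <- function(panel, windowMarkers = 10) {
  hd <- haplotypeDiversity(panel, windowMarkers)
  eh <- expectedHeterozygosity(panel)
  list(window_hap_div = hd$windows, mean_hap_div = hd$mean_hap_div,
       mean_exp_het = eh$mean_exp_het)
}

#' Mean pairwise nucleotide diversity per bp
#'
#' Average number of pairwise differences between haplotypes divided by the
#' sequence length; at neutral equilibrium its expectation is
#' theta = 4 Ne mu per bp. The block-jackknife standard error (over
#' \code{nBlocks} equal physical windows) accounts for linkage along the
#' chromosome.
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}}.
#' @param chromLenBp chromosome length the panel spans.
#' @param nBlocks jackknife blocks (default 10).
#' @return List with \code{pi_per_bp} and \code{se}.
#' @export
pairwiseDiversity <- function(panel, chromLenBp, nBlocks = 10) {
  a <- alleles(panel)
  n <- nrow(a)
  p <- colMeans(a)
  # per-site mean pairwise difference, sample version: 2p(1-p) * n/(n-1)
  persite <- 2 * p * (1 - p) * n / (n - 1)
  piAll <- sum(persite) / chromLenBp
  blk <- pmin(floor(positions(panel) / (chromLenBp / nBlocks)) + 1, nBlocks)
  loo <- vapply(seq_len(nBlocks), function(b) {
    sum(persite[blk != b]) / (chromLenBp * (nBlocks - 1) / nBlocks)
  }, numeric(1))
  se <- sqrt((nBlocks - 1) / nBlocks * sum((loo - mean(loo))^2))
  list(pi_per_bp = piAll, se = se)
}
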