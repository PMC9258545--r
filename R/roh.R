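#' ROH calling parameters
#'
#' Defaults follow the PLINK \code{--homozyg} parameterisation for
#' array-scale data: 50-SNP scanning windows with no heterozygote allowed
#' (\code{windowHet = 3} for sequencing data with higher genotype error),
#' up to 5 missing calls per window, a 5% window-hit threshold, and
#' reported runs of at least 50 SNPs and 1 Mb with no internal gap above
#' 1 Mb. \code{maxKbPerSnp} is PLINK's default density requirement (one
#' SNP per 50 kb on average inside a run).
#'
#' @param windowSnp scanning window size in SNPs.
#' @param windowHet heterozygous calls allowed per window (0 for array
#'   data, 3 for WGS).
#' @param windowMissing missing calls allowed per window.
#' @param windowThreshold minimum fraction of homozygous windows
#'   overlapping a SNP for it to qualify.
#' @param minSnp minimum SNPs per reported run.
#' @param minKb minimum run length in kb.
#' @param maxGapKb maximum adjacent-SNP gap inside a run, in kb.
#' @param maxKbPerSnp maximum average kb per SNP inside a run.
#' @return Named list of parameters.
#' @export
rohParams <- function(windowSnp = 50, windowHet = 0, windowMissing = 5,
                      windowThreshold = 0.05, minSnp = 50, minKb = 1000,
                      maxGapKb = 1000, maxKbPerSnp = 50) {
  stopifnot(windowSnp >= 1, windowHet >= 0, windowMissing >= 0,
            windowThreshold > 0, windowThreshold <= 1,
            minSnp >= 0, minKb >= 0, maxGapKb >= 0)
  list(windowSnp = windowSnp, windowHet = windowHet,
       windowMissing = windowMissing, windowThreshold = windowThreshold,
       minSnp = minSnp, minKb = minKb, maxGapKb = maxGapKb,
       maxKbPerSnp = maxKbPerSnp)
}

# rolling sum of k consecutive entries
.rollSum <- function(x, k) {
  cs <- cumsum(c(0, x))
  cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]
}

.rohOneIndividual <- function(g, pos, p) {
  m <- length(g)
  W <- m - p$windowSnp + 1L
  if (W < 1L) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  homWin <- (.rollSum(het, p$windowSnp) <= p$windowHet) &
            (.rollSum(mis, p$windowSnp) <= p$windowMissing)
  # windows overlapping SNP i: indices max(1, i-w+1) .. min(i, W)
  csW <- cumsum(c(0, homWin))
  i <- seq_len(m)
  loW <- pmax(1L, i - p$windowSnp + 1L)
  hiW <- pmin(i, W)
  nTot <- pmax(hiW - loW + 1L, 0L)
  nHit <- ifelse(nTot > 0, csW[hiW + 1L] - csW[loW], 0L)
  qual <- nTot > 0 & nHit / pmax(nTot, 1L) >= p$windowThreshold

  q <- which(qual)
  if (!length(q)) return(NULL)
  # split runs at non-consecutive indices or at gaps > maxGapKb
  brk <- c(TRUE, diff(q) > 1L |
                 (pos[q[-1]] - pos[q[-length(q)]]) > p$maxGapKb * 1000)
  runId <- cumsum(brk)
  res <- lapply(split(q, runId), function(idx) {
    nSnp <- length(idx)
    lenKb <- (pos[idx[nSnp]] - pos[idx[1]] + 1) / 1000
    if (nSnp < p$minSnp || lenKb < p$minKb) return(NULL)
    if (lenKb / nSnp > p$maxKbPerSnp) return(NULL)
    data.frame(start_bp = pos[idx[1]], end_bp = pos[idx[nSnp]],
               n_snp = nSnp, length_kb = lenKb)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

#' Call runs of homozygosity with a sliding-window scan
#'
#' PLINK-style algorithm: a window of \code{windowSnp} SNPs slides one SNP
#' at a time over each individual's genotypes; a window is homozygous when
#' it holds at most \code{windowHet} heterozygous and \code{windowMissing}
#' missing calls; a SNP qualifies when the fraction of homozygous windows
#' among all windows overlapping it reaches \code{windowThreshold}
#' (truncated window ranges near the chromosome ends use the reduced
#' overlap count); maximal runs of qualifying SNPs are reported when they
#' satisfy the \code{minSnp}, \code{minKb} and density constraints, runs
#' being split at adjacent-SNP gaps above \code{maxGapKb}.
#'
#' @param x a \code{\linkS4class{HaplotypePanel}} (individual genotypes are
#'   formed by pairing each individual's two haplotypes) or an
#'   individuals x markers dosage matrix with 0/1/2 and NA.
#' @param pos marker bp positions (from the panel when \code{x} is one);
#'   must be ascending.
#' @param params list from \code{\link{rohParams}}.
#' @return data.frame with \code{individual_id}, \code{start_bp},
#'   \code{end_bp}, \code{n_snp}, \code{length_kb}.
#' @export
callROH <- function(x, pos = NULL, params = rohParams()) {
  if (is(x, "HaplotypePanel")) {
    pos <- positions(x)
    x <- genotypeMatrix(x)
  }
  if (is.null(pos)) stop("marker positions required")
  if (is.unsorted(pos, strictly = FALSE)) stop("positions must be ascending")
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(x)))
  out <- lapply(seq_len(nrow(x)), function(i) {
    seg <- .rohOneIndividual(x[i, ], pos, params)
    if (is.null(seg)) return(NULL)
    cbind(data.frame(individual_id = ids[i], stringsAsFactors = FALSE), seg)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(individual_id = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snp = integer(),
                      length_kb = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-individual and population ROH summaries
#'
#' @param segments data.frame from \code{\link{callROH}}.
#' @param individuals character vector of all individual ids (individuals
#'   without segments are reported with count 0).
#' @return List with \code{per_individual} (data.frame: individual_id,
#'   n_segments, total_kb) and \code{median_length_kb} (population median
#'   of segment lengths; NA when there are none).
#' @export
summarizeROH <- function(segments, individuals) {
  cnt <- setNames(integer(length(individuals)), individuals)
  tot <- setNames(numeric(length(individuals)), individuals)
  if (nrow(segments)) {
    tb <- table(factor(segments$individual_id, levels = individuals))
    cnt[names(tb)] <- as.integer(tb)
    s <- tapply(segments$length_kb, factor(segments$individual_id,
                                           levels = individuals), sum)
    tot[!is.na(s)] <- s[!is.na(s)]
  }
  list(per_individual = data.frame(individual_id = individuals,
                                   n_segments = unname(cnt),
                                   total_kb = unname(tot),
                                   stringsAsFactors = FALSE),
       median_length_kb = if (nrow(segments)) median(segments$length_kb)
                          else NA_real_)
}
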