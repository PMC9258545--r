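#' Empirical iHS significance cutoffs from neutral simulations
#'
#' Derives a per-population pair of iHS thresholds from a pool of
#' standardised scores computed on neutral simulations, matched to the
#' number of tests run in the empirical population: the lower (upper)
#' cutoff is the mean, over \code{B} without-replacement draws of size
#' \code{nTests} from the pool, of the draw minimum (maximum) -- the
#' expected extremes at the matched test count. Smaller test counts thus
#' receive less extreme cutoffs. A plain tail-quantile alternative
#' (per-tail probability 1/nTests) is available via \code{method}.
#'
#' @param scores pooled standardised iHS values from neutral simulations
#'   (non-finite entries are dropped).
#' @param nTests number of tests in the population being calibrated.
#' @param B number of resampling draws (default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param method \code{"extremes"} (default) or \code{"quantile"}.
#' @return List with \code{lo}, \code{hi}, \code{n_tests}, \code{B},
#'   \code{seed}, \code{method}.
#' @export
deriveCutoffs <- function(scores, nTests, B = 1000, seed,
                          method = c("extremes", "quantile")) {
  method <- match.arg(method)
  scores <- scores[is.finite(scores)]
  N <- length(scores)
  if (nTests < 1) stop("nTests must be >= 1")
  if (nTests > N)
    stop("nTests (", nTests, ") exceeds pooled score count (", N, ")")
  if (method == "quantile") {
    alpha <- 1 / nTests
    lo <- unname(quantile(scores, alpha))
    hi <- unname(quantile(scores, 1 - alpha))
  } else {
    set.seed(seed)
    if (nTests == N) {
      lo <- min(scores)
      hi <- max(scores)
    } else {
      mins <- maxs <- numeric(B)
      for (b in seq_len(B)) {
        d <- scores[sample.int(N, nTests)]
        mins[b] <- min(d)
        maxs[b] <- max(d)
      }
      lo <- mean(mins)
      hi <- mean(maxs)
    }
  }
  if (!(lo < 0 && hi > 0))
    warning("cutoffs do not straddle 0 (lo = ", signif(lo, 4), ", hi = ",
            signif(hi, 4), "); the score pool may be too small")
  list(lo = lo, hi = hi, n_tests = as.integer(nTests), B = as.integer(B),
       seed = if (method == "extremes") seed else NA_integer_,
       method = method)
}

#' Filter standardised iHS records against simulation-derived cutoffs
#'
#' Retains records whose standardised score falls strictly outside
#' \code{(lo, hi)} (scores exactly equal to a cutoff are excluded). The
#' sign convention follows selscan: a positive score flags selection on
#' the derived allele, a negative one on the ancestral allele.
#'
#' @param records data.frame with an \code{sihs} column (from
#'   \code{\link{standardizeIHS}}).
#' @param cutoffs list from \code{\link{deriveCutoffs}}.
#' @param population population label attached to the candidates.
#' @return data.frame with \code{marker_id}, \code{population},
#'   \code{sihs}, \code{lo}, \code{hi}, \code{favored_allele}.
#' @export
filterCandidates <- function(records, cutoffs, population = "pop") {
  keep <- which(!is.na(records$sihs) &
    (records$sihs < cutoffs$lo | records$sihs > cutoffs$hi))
  data.frame(marker_id = records$marker_id[keep],
             population = rep(population, length(keep)),
             sihs = records$sihs[keep],
             lo = rep(cutoffs$lo, length(keep)),
             hi = rep(cutoffs$hi, length(keep)),
             favored_allele = ifelse(records$sihs[keep] > 0,
                                     "derived", "ancestral"),
             stringsAsFactors = FALSE)
}

#' Tally candidate markers across populations
#'
#' @param candidates named list, one element per population: either a
#'   candidate data.frame from \code{\link{filterCandidates}} or a
#'   character vector of marker ids.
#' @return List with \code{unique_markers} (size of the union),
#'   \code{shared_markers} (markers flagged in >= 2 populations) and
#'   \code{total_signals} (sum of per-population counts).
#' @export
tallyShared <- function(candidates) {
  ids <- lapply(candidates, function(x)
    unique(if (is.data.frame(x)) x$marker_id else as.character(x)))
  if (length(unique(names(ids))) != length(ids))
    stop("population labels must be distinct")
  all <- unlist(ids, use.names = FALSE)
  tb <- table(all)
  list(unique_markers = length(tb),
       shared_markers = sum(tb >= 2),
       total_signals = length(all))
}

#' Date a candidate allele by haplotype decay (TMRCA)
#'
#' Assuming a star-shaped genealogy of the carriers, the probability that a
#' chromosome keeps the ancestral haplotype intact out to recombination
#' distance r Morgans after T generations is exp(-2 r T) (two meioses per
#' generation path between two carriers). The selected haplotype is taken
#' to reach its breakpoints where its EHH decays to 0.25 (75% of
#' chromosomes recombined off); r is half the genetic span between the two
#' interpolated EHH = 0.25 crossings, so T = ln(4) / (2 r) generations and
#' the age in years is \code{g * T}. Spans above \code{maxSpanCm} flag an
#' allele too young for the clock and are skipped; cores whose EHH never
#' reaches 0.25 inside the panel are marked unresolved.
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}}.
#' @param gmap a \code{\linkS4class{GeneticMap}}.
#' @param coreIndex marker index of the candidate core.
#' @param favored \code{"derived"} or \code{"ancestral"}: allele whose
#'   haplotype is dated (from the sign of the candidate's iHS).
#' @param g years per generation (default 30).
#' @param homozTarget EHH level defining the breakpoints (default 0.25).
#' @param maxSpanCm skip threshold on the breakpoint span (default 1.1 cM).
#' @return One-row data.frame with \code{core}, \code{favored},
#'   \code{span_cM}, \code{r_morgans}, \code{t_gen}, \code{years},
#'   \code{status} (ok / skipped / unresolved).
#' @export
estimateTMRCA <- function(panel, gmap, coreIndex,
                          favored = c("derived", "ancestral"), g = 30,
                          homozTarget = 0.25, maxSpanCm = 1.1) {
  favored <- match.arg(favored)
  curve <- computeEHH(panel, gmap, coreIndex, allele = favored,
                      stopAt = homozTarget)
  na <- data.frame(core = coreIndex, favored = favored,
                   span_cM = NA_real_, r_morgans = NA_real_,
                   t_gen = NA_real_, years = NA_real_,
                   status = "unresolved", stringsAsFactors = FALSE)
  if (curve$skipped) return(na)
  crossing <- function(side) {
    e <- side$ehh
    k <- which(e <= homozTarget)[1]
    if (is.na(k)) return(NA_real_)
    if (e[k] == homozTarget || k == 1)
      return(abs(side$cm[k] - side$cm[1]))
    frac <- (e[k - 1] - homozTarget) / (e[k - 1] - e[k])
    abs(side$cm[k - 1] + frac * (side$cm[k] - side$cm[k - 1]) - side$cm[1])
  }
  dl <- crossing(curve$left)
  dr <- crossing(curve$right)
  if (is.na(dl) || is.na(dr)) return(na)
  span <- dl + dr
  if (span > maxSpanCm + 1e-9) {
    na$span_cM <- span
    na$status <- "skipped"
    return(na)
  }
  r <- span / 2 / 100            # cM -> Morgans
  tGen <- -log(homozTarget) / (2 * r)
  data.frame(core = coreIndex, favored = favored, span_cM = span,
             r_morgans = r, t_gen = tGen, years = g * tGen,
             status = "ok", stringsAsFactors = FALSE)
}
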