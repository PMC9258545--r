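#' SimSample: one simulated sample with its provenance
#'
#' @slot panel the sampled \code{\linkS4class{HaplotypePanel}}.
#' @slot seed integer seed the run was started from.
#' @slot runIndex index of the run within a multi-run batch.
#' @slot model the \code{\linkS4class{DemographyModel}} simulated.
#' @exportClass SimSample
setClass("SimSample",
  representation(panel = "HaplotypePanel", seed = "numeric",
                 runIndex = "integer", model = "DemographyModel"))

setMethod("show", "SimSample", function(object) {
  cat("SimSample (run", object@runIndex, ", seed", object@seed, ")\n")
  show(object@panel)
})

#' @rdname samplePanel
#' @export
setGeneric("samplePanel", function(x) standardGeneric("samplePanel"))

#' Extract the haplotype panel from a SimSample
#'
#' @param x a \code{\linkS4class{SimSample}}.
#' @return The \code{\linkS4class{HaplotypePanel}}.
#' @name samplePanel
#' @export
setMethod("samplePanel", "SimSample", function(x) x@panel)

# Convert the engine's list of real-valued mutation-position vectors into a
# HaplotypePanel: site frequencies are computed among sampled haplotypes,
# sites outside (minFreq, 1) are dropped (fixed sites carry no information,
# rare sites are below the panel's MAF floor), and positions are mapped to
# unique integer bp.
hapsToPanel <- function(haps, chromLenBp, minFreq = 0.05, chrom = "1") {
  nHap <- length(haps)
  allPos <- sort(unique(unlist(haps, use.names = FALSE)))
  if (!length(allPos)) {
    return(HaplotypePanel(matrix(0L, nHap, 0), positions = numeric(),
                          markerIds = character(),
                          individualIds = NULL, chrom = chrom))
  }
  cnt <- integer(length(allPos))
  for (h in haps) {
    idx <- match(h, allPos)
    cnt[idx] <- cnt[idx] + 1L
  }
  freq <- cnt / nHap
  keep <- which(freq > minFreq & freq < 1)
  keepPos <- allPos[keep]
  a <- matrix(0L, nrow = nHap, ncol = length(keep))
  for (i in seq_len(nHap)) {
    idx <- match(haps[[i]], keepPos)
    a[i, idx[!is.na(idx)]] <- 1L
  }
  ip <- floor(keepPos) + 1
  if (length(ip) > 1)
    for (k in 2:length(ip))
      if (ip[k] <= ip[k - 1]) ip[k] <- ip[k - 1] + 1
  HaplotypePanel(a, positions = ip, individualIds = NULL, chrom = chrom)
}

#' Burn a population to mutation-drift equilibrium
#'
#' Runs 10 * Ne (scaled) generations of constant-size neutral Wright--Fisher
#' reproduction starting from a mutation-free population, which is ample for
#' neutral-site mutation-drift equilibrium (expected diversity approaches
#' 4 Ne mu within a fraction of a percent). The returned opaque state can be
#' passed to \code{\link{simulatePanel}} so several runs share one burn-in,
#' mirroring a batch of runs forked from a common equilibrium ancestor.
#'
#' @param model a \code{\linkS4class{DemographyModel}} (usually rescaled).
#' @param seed integer seed.
#' @return Opaque population state (list of haplotypes).
#' @export
burninPopulation <- function(model, seed) {
  gp <- generationPlan(model)
  set.seed(seed)
  .wf_burnin(gp$burnNe, gp$burnGens, model@chromLenBp, model@mu, model@rec)
}

#' Simulate a sample of diploid individuals under a demographic model
#'
#' Discrete-generation Wright--Fisher forward simulation: each offspring
#' chromosome is a recombinant of one parent's two chromosomes (crossover
#' count Poisson with mean rec * chromLen, breakpoints uniform), new
#' mutations arise at Poisson(mu * chromLen) unique positions per
#' chromosome per generation (infinite sites), inbreeding-window offspring
#' are selfed with the model's probability, and the admixture pulse draws
#' the stated fraction of parents from the source lineage. At the end,
#' \code{nSample} individuals are drawn without replacement and the panel
#' retains sites with derived frequency in (0.05, 1) among the sampled
#' haplotypes.
#'
#' @param model a \code{\linkS4class{DemographyModel}}.
#' @param nSample number of diploid individuals to sample (at most the
#'   final population size).
#' @param seed integer seed; identical (model, nSample, seed) give an
#'   identical panel.
#' @param burnState optional state from \code{\link{burninPopulation}};
#'   when \code{NULL} a fresh burn-in is run first.
#' @param runIndex bookkeeping index stored in the result.
#' @param minFreq derived-frequency floor for retained markers (default
#'   0.05, the pipeline's marker filter; set to 0 to keep every
#'   segregating site, e.g. when comparing raw diversity against its
#'   closed-form expectation, which counts rare alleles too).
#' @return A \code{\linkS4class{SimSample}}.
#' @export
simulatePanel <- function(model, nSample, seed, burnState = NULL,
                          runIndex = 1L, minFreq = 0.05) {
  gp <- generationPlan(model)
  finalNe <- if (nrow(gp$plan)) gp$plan$neB[nrow(gp$plan)] else gp$burnNe
  if (nSample > finalNe)
    stop("sample larger than population: ", nSample, " > ", finalNe)
  set.seed(seed)
  if (is.null(burnState))
    burnState <- .wf_burnin(gp$burnNe, gp$burnGens, model@chromLenBp,
                            model@mu, model@rec)
  haps <- .wf_continue(burnState, gp$plan$neA, gp$plan$neB, gp$plan$selfing,
                       gp$plan$admix, model@chromLenBp, model@mu, model@rec,
                       as.integer(nSample))
  panel <- hapsToPanel(haps, model@chromLenBp, minFreq = minFreq)
  new("SimSample", panel = panel, seed = as.numeric(seed),
      runIndex = as.integer(runIndex), model = model)
}

#' Simulate several independent runs sharing one burn-in
#'
#' @param model a \code{\linkS4class{DemographyModel}}.
#' @param nRuns number of post-burn-in runs to fork.
#' @param nSample diploid individuals sampled per run.
#' @param seed integer seed (burn-in uses \code{seed}; run k uses
#'   \code{seed + k}).
#' @param burnState optional shared state from
#'   \code{\link{burninPopulation}}.
#' @return List of \code{\linkS4class{SimSample}} objects.
#' @export
simulateRuns <- function(model, nRuns, nSample, seed, burnState = NULL) {
  if (is.null(burnState)) burnState <- burninPopulation(model, seed)
  lapply(seq_len(nRuns), function(k)
    simulatePanel(model, nSample, seed + k, burnState = burnState,
                  runIndex = k))
}

#' Simulate matched samples from the admixed lineage and its source
#'
#' Like \code{\link{simulatePanel}}, but also samples the source
#' (European-like) lineage at the end of the run, returning both panels on
#' a common marker space so allele-frequency divergence between the
#' admixed population and its parental lineages can be measured.
#'
#' @inheritParams simulatePanel
#' @param nSourceSample diploid individuals sampled from the source deme.
#' @return List with \code{target} and \code{source}, both
#'   \code{\linkS4class{HaplotypePanel}}s sharing one marker set (sites
#'   segregating above \code{minFreq} in the pooled sample).
#' @export
simulateWithSource <- function(model, nSample, nSourceSample, seed,
                               burnState = NULL, minFreq = 0.05) {
  gp <- generationPlan(model)
  set.seed(seed)
  if (is.null(burnState))
    burnState <- .wf_burnin(gp$burnNe, gp$burnGens, model@chromLenBp,
                            model@mu, model@rec)
  res <- .wf_continue(burnState, gp$plan$neA, gp$plan$neB, gp$plan$selfing,
                      gp$plan$admix, model@chromLenBp, model@mu, model@rec,
                      as.integer(nSample), 50L, as.integer(nSourceSample))
  joint <- hapsToPanel(c(res$B, res$A), model@chromLenBp,
                       minFreq = minFreq)
  tIdx <- seq_len(nSample)
  sIdx <- nSample + seq_len(nSourceSample)
  list(target = joint[, tIdx], source = joint[, sIdx])
}

#' Partition sampled individuals into disjoint analysis groups
#'
#' Randomly divides sampled individuals into \code{nGroups} disjoint groups
#' of exactly \code{groupSize}, re-filtering each group's markers to minor
#' allele frequency >= \code{maf} within the group. Independent runs are
#' independent chromosomes with disjoint marker sets, so groups never span
#' runs: when a list of samples is given, each run contributes as many whole
#' groups as its individuals allow.
#'
#' @param samples a \code{\linkS4class{SimSample}}, a
#'   \code{\linkS4class{HaplotypePanel}}, or a list of either.
#' @param groupSize individuals per group.
#' @param nGroups number of groups.
#' @param seed integer seed for the random assignment.
#' @param maf within-group MAF filter (default 0.05).
#' @return List of \code{nGroups} \code{\linkS4class{HaplotypePanel}}s.
#' @export
partitionGroups <- function(samples, groupSize, nGroups, seed, maf = 0.05) {
  if (!is.list(samples)) samples <- list(samples)
  panels <- lapply(samples, function(s)
    if (is(s, "SimSample")) samplePanel(s) else s)
  perRun <- vapply(panels, nIndividuals, integer(1))
  capacity <- sum(perRun %/% groupSize)
  if (sum(perRun) < groupSize * nGroups)
    stop("insufficient individuals: have ", sum(perRun), ", need ",
         groupSize * nGroups)
  if (capacity < nGroups)
    stop("insufficient individuals: runs supply at most ", capacity,
         " whole groups of ", groupSize)
  set.seed(seed)
  out <- vector("list", nGroups)
  g <- 0L
  for (r in seq_along(panels)) {
    perm <- sample.int(perRun[r])
    avail <- perRun[r] %/% groupSize
    for (k in seq_len(avail)) {
      if (g >= nGroups) break
      g <- g + 1L
      idx <- perm[((k - 1L) * groupSize + 1L):(k * groupSize)]
      out[[g]] <- mafFilter(panels[[r]][, sort(idx)], maf = maf)
    }
    if (g >= nGroups) break
  }
  out
}
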