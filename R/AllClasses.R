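#' HaplotypePanel: phased 0/1 haplotypes with marker metadata
#'
#' A panel of phased haplotypes over biallelic autosomal SNPs. Alleles are
#' coded 0 = ancestral, 1 = derived; rows are haplotypes (rows \code{2i-1}
#' and \code{2i} belong to individual \code{i}), columns are markers in
#' ascending base-pair order.
#'
#' @slot alleles integer matrix of 0/1 with dimensions (2n haplotypes) x
#'   (m markers).
#' @slot positions numeric vector of 1-based bp coordinates, strictly
#'   increasing, one per marker.
#' @slot markerIds character vector of marker identifiers.
#' @slot individualIds character vector of n individual identifiers.
#' @slot chrom single chromosome name.
#'
#' @seealso \code{\link{HaplotypePanel}} (constructor),
#'   \code{\link{genotypeMatrix}}, \code{\link{derivedFreq}},
#'   \code{\link{mafFilter}}
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  representation(
    alleles = "matrix",
    positions = "numeric",
    markerIds = "character",
    individualIds = "character",
    chrom = "character"
  )
)

setValidity("HaplotypePanel", function(object) {
  a <- object@alleles
  msg <- character()
  if (nrow(a) %% 2L != 0L)
    msg <- c(msg, "number of haplotype rows must be even")
  if (nrow(a) != 2L * length(object@individualIds))
    msg <- c(msg, "need exactly 2 haplotype rows per individual")
  if (ncol(a) != length(object@positions))
    msg <- c(msg, "ncol(alleles) must equal length(positions)")
  if (ncol(a) != length(object@markerIds))
    msg <- c(msg, "ncol(alleles) must equal length(markerIds)")
  if (length(object@chrom) != 1L)
    msg <- c(msg, "chrom must be a single string")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(a) && !all(a == 0L | a == 1L))
    msg <- c(msg, "alleles must contain only 0 and 1")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param alleles 0/1 matrix, haplotypes x markers.
#' @param positions bp positions (1-based, strictly increasing).
#' @param markerIds marker identifiers; autogenerated when \code{NULL}.
#' @param individualIds individual identifiers; autogenerated when
#'   \code{NULL}.
#' @param chrom chromosome name.
#' @return A \code{\linkS4class{HaplotypePanel}}.
#' @examples
#' h <- matrix(c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 1L), nrow = 4)
#' HaplotypePanel(h, positions = c(100, 200))
#' @export
HaplotypePanel <- function(alleles, positions, markerIds = NULL,
                           individualIds = NULL, chrom = "1") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (is.null(markerIds))
    markerIds <- sprintf("m%06d", seq_len(ncol(alleles)))
  if (is.null(individualIds))
    individualIds <- sprintf("ind%04d", seq_len(nrow(alleles) %/% 2L))
  new("HaplotypePanel", alleles = alleles, positions = as.numeric(positions),
      markerIds = as.character(markerIds),
      individualIds = as.character(individualIds),
      chrom = as.character(chrom))
}

#' GeneticMap: monotone bp to cM mapping
#'
#' Piecewise-linear genetic map anchored at (bp, cM) pairs. Positions between
#' anchors are linearly interpolated; positions beyond either end take the
#' boundary cM value (constant extrapolation).
#'
#' @slot bp numeric anchor positions in bp, strictly increasing.
#' @slot cM numeric genetic positions in centimorgans, non-decreasing.
#' @seealso \code{\link{GeneticMap}}, \code{\link{interpolateCM}},
#'   \code{\link{uniformMap}}
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(bp = "numeric", cM = "numeric"))

setValidity("GeneticMap", function(object) {
  msg <- character()
  if (length(object@bp) != length(object@cM))
    msg <- c(msg, "bp and cM must have equal length")
  if (length(object@bp) < 1L)
    msg <- c(msg, "need at least one anchor")
  if (length(object@bp) > 1L && any(diff(object@bp) <= 0))
    msg <- c(msg, "bp anchors must be strictly increasing")
  if (length(object@cM) > 1L && any(diff(object@cM) < 0))
    msg <- c(msg, "cM values must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneticMap from anchor pairs
#'
#' @param bp anchor positions (bp), strictly increasing.
#' @param cM genetic positions (cM), non-decreasing.
#' @return A \code{\linkS4class{GeneticMap}}.
#' @examples
#' gm <- GeneticMap(bp = c(1000, 2000), cM = c(0, 0.001))
#' interpolateCM(gm, 1500)
#' @export
GeneticMap <- function(bp, cM) {
  new("GeneticMap", bp = as.numeric(bp), cM = as.numeric(cM))
}

#' Uniform genetic map at a constant recombination rate
#'
#' @param chromLenBp chromosome length in bp.
#' @param cmPerMb map rate in cM/Mb (1 cM/Mb corresponds to a crossover
#'   rate of 1e-8 per bp per generation).
#' @return A two-anchor \code{\linkS4class{GeneticMap}} spanning
#'   \code{[1, chromLenBp]}.
#' @export
uniformMap <- function(chromLenBp, cmPerMb = 1) {
  GeneticMap(bp = c(1, chromLenBp),
             cM = c(0, (chromLenBp - 1) * cmPerMb / 1e6))
}

#' DemographyModel: piecewise-constant demography with admixture and
#' inbreeding
#'
#' Describes a single-lineage Wright--Fisher history by epochs of constant
#' diploid effective size, an optional one-generation admixture pulse from a
#' separately maintained source lineage, and an inbreeding (selfing) window.
#' Times are stored in years before present and converted to generations by
#' \code{genYears * scaleQ} at simulation time.
#'
#' @slot epochs data.frame with columns \code{years_ago} (epoch start,
#'   decreasing downwards) and \code{ne} (diploid size from that time on).
#' @slot admixture list with \code{years_ago}, \code{fraction}, \code{source};
#'   \code{fraction = 0} disables the pulse.
#' @slot inbreeding list with \code{prob} and \code{window} (start, end) in
#'   years ago; \code{prob = 0} disables selfing.
#' @slot mu mutation rate per bp per generation.
#' @slot rec crossover rate per bp per generation.
#' @slot chromLenBp chromosome length in bp.
#' @slot genYears years per generation.
#' @slot scaleQ population-rescaling factor (>= 1); see
#'   \code{\link{rescaleModel}}.
#' @seealso \code{\link{colonizationModel}}, \code{\link{constantModel}},
#'   \code{\link{simulatePanel}}
#' @exportClass DemographyModel
setClass("DemographyModel",
  representation(
    epochs = "data.frame",
    admixture = "list",
    inbreeding = "list",
    mu = "numeric",
    rec = "numeric",
    chromLenBp = "numeric",
    genYears = "numeric",
    scaleQ = "numeric"
  )
)

setValidity("DemographyModel", function(object) {
  msg <- character()
  ep <- object@epochs
  if (!all(c("years_ago", "ne") %in% names(ep)))
    msg <- c(msg, "epochs needs columns years_ago and ne")
  else {
    if (nrow(ep) < 1L) msg <- c(msg, "need at least one epoch")
    if (nrow(ep) > 1L && any(diff(ep$years_ago) >= 0))
      msg <- c(msg, "epochs must be ordered oldest to youngest")
    if (any(ep$ne < 2)) msg <- c(msg, "all Ne must be >= 2")
  }
  adm <- object@admixture
  if (!is.null(adm$fraction) &&
      (adm$fraction < 0 || adm$fraction > 1))
    msg <- c(msg, "admixture fraction must lie in [0, 1]")
  inb <- object@inbreeding
  if (!is.null(inb$prob) && (inb$prob < 0 || inb$prob > 1))
    msg <- c(msg, "inbreeding prob must lie in [0, 1]")
  if (object@scaleQ < 1) msg <- c(msg, "scaleQ must be >= 1")
  if (object@mu < 0 || object@rec < 0)
    msg <- c(msg, "mu and rec must be non-negative")
  if (length(msg)) msg else TRUE
})
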