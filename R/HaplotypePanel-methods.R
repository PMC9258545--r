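#' Accessors for HaplotypePanel
#'
#' @param x a \code{\linkS4class{HaplotypePanel}}.
#' @return \code{alleles}: the 0/1 haplotype matrix; \code{positions}: bp
#'   coordinates; \code{markerIds}, \code{individualIds}, \code{chromName}:
#'   identifier vectors; \code{nHaplotypes}, \code{nIndividuals},
#'   \code{nMarkers}: counts.
#' @name HaplotypePanel-accessors
NULL

#' @rdname HaplotypePanel-accessors
setMethod("alleles", "HaplotypePanel", function(x) x@alleles)

#' @rdname HaplotypePanel-accessors
setMethod("positions", "HaplotypePanel", function(x) x@positions)

#' @rdname HaplotypePanel-accessors
setMethod("markerIds", "HaplotypePanel", function(x) x@markerIds)

#' @rdname HaplotypePanel-accessors
setMethod("individualIds", "HaplotypePanel", function(x) x@individualIds)

#' @rdname HaplotypePanel-accessors
setMethod("chromName", "HaplotypePanel", function(x) x@chrom)

#' @rdname HaplotypePanel-accessors
setMethod("nHaplotypes", "HaplotypePanel", function(x) nrow(x@alleles))

#' @rdname HaplotypePanel-accessors
setMethod("nIndividuals", "HaplotypePanel",
          function(x) length(x@individualIds))

#' @rdname HaplotypePanel-accessors
setMethod("nMarkers", "HaplotypePanel", function(x) ncol(x@alleles))

setMethod("show", "HaplotypePanel", function(object) {
  p <- object@positions
  cat("HaplotypePanel:", nrow(object@alleles), "haplotypes (",
      length(object@individualIds), "diploids ) x",
      ncol(object@alleles), "markers\n")
  cat("  chrom", object@chrom,
      if (length(p)) sprintf("span %d-%d bp", as.integer(min(p)),
                             as.integer(max(p))) else "(empty)", "\n")
})

#' Derived allele frequency per marker
#'
#' @param x a \code{\linkS4class{HaplotypePanel}}.
#' @return Numeric vector, one frequency per marker (fraction of haplotypes
#'   carrying the derived allele).
#' @name derivedFreq
#' @export
setMethod("derivedFreq", "HaplotypePanel", function(x) {
  colMeans(x@alleles)
})

#' Collapse haplotypes into diploid genotype dosages
#'
#' Sums each individual's two haplotype rows into 0/1/2 derived-allele
#' counts, the representation used by genotype-based statistics (LD decay,
#' ROH calling).
#'
#' @param x a \code{\linkS4class{HaplotypePanel}}.
#' @return Integer matrix, individuals x markers, entries 0/1/2.
#' @name genotypeMatrix
#' @export
setMethod("genotypeMatrix", "HaplotypePanel", function(x) {
  a <- x@alleles
  g <- a[seq(1L, nrow(a), by = 2L), , drop = FALSE] +
       a[seq(2L, nrow(a), by = 2L), , drop = FALSE]
  rownames(g) <- x@individualIds
  colnames(g) <- x@markerIds
  g
})

#' Filter markers by minor allele frequency
#'
#' Keeps markers whose derived-allele frequency lies in
#' \code{[maf, 1 - maf]}, the polymorphism filter applied throughout the
#' pipeline.
#'
#' @param x a \code{\linkS4class{HaplotypePanel}}.
#' @param maf minor allele frequency threshold (default 0.05).
#' @return A \code{\linkS4class{HaplotypePanel}} restricted to passing
#'   markers.
#' @name mafFilter
#' @export
setMethod("mafFilter", "HaplotypePanel", function(x, maf = 0.05) {
  p <- colMeans(x@alleles)
  keep <- p >= maf & p <= 1 - maf
  x[which(keep), ]
})

#' Subset a HaplotypePanel
#'
#' \code{x[i, j]} keeps markers \code{i} and individuals \code{j} (both of
#' an individual's haplotypes travel together).
#'
#' @param x a \code{\linkS4class{HaplotypePanel}}.
#' @param i marker indices (numeric or logical).
#' @param j individual indices (numeric or logical).
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "HaplotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(ncol(x@alleles))
  if (missing(j)) j <- seq_len(length(x@individualIds))
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  hapRows <- as.vector(rbind(2L * j - 1L, 2L * j))
  new("HaplotypePanel",
      alleles = x@alleles[hapRows, i, drop = FALSE],
      positions = x@positions[i],
      markerIds = x@markerIds[i],
      individualIds = x@individualIds[j],
      chrom = x@chrom)
})
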