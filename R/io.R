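#' Read phased haplotypes from a VCF
#'
#' Parses a phased VCF of biallelic autosomal SNPs into a
#' \code{\linkS4class{HaplotypePanel}}, polarising alleles so that 1 is the
#' derived allele. Polarity comes from an ancestral-allele INFO annotation
#' (default \code{AA}): sites whose annotation matches REF keep their coding,
#' sites whose annotation matches ALT are flipped, and sites lacking the
#' annotation (or carrying one that matches neither allele) are dropped with
#' a message reporting the count.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param ancestralTag INFO key holding the ancestral allele (default
#'   \code{"AA"}).
#' @return A \code{\linkS4class{HaplotypePanel}}.
#' @details All GT fields must be phased (\code{|} separator); an unphased
#'   genotype raises an error naming the offending record. Non-biallelic or
#'   non-SNP records are skipped with a warning.
#' @export
readPhasedVcf <- function(path, ancestralTag = "AA") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp)) {
    warning(sum(!snp), " non-biallelic or non-SNP record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  unphased <- which(grepl("/", gt, fixed = TRUE))
  if (length(unphased)) {
    k <- (unphased[1] - 1L) %% nrow(gt) + 1L
    stop("unphased genotype at ", fix[k, "CHROM"], ":", fix[k, "POS"])
  }
  aa <- vcfR::extract.info(v, element = ancestralTag)
  aa <- toupper(sub(",.*", "", sub("\\|.*", "", as.character(aa))))
  polarisable <- snp & !is.na(aa) & (aa == ref | aa == alt)
  nDropped <- sum(snp & !polarisable)
  if (nDropped > 0)
    message(nDropped, " site(s) without usable '", ancestralTag,
            "' polarity dropped")
  keep <- which(polarisable)
  if (!length(keep)) stop("no polarisable biallelic SNPs in ", path)
  gt <- gt[keep, , drop = FALSE]
  flip <- aa[keep] == alt[keep]

  h1 <- substr(gt, 1L, 1L) == "1"
  h2 <- substr(gt, 3L, 3L) == "1"
  m <- length(keep)
  n <- ncol(gt)
  allelesMat <- matrix(0L, nrow = 2L * n, ncol = m)
  allelesMat[seq(1L, 2L * n, by = 2L), ] <- t(h1) + 0L
  allelesMat[seq(2L, 2L * n, by = 2L), ] <- t(h2) + 0L
  if (any(flip))
    allelesMat[, flip] <- 1L - allelesMat[, flip]

  pos <- as.numeric(fix[keep, "POS"])
  ord <- order(pos)
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[is.na(ids) | ids == "."]
  HaplotypePanel(allelesMat[, ord, drop = FALSE], positions = pos[ord],
                 markerIds = ids[ord],
                 individualIds = colnames(gt),
                 chrom = fix[keep[1], "CHROM"])
}

#' Write a HaplotypePanel as a phased VCF
#'
#' Emits a minimal phased VCF (GT-only, with an \code{AA} INFO annotation)
#' whose re-import through \code{\link{readPhasedVcf}} reproduces the allele
#' matrix exactly. Ancestral alleles are written as A, derived as C.
#'
#' @param panel a \code{\linkS4class{HaplotypePanel}}.
#' @param path output file path (plain text).
#' @return Invisibly, \code{path}.
#' @export
writePhasedVcf <- function(panel, path) {
  a <- alleles(panel)
  n <- nIndividuals(panel)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chromName(panel)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individualIds(panel)), collapse = "\t")
  )
  gtRows <- matrix("", nrow = n, ncol = nMarkers(panel))
  for (i in seq_len(n)) {
    gtRows[i, ] <- paste0(a[2L * i - 1L, ], "|", a[2L * i, ])
  }
  body <- paste(chromName(panel), as.integer(positions(panel)),
                markerIds(panel), "A", "C", ".", "PASS", "AA=A", "GT",
                sep = "\t")
  body <- paste(body, apply(gtRows, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a genetic map
#'
#' @param path path to a map file.
#' @param dialect \code{"two_column"}: whitespace-separated \code{bp cM}
#'   pairs; \code{"plink_map"}: PLINK \code{.map} columns
#'   (chrom, id, cM, bp).
#' @return A \code{\linkS4class{GeneticMap}}.
#' @details The cM column must be non-decreasing in bp; a violation raises
#'   an error reporting the first offending line.
#' @export
readGeneticMap <- function(path, dialect = c("two_column", "plink_map")) {
  dialect <- match.arg(dialect)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (dialect == "two_column") {
    if (ncol(tab) < 2) stop("two_column map needs 2 columns")
    bp <- as.numeric(tab[[1]]); cM <- as.numeric(tab[[2]])
  } else {
    if (ncol(tab) < 4) stop("plink_map needs 4 columns (chrom id cM bp)")
    bp <- as.numeric(tab[[4]]); cM <- as.numeric(tab[[3]])
  }
  if (anyNA(bp) || anyNA(cM)) stop("non-numeric values in map ", path)
  ord <- order(bp)
  bp <- bp[ord]; cM <- cM[ord]
  bad <- which(diff(cM) < 0)
  if (length(bad))
    stop("cM not monotone at line ", ord[bad[1] + 1L], " of ", path)
  GeneticMap(bp, cM)
}

#' Write a results table as TSV
#'
#' Writes one homogeneous collection of result records (a data.frame, or a
#' list of data.frames with identical columns) as a tab-separated file with
#' a header row. Floating-point columns are written at 6 significant digits,
#' so a written table re-read with \code{\link{readResultsTable}} reproduces
#' values to that precision.
#'
#' @param records data.frame, or list of structurally identical data.frames.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeResultsTable <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (!length(records)) stop("empty record list: pass a data.frame ",
                               "(possibly 0-row) to fix the columns")
    ok <- vapply(records, is.data.frame, logical(1))
    if (!all(ok)) stop("mixed record types: all records must be data.frames")
    proto <- lapply(records[[1]], class)
    same <- vapply(records, function(r)
      identical(lapply(r, class), proto), logical(1))
    if (!all(same)) stop("mixed record types: records differ in columns")
    df <- do.call(rbind, records)
  } else {
    stop("records must be a data.frame or a list of data.frames")
  }
  out <- df
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by \code{writeResultsTable}
#'
#' @param path path to a TSV file with a header row.
#' @return A data.frame.
#' @export
readResultsTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
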