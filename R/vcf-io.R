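#' Write a cohort as minimal VCF v4.2 plus a samples TSV
#'
#' GT-only records (\code{0/0}, \code{0/1}, \code{1/1}, \code{./.}); the
#' companion TSV carries sample, label and sex columns.
#'
#' @param cohort a \code{CohortGenotypes}.
#' @param vcfPath output VCF path (uncompressed).
#' @param samplesPath output samples TSV path (omit to skip).
#' @export
writeCohortVcf <- function(cohort, vcfPath, samplesPath = NULL) {
  v <- cohortVariants(cohort)
  geno <- genotypes(cohort)
  gtStr <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
  ok <- !is.na(geno)
  gt[ok] <- gtStr[geno[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t"))
  body <- paste(as.character(seqnames(v)), start(v), v$id, v$ref, v$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcfPath)
  if (!is.null(samplesPath))
    write.table(cohortSamples(cohort), samplesPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(vcfPath)
}

#' Read a cohort from VCF plus a samples TSV
#'
#' Parses biallelic GT records through \pkg{vcfR}; multi-allelic records
#' raise an error instructing prior decomposition.
#'
#' @param vcfPath VCF path (gzip accepted by \pkg{vcfR}).
#' @param samplesPath samples TSV path (columns sample, label, sex).
#' @return a \code{CohortGenotypes}.
#' @export
readCohortVcf <- function(vcfPath, samplesPath) {
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic record found; decompose to biallelic records first")
  gtChar <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- matrix(NA_integer_, nrow = nrow(gtChar), ncol = ncol(gtChar))
  for (code in list(c("0/0", 0L), c("0|0", 0L), c("0/1", 1L), c("1/0", 1L),
                    c("0|1", 1L), c("1|0", 1L), c("1/1", 2L), c("1|1", 2L)))
    dosage[gtChar == code[[1]]] <- as.integer(code[[2]])
  samples <- read.table(samplesPath, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  samples <- samples[match(colnames(gtChar), samples$sample), ]
  variants <- GRanges(fix[, "CHROM"],
                      IRanges(as.integer(fix[, "POS"]), width = 1L))
  variants$id <- fix[, "ID"]
  variants$ref <- fix[, "REF"]
  variants$alt <- fix[, "ALT"]
  CohortGenotypes(samples, variants, dosage)
}
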