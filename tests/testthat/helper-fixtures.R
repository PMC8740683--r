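## Small in-code fixtures shared across test files.

## a BEDPE file with the given rows (each row a character line)
writeBedpe <- function(lines) {
  path <- tempfile(fileext = ".bedpe")
  writeLines(lines, path)
  path
}

## tiny cohort: explicit dosage matrix, variants at given 1-based positions
toyCohort <- function(dosage, pos, chrom = "chr1",
                      labels = NULL, sex = NULL) {
  nS <- ncol(dosage)
  if (is.null(labels)) labels <- rep(c("case", "control"), length.out = nS)
  if (is.null(sex)) sex <- rep(c("M", "F"), length.out = nS)
  samples <- data.frame(sample = sprintf("S%02d", seq_len(nS)),
                        label = labels, sex = sex)
  v <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  v$id <- sprintf("%s:%d:A:G", chrom, pos)
  v$ref <- "A"
  v$alt <- "G"
  CohortGenotypes(samples, v, dosage)
}

## minimal two-gene network: gene gA linked to an open distal anchor tile,
## gene gB with no loop
toyNetwork <- function() {
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(100001, 300001),
                                                   width = 20000),
                                  strand = c("+", "+"))
  names(genes) <- c("gA", "gB")
  loops <- S4Vectors::Pairs(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(98001, 103000)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(150001, 155000)),
    q_value = 0.001)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150101, 150400))
  res <- tileAndClassify(loops, peaks)
  prom <- makePromoters(genes)
  buildNetwork(loops, prom, res, genes, peaks)
}

## independent upper Poisson tail by term-wise series summation
poisTailOracle <- function(k, lambda) {
  if (k == 0) return(1)
  j <- seq(k, max(2 * k, 200) + ceiling(10 * lambda))
  sum(exp(-lambda + j * log(lambda) - lgamma(j + 1)))
}

## independent upper hypergeometric tail by enumeration
hyperTailOracle <- function(ov, nTerm, nUniv, nTarg) {
  tot <- choose(nUniv, nTarg)
  sum(vapply(ov:min(nTerm, nTarg), function(x)
    choose(nTerm, x) * choose(nUniv - nTerm, nTarg - x) / tot, numeric(1)))
}
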