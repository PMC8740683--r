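#' Run the whole analysis on a synthetic dataset
#'
#' Generates every input under \code{cfg} (writing them to
#' \code{file.path(outdir, "data")} in their exchange formats), then runs
#' the full pipeline: network construction from the written files,
#' per-individual openness scoring, per-RE differential-openness tests,
#' gene-level aggregation, coding burden testing, and combined
#' coding+noncoding gene-set ranking. Optionally fits the GWAS enrichment
#' model on the generated summary statistics. Result tables and a
#' ground-truth comparison report are written under \code{outdir}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param outdir output directory.
#' @param enrichment fit the GWAS enrichment model (adds a Bayes-factor
#'   table; the grid is deliberately small for turnaround).
#' @param fdr gene-level FDR threshold.
#' @return list with all result tables and the comparison report.
#' @export
runPipeline <- function(cfg = simConfig(), outdir = tempfile("revarnet"),
                        enrichment = FALSE, fdr = 0.01) {
  datadir <- file.path(outdir, "data")
  sim <- genAll(cfg, outdir = datadir)

  ## --- rebuild everything from the written files (exercises the I/O) ----
  loops <- readLoops(file.path(datadir, "loops.bedpe"), qThreshold = 0.01)
  peaks <- readBed(file.path(datadir, "peaks.bed"))
  genes <- readGenesBed(file.path(datadir, "genes.bed"))
  silencers <- readBed(file.path(datadir, "silencers.bed"))
  fpkm <- readExpression(file.path(datadir, "expression.tsv"))
  cohort <- readCohortVcf(file.path(datadir, "cohort.vcf"),
                          file.path(datadir, "samples.tsv"))
  goSets <- readGMT(file.path(datadir, "go.gmt"))

  res <- tileAndClassify(loops, peaks, cfg$tile_width)
  prom <- makePromoters(genes)
  network <- buildNetwork(loops, prom, res, genes, peaks)
  writeNetwork(network, file.path(outdir, "network"))
  quant <- expressionQuantiles(network, fpkm)

  ## --- differential openness -------------------------------------------
  baseline <- buildBaseline(cohort, mode = "major_allele")
  scored <- regulatoryElements(network)
  om <- scoreCohort(cohort, scored, sim$scorer, baseline)
  reRes <- reTest(om, cohortSamples(cohort)$label)
  geneRes <- geneCombine(network, reRes, k = 5, fdr = fdr)

  ## --- coding burden ----------------------------------------------------
  annTab <- read.table(file.path(datadir, "coding_scores.tsv"),
                       header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ann <- averageScores(annTab)
  rare <- filterRareNonsyn(cohort, ann)
  g <- burdenMatrix(cohort, rare, geneUniverse = names(genes))
  burdenRes <- burdenTest(g, cohortSamples(cohort)$label)

  ## --- gene-set combination --------------------------------------------
  codingP <- setNames(burdenRes$p, burdenRes$gene)
  targets <- geneRes$gene[geneRes$significant]
  terms <- if (length(targets))
    termAnalysis(goSets, targets, codingP) else NULL

  report <- groundTruthReport(sim$truth, geneRes, burdenRes, terms)

  bf <- NULL
  if (enrichment && !is.null(sim$sumstats)) {
    grid <- defaultGrid(cfg$gwas$n,
                        theta0 = c(0.005, 0.01, 0.02),
                        theta = c(0, 0.05, 0.1, 0.2),
                        sigma0sqScaled = cfg$gwas$sigma0sq * cfg$gwas$n,
                        sigmasqMult = 0)
    fit <- fitGrid(sim$sumstats$stats, sim$sumstats$ld,
                   sim$snpAnnotation, grid)
    bf <- data.frame(model = c("M11", "M1"),
                     bf = c(bayesFactor(fit, "M11"),
                            bayesFactor(fit, "M1")))
    write.table(bf, file.path(outdir, "enrichment_bf.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  write.table(reRes, file.path(outdir, "re_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(geneRes, file.path(outdir, "gene_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(burdenRes, file.path(outdir, "burden_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(terms))
    write.table(terms, file.path(outdir, "term_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  utils::write.csv(quant, file.path(outdir, "expression_quantiles.csv"))
  jsonlite::write_json(report, file.path(outdir, "ground_truth_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  list(network = network, quantiles = quant, reTests = reRes,
       geneTests = geneRes, burdenTests = burdenRes, terms = terms,
       enrichmentBF = bf, report = report, truth = sim$truth,
       outdir = outdir)
}

## compare pipeline calls against the generator's planted truth
groundTruthReport <- function(truth, geneRes, burdenRes, terms) {
  sigGenes <- geneRes$gene[geneRes$significant]
  planted <- truth$planted_gene
  recovered <- intersect(planted, sigGenes)
  burdenRank <- rank(burdenRes$p, ties.method = "average")
  names(burdenRank) <- burdenRes$gene
  pb <- intersect(truth$planted_burden_genes, names(burdenRank))
  topDecile <- if (length(pb))
    mean(burdenRank[pb] <= 0.1 * nrow(burdenRes)) else NA_real_
  termRank <- if (!is.null(terms) && !is.na(truth$planted_term) &&
                  truth$planted_term %in% terms$term)
    match(truth$planted_term, terms$term) else NA_integer_
  list(
    n_significant_genes = length(sigGenes),
    n_planted_genes = length(planted),
    n_planted_recovered = length(recovered),
    planted_gene_recovery = if (length(planted))
      length(recovered) / length(planted) else NA_real_,
    burden_top_decile_fraction = topDecile,
    planted_term_rank = termRank)
}
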