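test_that("major-allele baseline follows allele frequency with a ref tie rule", {
  ## afs: 0.8 (alt is major), 0.2, exactly 0.5
  dosage <- rbind(c(2L, 2L, 2L, 1L, 1L), # af 0.8
                  c(1L, 1L, 0L, 0L, 0L), # af 0.2
                  c(1L, 1L, 1L, 1L, 1L)) # af 0.5
  coh <- toyCohort(dosage, pos = c(100, 200, 300))
  expect_equal(cohortVariants(coh)$af, c(0.8, 0.2, 0.5))
  base <- buildBaseline(coh, mode = "major_allele")
  expect_equal(base, "chr1:100:A:G")
  expect_equal(buildBaseline(coh, mode = "reference"), character(0))
})

test_that("multi-allelic records are rejected with decomposition advice", {
  v <- GRanges("chr1", IRanges(100, width = 1))
  v$id <- "chr1:100:A:G,T"; v$ref <- "A"; v$alt <- "G,T"
  samples <- data.frame(sample = "S1", label = "case", sex = "M")
  expect_error(CohortGenotypes(samples, v, matrix(1L, 1, 1)), "decompose")
})

test_that("linear scorer adds planted weights exactly", {
  sc <- LinearScorer(base = c(re1 = 2), weights = c("chr1:150:A:G" = 0.7))
  expect_equal(scoreRE(sc, "re1", character(0)), 2)
  expect_equal(scoreRE(sc, "re1", "chr1:150:A:G"), 2.7)
  expect_equal(scoreRE(sc, "re1", "chr1:999:A:G"), 2)  # unknown variant: 0
  expect_error(scoreRE(sc, "re9", character(0)), "undefined")
})

test_that("cohort scoring matches the scorer and flags nonbaseline", {
  ## RE spans 1-based [101, 1100]; variants at 150 (w=.7) and 600 (w=.25)
  res <- GRanges("chr1", IRanges(101, 1100))
  res$re_id <- "re1"
  dosage <- rbind(c(1L, 0L, 0L, NA), # planted variant carried by sample 1
                  c(0L, 2L, 0L, 0L)) # second variant carried by sample 2
  coh <- toyCohort(dosage, pos = c(150, 600))
  sc <- LinearScorer(base = c(re1 = 2),
                     weights = c("chr1:150:A:G" = 0.7, "chr1:600:A:G" = 0.25))
  expect_message(om <- scoreCohort(coh, res, sc, baseline = character(0)),
                 "1 missing")
  expect_equal(unname(opennessScores(om)[, "re1"]), c(2.7, 2.25, 2, 2))
  expect_equal(unname(opennessBaseline(om)), 2)
  expect_equal(unname(nonbaselineFlags(om)[, "re1"]),
               c(TRUE, TRUE, FALSE, FALSE))

  ## with the planted allele in the baseline set, the carrier IS baseline
  om2 <- suppressMessages(
    scoreCohort(coh, res, sc, baseline = "chr1:150:A:G"))
  expect_equal(unname(opennessBaseline(om2)), 2.7)
  expect_equal(unname(nonbaselineFlags(om2)[, "re1"]),
               c(FALSE, TRUE, TRUE, FALSE))
  ## the missing genotype (sample 4, variant 1) imputes to the baseline
  ## allele, which now carries the alt: score = 2.7
  expect_equal(unname(opennessScores(om2)[4, "re1"]), 2.7)
})

test_that("generic scorer path agrees with the linear fast path", {
  set.seed(11)
  res <- GRanges("chr1", IRanges(c(101, 2101), width = 1000))
  res$re_id <- c("reA", "reB")
  pos <- c(150, 600, 2200, 2900)
  dosage <- matrix(rbinom(4 * 6, 2, 0.3), nrow = 4)
  coh <- toyCohort(dosage, pos = pos)
  w <- setNames(c(0.5, 0.25, 0.375, 0), sprintf("chr1:%d:A:G", pos))
  lin <- LinearScorer(base = c(reA = 1, reB = 3), weights = w)
  ## same scorer expressed as an opaque function
  setClass("FnScorer", representation(f = "function"),
           where = environment())
  setMethod("scoreRE", "FnScorer", function(scorer, reId, variantIds)
    scorer@f(reId, variantIds), where = environment())
  fn <- new("FnScorer", f = function(reId, ids)
    unname(c(reA = 1, reB = 3)[reId] + sum(w[intersect(ids, names(w))])))
  base <- buildBaseline(coh)
  omLin <- scoreCohort(coh, res, lin, base)
  omFn <- scoreCohort(coh, res, fn, base)
  expect_equal(opennessScores(omLin), opennessScores(omFn))
  expect_equal(opennessBaseline(omLin), opennessBaseline(omFn))
})

test_that("RE tests reproduce the hypergeometric tail and fall back sanely", {
  ## 20 samples, 10 cases; one RE where 3 cases and 0 controls deviate
  score <- matrix(0, nrow = 20, ncol = 3,
                  dimnames = list(NULL, c("reA", "reB", "reC")))
  score[1:3, "reA"] <- 0.5
  ## reB: nonbaseline in both groups with varying scores
  score[c(1:4, 11:14), "reB"] <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  om <- new("OpennessMatrix", score = score, baseline = c(reA = 0, reB = 0, reC = 0),
            nonbaseline = abs(score) > 1e-9, tolerance = 1e-9,
            nImputed = 0)
  labels <- rep(c("case", "control"), each = 10)
  rr <- reTest(om, labels)
  ## one-sided exact p: C(10,3)/C(20,3) = 120/1140
  expect_equal(rr$p_fisher[rr$re_id == "reA"], 120 / 1140,
               tolerance = 1e-12)
  expect_equal(rr$flag, c("fisher_only", "ok", "skipped"))
  expect_equal(rr$p_combined[rr$re_id == "reA"],
               rr$p_fisher[rr$re_id == "reA"])
  expect_equal(rr$p_combined[rr$re_id == "reC"], 1)
  ## the combined test applies Fisher's method to both components
  rB <- rr[rr$re_id == "reB", ]
  expect_equal(rB$p_combined,
               pchisq(-2 * (log(rB$p_fisher) + log(rB$p_wilcoxon)), 4,
                      lower.tail = FALSE), tolerance = 1e-12)
  expect_error(reTest(om, rep("case", 20)), "nonempty")
})

test_that("gene combination takes the k smallest RE p-values", {
  net <- toyNetwork()
  ed <- networkEdges(net)
  gA_res <- unique(ed$re_id[ed$gene == "gA"])   # 5 tiles + promoter
  ps <- c(.001, .002, .003, .004, .005, .9)
  rr <- data.frame(re_id = gA_res, p_combined = ps[seq_along(gA_res)],
                   flag = "ok")
  out <- geneCombine(net, rr, k = 5, fdr = 0.01)
  gA <- out[out$gene == "gA", ]
  expect_equal(gA$n_re, 5L)
  expect_equal(gA$p_combined, fisherMethod(c(.001, .002, .003, .004, .005)),
               tolerance = 1e-12)
  ## a single-RE gene reduces to the RE p-value, any k
  rr1 <- data.frame(re_id = "prom:gB", p_combined = 0.042, flag = "ok")
  out1 <- geneCombine(net, rr1, k = Inf)
  expect_equal(out1$p_combined, 0.042)
  ## all p = 1: BH q = 1, nothing significant
  rrAll <- data.frame(re_id = gA_res, p_combined = 1, flag = "ok")
  outAll <- geneCombine(net, rrAll)
  expect_equal(outAll$q_value, rep(1, nrow(outAll)))
  expect_false(any(outAll$significant))
  ## skipped REs never contribute
  rrSkip <- rbind(rr, data.frame(re_id = "prom:gB", p_combined = 1e-9,
                                 flag = "skipped"))
  expect_false("gB" %in% geneCombine(net, rrSkip)$gene)
})

test_that("baseline construction is blind to case/control labels", {
  sim <- genCohort(simConfig(seed = 8, n_cases = 30L, n_controls = 20L),
                   reVariants = NULL,
                   genes = genLandscape(simConfig(seed = 8))$genes)
  coh <- sim$cohort
  flipped <- coh
  flipped@samples$label <- rev(coh@samples$label)
  expect_equal(buildBaseline(coh), buildBaseline(flipped))
})

test_that("larger carrier-frequency gaps give smaller planted Fisher p", {
  meanP <- vapply(c(0.05, 0.10, 0.15), function(cfCase) {
    ps <- vapply(1:5, function(s) {
      cfg <- simConfig(seed = s, n_genes = 60L, n_loops = 60L,
                       planted_re_count = 4L, planted_res_per_gene = 1L,
                       planted_burden_genes = 0L,
                       carrier_freq_case = cfCase)
      sim <- genAll(cfg)
      coh <- sim$cohort
      om <- scoreCohort(coh, regulatoryElements(sim$network), sim$scorer,
                        buildBaseline(coh))
      rr <- reTest(om, cohortSamples(coh)$label)
      mean(rr$p_fisher[rr$re_id %in% sim$truth$planted_re])
    }, numeric(1))
    mean(ps)
  }, numeric(1))
  expect_true(all(diff(meanP) < 0))
})

test_that("external-control augmentation is stratified and deterministic", {
  cfg <- simConfig(seed = 12, n_cases = 40L, n_controls = 20L,
                   planted_re_count = 0L, planted_burden_genes = 0L,
                   male_frac = 0.8)
  land <- genLandscape(cfg)
  coh <- genCohort(cfg, genes = land$genes)$cohort
  poolCfg <- simConfig(seed = 13, n_cases = 0L, n_controls = 300L,
                       planted_re_count = 0L, planted_burden_genes = 0L,
                       male_frac = 0.5)
  pool <- genCohort(poolCfg, genes = land$genes)$cohort

  aug <- augmentControls(coh, pool, n = 100L, seed = 99L)
  s <- cohortSamples(aug)
  expect_equal(sum(s$label == "case"), 40L)
  expect_equal(sum(s$label == "control"), 100L)
  ## sex counts follow the case ratio by largest remainder
  caseM <- sum(s$sex[s$label == "case"] == "M") / 40
  ctrlM <- sum(s$sex[s$label == "control"] == "M")
  expect_equal(ctrlM, round(100 * caseM))
  ## variants absent from the original cohort are gone
  origCarried <- rownames(genotypes(coh))[
    rowSums(genotypes(coh) >= 1, na.rm = TRUE) > 0]
  expect_true(all(rownames(genotypes(aug)) %in% origCarried))
  ## determinism
  aug2 <- augmentControls(coh, pool, n = 100L, seed = 99L)
  expect_identical(cohortSamples(aug2)$sample, cohortSamples(aug)$sample)
  expect_identical(genotypes(aug2), genotypes(aug))
  expect_error(augmentControls(coh, pool, n = 400L, seed = 1L), "too few")
})
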