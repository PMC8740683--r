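#' Simulation configuration
#'
#' Default study conditions for the synthetic generators: a cohort of 268
#' cases and 133 controls (the shape of the whole-genome study the pipeline
#' is designed for), a four-chromosome toy genome, loop anchors 5 kb wide
#' tiled into 1-kb REs, planted case-enriched openness alleles (effect
#' weight 0.7, carrier frequencies 0.15 in cases vs 0.03 in controls, 20
#' planted REs), planted high-burden genes with case-private rare coding
#' SNVs, one GO term seeded with the planted genes, and GWAS summary
#' statistics generated under the spike-and-slab effect-size prior.
#'
#' @param seed global seed; every generator derives its own stream from it.
#' @param ... overrides for any configuration field (see Details in the
#'   package vignette).
#' @return a named list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    ## cohort
    n_cases = 268L, n_controls = 133L, male_frac = 0.8,
    ## genome geometry
    n_chrom = 4L, gene_spacing = 150000L, gene_margin = 12000000L,
    ## landscape
    n_genes = 300L, n_loops = 300L, anchor_width = 5000L,
    tile_width = 1000L, fraction_open = 0.6, frac_noise_q = 0.1,
    silencer_count = 60L,
    ## openness model
    re_weight_frac = 0.3, n_re_variants_max = 3L,
    background_weights = c(4:12) / 16,
    planted_re_count = 20L, planted_res_per_gene = 2L,
    planted_effect_weight = 0.7,
    carrier_freq_case = 0.15, carrier_freq_control = 0.03,
    ## coding burden
    planted_burden_genes = 10L, n_burden_snvs = 8L,
    burden_carrier_freq = 0.02, coding_bg_mean = 3,
    ## gene sets
    go_n_terms = 25L, go_size_range = c(10L, 60L),
    ## GWAS
    gwas = list(n = 20000L, p_snps = 500L, theta0 = 0.01, theta = 0.1,
                sigma0sq = 4.5e-4, sigmasq = 0, ld_block = 25L,
                ld_rho = 0.3))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, over)
  }
  genesPerChrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  cfg$chrom_len <- genesPerChrom * cfg$gene_spacing + 2 * cfg$gene_margin
  cfg$chroms <- paste0("chr", seq_len(cfg$n_chrom))
  class(cfg) <- c("SimConfig", "list")
  cfg
}

#' Generate the regulatory landscape
#'
#' Produces gene models, chromatin loops (with ~10\% of q-values above the
#' 0.01 filter to exercise loop filtering), ATAC peaks covering a
#' configurable fraction of anchor tiles, silencers, and an FPKM table in
#' which genes intended to be OpenLoop are drawn from a higher log-normal
#' than NonOpenLoop/NoLoop genes.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{genes}, \code{loops}, \code{peaks},
#'   \code{silencers} (\code{GRanges}/\code{Pairs}), \code{fpkm} (named
#'   numeric) and \code{intended_category} (named character).
#' @export
genLandscape <- function(cfg) {
  withSeed(stageSeed(cfg$seed, "landscape"), {
    n <- cfg$n_genes
    perChrom <- ceiling(n / cfg$n_chrom)
    slot <- (seq_len(n) - 1L) %% perChrom
    chrom <- cfg$chroms[((seq_len(n) - 1L) %/% perChrom) + 1L]
    tssPos <- cfg$gene_margin + slot * cfg$gene_spacing +
      sample(0:50000, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    glen <- sample(5000:30000, n, replace = TRUE)
    gstart <- ifelse(strand == "+", tssPos, tssPos - glen + 1L)
    genes <- GRanges(chrom, IRanges(gstart, width = glen), strand = strand)
    names(genes) <- sprintf("G%03d", seq_len(n))
    genes$name <- names(genes)

    ## loops: each loop ties a gene promoter anchor to a distal anchor;
    ## ~70% of genes are loopable with at most two loops each, so the
    ## multiplicity a gene contributes to the top-k combination stays in a
    ## realistic range and a NoLoop class remains
    loopable <- sample(n, round(0.7 * n))
    pool <- sample(rep(loopable, 2L))
    if (cfg$n_loops > length(pool))
      stop("n_loops too large for the loopable gene pool")
    tgt <- pool[seq_len(cfg$n_loops)]
    aw <- cfg$anchor_width
    ## anchors live on a fixed aw-sized genomic grid (as loop callers bin
    ## the genome), so anchors from different loops either coincide or are
    ## disjoint — never partially overlapping near-duplicates
    snap <- function(x) (pmax(x, 1L) %/% aw) * aw + 1L
    pStart <- snap(tssPos[tgt] - 1000L)
    off <- sample(20000:300000, cfg$n_loops, replace = TRUE) *
      sample(c(-1L, 1L), cfg$n_loops, replace = TRUE)
    dStart <- snap(tssPos[tgt] + off)
    noise <- runif(cfg$n_loops) < cfg$frac_noise_q
    q <- ifelse(noise, runif(cfg$n_loops, 0.011, 0.2),
                runif(cfg$n_loops, 0, 0.0099))
    a1 <- GRanges(chrom[tgt], IRanges(pmax(pStart, 1L), width = aw))
    a2 <- GRanges(chrom[tgt], IRanges(dStart, width = aw))
    loops <- Pairs(a1, a2, q_value = q)

    ## peaks: accessibility is regional — an anchor is open with prob
    ## fraction_open, and tiles inside an open anchor are open w.p. 0.7
    nt <- aw %/% cfg$tile_width
    tileStart <- rep(dStart, each = nt) +
      rep(seq_len(nt) - 1L, cfg$n_loops) * cfg$tile_width
    tileChrom <- rep(chrom[tgt], each = nt)
    anchorOpen <- runif(cfg$n_loops) < cfg$fraction_open
    openTile <- rep(anchorOpen, each = nt) &
      runif(length(tileStart)) < 0.7
    keepLoop <- rep(!noise, each = nt)
    peaks <- GRanges(tileChrom[openTile],
                     IRanges(tileStart[openTile] + 200L, width = 500L))
    ## promoter peaks scale with the overall openness level so that
    ## fraction_open = 0 really means a fully closed landscape
    promOpen <- runif(n) < 0.8 * cfg$fraction_open
    peaks <- sort(c(peaks,
                    GRanges(chrom[promOpen],
                            IRanges(pmax(tssPos[promOpen] - 1500L, 1L),
                                    width = 600L))))

    ## intended categories from retained (q < 0.01) loops
    anyOpen <- tapply(openTile & keepLoop, rep(seq_len(cfg$n_loops), each = nt),
                      any)
    hasLoop <- tapply(!noise, tgt, any)
    hasOpen <- tapply(anyOpen & !noise, tgt, any)
    cat <- setNames(rep("NoLoop", n), names(genes))
    linked <- as.integer(names(hasLoop))[hasLoop]
    openg <- as.integer(names(hasOpen))[hasOpen]
    cat[linked] <- "NonOpenLoop"
    cat[openg] <- "OpenLoop"

    fpkm <- numeric(n)
    for (i in seq_len(n)) {
      fpkm[i] <- switch(cat[i],
        OpenLoop = rlnorm(1, meanlog = 2.0, sdlog = 1),
        NonOpenLoop = if (runif(1) < 0.7) 0 else rlnorm(1, 0.3, 1),
        NoLoop = if (runif(1) < 0.5) 0 else rlnorm(1, 0.8, 1))
    }
    fpkm <- setNames(round(fpkm, 3), names(genes))

    sil <- GRanges(sample(cfg$chroms, cfg$silencer_count, replace = TRUE),
                   IRanges(sample(cfg$gene_margin:(cfg$chrom_len - 2000L),
                                  cfg$silencer_count), width = 1500L))
    ## make some silencers hit distal anchors so linkage stats are nonzero
    hit <- sample(which(!noise), min(20L, sum(!noise)))
    sil <- sort(c(sil, GRanges(chrom[tgt[hit]],
                               IRanges(dStart[hit] + 100L, width = 800L))))
    list(genes = genes, loops = loops, peaks = peaks, silencers = sil,
         fpkm = fpkm, intended_category = cat)
  })
}

#' Generate the toy openness model with planted effects
#'
#' Chooses \code{planted_re_count} loop-anchor REs (one per distinct target
#' gene) and plants in each a single variant with additive effect weight
#' \code{planted_effect_weight}; every RE additionally receives 1 to
#' \code{n_re_variants_max} background variants with exactly binary-
#' representable weights so that nonbaseline individuals exist everywhere.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param network the \code{RETGNetwork} built from the generated landscape.
#' @return list with \code{scorer} (a \code{\link{LinearScorer}}),
#'   \code{variantSpec} (data.frame chrom, pos, ref, alt, weight, planted,
#'   re_id) and \code{truth} (planted RE ids and target genes).
#' @export
genOpennessModel <- function(cfg, network) {
  withSeed(stageSeed(cfg$seed, "openness_model"), {
    el <- regulatoryElements(network)
    anchors <- el[el$source == "loop_anchor"]
    ed <- networkEdges(network)
    linked <- ed[!is.na(ed$loop), ]

    ## planted REs: grouped on target genes, planted_res_per_gene REs per
    ## gene — a disease gene is typically perturbed through several of its
    ## REs, which is what the top-k Fisher combination aggregates
    planted_re <- character(0); planted_gene <- character(0)
    if (cfg$planted_re_count > 0) {
      perGene <- cfg$planted_res_per_gene
      nGenes <- ceiling(cfg$planted_re_count / perGene)
      byGene <- split(unique(linked[, c("re_id", "gene")])$re_id,
                      unique(linked[, c("re_id", "gene")])$gene)
      byGene <- byGene[lengths(byGene) >= perGene]
      if (length(byGene) < nGenes)
        stop("not enough multi-RE genes to plant")
      genesPick <- sample(names(byGene), nGenes)
      picks <- lapply(genesPick, function(g) sample(byGene[[g]], perGene))
      planted_re <- unique(unlist(picks))
      planted_gene <- genesPick
    }

    mkVariants <- function(res, weights, planted) {
      pos <- start(res) + vapply(width(res), function(w)
        sample(seq(10L, w - 10L), 1L), integer(1))
      data.frame(chrom = as.character(seqnames(res)), pos = pos,
                 ref = sample(c("A", "C", "G", "T"), length(res), TRUE),
                 alt = rep(NA_character_, length(res)),
                 weight = weights, planted = rep(planted, length.out = length(res)),
                 re_id = res$re_id, stringsAsFactors = FALSE)
    }
    ## effects are sparse: only a seeded subset of REs carries nonzero
    ## weights, so most individuals score at the baseline genome-wide.
    ## Weighted background REs get 2+ variants with distinct weights so
    ## per-individual scores vary (the rank-sum test needs variability);
    ## planted REs carry exactly one variant, the planted effect.
    isPlanted <- anchors$re_id %in% planted_re
    nW <- round(cfg$re_weight_frac * sum(!isPlanted))
    wIdx <- sample(which(!isPlanted), nW)
    nBg <- sample(2:max(2L, cfg$n_re_variants_max), nW, replace = TRUE)
    bg <- mkVariants(rep(anchors[wIdx], nBg),
                     sample(cfg$background_weights, sum(nBg), replace = TRUE),
                     FALSE)
    ## remaining anchors get one weightless variant each (scored but inert)
    inert <- setdiff(which(!isPlanted), wIdx)
    spec <- rbind(bg, mkVariants(anchors[inert], rep(0, length(inert)),
                                 FALSE))
    if (length(planted_re)) {
      pres <- anchors[match(planted_re, anchors$re_id)]
      spec <- rbind(spec, mkVariants(pres,
                                     rep(cfg$planted_effect_weight,
                                         length(pres)), TRUE))
    }
    ## alt allele differs from ref; drop duplicate positions
    alts <- c(A = "G", C = "T", G = "A", T = "C")
    spec$alt <- unname(alts[spec$ref])
    spec <- spec[!duplicated(paste(spec$chrom, spec$pos)), ]
    spec$id <- sprintf("%s:%d:%s:%s", spec$chrom, spec$pos, spec$ref,
                       spec$alt)

    base <- setNames(round(runif(length(el), 1, 5), 3), el$re_id)
    scorer <- LinearScorer(base, setNames(spec$weight, spec$id))
    list(scorer = scorer, variantSpec = spec,
         truth = list(planted_re = planted_re,
                      planted_gene = planted_gene,
                      planted_variant = spec$id[spec$planted]))
  })
}

#' Generate the case/control cohort genotypes
#'
#' Biallelic SNVs under Hardy-Weinberg equilibrium with allele frequencies
#' from Beta(0.5, 5) truncated to `[0.001, 0.5]`. Variants flagged planted get
#' group-specific carrier frequencies (\code{carrier_freq_case} in cases,
#' \code{carrier_freq_control} in controls). Coding variants are placed in
#' gene bodies; planted burden genes additionally receive case-private rare
#' SNVs carried at \code{burden_carrier_freq} among cases.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param reVariants \code{variantSpec} from \code{\link{genOpennessModel}}
#'   (may be \code{NULL} for a cohort without RE variants).
#' @param genes named \code{GRanges} of gene bodies (for coding variants;
#'   may be \code{NULL}).
#' @param plantedBurdenGenes character vector of genes seeded with
#'   case-private burden SNVs.
#' @return list with \code{cohort} (a \code{CohortGenotypes}) and
#'   \code{coding} (data.frame of coding-variant annotations: id, gene,
#'   consequence, planted).
#' @export
genCohort <- function(cfg, reVariants = NULL, genes = NULL,
                      plantedBurdenGenes = character(0)) {
  withSeed(stageSeed(cfg$seed, "cohort"), {
    nS <- cfg$n_cases + cfg$n_controls
    labels <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
    sex <- ifelse(runif(nS) < cfg$male_frac, "M", "F")
    samples <- data.frame(
      sample = sprintf("S%04d", seq_len(nS)), label = labels, sex = sex,
      stringsAsFactors = FALSE)
    isCase <- labels == "case"

    truncBeta <- function(k) pmin(pmax(rbeta(k, 0.5, 5), 0.001), 0.5)
    hwe <- function(f) {
      matrix(rbinom(length(f) * nS, 2L, rep(f, nS)), nrow = length(f))
    }

    rows <- list(); genos <- list()
    if (!is.null(reVariants) && nrow(reVariants)) {
      rv <- reVariants
      g <- matrix(0L, nrow(rv), nS)
      bg <- !rv$planted
      if (any(bg)) g[bg, ] <- hwe(truncBeta(sum(bg)))
      if (any(rv$planted)) {
        pl <- which(rv$planted)
        cf <- ifelse(rep(isCase, each = length(pl)),
                     cfg$carrier_freq_case, cfg$carrier_freq_control)
        g[pl, ] <- matrix(as.integer(runif(length(pl) * nS) <
                                       cf), nrow = length(pl))
      }
      rows$re <- data.frame(chrom = rv$chrom, pos = rv$pos, ref = rv$ref,
                            alt = rv$alt, id = rv$id,
                            stringsAsFactors = FALSE)
      genos$re <- g
    }

    coding <- NULL
    if (!is.null(genes)) {
      nG <- length(genes)
      nBg <- 1L + rpois(nG, cfg$coding_bg_mean)
      gi <- rep(seq_len(nG), nBg)
      pos <- start(genes)[gi] + vapply(width(genes)[gi], function(w)
        sample(seq(5L, w - 5L), 1L), integer(1))
      cons <- sample(c("nonsynonymous", "synonymous"), length(gi), TRUE,
                     prob = c(0.7, 0.3))
      f <- runif(length(gi), 0.0005, 0.008)
      ## a few common nonsynonymous variants to exercise the rare filter
      common <- runif(length(gi)) < 0.05
      f[common] <- runif(sum(common), 0.05, 0.2)
      gcode <- hwe(f)
      planted <- rep(FALSE, length(gi))

      if (length(plantedBurdenGenes)) {
        pbi <- match(plantedBurdenGenes, names(genes))
        stopifnot(!anyNA(pbi))
        k <- cfg$n_burden_snvs
        gi2 <- rep(pbi, each = k)
        pos2 <- start(genes)[gi2] + vapply(width(genes)[gi2], function(w)
          sample(seq(5L, w - 5L), 1L), integer(1))
        g2 <- matrix(0L, length(gi2), nS)
        g2[, isCase] <- matrix(as.integer(
          runif(length(gi2) * sum(isCase)) < cfg$burden_carrier_freq),
          nrow = length(gi2))
        gi <- c(gi, gi2); pos <- c(pos, pos2)
        cons <- c(cons, rep("nonsynonymous", length(gi2)))
        gcode <- rbind(gcode, g2)
        planted <- c(planted, rep(TRUE, length(gi2)))
      }
      chrom <- as.character(seqnames(genes))[gi]
      ref <- sample(c("A", "C", "G", "T"), length(gi), TRUE)
      alts <- c(A = "G", C = "T", G = "A", T = "C")
      dup <- duplicated(paste(chrom, pos))
      keep <- !dup
      coding <- data.frame(
        chrom = chrom[keep], pos = pos[keep], ref = ref[keep],
        alt = unname(alts[ref[keep]]),
        gene = names(genes)[gi[keep]], consequence = cons[keep],
        planted = planted[keep], stringsAsFactors = FALSE)
      coding$id <- sprintf("%s:%d:%s:%s", coding$chrom, coding$pos,
                           coding$ref, coding$alt)
      rows$coding <- coding[, c("chrom", "pos", "ref", "alt", "id")]
      genos$coding <- gcode[keep, , drop = FALSE]
    }

    if (length(rows) == 0L) stop("nothing to generate")
    vdf <- do.call(rbind, rows)
    geno <- do.call(rbind, genos)
    ## drop cross-set positional duplicates
    dup <- duplicated(paste(vdf$chrom, vdf$pos))
    vdf <- vdf[!dup, ]; geno <- geno[!dup, , drop = FALSE]
    o <- order(vdf$chrom, vdf$pos)
    vdf <- vdf[o, ]; geno <- geno[o, , drop = FALSE]
    variants <- GRanges(vdf$chrom, IRanges(vdf$pos, width = 1L))
    variants$id <- vdf$id; variants$ref <- vdf$ref; variants$alt <- vdf$alt
    cohort <- CohortGenotypes(samples, variants, geno)
    if (!is.null(coding)) coding <- coding[coding$id %in% vdf$id, ]
    list(cohort = cohort, coding = coding)
  })
}

#' Generate three-predictor deleteriousness scores
#'
#' Background nonsynonymous SNVs get three independent Uniform(0, 1) scores
#' with 5\% missing entries; SNVs of planted burden genes get scores from
#' Uniform(0.7, 1).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param coding coding-variant data.frame from \code{\link{genCohort}}.
#' @return annotation data.frame with \code{id}, \code{gene},
#'   \code{consequence}, \code{score1..score3}.
#' @export
genCodingScores <- function(cfg, coding) {
  withSeed(stageSeed(cfg$seed, "coding_scores"), {
    k <- nrow(coding)
    sc <- matrix(runif(3 * k), ncol = 3)
    pl <- coding$planted
    sc[pl, ] <- matrix(runif(3 * sum(pl), 0.7, 1), ncol = 3)
    miss <- matrix(runif(3 * k) < 0.05, ncol = 3)
    miss[pl, ] <- FALSE
    sc[miss] <- NA_real_
    data.frame(id = coding$id, gene = coding$gene,
               consequence = coding$consequence,
               score1 = sc[, 1], score2 = sc[, 2], score3 = sc[, 3],
               stringsAsFactors = FALSE)
  })
}

#' Generate GO-style gene sets with one planted term
#'
#' Random sets of configured sizes over the gene universe, plus one term
#' seeded to contain the planted noncoding target genes and planted burden
#' genes.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param universe character vector of gene ids.
#' @param plantedGenes genes the planted term must contain.
#' @return list with \code{sets} (named list) and \code{planted_term}.
#' @export
genGoSets <- function(cfg, universe, plantedGenes = character(0)) {
  withSeed(stageSeed(cfg$seed, "go_sets"), {
    sizes <- pmin(sample(cfg$go_size_range[1]:cfg$go_size_range[2],
                         cfg$go_n_terms, replace = TRUE),
                  length(universe))
    sets <- lapply(sizes, function(s) sample(universe, s))
    names(sets) <- sprintf("TERM%03d", seq_along(sets))
    plantedTerm <- NA_character_
    if (length(plantedGenes)) {
      plantedTerm <- "TERM_PLANTED"
      extra <- sample(setdiff(universe, plantedGenes),
                      max(5L, cfg$go_size_range[1]))
      sets[[plantedTerm]] <- c(plantedGenes, extra)
    }
    list(sets = sets, planted_term = plantedTerm)
  })
}

#' Generate GWAS summary statistics under the enrichment prior
#'
#' True effects are drawn from the spike-and-slab prior with
#' \eqn{\pi_j = \theta_0 + a_j\theta}, \eqn{\sigma_j^2 = \sigma_0^2 +
#' a_j\sigma^2}; observed effects follow the summary-statistics likelihood
#' \eqn{\hat\beta \sim N(R\beta, R/n)} (all standard errors
#' \eqn{1/\sqrt{n}}) under block-diagonal AR(1) LD.
#'
#' @param cfg a \code{\link{simConfig}} (the \code{gwas} block is used).
#' @param annotation 0/1 vector of length \code{p_snps}.
#' @param seedTag optional tag mixed into the stage seed (for multi-seed
#'   experiments).
#' @return list with \code{stats} (data.frame snp_id, chrom, pos, betahat,
#'   se, n), \code{ld}, \code{beta}, \code{gamma}.
#' @export
genSumstats <- function(cfg, annotation, seedTag = "") {
  gw <- cfg$gwas
  p <- gw$p_snps
  stopifnot(length(annotation) == p)
  withSeed(stageSeed(cfg$seed, paste0("sumstats", seedTag)), {
    R <- ldBlockAR1(p, gw$ld_block, gw$ld_rho)
    pi <- gw$theta0 + annotation * gw$theta
    sig2 <- gw$sigma0sq + annotation * gw$sigmasq
    gamma <- runif(p) < pi
    beta <- ifelse(gamma, rnorm(p, 0, sqrt(sig2)), 0)
    se <- rep(1 / sqrt(gw$n), p)
    ch <- chol(R)
    betahat <- as.numeric(R %*% beta + crossprod(ch, rnorm(p)) / sqrt(gw$n))
    stats <- data.frame(snp_id = sprintf("rs%05d", seq_len(p)),
                        chrom = "chr1", pos = seq_len(p) * 1000L,
                        betahat = betahat, se = se, n = gw$n)
    list(stats = stats, ld = R, beta = beta, gamma = gamma)
  })
}

#' Block-diagonal AR(1) LD matrix
#'
#' @param p number of SNPs.
#' @param blockSize SNPs per block.
#' @param rho within-block AR(1) correlation.
#' @return p x p correlation matrix.
#' @export
ldBlockAR1 <- function(p, blockSize, rho) {
  R <- diag(p)
  if (rho != 0) {
    starts <- seq(1, p, by = blockSize)
    for (s in starts) {
      e <- min(s + blockSize - 1, p)
      idx <- s:e
      R[idx, idx] <- rho^abs(outer(idx, idx, "-"))
    }
  }
  R
}

#' Generate every pipeline input with ground truth
#'
#' Orchestrates all generators coherently: landscape, network, openness
#' model, cohort, coding scores, gene sets and GWAS summary statistics.
#' When \code{outdir} is given, writes BEDPE/BED/TSV/VCF/GMT files plus
#' \code{ground_truth.json}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param outdir optional output directory.
#' @return list with all in-memory objects and the \code{truth} record.
#' @export
genAll <- function(cfg, outdir = NULL) {
  land <- genLandscape(cfg)
  res <- tileAndClassify(land$loops[mcols(land$loops)$q_value < 0.01],
                         land$peaks, cfg$tile_width)
  prom <- makePromoters(land$genes)
  network <- buildNetwork(land$loops[mcols(land$loops)$q_value < 0.01],
                          prom, res, land$genes, land$peaks)
  om <- genOpennessModel(cfg, network)
  plantedBurden <- character(0)
  if (cfg$planted_burden_genes > 0) {
    pool <- setdiff(names(land$genes), om$truth$planted_gene)
    plantedBurden <- withSeed(stageSeed(cfg$seed, "burden_genes"),
                              sample(pool, cfg$planted_burden_genes))
  }
  coh <- genCohort(cfg, reVariants = om$variantSpec, genes = land$genes,
                   plantedBurdenGenes = plantedBurden)
  ann <- genCodingScores(cfg, coh$coding)
  go <- genGoSets(cfg, names(land$genes),
                  unique(c(om$truth$planted_gene, plantedBurden)))
  snpAnn <- NULL; sumstats <- NULL
  if (!is.null(cfg$gwas)) {
    snps <- withSeed(stageSeed(cfg$seed, "snp_panel"), {
      GRanges(sample(cfg$chroms, cfg$gwas$p_snps, replace = TRUE),
              IRanges(sample.int(cfg$chrom_len, cfg$gwas$p_snps),
                      width = 1L))
    })
    snpAnn <- annotateSnps(snps, network = network)
    sumstats <- genSumstats(cfg, snpAnn)
    sumstats$snps <- snps
  }
  truth <- list(
    planted_re = om$truth$planted_re,
    planted_gene = om$truth$planted_gene,
    planted_variant = om$truth$planted_variant,
    planted_burden_genes = plantedBurden,
    planted_term = go$planted_term,
    intended_category = land$intended_category,
    gwas_hyper = cfg$gwas[c("theta0", "theta", "sigma0sq", "sigmasq")])
  out <- list(cfg = cfg, landscape = land, network = network,
              scorer = om$scorer, cohort = coh$cohort, coding = coh$coding,
              codingScores = ann, goSets = go$sets, snpAnnotation = snpAnn,
              sumstats = sumstats, truth = truth)
  if (!is.null(outdir)) writeSynthData(out, outdir)
  out
}

## write every generated input in its on-disk exchange format
writeSynthData <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  land <- sim$landscape
  writeLoops(land$loops, file.path(outdir, "loops.bedpe"))
  writeBed(land$peaks, file.path(outdir, "peaks.bed"))
  writeBed(land$genes, file.path(outdir, "genes.bed"))
  writeBed(land$silencers, file.path(outdir, "silencers.bed"))
  write.table(data.frame(gene = names(land$fpkm), fpkm = land$fpkm),
              file.path(outdir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeCohortVcf(sim$cohort, file.path(outdir, "cohort.vcf"),
                 file.path(outdir, "samples.tsv"))
  write.table(sim$codingScores, file.path(outdir, "coding_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeGMT(sim$goSets, file.path(outdir, "go.gmt"))
  if (!is.null(sim$sumstats)) {
    write.table(sim$sumstats$stats, file.path(outdir, "sumstats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sim$sumstats$ld, file.path(outdir, "ld.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(sim$truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
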