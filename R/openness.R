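#' Construct the baseline variant set
#'
#' The baseline individual carries, at every variant site, the cohort's major
#' allele (\code{mode = "major_allele"}): the alternate allele is included
#' (homozygously) exactly when its frequency exceeds 0.5; at a 0.5 tie the
#' reference allele is kept. \code{mode = "reference"} yields the empty set
#' (reference-genome baseline, used with external control augmentation).
#'
#' @param cohort a \code{CohortGenotypes}.
#' @param mode \code{"major_allele"} or \code{"reference"}.
#' @return character vector of variant ids whose alternate allele the
#'   baseline genome carries.
#' @export
buildBaseline <- function(cohort, mode = c("major_allele", "reference")) {
  mode <- match.arg(mode)
  if (mode == "reference") return(character(0))
  v <- cohortVariants(cohort)
  v$id[v$af > 0.5]
}

#' Create a linear openness scorer
#'
#' @param base named numeric baseline openness per RE id.
#' @param weights named numeric per-variant additive weights (variant ids).
#' @return a \code{\link{LinearScorer-class}} object.
#' @export
LinearScorer <- function(base, weights = numeric(0)) {
  new("LinearScorer", base = base, weights = weights)
}

#' Score an RE for a set of carried variants
#'
#' @param scorer an openness scorer.
#' @param reId RE identifier.
#' @param variantIds character vector of variant ids carried inside the RE.
#' @return openness score (numeric scalar).
#' @export
setGeneric("scoreRE", function(scorer, reId, variantIds)
  standardGeneric("scoreRE"))

#' @rdname scoreRE
#' @export
setMethod("scoreRE", "LinearScorer", function(scorer, reId, variantIds) {
  if (!reId %in% names(scorer@base)) stop("scorer undefined for RE ", reId)
  w <- scorer@weights[intersect(variantIds, names(scorer@weights))]
  unname(scorer@base[reId] + sum(w))
})

#' Predicted openness of every individual at every RE
#'
#' Each sample's score at an RE is the scorer applied to the set of alternate
#' alleles the sample carries (dosage >= 1) inside the RE; the baseline
#' genome is scored once per RE with the baseline variant set. Missing
#' genotypes are imputed to the baseline allele (their count is recorded).
#' An individual is flagged \emph{nonbaseline} at an RE when its score
#' differs from the baseline score by more than \code{tolerance}.
#'
#' @param cohort a \code{CohortGenotypes}.
#' @param res \code{GRanges} of REs with \code{re_id} metadata (anchor tiles
#'   and/or promoters).
#' @param scorer an openness scorer (see \code{\link{LinearScorer}}); any
#'   object with a \code{scoreRE} method works, a \code{LinearScorer} is
#'   evaluated by sparse matrix algebra.
#' @param baseline character vector of baseline-carried variant ids from
#'   \code{\link{buildBaseline}}.
#' @param tolerance nonbaseline score tolerance.
#' @return an \code{\link{OpennessMatrix-class}} object (samples x REs).
#' @export
scoreCohort <- function(cohort, res, scorer, baseline = character(0),
                        tolerance = 1e-9) {
  v <- cohortVariants(cohort)
  geno <- genotypes(cohort)
  nS <- ncol(geno)
  reIds <- res$re_id
  ## carrier matrix: TRUE when the sample carries the alternate allele;
  ## missing genotypes fall back to the baseline carrier state
  carrier <- geno >= 1L
  nImp <- sum(is.na(carrier))
  if (nImp > 0) {
    basal <- v$id %in% baseline
    idx <- which(is.na(carrier), arr.ind = TRUE)
    carrier[idx] <- basal[idx[, 1]]
    message(nImp, " missing genotypes imputed to the baseline allele")
  }
  hits <- findOverlaps(v, res)

  if (is(scorer, "LinearScorer")) {
    miss <- setdiff(reIds, names(scorer@base))
    if (length(miss)) stop("scorer undefined for RE ", miss[1])
    w <- setNames(rep(0, length(v)), v$id)
    known <- intersect(v$id, names(scorer@weights))
    w[known] <- scorer@weights[known]
    ## RE x variant incidence weighted by the variant effect
    W <- Matrix::sparseMatrix(i = subjectHits(hits), j = queryHits(hits),
                              x = w[queryHits(hits)],
                              dims = c(length(res), length(v)))
    base <- unname(scorer@base[reIds])
    contrib <- as.matrix(W %*% (carrier * 1))      # REs x samples
    score <- t(contrib) + matrix(base, nrow = nS, ncol = length(res),
                                 byrow = TRUE)
    baseScore <- base + as.numeric(W %*% (v$id %in% baseline))
  } else {
    byRe <- split(queryHits(hits), factor(subjectHits(hits),
                                          levels = seq_along(res)))
    score <- matrix(0, nrow = nS, ncol = length(res))
    baseScore <- numeric(length(res))
    for (r in seq_along(res)) {
      vi <- byRe[[r]]
      ids <- v$id[vi]
      baseScore[r] <- scoreRE(scorer, reIds[r], intersect(ids, baseline))
      for (i in seq_len(nS))
        score[i, r] <- scoreRE(scorer, reIds[r], ids[carrier[vi, i]])
    }
  }
  dimnames(score) <- list(cohortSamples(cohort)$sample, reIds)
  nonb <- abs(sweep(score, 2, baseScore)) > tolerance
  new("OpennessMatrix", score = score, baseline = setNames(baseScore, reIds),
      nonbaseline = nonb, tolerance = tolerance, nImputed = nImp)
}

#' Per-RE differential-openness tests
#'
#' For every RE: (i) a one-sided Fisher exact test of whether individuals
#' with nonbaseline openness are enriched among cases; (ii) a two-sided
#' Wilcoxon rank-sum test comparing the openness scores of nonbaseline cases
#' vs nonbaseline controls; (iii) their combination with Fisher's method
#' (chi-squared, 4 df). When no individual is nonbaseline the RE is reported
#' with \code{p_combined = 1} and flagged skipped; when only one group has
#' nonbaseline individuals the Wilcoxon side is undefined and the combined
#' p-value falls back to the Fisher exact p alone (flagged).
#'
#' @param om an \code{OpennessMatrix}.
#' @param labels character vector (\code{"case"}/\code{"control"}) aligned
#'   with the rows of \code{om}.
#' @return \code{data.frame}: \code{re_id}, counts, \code{p_fisher},
#'   \code{p_wilcoxon}, \code{p_combined}, \code{flag}.
#' @export
reTest <- function(om, labels) {
  stopifnot(length(labels) == nrow(om@score),
            all(labels %in% c("case", "control")))
  isCase <- labels == "case"
  n1 <- sum(isCase); n2 <- sum(!isCase)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty")
  nb <- om@nonbaseline
  aCase <- colSums(nb[isCase, , drop = FALSE])
  aCtrl <- colSums(nb[!isCase, , drop = FALSE])
  pF <- fisherOneSided(aCase, n1, aCtrl, n2)
  nRe <- ncol(nb)
  pW <- rep(NA_real_, nRe)
  pC <- rep(1, nRe)
  flag <- rep("ok", nRe)
  for (r in seq_len(nRe)) {
    if (aCase[r] + aCtrl[r] == 0L) { flag[r] <- "skipped"; next }
    if (aCase[r] == 0L || aCtrl[r] == 0L) {
      flag[r] <- "fisher_only"
      pC[r] <- pF[r]
      next
    }
    x <- om@score[isCase & nb[, r], r]
    y <- om@score[!isCase & nb[, r], r]
    pW[r] <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = FALSE)$p.value)
    if (is.na(pW[r])) { flag[r] <- "fisher_only"; pC[r] <- pF[r]; next }
    pC[r] <- fisherMethod(c(pF[r], pW[r]))
  }
  pC <- pmin(pmax(pC, .Machine$double.xmin), 1)
  data.frame(re_id = colnames(nb), case_nonbaseline = aCase,
             control_nonbaseline = aCtrl, n_case = n1, n_control = n2,
             p_fisher = pF, p_wilcoxon = pW, p_combined = pC, flag = flag,
             row.names = NULL)
}

#' Aggregate RE-level evidence to genes
#'
#' For each gene, the \code{k} linked REs with the strongest differential
#' openness (smallest combined p-value) are combined with Fisher's method
#' (chi-squared with 2m df, m the number of REs used); Benjamini-Hochberg
#' q-values are computed across genes. REs flagged skipped are ignored.
#'
#' @param network a \code{RETGNetwork} (promoter REs participate).
#' @param reResults output of \code{\link{reTest}}.
#' @param k number of top REs combined per gene (5 by default;
#'   \code{Inf} uses all).
#' @param fdr significance level on the q-value.
#' @return \code{data.frame}: \code{gene}, \code{n_re}, \code{res} (comma
#'   separated contributing RE ids), \code{p_combined}, \code{q_value},
#'   \code{significant}.
#' @export
geneCombine <- function(network, reResults, k = 5, fdr = 0.01) {
  ed <- networkEdges(network)
  use <- reResults[reResults$flag != "skipped", ]
  ed <- ed[ed$re_id %in% use$re_id, c("re_id", "gene")]
  ed <- unique(ed)
  if (nrow(ed) == 0L)
    return(data.frame(gene = character(0), n_re = integer(0),
                      res = character(0), p_combined = numeric(0),
                      q_value = numeric(0), significant = logical(0)))
  p <- setNames(use$p_combined, use$re_id)
  out <- do.call(rbind, lapply(split(ed$re_id, ed$gene), function(ids) {
    ps <- sort(p[ids])
    m <- min(length(ps), k)
    ps <- ps[seq_len(m)]
    data.frame(n_re = m, res = paste(names(ps), collapse = ","),
               p_combined = fisherMethod(ps))
  }))
  out <- data.frame(gene = rownames(out), out, row.names = NULL)
  out$q_value <- p.adjust(out$p_combined, method = "BH")
  out$significant <- out$q_value < fdr
  out[order(out$p_combined), ]
}

#' Replace cohort controls with an external control panel
#'
#' Samples \code{n} external controls matching the case cohort's sex ratio
#' (largest-remainder apportionment, stratified sampling), replaces the
#' original controls with them, and removes variants that are carried only
#' by external samples and absent from the original cohort. Deterministic
#' for a given seed.
#'
#' @param cohort original \code{CohortGenotypes}.
#' @param pool external \code{CohortGenotypes} (labels ignored; sex used).
#' @param n number of external controls to draw.
#' @param seed RNG seed for the stratified draw.
#' @return augmented \code{CohortGenotypes}.
#' @export
augmentControls <- function(cohort, pool, n = 500L, seed = 1L) {
  cs <- cohortSamples(cohort)
  caseIdx <- cs$label == "case"
  sexes <- c("M", "F")
  propo <- vapply(sexes, function(s) mean(cs$sex[caseIdx] == s), numeric(1))
  want <- setNames(largestRemainder(n, propo), sexes)
  ps <- cohortSamples(pool)
  pick <- integer(0)
  for (s in sexes) {
    avail <- which(ps$sex == s)
    if (length(avail) < want[[s]])
      stop("external pool has too few samples of sex ", s)
    pick <- c(pick, withSeed(stageSeed(seed, paste0("augment_", s)),
                             sample(avail, want[[s]])))
  }
  ## variant universe: keep variants observed in the original cohort
  keep <- rowSums(genotypes(cohort) >= 1L, na.rm = TRUE) > 0
  sharedIds <- cohortVariants(cohort)$id[keep]
  pv <- cohortVariants(pool)
  pKeep <- match(sharedIds, pv$id)
  newSamples <- rbind(
    cs[caseIdx, c("sample", "label", "sex")],
    data.frame(sample = ps$sample[pick], label = "control",
               sex = ps$sex[pick]))
  ## cohort variants absent from the external call set have dosage 0 there
  poolGeno <- matrix(0L, nrow = length(sharedIds), ncol = length(pick))
  has <- !is.na(pKeep)
  poolGeno[has, ] <- genotypes(pool)[pKeep[has], pick, drop = FALSE]
  geno <- cbind(genotypes(cohort)[keep, caseIdx, drop = FALSE], poolGeno)
  CohortGenotypes(newSamples, cohortVariants(cohort)[keep], geno)
}
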