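#' Average per-variant deleteriousness predictions
#'
#' Each nonsynonymous SNV carries up to three predictor scores in `[0, 1]`
#' (any may be missing); the consensus deleteriousness is the arithmetic
#' mean of the available scores. SNVs with all three scores missing are
#' dropped (count reported via \code{message}).
#'
#' @param ann \code{data.frame} with columns \code{id} (variant id),
#'   \code{gene}, \code{consequence}, and \code{score1..score3}.
#' @return \code{ann} with an added \code{score} column, all-missing rows
#'   removed.
#' @export
averageScores <- function(ann) {
  sc <- as.matrix(ann[, c("score1", "score2", "score3")])
  if (any(sc < 0 | sc > 1, na.rm = TRUE))
    stop("predictor scores must lie in [0, 1]")
  s <- rowMeans(sc, na.rm = TRUE)
  drop <- is.nan(s)
  if (any(drop))
    message(sum(drop), " SNVs dropped: no predictor score available")
  out <- ann[!drop, , drop = FALSE]
  out$score <- s[!drop]
  out
}

#' Select rare nonsynonymous SNVs
#'
#' Keeps SNVs annotated nonsynonymous whose cohort alternate-allele
#' frequency is below \code{afThreshold} (rare; 1\% by default).
#'
#' @param cohort a \code{CohortGenotypes} (source of allele frequencies).
#' @param ann annotation \code{data.frame} with \code{id} and
#'   \code{consequence} columns.
#' @param afThreshold allele-frequency cutoff.
#' @return the retained rows of \code{ann}.
#' @export
filterRareNonsyn <- function(cohort, ann, afThreshold = 0.01) {
  v <- cohortVariants(cohort)
  af <- setNames(v$af, v$id)
  keep <- ann$consequence == "nonsynonymous" &
    ann$id %in% v$id & af[ann$id] < afThreshold
  keep[is.na(keep)] <- FALSE
  ann[keep, , drop = FALSE]
}

#' Per-gene, per-sample mutation burden
#'
#' The burden of gene \eqn{i} in sample \eqn{m} is the sum of averaged
#' deleteriousness scores over the rare nonsynonymous SNVs of the gene that
#' the sample carries, \eqn{g_{im} = \sum_j s_{ijm}}. A carrier contributes
#' each SNV once regardless of dosage 1 or 2 unless
#' \code{dosageWeighted = TRUE}.
#'
#' @param cohort a \code{CohortGenotypes}.
#' @param variants annotation rows (from \code{\link{filterRareNonsyn}} then
#'   \code{\link{averageScores}}) with \code{id}, \code{gene}, \code{score}.
#' @param geneUniverse optional character vector; genes without retained
#'   SNVs appear as all-zero rows, mirroring a fixed protein-coding universe.
#' @param dosageWeighted multiply each SNV score by the dosage instead of
#'   the carrier indicator.
#' @return numeric matrix genes x samples.
#' @export
burdenMatrix <- function(cohort, variants, geneUniverse = NULL,
                         dosageWeighted = FALSE) {
  if (is.null(variants$score)) stop("variants need averaged scores")
  noGene <- is.na(variants$gene) | variants$gene == ""
  if (any(noGene)) {
    message(sum(noGene), " SNVs dropped: no gene assignment")
    variants <- variants[!noGene, , drop = FALSE]
  }
  geno <- genotypes(cohort)
  idx <- match(variants$id, rownames(geno))
  stopifnot(!anyNA(idx))
  carry <- geno[idx, , drop = FALSE]
  carry[is.na(carry)] <- 0L
  if (!dosageWeighted) carry <- (carry >= 1L) * 1
  genes <- if (is.null(geneUniverse)) sort(unique(variants$gene)) else
    geneUniverse
  A <- Matrix::sparseMatrix(i = match(variants$gene, genes),
                            j = seq_len(nrow(variants)),
                            x = variants$score,
                            dims = c(length(genes), nrow(variants)))
  g <- as.matrix(A %*% carry)
  dimnames(g) <- list(genes, colnames(geno))
  g
}

#' One-tailed per-gene burden test
#'
#' Welch (unequal-variance) t test per gene with alternative "case mean
#' burden greater than control mean burden". Genes with zero variance in
#' both groups get p = 1.
#'
#' @param g burden matrix, genes x samples.
#' @param labels \code{"case"}/\code{"control"} per sample (columns).
#' @return \code{data.frame} with \code{gene}, \code{t}, \code{p}.
#' @export
burdenTest <- function(g, labels) {
  stopifnot(ncol(g) == length(labels), all(labels %in% c("case", "control")))
  isCase <- labels == "case"
  n1 <- sum(isCase); n2 <- sum(!isCase)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  x <- g[, isCase, drop = FALSE]; y <- g[, !isCase, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- pt(t, df, lower.tail = FALSE)
  degen <- v1 == 0 & v2 == 0
  p[degen] <- 1
  t[degen] <- 0
  data.frame(gene = rownames(g), t = t, p = p, row.names = NULL)
}
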