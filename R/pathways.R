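#' Poisson gene-set test for coding burden
#'
#' Given that \code{k} of the genes in a term reach the per-gene burden
#' significance threshold while the genome-wide rate of such genes is
#' \code{globalRate}, the term-level p-value is the upper Poisson tail
#' \eqn{P(X \ge k)} with mean \eqn{\lambda = |term| \times rate}.
#'
#' @param k number of significant genes in the term.
#' @param termSize number of (scored) genes in the term.
#' @param globalRate genome-wide fraction of significant genes, in (0, 1).
#' @return the upper-tail p-value; \code{k = 0} gives 1.
#' @export
poissonTermTest <- function(k, termSize, globalRate) {
  stopifnot(all(k >= 0), all(k <= termSize),
            globalRate > 0, globalRate < 1)
  lambda <- termSize * globalRate
  ifelse(k == 0, 1, ppois(k - 1, lambda, lower.tail = FALSE))
}

#' Hypergeometric gene-set test for noncoding target genes
#'
#' Upper-tail hypergeometric test of the overlap between a target-gene list
#' and a term, with fold enrichment
#' \code{(overlap/|targets|) / (|term|/|universe|)}.
#'
#' @param targets character vector of hit genes.
#' @param term character vector of term genes.
#' @param universe character vector, the gene universe.
#' @return list with \code{p}, \code{fold}, \code{overlap}.
#' @export
hypergeomTermTest <- function(targets, term, universe) {
  if (length(targets) == 0L) stop("empty target list")
  targets <- intersect(targets, universe)
  term <- intersect(term, universe)
  ov <- length(intersect(targets, term))
  p <- phyper(ov - 1, length(term), length(universe) - length(term),
              length(targets), lower.tail = FALSE)
  fold <- (ov / length(targets)) / (length(term) / length(universe))
  list(p = min(p, 1), fold = fold, overlap = ov)
}

#' Combine noncoding and coding term-level evidence
#'
#' Per shared term, the noncoding (hypergeometric) and coding (Poisson)
#' p-values are combined with Fisher's method (chi-squared, 4 df); terms are
#' ranked by the combined p-value and Benjamini-Hochberg q-values appended.
#' Terms present on only one side are excluded (count reported).
#'
#' @param noncoding named numeric vector of term p-values.
#' @param coding named numeric vector of term p-values.
#' @return ranked \code{data.frame}: \code{term}, \code{p_noncoding},
#'   \code{p_coding}, \code{p_combined}, \code{q_value}.
#' @export
combineAndRank <- function(noncoding, coding) {
  shared <- intersect(names(noncoding), names(coding))
  lost <- length(noncoding) + length(coding) - 2 * length(shared)
  if (lost > 0)
    message(lost, " term entries present on one side only were excluded")
  if (length(shared) == 0L) stop("no shared terms to combine")
  pc <- vapply(shared, function(tm)
    fisherMethod(c(noncoding[[tm]], coding[[tm]])), numeric(1))
  out <- data.frame(term = shared,
                    p_noncoding = unname(noncoding[shared]),
                    p_coding = unname(coding[shared]),
                    p_combined = unname(pc), row.names = NULL)
  out <- out[order(out$p_combined), ]
  out$q_value <- p.adjust(out$p_combined, method = "BH")
  ## BH on the sorted vector stays monotone with cummin from the tail
  out$q_value <- rev(cummin(rev(out$q_value)))
  rownames(out) <- NULL
  out
}

#' Full gene-set analysis of a pipeline run
#'
#' Runs the hypergeometric test on the noncoding target genes and the
#' Poisson test on coding burden results for every term of a gene-set
#' collection, then combines and ranks.
#'
#' @param geneSets named list of character vectors (e.g. from
#'   \code{\link{readGMT}}).
#' @param targetGenes noncoding hit genes (e.g. significant genes from
#'   \code{\link{geneCombine}}).
#' @param codingP named numeric vector of per-gene burden p-values over the
#'   scored protein-coding genes.
#' @param universe gene universe for the hypergeometric side; defaults to
#'   the scored genes (\code{names(codingP)}).
#' @param sigThreshold per-gene coding significance cutoff feeding the
#'   Poisson rate (0.05 by default).
#' @return ranked \code{data.frame} from \code{\link{combineAndRank}} with
#'   fold-enrichment and overlap columns added.
#' @export
termAnalysis <- function(geneSets, targetGenes, codingP,
                         universe = names(codingP), sigThreshold = 0.05) {
  geneSets <- lapply(geneSets, intersect, y = universe)
  geneSets <- geneSets[lengths(geneSets) > 0]
  sig <- names(codingP)[codingP <= sigThreshold]
  rate <- length(sig) / length(codingP)
  hg <- lapply(geneSets, hypergeomTermTest, targets = targetGenes,
               universe = universe)
  nc <- vapply(hg, `[[`, numeric(1), "p")
  fold <- vapply(hg, `[[`, numeric(1), "fold")
  ## a degenerate rate (no or all significant genes) makes the Poisson side
  ## uninformative: every term gets p = 1
  cd <- if (rate <= 0 || rate >= 1)
    setNames(rep(1, length(geneSets)), names(geneSets))
  else vapply(geneSets, function(tg)
    poissonTermTest(length(intersect(sig, tg)), length(tg), rate),
    numeric(1))
  out <- combineAndRank(nc, cd)
  out$fold <- fold[out$term]
  out$overlap <- vapply(geneSets[out$term], function(tg)
    length(intersect(targetGenes, tg)), integer(1))
  out
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (term, description, genes...).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets[lengths(sets) > 0]
}

#' Write gene sets to GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
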