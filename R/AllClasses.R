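#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors Pairs first second mcols mcols<- queryHits subjectHits
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors Pairs
NULL

#' Regulatory-element / target-gene network
#'
#' Container for a cell-type-specific regulatory network: regulatory elements
#' (1-kb tiles of chromatin-loop anchors plus 2-kb promoters), the loops that
#' produced them, RE-to-gene edges obtained by matching one loop anchor to a
#' gene promoter and taking the tiles of the opposite anchor, and the
#' resulting gene categories (\code{OpenLoop}: linked to at least one open
#' anchor RE; \code{NonOpenLoop}: linked only to nonopen anchor REs;
#' \code{NoLoop}: no loop-linked RE).
#'
#' @slot elements \code{GRanges} of regulatory elements with metadata columns
#'   \code{re_id}, \code{source} (\code{"loop_anchor"} or \code{"promoter"})
#'   and \code{open} (logical; may be \code{NA} for promoters when no peak set
#'   was supplied).
#' @slot edges \code{data.frame} with columns \code{re_id}, \code{gene},
#'   \code{loop} (index of the supporting loop; \code{NA} for promoter REs).
#' @slot loops \code{Pairs} of anchor \code{GRanges} with a \code{q_value}
#'   metadata column.
#' @slot geneCategory named character vector over the gene universe with
#'   values in \code{c("OpenLoop", "NonOpenLoop", "NoLoop")}.
#' @slot geneRanges named \code{GRanges} of gene bodies (used for SNP
#'   annotation windows).
#'
#' @export
setClass("RETGNetwork", representation(
  elements = "GRanges",
  edges = "data.frame",
  loops = "Pairs",
  geneCategory = "character",
  geneRanges = "GRanges"
))

setValidity("RETGNetwork", function(object) {
  msg <- character()
  el <- object@elements
  need <- c("re_id", "source", "open")
  if (!all(need %in% names(mcols(el))))
    msg <- c(msg, "elements must carry re_id, source, open metadata")
  else {
    if (anyDuplicated(el$re_id)) msg <- c(msg, "duplicate re_id in elements")
    bad <- !el$source %in% c("loop_anchor", "promoter")
    if (any(bad)) msg <- c(msg, "source must be loop_anchor or promoter")
    if (any(el$source == "loop_anchor" & width(el) > 1000))
      msg <- c(msg, "loop-anchor tiles must be at most 1 kb wide")
  }
  if (nrow(object@edges)) {
    if (!all(object@edges$re_id %in% el$re_id))
      msg <- c(msg, "edge references unknown RE")
    if (!all(object@edges$gene %in% names(object@geneCategory)))
      msg <- c(msg, "edge references gene outside the universe")
  }
  if (!all(object@geneCategory %in% c("OpenLoop", "NonOpenLoop", "NoLoop")))
    msg <- c(msg, "invalid gene category")
  if (length(msg)) msg else TRUE
})

#' Case/control cohort genotypes
#'
#' Biallelic variant calls for a labelled cohort. Dosages are 0/1/2 with
#' \code{NA} for missing genotypes; allele frequencies are computed from the
#' observed dosages.
#'
#' @slot samples \code{data.frame} with columns \code{sample}, \code{label}
#'   (\code{"case"}/\code{"control"}) and \code{sex} (\code{"M"}/\code{"F"}).
#' @slot variants \code{GRanges} (width-1 positions) with metadata columns
#'   \code{id} (\code{chrom:pos:ref:alt}, 1-based pos), \code{ref},
#'   \code{alt}, \code{af} (alternate-allele frequency).
#' @slot geno integer matrix, variants x samples.
#'
#' @export
setClass("CohortGenotypes", representation(
  samples = "data.frame",
  variants = "GRanges",
  geno = "matrix"
))

setValidity("CohortGenotypes", function(object) {
  msg <- character()
  if (!all(c("sample", "label", "sex") %in% names(object@samples)))
    msg <- c(msg, "samples needs columns sample, label, sex")
  if (!all(object@samples$label %in% c("case", "control")))
    msg <- c(msg, "labels must be case/control")
  if (anyDuplicated(object@variants$id))
    msg <- c(msg, "duplicate (chrom,pos,ref,alt) variant")
  if (nrow(object@geno) != length(object@variants) ||
      ncol(object@geno) != nrow(object@samples))
    msg <- c(msg, "geno must be variants x samples")
  d <- object@geno
  if (!all(d[!is.na(d)] %in% 0:2)) msg <- c(msg, "dosages must be 0/1/2/NA")
  if (length(msg)) msg else TRUE
})

#' Per-individual regulatory-element openness scores
#'
#' @slot score numeric matrix, samples x REs, of predicted openness.
#' @slot baseline numeric vector of per-RE openness of the baseline genome.
#' @slot nonbaseline logical matrix, samples x REs:
#'   \code{|score - baseline| > tolerance}.
#' @slot tolerance numeric score tolerance used for the flag.
#' @slot nImputed number of missing genotypes imputed to the baseline allele.
#'
#' @export
setClass("OpennessMatrix", representation(
  score = "matrix",
  baseline = "numeric",
  nonbaseline = "matrix",
  tolerance = "numeric",
  nImputed = "numeric"
))

setValidity("OpennessMatrix", function(object) {
  msg <- character()
  if (ncol(object@score) != length(object@baseline))
    msg <- c(msg, "baseline length must match number of REs")
  if (!identical(dim(object@score), dim(object@nonbaseline)))
    msg <- c(msg, "score and nonbaseline must have identical shape")
  ok <- abs(sweep(object@score, 2, object@baseline)) > object@tolerance
  if (!isTRUE(all.equal(ok, object@nonbaseline, check.attributes = FALSE)))
    msg <- c(msg, "nonbaseline inconsistent with score/baseline/tolerance")
  if (length(msg)) msg else TRUE
})

#' Grid fit of the network-enrichment model
#'
#' Holds, for every hyperparameter grid point (theta0, theta, sigma0sq,
#' sigmasq), the converged evidence lower bound used as approximate log
#' marginal likelihood, plus per-SNP posterior inclusion probabilities.
#'
#' @slot grid \code{data.frame} with columns \code{theta0}, \code{theta},
#'   \code{sigma0sq}, \code{sigmasq}.
#' @slot logml numeric vector of approximate log marginal likelihoods.
#' @slot pip matrix, SNPs x grid points, posterior inclusion probabilities.
#' @slot converged logical per grid point.
#' @slot niter integer iterations used per grid point.
#'
#' @export
setClass("EnrichmentFit", representation(
  grid = "data.frame",
  logml = "numeric",
  pip = "matrix",
  converged = "logical",
  niter = "integer"
))

setValidity("EnrichmentFit", function(object) {
  msg <- character()
  if (!all(c("theta0", "theta", "sigma0sq", "sigmasq") %in% names(object@grid)))
    msg <- c(msg, "grid needs theta0, theta, sigma0sq, sigmasq")
  if (length(object@logml) != nrow(object@grid))
    msg <- c(msg, "one logml per grid point required")
  if (length(msg)) msg else TRUE
})

#' Additive (linear) openness scorer
#'
#' Deterministic openness predictor of the form
#' \code{score(RE, carried) = base(RE) + sum of w(v) over carried variants v};
#' variants without a listed weight contribute 0. Stands in for a trained
#' sequence-to-accessibility model while honouring the same contract: the
#' score depends only on the variants carried inside the RE.
#'
#' @slot base named numeric, baseline openness per RE id (sequence-only
#'   context of the element).
#' @slot weights named numeric, per-variant additive effect keyed by variant
#'   id (\code{chrom:pos:ref:alt}).
#'
#' @export
setClass("LinearScorer", representation(
  base = "numeric",
  weights = "numeric"
))

setMethod("show", "RETGNetwork", function(object) {
  cat("RETGNetwork:", length(object@elements), "REs (",
      sum(object@elements$source == "loop_anchor"), "anchor tiles,",
      sum(object@elements$source == "promoter"), "promoters ),",
      nrow(object@edges), "edges,", length(object@geneCategory), "genes\n")
  print(table(object@geneCategory))
})

setMethod("show", "CohortGenotypes", function(object) {
  cat("CohortGenotypes:", length(object@variants), "variants x",
      nrow(object@samples), "samples (",
      sum(object@samples$label == "case"), "cases /",
      sum(object@samples$label == "control"), "controls )\n")
})

setMethod("show", "OpennessMatrix", function(object) {
  cat("OpennessMatrix:", nrow(object@score), "samples x",
      ncol(object@score), "REs;",
      sum(object@nonbaseline), "nonbaseline entries\n")
})

setMethod("show", "EnrichmentFit", function(object) {
  cat("EnrichmentFit:", nrow(object@grid), "grid points; logML in [",
      round(min(object@logml), 2), ",", round(max(object@logml), 2), "]\n")
})

## ---- accessors -------------------------------------------------------------

#' @rdname RETGNetwork-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("regulatoryElements", function(object) standardGeneric("regulatoryElements"))
#' @rdname RETGNetwork-class
#' @export
setMethod("regulatoryElements", "RETGNetwork", function(object) object@elements)

#' @rdname RETGNetwork-class
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname RETGNetwork-class
#' @export
setMethod("networkEdges", "RETGNetwork", function(object) object@edges)

#' @rdname RETGNetwork-class
#' @export
setGeneric("geneCategory", function(object) standardGeneric("geneCategory"))
#' @rdname RETGNetwork-class
#' @export
setMethod("geneCategory", "RETGNetwork", function(object) object@geneCategory)

#' @rdname CohortGenotypes-class
#' @param object an object of the documented class.
#' @export
setGeneric("cohortSamples", function(object) standardGeneric("cohortSamples"))
#' @rdname CohortGenotypes-class
#' @export
setMethod("cohortSamples", "CohortGenotypes", function(object) object@samples)

#' @rdname CohortGenotypes-class
#' @export
setGeneric("cohortVariants", function(object) standardGeneric("cohortVariants"))
#' @rdname CohortGenotypes-class
#' @export
setMethod("cohortVariants", "CohortGenotypes", function(object) object@variants)

#' @rdname CohortGenotypes-class
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))
#' @rdname CohortGenotypes-class
#' @export
setMethod("genotypes", "CohortGenotypes", function(object) object@geno)

#' @rdname OpennessMatrix-class
#' @param object an object of the documented class.
#' @export
setGeneric("opennessScores", function(object) standardGeneric("opennessScores"))
#' @rdname OpennessMatrix-class
#' @export
setMethod("opennessScores", "OpennessMatrix", function(object) object@score)

#' @rdname OpennessMatrix-class
#' @export
setGeneric("opennessBaseline", function(object) standardGeneric("opennessBaseline"))
#' @rdname OpennessMatrix-class
#' @export
setMethod("opennessBaseline", "OpennessMatrix", function(object) object@baseline)

#' @rdname OpennessMatrix-class
#' @export
setGeneric("nonbaselineFlags", function(object) standardGeneric("nonbaselineFlags"))
#' @rdname OpennessMatrix-class
#' @export
setMethod("nonbaselineFlags", "OpennessMatrix", function(object) object@nonbaseline)

#' @rdname EnrichmentFit-class
#' @param object an object of the documented class.
#' @export
setGeneric("gridLogML", function(object) standardGeneric("gridLogML"))
#' @rdname EnrichmentFit-class
#' @export
setMethod("gridLogML", "EnrichmentFit", function(object) object@logml)

#' @rdname EnrichmentFit-class
#' @export
setGeneric("hyperGrid", function(object) standardGeneric("hyperGrid"))
#' @rdname EnrichmentFit-class
#' @export
setMethod("hyperGrid", "EnrichmentFit", function(object) object@grid)

#' Construct a CohortGenotypes object
#'
#' Allele frequencies are (re)computed from the dosage matrix.
#'
#' @param samples data.frame with columns \code{sample}, \code{label},
#'   \code{sex}.
#' @param variants \code{GRanges} with \code{id}, \code{ref}, \code{alt}.
#' @param geno integer dosage matrix, variants x samples.
#' @return a \code{CohortGenotypes}.
#' @export
CohortGenotypes <- function(samples, variants, geno) {
  if (any(grepl(",", variants$alt, fixed = TRUE)))
    stop("multi-allelic record found; decompose to biallelic records first")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  variants$af <- rowMeans(geno, na.rm = TRUE) / 2
  variants$af[is.nan(variants$af)] <- 0
  rownames(geno) <- variants$id
  colnames(geno) <- samples$sample
  new("CohortGenotypes", samples = as.data.frame(samples),
      variants = variants, geno = geno)
}
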