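#' Tile loop anchors into 1-kb REs and classify openness
#'
#' Every distinct loop anchor is split into consecutive 1,000-bp tiles
#' starting at its 5' coordinate; the last tile is truncated at the anchor
#' end so that the tiles exactly cover the anchor. A tile is labelled
#' \emph{open} when it overlaps at least one ATAC-seq peak by at least 1 bp,
#' otherwise \emph{nonopen}.
#'
#' @param loops \code{Pairs} of anchors from \code{\link{readLoops}}.
#' @param peaks \code{GRanges} of accessibility peaks.
#' @param tileWidth tile width in bp (1,000 by default).
#' @return \code{GRanges} of tiles with \code{re_id}, \code{source}
#'   (\code{"loop_anchor"}) and \code{open} metadata.
#' @export
tileAndClassify <- function(loops, peaks, tileWidth = 1000L) {
  anchors <- unique(suppressWarnings(
    c(granges(first(loops)), granges(second(loops)))))
  if (length(anchors) == 0L) {
    gr <- GRanges()
    gr$re_id <- character(0); gr$source <- character(0); gr$open <- logical(0)
    return(gr)
  }
  tiles <- unlist(slidingWindows(anchors, width = tileWidth, step = tileWidth))
  tiles <- unique(granges(tiles))
  tiles$re_id <- reId(tiles)
  tiles$source <- "loop_anchor"
  tiles$open <- quietCountOverlaps(tiles, peaks, minoverlap = 1L) > 0
  tiles
}

## canonical RE identifier: 0-based half-open span
reId <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
}

#' Define promoter intervals from gene models
#'
#' Promoters are the \code{upstream} bp (2 kb by default) immediately 5' of
#' the transcription start site, strand-aware, clipped at the chromosome
#' start.
#'
#' @param genes named, stranded \code{GRanges} of gene bodies.
#' @param upstream promoter extent upstream of the TSS, bp.
#' @return named \code{GRanges} of promoter intervals.
#' @export
makePromoters <- function(genes, upstream = 2000L) {
  if (any(strand(genes) == "*")) stop("gene models must declare a strand")
  if (is.null(names(genes))) stop("gene models must be named")
  pr <- suppressWarnings(trim(promoters(genes, upstream = upstream,
                                        downstream = 0L)))
  ## trim() needs seqlengths for the right edge only; clip left edge manually
  start(pr) <- pmax(start(pr), 1L)
  pr <- pr[width(pr) > 0L]
  pr
}

#' Build the RE/target-gene network
#'
#' For each retained loop, if one anchor overlaps a gene's promoter (any
#' overlap), the 1-kb tiles of the \emph{other} anchor become regulatory
#' elements of that gene. Each gene's own promoter is additionally added as
#' an RE (\code{source = "promoter"}). Gene categories are derived from loop
#' linkage only: \code{OpenLoop} if any linked anchor tile is open,
#' \code{NonOpenLoop} if the gene has linked anchor tiles but none open,
#' \code{NoLoop} otherwise (promoter REs never affect the category).
#'
#' @param loops \code{Pairs} of anchors.
#' @param promoters named \code{GRanges} from \code{\link{makePromoters}}.
#' @param res anchor tiles from \code{\link{tileAndClassify}} built from the
#'   same loops.
#' @param genes named \code{GRanges} of gene bodies (the gene universe); must
#'   include every promoter's gene.
#' @param peaks optional \code{GRanges}; when supplied, promoter REs also get
#'   an openness label (informational only).
#' @return a \code{\link{RETGNetwork-class}} object.
#' @export
buildNetwork <- function(loops, promoters, res, genes, peaks = NULL) {
  if (!all(names(promoters) %in% names(genes)))
    stop("promoter refers to a gene absent from the gene universe")
  a1 <- first(loops); a2 <- second(loops)

  linkEdges <- function(promAnchor, otherAnchor) {
    ## loops whose promAnchor side touches a promoter
    hitP <- findOverlaps(promAnchor, promoters)
    if (length(hitP) == 0L)
      return(data.frame(re_id = character(0), gene = character(0),
                        loop = integer(0)))
    ## tiles lying within the opposite anchor of each hit loop
    hitT <- findOverlaps(res, otherAnchor[queryHits(hitP)], type = "within")
    data.frame(
      re_id = res$re_id[queryHits(hitT)],
      gene = names(promoters)[subjectHits(hitP)[subjectHits(hitT)]],
      loop = queryHits(hitP)[subjectHits(hitT)])
  }
  edges <- unique(rbind(linkEdges(a1, a2), linkEdges(a2, a1)))

  ## promoter REs for every gene in the universe with a promoter
  prom <- promoters
  promGr <- granges(prom)
  strand(promGr) <- "*"        # an RE has no orientation of its own
  promGr$re_id <- paste0("prom:", names(prom))
  promGr$source <- "promoter"
  promGr$open <- if (is.null(peaks)) NA else
    quietCountOverlaps(promGr, peaks, minoverlap = 1L) > 0
  names(promGr) <- NULL
  promEdges <- data.frame(re_id = promGr$re_id, gene = names(prom),
                          loop = NA_integer_)

  elements <- c(res, promGr)
  elements <- elements[!duplicated(elements$re_id)]
  allEdges <- rbind(edges, promEdges)
  rownames(allEdges) <- NULL

  ## gene categories from loop-anchor REs only
  universe <- names(genes)
  cat <- setNames(rep("NoLoop", length(universe)), universe)
  openRe <- setNames(res$open, res$re_id)
  if (nrow(edges)) {
    linkOpen <- tapply(openRe[edges$re_id], edges$gene, any)
    cat[names(linkOpen)] <- ifelse(linkOpen, "OpenLoop", "NonOpenLoop")
  }
  g <- genes
  mcols(g) <- NULL
  new("RETGNetwork", elements = elements, edges = allEdges, loops = loops,
      geneCategory = cat, geneRanges = g)
}

#' Expression quantiles per gene category
#'
#' Empirical FPKM quantiles of the genes in each network category. Genes
#' missing from the expression table are counted as unexpressed (FPKM 0).
#'
#' @param network a \code{RETGNetwork}.
#' @param expr named numeric FPKM vector (see \code{\link{readExpression}}).
#' @param probs quantile probabilities in (0, 1).
#' @return matrix, categories x probabilities; a category with no genes gives
#'   a row of \code{NA} with a warning.
#' @export
expressionQuantiles <- function(network, expr,
                                probs = c(.05, .1, .25, .5, .75, .9, .95)) {
  stopifnot(all(probs > 0), all(probs < 1))
  cats <- c("OpenLoop", "NonOpenLoop", "NoLoop")
  gc <- geneCategory(network)
  fpkm <- setNames(rep(0, length(gc)), names(gc))
  hit <- intersect(names(expr), names(fpkm))
  fpkm[hit] <- expr[hit]
  out <- matrix(NA_real_, nrow = length(cats), ncol = length(probs),
                dimnames = list(cats, paste0(probs * 100, "%")))
  for (ct in cats) {
    v <- fpkm[gc == ct]
    if (length(v) == 0L) {
      warning("no genes in category ", ct, "; quantiles undefined")
      next
    }
    out[ct, ] <- quantile(v, probs = probs, names = FALSE)
  }
  out
}

#' Silencer linkage statistics and network comparison
#'
#' For each network and gene category, the fraction of genes with at least
#' one RE overlapping a silencer (direct) or linked through a loop whose
#' opposite anchor overlaps a silencer (indirect). The two networks' counts
#' of silencer-linked vs unlinked genes in \code{category} are compared with
#' a two-sided Fisher exact test (point-probability summation).
#'
#' @param networkA,networkB \code{RETGNetwork} objects on the same genome.
#' @param silencers \code{GRanges} of silencer regions.
#' @param category gene category compared between the networks.
#' @return list with per-network fraction tables and the comparison
#'   \code{p.value}.
#' @export
silencerStats <- function(networkA, networkB, silencers,
                          category = "NonOpenLoop") {
  one <- function(net) {
    el <- net@elements
    reSil <- setNames(quietCountOverlaps(el, silencers) > 0, el$re_id)
    a1 <- first(net@loops); a2 <- second(net@loops)
    loopSil <- quietCountOverlaps(a1, silencers) > 0 |
      quietCountOverlaps(a2, silencers) > 0
    ed <- net@edges
    gc <- geneCategory(net)
    direct <- tapply(reSil[ed$re_id], ed$gene, any)
    indirect <- tapply(ifelse(is.na(ed$loop), FALSE, loopSil[ed$loop]),
                       ed$gene, any)
    linked <- setNames(rep(FALSE, length(gc)), names(gc))
    linked[names(direct)] <- direct | indirect
    frac <- vapply(split(linked, gc), mean, numeric(1))
    list(linked = linked, category = gc, fraction = frac)
  }
  A <- one(networkA); B <- one(networkB)
  inA <- A$category == category
  inB <- B$category == category
  if (!any(inA) || !any(inB))
    stop("no genes in category ", category, " in one of the networks")
  tab <- matrix(c(sum(A$linked[inA]), sum(!A$linked[inA]),
                  sum(B$linked[inB]), sum(!B$linked[inB])),
                nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  list(fractionA = A$fraction, fractionB = B$fraction,
       table = tab, p.value = min(p, 1))
}
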