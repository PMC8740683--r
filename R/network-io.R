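#' Read chromatin loops from a BEDPE file
#'
#' Parses a 7+ column BEDPE (chrom1, start1, end1, chrom2, start2, end2,
#' q-value; 0-based half-open coordinates) and keeps only loops whose
#' FDR-adjusted q-value is below \code{qThreshold} (the loop-calling
#' significance filter; q < 0.01 by default). Coordinates are converted to
#' 1-based closed \code{GRanges} on read.
#'
#' @param path BEDPE file path.
#' @param qThreshold retain loops with \code{q_value < qThreshold}.
#' @return \code{\link[S4Vectors]{Pairs}} of anchor \code{GRanges} with a
#'   \code{q_value} metadata column.
#' @export
readLoops <- function(path, qThreshold = 0.01) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    gr0 <- GRanges()
    return(Pairs(gr0, gr0, q_value = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7L))
    stop(sprintf("malformed BEDPE line %d in %s (fewer than 7 columns)",
                 which(nf < 7L)[1], path))
  m <- do.call(rbind, lapply(fields, `[`, 1:7))
  num <- suppressWarnings(apply(m[, c(2, 3, 5, 6, 7), drop = FALSE], 2,
                                as.numeric))
  num <- matrix(num, ncol = 5)
  bad <- which(rowSums(is.na(num)) > 0)
  if (length(bad))
    stop(sprintf("malformed BEDPE line %d in %s (non-numeric field)",
                 bad[1], path))
  s1 <- num[, 1]; e1 <- num[, 2]; s2 <- num[, 3]; e2 <- num[, 4]; q <- num[, 5]
  bad <- which(s1 >= e1 | s2 >= e2)
  if (length(bad))
    stop(sprintf("invalid interval (start >= end) at BEDPE line %d", bad[1]))
  if (any(q < 0 | q > 1)) stop("q-values must lie in [0, 1]")
  keep <- q < qThreshold
  a1 <- GRanges(m[keep, 1], IRanges(s1[keep] + 1, e1[keep]))
  a2 <- GRanges(m[keep, 4], IRanges(s2[keep] + 1, e2[keep]))
  Pairs(a1, a2, q_value = q[keep])
}

#' Write loops back to BEDPE
#'
#' Inverse of \code{\link{readLoops}} (coordinates converted back to 0-based
#' half-open).
#'
#' @param loops \code{Pairs} of anchors with \code{q_value} metadata.
#' @param path output path.
#' @export
writeLoops <- function(loops, path) {
  a1 <- first(loops); a2 <- second(loops)
  df <- data.frame(
    chrom1 = as.character(seqnames(a1)), start1 = start(a1) - 1, end1 = end(a1),
    chrom2 = as.character(seqnames(a2)), start2 = start(a2) - 1, end2 = end(a2),
    q = mcols(loops)$q_value)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' Thin wrapper over \code{rtracklayer::import} returning an unstranded
#' \code{GRanges} (1-based closed internally; the file is 0-based half-open).
#'
#' @param path BED3+ file path.
#' @return \code{GRanges}.
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read gene models from BED6
#'
#' Genes must carry a name (column 4) and strand (column 6); the transcription
#' start site is the strand-aware 5' end of the interval.
#'
#' @param path BED6 file path.
#' @return named \code{GRanges} of gene bodies.
#' @export
readGenesBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(strand(gr) == "*")) stop("gene models must declare a strand")
  if (is.null(gr$name) || anyNA(gr$name)) stop("gene models must be named")
  names(gr) <- gr$name
  gr
}

#' Read a gene-to-FPKM expression table
#'
#' Two-column TSV (gene, fpkm). Genes absent from the table are later treated
#' as unexpressed (FPKM 0).
#'
#' @param path TSV path.
#' @return named numeric vector of FPKM values.
#' @export
readExpression <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  v <- as.numeric(dt[[2]])
  if (any(v < 0)) stop("FPKM values must be nonnegative")
  setNames(v, as.character(dt[[1]]))
}

#' Serialize a network to a JSON + TSV pair
#'
#' Writes \code{<stem>.json} (loops, gene categories, gene ranges) and
#' \code{<stem>_elements.tsv} / \code{<stem>_edges.tsv} tables.
#'
#' @param network a \code{RETGNetwork}.
#' @param stem output path stem.
#' @return the stem, invisibly.
#' @export
writeNetwork <- function(network, stem) {
  el <- network@elements
  eldf <- data.frame(chrom = as.character(seqnames(el)),
                     start = start(el) - 1, end = end(el),
                     re_id = el$re_id, source = el$source, open = el$open)
  write.table(eldf, paste0(stem, "_elements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(network@edges, paste0(stem, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  g <- network@geneRanges
  a1 <- first(network@loops); a2 <- second(network@loops)
  obj <- list(
    loops = data.frame(
      chrom1 = as.character(seqnames(a1)), start1 = start(a1) - 1,
      end1 = end(a1),
      chrom2 = as.character(seqnames(a2)), start2 = start(a2) - 1,
      end2 = end(a2), q = mcols(network@loops)$q_value),
    gene_category = as.list(network@geneCategory),
    genes = data.frame(gene = names(g), chrom = as.character(seqnames(g)),
                       start = start(g) - 1, end = end(g),
                       strand = as.character(strand(g))))
  jsonlite::write_json(obj, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read a network serialized by \code{writeNetwork}
#'
#' @param stem the path stem given to \code{\link{writeNetwork}}.
#' @return a \code{RETGNetwork}.
#' @export
readNetwork <- function(stem) {
  obj <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  eldf <- read.table(paste0(stem, "_elements.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  edges <- read.table(paste0(stem, "_edges.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  el <- GRanges(eldf$chrom, IRanges(eldf$start + 1, eldf$end))
  el$re_id <- eldf$re_id; el$source <- eldf$source; el$open <- eldf$open
  lp <- obj$loops
  if (is.null(lp) || length(lp) == 0L || nrow(as.data.frame(lp)) == 0L) {
    gr0 <- GRanges()
    loops <- Pairs(gr0, gr0, q_value = numeric(0))
  } else {
    loops <- Pairs(GRanges(lp$chrom1, IRanges(lp$start1 + 1, lp$end1)),
                   GRanges(lp$chrom2, IRanges(lp$start2 + 1, lp$end2)),
                   q_value = lp$q)
  }
  g <- obj$genes
  gr <- GRanges(g$chrom, IRanges(g$start + 1, g$end), strand = g$strand)
  names(gr) <- g$gene
  new("RETGNetwork", elements = el, edges = edges, loops = loops,
      geneCategory = unlist(obj$gene_category), geneRanges = gr)
}

#' Write intervals to BED
#'
#' @param gr \code{GRanges}; \code{names} (or a \code{name} column) become
#'   BED names.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
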