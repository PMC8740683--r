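test_that("readLoops filters on q and converts coordinates", {
  path <- writeBedpe(c(
    "chr1\t1000\t6000\tchr1\t50000\t55000\t0.005",
    "chr1\t1000\t6000\tchr1\t70000\t75000\t0.02"))
  loops <- readLoops(path, qThreshold = 0.01)
  expect_length(loops, 1L)
  expect_equal(S4Vectors::mcols(loops)$q_value, 0.005)
  ## 0-based [1000, 6000) becomes 1-based [1001, 6000]
  expect_equal(start(S4Vectors::first(loops)), 1001L)
  expect_equal(end(S4Vectors::first(loops)), 6000L)

  empty <- writeBedpe(character(0))
  expect_length(readLoops(empty), 0L)
})

test_that("readLoops reports malformed input with a line number", {
  bad <- writeBedpe(c(
    "chr1\t1000\t6000\tchr1\t50000\t55000\t0.005",
    "chr1\tX\t6000\tchr1\t50000\t55000\t0.005"))
  expect_error(readLoops(bad), "line 2")
  rev <- writeBedpe("chr1\t6000\t1000\tchr1\t50000\t55000\t0.005")
  expect_error(readLoops(rev), "start >= end")
  short <- writeBedpe("chr1\t1000\t6000\tchr1\t50000\t55000")
  expect_error(readLoops(short), "line 1")
})

test_that("anchors tile into 1-kb windows with a truncated last tile", {
  mkLoop <- function(s, e) S4Vectors::Pairs(
    GRanges("chr1", IRanges(s, e)),
    GRanges("chr1", IRanges(900001, 905000)),
    q_value = 0.001)
  ## 0-based [0, 5000) -> 1-based [1, 5000]: five full tiles
  tiles <- tileAndClassify(mkLoop(1, 5000), GRanges())
  t1 <- tiles[seqnames(tiles) == "chr1" & start(tiles) <= 5000]
  expect_equal(start(t1), seq(1, 4001, by = 1000))
  expect_equal(width(t1), rep(1000L, 5))

  ## 0-based [0, 1500): a full tile plus a 500-bp remainder
  tiles <- tileAndClassify(mkLoop(1, 1500), GRanges())
  t1 <- tiles[start(tiles) <= 1500]
  expect_equal(width(t1), c(1000L, 500L))
  expect_false(any(tiles$open))
})

test_that("tiling conserves anchor coverage with disjoint tiles", {
  set.seed(42)
  for (i in 1:20) {
    s <- sample.int(1e6, 1)
    w <- sample(300:12000, 1)
    loop <- S4Vectors::Pairs(GRanges("chr2", IRanges(s, s + w - 1)),
                             GRanges("chr3", IRanges(5e6, 5e6 + 4999)),
                             q_value = 0)
    tiles <- tileAndClassify(loop, GRanges())
    a <- tiles[seqnames(tiles) == "chr2"]
    expect_equal(sum(width(a)), w)
    red <- reduce(a)
    expect_length(red, 1L)
    expect_equal(c(start(red), end(red)), c(s, s + w - 1))
    expect_true(isDisjoint(a))
  }
})

test_that("openness uses >= 1 bp overlap on half-open input boundaries", {
  loop <- S4Vectors::Pairs(GRanges("chr1", IRanges(1, 1000)),
                           GRanges("chr1", IRanges(900001, 905000)),
                           q_value = 0)
  ## peak written 0-based [999, 1200) overlaps the [0,1000) tile by 1 bp
  over <- GRanges("chr1", IRanges(1000, 1200))
  tiles <- tileAndClassify(loop, over)
  expect_true(tiles$open[tiles$re_id == "chr1:0-1000"])
  ## 0-based [1000, 1200) shares only the boundary: no overlap
  abut <- GRanges("chr1", IRanges(1001, 1200))
  tiles <- tileAndClassify(loop, abut)
  expect_false(tiles$open[tiles$re_id == "chr1:0-1000"])
})

test_that("openness is monotone in the peak set", {
  loop <- S4Vectors::Pairs(GRanges("chr1", IRanges(1, 5000)),
                           GRanges("chr1", IRanges(50001, 55000)),
                           q_value = 0)
  set.seed(7)
  peaks1 <- GRanges("chr1", IRanges(sample.int(55000, 5), width = 200))
  peaks2 <- c(peaks1, GRanges("chr1", IRanges(sample.int(55000, 5), width = 200)))
  t1 <- tileAndClassify(loop, peaks1)
  t2 <- tileAndClassify(loop, peaks2)
  expect_true(all(t2$open[t1$open[match(t2$re_id, t1$re_id)]]))
})

test_that("promoters are 2 kb upstream of the TSS, strand-aware, clipped", {
  g <- GRanges("chr1", IRanges(c(10001, 5001, 501), width = 1000),
               strand = c("+", "-", "+"))
  names(g) <- c("plus", "minus", "edge")
  pr <- makePromoters(g)
  ## + strand, BED start 10000: 0-based [8000, 10000) -> 1-based [8001, 10000]
  expect_equal(start(pr["plus"]), 8001L)
  expect_equal(end(pr["plus"]), 10000L)
  ## - strand, BED end 6000: 0-based [6000, 8000) -> 1-based [6001, 8000]
  expect_equal(start(pr["minus"]), 6001L)
  expect_equal(end(pr["minus"]), 8000L)
  ## clipped at the chromosome start
  expect_equal(start(pr["edge"]), 1L)
  expect_equal(end(pr["edge"]), 500L)
  expect_error(makePromoters(unname(g)), "named")
  strand(g) <- "*"
  expect_error(makePromoters(g), "strand")
})

test_that("network links promoter-anchored loops to opposite-anchor tiles", {
  net <- toyNetwork()
  ed <- networkEdges(net)
  loopEdges <- ed[!is.na(ed$loop), ]
  expect_true(all(loopEdges$gene == "gA"))
  ## tiles of the distal anchor [150001, 155000]
  expect_setequal(unique(loopEdges$re_id),
                  sprintf("chr1:%d-%d", seq(150000, 154000, 1000),
                          seq(151000, 155000, 1000)))
  gc <- geneCategory(net)
  expect_equal(unname(gc["gA"]), "OpenLoop")
  expect_equal(unname(gc["gB"]), "NoLoop")
  ## promoter REs exist for both genes but never set the category
  expect_true(all(paste0("prom:", c("gA", "gB")) %in%
                    regulatoryElements(net)$re_id))
})

test_that("categories partition the universe; any open anchor RE wins", {
  genes <- GRanges("chr1", IRanges(c(100001, 300001, 500001), width = 10000),
                   strand = "+")
  names(genes) <- c("g1", "g2", "g3")
  loops <- S4Vectors::Pairs(
    GRanges("chr1", IRanges(c(98001, 98001, 298001), width = 5000)),
    GRanges("chr1", IRanges(c(150001, 180001, 350001), width = 5000)),
    q_value = c(0, 0, 0))
  ## one open anchor and one nonopen anchor for g1; g2 all nonopen
  peaks <- GRanges("chr1", IRanges(150101, 150500))
  res <- tileAndClassify(loops, peaks)
  net <- buildNetwork(loops, makePromoters(genes), res, genes)
  gc <- geneCategory(net)
  expect_equal(unname(gc[c("g1", "g2", "g3")]),
               c("OpenLoop", "NonOpenLoop", "NoLoop"))
  expect_equal(sort(names(gc)), sort(names(genes)))
  expect_error(buildNetwork(loops, makePromoters(genes), res, genes[1:2]),
               "universe")
})

test_that("expression quantiles treat absent genes as zero", {
  net <- toyNetwork()
  q <- suppressWarnings(expressionQuantiles(net, c(gA = 10), probs = 0.5))
  ## gA alone in OpenLoop: median 10; gB missing from expr counts as 0
  expect_equal(unname(q["OpenLoop", 1]), 10)
  expect_equal(unname(q["NoLoop", 1]), 0)
  expect_warning(qq <- expressionQuantiles(net, c(gA = 1), probs = c(0.25, 0.5)),
                 "NonOpenLoop")
  expect_true(all(is.na(qq["NonOpenLoop", ])))
  ## monotone in the probability argument
  sim <- genAll(simConfig(seed = 2, planted_re_count = 0L,
                          planted_burden_genes = 0L))
  qs <- suppressWarnings(expressionQuantiles(sim$network, sim$landscape$fpkm))
  for (r in rownames(qs))
    expect_true(all(diff(qs[r, ]) >= 0))
})

test_that("planted landscape yields higher OpenLoop expression", {
  sim <- genAll(simConfig(seed = 4, planted_re_count = 0L,
                          planted_burden_genes = 0L))
  q <- expressionQuantiles(sim$network, sim$landscape$fpkm, probs = 0.5)
  expect_gt(q["OpenLoop", 1], q["NonOpenLoop", 1])
  expect_gt(q["OpenLoop", 1], q["NoLoop", 1])
})

test_that("silencer comparison matches hypergeometric enumeration", {
  net <- toyNetwork()
  none <- silencerStats(net, net, GRanges(), category = "OpenLoop")
  expect_true(all(none$fractionA == 0))
  expect_equal(none$p.value, 1)
  expect_error(silencerStats(net, net, GRanges(), category = "NonOpenLoop"),
               "no genes")

  ## identical networks: p = 1 by symmetry
  sil <- GRanges("chr1", IRanges(150101, 150300))
  same <- silencerStats(net, net, sil, category = "OpenLoop")
  expect_equal(same$p.value, 1)

  ## engineer counts [[3,7],[0,10]] across two 10-gene networks: by
  ## enumeration P(a=3) = P(a=0) = 120/1140 and the two-sided
  ## point-probability sum collects both extremes: 240/1140
  mkNet <- function(anchorStarts) {
    tss <- seq(1e6, by = 1e5, length.out = 10)
    genes <- GRanges("chr1", IRanges(tss + 1, width = 10000), strand = "+")
    names(genes) <- sprintf("g%02d", 1:10)
    loops <- S4Vectors::Pairs(
      GRanges("chr1", IRanges(tss - 2400, width = 5000)),
      GRanges("chr1", IRanges(anchorStarts, width = 5000)),
      q_value = rep(0, 10))
    res <- tileAndClassify(loops, GRanges())
    buildNetwork(loops, makePromoters(genes), res, genes)
  }
  tss <- seq(1e6, by = 1e5, length.out = 10)
  netA <- mkNet(tss + 30001)
  netB <- mkNet(tss + 60001)
  silA <- GRanges("chr1", IRanges(tss[1:3] + 30101, width = 300))
  out <- silencerStats(netA, netB, silA, category = "NonOpenLoop")
  expect_equal(out$table, matrix(c(3, 7, 0, 10), 2, byrow = TRUE))
  expect_equal(out$p.value, 240 / 1140, tolerance = 1e-12)
  expect_equal(unname(out$fractionA["NonOpenLoop"]), 0.3)
})

test_that("network serialization round-trips", {
  net <- toyNetwork()
  stem <- tempfile("net")
  writeNetwork(net, stem)
  back <- readNetwork(stem)
  expect_equal(geneCategory(back), geneCategory(net))
  expect_equal(networkEdges(back)$re_id, networkEdges(net)$re_id)
  a <- regulatoryElements(back); b <- regulatoryElements(net)
  expect_equal(start(a), start(b))
  expect_equal(end(a), end(b))
  expect_equal(as.character(seqnames(a)), as.character(seqnames(b)))
  expect_equal(unname(a$open), unname(b$open))
})
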