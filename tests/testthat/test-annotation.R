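test_that("GTF parsing converts coordinates and groups transcripts by gene", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\tsrc\texon\t201\t300\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\tsrc\texon\t1\t300\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t2";',
    'chr1\tsrc\texon\t401\t500\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t1";'
  ), gtf)
  gms <- parse_annotation(gtf)
  expect_equal(length(gms$genes), 2L)
  expect_equal(length(gms$transcripts), 3L)
  gA <- gms$genes[gms$genes$gene_id == "gA"]
  expect_equal(GenomicRanges::start(gA), 1L)
  expect_equal(GenomicRanges::end(gA), 300L)
  t1 <- gms$transcripts[["gA.t1"]]
  expect_equal(GenomicRanges::start(t1), c(1L, 201L))
  expect_equal(GenomicRanges::end(t1), c(100L, 300L))
  # minus-strand gene: TSS on the right end of the span
  expect_equal(unname(gene_tss(gms)["gB"]), 500)
  expect_equal(unname(gene_tts(gms)["gB"]), 401)
})

test_that("GFF3 parsing resolves exon -> mRNA -> gene parents", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=gA.t1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tParent=gA.t1"
  ), gff)
  gms <- parse_annotation(gff)
  expect_equal(gms$genes$gene_id, "gA")
  expect_equal(lengths(gms$transcripts)[["gA.t1"]], 2L)
})

test_that("malformed annotations and overlapping exon chains error", {
  bad <- tempfile(fileext = ".gtf")
  writeLines("chr1\tonly\tthree", bad)
  expect_error(parse_annotation(bad), "parse error")
  expect_error(
    new_gene_model_set(gr("chr1", c(1, 50), c(100, 150)),
                       c("t1", "t1"), c("g", "g")),
    "overlapping exons")
})

test_that("unit construction matches the spec fixtures", {
  # single transcript: introns are the gaps
  gms <- toy_gms(list(g1 = list(strand = "+",
                                txs = list(list(c(1, 100), c(201, 300),
                                                c(401, 500))))))
  u <- build_units(gms)
  expect_equal(GenomicRanges::start(u$introns), c(101L, 301L))
  expect_equal(GenomicRanges::end(u$introns), c(200L, 400L))
  expect_equal(u$introns$left_flank, c("g1.e1", "g1.e2"))
  expect_equal(u$introns$right_flank, c("g1.e2", "g1.e3"))

  # second transcript's exon 151-250 splits the first intron and eats the
  # start of the second
  gms2 <- toy_gms(list(g1 = list(strand = "+",
                                 txs = list(list(c(1, 100), c(201, 300),
                                                 c(401, 500)),
                                            list(c(151, 250))))))
  u2 <- build_units(gms2)
  expect_equal(GenomicRanges::start(u2$introns), c(101L, 301L))
  expect_equal(GenomicRanges::end(u2$introns), c(150L, 400L))

  # an exon covering 90-410 wipes the whole intronic region
  gms3 <- toy_gms(list(g1 = list(strand = "+",
                                 txs = list(list(c(1, 100), c(201, 300),
                                                 c(401, 500)),
                                            list(c(90, 410))))))
  expect_equal(length(build_units(gms3)$introns), 0L)

  # single-exon gene contributes no introns
  gms4 <- toy_gms(list(g1 = list(strand = "+", txs = list(list(c(1, 200))))))
  expect_equal(length(build_units(gms4)$introns), 0L)
})

test_that("intron and exon units are base-wise disjoint and tile the span", {
  gms <- random_toy_gms(6, seed = 42)
  u <- build_units(gms, min_fragment = 1L)
  ov <- GenomicRanges::intersect(u$introns, u$exons, ignore.strand = TRUE)
  expect_equal(sum(GenomicRanges::width(ov)), 0L)
  # single-transcript genes: merged exons + introns cover the span exactly
  gms1 <- toy_gms(list(g1 = list(strand = "+",
                                 txs = list(list(c(11, 60), c(101, 160),
                                                 c(221, 300))))))
  u1 <- build_units(gms1, min_fragment = 1L)
  total <- sum(GenomicRanges::width(u1$introns)) +
    sum(GenomicRanges::width(u1$exons))
  expect_equal(total, 300L - 11L + 1L)
})

test_that("exon_universe = same_gene ignores other genes' exons", {
  spec <- list(
    g1 = list(strand = "+", txs = list(list(c(1, 100), c(301, 400)))),
    g2 = list(strand = "+", txs = list(list(c(150, 250), c(501, 600)))))
  gms <- toy_gms(spec)
  u_all <- build_units(gms, exon_universe = "all_genes")
  u_same <- build_units(gms, exon_universe = "same_gene")
  i1_all <- u_all$introns[u_all$introns$gene_id == "g1"]
  i1_same <- u_same$introns[u_same$introns$gene_id == "g1"]
  # g2's exon 150-250 punches a hole in g1's intron only under all_genes
  expect_equal(length(i1_all), 2L)
  expect_equal(length(i1_same), 1L)
  expect_equal(GenomicRanges::start(i1_same), 101L)
  expect_equal(GenomicRanges::end(i1_same), 300L)
})

test_that("relative_position follows the midpoint convention and mirrors", {
  gms <- toy_gms(list(g1 = list(strand = "+",
                                txs = list(list(c(1, 100), c(201, 500))))))
  x <- gr("chr1", 101, 200); x$gene_id <- "g1"
  expect_equal(relative_position(x, gms), 0.3)
  gms_m <- toy_gms(list(g1 = list(strand = "-",
                                  txs = list(list(c(1, 100), c(201, 500))))))
  expect_equal(relative_position(x, gms_m), 0.7)
  # whole-span interval sits at the midpoint either way
  w <- gr("chr1", 1, 500); w$gene_id <- "g1"
  expect_equal(relative_position(w, gms), 0.5)
  expect_equal(relative_position(w, gms_m), 0.5)
})

test_that("strand mirror reproduces mirrored intron positions", {
  set.seed(7)
  for (rep in 1:5) {
    n_ex <- sample(3:5, 1)
    ew <- sample(30:80, n_ex, replace = TRUE)
    iw <- sample(20:90, n_ex - 1, replace = TRUE)
    es <- 1 + cumsum(c(0, head(ew, -1) + iw))
    txs <- Map(c, es, es + ew - 1)
    L <- max(es + ew - 1)
    gms_p <- toy_gms(list(g = list(strand = "+", txs = list(txs))))
    mirror <- lapply(rev(txs), function(e) c(L - e[2] + 1, L - e[1] + 1))
    gms_m <- toy_gms(list(g = list(strand = "-", txs = list(mirror))))
    rp <- sort(build_units(gms_p, min_fragment = 1)$introns$rel_position)
    rm <- sort(build_units(gms_m, min_fragment = 1)$introns$rel_position)
    expect_equal(rp, rm, tolerance = 1e-12)
  }
})
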