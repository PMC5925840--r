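# build a transcript + genome pair with a fully specified spliced sequence
tx_fixture <- function(spliced, exon_widths, strand = "+", chrom = "chr1",
                       gap = 50L) {
  stopifnot(sum(exon_widths) == nchar(spliced))
  n <- length(exon_widths)
  starts <- 101L + cumsum(c(0L, head(exon_widths, -1) + gap))
  ends <- starts + exon_widths - 1L
  exons <- gr(chrom, starts, ends, strand)
  # write exon pieces of the spliced sequence into a random background
  L <- max(ends) + 200L
  set.seed(1234)
  bg <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  pieces_w <- if (strand == "-") rev(exon_widths) else exon_widths
  off <- cumsum(c(0L, head(pieces_w, -1)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in seq_len(n)) {
    piece <- substring(spliced, off[k] + 1, off[k] + pieces_w[k])
    chars <- strsplit(piece, "")[[1]]
    if (strand == "+") {
      bg[starts[k]:ends[k]] <- chars
    } else {
      # k-th piece 5'->3' maps to the k-th exon from the right, complemented
      idx <- (n - k + 1L)
      bg[ends[idx]:starts[idx]] <- comp[chars]
    }
  }
  genome <- Biostrings::DNAStringSet(paste(bg, collapse = ""))
  names(genome) <- chrom
  list(tm = transcript_model("t1", "g1", exons, 1L), genome = genome)
}

codons <- function(...) paste0(...)

test_that("ORF prediction finds the first in-frame stop", {
  fx <- tx_fixture("ATGAAATAA", c(5L, 4L))
  expect_identical(spliced_sequence(fx$tm, fx$genome) |> as.character(),
                   "ATGAAATAA")
  orf <- predict_orf(fx$tm, fx$genome)
  expect_equal(orf$stop_position, 7L)   # 1-based first stop base
  expect_false(orf$no_stop)

  # 30 non-stop codons then TGA: stop begins at codon 32 -> position 94
  mid <- paste(rep("GCT", 30), collapse = "")
  fx2 <- tx_fixture(paste0("ATG", mid, "TGAGG"), c(50L, 48L))
  expect_equal(predict_orf(fx2$tm, fx2$genome)$stop_position, 94L)

  # no in-frame stop
  fx3 <- tx_fixture(paste0("ATG", paste(rep("GCA", 10), collapse = "")),
                    c(15L, 18L))
  expect_true(predict_orf(fx3$tm, fx3$genome)$no_stop)

  # non-ATG start errors
  fx4 <- tx_fixture("CCGAAATAA", c(5L, 4L))
  expect_error(predict_orf(fx4$tm, fx4$genome), "ATG")
})

test_that("minus-strand transcripts splice through reverse complement", {
  s <- paste0("ATG", paste(rep("CGT", 8), collapse = ""), "TAGAAC")
  fp <- tx_fixture(s, c(13L, 10L, 10L), strand = "+")
  fm <- tx_fixture(s, c(13L, 10L, 10L), strand = "-")
  expect_equal(as.character(spliced_sequence(fm$tm, fm$genome)), s)
  expect_equal(predict_orf(fp$tm, fp$genome)$stop_position,
               predict_orf(fm$tm, fm$genome)$stop_position)
})

test_that("PTC rule is the strict >50 nt inequality", {
  # property over distances around the boundary: junction at J, stop end at
  # J - d  ->  is_ptc iff d > 50
  for (d in c(-10, 0, 1, 49, 50, 51, 60, 100)) {
    J <- 300L
    stop_pos <- J - d - 2L
    res <- classify_ptc(stop_pos, exon_widths = c(200L, 100L, 80L))
    expect_equal(res$distance, d)
    expect_identical(res$is_ptc, d > 50)
  }
  # single-exon transcript: never PTC
  res1 <- classify_ptc(10L, exon_widths = 500L)
  expect_false(res1$is_ptc)
  # measuring from the stop's first base shifts the distance by 2
  r2 <- classify_ptc(247L, c(200L, 100L, 80L), measure_from = "start")
  expect_equal(r2$distance, 53)
})

test_that("NMD candidates need PTC, fold change and significance", {
  calls <- data.frame(transcript_id = c("t1", "t2", "t3"),
                      is_ptc = c(TRUE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  set.seed(41)
  expr_a <- matrix(rep(c(10, 10, 10), 3), 3, 3,
                   dimnames = list(calls$transcript_id, NULL))
  expr_b <- expr_a
  expr_b["t1", ] <- c(31, 29, 33)   # 3x up
  expr_b["t2", ] <- c(99, 101, 103) # 10x up but no PTC
  res <- call_nmd_targets(calls, expr_a, expr_b)
  expect_true(res$nmd_candidate[res$transcript_id == "t1"])
  expect_false(res$nmd_candidate[res$transcript_id == "t2"])
  expect_false(res$nmd_candidate[res$transcript_id == "t3"])
  # single replicate: error unless explicitly overridden
  expect_error(call_nmd_targets(calls, expr_a[, 1, drop = FALSE],
                                expr_b[, 1, drop = FALSE]), "replicates")
  res1 <- call_nmd_targets(calls, expr_a[, 1, drop = FALSE],
                           expr_b[, 1, drop = FALSE], no_test = TRUE)
  expect_true(res1$nmd_candidate[1])
})

test_that("planted 4x increases on PTC transcripts are recovered", {
  set.seed(42)
  n <- 60
  ids <- paste0("t", 1:n)
  calls <- data.frame(transcript_id = ids, is_ptc = rep(c(TRUE, FALSE), n / 2),
                      stringsAsFactors = FALSE)
  base <- rlnorm(n, log(20), 0.3)
  expr_a <- matrix(rep(base, 3) * rlnorm(3 * n, 0, 0.15), n, 3,
                   dimnames = list(ids, NULL))
  up <- ifelse(calls$is_ptc, 4, 1)
  expr_b <- matrix(rep(base * up, 3) * rlnorm(3 * n, 0, 0.15), n, 3,
                   dimnames = list(ids, NULL))
  res <- call_nmd_targets(calls, expr_a, expr_b)
  expect_gte(mean(res$nmd_candidate[calls$is_ptc]), 0.9)
  expect_false(any(res$nmd_candidate[!calls$is_ptc]))
})

test_that("intron features: GC, length, reverse-complement invariance", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "GGCCATATAAGGCCGGAATT"))
  introns <- gr("chr1", c(1, 5), c(4, 8))
  introns$intron_id <- c("iGC", "iAT")
  f <- intron_features(introns, genome)$features
  expect_equal(f$gc, c(1, 0))
  expect_equal(f$length, c(4L, 4L))
  # GC is invariant under reverse complement
  set.seed(43)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  g1 <- Biostrings::DNAStringSet(c(chr1 = s))
  g2 <- Biostrings::DNAStringSet(c(chr1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))))
  iv <- gr("chr1", 101, 200); iv$intron_id <- "i"
  iv2 <- gr("chr1", 201, 300); iv2$intron_id <- "i"
  expect_equal(intron_features(iv, g1)$features$gc,
               intron_features(iv2, g2)$features$gc)
  # direct counting oracle on a random interval
  sub <- substring(s, 101, 200)
  gc_oracle <- mean(strsplit(sub, "")[[1]] %in% c("G", "C"))
  expect_equal(intron_features(iv, g1)$features$gc, gc_oracle)
  # out-of-bounds interval errors
  bad <- gr("chr1", 390, 450); bad$intron_id <- "b"
  expect_error(intron_features(bad, g1), "bounds")
  # grouped comparison returns tests
  introns10 <- gr("chr1", seq(1, 361, 40), seq(20, 380, 40))
  introns10$intron_id <- paste0("i", 1:10)
  grp <- rep(c("retained", "spliced"), 5)
  expect_true(!is.null(intron_features(introns10, g1, grp)$tests))
})

test_that("transcript models load from GTF with start codons on both strands", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ts\texon\t101\t200\t.\t+\t.\tgene_id "gP"; transcript_id "gP.t1";',
    'chr1\ts\texon\t301\t400\t.\t+\t.\tgene_id "gP"; transcript_id "gP.t1";',
    'chr1\ts\tstart_codon\t151\t153\t.\t+\t.\tgene_id "gP"; transcript_id "gP.t1";',
    'chr1\ts\texon\t501\t600\t.\t-\t.\tgene_id "gM"; transcript_id "gM.t1";',
    'chr1\ts\texon\t701\t800\t.\t-\t.\tgene_id "gM"; transcript_id "gM.t1";',
    'chr1\ts\tstart_codon\t752\t754\t.\t-\t.\tgene_id "gM"; transcript_id "gM.t1";',
    'chr1\ts\texon\t901\t950\t.\t+\t.\tgene_id "gX"; transcript_id "gX.t1";'
  ), gtf)
  tms <- NULL
  expect_warning(tms <- transcript_models_from_gtf(gtf), "gX.t1")
  expect_setequal(names(tms), c("gP.t1", "gM.t1"))
  expect_equal(tms$gP.t1$start_codon_tx, 51L)
  # minus strand: transcript starts at genomic end 800; A of ATG at 754
  expect_equal(tms$gM.t1$start_codon_tx, 47L)
  expect_equal(tms$gM.t1$exon_widths, c(100L, 100L))
})

test_that("planted ORFs in the synthetic genome drive the PTC boundary", {
  sc <- simulation_scenario(seed = 5, n_genes = 6)
  ann <- generate_annotation(sc)
  txids <- names(ann$gms$transcripts)[1:3]
  stops <- setNames(c(16L, 61L, 151L), txids)
  genome <- plant_orfs(ann, stops)
  for (txid in txids) {
    tx <- ann$gms$transcripts[[txid]]
    tm <- transcript_model(txid, sub("\\.t1$", "", txid), tx, 1L)
    orf <- predict_orf(tm, genome)
    expect_equal(orf$stop_position, unname(stops[txid]))
  }
})
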