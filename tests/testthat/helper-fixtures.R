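# Shared fixtures and independent brute-force oracles.
# Oracles work per base on plain integer vectors so they share no interval
# arithmetic with the implementation they check.

gr <- function(chrom, start, end, strand = "+") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

# GeneModelSet from a compact spec: list(gene_id = list(strand=, txs=list(
#   list(c(start, end), c(start, end), ...), ...)), ...)
toy_gms <- function(spec, chrom = "chr1") {
  es <- list(); tx <- character(0); gene <- character(0)
  for (gid in names(spec)) {
    g <- spec[[gid]]
    for (ti in seq_along(g$txs)) {
      ex <- g$txs[[ti]]
      for (e in ex) {
        es[[length(es) + 1]] <- gr(chrom, e[1], e[2], g$strand)
        tx <- c(tx, paste0(gid, ".t", ti))
        gene <- c(gene, gid)
      }
    }
  }
  new_gene_model_set(do.call(c, es), tx, gene)
}

# per-base oracle for build_units(): occupancy vectors over a window
oracle_units <- function(gms, min_fragment = 10L,
                         exon_universe = "all_genes") {
  genes <- gms$genes
  L <- max(GenomicRanges::end(genes)) + 10L
  all_exon <- logical(L); all_gap <- logical(L)
  per_gene <- list()
  for (i in seq_along(genes)) {
    gid <- genes$gene_id[i]
    tids <- names(gms$transcripts)[gms$tx_gene == gid]
    ex <- logical(L); gap <- logical(L)
    for (t in tids) {
      e <- gms$transcripts[[t]]
      v <- logical(L)
      for (k in seq_along(e))
        v[GenomicRanges::start(e)[k]:GenomicRanges::end(e)[k]] <- TRUE
      ex <- ex | v
      span <- range(which(v))
      g <- logical(L); g[span[1]:span[2]] <- TRUE
      gap <- gap | (g & !v)
    }
    per_gene[[gid]] <- list(exon = ex, gap = gap)
    all_exon <- all_exon | ex; all_gap <- all_gap | gap
  }
  runs_of <- function(v) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cbind(starts[r$values], ends[r$values])
  }
  out <- list()
  for (gid in names(per_gene)) {
    ex_uni <- if (exon_universe == "all_genes") all_exon else
      per_gene[[gid]]$exon
    gap_uni <- if (exon_universe == "all_genes") all_gap else
      per_gene[[gid]]$gap
    iv <- per_gene[[gid]]$gap & !ex_uni
    runs <- runs_of(iv)
    if (nrow(runs)) runs <- runs[runs[, 2] - runs[, 1] + 1 >= min_fragment, ,
                                 drop = FALSE]
    ev <- per_gene[[gid]]$exon & !gap_uni
    out[[gid]] <- list(introns = runs, exons = runs_of(ev))
  }
  out
}

# random multi-transcript toy annotation for oracle equivalence tests
random_toy_gms <- function(n_genes = 5, seed = 1) {
  set.seed(seed)
  spec <- list()
  pos <- 1L
  for (i in seq_len(n_genes)) {
    gid <- sprintf("tg%02d", i)
    n_tx <- sample(1:3, 1)
    txs <- list()
    n_ex <- sample(2:5, 1)
    ew <- sample(20:120, n_ex, replace = TRUE)
    iw <- sample(5:150, max(n_ex - 1, 1), replace = TRUE)
    es <- pos + cumsum(c(0, head(ew, -1) + iw[seq_len(n_ex - 1)]))
    base <- Map(c, es, es + ew - 1)
    txs[[1]] <- base
    if (n_tx > 1) for (t in 2:n_tx) {
      # perturb: drop an internal exon or extend one into its intron
      alt <- base
      if (length(alt) > 2 && runif(1) < 0.5) alt[[sample(2:(length(alt) - 1), 1)]] <- NULL
      else {
        k <- sample(seq_along(alt), 1)
        alt[[k]][2] <- alt[[k]][2] + sample(0:40, 1)
      }
      # keep exons sorted & disjoint
      m <- do.call(rbind, alt)
      m <- m[order(m[, 1]), , drop = FALSE]
      ok <- nrow(m) < 2 || all(m[-1, 1] > m[-nrow(m), 2])
      if (ok) txs[[t]] <- lapply(seq_len(nrow(m)), function(r) m[r, ])
    }
    spec[[gid]] <- list(strand = sample(c("+", "-"), 1), txs = txs)
    pos <- max(vapply(base, `[`, numeric(1), 2)) + sample(50:200, 1)
  }
  toy_gms(spec)
}

# per-base coverage/count oracle over explicit block matrices
oracle_count <- function(blocks, feat, min_bases = 1) {
  # blocks: list per read of rbind(c(s, e), ...); feat: c(s, e)
  sum(vapply(blocks, function(b) {
    ov <- 0L
    for (r in seq_len(nrow(b)))
      ov <- ov + max(0L, min(b[r, 2], feat[2]) - max(b[r, 1], feat[1]) + 1L)
    ov >= min_bases
  }, logical(1)))
}

oracle_coverage_frac <- function(blocks, feat) {
  v <- logical(feat[2] - feat[1] + 1)
  for (b in blocks) for (r in seq_len(nrow(b))) {
    s <- max(b[r, 1], feat[1]); e <- min(b[r, 2], feat[2])
    if (s <= e) v[(s - feat[1] + 1):(e - feat[1] + 1)] <- TRUE
  }
  mean(v)
}

blocks_to_grl <- function(blocks, chrom = "chr1", strand = "+") {
  nb <- vapply(blocks, nrow, integer(1))
  m <- do.call(rbind, blocks)
  if (is.null(m)) return(GenomicRanges::GRangesList())
  flat <- gr(chrom, m[, 1], m[, 2], strand)
  IRanges::relist(flat, IRanges::PartitioningByWidth(nb))
}

as_alignment_set <- function(reads, sample_id = "s") {
  structure(list(reads = reads, library_size = length(reads),
                 sample_id = sample_id), class = "AlignmentSet")
}

# hand-rolled two-sample KS statistic: sup |ECDF difference| over pooled points
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  Fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(Fx - Fy))
}

# asymptotic two-sided KS p-value (Kolmogorov series)
oracle_ks_p <- function(D, n, m) {
  t <- sqrt(n * m / (n + m)) * D
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

# exact two-sided two-sample KS p-value by lattice-path counting (no ties):
# count monotone paths (0,0)->(n,m) avoiding |i/n - j/m| >= D
oracle_ks_p_exact <- function(D, n, m) {
  u <- matrix(0, n + 1, m + 1)
  ok <- function(i, j) abs(i / n - j / m) < D - 1e-12
  u[1, 1] <- 1
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    if (!ok(i, j)) next
    acc <- 0
    if (i > 0) acc <- acc + u[i, j + 1]
    if (j > 0) acc <- acc + u[i + 1, j]
    u[i + 1, j + 1] <- acc
  }
  1 - u[n + 1, m + 1] / choose(n + m, n)
}

# minimal IRI table row constructor for differential-IR tests
iri_row <- function(intron_id, iri, gene_id = "g1", reads = 10, cov = 1,
                    gene_fpkm = 5, flank = 5, rel = 0.5, sample_id = "s") {
  data.frame(intron_id = intron_id, gene_id = gene_id, sample_id = sample_id,
             supporting_reads = reads, intron_fpkm = iri * flank,
             flank_left_fpkm = flank, flank_right_fpkm = flank,
             flank_mean_fpkm = flank, gene_fpkm = gene_fpkm,
             length_coverage = cov, iri = iri, eligible = flank > 1,
             rel_position = rel, stringsAsFactors = FALSE)
}
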