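#' Simulation scenario
#'
#' Parameter bundle for the seeded synthetic-data generator. Defaults
#' describe a desk-scale two-condition experiment: 60 multi-exon genes on
#' two chromosomes, moderate retention at baseline, a subset of introns
#' with planted 5'-biased retention increases and 3'-biased decreases, and
#' ChIP libraries in which the mutant shows a global loss of the mark on
#' half the genes plus a promoter-proximal redistribution on a planted
#' subset. Gene-level replicate noise is a Gamma rate multiplier with
#' coefficient of variation \code{replicate_cv}.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_genes Number of genes.
#' @param n_exons_range,exon_len_range,intron_len_range Integer ranges
#'   (min, max) drawn uniformly per gene/feature, in bp.
#' @param intergenic_range Gap between consecutive genes, bp.
#' @param expression_meanlog,expression_sdlog Log-normal per-gene
#'   expression weights.
#' @param base_retention Baseline intron retention level r.
#' @param retention_fold Fold applied to planted retention changes.
#' @param frac_up,frac_down Fractions of introns planted as retention-up
#'   (5'-biased) and retention-down (3'-biased).
#' @param up_beta,down_beta Beta parameters governing where planted
#'   changes land along the gene body.
#' @param rna_depth Expected exonic fragments per RNA library.
#' @param read_length Fragment length, bp (single-end).
#' @param replicate_cv Gamma noise coefficient of variation per feature
#'   and library.
#' @param chip_depth Reads per ChIP/input library.
#' @param chip_frac_shifted,chip_frac_reduced Fractions of genes with a
#'   promoter-proximal shift and with a global reduction in the mutant;
#'   the rest stay flat.
#' @param chip_reduced_factor Multiplier on reduced genes in the mutant.
#' @param front_gain,rear_loss Relative gain over the front half and loss
#'   over the rear half of the body for shifted genes.
#' @param chip_flank_level Flank intensity relative to the body.
#' @return A list of class \code{SimulationScenario}.
#' @export
simulation_scenario <- function(seed = 1L, n_genes = 60L,
                                n_exons_range = c(4L, 7L),
                                exon_len_range = c(150L, 350L),
                                intron_len_range = c(150L, 350L),
                                intergenic_range = c(2500L, 4000L),
                                expression_meanlog = log(50),
                                expression_sdlog = 0.5,
                                base_retention = 0.15,
                                retention_fold = 4,
                                frac_up = 0.2, frac_down = 0.2,
                                up_beta = c(2, 5), down_beta = c(5, 2),
                                rna_depth = 3e4, read_length = 100L,
                                replicate_cv = 0.15,
                                chip_depth = 2e5,
                                chip_frac_shifted = 0.25,
                                chip_frac_reduced = 0.5,
                                chip_reduced_factor = 0.25,
                                front_gain = 0.5, rear_loss = 0.8,
                                chip_flank_level = 0.5) {
  sc <- as.list(environment())
  stopifnot(sc$base_retention >= 0, sc$base_retention <= 1,
            sc$frac_up + sc$frac_down <= 1,
            sc$chip_frac_shifted + sc$chip_frac_reduced <= 1,
            sc$replicate_cv >= 0, sc$read_length > 0)
  class(sc) <- "SimulationScenario"
  sc
}

# deterministic per-task seed derived from the scenario seed
.derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * (seq_along(utf8ToInt(tag)) %% 7 + 1))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.gamma_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape)
}

#' Generate a synthetic annotation and genome
#'
#' Places \code{n_genes} non-overlapping multi-exon genes (one transcript
#' each) on two chromosomes with random strands, writes a GTF and a
#' uniform-composition FASTA, and returns the in-memory gene models. Runs
#' are byte-identical for a fixed scenario seed.
#'
#' @param scenario A \code{\link{simulation_scenario}}.
#' @param dir Output directory (created if needed).
#' @return List with \code{gms} (\code{GeneModelSet}), \code{genome}
#'   (\code{DNAStringSet}), \code{gtf}, \code{fasta} (paths), and
#'   \code{units} (the intron/exon units of the annotation, via
#'   \code{\link{build_units}}).
#' @export
generate_annotation <- function(scenario, dir = tempfile("sim")) {
  sc <- scenario
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.derive_seed(sc$seed, "annotation"))
  n_chrom <- 2L
  chrom_of <- rep(paste0("chr", seq_len(n_chrom)), length.out = sc$n_genes)
  chrom_of <- sort(chrom_of)
  rows <- list(); chr_len <- setNames(rep(0L, n_chrom), paste0("chr", 1:n_chrom))
  exon_gr <- list()
  for (i in seq_len(sc$n_genes)) {
    gid <- sprintf("g%03d", i)
    ch <- chrom_of[i]
    n_ex <- sample(seq(sc$n_exons_range[1], sc$n_exons_range[2]), 1)
    ex_w <- sample(seq(sc$exon_len_range[1], sc$exon_len_range[2]), n_ex,
                   replace = TRUE)
    in_w <- sample(seq(sc$intron_len_range[1], sc$intron_len_range[2]),
                   n_ex - 1, replace = TRUE)
    gap <- sample(seq(sc$intergenic_range[1], sc$intergenic_range[2]), 1)
    start <- chr_len[ch] + gap
    pos <- start
    es <- integer(n_ex); ee <- integer(n_ex)
    for (k in seq_len(n_ex)) {
      es[k] <- pos; ee[k] <- pos + ex_w[k] - 1
      pos <- ee[k] + 1 + if (k < n_ex) in_w[k] else 0
    }
    chr_len[ch] <- ee[n_ex]
    strand <- sample(c("+", "-"), 1)
    exon_gr[[gid]] <- GenomicRanges::GRanges(ch, IRanges::IRanges(es, ee),
                                             strand = strand)
  }
  chr_len <- chr_len + 3000L
  exons <- unlist(GenomicRanges::GRangesList(exon_gr), use.names = FALSE)
  gid_vec <- rep(names(exon_gr), lengths(exon_gr))
  gms <- new_gene_model_set(exons, paste0(gid_vec, ".t1"), gid_vec)

  gtf <- file.path(dir, "annotation.gtf")
  lines <- character(0)
  for (gid in names(exon_gr)) {
    e <- exon_gr[[gid]]
    ch <- as.character(GenomicRanges::seqnames(e))[1]
    st <- as.character(GenomicRanges::strand(e))[1]
    attr0 <- sprintf('gene_id "%s"; transcript_id "%s.t1";', gid, gid)
    lines <- c(lines,
               paste(ch, "sim", "gene", min(GenomicRanges::start(e)),
                     max(GenomicRanges::end(e)), ".", st, ".",
                     sprintf('gene_id "%s";', gid), sep = "\t"),
               paste(ch, "sim", "transcript", min(GenomicRanges::start(e)),
                     max(GenomicRanges::end(e)), ".", st, ".", attr0,
                     sep = "\t"),
               paste(ch, "sim", "exon", GenomicRanges::start(e),
                     GenomicRanges::end(e), ".", st, ".", attr0, sep = "\t"))
  }
  writeLines(lines, gtf)

  genome <- Biostrings::DNAStringSet(vapply(chr_len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
  names(genome) <- names(chr_len)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta, width = 80L)

  list(gms = gms, genome = genome, gtf = gtf, fasta = fasta,
       units = build_units(gms), dir = dir)
}

#' Plant per-intron retention truth with positional bias
#'
#' Assigns each annotated intron a true retention level per condition:
#' unchanged introns sit at \code{base_retention} in both; a fraction
#' \code{frac_up} is raised \code{retention_fold}-fold in condition B at
#' positions drawn with Beta(\code{up_beta}) weights (5'-biased by
#' default), and \code{frac_down} is lowered symmetrically at
#' Beta(\code{down_beta}) (3'-biased) positions.
#'
#' @param scenario A \code{\link{simulation_scenario}}.
#' @param ann Output of \code{\link{generate_annotation}}.
#' @return \code{data.frame} truth table: \code{intron_id}, \code{gene_id},
#'   \code{rel_position}, \code{r_a}, \code{r_b}, \code{direction}.
#' @export
plant_retention <- function(scenario, ann) {
  sc <- scenario
  set.seed(.derive_seed(sc$seed, "retention"))
  introns <- ann$units$introns
  n <- length(introns)
  pos <- introns$rel_position
  n_up <- round(sc$frac_up * n); n_down <- round(sc$frac_down * n)
  w_up <- stats::dbeta(pos, sc$up_beta[1], sc$up_beta[2]) + 1e-9
  idx_up <- sample(n, n_up, prob = w_up)
  rest <- setdiff(seq_len(n), idx_up)
  w_down <- stats::dbeta(pos[rest], sc$down_beta[1], sc$down_beta[2]) + 1e-9
  idx_down <- rest[sample(length(rest), n_down, prob = w_down)]
  r_a <- rep(sc$base_retention, n)
  r_b <- rep(sc$base_retention, n)
  hi <- min(1, sc$base_retention * sc$retention_fold)
  r_b[idx_up] <- hi
  r_a[idx_down] <- hi
  direction <- rep("unchanged", n)
  direction[idx_up] <- "up"; direction[idx_down] <- "down"
  data.frame(intron_id = introns$intron_id, gene_id = introns$gene_id,
             rel_position = pos, r_a = r_a, r_b = r_b,
             direction = direction, stringsAsFactors = FALSE)
}

# map retention truth (keyed by unit intron ids) onto the per-transcript
# segment table of one gene: exons and introns in genomic order
.gene_segments <- function(gms, gene_idx) {
  tx <- gms$transcripts[[which(gms$tx_gene == gms$genes$gene_id[gene_idx])[1]]]
  es <- GenomicRanges::start(tx); ee <- GenomicRanges::end(tx)
  o <- order(es); es <- es[o]; ee <- ee[o]
  n <- length(es)
  seg_s <- integer(2 * n - 1); seg_e <- integer(2 * n - 1)
  is_intron <- logical(2 * n - 1)
  seg_s[seq(1, 2 * n - 1, 2)] <- es; seg_e[seq(1, 2 * n - 1, 2)] <- ee
  if (n > 1) {
    seg_s[seq(2, 2 * n - 2, 2)] <- ee[-n] + 1
    seg_e[seq(2, 2 * n - 2, 2)] <- es[-1] - 1
    is_intron[seq(2, 2 * n - 2, 2)] <- TRUE
  }
  list(start = seg_s, end = seg_e, is_intron = is_intron)
}

#' Simulate one spliced RNA-seq library
#'
#' Fragments are drawn per gene from a retention-aware mixture: fragment
#' starts arise on exons at the gene's expression rate and inside intron j
#' at that rate times r_j; a fragment crossing a splice junction traverses
#' the intron with probability r_j and otherwise skips it as a gapped
#' (spliced) block. This makes per-base intron coverage r times the exon
#' coverage, so the retention index estimates r without bias. Gamma noise
#' multiplies each gene's rate and each intron's r per library.
#'
#' @param scenario \code{\link{simulation_scenario}}.
#' @param ann Output of \code{\link{generate_annotation}}.
#' @param truth Truth table from \code{\link{plant_retention}}.
#' @param condition \code{"a"} or \code{"b"} (selects \code{r_a}/\code{r_b}).
#' @param replicate Replicate number (enters the derived seed).
#' @param path Output alignment path (\code{.bed} for BED12, \code{.sam}).
#' @param expression Optional named per-gene expression weights; drawn
#'   log-normally from the scenario when missing (fixed per seed, shared
#'   by conditions).
#' @return List with \code{path}, \code{n_fragments} and the
#'   \code{expression} used.
#' @export
simulate_rnaseq <- function(scenario, ann, truth, condition = c("a", "b"),
                            replicate = 1L, path = tempfile(fileext = ".bed"),
                            expression = NULL) {
  sc <- scenario
  condition <- match.arg(condition)
  if (sc$rna_depth <= 0) stop("rna_depth must be positive")
  gms <- ann$gms
  n_genes <- length(gms$genes)
  if (is.null(expression)) {
    set.seed(.derive_seed(sc$seed, "expression"))
    expression <- setNames(stats::rlnorm(n_genes, sc$expression_meanlog,
                                         sc$expression_sdlog),
                           gms$genes$gene_id)
  }
  set.seed(.derive_seed(sc$seed, paste0("rna_", condition, "_", replicate)))
  rl <- sc$read_length
  r_col <- if (condition == "a") "r_a" else "r_b"

  # annotated intron -> truth r lookup by coordinates of the unit set
  introns_gr <- ann$units$introns
  r_truth <- setNames(truth[[r_col]], truth$intron_id)

  spl_len <- vapply(seq_len(n_genes), function(i)
    sum(GenomicRanges::width(
      gms$transcripts[[which(gms$tx_gene == gms$genes$gene_id[i])[1]]])),
    numeric(1))
  w <- expression[gms$genes$gene_id] * spl_len
  rho <- sc$rna_depth * (expression[gms$genes$gene_id] / sum(w))  # per-bp rate

  gene_mult <- .gamma_mult(n_genes, sc$replicate_cv)
  all_s <- vector("list", n_genes); all_e <- vector("list", n_genes)
  all_read <- vector("list", n_genes); all_chr <- character(n_genes)
  all_strand <- character(n_genes)
  read_count <- 0L
  for (gi in seq_len(n_genes)) {
    gid <- gms$genes$gene_id[gi]
    seg <- .gene_segments(gms, gi)
    ns <- length(seg$start)
    seg_r <- rep(1, ns)
    if (any(seg$is_intron)) {
      ii <- which(seg$is_intron)
      # match each annotated intron to its unit id (identical coordinates
      # for the non-overlapping simulated genes)
      gi_units <- introns_gr[introns_gr$gene_id == gid]
      m <- match(seg$start[ii], GenomicRanges::start(gi_units))
      r0 <- ifelse(is.na(m), 0, unname(r_truth[gi_units$intron_id[m]]))
      r_mult <- .gamma_mult(length(ii), sc$replicate_cv)
      seg_r[ii] <- pmin(1, r0 * r_mult)
    }
    lens <- seg$end - seg$start + 1
    rate <- rho[gi] * gene_mult[gi] * lens * ifelse(seg$is_intron, seg_r, 1)
    n_seg <- stats::rpois(ns, rate)
    total <- sum(n_seg)
    if (total == 0L) next
    seg_idx <- rep(seq_len(ns), n_seg)
    offs <- floor(stats::runif(total) * lens[seg_idx])
    starts0 <- seg$start[seg_idx] + offs
    if (all(lens >= rl)) {
      # fast path: every feature is at least one read long, so a fragment
      # spans at most one junction -> at most two blocks, fully vectorised
      rem <- seg$end[seg_idx] - starts0 + 1
      need2 <- rem < rl
      e1 <- starts0 + rl - 1
      last_seg <- seg_idx == ns
      e1[need2 & last_seg] <- seg$end[ns]        # clipped at transcript end
      cross <- need2 & !last_seg
      entering <- cross & seg$is_intron[pmin(seg_idx + 1L, ns)]
      keep <- rep(TRUE, total)
      if (any(entering))
        keep[entering] <-
          stats::runif(sum(entering)) <= seg_r[seg_idx[entering] + 1L]
      split2 <- entering & !keep                 # spliced: gap over the intron
      e1[split2] <- seg$end[seg_idx[split2]]
      s2 <- seg$start[pmin(seg_idx + 2L, ns)][split2]
      e2 <- s2 + (rl - rem[split2]) - 1
      bs <- as.list(starts0); be <- as.list(e1)
      two <- which(split2)
      if (length(two)) {
        bs[two] <- Map(c, starts0[two], s2)
        be[two] <- Map(c, e1[two], e2)
      }
    } else {
      bs <- vector("list", total); be <- vector("list", total)
      for (k in seq_len(total)) {
        i <- seg_idx[k]; cur <- starts0[k]; remaining <- rl
        s_vec <- integer(0); e_vec <- integer(0)
        repeat {
          take <- min(seg$end[i] - cur + 1, remaining)
          if (length(e_vec) && cur == e_vec[length(e_vec)] + 1)
            e_vec[length(e_vec)] <- cur + take - 1
          else { s_vec <- c(s_vec, cur); e_vec <- c(e_vec, cur + take - 1) }
          remaining <- remaining - take
          if (remaining == 0L) break
          i <- i + 1L
          while (i <= ns && seg$is_intron[i] && stats::runif(1) > seg_r[i])
            i <- i + 1L
          if (i > ns) break
          cur <- seg$start[i]
        }
        bs[[k]] <- s_vec; be[[k]] <- e_vec
      }
    }
    all_s[[gi]] <- bs; all_e[[gi]] <- be
    all_chr[gi] <- as.character(GenomicRanges::seqnames(gms$genes))[gi]
    all_strand[gi] <- as.character(GenomicRanges::strand(gms$genes))[gi]
    read_count <- read_count + total
  }
  # flatten into a GRangesList of fragments
  nblocks <- unlist(lapply(all_s, function(x) lengths(x)), use.names = FALSE)
  if (is.null(nblocks)) nblocks <- integer(0)
  starts <- unlist(lapply(all_s, unlist), use.names = FALSE)
  ends <- unlist(lapply(all_e, unlist), use.names = FALSE)
  chrs <- rep(rep(all_chr, vapply(all_s, length, integer(1))), nblocks)
  strands <- rep(rep(all_strand, vapply(all_s, length, integer(1))), nblocks)
  gr <- GenomicRanges::GRanges(chrs, IRanges::IRanges(starts, ends),
                               strand = strands)
  GenomeInfoDb::seqlevels(gr) <- names(ann$genome)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(ann$genome)
  reads <- IRanges::relist(gr, IRanges::PartitioningByWidth(nblocks))
  write_alignments(reads, path,
                   seqlengths = stats::setNames(Biostrings::width(ann$genome),
                                                names(ann$genome)))
  list(path = path, n_fragments = length(reads), expression = expression)
}

#' Plant ChIP profile shapes per gene
#'
#' Assigns each gene a mutant profile shape: \code{shifted} (front-half
#' gain, rear-half loss), \code{reduced} (global loss of the mark), or
#' \code{flat} (unchanged). Wild type is always flat. Shift status is
#' drawn independently per mark so all four gene types occur.
#'
#' @param scenario \code{\link{simulation_scenario}}.
#' @param ann Output of \code{\link{generate_annotation}}.
#' @param marks Mark names to assign (default me2 and me3).
#' @return \code{data.frame}: \code{gene_id} plus one shape column per
#'   mark and logical \code{<mark>_shifted} truth columns and the
#'   implied \code{type} (I, II, III, IV).
#' @export
plant_chip_shapes <- function(scenario, ann,
                              marks = c("H3K36me2", "H3K36me3")) {
  sc <- scenario
  set.seed(.derive_seed(sc$seed, "chipshapes"))
  gids <- ann$gms$genes$gene_id
  n <- length(gids)
  out <- data.frame(gene_id = gids, stringsAsFactors = FALSE)
  n_sh <- round(sc$chip_frac_shifted * n)
  n_red <- round(sc$chip_frac_reduced * n)
  for (mk in marks) {
    shape <- rep("flat", n)
    idx <- sample(n, n_sh + n_red)
    shape[idx[seq_len(n_sh)]] <- "shifted"
    shape[idx[n_sh + seq_len(n_red)]] <- "reduced"
    out[[paste0(mk, "_shape")]] <- shape
    out[[paste0(mk, "_shifted")]] <- shape == "shifted"
  }
  if (length(marks) == 2) {
    a <- out[[paste0(marks[1], "_shifted")]]
    b <- out[[paste0(marks[2], "_shifted")]]
    out$type <- ifelse(a & b, "III", ifelse(a, "I", ifelse(b, "II", "IV")))
  }
  out
}

#' Simulate one ChIP library (and optionally its input control)
#'
#' Each gene's read density over its 100/300/100 bin layout follows the
#' assigned shape (flat, reduced, or shifted with front-half gain and
#' rear-half loss in transcription orientation); reads are placed by
#' sampling a bin proportional to intensity times bin width, then
#' uniformly within it. The library is sequenced to a fixed total depth,
#' so a global loss of signal on reduced genes inflates the remaining
#' genes after depth normalization, exactly as in a real fixed-depth
#' sequencing run. Input reads are uniform over the genome.
#'
#' @param scenario \code{\link{simulation_scenario}}.
#' @param ann Output of \code{\link{generate_annotation}}.
#' @param shapes Character vector of per-gene shapes (names = gene ids),
#'   e.g. one mark's column of \code{\link{plant_chip_shapes}}; use
#'   \code{"flat"} everywhere for a wild-type library.
#' @param condition \code{"wt"} forces every gene flat at full level;
#'   \code{"mut"} applies \code{shapes}.
#' @param path Output BED path for the ChIP reads.
#' @param input_path Optional output BED path for a matched uniform input
#'   library.
#' @param tag Extra string entering the derived seed (e.g. the mark).
#' @return List with \code{path}, \code{input_path}, \code{n_reads}.
#' @export
simulate_chip <- function(scenario, ann, shapes, condition = c("mut", "wt"),
                          path = tempfile(fileext = ".bed"),
                          input_path = NULL, tag = "chip") {
  sc <- scenario
  condition <- match.arg(condition)
  set.seed(.derive_seed(sc$seed, paste0(tag, "_", condition)))
  gms <- ann$gms
  g <- gms$genes
  n <- length(g)
  if (is.null(names(shapes))) names(shapes) <- g$gene_id
  if (!all(shapes %in% c("flat", "reduced", "shifted")))
    stop("unknown profile shape: ",
         paste(setdiff(unique(shapes), c("flat", "reduced", "shifted")),
               collapse = ", "))
  rl <- sc$read_length
  flank_bp <- 2000L
  nb <- 300L; nf <- 100L
  weights <- vector("list", n)
  for (i in seq_len(n)) {
    body <- rep(1, nb)
    shp <- if (condition == "wt") "flat" else shapes[[g$gene_id[i]]]
    if (shp == "shifted") {
      body[1:(nb / 2)] <- 1 + sc$front_gain
      body[(nb / 2 + 1):nb] <- 1 - sc$rear_loss
    } else if (shp == "reduced") body <- body * sc$chip_reduced_factor
    flank <- rep(sc$chip_flank_level *
                   if (shp == "reduced") sc$chip_reduced_factor else 1, nf)
    intens <- c(flank, body, flank)
    minus <- as.character(GenomicRanges::strand(g))[i] == "-"
    if (minus) intens <- rev(intens)
    bw <- c(rep(flank_bp / nf, nf),
            rep(GenomicRanges::width(g)[i] / nb, nb),
            rep(flank_bp / nf, nf))
    weights[[i]] <- intens * bw
  }
  per_gene <- vapply(weights, sum, numeric(1)) *
    .gamma_mult(n, sc$replicate_cv)
  n_reads <- stats::rpois(n, sc$chip_depth * per_gene / sum(per_gene))
  starts <- vector("list", n)
  for (i in seq_len(n)) {
    if (n_reads[i] == 0L) next
    wv <- weights[[i]]
    bins <- sample.int(length(wv), n_reads[i], replace = TRUE, prob = wv)
    bw <- c(rep(flank_bp / 100, 100),
            rep(GenomicRanges::width(g)[i] / 300, 300),
            rep(flank_bp / 100, 100))
    edges <- cumsum(c(0, bw))
    pos <- GenomicRanges::start(g)[i] - flank_bp + edges[bins] +
      stats::runif(n_reads[i]) * bw[bins]
    starts[[i]] <- floor(pos) - rl %/% 2L
  }
  chr <- rep(as.character(GenomicRanges::seqnames(g)), n_reads)
  st <- unlist(starts, use.names = FALSE)
  if (is.null(st)) st <- numeric(0)
  chrlen <- stats::setNames(Biostrings::width(ann$genome), names(ann$genome))
  st <- pmax(1, pmin(st, chrlen[chr] - rl + 1))
  gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, width = rl),
                               strand = "*")
  GenomeInfoDb::seqlevels(gr) <- names(ann$genome)
  GenomeInfoDb::seqlengths(gr) <- chrlen
  gr <- GenomicRanges::sort(gr)
  rtracklayer::export(gr, path, format = "bed")
  if (!is.null(input_path)) {
    n_in <- stats::rpois(1, sc$chip_depth)
    p_chr <- chrlen / sum(chrlen)
    chr_in <- sample(names(chrlen), n_in, replace = TRUE, prob = p_chr)
    st_in <- floor(stats::runif(n_in) * (chrlen[chr_in] - rl)) + 1
    gri <- GenomicRanges::GRanges(chr_in, IRanges::IRanges(st_in, width = rl))
    GenomeInfoDb::seqlevels(gri) <- names(ann$genome)
    GenomeInfoDb::seqlengths(gri) <- chrlen
    gri <- GenomicRanges::sort(gri)
    rtracklayer::export(gri, input_path, format = "bed")
  }
  list(path = path, input_path = input_path, n_reads = sum(n_reads))
}

#' Plant clean open reading frames into the synthetic genome
#'
#' Rewrites the genome so that each listed transcript begins with ATG at
#' spliced position 1, contains no in-frame stop before the requested
#' position, and carries a TAA stop whose first base sits at
#' \code{stop_tx}. Used to exercise ORF prediction and the PTC rule with
#' known truth.
#'
#' @param ann Output of \code{\link{generate_annotation}} (its
#'   \code{genome} is modified and returned).
#' @param stop_tx Named integer vector: first-base spliced position of the
#'   planted stop codon per transcript id; must be \code{1 + 3k}.
#' @return The modified \code{DNAStringSet} genome.
#' @export
plant_orfs <- function(ann, stop_tx) {
  genome <- as.character(ann$genome)
  gms <- ann$gms
  for (txid in names(stop_tx)) {
    tx <- gms$transcripts[[txid]]
    if (is.null(tx)) stop("unknown transcript: ", txid)
    strand <- as.character(GenomicRanges::strand(tx))[1]
    ch <- as.character(GenomicRanges::seqnames(tx))[1]
    tx <- GenomicRanges::sort(tx)
    gpos <- unlist(lapply(seq_along(tx), function(i)
      GenomicRanges::start(tx)[i]:GenomicRanges::end(tx)[i]))
    if (strand == "-") gpos <- rev(gpos)
    S <- length(gpos)
    sp <- stop_tx[[txid]]
    if (sp %% 3 != 1 || sp + 2 > S)
      stop("stop_tx must be in frame and inside transcript ", txid)
    seq_chars <- strsplit(genome[[ch]], "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    get_tx <- function(i) if (strand == "+") seq_chars[gpos[i]] else
      comp[seq_chars[gpos[i]]]
    set_tx <- function(i, base) {
      if (strand == "+") seq_chars[gpos[i]] <<- base
      else seq_chars[gpos[i]] <<- comp[base]
    }
    put <- function(at, codon) for (k in 0:2)
      set_tx(at + k, substr(codon, k + 1, k + 1))
    put(1, "ATG")
    if (sp > 4) for (cs in seq(4, sp - 3, by = 3)) {
      cod <- paste0(get_tx(cs), get_tx(cs + 1), get_tx(cs + 2))
      if (cod %in% c("TAA", "TAG", "TGA")) put(cs, "CAA")
    }
    put(sp, "TAA")
    # scrub stops downstream of planted one? not needed: first stop wins
    genome[[ch]] <- paste(seq_chars, collapse = "")
  }
  out <- Biostrings::DNAStringSet(genome)
  names(out) <- names(ann$genome)
  out
}
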