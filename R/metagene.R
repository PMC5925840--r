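#' Fractional-edge bin means of a per-base signal
#'
#' Splits a numeric per-base vector into \code{n} bins of equal (possibly
#' fractional) width and returns the coverage-weighted mean of each bin.
#' Because bin means are formed from the interpolated cumulative sum, the
#' bin means times the bin width always sum back to the total signal.
#'
#' @param v Numeric per-base signal.
#' @param n Number of bins.
#' @return Numeric vector of length \code{n}.
#' @keywords internal
bin_means <- function(v, n) {
  L <- length(v)
  if (L == 0L) return(numeric(n))
  cs <- c(0, cumsum(as.numeric(v)))
  edges <- seq(0, L, length.out = n + 1)
  lo <- floor(edges); frac <- edges - lo
  F <- cs[lo + 1] + frac * c(v, 0)[pmin(lo + 1, L + 1)]
  diff(F) / diff(edges)
}

.gene_windows <- function(gms, flank_bp) {
  g <- gms$genes
  data.frame(gene_id = g$gene_id,
             chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g),
             minus = as.character(GenomicRanges::strand(g)) == "-",
             win_start = GenomicRanges::start(g) - flank_bp,
             win_end = GenomicRanges::end(g) + flank_bp,
             stringsAsFactors = FALSE)
}

.base_vector <- function(cov, chrom, from, to) {
  n <- to - from + 1
  out <- numeric(n)
  if (!chrom %in% names(cov)) return(out)
  rl <- cov[[chrom]]
  L <- length(rl)
  s <- max(1L, from); e <- min(L, to)
  if (s <= e)
    out[(s - from + 1):(e - from + 1)] <-
      as.numeric(S4Vectors::window(rl, s, e))
  out
}

#' 500-bin metagene profiles of input-calibrated ChIP coverage
#'
#' For every gene whose body (TSS to TTS, the annotation span) is longer
#' than 500 bp, per-base read coverage over the body and the upstream and
#' downstream flanks is averaged into 300 + 2 x 100 bins (fractional bin
#' edges for the body, so profiles are length-invariant), scaled to a
#' 10-million-read library, and calibrated against the identically binned
#' input control. Profiles of minus-strand genes are flipped so bins always
#' run TSS to TTS.
#'
#' @param chip_aln,input_aln \code{AlignmentSet}s for the ChIP library and
#'   its input control; \code{input_aln} may be \code{NULL} only when
#'   \code{calibration = "none"}.
#' @param gms \code{GeneModelSet}.
#' @param n_body,n_flank Bins over the gene body and over each flank.
#' @param flank_bp Flank extent in bp (default 2000).
#' @param calibration \code{"difference"} (default): normalized ChIP minus
#'   normalized input, giving signed values around zero as the shift caller
#'   requires; \code{"log2ratio"}: log2 of the pseudocounted ratio;
#'   \code{"none"}: normalized ChIP only.
#' @param pseudocount Pseudocount for \code{"log2ratio"}.
#' @param scale_to Library size the profiles are scaled to (1e7 reads).
#' @return Numeric matrix genes x \code{n_body + 2 * n_flank} with gene ids
#'   as rownames and attributes \code{layout} (n_flank/n_body) and
#'   \code{excluded} (named character vector of excluded genes with
#'   reasons).
#' @export
bin_coverage <- function(chip_aln, input_aln, gms, n_body = 300L,
                         n_flank = 100L, flank_bp = 2000L,
                         calibration = c("difference", "log2ratio", "none"),
                         pseudocount = 0.5, scale_to = 1e7) {
  calibration <- match.arg(calibration)
  if (is.null(input_aln) && calibration != "none")
    stop("input control alignments are required for input calibration")
  min_body <- n_body + 2L * n_flank  # genes must exceed total bin count
  covC <- GenomicRanges::coverage(unlist(chip_aln$reads, use.names = FALSE))
  sC <- scale_to / chip_aln$library_size
  if (!is.null(input_aln)) {
    covI <- GenomicRanges::coverage(unlist(input_aln$reads, use.names = FALSE))
    sI <- scale_to / input_aln$library_size
  }
  wins <- .gene_windows(gms, flank_bp)
  body_len <- wins$end - wins$start + 1
  keep <- body_len > 500L
  excluded <- setNames(rep("gene body <= 500 bp", sum(!keep)),
                       wins$gene_id[!keep])
  wins <- wins[keep, , drop = FALSE]
  nbin <- n_body + 2L * n_flank
  mat <- matrix(0, nrow(wins), nbin, dimnames = list(wins$gene_id, NULL))
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    profile_one <- function(cov, sc) {
      up <- bin_means(.base_vector(cov, w$chrom, w$win_start, w$start - 1),
                      n_flank)
      body <- bin_means(.base_vector(cov, w$chrom, w$start, w$end), n_body)
      down <- bin_means(.base_vector(cov, w$chrom, w$end + 1, w$win_end),
                        n_flank)
      c(up, body, down) * sc
    }
    pc <- profile_one(covC, sC)
    row <- switch(calibration,
                  none = pc,
                  difference = pc - profile_one(covI, sI),
                  log2ratio = log2((pc + pseudocount) /
                                     (profile_one(covI, sI) + pseudocount)))
    if (w$minus) row <- rev(row)
    mat[i, ] <- row
  }
  attr(mat, "layout") <- c(n_flank = n_flank, n_body = n_body)
  attr(mat, "excluded") <- excluded
  mat
}

#' Across-gene mean metagene profile
#'
#' @param profiles Matrix from \code{\link{bin_coverage}}.
#' @return Numeric vector of per-bin means with attribute \code{n_genes}.
#' @export
aggregate_profile <- function(profiles) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  if (nrow(profiles) == 0L) stop("no profiles to aggregate")
  out <- colMeans(profiles)
  attr(out, "n_genes") <- nrow(profiles)
  out
}

#' Mutant-minus-wild-type difference matrix
#'
#' Per-gene difference of metagene profiles, with rows ordered by
#' descending number of strictly positive gene-body bins ("red bins"; a
#' zero difference is neither red nor green), ties broken by gene id.
#'
#' @param profiles_mut,profiles_wt Matrices from \code{\link{bin_coverage}}
#'   over the same gene set and layout.
#' @return Matrix of differences with attribute \code{sort_key} (the
#'   per-row red-bin count, in row order) and the layout attribute carried
#'   over.
#' @export
diff_matrix <- function(profiles_mut, profiles_wt) {
  gm <- rownames(profiles_mut); gw <- rownames(profiles_wt)
  if (!setequal(gm, gw))
    stop("gene sets differ between conditions: ",
         paste(union(setdiff(gm, gw), setdiff(gw, gm)), collapse = ", "))
  layout <- attr(profiles_mut, "layout")
  if (is.null(layout))
    layout <- c(n_flank = 100L,
                n_body = ncol(profiles_mut) - 200L)
  d <- profiles_mut - profiles_wt[gm, , drop = FALSE]
  body <- layout["n_flank"] + seq_len(layout["n_body"])
  key <- rowSums(d[, body, drop = FALSE] > 0)
  o <- order(-key, rownames(d))
  d <- d[o, , drop = FALSE]
  attr(d, "sort_key") <- key[o]
  attr(d, "layout") <- layout
  d
}

#' Promoter-proximal shift call on a difference profile
#'
#' A gene's histone mark is called shifted toward the promoter when, in the
#' mutant-minus-wild-type difference, at least 30 percent of the bins of
#' the front half of the gene body (45 of 150 under the default layout)
#' are strictly positive while at least 30 percent of the rear-half bins
#' are strictly negative. Flank bins are ignored and no magnitude
#' threshold is applied.
#'
#' @param diff Difference matrix (or single profile vector) in the
#'   100/300/100 layout from \code{\link{diff_matrix}}.
#' @param min_frac Required fraction of qualifying bins per half (0.3).
#' @param n_flank,n_body Layout (taken from the matrix attribute when
#'   present).
#' @return Named logical vector, one call per gene.
#' @export
call_shift <- function(diff, min_frac = 0.3, n_flank = NULL, n_body = NULL) {
  if (is.null(dim(diff))) diff <- matrix(diff, nrow = 1)
  layout <- attr(diff, "layout")
  if (is.null(n_flank)) n_flank <- if (!is.null(layout)) layout[["n_flank"]] else 100L
  if (is.null(n_body)) n_body <- if (!is.null(layout)) layout[["n_body"]] else 300L
  half <- n_body %/% 2L
  need <- ceiling(min_frac * half)
  front <- diff[, n_flank + seq_len(half), drop = FALSE]
  rear <- diff[, n_flank + half + seq_len(n_body - half), drop = FALSE]
  out <- rowSums(front > 0) >= need & rowSums(rear < 0) >= need
  setNames(out, rownames(diff))
}

#' Four-way gene classes from two marks' shift calls
#'
#' Type I: only the first mark (H3K36me2) shifts; type II: only the second
#' (H3K36me3); type III: both; type IV: neither.
#'
#' @param me2_calls,me3_calls Named logical vectors over the same genes.
#' @return \code{data.frame} with \code{gene_id}, \code{me2_shifted},
#'   \code{me3_shifted}, \code{type}.
#' @export
classify_shift_types <- function(me2_calls, me3_calls) {
  if (!setequal(names(me2_calls), names(me3_calls)))
    stop("shift calls cover different gene sets")
  g <- names(me2_calls)
  m3 <- me3_calls[g]
  type <- ifelse(me2_calls & m3, "III",
                 ifelse(me2_calls, "I", ifelse(m3, "II", "IV")))
  data.frame(gene_id = g, me2_shifted = unname(me2_calls),
             me3_shifted = unname(m3), type = unname(type),
             stringsAsFactors = FALSE)
}

#' Normalized ChIP signal over intron groups
#'
#' Mean input-calibrated, depth-normalized per-base coverage over each
#' intron, compared between groups (e.g. IRI-up vs IRI-down introns) with
#' a two-sided Welch t-test.
#'
#' @param chip_aln,input_aln \code{AlignmentSet}s; input may be \code{NULL}.
#' @param intron_groups Named list of \code{GRanges} of introns, one
#'   element per group; every group must be non-empty.
#' @param scale_to Normalization target library size.
#' @return List with \code{values} (named list of per-intron signals),
#'   \code{medians}, and \code{tests} (pairwise t-test table).
#' @export
signal_at_introns <- function(chip_aln, input_aln, intron_groups,
                              scale_to = 1e7) {
  if (any(!vapply(intron_groups, length, integer(1))))
    stop("every intron group must be non-empty")
  covC <- GenomicRanges::coverage(unlist(chip_aln$reads, use.names = FALSE))
  sC <- scale_to / chip_aln$library_size
  covI <- if (!is.null(input_aln))
    GenomicRanges::coverage(unlist(input_aln$reads, use.names = FALSE))
  sI <- if (!is.null(input_aln)) scale_to / input_aln$library_size
  mean_signal <- function(gr) {
    vapply(seq_along(gr), function(i) {
      ch <- as.character(GenomicRanges::seqnames(gr))[i]
      s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
      m <- mean(.base_vector(covC, ch, s, e)) * sC
      if (!is.null(covI)) m <- m - mean(.base_vector(covI, ch, s, e)) * sI
      m
    }, numeric(1))
  }
  vals <- lapply(intron_groups, mean_signal)
  pairs <- utils::combn(names(vals), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(group_a = p[1], group_b = p[2],
               p_value = tryCatch(stats::t.test(vals[[p[1]]],
                                                vals[[p[2]]])$p.value,
                                  error = function(e) NA_real_))
  }))
  list(values = vals, medians = vapply(vals, stats::median, numeric(1)),
       tests = tests)
}

#' Association between gene-body ChIP signal and expression
#'
#' Bins genes into expression quantiles, reports the mean signal per
#' quantile, and computes the Spearman rank correlation between signal and
#' expression across genes (defined as 0 when either variable is
#' constant).
#'
#' @param signal Named per-gene mean signal vector.
#' @param gene_fpkm Named per-gene expression vector.
#' @param n_quantiles Number of quantile bins.
#' @return List with \code{quantile_summary} and \code{spearman_rho}.
#' @export
signal_expression_association <- function(signal, gene_fpkm,
                                          n_quantiles = 5) {
  genes <- intersect(names(signal), names(gene_fpkm))
  if (length(genes) < n_quantiles)
    stop("fewer genes than quantiles")
  s <- signal[genes]; f <- gene_fpkm[genes]
  q <- cut(rank(f, ties.method = "first"), breaks = n_quantiles,
           labels = FALSE)
  summ <- data.frame(quantile = seq_len(n_quantiles),
                     mean_signal = as.numeric(tapply(s, q, mean)),
                     mean_fpkm = as.numeric(tapply(f, q, mean)))
  rho <- if (stats::sd(s) == 0 || stats::sd(f) == 0) 0 else
    stats::cor(s, f, method = "spearman")
  list(quantile_summary = summ, spearman_rho = rho)
}
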