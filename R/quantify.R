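#' Count fragments supporting a feature
#'
#' A fragment supports a feature when at least \code{min_overlap} bp of one
#' of its aligned blocks overlap the feature (default 1 bp, the most
#' inclusive rule). A spliced fragment whose gap spans the feature
#' contributes nothing. With \code{rule = "contained"} a fragment counts
#' only when all its blocks lie inside the feature.
#'
#' @param aln An \code{AlignmentSet} or a \code{GRangesList} of fragments.
#' @param features \code{GRanges} of features to count over.
#' @param min_overlap Minimum block overlap in bp under the default rule.
#' @param rule \code{"overlap"} (default) or \code{"contained"}.
#' @param stranded Count only fragments on the feature's strand.
#' @return Integer vector of counts parallel to \code{features}.
#' @export
count_feature_reads <- function(aln, features, min_overlap = 1L,
                                rule = c("overlap", "contained"),
                                stranded = FALSE) {
  rule <- match.arg(rule)
  reads <- if (inherits(aln, "AlignmentSet")) aln$reads else aln
  if (length(reads) == 0L) return(integer(length(features)))
  if (rule == "overlap") {
    GenomicRanges::countOverlaps(features, reads,
                                     minoverlap = min_overlap,
                                     ignore.strand = !stranded)
  } else {
    spans <- unlist(range(reads), use.names = FALSE)
    hits <- GenomicRanges::findOverlaps(spans, features, type = "within",
                                        ignore.strand = !stranded)
    tabulate(S4Vectors::subjectHits(hits), nbins = length(features))
  }
}

#' Fragments per kilobase per million mapped fragments
#'
#' @param count Fragment count(s) over the feature.
#' @param feature_length_bp Feature length(s) in bp; must be positive.
#' @param total_mapped_reads Library size (uniquely mapped fragments).
#' @return Numeric FPKM value(s).
#' @export
fpkm <- function(count, feature_length_bp, total_mapped_reads) {
  if (any(feature_length_bp <= 0)) stop("feature length must be positive")
  if (length(total_mapped_reads) != 1L || total_mapped_reads <= 0)
    stop("library size must be a single positive number")
  count / (feature_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Fraction of feature bases covered by at least one read block
#'
#' @inheritParams count_feature_reads
#' @return Numeric fractions in \code{[0, 1]} parallel to \code{features}.
#' @export
length_coverage <- function(aln, features) {
  reads <- if (inherits(aln, "AlignmentSet")) aln$reads else aln
  out <- numeric(length(features))
  if (length(reads) == 0L || length(features) == 0L) return(out)
  blk <- GenomicRanges::reduce(unlist(reads, use.names = FALSE),
                               ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(features, blk, ignore.strand = TRUE)
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(features[S4Vectors::queryHits(hits)],
                                    blk[S4Vectors::subjectHits(hits)],
                                    ignore.strand = TRUE)
    covered <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    out[as.integer(names(covered))] <- as.numeric(covered)
  }
  out / GenomicRanges::width(features)
}

#' Intron retention index
#'
#' IRI of an intron is its FPKM divided by the mean FPKM of its two
#' neighbouring exons. When the flank mean is zero the index is undefined
#' and returned as \code{NA} (never a silent 0/0).
#'
#' @param intron_fpkm Intron FPKM value(s).
#' @param flank_fpkm_left,flank_fpkm_right Flanking exon FPKM values.
#' @return Numeric IRI value(s); \code{NA} where undefined.
#' @export
compute_iri <- function(intron_fpkm, flank_fpkm_left, flank_fpkm_right) {
  fm <- (flank_fpkm_left + flank_fpkm_right) / 2
  ifelse(is.na(fm) | fm <= 0, NA_real_, intron_fpkm / fm)
}

#' Quantify intron retention for one sample
#'
#' Produces one row per intron unit with supporting-read count, intron FPKM,
#' flanking-exon FPKMs, host-gene FPKM (over the gene's merged exon units),
#' intron length coverage, the IRI, and an eligibility flag (both flanking
#' exons expressed above \code{min_flank_fpkm}).
#'
#' @param aln \code{AlignmentSet} for the sample.
#' @param units Unit sets from \code{\link{build_units}}.
#' @param gms The \code{GeneModelSet}.
#' @param min_overlap,rule,stranded Support-rule parameters passed to
#'   \code{\link{count_feature_reads}}.
#' @param min_flank_fpkm Eligibility threshold on each flanking exon's FPKM
#'   (strict inequality; default 1).
#' @return \code{data.frame} with columns \code{intron_id}, \code{gene_id},
#'   \code{sample_id}, \code{supporting_reads}, \code{intron_fpkm},
#'   \code{flank_left_fpkm}, \code{flank_right_fpkm}, \code{flank_mean_fpkm},
#'   \code{gene_fpkm}, \code{length_coverage}, \code{iri}, \code{eligible},
#'   \code{rel_position}.
#' @export
quantify_sample <- function(aln, units, gms, min_overlap = 1L,
                            rule = "overlap", stranded = FALSE,
                            min_flank_fpkm = 1) {
  introns <- units$introns; exons <- units$exons
  reads <- aln$reads
  lib <- aln$library_size
  if (lib <= 0) stop("empty alignment library")
  ann_chr <- unique(as.character(GenomicRanges::seqnames(gms$genes)))
  aln_chr <- GenomeInfoDb::seqlevels(reads)
  if (!any(ann_chr %in% aln_chr))
    stop("chromosome names in alignments do not match the annotation: ",
         "annotation has [", paste(ann_chr, collapse = ","),
         "], alignments have [", paste(utils::head(aln_chr, 10), collapse = ","),
         "]")

  n_int <- count_feature_reads(aln, introns, min_overlap, rule, stranded)
  int_fpkm <- fpkm(n_int, GenomicRanges::width(introns), lib)
  n_ex <- count_feature_reads(aln, exons, min_overlap, rule, stranded)
  ex_fpkm <- fpkm(n_ex, GenomicRanges::width(exons), lib)
  names(ex_fpkm) <- exons$exon_id
  lf <- unname(ex_fpkm[introns$left_flank])
  rf <- unname(ex_fpkm[introns$right_flank])

  # gene FPKM over the merged exon units of the host gene
  gcounts <- tapply(n_ex, factor(exons$gene_id), sum)
  glens <- tapply(GenomicRanges::width(exons), factor(exons$gene_id), sum)
  gf <- fpkm(as.numeric(gcounts), as.numeric(glens), lib)
  names(gf) <- names(gcounts)
  lc <- length_coverage(aln, introns)
  iri <- compute_iri(int_fpkm, lf, rf)
  iri[n_int == 0 & !is.na(iri)] <- 0

  data.frame(
    intron_id = introns$intron_id,
    gene_id = introns$gene_id,
    sample_id = aln$sample_id,
    supporting_reads = as.integer(n_int),
    intron_fpkm = int_fpkm,
    flank_left_fpkm = lf,
    flank_right_fpkm = rf,
    flank_mean_fpkm = (lf + rf) / 2,
    gene_fpkm = unname(gf[introns$gene_id]),
    length_coverage = lc,
    iri = iri,
    eligible = !is.na(lf) & !is.na(rf) &
      lf > min_flank_fpkm & rf > min_flank_fpkm,
    rel_position = introns$rel_position,
    stringsAsFactors = FALSE
  )
}

#' Gene-level FPKM for one sample
#'
#' FPKM over each gene's merged exons (all transcripts), used for
#' expression-change comparisons and metagene/expression association.
#'
#' @inheritParams quantify_sample
#' @return Named numeric vector of FPKM, one element per gene.
#' @export
gene_fpkm_table <- function(aln, gms, stranded = FALSE) {
  merged <- GenomicRanges::reduce(
    S4Vectors::split(unlist(gms$transcripts, use.names = FALSE),
                     factor(rep(gms$tx_gene, lengths(gms$transcripts)),
                            levels = gms$genes$gene_id)))
  flat <- unlist(merged, use.names = FALSE)
  gid <- rep(names(merged), lengths(merged))
  n <- count_feature_reads(aln, flat, stranded = stranded)
  cnt <- tapply(n, factor(gid, levels = gms$genes$gene_id), sum)
  len <- tapply(GenomicRanges::width(flat),
                factor(gid, levels = gms$genes$gene_id), sum)
  out <- fpkm(as.numeric(cnt), as.numeric(len), aln$library_size)
  setNames(out, gms$genes$gene_id)
}

#' Write an IRI table as TSV
#'
#' @param tab Data frame from \code{\link{quantify_sample}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_iri_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
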