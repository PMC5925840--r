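#' Non-overlapping intron and exon units
#'
#' Builds, per gene, the set of introns (or intron fragments) that overlap no
#' exon in the configured exon universe, and the reciprocal set of exon
#' fragments that overlap no annotated intron. Retention is then quantified
#' on these units only, so that reads over an alternatively used exon are
#' never mistaken for intronic coverage.
#'
#' Per gene, candidate introns are the gaps between consecutive exons of
#' each transcript, merged across transcripts. Every base overlapping an
#' exon of the universe is subtracted; surviving fragments shorter than
#' \code{min_fragment} bp are dropped. Exon units are the merged exons of
#' the gene minus every base covered by a candidate intron of the universe.
#' Each intron unit records its genomically nearest flanking exon units of
#' the same gene and its position along the gene body relative to the TSS.
#'
#' @param gms A \code{GeneModelSet} from \code{\link{parse_annotation}}.
#' @param exon_universe \code{"all_genes"} (default) subtracts exons of all
#'   genes on both strands; \code{"same_gene"} only the host gene's exons.
#'   The reciprocal intron universe used for exon units follows the same
#'   setting.
#' @param min_fragment Minimum surviving intron-fragment width in bp
#'   (default 10); shorter slivers are discarded.
#' @param position \code{"midpoint"} (default) or \code{"five_prime"}:
#'   which point of the intron defines its gene-body relative position.
#' @return List with elements \code{introns} and \code{exons}, both
#'   \code{GRanges}. \code{introns} carries metadata columns
#'   \code{intron_id}, \code{gene_id}, \code{left_flank}, \code{right_flank}
#'   (exon-unit ids, \code{NA} when no same-gene exon unit survives on that
#'   side) and \code{rel_position}; \code{exons} carries \code{exon_id} and
#'   \code{gene_id}.
#' @export
build_units <- function(gms, exon_universe = c("all_genes", "same_gene"),
                        min_fragment = 10L,
                        position = c("midpoint", "five_prime")) {
  exon_universe <- match.arg(exon_universe)
  position <- match.arg(position)
  txs <- gms$transcripts
  tx_gene <- gms$tx_gene
  genes <- gms$genes

  # candidate introns: gaps between consecutive exons within each transcript
  tx_spans <- unlist(range(txs), use.names = FALSE)
  gaps_tx <- GenomicRanges::psetdiff(tx_spans, txs)
  gap_gene <- rep(tx_gene, lengths(gaps_tx))
  gaps <- unlist(gaps_tx, use.names = FALSE)
  intron_cand <- GenomicRanges::reduce(
    S4Vectors::split(gaps, factor(gap_gene, levels = genes$gene_id)))
  exon_merged <- GenomicRanges::reduce(
    S4Vectors::split(unlist(txs, use.names = FALSE),
                         factor(rep(tx_gene, lengths(txs)),
                                levels = genes$gene_id)))

  all_exons <- unlist(exon_merged, use.names = FALSE)
  all_introns <- unlist(intron_cand, use.names = FALSE)

  int_meta <- list(); ex_meta <- list()
  for (i in seq_along(genes)) {
    gid <- genes$gene_id[i]
    ex_uni <- if (exon_universe == "all_genes") all_exons else exon_merged[[i]]
    in_uni <- if (exon_universe == "all_genes") all_introns else intron_cand[[i]]
    iu <- GenomicRanges::setdiff(intron_cand[[i]], ex_uni, ignore.strand = TRUE)
    iu <- iu[GenomicRanges::width(iu) >= min_fragment]
    eu <- GenomicRanges::setdiff(exon_merged[[i]], in_uni, ignore.strand = TRUE)
    GenomicRanges::strand(iu) <- GenomicRanges::strand(genes)[i]
    GenomicRanges::strand(eu) <- GenomicRanges::strand(genes)[i]
    int_meta[[gid]] <- iu
    ex_meta[[gid]] <- eu
  }
  label <- function(gene_ids, infix, counts)
    if (length(gene_ids)) paste0(gene_ids, infix, sequence(counts[counts > 0]))
    else character(0)
  exons <- unlist(GenomicRanges::GRangesList(ex_meta), use.names = FALSE)
  exons$gene_id <- rep(names(ex_meta), lengths(ex_meta))
  exons$exon_id <- label(exons$gene_id, ".e", lengths(ex_meta))
  introns <- unlist(GenomicRanges::GRangesList(int_meta), use.names = FALSE)
  introns$gene_id <- rep(names(int_meta), lengths(int_meta))
  introns$intron_id <- label(introns$gene_id, ".i", lengths(int_meta))

  # nearest same-gene flanking exon units (genomic left/right)
  lf <- rf <- rep(NA_character_, length(introns))
  if (length(introns) && length(exons)) {
    for (gid in unique(introns$gene_id)) {
      ii <- which(introns$gene_id == gid)
      ei <- which(exons$gene_id == gid)
      if (!length(ei)) next
      es <- GenomicRanges::start(exons)[ei]; ee <- GenomicRanges::end(exons)[ei]
      for (j in ii) {
        s <- GenomicRanges::start(introns)[j]; e <- GenomicRanges::end(introns)[j]
        left <- ei[ee < s]
        right <- ei[es > e]
        if (length(left))
          lf[j] <- exons$exon_id[left[which.max(ee[ee < s])]]
        if (length(right))
          rf[j] <- exons$exon_id[right[which.min(es[es > e])]]
      }
    }
  }
  introns$left_flank <- lf
  introns$right_flank <- rf
  introns$rel_position <- relative_position(introns, gms, convention = position)
  list(introns = introns, exons = exons)
}

#' Gene-body relative position of intervals
#'
#' Position of an interval along its host gene body as a fraction in
#' \code{[0, 1]} measured from the TSS: 0 at the TSS, 1 at the TTS. On the
#' minus strand the axis is flipped, so a mirrored gene yields the mirrored
#' position.
#'
#' @param x \code{GRanges} with a \code{gene_id} metadata column.
#' @param gms The \code{GeneModelSet} supplying gene spans and strands.
#' @param convention \code{"midpoint"} (default) uses the interval midpoint;
#'   \code{"five_prime"} the interval end closest to the TSS.
#' @return Numeric vector of fractions in \code{[0, 1]}.
#' @export
relative_position <- function(x, gms, convention = c("midpoint", "five_prime")) {
  convention <- match.arg(convention)
  if (length(x) == 0L) return(numeric(0))
  g <- gms$genes
  idx <- match(x$gene_id, g$gene_id)
  if (anyNA(idx)) stop("unknown gene_id in relative_position()")
  gs <- GenomicRanges::start(g)[idx]; ge <- GenomicRanges::end(g)[idx]
  w <- ge - gs + 1
  if (any(w <= 0)) stop("zero-length gene span")
  minus <- as.character(GenomicRanges::strand(g))[idx] == "-"
  # work on the 0-based continuous axis so mirror symmetry is exact
  if (convention == "midpoint") {
    pos0 <- (GenomicRanges::start(x) - 1 + GenomicRanges::end(x)) / 2
  } else {
    pos0 <- ifelse(minus, GenomicRanges::end(x), GenomicRanges::start(x) - 1)
  }
  rel <- (pos0 - (gs - 1)) / w
  rel[minus] <- 1 - rel[minus]
  pmin(pmax(rel, 0), 1)
}

#' Export intron/exon units as BED6
#'
#' Writes units with \code{name} = unit id and, for introns,
#' \code{score} = \code{rel_position * 1000}; strand is the host gene's.
#'
#' @param units Output of \code{\link{build_units}}.
#' @param intron_path,exon_path Output BED file paths (either may be
#'   \code{NULL} to skip).
#' @return Invisibly, the written paths.
#' @export
export_units_bed <- function(units, intron_path = NULL, exon_path = NULL) {
  if (!is.null(intron_path)) {
    gr <- units$introns
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::ranges(gr),
                                  strand = GenomicRanges::strand(gr))
    out$name <- gr$intron_id
    out$score <- round(gr$rel_position * 1000)
    rtracklayer::export(out, intron_path, format = "bed")
  }
  if (!is.null(exon_path)) {
    gr <- units$exons
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::ranges(gr),
                                  strand = GenomicRanges::strand(gr))
    out$name <- gr$exon_id
    out$score <- 0L
    rtracklayer::export(out, exon_path, format = "bed")
  }
  invisible(c(intron_path, exon_path))
}
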