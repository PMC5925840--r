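#' Gene models from a GTF/GFF3 annotation
#'
#' Parses exon features from a GTF or GFF3 file and assembles one gene model
#' per gene: the genomic span, strand, and the exon chains of all transcripts
#' assigned to the gene. Coordinates follow the Bioconductor convention
#' (1-based, closed intervals); GTF/GFF 1-based inclusive coordinates map
#' onto it directly and BED input/output is converted at the boundary by
#' \pkg{rtracklayer}.
#'
#' @param path Path to a GTF (attributes \code{gene_id}/\code{transcript_id})
#'   or GFF3 (\code{ID}/\code{Parent}) annotation file. The format is chosen
#'   from the file extension (\code{.gff}/\code{.gff3} vs anything else).
#' @return A \code{GeneModelSet}: a list with elements
#'   \describe{
#'     \item{genes}{\code{GRanges}, one range per gene (the gene span, i.e.
#'       the range of all its exons) with metadata column \code{gene_id}.}
#'     \item{transcripts}{named \code{GRangesList} of exon chains, one
#'       element per transcript, each with a \code{gene_id} in
#'       \code{metadata(transcripts)$gene_id} order-matched to the list.}
#'   }
#' @details Transcripts without any exon feature are skipped with a warning.
#'   On the minus strand the transcription start site (TSS) is the right
#'   (largest-coordinate) end of the span; see \code{\link{gene_tss}}.
#' @export
parse_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  fmt <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  gr <- tryCatch(
    rtracklayer::import(path, format = fmt),
    error = function(e) stop("annotation parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  if (fmt == "gff3") {
    # exon Parent points at the transcript; transcript Parent at the gene
    tx_id <- vapply(ex$Parent, function(p) as.character(p)[1], character(1))
    feat <- gr[tolower(as.character(gr$type)) %in%
                 c("mrna", "transcript", "gene")]
    parent_of <- setNames(
      vapply(feat$Parent, function(p)
        if (length(p)) as.character(p)[1] else NA_character_, character(1)),
      feat$ID)
    gene_id <- parent_of[tx_id]
    gene_id[is.na(gene_id)] <- tx_id[is.na(gene_id)]
  } else {
    tx_id <- as.character(ex$transcript_id)
    gene_id <- as.character(ex$gene_id)
  }
  if (anyNA(tx_id) || anyNA(gene_id))
    stop("exon features missing gene/transcript identifiers in ", path)
  new_gene_model_set(ex, tx_id, gene_id)
}

#' Build a GeneModelSet from exon ranges
#'
#' Lower-level constructor used by \code{\link{parse_annotation}} and by the
#' synthetic-data generator.
#'
#' @param exons \code{GRanges} of exons.
#' @param tx_id,gene_id character vectors parallel to \code{exons}.
#' @return A \code{GeneModelSet} (see \code{\link{parse_annotation}}).
#' @export
new_gene_model_set <- function(exons, tx_id, gene_id) {
  stopifnot(length(exons) == length(tx_id), length(exons) == length(gene_id))
  o <- order(gene_id, tx_id, GenomicRanges::start(exons))
  exons <- exons[o]; tx_id <- tx_id[o]; gene_id <- gene_id[o]
  S4Vectors::mcols(exons) <- NULL
  txs <- S4Vectors::split(exons, factor(tx_id, levels = unique(tx_id)))
  tx_gene <- tapply(gene_id, factor(tx_id, levels = unique(tx_id)),
                    function(g) g[1])
  # per-transcript exon chains must be non-overlapping
  bad <- vapply(seq_along(txs), function(i) {
    e <- txs[[i]]
    length(GenomicRanges::reduce(e, min.gapwidth = 0L)) != length(e)
  }, logical(1))
  if (any(bad))
    stop("overlapping exons within transcript(s): ",
         paste(names(txs)[bad], collapse = ", "))
  gene_lv <- unique(as.character(tx_gene))
  spans <- unlist(range(S4Vectors::split(
    exons, factor(as.character(tx_gene)[match(tx_id, names(tx_gene))],
                  levels = gene_lv))))
  genes <- GenomicRanges::GRanges(spans)
  genes$gene_id <- gene_lv
  obj <- list(genes = genes,
              transcripts = txs,
              tx_gene = as.character(tx_gene))
  class(obj) <- "GeneModelSet"
  obj
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", length(x$genes), "genes,",
      length(x$transcripts), "transcripts\n")
  invisible(x)
}

#' Transcription start / termination sites
#'
#' Strand-aware endpoints of each gene span: on \code{+} the TSS is the left
#' end of the span, on \code{-} the right end (and conversely for the TTS).
#'
#' @param gms A \code{GeneModelSet}.
#' @return Named integer vector of genomic positions, one per gene.
#' @export
gene_tss <- function(gms) {
  g <- gms$genes
  pos <- ifelse(as.character(GenomicRanges::strand(g)) == "-",
                GenomicRanges::end(g), GenomicRanges::start(g))
  setNames(pos, g$gene_id)
}

#' @rdname gene_tss
#' @export
gene_tts <- function(gms) {
  g <- gms$genes
  pos <- ifelse(as.character(GenomicRanges::strand(g)) == "-",
                GenomicRanges::start(g), GenomicRanges::end(g))
  setNames(pos, g$gene_id)
}
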