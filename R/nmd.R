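#' Transcript model for ORF prediction
#'
#' A transcript's exon chain plus the annotated start-codon position in
#' spliced transcript coordinates, the anchor for open-reading-frame
#' prediction.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param exons \code{GRanges} of the transcript's exons (any order; sorted
#'   genomically internally). All exons must share one chromosome/strand.
#' @param start_codon_tx 1-based position of the A of the start ATG in
#'   spliced transcript coordinates.
#' @return A \code{TranscriptModel} list with fields \code{transcript_id},
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{exons} (genomic,
#'   sorted), \code{exon_widths} (5' to 3' in transcript orientation) and
#'   \code{start_codon_tx}.
#' @export
transcript_model <- function(transcript_id, gene_id, exons, start_codon_tx) {
  strand <- as.character(GenomicRanges::strand(exons))[1]
  if (!strand %in% c("+", "-")) stop("transcript strand must be + or -")
  exons <- GenomicRanges::sort(exons)
  w <- GenomicRanges::width(exons)
  if (strand == "-") w <- rev(w)
  if (start_codon_tx < 1 || start_codon_tx > sum(w) - 2)
    stop("start codon outside the spliced transcript: ", transcript_id)
  list(transcript_id = transcript_id, gene_id = gene_id,
       chrom = as.character(GenomicRanges::seqnames(exons))[1],
       strand = strand, exons = exons, exon_widths = w,
       start_codon_tx = as.integer(start_codon_tx))
}

#' Transcript models from a GTF with start_codon features
#'
#' Reads exon and \code{start_codon} features and builds one
#' \code{\link{transcript_model}} per transcript that carries an annotated
#' start codon, mapping the genomic start-codon position into spliced
#' transcript coordinates. Transcripts without a start codon are skipped
#' with a warning.
#'
#' @param path GTF file with \code{exon} and \code{start_codon} features
#'   carrying \code{gene_id}/\code{transcript_id} attributes.
#' @return Named list of \code{TranscriptModel}s.
#' @export
transcript_models_from_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  type <- tolower(as.character(gr$type))
  ex <- gr[type == "exon"]
  st <- gr[type == "start_codon"]
  if (!length(st))
    stop("no start_codon features in ", path)
  out <- list()
  skipped <- character(0)
  for (txid in unique(as.character(ex$transcript_id))) {
    exons <- GenomicRanges::sort(ex[ex$transcript_id == txid])
    sc <- st[st$transcript_id == txid]
    if (!length(sc)) { skipped <- c(skipped, txid); next }
    strand <- as.character(GenomicRanges::strand(exons))[1]
    # genomic position of the A of ATG
    gpos <- if (strand == "-") max(GenomicRanges::end(sc)) else
      min(GenomicRanges::start(sc))
    w <- GenomicRanges::width(exons)
    es <- GenomicRanges::start(exons); ee <- GenomicRanges::end(exons)
    k <- which(gpos >= es & gpos <= ee)
    if (length(k) != 1) stop("start codon outside exons of ", txid)
    tx_pos <- if (strand == "+")
      sum(w[seq_len(k - 1)]) + (gpos - es[k] + 1)
    else
      sum(rev(w)[seq_len(length(w) - k)]) + (ee[k] - gpos + 1)
    out[[txid]] <- transcript_model(txid,
                                    as.character(exons$gene_id)[1],
                                    GenomicRanges::granges(exons), tx_pos)
  }
  if (length(skipped))
    warning("skipped transcript(s) without start_codon: ",
            paste(skipped, collapse = ", "))
  out
}

#' Load a genome FASTA as a named DNAStringSet
#'
#' Thin wrapper around \code{Biostrings::readDNAStringSet} that trims FASTA
#' descriptions to bare sequence names.
#'
#' @param path FASTA file.
#' @return Named \code{DNAStringSet}.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*", "", names(g))
  g
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences in transcript orientation
#' (reverse-complemented for minus-strand transcripts).
#'
#' @param tm A \code{\link{transcript_model}}.
#' @param genome \code{DNAStringSet} of chromosome sequences (named).
#' @return A \code{DNAString}.
#' @export
spliced_sequence <- function(tm, genome) {
  if (!tm$chrom %in% names(genome))
    stop("chromosome ", tm$chrom, " absent from the genome")
  chr <- genome[[tm$chrom]]
  s <- GenomicRanges::start(tm$exons); e <- GenomicRanges::end(tm$exons)
  if (any(s < 1) || any(e > length(chr)))
    stop("exon interval outside chromosome bounds for ", tm$transcript_id)
  parts <- lapply(seq_along(s), function(i) Biostrings::subseq(chr, s[i], e[i]))
  seqs <- do.call(Biostrings::xscat, parts)
  if (tm$strand == "-") seqs <- Biostrings::reverseComplement(seqs)
  seqs
}

#' First in-frame stop codon after the annotated start
#'
#' Scans codons from the annotated start (which must be ATG) and returns
#' the 1-based spliced-transcript position of the first base of the first
#' in-frame stop codon (TAA, TAG or TGA), or \code{NA} with a
#' \code{no_stop} flag when translation runs off the transcript end.
#'
#' @param tm A \code{\link{transcript_model}}.
#' @param genome Named \code{DNAStringSet}.
#' @return List with \code{stop_position} (1-based first stop base, or
#'   \code{NA}) and \code{no_stop}.
#' @export
predict_orf <- function(tm, genome) {
  seqs <- as.character(spliced_sequence(tm, genome))
  st <- tm$start_codon_tx
  if (substr(seqs, st, st + 2) != "ATG")
    stop("annotated start codon is not ATG for transcript ", tm$transcript_id)
  starts <- seq.int(st, nchar(seqs) - 2L, by = 3L)
  codons <- substring(seqs, starts, starts + 2L)
  hit <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (!length(hit)) return(list(stop_position = NA_integer_, no_stop = TRUE))
  list(stop_position = starts[hit[1]], no_stop = FALSE)
}

#' Premature-termination-codon classification
#'
#' A stop codon is premature when it lies more than 50 nt upstream of the
#' last exon-exon junction, measured in spliced coordinates from the end
#' of the stop codon (\code{measure_from = "end"}, default) or from its
#' first base. Single-exon transcripts have no junction and are never PTC.
#'
#' @param stop_position 1-based spliced position of the first stop base
#'   (\code{NA} allowed: yields \code{is_ptc = FALSE}).
#' @param exon_widths Exon lengths 5' to 3' in transcript orientation.
#' @param min_distance Distance that must be exceeded (default 50 nt).
#' @param measure_from \code{"end"} or \code{"start"} of the stop codon.
#' @return List with \code{stop_position}, \code{last_junction}
#'   (spliced nt upstream of the junction, \code{NA} for single-exon),
#'   \code{distance} and \code{is_ptc}.
#' @export
classify_ptc <- function(stop_position, exon_widths, min_distance = 50,
                         measure_from = c("end", "start")) {
  measure_from <- match.arg(measure_from)
  if (length(exon_widths) < 2 || is.na(stop_position))
    return(list(stop_position = stop_position, last_junction = NA_real_,
                distance = NA_real_, is_ptc = FALSE))
  last_junction <- sum(exon_widths[-length(exon_widths)])
  ref <- if (measure_from == "end") stop_position + 2 else stop_position
  distance <- last_junction - ref
  list(stop_position = stop_position, last_junction = last_junction,
       distance = distance, is_ptc = distance > min_distance)
}

#' Nonsense-mediated decay candidate calls
#'
#' A PTC-containing transcript is an NMD candidate when its abundance
#' increases more than \code{fold}-fold between the two conditions with a
#' p-value below \code{alpha} (default: Welch t-test on log2(FPKM + 1)
#' across replicates; any vectorised two-sample test can be plugged in).
#'
#' @param ptc_calls \code{data.frame} with \code{transcript_id} and
#'   \code{is_ptc} (e.g. assembled from \code{\link{classify_ptc}}).
#' @param expr_a,expr_b Numeric matrices transcripts x replicates of FPKM
#'   for the reference and test condition (rownames = transcript ids).
#' @param fold,alpha Call thresholds (strict inequalities).
#' @param test Function \code{(xa, xb) -> p.value} on log2(FPKM+1)
#'   replicate vectors; defaults to the Welch t-test.
#' @param no_test Allow candidate calls without a p-value when fewer than
#'   two replicates are available.
#' @return \code{ptc_calls} with added \code{fold_change}, \code{p_value}
#'   and \code{nmd_candidate}.
#' @export
call_nmd_targets <- function(ptc_calls, expr_a, expr_b, fold = 2,
                             alpha = 0.05, test = NULL, no_test = FALSE) {
  ids <- ptc_calls$transcript_id
  missing <- setdiff(ids, intersect(rownames(expr_a), rownames(expr_b)))
  if (length(missing))
    stop("expression missing for transcripts: ",
         paste(utils::head(missing, 5), collapse = ", "))
  xa <- expr_a[ids, , drop = FALSE]; xb <- expr_b[ids, , drop = FALSE]
  fc <- (rowMeans(xb) + 0.01) / (rowMeans(xa) + 0.01)
  few_reps <- ncol(xa) < 2 || ncol(xb) < 2
  if (few_reps && !no_test)
    stop("fewer than two replicates: p-values undefined; ",
         "set no_test = TRUE to call on fold change alone")
  if (is.null(test))
    test <- function(a, b) stats::t.test(a, b)$p.value
  pv <- if (few_reps) rep(NA_real_, length(ids)) else
    vapply(seq_along(ids), function(i)
      tryCatch(test(log2(xa[i, ] + 1), log2(xb[i, ] + 1)),
               error = function(e) NA_real_), numeric(1))
  ptc_calls$fold_change <- unname(fc)
  ptc_calls$p_value <- pv
  ptc_calls$nmd_candidate <- ptc_calls$is_ptc & fc > fold &
    (if (few_reps) no_test else !is.na(pv) & pv < alpha)
  ptc_calls
}

#' Intron length and GC content, with group comparison
#'
#' @param introns \code{GRanges} of introns with an \code{intron_id}
#'   column.
#' @param genome Named \code{DNAStringSet}.
#' @param groups Optional factor/character vector parallel to
#'   \code{introns} (e.g. retained vs spliced); when given, per-group
#'   summaries and Welch t-tests on length and GC are added.
#' @return List with \code{features} (\code{data.frame}: id, length, GC)
#'   and, when grouped, \code{tests}.
#' @export
intron_features <- function(introns, genome, groups = NULL) {
  ch <- as.character(GenomicRanges::seqnames(introns))
  bad <- !ch %in% names(genome) |
    GenomicRanges::start(introns) < 1 |
    GenomicRanges::end(introns) >
      Biostrings::width(genome)[match(ch, names(genome))]
  if (any(bad)) stop("intron interval(s) outside chromosome bounds")
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(introns), function(i)
    Biostrings::subseq(genome[[ch[i]]],
                       GenomicRanges::start(introns)[i],
                       GenomicRanges::end(introns)[i])))
  gc <- as.numeric(Biostrings::letterFrequency(seqs, "GC")) /
    Biostrings::width(seqs)
  feats <- data.frame(intron_id = introns$intron_id %||%
                        as.character(seq_along(introns)),
                      length = GenomicRanges::width(introns),
                      gc = gc, stringsAsFactors = FALSE)
  out <- list(features = feats)
  if (!is.null(groups)) {
    feats$group <- as.character(groups)
    out$features <- feats
    lv <- unique(feats$group)
    if (length(lv) >= 2) {
      pairs <- utils::combn(lv, 2, simplify = FALSE)
      out$tests <- do.call(rbind, lapply(pairs, function(p) {
        a <- feats[feats$group == p[1], ]; b <- feats[feats$group == p[2], ]
        data.frame(group_a = p[1], group_b = p[2],
                   p_length = tryCatch(stats::t.test(a$length, b$length)$p.value,
                                       error = function(e) NA_real_),
                   p_gc = tryCatch(stats::t.test(a$gc, b$gc)$p.value,
                                   error = function(e) NA_real_))
      }))
    }
  }
  out
}
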