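#' Read aligned fragments from BED or BAM/SAM
#'
#' Loads uniquely aligned fragments as sets of genomic blocks. A spliced
#' fragment carries one block per aligned segment; the skipped gap between
#' blocks never counts as coverage. BED12 block structure and BAM/SAM
#' N-gapped CIGARs are both honoured.
#'
#' @param path Alignment file; format by extension: \code{.bed} (BED6 or
#'   BED12), \code{.bam}, or \code{.sam} (converted on the fly).
#' @param sample_id Optional label stored on the returned object.
#' @return An \code{AlignmentSet}: list with \code{reads} (a
#'   \code{GRangesList}, one element per fragment) and \code{library_size}
#'   (number of fragments, used as the FPKM denominator).
#' @export
read_alignments <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    if (!is.null(gr$blocks)) {
      reads <- rtracklayer::blocks(gr)
    } else {
      S4Vectors::mcols(gr) <- NULL
      reads <- S4Vectors::split(gr, seq_along(gr))
    }
  } else if (ext %in% c("bam", "sam")) {
    bam <- path
    if (ext == "sam") bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
    ga <- GenomicAlignments::readGAlignments(bam)
    reads <- GenomicAlignments::grglist(ga)
  } else stop("unsupported alignment format: .", ext)
  obj <- list(reads = reads, library_size = length(reads),
              sample_id = sample_id %||% basename(path))
  class(obj) <- "AlignmentSet"
  obj
}

#' @export
print.AlignmentSet <- function(x, ...) {
  cat("AlignmentSet '", x$sample_id, "': ", x$library_size, " fragments\n",
      sep = "")
  invisible(x)
}

#' Write fragments as BED12 (or SAM)
#'
#' Used by the synthetic-data generator; BED12 encodes spliced fragments as
#' blocks. SAM emission writes gapped CIGARs with \code{*} sequence, enough
#' for the BAM ingestion path to be exercised.
#'
#' @param reads \code{GRangesList} of per-fragment blocks.
#' @param path Output path ending in \code{.bed} or \code{.sam}.
#' @param seqlengths Named vector of chromosome lengths (required for SAM).
#' @return Invisibly, \code{path}.
#' @export
write_alignments <- function(reads, path, seqlengths = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    bed <- rtracklayer::asBED(reads)
    bed <- GenomicRanges::sort(bed, ignore.strand = TRUE)
    rtracklayer::export(bed, path, format = "bed")
  } else if (ext == "sam") {
    if (is.null(seqlengths)) stop("SAM output needs seqlengths")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 paste0("@SQ\tSN:", names(seqlengths), "\tLN:", seqlengths)),
               con)
    n <- length(reads)
    if (n) {
      starts_l <- GenomicRanges::start(reads)
      widths_l <- GenomicRanges::width(reads)
      flat <- unlist(reads, use.names = FALSE)
      first <- cumsum(lengths(reads)) - lengths(reads) + 1
      chrom <- as.character(GenomicRanges::seqnames(flat))[first]
      strand1 <- as.character(GenomicRanges::strand(flat))[first]
      cigar <- vapply(seq_len(n), function(i) {
        w <- widths_l[[i]]; s <- starts_l[[i]]
        if (length(w) == 1L) paste0(w, "M")
        else paste(paste0(w, "M"),
                   c(paste0(s[-1] - (s[-length(s)] + w[-length(w)]), "N"), ""),
                   sep = "", collapse = "")
      }, character(1))
      flag <- ifelse(strand1 == "-", 16L, 0L)
      writeLines(paste(paste0("r", seq_len(n)), flag, chrom,
                       vapply(starts_l, `[`, numeric(1), 1L),
                       60L, cigar, "*", 0L, 0L, "*", "*", sep = "\t"), con)
    }
  } else stop("unsupported alignment output format: .", ext)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
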