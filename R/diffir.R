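#' Thresholds for differential intron-retention calling
#'
#' Bundles the filters applied before a retention change is called: minimum
#' replicate-averaged supporting reads, minimum intron length coverage,
#' minimum host-gene FPKM, the strict flanking-exon FPKM bound, the fold
#' cutoff on the IRI ratio, and the pseudocount added to both averaged IRIs
#' before forming the ratio (guards zero denominators; the index itself is
#' a ratio of FPKMs and can legitimately be 0).
#'
#' @param min_reads Minimum supporting reads in the asserting condition.
#' @param min_coverage Minimum intron length coverage (fraction).
#' @param min_gene_fpkm Minimum host-gene FPKM.
#' @param min_flank_fpkm Each flanking exon must exceed this FPKM.
#' @param fold Fold-change cutoff on the pseudocount-adjusted IRI ratio.
#' @param pseudocount Added to both averaged IRIs before the ratio.
#' @param filter_scope \code{"higher"} (default): filters are evaluated in
#'   the condition with the higher averaged IRI, the one asserting
#'   retention; \code{"both"} requires them in both conditions.
#' @return A list of class \code{ir_thresholds}.
#' @export
ir_thresholds <- function(min_reads = 3, min_coverage = 0.8,
                          min_gene_fpkm = 1, min_flank_fpkm = 1,
                          fold = 2, pseudocount = 0.01,
                          filter_scope = c("higher", "both")) {
  stopifnot(min_reads >= 0, min_coverage >= 0, fold > 1, pseudocount >= 0)
  out <- list(min_reads = min_reads, min_coverage = min_coverage,
              min_gene_fpkm = min_gene_fpkm, min_flank_fpkm = min_flank_fpkm,
              fold = fold, pseudocount = pseudocount,
              filter_scope = match.arg(filter_scope))
  class(out) <- "ir_thresholds"
  out
}

.average_replicates <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  ids <- tables[[1]]$intron_id
  for (t in tables[-1])
    if (!identical(t$intron_id, ids))
      tables <- lapply(tables, function(x) x[match(ids, x$intron_id), ])
  num <- c("supporting_reads", "intron_fpkm", "flank_left_fpkm",
           "flank_right_fpkm", "flank_mean_fpkm", "gene_fpkm",
           "length_coverage", "iri")
  avg <- tables[[1]][c("intron_id", "gene_id", "rel_position")]
  for (cn in num)
    avg[[cn]] <- rowMeans(do.call(cbind, lapply(tables, `[[`, cn)),
                          na.rm = TRUE)
  avg$iri[is.nan(avg$iri)] <- NA_real_
  avg
}

.passes_filters <- function(avg, th) {
  !is.na(avg$flank_left_fpkm) & !is.na(avg$flank_right_fpkm) &
    avg$supporting_reads >= th$min_reads &
    avg$length_coverage >= th$min_coverage &
    avg$gene_fpkm >= th$min_gene_fpkm &
    avg$flank_left_fpkm > th$min_flank_fpkm &
    avg$flank_right_fpkm > th$min_flank_fpkm
}

#' Call differential intron retention between two conditions
#'
#' IRI values are averaged over replicates within each condition; the
#' change statistic is \code{(iri_b + eps) / (iri_a + eps)}. An intron is
#' called \emph{up} when the ratio meets the fold cutoff and the filters
#' pass, \emph{down} when the inverse ratio does. Filters (supporting
#' reads, length coverage, host-gene FPKM, flanking-exon FPKM) are checked
#' in the condition with the higher averaged IRI by default.
#'
#' @param tables_a,tables_b Lists of per-replicate tables from
#'   \code{\link{quantify_sample}} (a bare data.frame is taken as one
#'   replicate).
#' @param thresholds An \code{\link{ir_thresholds}} object.
#' @return \code{data.frame} with one row per shared intron: averaged IRIs,
#'   \code{ratio}, \code{direction} (\code{up}/\code{down}/
#'   \code{unchanged}), \code{filters_passed} and \code{rel_position}.
#' @export
call_differential_ir <- function(tables_a, tables_b,
                                 thresholds = ir_thresholds()) {
  th <- thresholds
  a <- .average_replicates(tables_a)
  b <- .average_replicates(tables_b)
  shared <- intersect(a$intron_id, b$intron_id)
  if (length(shared) == 0L)
    stop("no introns shared between the two condition tables")
  a <- a[match(shared, a$intron_id), ]
  b <- b[match(shared, b$intron_id), ]
  iri_a <- ifelse(is.na(a$iri), 0, a$iri)
  iri_b <- ifelse(is.na(b$iri), 0, b$iri)
  ratio <- (iri_b + th$pseudocount) / (iri_a + th$pseudocount)
  pass_a <- .passes_filters(a, th)
  pass_b <- .passes_filters(b, th)
  pass_hi <- ifelse(iri_b >= iri_a, pass_b, pass_a)
  pass <- if (th$filter_scope == "both") pass_a & pass_b else pass_hi
  direction <- rep("unchanged", length(shared))
  direction[pass & ratio >= th$fold] <- "up"
  direction[pass & ratio <= 1 / th$fold] <- "down"
  data.frame(intron_id = shared, gene_id = a$gene_id,
             iri_cond_a = iri_a, iri_cond_b = iri_b,
             ratio = ratio, direction = direction,
             filters_passed = pass, rel_position = a$rel_position,
             stringsAsFactors = FALSE)
}

#' Classify genes by the direction of their retention changes
#'
#' @param diff_records Output of \code{\link{call_differential_ir}}.
#' @return \code{data.frame} with \code{gene_id}, \code{n_up},
#'   \code{n_down} and \code{class} in \code{up_only}, \code{down_only},
#'   \code{both}, \code{none}.
#' @export
classify_genes <- function(diff_records) {
  g <- factor(diff_records$gene_id)
  n_up <- tapply(diff_records$direction == "up", g, sum)
  n_down <- tapply(diff_records$direction == "down", g, sum)
  cls <- ifelse(n_up > 0 & n_down > 0, "both",
                ifelse(n_up > 0, "up_only",
                       ifelse(n_down > 0, "down_only", "none")))
  data.frame(gene_id = levels(g), n_up = as.integer(n_up),
             n_down = as.integer(n_down), class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Expression change by gene retention class
#'
#' Summarises log2 fold changes of gene expression per retention class and
#' runs two-sided Welch t-tests between every pair of classes with at least
#' two genes; smaller classes are flagged as skipped.
#'
#' @param classes Output of \code{\link{classify_genes}}.
#' @param fpkm_a,fpkm_b Named per-gene FPKM vectors for the two conditions
#'   (replicate-averaged).
#' @param pseudocount Added to both FPKMs inside the log ratio.
#' @return List with \code{summary} (per-class median/quartiles of log2FC),
#'   \code{tests} (pairwise t-test table with a \code{skipped} flag) and
#'   \code{log2fc} (named per-gene values).
#' @export
compare_expression_by_class <- function(classes, fpkm_a, fpkm_b,
                                        pseudocount = 0.01) {
  genes <- intersect(classes$gene_id, intersect(names(fpkm_a), names(fpkm_b)))
  cls <- setNames(classes$class, classes$gene_id)[genes]
  lfc <- log2((fpkm_b[genes] + pseudocount) / (fpkm_a[genes] + pseudocount))
  groups <- split(lfc, cls)
  summ <- do.call(rbind, lapply(names(groups), function(k) {
    q <- stats::quantile(groups[[k]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(class = k, n = length(groups[[k]]),
               q25 = q[1], median = q[2], q75 = q[3])
  }))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    x <- groups[[p[1]]]; y <- groups[[p[2]]]
    skip <- length(x) < 2 || length(y) < 2
    pv <- if (skip) NA_real_ else stats::t.test(x, y)$p.value
    data.frame(class_a = p[1], class_b = p[2], p_value = pv, skipped = skip)
  }))
  list(summary = summ, tests = tests, log2fc = lfc)
}

#' Compare IRI between nuclear and cytoplasmic fractions
#'
#' Restricts the shared intron set to (a) the given differential introns
#' and (b) introns detected as retained in both fractions (supporting
#' reads at or above \code{min_reads} and a defined positive IRI in each),
#' then summarises the per-fraction IRI distributions and runs a paired
#' t-test on each restriction.
#'
#' @param tab_nuclear,tab_cytoplasmic Tables from
#'   \code{\link{quantify_sample}} (or replicate lists).
#' @param diff_introns Character vector of differential intron ids
#'   (restriction (a)); may be \code{NULL} to use all shared introns.
#' @param min_reads Detection threshold for restriction (b).
#' @return List with one element per restriction (\code{differential},
#'   \code{shared_retained}), each containing per-fraction medians,
#'   \code{n}, and the paired t-test p-value.
#' @export
compare_fractions <- function(tab_nuclear, tab_cytoplasmic,
                              diff_introns = NULL, min_reads = 3) {
  nu <- .average_replicates(tab_nuclear)
  cy <- .average_replicates(tab_cytoplasmic)
  shared <- intersect(nu$intron_id, cy$intron_id)
  if (!length(shared)) stop("no introns shared between fractions")
  nu <- nu[match(shared, nu$intron_id), ]
  cy <- cy[match(shared, cy$intron_id), ]
  ni <- ifelse(is.na(nu$iri), 0, nu$iri)
  ci <- ifelse(is.na(cy$iri), 0, cy$iri)
  one <- function(keep) {
    n <- sum(keep)
    pv <- if (n >= 2 && stats::sd(ni[keep] - ci[keep]) > 0)
      stats::t.test(ni[keep], ci[keep], paired = TRUE)$p.value else
        if (n >= 2) 1 else NA_real_
    list(n = n,
         median_nuclear = stats::median(ni[keep]),
         median_cytoplasmic = stats::median(ci[keep]),
         p_value = pv)
  }
  keep_a <- if (is.null(diff_introns)) rep(TRUE, length(shared)) else
    shared %in% diff_introns
  keep_b <- nu$supporting_reads >= min_reads &
    cy$supporting_reads >= min_reads & ni > 0 & ci > 0
  list(differential = one(keep_a), shared_retained = one(keep_b))
}
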