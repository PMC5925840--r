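#' Pipeline configuration
#'
#' Validates and bundles everything one end-to-end run needs: the
#' simulation scenario (or paths to existing annotation/alignments), the
#' differential-retention thresholds, the metagene layout, and the output
#' directory.
#'
#' @param output_dir Output directory (created on run).
#' @param seed Integer seed; overrides the scenario's.
#' @param scenario \code{\link{simulation_scenario}} used when inputs are
#'   simulated.
#' @param thresholds \code{\link{ir_thresholds}}.
#' @param n_replicates RNA replicates per condition.
#' @param ks_alpha Significance level reported alongside the KS test.
#' @param marks ChIP marks to simulate and classify.
#' @return List of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(output_dir, seed = 1L,
                            scenario = simulation_scenario(seed = seed),
                            thresholds = ir_thresholds(),
                            n_replicates = 2L, ks_alpha = 0.05,
                            marks = c("H3K36me2", "H3K36me3")) {
  stopifnot(n_replicates >= 1, ks_alpha > 0, ks_alpha < 1)
  scenario$seed <- as.integer(seed)
  cfg <- list(output_dir = output_dir, seed = as.integer(seed),
              scenario = scenario, thresholds = thresholds,
              n_replicates = as.integer(n_replicates),
              ks_alpha = ks_alpha, marks = marks)
  class(cfg) <- "PipelineConfig"
  cfg
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-data pipeline
#'
#' Generates the annotation and genome, simulates replicated RNA-seq for
#' two conditions and ChIP/input libraries for each mark, then runs every
#' stage: unit construction, per-sample retention quantification,
#' differential-retention calling, gene classification, the positional KS
#' test, 500-bin metagene profiles, the mutant-minus-WT difference matrix,
#' per-gene shift calls and four-way type classification. All tables are
#' written as TSV under the output directory together with a JSON run
#' manifest; a rerun with the same config reproduces identical tables.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the in-memory results: \code{ann},
#'   \code{truth}, \code{diff_ir}, \code{gene_classes}, \code{ks},
#'   \code{shift_calls}, \code{shift_types}, \code{tables} (paths).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  data_dir <- file.path(out, "data")
  sc <- cfg$scenario

  ann <- generate_annotation(sc, data_dir)
  truth <- plant_retention(sc, ann)
  shapes <- plant_chip_shapes(sc, ann, marks = cfg$marks)
  units <- ann$units

  quantify_cond <- function(cond) {
    lapply(seq_len(cfg$n_replicates), function(r) {
      p <- file.path(data_dir, sprintf("rna_%s_rep%d.bed", cond, r))
      simulate_rnaseq(sc, ann, truth, condition = cond, replicate = r,
                      path = p)
      aln <- read_alignments(p, sample_id = sprintf("%s_rep%d", cond, r))
      quantify_sample(aln, units, ann$gms,
                      min_flank_fpkm = cfg$thresholds$min_flank_fpkm)
    })
  }
  tabs_a <- quantify_cond("a")
  tabs_b <- quantify_cond("b")
  paths <- character(0)
  for (i in seq_along(tabs_a))
    paths <- c(paths, .write_tsv(tabs_a[[i]],
                                 file.path(out, sprintf("iri_a_rep%d.tsv", i))))
  for (i in seq_along(tabs_b))
    paths <- c(paths, .write_tsv(tabs_b[[i]],
                                 file.path(out, sprintf("iri_b_rep%d.tsv", i))))

  diff_ir <- call_differential_ir(tabs_a, tabs_b, cfg$thresholds)
  paths <- c(paths, .write_tsv(diff_ir, file.path(out, "diff_ir.tsv")))
  gene_classes <- classify_genes(diff_ir)
  paths <- c(paths, .write_tsv(gene_classes, file.path(out, "gene_classes.tsv")))

  up <- diff_ir$rel_position[diff_ir$direction == "up"]
  down <- diff_ir$rel_position[diff_ir$direction == "down"]
  ks <- if (length(up) && length(down)) ks_location_test(up, down) else
    list(statistic = NA_real_, p_value = NA_real_,
         n_up = length(up), n_down = length(down))
  paths <- c(paths, .write_tsv(
    data.frame(n_up = ks$n_up, n_down = ks$n_down, D = ks$statistic,
               p_value = ks$p_value, alpha = cfg$ks_alpha),
    file.path(out, "ks_positions.tsv")))

  # ChIP: one shared input per condition, one ChIP library per mark
  inputs <- list()
  for (cond in c("mut", "wt")) {
    ip <- file.path(data_dir, sprintf("input_%s.bed", cond))
    simulate_chip(sc, ann, setNames(rep("flat", length(ann$gms$genes)),
                                    ann$gms$genes$gene_id),
                  condition = cond, path = tempfile(fileext = ".bed"),
                  input_path = ip, tag = "inputonly")
    inputs[[cond]] <- read_alignments(ip, sample_id = paste0("input_", cond))
  }
  shift_calls <- list(); shift_profiles <- list()
  for (mk in cfg$marks) {
    shp <- setNames(shapes[[paste0(mk, "_shape")]], shapes$gene_id)
    prof <- list()
    for (cond in c("mut", "wt")) {
      cp <- file.path(data_dir, sprintf("chip_%s_%s.bed", mk, cond))
      simulate_chip(sc, ann, shp, condition = cond, path = cp,
                    tag = paste0("chip_", mk))
      caln <- read_alignments(cp, sample_id = paste(mk, cond))
      prof[[cond]] <- bin_coverage(caln, inputs[[cond]], ann$gms)
    }
    d <- diff_matrix(prof$mut, prof$wt)
    shift_calls[[mk]] <- call_shift(d)
    shift_profiles[[mk]] <- d
    paths <- c(paths, .write_tsv(
      data.frame(gene_id = rownames(d), sort_key = attr(d, "sort_key")),
      file.path(out, sprintf("diff_matrix_order_%s.tsv", mk))))
  }
  shift_types <- classify_shift_types(shift_calls[[cfg$marks[1]]],
                                      shift_calls[[cfg$marks[2]]])
  paths <- c(paths, .write_tsv(shift_types, file.path(out, "shift_types.tsv")))
  paths <- c(paths, .write_tsv(truth, file.path(out, "truth_introns.tsv")))
  paths <- c(paths, .write_tsv(shapes, file.path(out, "truth_chip.tsv")))

  manifest <- list(
    package_version = as.character(utils::packageVersion("retentionshift")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    n_replicates = cfg$n_replicates,
    thresholds = unclass(cfg$thresholds),
    scenario = unclass(cfg$scenario),
    tables = basename(paths))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(ann = ann, truth = truth, chip_truth = shapes,
                 tables_a = tabs_a, tables_b = tabs_b,
                 diff_ir = diff_ir, gene_classes = gene_classes, ks = ks,
                 shift_calls = shift_calls, shift_profiles = shift_profiles,
                 shift_types = shift_types, tables = paths))
}
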