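#' Pipeline configuration
#'
#' Machine-readable record of one analysis run: where the counts come
#' from, which panel and neuron-selection rule apply, and the
#' classification parameters. Every run writes the full configuration
#' back out (the run log), so any artifact can be reproduced from its
#' log alone.
#'
#' @param input path to the expression input (Matrix Market triplet
#'   directory or dense table), or `NULL` for `simulate`.
#' @param format `"mtx"`, `"dense-cells-as-rows"` or
#'   `"dense-genes-as-rows"`.
#' @param panel path to a panel YAML/JSON config.
#' @param gating optional gating-rule string selecting neurons before
#'   classification.
#' @param whitelist optional path to a one-column cell-ID file (the
#'   externally supplied neuron selection); mutually exclusive with
#'   `gating`.
#' @param threshold classification threshold.
#' @param layer `"normalized"` or `"counts"`.
#' @param scale_factor log-normalization scale factor.
#' @param case_insensitive fold case when resolving panel genes.
#' @param output_dir artifact directory.
#' @param seed RNG seed (simulate only).
#' @param sim optional list of generator settings for `simulate`
#'   (n_cells, subset_prevalence, mu_marker, mu_background, dispersion,
#'   dropout, n_background_genes).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(input = NULL, format = "mtx", panel = NULL,
                            gating = NULL, whitelist = NULL,
                            threshold = 1,
                            layer = c("normalized", "counts"),
                            scale_factor = 10000,
                            case_insensitive = FALSE,
                            output_dir = ".", seed = 1, sim = NULL,
                            log_level = c("info", "quiet")) {
  layer <- match.arg(layer)
  log_level <- match.arg(log_level)
  if (!is.null(gating) && !is.null(whitelist))
    stop("give either a gating rule or a whitelist, not both")
  if (!is.finite(threshold)) stop("threshold must be finite")
  structure(
    list(input = input, format = format, panel = panel, gating = gating,
         whitelist = whitelist, threshold = threshold, layer = layer,
         scale_factor = scale_factor,
         case_insensitive = case_insensitive,
         output_dir = output_dir, seed = seed, sim = sim,
         log_level = log_level),
    class = "PipelineConfig")
}

pipeline_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message("[cotransmitr] ", ...)
  invisible(NULL)
}

write_run_log <- function(config, path, extra = list()) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  rec <- c(list(tool = "cotransmitr",
                version = as.character(utils::packageVersion("cotransmitr"))),
           extra, list(config = cfg))
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' Reconstruct a PipelineConfig from a run log
#' @param path `run_log.yaml` written by [run_pipeline()].
#' @return The `PipelineConfig` the run used.
#' @export
read_run_log <- function(path) {
  rec <- yaml::read_yaml(path)
  if (is.null(rec$config)) stop("not a run log: ", path)
  do.call(pipeline_config, rec$config)
}

load_pipeline_input <- function(config) {
  if (is.null(config$input)) stop("config has no input path")
  switch(config$format,
    "mtx" = read_mtx(config$input),
    "dense-cells-as-rows" = read_dense_table(config$input,
                                             "cells-as-rows"),
    "dense-genes-as-rows" = read_dense_table(config$input,
                                             "genes-as-rows"),
    stop("unknown input format: ", config$format))
}

load_pipeline_panel <- function(config) {
  if (is.null(config$panel)) stop("config names no panel file")
  if (!file.exists(config$panel))
    stop("panel file not found: ", config$panel)
  load_panel_config(config$panel)
}

#' Run the classification / counting pipeline
#'
#' `run_pipeline()` executes read -> log-normalize -> neuron selection
#' (gating rule or whitelist) -> panel resolution -> class assignment ->
#' combination counting, and writes deterministic artifacts into
#' `config$output_dir`: `class_profile.tsv`, `combination_counts.tsv`,
#' `normalization_summary.tsv`, the selection mask when a gating rule is
#' used, and `run_log.yaml` echoing the full configuration. Re-running
#' an identical configuration byte-reproduces all TSV artifacts.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the `profile`, `counts` and artifact
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  x <- load_pipeline_input(config)
  pipeline_log(config, "loaded ", nrow(x$counts), " cells x ",
               ncol(x$counts), " genes")
  x <- log_normalize(x, config$scale_factor)
  selection <- NULL
  if (!is.null(config$gating)) {
    rule <- parse_gating_rule(config$gating)
    selection <- evaluate_gating_rule(x, rule, config$layer)
    write_cell_mask(selection,
                    file.path(config$output_dir, "selection_mask.tsv"))
    x <- subset_cells(x, selection)
    pipeline_log(config, sum(selection), " cells pass gating rule")
  } else if (!is.null(config$whitelist)) {
    ids <- readLines(config$whitelist)
    ids <- ids[nzchar(ids)]
    x <- subset_cells(x, ids)
    pipeline_log(config, length(ids), " whitelisted cells retained")
  }
  panel <- load_pipeline_panel(config)
  resolved <- resolve_panels(panel, x, config$case_insensitive)
  profile <- assign_classes(x, resolved, config$threshold, config$layer)
  counts <- combination_counts(profile)
  paths <- list(
    profile = file.path(config$output_dir, "class_profile.tsv"),
    counts = file.path(config$output_dir, "combination_counts.tsv"),
    norm = file.path(config$output_dir, "normalization_summary.tsv"),
    log = file.path(config$output_dir, "run_log.yaml"))
  write_class_profile(profile, paths$profile)
  write_combination_table(counts, paths$counts)
  write_tsv(normalization_summary(x), paths$norm)
  write_run_log(config, paths$log,
                extra = list(n_cells = counts$total_cells,
                             classes = resolved$class_names))
  pipeline_log(config, "artifacts written to ", config$output_dir)
  invisible(list(profile = profile, counts = counts, matrix = x,
                 paths = paths))
}

normalization_summary <- function(x) {
  ti <- Matrix::rowSums(x$counts)
  nm <- if (!is.null(x$normalized)) x$normalized else x$counts
  data.frame(cell_id = cell_ids(x),
             total_counts = as.numeric(ti),
             genes_detected = as.integer(Matrix::rowSums(x$counts > 0)),
             max_normalized = apply_rows_max(nm))
}

apply_rows_max <- function(m) {
  out <- numeric(nrow(m))
  tm <- methods::as(m, "TsparseMatrix")
  if (length(tm@x)) {
    agg <- tapply(tm@x, tm@i, max)
    out[as.integer(names(agg)) + 1L] <- agg
  }
  out
}

#' Simulate a dataset and write it as pipeline input
#'
#' The `simulate` subcommand: generates a matrix with planted class
#' subsets from `config$sim` + `config$panel` + `config$seed`, writes it
#' as a Matrix Market triplet directory under
#' `output_dir/simulated_matrix/`, and stores the ground truth as JSON
#' and TSV.
#'
#' @param config a [pipeline_config()] with a `sim` list.
#' @return Invisibly, the [generate_dataset()] result plus paths.
#' @export
pipeline_simulate <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(config$sim)) stop("config has no 'sim' section")
  panel <- load_pipeline_panel(config)
  sim <- config$sim
  params <- simulation_params(
    n_cells = sim$n_cells, panel = panel,
    subset_prevalence = unlist(sim$subset_prevalence),
    mu_marker = sim$mu_marker,
    mu_background = sim$mu_background %||% 0,
    dispersion = sim$dispersion %||% 1,
    dropout = sim$dropout %||% 0,
    n_background_genes = sim$n_background_genes %||% 0,
    seed = config$seed)
  res <- generate_dataset(params)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  mtx_dir <- file.path(config$output_dir, "simulated_matrix")
  write_mtx(res$matrix, mtx_dir)
  truth_json <- file.path(config$output_dir, "truth.json")
  jsonlite::write_json(
    list(cell_ids = res$truth$cell_ids, subsets = res$truth$subsets,
         rng = res$truth$rng,
         params = unclass(params)[setdiff(names(unclass(params)),
                                          "panel")]),
    truth_json, auto_unbox = TRUE, digits = NA)
  truth_tsv <- file.path(config$output_dir, "truth.tsv")
  write_tsv(data.frame(cell_id = res$truth$cell_ids,
                       subset = res$truth$subsets), truth_tsv)
  write_run_log(config, file.path(config$output_dir, "run_log.yaml"))
  pipeline_log(config, "simulated ", params$n_cells, " cells into ",
               mtx_dir)
  invisible(c(res, list(paths = list(matrix = mtx_dir,
                                     truth_json = truth_json,
                                     truth_tsv = truth_tsv))))
}

#' Recompute a combination table from an inclusive-count table
#'
#' The `count --from-inclusive` subcommand: reads a table of inclusive
#' subset counts (the convention of in-text published counts), converts
#' it to exclusive counts via the Moebius transform, and writes the full
#' combination table.
#'
#' @param table_path TSV with `combination` and `inclusive` columns.
#' @param out_path output combination table.
#' @param class_names optional class universe (defaults to classes seen
#'   in the labels).
#' @param total_cells optional population size.
#' @return Invisibly, the `CombinationCounts`.
#' @export
pipeline_count_from_inclusive <- function(table_path, out_path,
                                          class_names = NULL,
                                          total_cells = NULL) {
  df <- utils::read.table(table_path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "")
  if (!all(c("combination", "inclusive") %in% names(df)))
    stop("format error in ", table_path,
         ": need 'combination' and 'inclusive' columns")
  if (is.null(class_names)) {
    parts <- strsplit(df$combination[df$combination != "none"], "+",
                      fixed = TRUE)
    class_names <- unique(trimws(unlist(parts)))
  }
  incl <- stats::setNames(df$inclusive, df$combination)
  excl <- exclusive_from_inclusive(incl, class_names, total_cells)
  counts <- combination_counts_from_exclusive(excl, class_names,
                                              total_cells)
  write_combination_table(counts, out_path)
  invisible(counts)
}

#' Compare two combination tables and write the comparison
#'
#' The `compare` subcommand over artifacts of [run_pipeline()].
#'
#' @param table_a,table_b combination tables (TSV).
#' @param out_path output TSV.
#' @param label_a,label_b dataset labels.
#' @param type `"exclusive"` or `"inclusive"`.
#' @return Invisibly, the comparison data.frame.
#' @export
pipeline_compare <- function(table_a, table_b, out_path,
                             label_a = "A", label_b = "B",
                             type = "exclusive") {
  ca <- read_combination_table(table_a)
  cb <- read_combination_table(table_b)
  cmp <- compare_datasets(ca, cb, label_a, label_b, type)
  write_tsv(cmp, out_path)
  invisible(cmp)
}
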