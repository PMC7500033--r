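## Orchestration of the full detection-to-patterns pipeline.

#' Run the deletion-mapping pipeline on one sample
#'
#' Executes detection (split-read catalog), quantification (frequencies,
#' ablation), context annotation (TMH), and pattern summaries, writing
#' all artifacts plus a run manifest into `out_dir`.  Reruns on identical
#' inputs are byte-identical.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `fq1`, `fq2` (paired FASTQ paths); optional `reference` /
#'   `feature_map` (paths; defaults to the bundled synthetic reference);
#'   optional `control_dir` (a catalog directory from [write_catalog()];
#'   when absent, mappability factors are 1 and no background is
#'   subtracted, with a logged warning); optional stage parameters
#'   `min_mean_q`, `k`, `min_anchor`, `max_mm`, `pattern_bins`,
#'   `terminus_bin_bp`, `sample_id`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the catalog, frequency table,
#'   annotations, and artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(min_mean_q = 20, k = DEFAULT_K,
                   min_anchor = DEFAULT_MIN_ANCHOR, max_mm = DEFAULT_MAX_MM,
                   pattern_bins = 80L, terminus_bin_bp = 250L,
                   sample_id = "sample")
  cfg <- utils::modifyList(defaults, config)
  for (p in c("fq1", "fq2"))
    if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
      stop("config error: missing input file for '", p, "'")
  ref <- if (is.null(cfg$reference)) default_reference() else
    read_reference(cfg$reference)
  fmap <- if (is.null(cfg$feature_map)) default_feature_map() else
    read_feature_map(cfg$feature_map)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  catalog <- build_catalog(cfg$fq1, cfg$fq2, ref,
                           min_mean_q = cfg$min_mean_q, k = cfg$k,
                           min_anchor = cfg$min_anchor, max_mm = cfg$max_mm,
                           sample_id = cfg$sample_id)
  write_catalog(catalog, out_dir)

  control <- NULL
  if (!is.null(cfg$control_dir)) {
    control <- read_catalog(cfg$control_dir)
  } else {
    message("no control sample supplied: delta_i = 1, no background subtraction")
  }
  freqs <- frequencies(catalog, ref,
                       control_depth = if (is.null(control)) NULL else
                         control$depth,
                       min_anchor = cfg$min_anchor)
  if (!is.null(control) && catalog$r_t > 0L && control$r_t > 0L)
    freqs <- subtract_background(freqs, frequencies(control, ref))
  write_frequencies(freqs, out_dir)

  ann <- annotate_context(freqs$table, ref)
  write.table(cbind(ann, f_i_bg = freqs$table$f_i_bg),
              file.path(out_dir, "context.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  pm <- suppressWarnings(bin_breakpoints(freqs, ref,
                                         n_bins = cfg$pattern_bins))
  th <- terminus_histogram(freqs, ann, bin_bp = cfg$terminus_bin_bp)
  ls <- length_spectrum(freqs)
  write_patterns(pm, th, ls, out_dir)

  manifest <- list(package_version = as.character(utils::packageVersion("mitoarc")),
                   reference = ref$name, L_u = ref$length,
                   parameters = cfg[c("min_mean_q", "k", "min_anchor",
                                      "max_mm", "pattern_bins",
                                      "terminus_bin_bp")],
                   control = !is.null(control),
                   sample_id = cfg$sample_id,
                   r_t = catalog$r_t, L_r = catalog$L_r,
                   a_biopsy = ablation_at_biopsy(freqs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(catalog = catalog, frequencies = freqs, annotations = ann,
                 pattern = pm, terminus = th, out_dir = out_dir))
}
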