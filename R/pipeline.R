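# One-call pipeline binding the modules: demultiplex sequencing reads,
# normalize, test for differential enrichment, and write versioned,
# machine-readable outputs. Configured by a validated list (or YAML file);
# logs go to stderr via message(), data only to files.

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  required <- c("dictionary", "output_dir")
  missing_f <- setdiff(required, names(config))
  if (length(missing_f))
    stop("config missing field(s): ", paste(missing_f, collapse = ", "))
  config$alpha <- config$alpha %||% 0.05
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha > 1)
    stop("config: alpha must be in (0, 1]")
  config$normalization <- config$normalization %||% "invariant_set"
  if (!config$normalization %in% c("invariant_set", "tmm", "naive_composition"))
    stop("config: unknown normalization method ", config$normalization)
  config$max_mismatch <- config$max_mismatch %||% 0L
  config$max_flank_mismatch <- config$max_flank_mismatch %||% 0L
  if (config$max_mismatch < 0 || config$max_flank_mismatch < 0)
    stop("config: mismatch tolerances must be >= 0")
  config
}

#' Run the demultiplex-normalize-enrich pipeline
#'
#' Stages: read the dictionary, count reads per clone from the FASTQ inputs,
#' run the differential-enrichment contrast, and write `counts.tsv` (+ totals
#' sidecar), `enrichment.tsv` (+ heatmap), and `config_used.yaml` into the
#' output directory. Inputs are never mutated; a rerun with identical inputs
#' writes byte-identical result tables.
#'
#' @param config List or YAML path with fields: `dictionary` (path or
#'   `liga_dictionary`), `fastq_r1` (named vector of per-sample paths),
#'   `test_samples`, `control_samples`, and optionally `normalization`,
#'   `alpha`, `max_mismatch`, `max_flank_mismatch`, `design` (list of
#'   [amplicon_design()] arguments), `output_dir`.
#' @return Invisibly, a list with the `counts` and `enrichment` objects and
#'   the output directory.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  dict <- if (inherits(config$dictionary, "liga_dictionary")) config$dictionary
  else read_liga_dictionary(config$dictionary)
  message(sprintf("[dictionary] %d entries (library %s)",
                  nrow(dict$entries), dict$library_id))

  design <- do.call(amplicon_design, config$design %||% list())

  fastq_r1 <- unlist(config$fastq_r1)
  if (is.null(fastq_r1)) stop("[demux] config needs fastq_r1")
  counts <- count_reads(fastq_r1, design, dict,
                        max_flank_mismatch = config$max_flank_mismatch,
                        max_mismatch = config$max_mismatch)
  totals <- attr(counts, "totals")
  message(sprintf("[demux] %s", paste(
    sprintf("%s: mapped %d / %d", totals$sample, totals$mapped, totals$total),
    collapse = "; ")))
  write_counts(counts, file.path(config$output_dir, "counts.tsv"))

  result <- list(counts = counts, output_dir = config$output_dir)
  if (!is.null(config$test_samples) && !is.null(config$control_samples)) {
    contrast <- contrast_spec(unlist(config$test_samples),
                              unlist(config$control_samples),
                              config$label %||% "test vs control")
    enr <- run_enrichment(counts, dict, contrast,
                          normalization = config$normalization,
                          alpha = config$alpha)
    n_sig <- sum(enr$significant)
    message(sprintf("[enrich] %s: %d/%d entries significant at FDR <= %g",
                    contrast$label, n_sig, nrow(enr), config$alpha))
    write_enrichment(enr, file.path(config$output_dir, "enrichment.tsv"))
    result$enrichment <- enr
  }

  cfg_out <- config
  cfg_out$dictionary <- if (is.character(config$dictionary)) config$dictionary
  else sprintf("<in-memory dictionary %s>", dict$library_id)
  cfg_out$package_version <- as.character(utils::packageVersion("ligar"))
  yaml::write_yaml(cfg_out, file.path(config$output_dir, "config_used.yaml"))
  invisible(result)
}
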