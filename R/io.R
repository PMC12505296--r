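#' Schema-checked TSV input and output
#'
#' All tables in the pipeline are tab-separated files with an \code{NA}
#' missing-value token and optional \code{# key: value} header comments
#' recording provenance (tool version, seed, configuration hash).
#'
#' @param df Data.frame to write.
#' @param path File path.
#' @param meta Optional named list; each entry is written as a
#'   \code{# name: value} comment line before the header. The tool version is
#'   always recorded.
#' @return \code{path} invisibly.
#' @export
write_tsv_checked <- function(df, path, meta = NULL) {
  stopifnot(is.data.frame(df))
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(list(tool = paste0("dhfrscan ",
                               as.character(packageVersion("dhfrscan")))),
            meta)
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_tsv_checked
#' @param schema Optional named character vector mapping required column names
#'   to types (\code{"character"}, \code{"integer"}, \code{"numeric"},
#'   \code{"logical"}). Extra or missing columns are an error naming the
#'   offending column.
#' @export
read_tsv_checked <- function(path, schema = NULL) {
  df <- read.delim(path, sep = "\t", comment.char = "#", na.strings = "NA",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(names(schema), names(df))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "))
    extra <- setdiff(names(df), names(schema))
    if (length(extra))
      stop("unexpected column(s): ", paste(extra, collapse = ", "))
    df <- df[names(schema)]
    for (j in names(schema)) {
      df[[j]] <- switch(schema[[j]],
                        character = as.character(df[[j]]),
                        integer = as.integer(df[[j]]),
                        numeric = as.numeric(df[[j]]),
                        logical = as.logical(df[[j]]),
                        stop("unknown schema type for column ", j))
    }
  }
  df
}

#' Pipeline configuration
#'
#' Bundles paths, thresholds and switches for \code{\link{run_pipeline}}. The
#' configuration round-trips losslessly through YAML.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Integer seed governing every source of randomness.
#' @param min_reads Pre-selection read-count filter (default 20).
#' @param min_replicates Minimum contributing replicate-level scores per
#'   amino-acid change (default 3).
#' @param alpha Significance level for all tests (default 0.05).
#' @param wt_policy Wild-type anchor policy for rescaling,
#'   \code{"wt_silent"} (wild-type plus synonymous codons) or
#'   \code{"wt_identical"}.
#' @param pseudocount Pseudocount added to read counts (default 0.5).
#' @param exclude_strains Character vector of strain/mutant identifiers
#'   excluded by manual QC before analysis.
#' @param reads_level Logical: if \code{TRUE} the synthetic stage emits FASTQ
#'   reads and the pipeline calls variants from them; otherwise the count
#'   table is used directly.
#' @param design,counts,od,colony Optional input file paths (design YAML,
#'   counts/OD/colony TSV). When \code{design} is \code{NULL} the bundled
#'   \code{\link{example_design}} is used and counts are simulated.
#' @param sim Named list of overrides passed to \code{\link{sim_params}}.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir, seed = 1L, min_reads = 20L,
                            min_replicates = 3L, alpha = 0.05,
                            wt_policy = c("wt_silent", "wt_identical"),
                            pseudocount = 0.5, exclude_strains = character(),
                            reads_level = FALSE, design = NULL, counts = NULL,
                            od = NULL, colony = NULL, sim = list()) {
  wt_policy <- match.arg(wt_policy)
  if (min_reads < 0L || min_replicates < 1L || alpha <= 0 || alpha >= 1)
    stop("invalid threshold in pipeline configuration")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 min_reads = as.integer(min_reads),
                 min_replicates = as.integer(min_replicates), alpha = alpha,
                 wt_policy = wt_policy, pseudocount = pseudocount,
                 exclude_strains = exclude_strains,
                 reads_level = reads_level, design = design, counts = counts,
                 od = od, colony = colony, sim = sim),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config A \code{pipeline_config}.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Executes, as configured: synthetic-data generation (when no counts input is
#' given), variant calling from reads, interaction scoring and rescaling, the
#' statistical filter/classification cascade, and optional growth-curve and
#' colony-array stages. Writes one TSV per stage plus a YAML run log recording
#' every threshold used and the number of variants surviving each filter.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the stage tables and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = config$seed,
               config_hash = config_hash(config))
  log <- list(thresholds = list(min_reads = config$min_reads,
                                min_replicates = config$min_replicates,
                                alpha = config$alpha,
                                pseudocount = config$pseudocount,
                                wt_policy = config$wt_policy),
              seed = config$seed)

  design <- if (is.null(config$design)) example_design()
            else read_design(config$design)

  if (is.null(config$counts)) {
    params <- do.call(sim_params, c(list(seed = config$seed), config$sim))
    effects <- simulate_effects(design, params)
    counts <- simulate_counts(design, effects, params)
    write_tsv_checked(effects, file.path(config$out_dir, "true_effects.tsv"),
                      meta = meta)
    if (isTRUE(config$reads_level)) {
      manifest <- build_manifest(counts)
      fq <- file.path(config$out_dir, "reads.fastq")
      emit_reads(design, counts, params, manifest, fq)
      counts <- call_variants(fq, design, manifest)
    }
  } else {
    counts <- read_tsv_checked(config$counts)
  }
  write_tsv_checked(counts, file.path(config$out_dir, "counts.tsv"),
                    meta = meta)

  cascade <- filter_cascade(counts, design,
                            min_reads = config$min_reads,
                            min_contrib = config$min_replicates,
                            alpha = config$alpha,
                            wt_policy = config$wt_policy,
                            pseudocount = config$pseudocount,
                            exclude_keys = config$exclude_strains)
  write_tsv_checked(cascade$scores, file.path(config$out_dir, "scores.tsv"),
                    meta = meta)
  write_tsv_checked(cascade$aa_scores,
                    file.path(config$out_dir, "aa_scores.tsv"), meta = meta)
  log$filter_summary <- cascade$summary

  if (!is.null(config$od)) {
    od <- read_tsv_checked(config$od)
    growth <- growth_rates(od)
    write_tsv_checked(growth, file.path(config$out_dir, "growth.tsv"),
                      meta = meta)
  }
  if (!is.null(config$colony)) {
    grid <- read_tsv_checked(config$colony)
    colony <- colony_scores(grid)
    write_tsv_checked(colony, file.path(config$out_dir, "colony_scores.tsv"),
                      meta = meta)
  }

  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))
  invisible(list(counts = counts, scores = cascade$scores,
                 aa_scores = cascade$aa_scores, summary = cascade$summary))
}

# Stable short polynomial hash of the configuration's YAML serialization,
# recorded in output headers so tables can be traced to the run that made them.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # analysis identity must not depend on where it lands
  s <- yaml::as.yaml(cfg)
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
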