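RUN_CONFIG_KEYS <- c("reference", "gff", "variants", "markers", "ko_table",
                     "out_dir", "seed", "filter", "severity", "summary",
                     "simulate")

FILTER_KEYS <- c("min_depth", "min_consensus_quality", "min_map_quality",
                 "indel_proximity_window", "max_snps_in_window")
SEVERITY_KEYS <- c("include_tier2", "shared_orf_same_tier_only")
SUMMARY_KEYS <- c("window", "step", "high_threshold", "low_threshold",
                  "min_run")

#' Load and validate a pipeline run configuration
#'
#' YAML with the keys `reference`, `gff`, `variants` (map of strain to VCF/
#' TSV path), `markers`, `ko_table`, `out_dir`, `seed`, and the option maps
#' `filter`, `severity`, `summary`. Unknown keys are rejected (fail-closed);
#' omitted options take package defaults (10 kb window, 1 kb step, the
#' default [filter_policy()] and [severity_policy()]).
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "),
           "; accepted keys: ", paste(allowed, collapse = ", "),
           call. = FALSE)
    }
  }
  check_keys(raw, RUN_CONFIG_KEYS, "config")
  check_keys(raw$filter, FILTER_KEYS, "filter")
  check_keys(raw$severity, SEVERITY_KEYS, "severity")
  check_keys(raw$summary, SUMMARY_KEYS, "summary")
  cfg <- list(
    reference = raw$reference, gff = raw$gff, variants = raw$variants,
    markers = raw$markers, ko_table = raw$ko_table,
    out_dir = if (is.null(raw$out_dir)) "mutmapr_run" else raw$out_dir,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    filter = do.call(filter_policy, raw$filter %||% list()),
    severity = do.call(severity_policy, raw$severity %||% list()),
    summary = utils::modifyList(
      list(window = 10000L, step = 1000L, min_run = 3L), raw$summary %||% list()))
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the comparative mapping pipeline
#'
#' Executes annotate, compare, prioritize, and summarize stages over the
#' inputs named in a [load_run_config()] configuration, writing fixed-name
#' TSV outputs plus a JSON run manifest (config hash, seed, package version,
#' output checksums) under the configured output directory. Output ordering
#' is deterministic.
#'
#' @param config A `run_config` (or path to one).
#' @param stages Subset of `c("annotate", "compare", "prioritize",
#'   "summarize")`.
#' @return Invisibly, a list with the pipeline objects and the manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("annotate", "compare", "prioritize",
                                    "summarize")) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  note <- function(p) { outputs <<- c(outputs, p); p }

  message("reading reference and gene models")
  annotation <- read_gene_models(config$gff, config$reference)
  records <- dplyr::bind_rows(lapply(names(config$variants), function(s) {
    read_variants(config$variants[[s]], strain = s)
  }))
  filt <- filter_calls(records, config$filter)
  records <- left_normalize_indels(filt$kept, annotation$reference)
  records <- add_variant_keys(records)

  effects <- NULL
  if ("annotate" %in% stages || "prioritize" %in% stages ||
      "summarize" %in% stages) {
    message("classifying ", nrow(records), " variant records")
    effects <- classify_variants(records, annotation)
    readr::write_tsv(effects, note(file.path(config$out_dir, "effects.tsv")),
                     na = ".")
  }

  matrix <- build_occurrence_matrix(records)
  if ("compare" %in% stages) {
    spec <- occurrence_spectrum(matrix)
    readr::write_tsv(spec, note(file.path(config$out_dir, "spectrum.tsv")))
    uniq <- tibble::tibble(
      strain = matrix$strains,
      n_unique = vapply(matrix$strains,
                        function(s) length(unique_variants(matrix, s)), 1L))
    readr::write_tsv(uniq, note(file.path(config$out_dir, "unique_counts.tsv")))
    wide <- dplyr::bind_cols(
      matrix$keys[, c("key", "contig", "pos", "kind")],
      tibble::as_tibble(as.matrix(matrix$presence) * 1L))
    readr::write_tsv(wide, note(file.path(config$out_dir, "occurrence.tsv")))
  }

  reports <- list()
  if ("prioritize" %in% stages && !is.null(config$markers)) {
    intervals <- read_marker_intervals(config$markers)
    ko <- if (!is.null(config$ko_table)) {
      readr::read_tsv(config$ko_table, show_col_types = FALSE)
    } else NULL
    for (s in names(intervals)) {
      rep <- prioritize(s, intervals[[s]], matrix, effects, annotation,
                        config$severity, ko)
      reports[[s]] <- rep
      write_candidate_report(
        rep,
        tsv_path = note(file.path(config$out_dir,
                                  paste0("candidates_", s, ".tsv"))),
        txt_path = note(file.path(config$out_dir,
                                  paste0("report_", s, ".txt"))))
    }
  }

  summaries <- NULL
  if ("summarize" %in% stages) {
    uniq_keys <- unlist(lapply(matrix$strains,
                               function(s) unique_variants(matrix, s)))
    snp_tab <- dplyr::bind_rows(lapply(split(effects, effects$strain),
                                       strain_snp_summary))
    indel_tab <- dplyr::bind_rows(lapply(split(effects, effects$strain),
                                         strain_indel_summary,
                                         unique_keys = uniq_keys))
    readr::write_tsv(snp_tab, note(file.path(config$out_dir,
                                             "snp_summary.tsv")))
    readr::write_tsv(indel_tab, note(file.path(config$out_dir,
                                               "indel_summary.tsv")))
    sizes <- indel_size_spectrum(matrix, mode = "distinct")
    readr::write_tsv(sizes, note(file.path(config$out_dir,
                                           "indel_sizes.tsv")))
    cfrac <- coding_fraction_by_size(effects)
    readr::write_tsv(cfrac, note(file.path(config$out_dir,
                                           "coding_fraction.tsv")))
    for (ctg in names(annotation$reference)) {
      prof <- window_density_profile(
        records, ctg, Biostrings::width(annotation$reference[ctg]),
        window = config$summary$window, step = config$summary$step,
        unique_keys = uniq_keys)
      write_profile_bedgraph(prof, note(file.path(
        config$out_dir, paste0("profile_", ctg, ".bedgraph"))))
    }
    summaries <- list(snp = snp_tab, indel = indel_tab, sizes = sizes)
  }

  manifest <- list(
    package = "mutmapr",
    version = as.character(utils::packageVersion("mutmapr")),
    seed = config$seed,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(annotation = annotation, records = records,
                 effects = effects, matrix = matrix, reports = reports,
                 summaries = summaries, manifest = manifest))
}
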