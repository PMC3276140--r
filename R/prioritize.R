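#' Effect-severity policy for candidate ranking
#'
#' Tier 1 holds the effect classes treated as presumptively causative in a
#' forward-genetics screen (premature stops, frame-breaking indels, whole-
#' exon structural deletions, splice-site lesions); tier 2 holds
#' nonsynonymous substitutions, consulted only when `include_tier2` is set.
#'
#' @param tier1,tier2 Character vectors of effect categories.
#' @param include_tier2 Consider tier-2 variants as candidates.
#' @param shared_orf_same_tier_only When excluding candidate genes hit in
#'   other strains, trigger only on variants of the same or higher tier as
#'   the candidate (default) rather than on any tiered variant.
#' @return A list of class `severity_policy`.
#' @export
severity_policy <- function(tier1 = c("nonsense", "cds_frameshift",
                                      "sv_gene_deletion", "splice_site"),
                            tier2 = "nonsynonymous",
                            include_tier2 = FALSE,
                            shared_orf_same_tier_only = TRUE) {
  if (length(intersect(tier1, tier2))) {
    stop("severity tiers must be disjoint", call. = FALSE)
  }
  p <- list(tier1 = tier1, tier2 = tier2, include_tier2 = include_tier2,
            shared_orf_same_tier_only = shared_orf_same_tier_only)
  class(p) <- "severity_policy"
  p
}

candidate_tier <- function(category, policy) {
  ifelse(category %in% policy$tier1, 1L,
         ifelse(category %in% policy$tier2, 2L, NA_integer_))
}

# deterministic within-tier ranking: stop-making lesions first, then splice,
# then nonsynonymous; ties broken by genomic coordinate
CATEGORY_RANK <- c(nonsense = 1, cds_frameshift = 2, sv_gene_deletion = 3,
                   splice_site = 4, nonsynonymous = 5)

#' Restrict effect calls to a marker interval
#'
#' @param effects Effect calls for one strain.
#' @param interval Resolved interval (`c(lo, hi)`) from
#'   [resolve_marker_interval()].
#' @param contig Contig the interval lies on.
#' @param annotation A `gene_annotation` (used to count genes whose span
#'   intersects the interval).
#' @return List with `subset` (calls inside the closed interval) and
#'   `n_genes_in_interval`.
#' @export
restrict_to_interval <- function(effects, interval, contig, annotation) {
  inside <- effects$contig == contig &
    effects$pos >= interval["lo"] & effects$pos <= interval["hi"]
  g <- annotation$summary
  n_genes <- sum(g$contig == contig & g$start <= interval["hi"] &
                   g$end >= interval["lo"])
  list(subset = effects[inside, , drop = FALSE],
       n_genes_in_interval = as.integer(n_genes))
}

#' Exclude candidate genes carrying qualified variants in other strains
#'
#' A gene whose coding sequence is also damaged in strains that do not show
#' the phenotype cannot explain it; such candidates are marked
#' `excluded_shared_orf`. By default only variants of the same or higher
#' severity tier as the candidate trigger exclusion.
#'
#' @param candidates Candidate tibble (must carry `gene_id`, `tier`,
#'   `status`).
#' @param effects_all Effect calls for the whole cohort.
#' @param focal_strain Strain under study.
#' @param policy A [severity_policy()].
#' @return `candidates` with updated `status`.
#' @export
exclude_shared_orfs <- function(candidates, effects_all, focal_strain,
                                policy = severity_policy()) {
  if (!nrow(candidates)) return(candidates)
  other <- effects_all[effects_all$strain != focal_strain &
                         !is.na(effects_all$gene_id), , drop = FALSE]
  other$tier <- candidate_tier(other$category, policy)
  for (i in which(candidates$status == "top")) {
    g <- candidates$gene_id[i]
    hits <- other$tier[other$gene_id == g]
    hits <- hits[!is.na(hits)]
    trigger <- if (policy$shared_orf_same_tier_only) {
      any(hits <= candidates$tier[i])
    } else {
      length(hits) > 0L
    }
    if (trigger) candidates$status[i] <- "excluded_shared_orf"
  }
  candidates
}

#' Attach knockout-phenotype evidence to candidates
#'
#' Candidates in genes whose deletion mutant is annotated as phenotypically
#' normal are demoted (`demoted_ko_normal`) but kept in the report; genes
#' whose knockout is recoverable only as a heterokaryon (suggesting
#' essentiality) are annotated as corroborating and left in place.
#'
#' @param candidates Candidate tibble.
#' @param ko_table Named character vector or two-column data frame
#'   (`gene_id`, `phenotype`) of knockout phenotypes; free text with the
#'   reserved tokens `"normal"` and `"heterokaryon"` recognised anywhere in
#'   the string.
#' @return `candidates` with `ko_phenotype` and `ko_corroborates` columns and
#'   updated `status`.
#' @export
attach_knockout_evidence <- function(candidates, ko_table = NULL) {
  candidates$ko_phenotype <- NA_character_
  candidates$ko_corroborates <- FALSE
  if (is.null(ko_table) || !nrow(candidates)) return(candidates)
  if (is.data.frame(ko_table)) {
    ko <- stats::setNames(as.character(ko_table$phenotype), ko_table$gene_id)
  } else {
    ko <- ko_table
  }
  hit <- candidates$gene_id %in% names(ko)
  candidates$ko_phenotype[hit] <- unname(ko[candidates$gene_id[hit]])
  is_normal <- hit & grepl("normal", candidates$ko_phenotype, ignore.case = TRUE)
  is_het <- hit & grepl("heterokaryon", candidates$ko_phenotype,
                        ignore.case = TRUE)
  candidates$status[is_normal & candidates$status == "top"] <- "demoted_ko_normal"
  candidates$ko_corroborates[is_het] <- TRUE
  candidates
}

#' Identify candidate causative mutations for one strain
#'
#' Applies the comparative mapping procedure: restrict the focal strain's
#' classified variants to the genetically delimited marker interval, keep
#' only variants private to the strain, keep only effect classes severe
#' enough to qualify, drop candidates whose gene is also damaged in
#' phenotypically normal strains, demote candidates contradicted by a normal
#' knockout phenotype, and rank what survives. Every variant of the focal
#' strain receives exactly one status.
#'
#' @param strain Focal strain identifier.
#' @param interval A [marker_interval()] (or resolved `c(lo, hi)` vector
#'   plus `contig`).
#' @param matrix Cohort [build_occurrence_matrix()].
#' @param effects_all Cohort effect calls from [classify_variants()].
#' @param annotation A `gene_annotation`.
#' @param policy A [severity_policy()].
#' @param ko_table Optional knockout-phenotype table (see
#'   [attach_knockout_evidence()]).
#' @return A `candidate_report`: list with `strain`, `contig`, `interval`,
#'   `n_genes_in_interval`, `candidates` (every considered variant with its
#'   status, ranked tops first) and `verdict` (`single_candidate`,
#'   `multiple_candidates`, `ambiguous`, or `none`). The verdict is decided
#'   at the gene level: several top variants in one gene still name a single
#'   candidate gene.
#' @export
prioritize <- function(strain, interval, matrix, effects_all, annotation,
                       policy = severity_policy(), ko_table = NULL) {
  if (!strain %in% unique(effects_all$strain)) {
    stop("unknown strain: ", strain, call. = FALSE)
  }
  if (inherits(interval, "marker_interval")) {
    contig <- interval$contig
    if (!contig %in% names(annotation$reference)) {
      stop("unknown contig in interval: ", contig, call. = FALSE)
    }
    resolved <- resolve_marker_interval(
      interval, Biostrings::width(annotation$reference[contig]))
  } else {
    stop("interval must be a marker_interval", call. = FALSE)
  }

  focal <- effects_all[effects_all$strain == strain, , drop = FALSE]
  focal$tier <- candidate_tier(focal$category, policy)
  focal$status <- NA_character_

  inside <- focal$contig == contig & focal$pos >= resolved["lo"] &
    focal$pos <= resolved["hi"]
  focal$status[!inside] <- "excluded_outside_interval"

  uniq <- unique_variants(matrix, strain)
  not_unique <- is.na(focal$status) & !focal$key %in% uniq
  focal$status[not_unique] <- "excluded_not_unique"

  qualified_tiers <- if (policy$include_tier2) c(1L, 2L) else 1L
  low <- is.na(focal$status) & !focal$tier %in% qualified_tiers
  focal$status[low] <- "excluded_low_severity"
  focal$status[is.na(focal$status)] <- "top"

  focal <- exclude_shared_orfs(focal, effects_all, strain, policy)
  focal <- attach_knockout_evidence(focal, ko_table)

  rank_key <- order(focal$status != "top",
                    focal$tier,
                    CATEGORY_RANK[focal$category],
                    focal$contig, focal$pos)
  focal <- focal[rank_key, , drop = FALSE]

  g <- annotation$summary
  n_genes <- sum(g$contig == contig & g$start <= resolved["hi"] &
                   g$end >= resolved["lo"])

  top <- focal[focal$status == "top", , drop = FALSE]
  top_genes <- unique(top$gene_id)
  verdict <- if (nrow(top) == 0L) {
    "none"
  } else if (length(top_genes) == 1L) {
    "single_candidate"
  } else if (length(unique(top$tier)) > 1L) {
    "multiple_candidates"
  } else {
    "ambiguous"
  }
  out <- list(strain = strain, contig = contig, interval = resolved,
              n_genes_in_interval = as.integer(n_genes),
              candidates = focal, verdict = verdict,
              top_gene = if (length(top_genes) == 1L) top_genes else NA_character_)
  class(out) <- "candidate_report"
  out
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate report for strain ", x$strain, "\n", sep = "")
  cat("  interval: ", x$contig, ":", x$interval["lo"], "-", x$interval["hi"],
      " (", x$n_genes_in_interval, " genes)\n", sep = "")
  cat("  verdict: ", x$verdict, "\n", sep = "")
  top <- x$candidates[x$candidates$status == "top", , drop = FALSE]
  if (nrow(top)) {
    for (i in seq_len(nrow(top))) {
      cat("   * ", top$gene_id[i], " ", top$key[i], " [", top$category[i],
          "]\n", sep = "")
    }
  }
  dem <- x$candidates[x$candidates$status == "demoted_ko_normal", , drop = FALSE]
  if (nrow(dem)) {
    cat("  demoted by normal knockout phenotype: ",
        paste(unique(dem$gene_id), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a candidate report
#'
#' Writes the per-variant candidate table as TSV and a short human-readable
#' narrative block.
#'
#' @param report A `candidate_report`.
#' @param tsv_path,txt_path Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_candidate_report <- function(report, tsv_path = NULL, txt_path = NULL) {
  if (!is.null(tsv_path)) {
    x <- report$candidates
    x$strains_involved <- NULL
    readr::write_tsv(x, tsv_path, na = ".")
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  }
  invisible(report)
}
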