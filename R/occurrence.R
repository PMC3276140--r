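#' Build the cohort-wide variant occurrence matrix
#'
#' The occurrence matrix is the substrate of the in-silico bulk comparison:
#' one row per distinct canonical variant key, one column per strain,
#' presence marked when the strain carries the key. Multi-allelic records
#' are excluded by default (on haploid genomes they are predominantly
#' alignment artifacts); indel sizes are retained per carrying strain so
#' downstream size spectra can distinguish co-located events that share a
#' key.
#'
#' @param records Cohort `variant_records` (all strains in one tibble; a
#'   `key` column is added if absent).
#' @param include_multiallelic Keep records flagged multi-allelic.
#' @return An object of class `occurrence_matrix` with fields `keys` (tibble:
#'   `key`, `contig`, `pos`, `kind`, `sizes` list-column of per-carrier
#'   sizes, `any_multi`), `strains`, and `presence` (sparse logical matrix,
#'   keys x strains).
#' @export
build_occurrence_matrix <- function(records, include_multiallelic = FALSE) {
  if (!"key" %in% names(records)) records <- add_variant_keys(records)
  if (!include_multiallelic) records <- records[!records$multi, , drop = FALSE]
  dup <- duplicated(records[, c("strain", "key")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (strain, key) record(s) collapsed",
            call. = FALSE)
    records <- records[!dup, , drop = FALSE]
  }
  strains <- sort(unique(records$strain))
  keys <- records |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      contig = .data$contig[1], pos = .data$pos[1], kind = .data$kind[1],
      sizes = list(.data$size), any_multi = any(.data$multi),
      .groups = "drop") |>
    dplyr::arrange(.data$contig, .data$pos, .data$key)
  i <- match(records$key, keys$key)
  j <- match(records$strain, strains)
  presence <- Matrix::sparseMatrix(i = i, j = j,
                                   dims = c(nrow(keys), length(strains)),
                                   dimnames = list(keys$key, strains))
  out <- list(keys = keys, strains = strains, presence = presence)
  class(out) <- "occurrence_matrix"
  out
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("<occurrence_matrix> ", nrow(x$keys), " keys x ", length(x$strains),
      " strains\n", sep = "")
  invisible(x)
}

#' Occurrence counts per key
#' @param matrix An `occurrence_matrix`.
#' @return Integer vector named by key: in how many strains each key occurs.
#' @export
key_occurrence <- function(matrix) {
  stopifnot(inherits(matrix, "occurrence_matrix"))
  n <- Matrix::rowSums(matrix$presence)
  stats::setNames(as.integer(n), matrix$keys$key)
}

#' Occurrence spectrum of a cohort
#'
#' Tabulates how many distinct variant keys occur in exactly `n` strains,
#' for `n` from 1 to the cohort size.
#'
#' @param matrix An `occurrence_matrix`.
#' @param kind Optional filter, e.g. `"snp"` or `"indel"`.
#' @return Tibble with columns `n_strains`, `n_keys`.
#' @export
occurrence_spectrum <- function(matrix, kind = NULL) {
  occ <- key_occurrence(matrix)
  if (!is.null(kind)) occ <- occ[matrix$keys$kind %in% kind]
  if (!length(occ)) stop("empty occurrence matrix", call. = FALSE)
  tab <- table(factor(occ, levels = seq_along(matrix$strains)))
  tibble::tibble(n_strains = as.integer(names(tab)),
                 n_keys = as.integer(tab))
}

#' Totals of an occurrence spectrum
#'
#' The distinct total counts each key once; the mapped total weights each key
#' by the number of strains carrying it, i.e. the number of per-strain
#' variant observations the spectrum summarises.
#'
#' @param spectrum Tibble with columns `n_strains` and `n_keys` (as returned
#'   by [occurrence_spectrum()], or a published spectrum table).
#' @return List with `distinct` and `mapped` totals.
#' @export
spectrum_totals <- function(spectrum) {
  stopifnot(all(c("n_strains", "n_keys") %in% names(spectrum)))
  list(distinct = sum(spectrum$n_keys),
       mapped = sum(spectrum$n_keys * spectrum$n_strains))
}

#' Variant keys private to one strain
#'
#' @param matrix An `occurrence_matrix`.
#' @param strain Focal strain.
#' @return Character vector of keys carried by the focal strain and by no
#'   other strain.
#' @export
unique_variants <- function(matrix, strain) {
  stopifnot(inherits(matrix, "occurrence_matrix"))
  j <- match(strain, matrix$strains)
  if (is.na(j)) stop("unknown strain: ", strain, call. = FALSE)
  occ <- Matrix::rowSums(matrix$presence)
  has <- matrix$presence[, j]
  matrix$keys$key[has & occ == 1]
}

#' Flag putative reference-background variants
#'
#' Keys present in every strain of the cohort most plausibly reflect
#' polymorphisms of the reference genome itself (or systematic artifacts)
#' rather than mutations of any strain; they are reported separately and
#' excluded from uniqueness-based analyses.
#'
#' @param matrix An `occurrence_matrix`.
#' @return Character vector of keys with occurrence equal to the cohort size.
#' @export
flag_reference_background <- function(matrix) {
  stopifnot(inherits(matrix, "occurrence_matrix"))
  if (length(matrix$strains) < 2L) {
    warning("cohort of one strain: every key is trivially shared by all",
            call. = FALSE)
  }
  occ <- Matrix::rowSums(matrix$presence)
  matrix$keys$key[occ == length(matrix$strains)]
}

#' Tally variants per ORF across the cohort
#'
#' Counts, for each gene, the number of distinct indel keys and distinct
#' severe SNP keys (nonsense) observed anywhere in the cohort, together with
#' the strains involved. A key observed in several strains counts once.
#'
#' @param effects Effect calls from [classify_variants()] (all strains).
#' @return Tibble: `gene_id`, `indel_count`, `severe_snp_count`,
#'   `strains_involved` (list-column).
#' @export
tally_variants_per_orf <- function(effects) {
  x <- effects[!is.na(effects$gene_id), , drop = FALSE]
  if (!nrow(x)) {
    return(tibble::tibble(gene_id = character(0), indel_count = integer(0),
                          severe_snp_count = integer(0),
                          strains_involved = list()))
  }
  x |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      indel_count = dplyr::n_distinct(.data$key[.data$kind != "snp"]),
      severe_snp_count = dplyr::n_distinct(
        .data$key[.data$category == "nonsense"]),
      strains_involved = list(sort(unique(.data$strain))),
      .groups = "drop")
}
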