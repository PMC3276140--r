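#' Construct a table of variant records
#'
#' A variant record describes one SNP, small indel, or structural deletion
#' observed in one haploid strain, together with the call-quality fields used
#' for filtering. Records are held in an ordinary tibble so that the whole
#' pipeline composes with dplyr verbs.
#'
#' @param strain Character, strain identifier.
#' @param contig Character, contig/supercontig name.
#' @param pos Integer, 1-based position. For deletions this is the first
#'   deleted base; for insertions the position at which inserted bases begin.
#' @param kind One of `"snp"`, `"indel"`, `"sv_del"`.
#' @param ref,alt Reference and alternate alleles. SNPs use single bases;
#'   deletions carry the deleted sequence in `ref` (empty `alt`), insertions
#'   the inserted sequence in `alt` (empty `ref`).
#' @param size Signed indel size in bases (+ insertion, - deletion, 0 for
#'   SNPs). Structural deletions use the negative deleted length.
#' @param sv_end 1-based end of a structural deletion (`NA` otherwise).
#' @param cq Phred-scaled consensus quality.
#' @param dp Read depth.
#' @param mq Mapping quality.
#' @param multi Logical, `TRUE` if the site was called multi-allelic.
#'
#' @return A tibble of class `variant_records` with one row per record.
#' @export
variant_records <- function(strain, contig, pos, kind,
                            ref = "", alt = "", size = 0L, sv_end = NA_integer_,
                            cq = 99L, dp = 50L, mq = 60L, multi = FALSE) {
  x <- tibble::tibble(
    strain = as.character(strain),
    contig = as.character(contig),
    pos = as.integer(pos),
    kind = as.character(kind),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    size = as.integer(size),
    sv_end = as.integer(sv_end),
    cq = as.integer(cq),
    dp = as.integer(dp),
    mq = as.integer(mq),
    multi = as.logical(multi)
  )
  validate_variant_records(x)
  class(x) <- c("variant_records", class(x))
  x
}

#' @keywords internal
validate_variant_records <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$pos < 1L)) stop("variant positions must be >= 1", call. = FALSE)
  bad_kind <- setdiff(unique(x$kind), c("snp", "indel", "sv_del"))
  if (length(bad_kind)) {
    stop("unknown variant kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  snp <- x$kind == "snp"
  if (any(snp)) {
    ok <- x$ref[snp] %in% c("A", "C", "G", "T") &
      x$alt[snp] %in% c("A", "C", "G", "T") &
      x$ref[snp] != x$alt[snp]
    if (!all(ok)) stop("SNPs require single, distinct A/C/G/T alleles",
                       call. = FALSE)
  }
  if (any(x$size[x$kind == "indel"] == 0L)) {
    stop("indels must have non-zero size", call. = FALSE)
  }
  sv <- x$kind == "sv_del"
  if (any(sv) && any(is.na(x$sv_end[sv]) | x$sv_end[sv] <= x$pos[sv])) {
    stop("structural deletions require sv_end > pos", call. = FALSE)
  }
  q <- c(x$cq, x$dp, x$mq)
  if (any(q[!is.na(q)] < 0L)) stop("quality fields must be >= 0", call. = FALSE)
  invisible(x)
}

#' Encode canonical variant identifiers
#'
#' Variants are compared across strains through a compact string key built
#' from contig and position: SNPs additionally carry the alternate base
#' (distinct substitutions at one site are distinct variants), while indels
#' and structural deletions are keyed by location only, so the same event is
#' matched across strains regardless of how its sequence was reported.
#'
#' @param contig Character vector of contig names.
#' @param pos Integer vector of 1-based positions.
#' @param alt_base Optional character vector of alternate bases; `NA` (or
#'   `NULL`) for indel-style keys.
#'
#' @return Character vector of identifiers, e.g. `"3_591470_C"` for a SNP and
#'   `"6_91954"` for an indel.
#' @export
#' @examples
#' encode_variant_id("3", 591470, "C")
#' encode_variant_id("6", 91954)
encode_variant_id <- function(contig, pos, alt_base = NULL) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("position must be a positive integer", call. = FALSE)
  }
  if (is.null(alt_base)) alt_base <- rep(NA_character_, length(pos))
  alt_base <- as.character(alt_base)
  has_alt <- !is.na(alt_base)
  if (any(!alt_base[has_alt] %in% c("A", "C", "G", "T"))) {
    stop("alt_base must be one of A, C, G, T", call. = FALSE)
  }
  out <- paste(contig, pos, sep = "_")
  out[has_alt] <- paste(out[has_alt], alt_base[has_alt], sep = "_")
  out
}

#' Parse canonical variant identifiers
#'
#' Exact inverse of [encode_variant_id()]. Identifiers take the form
#' `contig_pos` (indel) or `contig_pos_base` (SNP); contig names may
#' themselves contain underscores, in which case the final one or two tokens
#' are interpreted as position and base.
#'
#' @param id Character vector of identifiers.
#' @return A tibble with columns `contig`, `pos`, `alt_base` (`NA` for
#'   indel keys).
#' @export
parse_variant_id <- function(id) {
  parts <- strsplit(as.character(id), "_", fixed = TRUE)
  one <- function(p, full) {
    n <- length(p)
    if (n >= 2L && p[n] %in% c("A", "C", "G", "T") &&
        grepl("^[0-9]+$", p[n - 1L])) {
      if (n < 3L) stop("malformed variant id: ", full, call. = FALSE)
      return(list(contig = paste(p[seq_len(n - 2L)], collapse = "_"),
                  pos = as.integer(p[n - 1L]), alt = p[n]))
    }
    if (n >= 2L && grepl("^[0-9]+$", p[n])) {
      return(list(contig = paste(p[seq_len(n - 1L)], collapse = "_"),
                  pos = as.integer(p[n]), alt = NA_character_))
    }
    stop("malformed variant id: '", full, "' (offending token: '",
         p[n], "')", call. = FALSE)
  }
  parsed <- Map(one, parts, id)
  tibble::tibble(
    contig = vapply(parsed, `[[`, "", "contig"),
    pos = vapply(parsed, `[[`, 1L, "pos"),
    alt_base = vapply(parsed, `[[`, "", "alt")
  )
}

#' Add canonical keys to a variant table
#'
#' @param records A `variant_records` tibble.
#' @return The same tibble with a `key` column.
#' @export
add_variant_keys <- function(records) {
  alt <- ifelse(records$kind == "snp", records$alt, NA_character_)
  records$key <- encode_variant_id(records$contig, records$pos, alt)
  records
}

#' Classify a substitution as transition or transversion
#'
#' Purine-to-purine (A/G) and pyrimidine-to-pyrimidine (C/T) changes are
#' transitions; all other changes are transversions.
#'
#' @param ref,alt Character vectors of single bases.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @export
classify_substitution_type <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (any(!ok)) stop("ref and alt must be distinct A/C/G/T bases",
                     call. = FALSE)
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}
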