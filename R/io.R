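TSV_COLUMNS <- c("strain", "contig", "pos", "kind", "ref", "alt", "size",
                 "sv_end", "cq", "dp", "mq", "multi")

#' Read variant records from VCF or the package TSV dialect
#'
#' VCF v4.x records are converted to internal coordinates: the anchor-base
#' convention of VCF indels is undone, so a deletion is reported at the first
#' deleted base with its negative length, and an insertion at the base before
#' which the inserted sequence begins, with its positive length. Sites with
#' comma-separated ALT alleles are split into one record per allele and
#' flagged multi-allelic. Records with ALT `<DEL>` (and an INFO `END`) become
#' structural deletions.
#'
#' The TSV dialect has one header line and the columns
#' `strain contig pos kind ref alt size sv_end cq dp mq multi`, with `.` for
#' absent values; [write_variants()] round-trips it losslessly.
#'
#' @param path File path.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (sniffed from the first line).
#' @param strain Strain identifier to assign to VCF records (VCFs are
#'   per-strain; the TSV dialect carries its own strain column).
#' @return A `variant_records` tibble.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          strain = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "##fileformat=VCF")) "vcf" else "tsv"
  }
  if (format == "tsv") read_variants_tsv(path) else read_variants_vcf(path, strain)
}

read_variants_tsv <- function(path) {
  x <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                       col_types = readr::cols(
                         strain = "c", contig = "c", pos = "i", kind = "c",
                         ref = "c", alt = "c", size = "i", sv_end = "i",
                         cq = "i", dp = "i", mq = "i", multi = "l"))
  missing <- setdiff(TSV_COLUMNS, names(x))
  if (length(missing)) {
    stop("TSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x$ref[is.na(x$ref)] <- ""
  x$alt[is.na(x$alt)] <- ""
  out <- variant_records(x$strain, x$contig, x$pos, x$kind, x$ref, x$alt,
                         x$size, x$sv_end, x$cq, x$dp, x$mq, x$multi)
  out
}

read_variants_vcf <- function(path, strain) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(variant_records(character(0), character(0), integer(0), character(0)))
  }
  info_field <- function(key) {
    suppressWarnings(vcfR::extract.info(v, element = key))
  }
  dp <- suppressWarnings(as.integer(info_field("DP")))
  mq <- suppressWarnings(as.integer(info_field("MQ")))
  end <- suppressWarnings(as.integer(info_field("END")))
  qual <- suppressWarnings(as.integer(round(as.numeric(fix$QUAL))))
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    multi <- length(alts) > 1L
    pos <- as.integer(fix$POS[i])
    ref <- toupper(fix$REF[i])
    rr <- lapply(alts, function(a) {
      a <- toupper(a)
      if (a == "<DEL>") {
        if (is.na(end[i])) {
          stop("line ", i, ": <DEL> record without INFO END", call. = FALSE)
        }
        list(pos = pos, kind = "sv_del", ref = "", alt = "",
             size = -(end[i] - pos + 1L), sv_end = end[i])
      } else if (nchar(ref) == 1L && nchar(a) == 1L) {
        list(pos = pos, kind = "snp", ref = ref, alt = a, size = 0L,
             sv_end = NA_integer_)
      } else if (nchar(ref) > nchar(a)) {
        if (substr(ref, 1L, nchar(a)) != a) {
          stop("line ", i, ": unsupported complex allele ", ref, ">", a,
               call. = FALSE)
        }
        del <- substr(ref, nchar(a) + 1L, nchar(ref))
        list(pos = pos + nchar(a), kind = "indel", ref = del, alt = "",
             size = -nchar(del), sv_end = NA_integer_)
      } else if (nchar(a) > nchar(ref)) {
        if (substr(a, 1L, nchar(ref)) != ref) {
          stop("line ", i, ": unsupported complex allele ", ref, ">", a,
               call. = FALSE)
        }
        ins <- substr(a, nchar(ref) + 1L, nchar(a))
        list(pos = pos + nchar(ref), kind = "indel", ref = "", alt = ins,
             size = nchar(ins), sv_end = NA_integer_)
      } else {
        stop("line ", i, ": unsupported allele pair ", ref, ">", a,
             call. = FALSE)
      }
    })
    rows[[i]] <- tibble::tibble(
      pos = vapply(rr, `[[`, 1L, "pos"),
      kind = vapply(rr, `[[`, "", "kind"),
      ref = vapply(rr, `[[`, "", "ref"),
      alt = vapply(rr, `[[`, "", "alt"),
      size = vapply(rr, `[[`, 1L, "size"),
      sv_end = vapply(rr, `[[`, 1L, "sv_end"),
      contig = fix$CHROM[i], cq = qual[i], dp = dp[i], mq = mq[i],
      multi = multi)
  }
  x <- dplyr::bind_rows(rows)
  variant_records(strain, x$contig, x$pos, x$kind, x$ref, x$alt, x$size,
                  x$sv_end, x$cq, x$dp, x$mq, x$multi)
}

#' Write variant records
#'
#' @param records A `variant_records` tibble.
#' @param path Output path.
#' @param format `"tsv"` (lossless round trip with [read_variants()]) or
#'   `"vcf"` (sites-only VCF v4.2; requires `reference` to reconstruct indel
#'   anchor bases).
#' @param reference A named `DNAStringSet` (required for `format = "vcf"`).
#' @return `path`, invisibly.
#' @export
write_variants <- function(records, path, format = c("tsv", "vcf"),
                           reference = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    x <- as.data.frame(records)[, TSV_COLUMNS]
    x$ref[x$ref == ""] <- NA_character_
    x$alt[x$alt == ""] <- NA_character_
    readr::write_tsv(tibble::as_tibble(x), path, na = ".")
    return(invisible(path))
  }
  if (is.null(reference)) {
    stop("writing VCF requires the reference sequence", call. = FALSE)
  }
  write_vcf_records(records, path, reference)
}

write_vcf_records <- function(records, path, reference) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(reference), ",length=",
                  Biostrings::width(reference), ">"),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"Mapping quality\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  n <- nrow(records)
  if (n == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  base_at <- function(contig, p) {
    as.character(Biostrings::subseq(reference[[contig]], p, p))
  }
  pos <- integer(n); ref <- character(n); alt <- character(n)
  info <- character(n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    base_info <- paste0("DP=", r$dp, ";MQ=", r$mq)
    if (r$kind == "snp") {
      pos[i] <- r$pos; ref[i] <- r$ref; alt[i] <- r$alt; info[i] <- base_info
    } else if (r$kind == "sv_del") {
      pos[i] <- r$pos; ref[i] <- base_at(r$contig, r$pos); alt[i] <- "<DEL>"
      info[i] <- paste0(base_info, ";SVTYPE=DEL;END=", r$sv_end)
    } else if (r$size < 0L) {
      anchor <- base_at(r$contig, r$pos - 1L)
      pos[i] <- r$pos - 1L
      ref[i] <- paste0(anchor, r$ref)
      alt[i] <- anchor
      info[i] <- base_info
    } else {
      anchor <- base_at(r$contig, r$pos - 1L)
      pos[i] <- r$pos - 1L
      ref[i] <- anchor
      alt[i] <- paste0(anchor, r$alt)
      info[i] <- base_info
    }
  }
  body <- paste(records$contig, pos, ".", ref, alt, records$cq, "PASS", info,
                sep = "\t")
  o <- order(records$contig, pos)
  writeLines(c(hdr, body[o]), path)
  invisible(path)
}

#' Marker interval
#'
#' A genetically delimited search region on one contig. Bounds may be open
#' (`NA`), mirroring map-derived ranges written as `"> pos"` or `"< pos"`;
#' open bounds resolve to the contig ends at evaluation time.
#'
#' @param contig Contig name.
#' @param left,right Integer bounds, `NA` for open.
#' @param left_marker,right_marker Optional marker labels.
#' @return A list of class `marker_interval`.
#' @export
marker_interval <- function(contig, left = NA_integer_, right = NA_integer_,
                            left_marker = NA_character_,
                            right_marker = NA_character_) {
  x <- list(contig = as.character(contig), left = as.integer(left),
            right = as.integer(right), left_marker = left_marker,
            right_marker = right_marker)
  if (!is.na(x$left) && !is.na(x$right) && x$left >= x$right) {
    stop("marker interval requires left < right", call. = FALSE)
  }
  class(x) <- "marker_interval"
  x
}

#' Parse a textual range specification
#'
#' Accepts the three forms used in genetic-mapping tables: `"A to B"` (both
#' bounds closed), `"> A"` (right-open: the region right of A), and `"< B"`
#' (left-open: the region left of B).
#'
#' @param text Range text.
#' @param contig Contig the range lives on.
#' @return A [marker_interval()].
#' @export
parse_range_spec <- function(text, contig) {
  t <- chartr("＞＜", "><", text)  # normalize full-width comparators
  t <- gsub("[,  ]", "", t)
  if (grepl("^>", t)) {
    marker_interval(contig, left = as.integer(sub("^>", "", t)))
  } else if (grepl("^<", t)) {
    marker_interval(contig, right = as.integer(sub("^<", "", t)))
  } else if (grepl("to", text)) {
    b <- as.integer(strsplit(gsub("[, ]", "", text), "to")[[1]])
    marker_interval(contig, left = b[1], right = b[2])
  } else {
    stop("cannot parse range spec: ", text, call. = FALSE)
  }
}

#' Resolve a marker interval against a contig length
#'
#' @param interval A [marker_interval()].
#' @param contig_length Length of the interval's contig.
#' @return Named integer vector `c(lo, hi)` (closed bounds).
#' @export
resolve_marker_interval <- function(interval, contig_length) {
  stopifnot(inherits(interval, "marker_interval"), contig_length >= 1)
  lo <- if (is.na(interval$left)) 1L else interval$left
  hi <- if (is.na(interval$right)) as.integer(contig_length) else interval$right
  if (lo > hi) stop("resolved interval has lo > hi", call. = FALSE)
  c(lo = lo, hi = hi)
}

#' Read a marker-interval table
#'
#' Tab-separated columns `strain`, `trait`, `contig`, `left`, `right`; the
#' bound columns accept plain integers, `>pos` / `<pos` tokens (which open the
#' opposite bound) or `.` for open.
#'
#' @param path File path.
#' @return A named list of [marker_interval()] objects keyed by strain.
#' @export
read_marker_intervals <- function(path) {
  x <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  parse_bound <- function(tok, side) {
    if (is.na(tok)) return(list(left = NA_integer_, right = NA_integer_))
    if (grepl("^>", tok)) {
      list(left = as.integer(sub("^>", "", tok)), right = NA_integer_)
    } else if (grepl("^<", tok)) {
      list(left = NA_integer_, right = as.integer(sub("^<", "", tok)))
    } else if (side == "left") {
      list(left = as.integer(tok), right = NA_integer_)
    } else {
      list(left = NA_integer_, right = as.integer(tok))
    }
  }
  out <- list()
  for (i in seq_len(nrow(x))) {
    lb <- parse_bound(x$left[i], "left")
    rb <- parse_bound(x$right[i], "right")
    left <- if (!is.na(lb$left)) lb$left else rb$left
    right <- if (!is.na(rb$right)) rb$right else lb$right
    out[[x$strain[i]]] <- marker_interval(x$contig[i], left, right)
  }
  out
}
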