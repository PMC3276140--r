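EFFECT_CATEGORIES <- c("noncoding_intergenic", "utr5", "utr3", "intron",
                       "splice_site", "synonymous", "nonsynonymous",
                       "nonsense", "cds_frameshift", "cds_inframe",
                       "sv_gene_deletion")

complement_bases <- function(x) chartr("ACGT", "TGCA", x)

translate_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Classify variants against gene models
#'
#' Assigns every record exactly one effect category. SNPs inside coding
#' sequence are classified by strand-aware codon translation into
#' `synonymous`, `nonsynonymous` or `nonsense` (with the affected residue);
#' other SNPs fall through the precedence CDS > splice site > UTR > intron >
#' intergenic. Indels overlapping coding sequence become `cds_frameshift`
#' (length not a multiple of 3) or `cds_inframe`; indel precedence is splice
#' site > CDS > intron > UTR > intergenic. A structural deletion that removes
#' at least one complete CDS exon is `sv_gene_deletion`.
#'
#' The splice-site window is the first and last two bases of each intron
#' (canonical donor/acceptor dinucleotides).
#'
#' @param records A `variant_records` tibble (a `key` column is added if
#'   absent).
#' @param annotation A `gene_annotation` from [read_gene_models()].
#' @param check_reference Verify that each SNP's reference allele (and each
#'   deletion's deleted sequence) matches the reference genome; a mismatch is
#'   a data-integrity error naming strain, contig and position.
#' @return A tibble of effect calls: `key`, `strain`, `contig`, `pos`,
#'   `kind`, `size`, `multi`, `gene_id`, `category`, `aa_pos`, `ref_aa`,
#'   `alt_aa`.
#' @export
classify_variants <- function(records, annotation, check_reference = TRUE) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (!"key" %in% names(records)) records <- add_variant_keys(records)
  n <- nrow(records)
  out <- tibble::tibble(
    key = records$key, strain = records$strain, contig = records$contig,
    pos = records$pos, kind = records$kind, size = records$size,
    multi = records$multi,
    gene_id = NA_character_, category = "noncoding_intergenic",
    aa_pos = NA_integer_, ref_aa = NA_character_, alt_aa = NA_character_)
  if (n == 0L) return(out)
  if (check_reference) check_reference_alleles(records, annotation$reference)

  idx <- annotation$index
  is_snp <- records$kind == "snp"
  width <- ifelse(records$kind == "sv_del",
                  records$sv_end - records$pos + 1L,
                  ifelse(records$size < 0L, -records$size, 1L))
  gr <- GenomicRanges::GRanges(records$contig,
                               IRanges::IRanges(records$pos,
                                                records$pos + width - 1L))

  assign_hits <- function(which_rows, subject, category) {
    if (!length(subject) || !any(which_rows)) return(invisible(NULL))
    hits <- GenomicRanges::findOverlaps(gr[which_rows], subject)
    if (!length(hits)) return(invisible(NULL))
    q <- which(which_rows)[S4Vectors::queryHits(hits)]
    s <- S4Vectors::subjectHits(hits)
    first <- !duplicated(q)
    q <- q[first]; s <- s[first]
    out$category[q] <<- category
    out$gene_id[q] <<- S4Vectors::mcols(subject)$gene_id[s]
    invisible(list(q = q, s = s))
  }

  # --- SNPs: precedence intergenic < intron < UTR < splice < CDS ---
  assign_hits(is_snp, idx$intron, "intron")
  assign_hits(is_snp, idx$utr3, "utr3")
  assign_hits(is_snp, idx$utr5, "utr5")
  assign_hits(is_snp, idx$splice, "splice_site")
  cds_hit <- assign_hits(is_snp, idx$cds, "cds")
  if (!is.null(cds_hit)) {
    q <- cds_hit$q; s <- cds_hit$s
    piece_start <- GenomicRanges::start(idx$cds)[s]
    piece_end <- GenomicRanges::end(idx$cds)[s]
    strand_gene <- S4Vectors::mcols(idx$cds)$strand_gene[s]
    offset <- S4Vectors::mcols(idx$cds)$offset[s]
    gid <- S4Vectors::mcols(idx$cds)$gene_id[s]
    coding_pos <- ifelse(strand_gene == "+",
                         offset + (records$pos[q] - piece_start + 1L),
                         offset + (piece_end - records$pos[q] + 1L))
    codon_idx <- (coding_pos - 1L) %/% 3L + 1L
    codon_off <- (coding_pos - 1L) %% 3L + 1L
    for (k in seq_along(q)) {
      gene <- annotation$genes[[gid[k]]]
      codon <- substr(gene$cds_seq, 3L * (codon_idx[k] - 1L) + 1L,
                      3L * codon_idx[k])
      alt <- records$alt[q[k]]
      if (strand_gene[k] == "-") alt <- complement_bases(alt)
      mutant <- codon
      substr(mutant, codon_off[k], codon_off[k]) <- alt
      ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
      alt_aa <- unname(Biostrings::GENETIC_CODE[mutant])
      out$aa_pos[q[k]] <- codon_idx[k]
      out$ref_aa[q[k]] <- ref_aa
      out$alt_aa[q[k]] <- alt_aa
      out$category[q[k]] <-
        if (alt_aa == "*" && ref_aa != "*") "nonsense"
        else if (alt_aa == ref_aa) "synonymous"
        else "nonsynonymous"
    }
  }

  # --- indels and structural deletions:
  #     precedence intergenic < UTR < intron < CDS < splice ---
  is_ind <- !is_snp
  assign_hits(is_ind, idx$utr3, "utr3")
  assign_hits(is_ind, idx$utr5, "utr5")
  assign_hits(is_ind, idx$intron, "intron")
  cds_hit <- assign_hits(is_ind, idx$cds, "cds")
  if (!is.null(cds_hit)) {
    q <- cds_hit$q; s <- cds_hit$s
    frameshift <- records$size[q] %% 3L != 0L
    out$category[q] <- ifelse(frameshift, "cds_frameshift", "cds_inframe")
    # first affected residue where the indel starts inside the CDS piece
    piece_start <- GenomicRanges::start(idx$cds)[s]
    piece_end <- GenomicRanges::end(idx$cds)[s]
    strand_gene <- S4Vectors::mcols(idx$cds)$strand_gene[s]
    offset <- S4Vectors::mcols(idx$cds)$offset[s]
    inside <- records$pos[q] >= piece_start & records$pos[q] <= piece_end
    coding_pos <- ifelse(strand_gene == "+",
                         offset + (records$pos[q] - piece_start + 1L),
                         offset + (piece_end - records$pos[q] + 1L))
    out$aa_pos[q[inside]] <- (coding_pos[inside] - 1L) %/% 3L + 1L
  }
  assign_hits(is_ind, idx$splice, "splice_site")

  # structural deletions that swallow a whole CDS exon trump everything
  is_sv <- records$kind == "sv_del"
  if (any(is_sv) && length(idx$cds)) {
    hits <- GenomicRanges::findOverlaps(idx$cds, gr[is_sv], type = "within")
    if (length(hits)) {
      q <- which(is_sv)[S4Vectors::subjectHits(hits)]
      gid <- S4Vectors::mcols(idx$cds)$gene_id[S4Vectors::queryHits(hits)]
      first <- !duplicated(q)
      out$category[q[first]] <- "sv_gene_deletion"
      out$gene_id[q[first]] <- gid[first]
      out$aa_pos[q[first]] <- NA_integer_
    }
  }
  out
}

check_reference_alleles <- function(records, reference) {
  for (ctg in unique(records$contig)) {
    if (!ctg %in% names(reference)) next
    in_c <- which(records$contig == ctg)
    refseq <- reference[[ctg]]
    snps <- in_c[records$kind[in_c] == "snp"]
    if (length(snps)) {
      at <- IRanges::IRanges(records$pos[snps], records$pos[snps])
      obs <- as.character(Biostrings::extractAt(refseq, at))
      bad <- which(obs != records$ref[snps])
      if (length(bad)) {
        b <- snps[bad[1]]
        stop("reference mismatch for strain ", records$strain[b],
             " at ", ctg, ":", records$pos[b], " (expected ",
             records$ref[b], ", reference has ", obs[bad[1]], ")",
             call. = FALSE)
      }
    }
    dels <- in_c[records$kind[in_c] == "indel" & records$size[in_c] < 0L &
                   nzchar(records$ref[in_c])]
    if (length(dels)) {
      at <- IRanges::IRanges(records$pos[dels],
                             records$pos[dels] - records$size[dels] - 1L)
      obs <- as.character(Biostrings::extractAt(refseq, at))
      bad <- which(obs != records$ref[dels])
      if (length(bad)) {
        b <- dels[bad[1]]
        stop("reference mismatch for strain ", records$strain[b],
             " at ", ctg, ":", records$pos[b], " (deleted sequence ",
             records$ref[b], " != reference ", obs[bad[1]], ")",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Scan a frameshifted transcript for premature stop codons
#'
#' Applies an indel to a gene's coding sequence, translates the mutant CDS in
#' the original reading frame from the start codon, and reports the first
#' stop codon occurring strictly before the wild-type terminal stop, plus the
#' number of stop codons observed up to the wild-type protein length.
#'
#' @param annotation A `gene_annotation`.
#' @param gene_id Gene carrying the indel.
#' @param record A single-row `variant_records` tibble with `kind = "indel"`
#'   whose position lies inside the gene's CDS.
#' @return A list with `first_stop_aa` (`NA` when no premature stop) and
#'   `stop_count`.
#' @export
scan_premature_stops <- function(annotation, gene_id, record) {
  gene <- annotation$genes[[gene_id]]
  if (is.null(gene) || !gene$valid) stop("unknown or invalid gene: ", gene_id,
                                         call. = FALSE)
  stopifnot(nrow(record) == 1L, record$kind == "indel")
  map <- coding_map(gene)
  seq <- gene$cds_seq
  if (record$size < 0L) {
    del <- record$pos:(record$pos - record$size - 1L)
    hit <- which(map %in% del)
    if (!length(hit)) stop("indel does not touch the CDS of ", gene_id,
                           call. = FALSE)
    keep <- setdiff(seq_len(nchar(seq)), hit)
    chars <- strsplit(seq, "")[[1]]
    mutant <- paste(chars[keep], collapse = "")
  } else {
    i <- match(record$pos, map)
    if (is.na(i)) stop("indel does not touch the CDS of ", gene_id,
                       call. = FALSE)
    ins <- record$alt
    if (gene$strand == "+") {
      mutant <- paste0(substr(seq, 1L, i - 1L), ins,
                       substr(seq, i, nchar(seq)))
    } else {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ins)))
      mutant <- paste0(substr(seq, 1L, i), rc,
                       substr(seq, i + 1L, nchar(seq)))
    }
  }
  aas <- translate_codons(mutant)
  horizon <- min(gene$protein_length, length(aas))
  stops <- which(aas[seq_len(horizon)] == "*")
  premature <- stops[stops < gene$protein_length]
  list(first_stop_aa = if (length(premature)) premature[1] else NA_integer_,
       stop_count = length(stops))
}
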