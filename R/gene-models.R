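#' Build a gene annotation set from feature intervals and a reference
#'
#' Internal constructor shared by [read_gene_models()] and the cohort
#' simulator. Exon/CDS intervals are 1-based and closed; UTRs are derived
#' from the exonic sequence outside the CDS (transcription-wise upstream =
#' 5' UTR). Genes whose total CDS length is not divisible by 3 are flagged
#' invalid, excluded from codon-level classification, and reported with a
#' warning.
#'
#' @param features Tibble with columns `gene_id`, `contig`, `strand`
#'   (`"+"`/`"-"`), `type` (`"exon"` or `"CDS"`), `start`, `end`.
#' @param reference Named `DNAStringSet`.
#' @return An object of class `gene_annotation`.
#' @keywords internal
gene_annotation <- function(features, reference) {
  stopifnot(all(c("gene_id", "contig", "strand", "type", "start", "end")
                %in% names(features)))
  gids <- unique(features$gene_id)
  genes <- vector("list", length(gids))
  names(genes) <- gids
  invalid <- character(0)
  refchar <- lapply(reference, as.character)
  for (g in gids) {
    f <- features[features$gene_id == g, ]
    exons <- f[f$type == "exon", c("start", "end")]
    cds <- f[f$type == "CDS", c("start", "end")]
    exons <- exons[order(exons$start), , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    if (nrow(exons) == 0L) exons <- cds
    strand <- f$strand[1]
    contig <- f$contig[1]
    cds_len <- if (nrow(cds)) sum(cds$end - cds$start + 1L) else 0L
    ok <- cds_len > 0L && cds_len %% 3L == 0L
    if (!ok && cds_len > 0L) invalid <- c(invalid, g)
    cds_seq <- NULL
    if (ok) {
      pieces <- substring(refchar[[contig]], cds$start, cds$end)
      cds_seq <- paste(pieces, collapse = "")
      # strand correction is batched over all minus-strand genes below
    }
    # exonic-but-not-CDS intervals, split into upstream/downstream of the CDS
    utr5 <- utr3 <- data.frame(start = integer(0), end = integer(0))
    if (nrow(cds) && nrow(exons)) {
      cds_lo <- min(cds$start); cds_hi <- max(cds$end)
      clip <- function(lo, hi) {
        s <- pmax(exons$start, lo); e <- pmin(exons$end, hi)
        keep <- s <= e
        data.frame(start = s[keep], end = e[keep])
      }
      left <- clip(1L, cds_lo - 1L)
      right <- clip(cds_hi + 1L, .Machine$integer.max)
      if (strand == "+") { utr5 <- left; utr3 <- right }
      else { utr5 <- right; utr3 <- left }
    }
    # introns: gaps between consecutive exons
    introns <- data.frame(start = integer(0), end = integer(0))
    if (nrow(exons) > 1L) {
      introns <- data.frame(start = exons$end[-nrow(exons)] + 1L,
                            end = exons$start[-1] - 1L)
      introns <- introns[introns$end >= introns$start, , drop = FALSE]
    }
    genes[[g]] <- list(
      gene_id = g, contig = contig, strand = strand,
      start = min(exons$start), end = max(exons$end),
      exons = exons, cds = as.data.frame(cds), introns = introns,
      utr5 = utr5, utr3 = utr3,
      cds_len = cds_len, valid = ok, cds_seq = cds_seq,
      protein_length = if (ok) cds_len %/% 3L else NA_integer_)
  }
  minus_ok <- vapply(genes, function(x) x$valid && x$strand == "-", TRUE)
  if (any(minus_ok)) {
    rc <- unname(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(
        unname(vapply(genes[minus_ok], `[[`, "", "cds_seq"))))))
    for (k in seq_along(which(minus_ok))) {
      genes[[which(minus_ok)[k]]]$cds_seq <- rc[k]
    }
  }
  if (length(invalid)) {
    warning("CDS length not divisible by 3 for gene(s) ",
            paste(invalid, collapse = ", "),
            "; excluded from codon-level classification", call. = FALSE)
  }
  ann <- list(genes = genes, reference = reference)
  ann$summary <- tibble::tibble(
    gene_id = gids,
    contig = vapply(genes, `[[`, "", "contig"),
    strand = vapply(genes, `[[`, "", "strand"),
    start = vapply(genes, `[[`, 1L, "start"),
    end = vapply(genes, `[[`, 1L, "end"),
    cds_len = vapply(genes, `[[`, 1L, "cds_len"),
    protein_length = vapply(genes, `[[`, 1L, "protein_length"),
    valid = vapply(genes, `[[`, TRUE, "valid"))
  ann$index <- build_annotation_index(genes)
  class(ann) <- "gene_annotation"
  ann
}

# GRanges lookup tables: CDS pieces carry the coding offset of their first
# base (in transcription order) so a genomic hit converts to a coding
# coordinate without walking the gene.
build_annotation_index <- function(genes) {
  gr <- function(contig, start, end, gene_id, extra = NULL) {
    if (!length(start)) {
      g <- GenomicRanges::GRanges()
      S4Vectors::mcols(g)$gene_id <- character(0)
      return(g)
    }
    g <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
    S4Vectors::mcols(g)$gene_id <- gene_id
    if (!is.null(extra)) for (nm in names(extra)) S4Vectors::mcols(g)[[nm]] <- extra[[nm]]
    g
  }
  acc <- function(field) {
    parts <- lapply(genes, function(x) {
      d <- x[[field]]
      if (!nrow(d)) return(NULL)
      data.frame(contig = x$contig, start = d$start, end = d$end,
                 gene_id = x$gene_id, strand = x$strand,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  }
  # CDS pieces with coding offsets, valid genes only
  cds_parts <- lapply(genes, function(x) {
    if (!x$valid || !nrow(x$cds)) return(NULL)
    d <- x$cds
    widths <- d$end - d$start + 1L
    if (x$strand == "+") {
      off <- cumsum(c(0L, widths[-length(widths)]))
    } else {
      rev_w <- rev(widths)
      off <- rev(cumsum(c(0L, rev_w[-length(rev_w)])))
    }
    data.frame(contig = x$contig, start = d$start, end = d$end,
               gene_id = x$gene_id, strand = x$strand, offset = off,
               stringsAsFactors = FALSE)
  })
  cds_df <- do.call(rbind, cds_parts[!vapply(cds_parts, is.null, TRUE)])
  # splice windows: terminal 2 bases of each intron (donor + acceptor)
  spl_parts <- lapply(genes, function(x) {
    if (!nrow(x$introns)) return(NULL)
    d <- x$introns
    w <- pmin(2L, d$end - d$start + 1L)
    data.frame(contig = x$contig,
               start = c(d$start, d$end - w + 1L),
               end = c(d$start + w - 1L, d$end),
               gene_id = x$gene_id, strand = x$strand,
               stringsAsFactors = FALSE)
  })
  spl_df <- do.call(rbind, spl_parts[!vapply(spl_parts, is.null, TRUE)])
  span_df <- data.frame(
    contig = vapply(genes, `[[`, "", "contig"),
    start = vapply(genes, `[[`, 1L, "start"),
    end = vapply(genes, `[[`, 1L, "end"),
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    strand = vapply(genes, `[[`, "", "strand"), stringsAsFactors = FALSE)
  as_gr <- function(d, extra_cols = character(0)) {
    if (is.null(d) || !nrow(d)) {
      g <- GenomicRanges::GRanges()
      S4Vectors::mcols(g)$gene_id <- character(0)
      S4Vectors::mcols(g)$strand_gene <- character(0)
      for (nm in extra_cols) S4Vectors::mcols(g)[[nm]] <- integer(0)
      return(g)
    }
    g <- GenomicRanges::GRanges(d$contig, IRanges::IRanges(d$start, d$end))
    S4Vectors::mcols(g)$gene_id <- d$gene_id
    S4Vectors::mcols(g)$strand_gene <- d$strand
    for (nm in extra_cols) S4Vectors::mcols(g)[[nm]] <- d[[nm]]
    g
  }
  list(
    cds = as_gr(cds_df, "offset"),
    splice = as_gr(spl_df),
    intron = as_gr(acc("introns")),
    utr5 = as_gr(acc("utr5")),
    utr3 = as_gr(acc("utr3")),
    span = as_gr(span_df)
  )
}

#' Read gene models from GFF3 and FASTA
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features, assembles each gene's coding
#' sequence in transcription order (minus-strand CDS reverse-complemented),
#' and derives UTRs and introns from the exon/CDS geometry. Genes with a CDS
#' length not divisible by 3 are flagged and excluded from codon-level
#' classification with a warning.
#'
#' @param gff_path Path to a GFF3 file.
#' @param fasta_path Path to the reference FASTA.
#' @return A `gene_annotation` object.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  reference <- Biostrings::readDNAStringSet(fasta_path)
  names(reference) <- sub("\\s.*$", "", names(reference))
  gff <- rtracklayer::import(gff_path, format = "gff3")
  md <- S4Vectors::mcols(gff)
  type <- as.character(md$type)
  # map every feature to its gene through the Parent chain (mRNA -> gene)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, length(gff))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_, "")
  } else rep(NA_character_, length(gff))
  gene_of <- ids
  is_gene <- type == "gene"
  gene_ids <- ids[is_gene]
  # resolve transcript parents to genes
  tx <- type %in% c("mRNA", "transcript")
  tx_gene <- stats::setNames(parents[tx], ids[tx])
  feat <- type %in% c("exon", "CDS")
  owner <- parents[feat]
  owner_gene <- ifelse(owner %in% names(tx_gene), tx_gene[owner], owner)
  features <- tibble::tibble(
    gene_id = unname(owner_gene),
    contig = as.character(GenomicRanges::seqnames(gff))[feat],
    strand = as.character(GenomicRanges::strand(gff))[feat],
    type = type[feat],
    start = GenomicRanges::start(gff)[feat],
    end = GenomicRanges::end(gff)[feat])
  missing_ref <- setdiff(unique(features$contig), names(reference))
  if (length(missing_ref)) {
    stop("contigs in GFF absent from FASTA: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  gene_annotation(features, reference)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation> ", length(x$genes), " genes on ",
      length(x$reference), " contig(s); ",
      sum(!x$summary$valid), " flagged invalid\n", sep = "")
  invisible(x)
}

#' Genomic positions of a gene's CDS in transcription order
#' @keywords internal
coding_map <- function(gene) {
  pos <- unlist(mapply(function(s, e) s:e, gene$cds$start, gene$cds$end,
                       SIMPLIFY = FALSE))
  if (gene$strand == "-") pos <- rev(pos)
  pos
}
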