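#' Configuration for a synthetic resequencing cohort
#'
#' The generator emulates the polymorphism structure of a multi-strain
#' haploid fungal resequencing panel: per-strain divergence from the
#' reference spanning an order of magnitude, most variation shared through
#' chromosome-scale haplotype blocks, a transition bias near 3:1, indels
#' depleted in coding sequence and biased toward frame-preserving sizes
#' there, a small set of variants present in every strain (reference-genome
#' background), and one planted severe causative mutation per focal strain
#' inside its marker interval.
#'
#' @param n_contigs Number of contigs (default 1).
#' @param contig_length Contig length in bases (default 1e6).
#' @param n_genes Total genes placed, both strands (default 200).
#' @param exons_per_gene Exons per gene (default 2, i.e. one intron).
#' @param n_strains Cohort size (default 6).
#' @param divergence Per-strain SNP density, SNPs/kb; default spans an
#'   order of magnitude (0.05 to 0.5/kb) on a log scale, emulating the
#'   spread between backcrossed and divergent lineages.
#' @param titv_ratio Transition:transversion ratio (default 3).
#' @param indel_fraction Indels generated per SNP (default 0.1).
#' @param cds_indel_acceptance Probability that an indel proposed inside
#'   coding sequence is retained (purifying selection; default 0.35).
#' @param cds_inframe_enrichment Probability that a retained CDS indel has a
#'   length that is a multiple of 3 (default 0.7).
#' @param n_haplotype_blocks Number of equal-width haplotype blocks per
#'   contig through which shared variation is inherited (default 8; 0
#'   disables sharing, making every variant private).
#' @param shared_fraction Fraction of each strain's divergence inherited
#'   through shared blocks (default 0.95).
#' @param n_reference_background_variants Variants planted in every strain
#'   (default 50).
#' @param causative_plan `NULL` for an automatic plan (one focal strain of
#'   median divergence, one ~40 kb marker interval, category drawn from
#'   nonsense/frameshift), or a list of entries
#'   `list(strain=, contig=, lo=, hi=, category=)`.
#' @param interval_length Interval length used by the automatic plan
#'   (default 40,000 bases, i.e. the same fraction of the toy genome as a
#'   typical genetic-map interval of a full-size genome).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_contigs = 1L, contig_length = 1000000L,
                          n_genes = 200L, exons_per_gene = 2L,
                          n_strains = 6L,
                          divergence = NULL, titv_ratio = 3,
                          indel_fraction = 0.1,
                          cds_indel_acceptance = 0.35,
                          cds_inframe_enrichment = 0.7,
                          n_haplotype_blocks = 8L,
                          shared_fraction = 0.95,
                          n_reference_background_variants = 50L,
                          causative_plan = NULL,
                          interval_length = 40000L) {
  if (is.null(divergence)) {
    divergence <- 10^seq(log10(0.05), log10(0.5), length.out = n_strains)
  }
  stopifnot(length(divergence) == n_strains, all(divergence >= 0))
  cfg <- list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    n_strains = as.integer(n_strains),
    strains = sprintf("S%02d", seq_len(n_strains)),
    divergence = divergence,
    titv_ratio = titv_ratio,
    indel_fraction = indel_fraction,
    cds_indel_acceptance = cds_indel_acceptance,
    cds_inframe_enrichment = cds_inframe_enrichment,
    n_haplotype_blocks = as.integer(n_haplotype_blocks),
    shared_fraction = shared_fraction,
    n_reference_background_variants = as.integer(n_reference_background_variants),
    causative_plan = causative_plan,
    interval_length = as.integer(interval_length))
  class(cfg) <- "cohort_config"
  cfg
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_codons <- function(n) {
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  paste(sample(non_stop, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference genome with gene models
#'
#' Genes are placed without overlap on alternating random strands. Each gene
#' has exonic UTRs, `exons_per_gene` CDS pieces separated by GT..AG introns,
#' a CDS beginning with ATG, free of internal stop codons, and ending in a
#' stop codon, so every emitted gene translates cleanly. Output is
#' deterministic under the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `gene_annotation` (reference sequences plus gene models).
#' @export
generate_reference <- function(config, seed = 1L) {
  set.seed(seed)
  genes_per_contig <- rep(config$n_genes %/% config$n_contigs,
                          config$n_contigs)
  if (config$n_contigs >= 1) {
    genes_per_contig[1] <- genes_per_contig[1] +
      config$n_genes %% config$n_contigs
  }
  ref_seqs <- character(config$n_contigs)
  feat_list <- list()
  gene_no <- 0L
  for (ci in seq_len(config$n_contigs)) {
    contig <- paste0("ctg", ci)
    layouts <- list()
    for (k in seq_len(genes_per_contig[ci])) {
      gene_no <- gene_no + 1L
      layouts[[k]] <- build_gene_layout(
        gene_id = sprintf("G%04d", gene_no),
        exons = config$exons_per_gene)
    }
    total_gene_len <- sum(vapply(layouts, function(x) nchar(x$seq), 1L))
    slack <- config$contig_length - total_gene_len
    n_gaps <- length(layouts) + 1L
    if (slack < n_gaps * 50L) {
      stop("contig too short for requested gene density", call. = FALSE)
    }
    cuts <- sort(sample.int(slack - n_gaps * 50L + n_gaps, n_gaps - 1L))
    gaps <- diff(c(0L, cuts, slack - n_gaps * 50L + n_gaps)) - 1L + 50L
    pieces <- character(0)
    cursor <- 0L
    for (k in seq_along(layouts)) {
      gap_seq <- random_dna(gaps[k])
      pieces <- c(pieces, gap_seq)
      cursor <- cursor + gaps[k]
      lay <- layouts[[k]]
      strand <- sample(c("+", "-"), 1L)
      L <- nchar(lay$seq)
      if (strand == "+") {
        seg <- lay$seq
        map_int <- function(iv) iv + cursor
      } else {
        seg <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(lay$seq)))
        map_int <- function(iv) {
          cbind(start = cursor + L - iv[, "end"] + 1L,
                end = cursor + L - iv[, "start"] + 1L)
        }
      }
      pieces <- c(pieces, seg)
      ex <- map_int(lay$exons)
      cd <- map_int(lay$cds)
      feat_list[[length(feat_list) + 1L]] <- tibble::tibble(
        gene_id = lay$gene_id, contig = contig, strand = strand,
        type = rep(c("exon", "CDS"), c(nrow(ex), nrow(cd))),
        start = c(ex[, "start"], cd[, "start"]),
        end = c(ex[, "end"], cd[, "end"]))
      cursor <- cursor + L
    }
    tail_len <- config$contig_length - cursor
    if (tail_len > 0L) pieces <- c(pieces, random_dna(tail_len))
    ref_seqs[ci] <- paste(pieces, collapse = "")
  }
  reference <- Biostrings::DNAStringSet(ref_seqs)
  names(reference) <- paste0("ctg", seq_len(config$n_contigs))
  features <- dplyr::bind_rows(feat_list)
  gene_annotation(features, reference)
}

# transcript-orientation layout of one gene; intervals are local 1-based
build_gene_layout <- function(gene_id, exons = 2L) {
  n_codons <- sample(100:300, 1L)
  cds_seq <- paste0("ATG", random_codons(n_codons - 2L),
                    sample(STOP_CODONS, 1L))
  cds_len <- nchar(cds_seq)
  # split the CDS into `exons` pieces of >= 30 bases
  if (exons > 1L) {
    cuts <- sort(sample(seq(30L, cds_len - 30L), exons - 1L))
    piece_bounds <- cbind(start = c(1L, cuts + 1L), end = c(cuts, cds_len))
  } else {
    piece_bounds <- cbind(start = 1L, end = cds_len)
  }
  utr5 <- sample(50:150, 1L)
  utr3 <- sample(50:150, 1L)
  intron_len <- if (exons > 1L) sample(60:200, exons - 1L, replace = TRUE)
                else integer(0)
  seq_parts <- character(0)
  exon_iv <- NULL
  cds_iv <- NULL
  cursor <- 0L
  seq_parts <- c(seq_parts, random_dna(utr5))
  cursor <- cursor + utr5
  for (i in seq_len(nrow(piece_bounds))) {
    p_start <- cursor + 1L
    p_seq <- substr(cds_seq, piece_bounds[i, "start"], piece_bounds[i, "end"])
    seq_parts <- c(seq_parts, p_seq)
    cursor <- cursor + nchar(p_seq)
    cds_iv <- rbind(cds_iv, c(start = p_start, end = cursor))
    if (i < nrow(piece_bounds)) {
      intr <- paste0("GT", random_dna(intron_len[i] - 4L), "AG")
      seq_parts <- c(seq_parts, intr)
      exon_end <- p_start - 1L + nchar(p_seq)
      cursor <- cursor + nchar(intr)
    }
  }
  seq_parts <- c(seq_parts, random_dna(utr3))
  seq <- paste(seq_parts, collapse = "")
  # exons: utr5+first CDS piece, internal pieces, last piece+utr3
  ex <- cds_iv
  ex[1, "start"] <- 1L
  ex[nrow(ex), "end"] <- nchar(seq)
  layout <- list(gene_id = gene_id, seq = seq, exons = ex, cds = cds_iv)
  layout
}

#' Write a synthetic reference to FASTA and GFF3
#'
#' @param annotation A `gene_annotation` (e.g. from [generate_reference()]).
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_reference <- function(annotation, fasta_path, gff_path) {
  Biostrings::writeXStringSet(annotation$reference, fasta_path)
  rows <- list()
  for (g in annotation$genes) {
    mrna_id <- paste0(g$gene_id, ".t1")
    # CDS phase: bases to skip to reach the next codon start, in
    # transcription order
    w <- g$cds$end - g$cds$start + 1L
    off <- if (g$strand == "+") {
      cumsum(c(0L, w[-length(w)]))
    } else {
      rev(cumsum(c(0L, rev(w)[-length(w)])))
    }
    phase <- (3L - off %% 3L) %% 3L
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = g$contig,
      start = c(g$start, g$start, g$exons$start, g$cds$start),
      end = c(g$end, g$end, g$exons$end, g$cds$end),
      strand = g$strand,
      type = c("gene", "mRNA", rep("exon", nrow(g$exons)),
               rep("CDS", nrow(g$cds))),
      phase = c(rep(NA_integer_, 2L + nrow(g$exons)), phase),
      ID = c(g$gene_id, mrna_id, rep(NA, nrow(g$exons) + nrow(g$cds))),
      Parent = c(NA, g$gene_id, rep(mrna_id, nrow(g$exons) + nrow(g$cds))),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$Parent <- S4Vectors::splitAsList(
    df$Parent[!is.na(df$Parent)],
    factor(seq_along(gr)[!is.na(df$Parent)], levels = seq_along(gr)))
  S4Vectors::mcols(gr)$source <- "mutmapr"
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(list(fasta = fasta_path, gff = gff_path))
}

# --- variant drawing helpers -------------------------------------------------

draw_snvs <- function(n, contig, reference, titv, lo = 1L, hi = NULL) {
  if (n <= 0L) return(NULL)
  refseq <- reference[[contig]]
  if (is.null(hi)) hi <- length(refseq)
  pos <- sample(lo:hi, min(n, hi - lo + 1L))
  ref <- as.character(Biostrings::extractAt(
    refseq, IRanges::IRanges(pos, pos)))
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  p_ti <- titv / (titv + 1)
  is_ti <- stats::runif(length(pos)) < p_ti
  alt <- character(length(pos))
  alt[is_ti] <- transition_of[ref[is_ti]]
  tv_choices <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
  for (i in which(!is_ti)) alt[i] <- sample(tv_choices[[ref[i]]], 1L)
  tibble::tibble(contig = contig, pos = as.integer(pos), kind = "snp",
                 ref = ref, alt = alt, size = 0L, sv_end = NA_integer_)
}

draw_indels <- function(n, contig, reference, annotation, config,
                        lo = 1L, hi = NULL) {
  if (n <= 0L) return(NULL)
  refseq <- reference[[contig]]
  if (is.null(hi)) hi <- length(refseq)
  hi <- min(hi, length(refseq) - 10L)
  cds <- annotation$index$cds
  cds_c <- cds[GenomicRanges::seqnames(cds) == contig]
  # oversample proposals; CDS placements survive with configured probability
  prop <- sample(lo:hi, min(3L * n + 20L, hi - lo + 1L))
  in_cds <- rep(FALSE, length(prop))
  if (length(cds_c)) {
    ov <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(contig, IRanges::IRanges(prop, prop)), cds_c)
    in_cds[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  keep <- !in_cds | stats::runif(length(prop)) < config$cds_indel_acceptance
  prop <- prop[keep][seq_len(min(n, sum(keep)))]
  in_cds <- in_cds[keep][seq_len(length(prop))]
  if (!length(prop)) return(NULL)
  sizes <- integer(length(prop))
  for (i in seq_along(prop)) {
    if (in_cds[i] && stats::runif(1) < config$cds_inframe_enrichment) {
      sizes[i] <- sample(c(3L, 6L), 1L, prob = c(0.8, 0.2))
    } else {
      sizes[i] <- sample(c(1L, 2L, 3L, 4L, 5L, 6L), 1L,
                         prob = c(0.22, 0.13, 0.08, 0.35, 0.12, 0.10))
    }
  }
  is_del <- stats::runif(length(prop)) < 0.5
  rows <- vector("list", length(prop))
  for (i in seq_along(prop)) {
    p <- prop[i]; s <- sizes[i]
    if (is_del[i]) {
      del_seq <- as.character(Biostrings::subseq(refseq, p, p + s - 1L))
      rows[[i]] <- tibble::tibble(contig = contig, pos = as.integer(p),
                                  kind = "indel", ref = del_seq, alt = "",
                                  size = -s, sv_end = NA_integer_)
    } else {
      ins <- if (s == 4L && stats::runif(1) < 0.3) {
        sample(c("TACC", "TAGG"), 1L)
      } else {
        random_dna(s)
      }
      rows[[i]] <- tibble::tibble(contig = contig, pos = as.integer(p),
                                  kind = "indel", ref = "", alt = ins,
                                  size = s, sv_end = NA_integer_)
    }
  }
  dplyr::bind_rows(rows)
}

draw_variant_set <- function(n_snp, n_indel, contig, annotation, config,
                             lo = 1L, hi = NULL) {
  dplyr::bind_rows(
    draw_snvs(n_snp, contig, annotation$reference, config$titv_ratio, lo, hi),
    draw_indels(n_indel, contig, annotation$reference, annotation, config,
                lo, hi))
}

# --- causative planting ------------------------------------------------------

plant_causative <- function(annotation, entry, config) {
  g <- annotation$summary
  inside <- g$valid & g$contig == entry$contig &
    g$start >= entry$lo & g$end <= entry$hi
  if (!any(inside)) {
    stop("causative interval ", entry$contig, ":", entry$lo, "-", entry$hi,
         " contains no complete gene", call. = FALSE)
  }
  gene_id <- sample(g$gene_id[inside], 1L)
  gene <- annotation$genes[[gene_id]]
  map <- coding_map(gene)
  v <- switch(
    entry$category,
    nonsense = plant_nonsense(gene, map, annotation$reference),
    cds_frameshift = plant_frameshift(gene, map, annotation$reference),
    splice_site = plant_splice(gene, annotation$reference),
    sv_gene_deletion = plant_sv_deletion(gene),
    stop("unsupported planted category: ", entry$category, call. = FALSE))
  v$contig <- gene$contig
  list(record = v, gene_id = gene_id)
}

plant_nonsense <- function(gene, map, reference) {
  n_cod <- gene$protein_length
  candidates <- list()
  for (ci in sample(seq(5L, n_cod - 5L))) {
    codon <- substr(gene$cds_seq, 3L * ci - 2L, 3L * ci)
    for (stop_c in STOP_CODONS) {
      diffs <- which(strsplit(codon, "")[[1]] != strsplit(stop_c, "")[[1]])
      if (length(diffs) == 1L) {
        cpos <- 3L * (ci - 1L) + diffs
        gpos <- map[cpos]
        tx_alt <- substr(stop_c, diffs, diffs)
        alt <- if (gene$strand == "+") tx_alt else complement_bases(tx_alt)
        ref <- as.character(Biostrings::subseq(reference[[gene$contig]],
                                               gpos, gpos))
        if (ref == alt) next
        return(tibble::tibble(pos = gpos, kind = "snp", ref = ref, alt = alt,
                              size = 0L, sv_end = NA_integer_))
      }
    }
  }
  stop("no nonsense-mutable codon found in ", gene$gene_id, call. = FALSE)
}

plant_frameshift <- function(gene, map, reference) {
  # 1-base deletion well inside a CDS piece
  mid <- map[sample(seq(10L, length(map) - 10L), 1L)]
  ref <- as.character(Biostrings::subseq(reference[[gene$contig]], mid, mid))
  tibble::tibble(pos = as.integer(mid), kind = "indel", ref = ref, alt = "",
                 size = -1L, sv_end = NA_integer_)
}

plant_splice <- function(gene, reference) {
  if (!nrow(gene$introns)) stop("gene has no intron for a splice lesion",
                                call. = FALSE)
  i <- sample(seq_len(nrow(gene$introns)), 1L)
  gpos <- gene$introns$start[i]  # donor +1 position
  ref <- as.character(Biostrings::subseq(reference[[gene$contig]], gpos, gpos))
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  tibble::tibble(pos = as.integer(gpos), kind = "snp", ref = ref, alt = alt,
                 size = 0L, sv_end = NA_integer_)
}

plant_sv_deletion <- function(gene) {
  lo <- max(1L, gene$start - 10L)
  hi <- gene$end + 10L
  tibble::tibble(pos = as.integer(lo), kind = "sv_del", ref = "", alt = "",
                 size = -(hi - lo + 1L), sv_end = as.integer(hi))
}

# --- cohort assembly ---------------------------------------------------------

#' Generate a strain cohort over a synthetic reference
#'
#' Draws shared haplotype-block variant pools, per-strain private variants,
#' and reference-background variants present in every strain; plants one
#' severe causative mutation per focal strain inside its marker interval
#' (absent from all other strains); and returns the combined variant table
#' together with a truth table for benchmarking. Each strain carries a
#' number of haplotype blocks proportional to its configured divergence, so
#' per-strain SNP counts track the configured densities while variation
#' remains block-structured and shared.
#'
#' @param annotation Reference from [generate_reference()].
#' @param config The same [cohort_config()].
#' @param seed Integer seed (per-strain substreams are derived from it, so
#'   one strain's variants do not depend on the cohort size).
#' @return A list with `records` (cohort `variant_records`, key-encoded and
#'   left-normalized), `truth` (list: `causative`, `private`, `background`,
#'   `blocks`), and `plan` (the realized causative plan).
#' @export
generate_cohort <- function(annotation, config, seed = 1L) {
  set.seed(seed)
  strains <- config$strains
  contigs <- names(annotation$reference)
  contig_len <- stats::setNames(Biostrings::width(annotation$reference),
                                contigs)
  genome_kb <- sum(contig_len) / 1000
  max_d <- max(config$divergence, 1e-9)

  plan <- config$causative_plan
  if (is.null(plan)) plan <- auto_causative_plan(annotation, config)

  # shared haplotype-block pools
  pool <- list()
  blocks <- NULL
  if (config$n_haplotype_blocks > 0L && config$shared_fraction > 0) {
    pool_density <- config$shared_fraction * max_d  # SNPs/kb in the pool
    for (ctg in contigs) {
      bounds <- round(seq(1, contig_len[ctg] + 1,
                          length.out = config$n_haplotype_blocks + 1L))
      for (b in seq_len(config$n_haplotype_blocks)) {
        lo <- bounds[b]; hi <- bounds[b + 1L] - 1L
        kb <- (hi - lo + 1) / 1000
        n_snp <- stats::rpois(1L, pool_density * kb)
        n_ind <- stats::rpois(1L, pool_density * kb * config$indel_fraction)
        pool[[length(pool) + 1L]] <- list(
          contig = ctg, lo = lo, hi = hi,
          variants = draw_variant_set(n_snp, n_ind, ctg, annotation, config,
                                      lo, hi))
        blocks <- dplyr::bind_rows(blocks,
                                   tibble::tibble(contig = ctg, start = lo,
                                                  end = hi))
      }
    }
  }
  n_blocks_total <- length(pool)

  # reference-background variants: present in every strain
  bg <- NULL
  if (config$n_reference_background_variants > 0L) {
    per_contig <- table(sample(contigs,
                               config$n_reference_background_variants,
                               replace = TRUE,
                               prob = contig_len / sum(contig_len)))
    for (ctg in names(per_contig)) {
      n <- per_contig[[ctg]]
      n_ind <- stats::rbinom(1L, n, config$indel_fraction /
                               (1 + config$indel_fraction))
      bg <- dplyr::bind_rows(bg, draw_variant_set(n - n_ind, n_ind, ctg,
                                                  annotation, config))
    }
  }

  # per-strain assembly
  per_strain <- vector("list", length(strains))
  names(per_strain) <- strains
  truth_causative <- NULL
  planted_keys <- character(0)
  planted <- list()
  for (entry in plan) {
    p <- plant_causative(annotation, entry, config)
    rec <- p$record
    key <- encode_variant_id(rec$contig, rec$pos,
                             if (rec$kind == "snp") rec$alt else NULL)
    planted[[entry$strain]] <- c(planted[[entry$strain]],
                                 list(list(record = rec, key = key)))
    planted_keys <- c(planted_keys, key)
    truth_causative <- dplyr::bind_rows(truth_causative, tibble::tibble(
      strain = entry$strain, gene_id = p$gene_id, key = key,
      category = entry$category, contig = rec$contig, pos = rec$pos))
  }

  for (si in seq_along(strains)) {
    s <- strains[si]
    d <- config$divergence[si]
    set.seed((seed + si * 10007L) %% 2147483629L)
    parts <- list()
    if (n_blocks_total > 0L) {
      n_carry <- round(config$n_haplotype_blocks * d / max_d) *
        (n_blocks_total %/% config$n_haplotype_blocks)
      n_carry <- min(n_carry, n_blocks_total)
      if (n_carry > 0L) {
        carried <- sample.int(n_blocks_total, n_carry)
        parts <- c(parts, lapply(pool[carried], `[[`, "variants"))
      }
      priv_d <- (1 - config$shared_fraction) * d
    } else {
      priv_d <- d
    }
    for (ctg in contigs) {
      kb <- contig_len[ctg] / 1000
      n_snp <- stats::rpois(1L, priv_d * kb)
      n_ind <- stats::rpois(1L, priv_d * kb * config$indel_fraction)
      parts <- c(parts, list(draw_variant_set(n_snp, n_ind, ctg, annotation,
                                              config, 1L, contig_len[ctg])))
    }
    parts <- c(parts, list(bg))
    x <- dplyr::bind_rows(parts[!vapply(parts, is.null, TRUE)])
    if (nrow(x)) x$strain <- s
    per_strain[[s]] <- x
  }

  all_records <- dplyr::bind_rows(per_strain)
  n <- nrow(all_records)
  if (n > 0L) {
    records <- variant_records(all_records$strain, all_records$contig,
                               all_records$pos, all_records$kind,
                               all_records$ref, all_records$alt,
                               all_records$size, all_records$sv_end,
                               cq = sample(60:255, n, replace = TRUE),
                               dp = 15L + stats::rpois(n, 35),
                               mq = sample(45:60, n, replace = TRUE),
                               multi = FALSE)
  } else {
    records <- variant_records(character(0), character(0), integer(0),
                               character(0))
  }
  records <- left_normalize_indels(records, annotation$reference)
  records <- add_variant_keys(records)
  # the planted causative must be private: drop colliding background keys
  # everywhere, then add the planted record to its focal strain only
  records <- records[!records$key %in% planted_keys, , drop = FALSE]
  for (s in names(planted)) {
    for (p in planted[[s]]) {
      rec <- p$record
      prow <- variant_records(s, rec$contig, rec$pos, rec$kind, rec$ref,
                              rec$alt, rec$size, rec$sv_end,
                              cq = 200L, dp = 60L, mq = 60L, multi = FALSE)
      prow <- add_variant_keys(prow)
      records <- dplyr::bind_rows(records, prow)
    }
  }
  records <- records[!duplicated(records[, c("strain", "key")]), , drop = FALSE]
  records <- records[order(records$strain, records$contig, records$pos), ,
                     drop = FALSE]

  # truth from the assembled cohort (set arithmetic, independent of the
  # occurrence-matrix implementation)
  carriers <- split(records$strain, records$key)
  occ <- vapply(carriers, function(x) length(unique(x)), 1L)
  uniq_keys <- names(occ)[occ == 1L]
  all_keys <- names(occ)[occ == length(strains)]
  private <- records[records$key %in% uniq_keys, c("strain", "key")]
  truth <- list(
    causative = truth_causative,
    private = tibble::as_tibble(private),
    background = all_keys,
    blocks = blocks)
  list(records = records, truth = truth, plan = plan)
}

auto_causative_plan <- function(annotation, config) {
  focal <- config$strains[ceiling(config$n_strains / 2)]
  g <- annotation$summary[annotation$summary$valid, ]
  if (!nrow(g)) stop("no valid genes to plant a causative mutation in",
                     call. = FALSE)
  anchor <- g[sample.int(nrow(g), 1L), ]
  len <- Biostrings::width(annotation$reference[anchor$contig])
  lo <- max(1L, anchor$start - config$interval_length %/% 2L)
  hi <- min(len, lo + config$interval_length - 1L)
  lo <- max(1L, hi - config$interval_length + 1L)
  list(list(strain = focal, contig = anchor$contig, lo = as.integer(lo),
            hi = as.integer(hi),
            category = sample(c("nonsense", "cds_frameshift"), 1L)))
}

#' Write a cohort truth table
#'
#' One TSV with a `fact` column distinguishing causative plantings, private
#' keys, reference-background keys, and haplotype-block boundaries.
#'
#' @param truth Truth list from [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  rows <- list()
  if (!is.null(truth$causative) && nrow(truth$causative)) {
    x <- truth$causative
    rows[[1]] <- tibble::tibble(fact = "causative", strain = x$strain,
                                key = x$key, gene_id = x$gene_id,
                                category = x$category, contig = x$contig,
                                start = x$pos, end = x$pos)
  }
  if (!is.null(truth$private) && nrow(truth$private)) {
    rows[[2]] <- tibble::tibble(fact = "private", strain = truth$private$strain,
                                key = truth$private$key, gene_id = NA,
                                category = NA, contig = NA,
                                start = NA_integer_, end = NA_integer_)
  }
  if (length(truth$background)) {
    rows[[3]] <- tibble::tibble(fact = "reference_background", strain = NA,
                                key = truth$background, gene_id = NA,
                                category = NA, contig = NA,
                                start = NA_integer_, end = NA_integer_)
  }
  if (!is.null(truth$blocks) && nrow(truth$blocks)) {
    rows[[4]] <- tibble::tibble(fact = "block", strain = NA, key = NA,
                                gene_id = NA, category = NA,
                                contig = truth$blocks$contig,
                                start = truth$blocks$start,
                                end = truth$blocks$end)
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || !nrow(out)) {
    out <- tibble::tibble(fact = character(0), strain = character(0),
                          key = character(0), gene_id = character(0),
                          category = character(0), contig = character(0),
                          start = integer(0), end = integer(0))
  }
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' Read a truth table written by [write_truth_table()]
#' @param path File path.
#' @return Truth list with `causative`, `private`, `background`, `blocks`.
#' @export
read_truth_table <- function(path) {
  x <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                       col_types = readr::cols(.default = "c",
                                               start = "i", end = "i"))
  list(
    causative = {
      c0 <- x[x$fact == "causative",
              c("strain", "gene_id", "key", "category", "contig", "start")]
      names(c0)[names(c0) == "start"] <- "pos"
      tibble::as_tibble(c0)
    },
    private = tibble::as_tibble(x[x$fact == "private", c("strain", "key")]),
    background = x$key[x$fact == "reference_background"],
    blocks = tibble::as_tibble(
      x[x$fact == "block", c("contig", "start", "end")]))
}

#' Simulate a cohort and write all standard files
#'
#' Convenience wrapper: generates reference and cohort, then writes FASTA,
#' GFF3, one VCF per strain, a marker-interval table covering the causative
#' plan, and the truth table into `dir`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return List with the annotation, cohort, and file paths.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            dir = tempfile("cohort")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  annotation <- generate_reference(config, seed)
  cohort <- generate_cohort(annotation, config, seed)
  paths <- list(fasta = file.path(dir, "reference.fa"),
                gff = file.path(dir, "genes.gff3"),
                truth = file.path(dir, "truth.tsv"),
                markers = file.path(dir, "markers.tsv"),
                vcf = character(0))
  write_reference(annotation, paths$fasta, paths$gff)
  write_truth_table(cohort$truth, paths$truth)
  mk <- dplyr::bind_rows(lapply(cohort$plan, function(e) {
    tibble::tibble(strain = e$strain, trait = "planted", contig = e$contig,
                   left = as.character(e$lo), right = as.character(e$hi))
  }))
  readr::write_tsv(mk, paths$markers, na = ".")
  for (s in config$strains) {
    p <- file.path(dir, paste0(s, ".vcf"))
    write_variants(cohort$records[cohort$records$strain == s, , drop = FALSE],
                   p, format = "vcf", reference = annotation$reference)
    paths$vcf <- c(paths$vcf, stats::setNames(p, s))
  }
  list(annotation = annotation, cohort = cohort, paths = paths, dir = dir)
}
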