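# Test helpers: toy annotation builders and independent brute-force oracles.
# Oracles deliberately avoid the package's GRanges-based classification path:
# they scan intervals and rebuild mutant genomes with plain string operations.

# Build an annotation by writing FASTA + GFF3 to temp files and reading them
# back, so the readers are exercised on every toy fixture.
# genes: list of lists with gene_id, contig, strand, exons (2-col matrix),
# cds (2-col matrix).
make_annotation <- function(seqs, genes) {
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), fa)
  lines <- c("##gff-version 3")
  for (g in genes) {
    span <- range(c(g$exons, g$cds))
    mrna <- paste0(g$gene_id, ".t1")
    gffrow <- function(type, s, e, attrs) {
      paste(g$contig, "test", type, s, e, ".", g$strand, ".", attrs,
            sep = "\t")
    }
    lines <- c(lines,
               gffrow("gene", span[1], span[2], paste0("ID=", g$gene_id)),
               gffrow("mRNA", span[1], span[2],
                      paste0("ID=", mrna, ";Parent=", g$gene_id)))
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines, gffrow("exon", g$exons[i, 1], g$exons[i, 2],
                               paste0("Parent=", mrna)))
    }
    for (i in seq_len(nrow(g$cds))) {
      lines <- c(lines, gffrow("CDS", g$cds[i, 1], g$cds[i, 2],
                               paste0("Parent=", mrna)))
    }
  }
  writeLines(lines, gff)
  read_gene_models(gff, fa)
}

# A single-contig toy locus: one gene with UTRs, two CDS exons and one
# GT..AG intron, placed inside intergenic flank. Returns the annotation plus
# the layout coordinates for hand-derived expectations.
toy_locus <- function(strand = "+", cds_codons = "ATGTGGGGTAAACCCCATTAA") {
  flank <- 50L
  utr <- 10L
  intron <- 20L
  stopifnot(nchar(cds_codons) %% 3 == 0)
  cut <- 9L  # split CDS after 9 bases (codon boundary not required)
  cds1 <- substr(cds_codons, 1, cut)
  cds2 <- substr(cds_codons, cut + 1, nchar(cds_codons))
  set.seed(99)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  tx <- paste0(rnd(utr), cds1, paste0("GT", rnd(intron - 4L), "AG"),
               cds2, rnd(utr))
  seg <- if (strand == "+") tx else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  seq <- paste0(rnd(flank), seg, rnd(flank))
  L <- nchar(tx)
  # local (transcript-layout) coordinates
  l_exon1 <- c(1L, utr + nchar(cds1))
  l_intron <- c(utr + nchar(cds1) + 1L, utr + nchar(cds1) + intron)
  l_exon2 <- c(l_intron[2] + 1L, L)
  l_cds1 <- c(utr + 1L, utr + nchar(cds1))
  l_cds2 <- c(l_intron[2] + 1L, l_intron[2] + nchar(cds2))
  tolocal <- function(iv) {
    if (strand == "+") flank + iv
    else c(flank + L - iv[2] + 1L, flank + L - iv[1] + 1L)
  }
  exons <- rbind(tolocal(l_exon1), tolocal(l_exon2))
  cds <- rbind(tolocal(l_cds1), tolocal(l_cds2))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  ann <- make_annotation(
    list(c1 = seq),
    list(list(gene_id = "toy1", contig = "c1", strand = strand,
              exons = exons, cds = cds)))
  # genomic position of coding coordinate i (1-based along the transcript)
  coding_to_genomic <- function(i) {
    if (strand == "+") {
      if (i <= nchar(cds1)) cds[1, 1] + i - 1L
      else cds[2, 1] + (i - nchar(cds1)) - 1L
    } else {
      if (i <= nchar(cds1)) cds[2, 2] - i + 1L
      else cds[1, 2] - (i - nchar(cds1)) + 1L
    }
  }
  list(ann = ann, seq = seq, strand = strand, exons = exons, cds = cds,
       cds_seq = cds_codons, coding_to_genomic = coding_to_genomic,
       flank = flank, contig = "c1")
}

# Independent SNP-effect oracle: mutate the genome string, re-extract the
# CDS from both genomes, translate, and compare proteins; region membership
# by linear scan over the gene's intervals.
oracle_classify_snp <- function(locus, pos, alt) {
  g <- locus$ann$genes[[1]]
  in_iv <- function(iv) any(pos >= iv$start & pos <= iv$end)
  cds_df <- g$cds
  if (in_iv(cds_df)) {
    mutate <- function(s) { substr(s, pos, pos) <- alt; s }
    extract_cds <- function(s) {
      p <- paste(substring(s, cds_df$start, cds_df$end), collapse = "")
      if (g$strand == "-") p <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(p)))
      p
    }
    wt <- extract_cds(locus$seq)
    mut <- extract_cds(mutate(locus$seq))
    tr <- function(s) {
      n <- nchar(s) %/% 3
      vapply(seq_len(n), function(i) {
        unname(Biostrings::GENETIC_CODE[substr(s, 3 * i - 2, 3 * i)])
      }, "")
    }
    p_wt <- tr(wt); p_mut <- tr(mut)
    diff <- which(p_wt != p_mut)
    if (!length(diff)) return(list(category = "synonymous"))
    if (p_mut[diff[1]] == "*") {
      return(list(category = "nonsense", aa_pos = diff[1]))
    }
    return(list(category = "nonsynonymous", aa_pos = diff[1]))
  }
  splice <- do.call(rbind, lapply(seq_len(nrow(g$introns)), function(i) {
    rbind(c(g$introns$start[i], g$introns$start[i] + 1L),
          c(g$introns$end[i] - 1L, g$introns$end[i]))
  }))
  if (!is.null(splice) &&
      any(pos >= splice[, 1] & pos <= splice[, 2])) {
    return(list(category = "splice_site"))
  }
  if (in_iv(g$utr5)) return(list(category = "utr5"))
  if (in_iv(g$utr3)) return(list(category = "utr3"))
  if (in_iv(g$introns)) return(list(category = "intron"))
  list(category = "noncoding_intergenic")
}

# Brute-force filter oracle: evaluates each rule independently per record.
oracle_filter <- function(records, policy) {
  n <- nrow(records)
  fail_quality <- records$dp < policy$min_depth |
    records$cq < policy$min_consensus_quality |
    records$mq < policy$min_map_quality
  fail_prox <- rep(FALSE, n)
  fail_dense <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (fail_quality[i] || records$kind[i] != "snp") next
    same <- which(records$strain == records$strain[i] &
                    records$contig == records$contig[i] & !fail_quality)
    indels <- same[records$kind[same] != "snp"]
    for (j in indels) {
      lo <- records$pos[j]
      hi <- if (records$kind[j] == "sv_del") records$sv_end[j]
            else if (records$size[j] < 0) records$pos[j] - records$size[j] - 1L
            else records$pos[j]
      if (records$pos[i] >= lo - policy$indel_proximity_window &&
          records$pos[i] <= hi + policy$indel_proximity_window) {
        fail_prox[i] <- TRUE
      }
    }
  }
  for (i in seq_len(n)) {
    if (fail_quality[i] || fail_prox[i] || records$kind[i] != "snp") next
    peers <- which(records$strain == records$strain[i] &
                     records$contig == records$contig[i] &
                     records$kind == "snp" & !fail_quality & !fail_prox)
    # any window of w bases containing this SNP and > N peers
    w <- policy$indel_proximity_window
    for (start in (records$pos[i] - w + 1L):records$pos[i]) {
      cnt <- sum(records$pos[peers] >= start &
                   records$pos[peers] <= start + w - 1L)
      if (cnt > policy$max_snps_in_window) { fail_dense[i] <- TRUE; break }
    }
  }
  !(fail_quality | fail_prox | fail_dense)
}

# random valid variant keys for round-trip properties
random_keys <- function(n, seed = 1) {
  set.seed(seed)
  contig <- sample(c("1", "7", "ctg1", "super_2"), n, TRUE)
  pos <- sample.int(1e7, n, TRUE)
  alt <- ifelse(stats::runif(n) < 0.5,
                sample(c("A", "C", "G", "T"), n, TRUE), NA_character_)
  tibble::tibble(contig = contig, pos = pos, alt_base = alt)
}

extdata <- function(f) system.file("extdata", f, package = "mutmapr")

read_fixture <- function(f) {
  readr::read_tsv(extdata(f), comment = "#", show_col_types = FALSE)
}

small_cfg <- function(...) {
  cohort_config(n_genes = 40L, contig_length = 200000L, n_strains = 3L,
                divergence = c(0.2, 0.6, 1.2), ...)
}
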