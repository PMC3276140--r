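# cds_codons = ATG TGG GGT AAA CCC CAT TAA -> M W G K P H *
snp_at_coding <- function(loc, coding_pos, tx_alt) {
  gpos <- loc$coding_to_genomic(coding_pos)
  alt <- if (loc$strand == "+") tx_alt else chartr("ACGT", "TGCA", tx_alt)
  ref <- substr(loc$seq, gpos, gpos)
  variant_records("s1", loc$contig, gpos, "snp", ref, alt)
}

test_that("codon-level SNP classes are called on both strands", {
  for (strand in c("+", "-")) {
    loc <- toy_locus(strand)
    # TGG -> TAG: transcript coding position 5 (codon 2, offset 2) to A
    eff <- classify_variants(snp_at_coding(loc, 5L, "A"), loc$ann)
    expect_equal(eff$category, "nonsense")
    expect_equal(eff$aa_pos, 2L)
    expect_equal(eff$ref_aa, "W")
    expect_equal(eff$alt_aa, "*")
    # GGT -> GGC: coding position 9 (codon 3 wobble) to C
    eff <- classify_variants(snp_at_coding(loc, 9L, "C"), loc$ann)
    expect_equal(eff$category, "synonymous")
    # AAA -> GAA: coding position 10 (codon 4) to G
    eff <- classify_variants(snp_at_coding(loc, 10L, "G"), loc$ann)
    expect_equal(eff$category, "nonsynonymous")
    expect_equal(eff$aa_pos, 4L)
  }
})

test_that("non-coding SNPs fall through the positional precedence", {
  loc <- toy_locus("+")
  g <- loc$ann$genes[["toy1"]]
  mk <- function(pos, alt = NULL) {
    ref <- substr(loc$seq, pos, pos)
    if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    variant_records("s1", "c1", pos, "snp", ref, alt)
  }
  expect_equal(classify_variants(mk(5L), loc$ann)$category,
               "noncoding_intergenic")
  expect_equal(classify_variants(mk(g$utr5$start + 2L), loc$ann)$category,
               "utr5")
  expect_equal(classify_variants(mk(g$utr3$end - 2L), loc$ann)$category,
               "utr3")
  expect_equal(classify_variants(mk(g$introns$start), loc$ann)$category,
               "splice_site")
  expect_equal(classify_variants(mk(g$introns$end - 1L), loc$ann)$category,
               "splice_site")
  expect_equal(classify_variants(mk(g$introns$start + 5L), loc$ann)$category,
               "intron")
})

test_that("a reference-allele mismatch raises a data-integrity error", {
  loc <- toy_locus("+")
  pos <- 5L
  ref <- substr(loc$seq, pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  alt <- setdiff(c("A", "C", "G", "T"), c(ref, wrong))[1]
  r <- variant_records("strainX", "c1", pos, "snp", wrong, alt)
  expect_error(classify_variants(r, loc$ann), "strainX.*c1:5")
})

test_that("indels classify by frame effect and positional precedence", {
  loc <- toy_locus("+")
  g <- loc$ann$genes[["toy1"]]
  cds_pos <- loc$coding_to_genomic(7L)
  mk_del <- function(pos, size) {
    variant_records("s1", "c1", pos, "indel",
                    ref = substr(loc$seq, pos, pos + size - 1L), alt = "",
                    size = -size)
  }
  expect_equal(classify_variants(mk_del(cds_pos, 1L), loc$ann)$category,
               "cds_frameshift")
  expect_equal(classify_variants(mk_del(cds_pos, 3L), loc$ann)$category,
               "cds_inframe")
  # an 8-base deletion breaks the frame (placed inside the 12-base second
  # CDS piece so it stays clear of the splice windows)
  expect_equal(
    classify_variants(mk_del(loc$coding_to_genomic(10L), 8L),
                      loc$ann)$category,
    "cds_frameshift")
  ins <- variant_records("s1", "c1", cds_pos, "indel", ref = "", alt = "GCT",
                         size = 3L)
  expect_equal(classify_variants(ins, loc$ann)$category, "cds_inframe")
  # intronic deletion away from junctions
  intr <- mk_del(g$introns$start + 6L, 2L)
  expect_equal(classify_variants(intr, loc$ann)$category, "intron")
  # deletion covering a donor site is a splice lesion regardless of frame
  spl <- mk_del(g$introns$start - 1L, 3L)
  expect_equal(classify_variants(spl, loc$ann)$category, "splice_site")
})

test_that("a structural deletion swallowing a CDS exon is a gene deletion", {
  loc <- toy_locus("+")
  g <- loc$ann$genes[["toy1"]]
  sv <- variant_records("s1", "c1", g$start - 5L, "sv_del",
                        sv_end = g$end + 5L,
                        size = -(g$end - g$start + 11L))
  eff <- classify_variants(sv, loc$ann)
  expect_equal(eff$category, "sv_gene_deletion")
  expect_equal(eff$gene_id, "toy1")
  # an SV clipping only intergenic sequence is not
  sv2 <- variant_records("s1", "c1", 2L, "sv_del", sv_end = 20L, size = -19L)
  expect_equal(classify_variants(sv2, loc$ann)$category,
               "noncoding_intergenic")
})

test_that("SNP classification agrees with the mutant-translation oracle on random variants", {
  set.seed(202)
  n_checked <- 0
  for (strand in c("+", "-")) {
    loc <- toy_locus(strand, cds_codons = paste0(
      "ATG", paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                  c("TAA", "TAG", "TGA")), 40, TRUE),
                   collapse = ""), "TAA"))
    L <- nchar(loc$seq)
    for (i in 1:150) {
      pos <- sample.int(L, 1)
      ref <- substr(loc$seq, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      r <- variant_records("s", "c1", pos, "snp", ref, alt)
      got <- classify_variants(r, loc$ann)
      want <- oracle_classify_snp(loc, pos, alt)
      expect_equal(got$category, want$category,
                   label = sprintf("strand %s pos %d %s>%s: %s", strand, pos,
                                   ref, alt, got$category))
      if (!is.null(want$aa_pos) && got$category != "synonymous") {
        expect_equal(got$aa_pos, want$aa_pos)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 300)
})

test_that("strand symmetry: mirrored locus gives the same category and residue", {
  plus <- toy_locus("+")
  minus <- toy_locus("-")
  set.seed(7)
  for (cpos in sample(3:nchar(plus$cds_seq), 15)) {
    tx_alt <- sample(setdiff(c("A", "C", "G", "T"),
                             substr(plus$cds_seq, cpos, cpos)), 1)
    e1 <- classify_variants(snp_at_coding(plus, cpos, tx_alt), plus$ann)
    e2 <- classify_variants(snp_at_coding(minus, cpos, tx_alt), minus$ann)
    expect_equal(e1$category, e2$category)
    expect_equal(e1$aa_pos, e2$aa_pos)
    expect_equal(e1$ref_aa, e2$ref_aa)
    expect_equal(e1$alt_aa, e2$alt_aa)
  }
})

test_that("premature-stop scanning matches a direct codon walk", {
  # 30-codon gene; engineer a -1 frameshift and compare against translating
  # the hand-built mutant CDS
  set.seed(55)
  for (strand in c("+", "-")) {
    loc <- toy_locus(strand, cds_codons = paste0(
      "ATG", paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                  c("TAA", "TAG", "TGA")), 28, TRUE),
                   collapse = ""), "TGA"))
    gene <- loc$ann$genes[["toy1"]]
    for (cpos in c(5L, 13L, 40L, 3L * gene$protein_length - 3L)) {
      gpos <- loc$coding_to_genomic(cpos)
      rec <- variant_records("s", "c1", gpos, "indel",
                             ref = substr(loc$seq, gpos, gpos), alt = "",
                             size = -1L)
      got <- scan_premature_stops(loc$ann, "toy1", rec)
      # oracle: drop coding position cpos from the transcript CDS
      mut <- paste0(substr(loc$cds_seq, 1, cpos - 1),
                    substr(loc$cds_seq, cpos + 1, nchar(loc$cds_seq)))
      n_cod <- nchar(mut) %/% 3
      aas <- vapply(seq_len(min(n_cod, gene$protein_length)), function(i) {
        unname(Biostrings::GENETIC_CODE[substr(mut, 3 * i - 2, 3 * i)])
      }, "")
      stops <- which(aas == "*")
      prem <- stops[stops < gene$protein_length]
      expect_equal(got$first_stop_aa,
                   if (length(prem)) prem[1] else NA_integer_)
      expect_equal(got$stop_count, length(stops))
    }
    # an in-frame GCT insertion introduces no stop
    gpos <- loc$coding_to_genomic(10L)
    ins_tx <- "GCT"
    ins <- if (strand == "+") ins_tx else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(ins_tx)))
    rec <- variant_records("s", "c1", gpos, "indel", ref = "", alt = ins,
                           size = 3L)
    got <- scan_premature_stops(loc$ann, "toy1", rec)
    expect_true(is.na(got$first_stop_aa))
  }
})

test_that("every record gets exactly one category and counts are conserved", {
  cfg <- cohort_config(n_genes = 40L, contig_length = 200000L,
                       n_strains = 3L, divergence = c(0.5, 1, 2),
                       n_reference_background_variants = 10L)
  ann <- generate_reference(cfg, seed = 5)
  coh <- generate_cohort(ann, cfg, seed = 5)
  eff <- classify_variants(coh$records, ann)
  expect_equal(nrow(eff), nrow(coh$records))
  expect_true(all(eff$category %in% c(
    "noncoding_intergenic", "utr5", "utr3", "intron", "splice_site",
    "synonymous", "nonsynonymous", "nonsense", "cds_frameshift",
    "cds_inframe", "sv_gene_deletion")))
  for (s in unique(eff$strain)) {
    sub <- eff[eff$strain == s, ]
    expect_equal(sum(table(sub$category)), nrow(sub))
  }
})
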