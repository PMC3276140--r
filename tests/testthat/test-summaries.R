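test_that("percentage columns reproduce from the printed category counts", {
  t3 <- read_fixture("strain_snp_categories.tsv")
  got <- snp_summary_from_counts(t3[, 1:9])
  # spot checks at printed precision
  r106 <- got[got$strain == 106, ]
  expect_equal(r106$pct_nc, 59.84)
  expect_equal(r106$pct_syn, 32.15)
  expect_equal(r106$pct_nonsyn, 9.62)
  r1363 <- got[got$strain == 1363, ]
  expect_equal(r1363$pct_nc, 48.59)
  expect_equal(r1363$pct_syn, 50.46)
  # all cells at the precision each printed value carries
  decimals <- function(x) {
    s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(x, scientific = FALSE)))
    nchar(s)
  }
  for (col in c("pct_nc", "pct_syn", "pct_nonsyn", "pct_nonsense")) {
    printed <- t3[[col]]
    for (i in seq_along(printed)) {
      expect_equal(round_half_up(got[[col]][i], decimals(printed[i])),
                   printed[i],
                   label = paste("strain", t3$strain[i], col))
    }
  }
})

test_that("a zero-SNP strain summarises to a zero row with a warning", {
  eff <- tibble::tibble(key = character(0), strain = character(0),
                        kind = character(0), category = character(0))
  expect_warning(z <- strain_snp_summary(eff), "zero")
  expect_equal(z$total, 0L)
  expect_equal(z$pct_nc, 0)
})

test_that("strain summaries conserve counts against the occurrence matrix", {
  cfg <- cohort_config(n_genes = 40L, contig_length = 200000L,
                       n_strains = 4L, divergence = c(0.5, 1, 1.5, 2))
  ann <- generate_reference(cfg, seed = 8)
  coh <- generate_cohort(ann, cfg, seed = 8)
  eff <- classify_variants(coh$records, ann)
  m <- build_occurrence_matrix(coh$records)
  tab <- dplyr::bind_rows(lapply(split(eff, eff$strain), strain_snp_summary))
  # per-strain category sums equal totals
  expect_equal(tab$nc + tab$synonymous + tab$nonsynonymous + tab$utr3 +
                 tab$utr5 + tab$intron + tab$nonsense, tab$total)
  # sum of per-strain totals equals occurrence-weighted key count
  spec <- occurrence_spectrum(m, kind = "snp")
  expect_equal(sum(tab$total), spectrum_totals(spec)$mapped)
  # indel identity: weighted indel spectrum equals summed indel totals
  itab <- dplyr::bind_rows(lapply(split(eff, eff$strain),
                                  strain_indel_summary))
  ispec <- occurrence_spectrum(m, kind = c("indel", "sv_del"))
  expect_equal(sum(itab$total), spectrum_totals(ispec)$mapped)
  expect_equal(itab$cds + itab$nc + itab$intron + itab$splice_site +
                 itab$other, itab$total)
})

test_that("indel size spectra count keys once or per carrier", {
  r <- variant_records(
    strain = c("a", "b", "c", "a"),
    contig = "1", pos = c(100, 100, 100, 300),
    kind = "indel",
    ref = c("TTTT", "TTTT", "TTTT", ""),
    alt = c("", "", "", "GG"),
    size = c(-4L, -4L, -4L, 2L))
  m <- build_occurrence_matrix(r)
  dist <- indel_size_spectrum(m, "distinct")
  expect_equal(dist$n[dist$size == 4], 1L)
  expect_equal(dist$n[dist$size == 2], 1L)
  mapped <- indel_size_spectrum(m, "mapped")
  expect_equal(mapped$n[mapped$size == 4], 3L)

  # counting oracle on a random fixture
  set.seed(17)
  n <- 150
  r2 <- variant_records(
    strain = sample(c("a", "b", "c"), n, TRUE), contig = "1",
    pos = sample.int(500, n, TRUE) * 10L, kind = "indel",
    ref = "", alt = "X", size = sample(c(1:6, -(1:6)), n, TRUE))
  r2$alt <- strrep("T", abs(r2$size)) ; r2$alt[r2$size < 0] <- ""
  r2$ref[r2$size < 0] <- strrep("A", abs(r2$size[r2$size < 0]))
  r2 <- r2[!duplicated(r2[, c("strain", "pos")]), ]
  m2 <- build_occurrence_matrix(r2)
  mapped2 <- indel_size_spectrum(m2, "mapped")
  oracle <- table(abs(r2$size))
  expect_equal(mapped2$n, as.integer(oracle), ignore_attr = TRUE)
})

test_that("coding fraction by size is a direct ratio and tracks 3n enrichment", {
  eff <- tibble::tibble(
    kind = "indel",
    size = c(rep(3L, 10), rep(2L, 5)),
    category = c(rep("cds_inframe", 4), rep("noncoding_intergenic", 6),
                 rep("noncoding_intergenic", 5)))
  cf <- coding_fraction_by_size(eff)
  expect_equal(cf$pct_cds[cf$size == 3], 40)
  expect_equal(cf$pct_cds[cf$size == 2], 0)

  # generator property: 3n indels are enriched in CDS relative to 2 and 4
  cfg <- cohort_config(n_genes = 150L, contig_length = 600000L,
                       n_strains = 4L, divergence = rep(8, 4),
                       indel_fraction = 0.5, n_haplotype_blocks = 0L,
                       n_reference_background_variants = 0L)
  ann <- generate_reference(cfg, seed = 23)
  coh <- generate_cohort(ann, cfg, seed = 23)
  eff2 <- classify_variants(coh$records, ann)
  cf2 <- coding_fraction_by_size(eff2)
  expect_gt(cf2$pct_cds[cf2$size == 3], cf2$pct_cds[cf2$size == 2])
  expect_gt(cf2$pct_cds[cf2$size == 3], cf2$pct_cds[cf2$size == 4])
})

test_that("window profiles match a brute-force interval count", {
  r <- variant_records(
    strain = "s", contig = "c",
    pos = c(500L, 800L, 1200L, 5400L, 5450L, 9900L),
    kind = c("snp", "snp", "snp", "snp", "indel", "snp"),
    ref = c("G", "G", "G", "G", "T", "G"),
    alt = c("A", "A", "A", "A", "", "A"),
    size = c(0L, 0L, 0L, 0L, -1L, 0L))
  prof <- window_density_profile(r, "c", 20000L, window = 2000L, step = 500L)
  for (i in seq_len(nrow(prof))) {
    expect_equal(prof$n_snps[i],
                 sum(r$pos[r$kind == "snp"] >= prof$start[i] &
                       r$pos[r$kind == "snp"] <= prof$end[i]))
    expect_equal(prof$n_indels[i],
                 sum(r$pos[r$kind != "snp"] >= prof$start[i] &
                       r$pos[r$kind != "snp"] <= prof$end[i]))
  }
  # disjoint binning conserves totals
  prof2 <- window_density_profile(r, "c", 20000L, window = 2000L,
                                  step = 2000L)
  expect_equal(sum(prof2$n_snps), sum(r$kind == "snp"))
  expect_equal(sum(prof2$n_indels), sum(r$kind != "snp"))
  # no variants -> all-zero profile
  empty <- window_density_profile(r[0, ], "c", 20000L)
  expect_true(all(empty$n_snps == 0))
  # short contig warns and truncates
  expect_warning(window_density_profile(r, "c", 5000L, window = 10000L),
                 "shorter")
})

test_that("hysteresis segmentation finds the block boundary of a step profile", {
  prof <- tibble::tibble(start = seq(1, by = 1000, length.out = 100),
                         end = seq(1000, by = 1000, length.out = 100),
                         n_snps = rep(c(0L, 100L), each = 50))
  blocks <- detect_divergence_blocks(prof, high_threshold = 20,
                                     low_threshold = 5, min_run = 3)
  expect_equal(nrow(blocks), 2L)
  expect_equal(blocks$state, c("low", "high"))
  expect_equal(blocks$end_window[1], 50L)
  # data-driven default thresholds find the same boundary
  blocks_d <- detect_divergence_blocks(prof)
  expect_equal(blocks_d$end_window[1], 50L)
  # flat profile -> one block (also under default thresholds)
  flat <- tibble::tibble(start = 1:10, end = 1:10, n_snps = rep(2L, 10))
  expect_equal(nrow(detect_divergence_blocks(flat, 20, 5)), 1L)
  expect_equal(nrow(detect_divergence_blocks(flat)), 1L)
  # brief excursions shorter than min_run do not switch state
  jitter <- tibble::tibble(start = 1:20, end = 1:20,
                           n_snps = c(rep(0L, 9), 50L, rep(0L, 10)))
  expect_equal(nrow(detect_divergence_blocks(jitter, 20, 5, min_run = 3)), 1L)
})

test_that("block recovery on a simulated block cohort is within two windows", {
  cfg <- cohort_config(n_genes = 60L, contig_length = 400000L,
                       n_strains = 3L, divergence = c(0.5, 1, 2),
                       n_haplotype_blocks = 4L, shared_fraction = 0.95,
                       n_reference_background_variants = 0L)
  ann <- generate_reference(cfg, seed = 31)
  coh <- generate_cohort(ann, cfg, seed = 31)
  # segment a strain carrying a strict subset of the four blocks
  s <- "S02"
  prof <- window_density_profile(
    coh$records[coh$records$strain == s, ], "ctg1", 400000L,
    window = 10000L, step = 10000L)
  blocks <- detect_divergence_blocks(prof, high_threshold = 8,
                                     low_threshold = 2, min_run = 2)
  planted <- coh$truth$blocks
  expect_gt(nrow(blocks), 1)  # the subset strain shows real block structure
  switches <- prof$start[blocks$start_window[-1]]
  dist <- vapply(switches, function(p) {
    min(abs(p - c(planted$start, planted$end + 1L)))
  }, 1)
  # every detected state switch sits within two windows of a planted boundary
  expect_true(all(dist <= 2 * 10000L))
})

test_that("mutation-rate and density estimators reproduce closed-form values", {
  expect_equal(mutation_rate(704, 41061603)$mu, 1.71e-5)
  expect_equal(mutation_rate(1033, 41061603)$mu, 2.52e-5)
  expect_equal(mutation_rate(0, 1e6)$mu, 0)
  expect_equal(mutation_rate(704, 41061603, unique_indels = 123)$mu, 2.01e-5)
  expect_error(mutation_rate(10, 0), "positive")
  expect_equal(unique_density_per_kb(73336, 41061603), 1.8)
  expect_equal(unique_density_per_kb(704, 41061603), 0.02)
  expect_equal(unique_density_per_kb(0, 1e6), 0)
})

test_that("ti/tv ratio computes and recovers the generator parameter", {
  r <- variant_records(strain = "s", contig = "1", pos = 1:4, kind = "snp",
                       ref = c("G", "C", "A", "A"),
                       alt = c("A", "T", "G", "T"))
  expect_equal(titv_ratio(r), 3)
  r_ti <- r[1:3, ]
  expect_warning(expect_true(is.na(titv_ratio(r_ti))), "transversion")
  expect_error(titv_ratio(r[0, ]), "no SNPs")

  cfg <- cohort_config(n_genes = 20L, contig_length = 500000L,
                       n_strains = 2L, divergence = c(12, 12),
                       n_haplotype_blocks = 0L,
                       n_reference_background_variants = 0L)
  ann <- generate_reference(cfg, seed = 4)
  coh <- generate_cohort(ann, cfg, seed = 4)
  snps <- coh$records[coh$records$kind == "snp", ]
  expect_gt(nrow(snps), 10000)
  est <- titv_ratio(snps)
  # within three binomial standard errors of the configured ratio
  p <- 3 / 4
  se <- sqrt(p * (1 - p) / nrow(snps))
  expect_lt(abs(est / (1 + est) - p), 3 * se)
})

test_that("annotation-class enrichment reports observed, background and ratio", {
  t <- read_fixture("nonsense_annotation_classes.tsv")
  enr <- annotation_class_enrichment(t[, c("class", "n_nonsense")],
                                     t[, c("class", "n_genes")])
  ch <- enr[enr$class == "conserved_hypothetical", ]
  expect_equal(round(ch$observed_pct), 77)
  expect_equal(ch$ratio, ch$observed_pct / ch$background_pct)
  # uniform classes give ratio 1 everywhere
  u <- annotation_class_enrichment(
    data.frame(class = c("a", "b"), n = c(10, 10)),
    data.frame(class = c("a", "b"), n = c(50, 50)))
  expect_equal(u$ratio, c(1, 1))
  expect_error(annotation_class_enrichment(
    data.frame(class = "a", n = 1), data.frame(class = character(0),
                                               n = integer(0))),
    "empty")
})
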