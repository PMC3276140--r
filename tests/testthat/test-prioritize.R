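# A hand-built five-strain fixture modeled on a mapping experiment: focal
# strain "F" carries several lesions inside and outside its marker interval;
# other strains provide sharing and exclusion context.
make_fixture <- function() {
  loc_seq <- paste(rep("ACGT", 6000), collapse = "")  # 24 kb backdrop
  genes <- lapply(1:6, function(i) {
    s <- 1000L + (i - 1L) * 3000L
    list(gene_id = paste0("G", i), contig = "c1", strand = "+",
         exons = rbind(c(s, s + 599L)), cds = rbind(c(s, s + 599L)))
  })
  seqs <- list(c1 = loc_seq)
  suppressWarnings(ann <- make_annotation(seqs, genes))
  ann
}

fx_effects <- function() {
  # effect calls are constructed directly; positions refer to make_fixture().
  # F carries its own unique frameshift in each of G1/G2/G3; G1 additionally
  # carries a *different* frameshift in another strain (shared-ORF context),
  # while other2's lesion sits outside the interval in G5.
  tibble::tibble(
    key = c("c1_1100", "c1_4100", "c1_7100", "c1_19100_A", "c1_1150",
            "c1_13100", "c1_10100_A"),
    strain = c("F", "F", "F", "F", "other1", "other2", "F"),
    contig = "c1",
    pos = c(1100, 4100, 7100, 19100, 1150, 13100, 10100),
    kind = c("indel", "indel", "indel", "snp", "indel", "indel", "snp"),
    size = c(-1L, -1L, -1L, 0L, -1L, -2L, 0L),
    multi = FALSE,
    gene_id = c("G1", "G2", "G3", "G7", "G1", "G5", "G4"),
    category = c("cds_frameshift", "cds_frameshift", "cds_frameshift",
                 "nonsense", "cds_frameshift", "cds_frameshift",
                 "synonymous"))
}

fx_matrix <- function(effects) {
  r <- variant_records(effects$strain, effects$contig, effects$pos,
                       effects$kind,
                       ref = ifelse(effects$kind == "snp", "G", "T"),
                       alt = ifelse(effects$kind == "snp", "A", ""),
                       size = effects$size)
  build_occurrence_matrix(r)
}

test_that("interval restriction keeps closed-bound hits and counts genes", {
  ann <- make_fixture()
  eff <- fx_effects()
  out <- restrict_to_interval(eff[eff$strain == "F", ],
                              c(lo = 1000L, hi = 12000L), "c1", ann)
  expect_equal(out$n_genes_in_interval, 4L)  # G1..G4 span 1000..10599
  expect_setequal(out$subset$key,
                  c("c1_1100", "c1_4100", "c1_7100", "c1_10100_A"))
  # a variant exactly at a closed bound is included
  at_bound <- restrict_to_interval(
    tibble::tibble(contig = "c1", pos = 12000, key = "x"),
    c(lo = 1000L, hi = 12000L), "c1", ann)
  expect_equal(nrow(at_bound$subset), 1L)
  # empty overlap
  none <- restrict_to_interval(eff[eff$strain == "F", ],
                               c(lo = 20000L, hi = 21000L), "c1", ann)
  expect_equal(nrow(none$subset), 0L)

  # exhaustive per-gene intersection oracle on random intervals
  set.seed(14)
  for (i in 1:20) {
    lo <- sample.int(20000, 1); hi <- lo + sample.int(8000, 1)
    got <- restrict_to_interval(eff, c(lo = lo, hi = hi), "c1", ann)
    manual <- sum(vapply(ann$genes, function(g) {
      g$start <= hi && g$end >= lo
    }, TRUE))
    expect_equal(got$n_genes_in_interval, manual)
  }
})

test_that("shared-ORF exclusion triggers on qualified variants in other strains", {
  eff <- fx_effects()
  cand <- eff[eff$strain == "F" & eff$gene_id %in% c("G1", "G2", "G3"), ]
  cand$tier <- 1L
  cand$status <- "top"
  out <- exclude_shared_orfs(cand, eff, "F")
  st <- setNames(out$status, out$gene_id)
  expect_equal(unname(st["G1"]), "excluded_shared_orf")
  expect_equal(unname(st["G2"]), "top")
  expect_equal(unname(st["G3"]), "top")

  # pair-scan oracle over all (gene, strain) pairs
  other_hit <- unique(eff$gene_id[eff$strain != "F" &
                                    eff$category %in% c(
                                      "nonsense", "cds_frameshift",
                                      "sv_gene_deletion", "splice_site")])
  for (i in seq_len(nrow(out))) {
    expect_equal(out$status[i] == "excluded_shared_orf",
                 out$gene_id[i] %in% other_hit)
  }
})

test_that("tier-2 lesions in other strains do not exclude a tier-1 candidate by default", {
  eff <- fx_effects()
  eff$category[eff$strain == "other1"] <- "nonsynonymous"
  cand <- eff[eff$strain == "F" & eff$gene_id == "G1", ]
  cand$tier <- 1L
  cand$status <- "top"
  out <- exclude_shared_orfs(cand, eff, "F")
  expect_equal(out$status, "top")
  # but with the cross-tier switch it does
  out2 <- exclude_shared_orfs(cand, eff, "F",
                              severity_policy(shared_orf_same_tier_only = FALSE))
  expect_equal(out2$status, "excluded_shared_orf")
})

test_that("knockout evidence demotes normal-phenotype genes and flags essentials", {
  cand <- tibble::tibble(gene_id = c("G1", "G2", "G3"), tier = 1L,
                         status = "top")
  ko <- tibble::tibble(
    gene_id = c("G1", "G3"),
    phenotype = c("normal growth and sexual development",
                  "only recovered as heterokaryon"))
  out <- attach_knockout_evidence(cand, ko)
  expect_equal(out$status, c("demoted_ko_normal", "top", "top"))
  expect_equal(out$ko_corroborates, c(FALSE, FALSE, TRUE))
  expect_true(is.na(out$ko_phenotype[2]))
})

test_that("the full pipeline resolves a ty-1-style fixture to one candidate", {
  # three unique in-interval frameshift genes; one excluded because the gene
  # is frameshifted in another strain; one demoted by a normal knockout
  ann <- make_fixture()
  eff <- fx_effects()
  m <- fx_matrix(eff)
  ko <- tibble::tibble(gene_id = "G2", phenotype = "normal")
  rep <- prioritize("F", marker_interval("c1", 1000L, 12000L), m, eff, ann,
                    ko_table = ko)
  expect_equal(rep$verdict, "single_candidate")
  expect_equal(rep$top_gene, "G3")
  st <- setNames(rep$candidates$status, rep$candidates$key)
  expect_equal(unname(st["c1_1100"]), "excluded_shared_orf")
  expect_equal(unname(st["c1_4100"]), "demoted_ko_normal")
  expect_equal(unname(st["c1_19100_A"]), "excluded_outside_interval")
  expect_equal(unname(st["c1_10100_A"]), "excluded_low_severity")
  # every focal variant has exactly one status
  expect_equal(nrow(rep$candidates), sum(fx_effects()$strain == "F"))
  expect_false(any(is.na(rep$candidates$status)))
})

test_that("ambiguity and absence verdicts are reported honestly", {
  ann <- make_fixture()
  eff <- fx_effects()
  eff <- eff[eff$strain == "F" | eff$gene_id == "G9", ]  # drop exclusions
  m <- fx_matrix(eff)
  rep <- prioritize("F", marker_interval("c1", 1000L, 12000L), m, eff, ann)
  # three surviving same-tier candidates in different genes
  expect_equal(rep$verdict, "ambiguous")
  # empty interval
  rep2 <- prioritize("F", marker_interval("c1", 20000L, 23000L), m, eff, ann)
  expect_equal(rep2$verdict, "none")
})

test_that("a non-unique candidate is excluded by the cross-strain comparison", {
  ann <- make_fixture()
  eff <- fx_effects()
  shared <- eff[eff$key == "c1_7100", ]
  shared$strain <- "other1"
  eff2 <- dplyr::bind_rows(eff, shared)
  m <- fx_matrix(eff2)
  rep <- prioritize("F", marker_interval("c1", 1000L, 12000L), m, eff2, ann)
  st <- setNames(rep$candidates$status, rep$candidates$key)
  expect_equal(unname(st["c1_7100"]), "excluded_not_unique")
})

test_that("shrinking the interval never adds candidates", {
  ann <- make_fixture()
  eff <- fx_effects()
  m <- fx_matrix(eff)
  wide <- prioritize("F", marker_interval("c1", 1000L, 20000L), m, eff, ann)
  narrow <- prioritize("F", marker_interval("c1", 4000L, 8000L), m, eff, ann)
  top_wide <- wide$candidates$key[wide$candidates$status == "top"]
  top_narrow <- narrow$candidates$key[narrow$candidates$status == "top"]
  expect_true(all(top_narrow %in% top_wide))
})
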