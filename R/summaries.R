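#' Round half away from zero
#'
#' Tabulated percentages in legacy genome reports are rounded half away from
#' zero rather than banker's style; this helper reproduces that convention.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-strain SNP category summary from counts
#'
#' Computes the percentage columns of a per-strain SNP classification table
#' from its count columns. Percentages of non-coding, nonsynonymous and
#' nonsense SNPs are taken over the strain total; the synonymous percentage
#' is taken over the non-coding count — a quirk of the legacy table layout
#' this summary mirrors, retained so published tables reproduce exactly.
#'
#' @param counts Tibble with columns `strain`, `total`, `nc`, `synonymous`,
#'   `nonsynonymous`, `utr3`, `utr5`, `intron`, `nonsense`.
#' @return The input with `pct_nc`, `pct_syn`, `pct_nonsyn`, `pct_nonsense`
#'   columns (2 decimals, half away from zero).
#' @export
snp_summary_from_counts <- function(counts) {
  need <- c("strain", "total", "nc", "synonymous", "nonsynonymous",
            "utr3", "utr5", "intron", "nonsense")
  stopifnot(all(need %in% names(counts)))
  tot <- counts$total
  zero <- tot == 0
  if (any(zero)) warning("strain(s) with zero SNPs: percentages set to 0",
                         call. = FALSE)
  safe_pct <- function(num, den) {
    ifelse(den == 0, 0, round_half_up(100 * num / den, 2))
  }
  counts$pct_nc <- safe_pct(counts$nc, tot)
  counts$pct_syn <- safe_pct(counts$synonymous, counts$nc)
  counts$pct_nonsyn <- safe_pct(counts$nonsynonymous, tot)
  counts$pct_nonsense <- safe_pct(counts$nonsense, tot)
  counts
}

#' Per-strain SNP category summary from effect calls
#'
#' Counts one strain's classified SNPs by effect category. Splice-site SNPs
#' are tallied with introns, matching the category layout of per-strain SNP
#' tables (non-coding, synonymous, nonsynonymous, 3' UTR, 5' UTR, intron,
#' nonsense).
#'
#' @param effects Effect calls for one strain (SNPs of other kinds are
#'   ignored).
#' @return One-row tibble of counts plus percentage columns (see
#'   [snp_summary_from_counts()]).
#' @export
strain_snp_summary <- function(effects) {
  x <- effects[effects$kind == "snp", , drop = FALSE]
  cnt <- function(cat) sum(x$category %in% cat)
  counts <- tibble::tibble(
    strain = if (nrow(x)) x$strain[1] else NA_character_,
    total = nrow(x),
    nc = cnt("noncoding_intergenic"),
    synonymous = cnt("synonymous"),
    nonsynonymous = cnt("nonsynonymous"),
    utr3 = cnt("utr3"),
    utr5 = cnt("utr5"),
    intron = cnt(c("intron", "splice_site")),
    nonsense = cnt("nonsense"))
  snp_summary_from_counts(counts)
}

#' Per-strain indel category summary
#'
#' @param effects Effect calls for one strain (indels and structural
#'   deletions).
#' @param unique_keys Optional character vector of cohort-unique keys, used
#'   to fill the `unique` column.
#' @return One-row tibble: `strain`, `total`, `unique`, `cds`, `nc`,
#'   `intron`, `splice_site`, `other`. `other` collects indels assigned to a
#'   gene but not classifiable at codon level (no usable CDS annotation) and
#'   UTR indels.
#' @export
strain_indel_summary <- function(effects, unique_keys = NULL) {
  x <- effects[effects$kind != "snp", , drop = FALSE]
  cds <- sum(x$category %in% c("cds_frameshift", "cds_inframe",
                               "sv_gene_deletion"))
  nc <- sum(x$category == "noncoding_intergenic")
  intron <- sum(x$category == "intron")
  splice <- sum(x$category == "splice_site")
  tibble::tibble(
    strain = if (nrow(x)) x$strain[1] else NA_character_,
    total = nrow(x),
    unique = if (is.null(unique_keys)) NA_integer_
             else sum(x$key %in% unique_keys),
    cds = cds, nc = nc, intron = intron, splice_site = splice,
    other = nrow(x) - cds - nc - intron - splice)
}

#' Indel size spectrum
#'
#' Pools insertions and deletions by absolute size. In `distinct` mode each
#' variant key contributes each of its observed sizes once regardless of how
#' many strains carry it; in `mapped` mode every per-strain observation
#' counts.
#'
#' @param matrix An `occurrence_matrix`.
#' @param mode `"distinct"` or `"mapped"`.
#' @param signed Keep the sign of the size instead of pooling by magnitude.
#' @return Tibble with columns `size`, `n`.
#' @export
indel_size_spectrum <- function(matrix, mode = c("distinct", "mapped"),
                                signed = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "occurrence_matrix"))
  ind <- matrix$keys[matrix$keys$kind %in% c("indel", "sv_del"), , drop = FALSE]
  sizes <- if (mode == "distinct") {
    unlist(lapply(ind$sizes, unique))
  } else {
    unlist(ind$sizes)
  }
  if (!signed) sizes <- abs(sizes)
  tab <- table(sizes)
  tibble::tibble(size = as.integer(names(tab)), n = as.integer(tab)) |>
    dplyr::arrange(.data$size)
}

#' Fraction of indels in coding sequence, by size
#'
#' For each absolute indel size, the percentage of indels of that size whose
#' effect category places them in coding sequence. In genomes under
#' selection this fraction is strongly elevated at sizes that are multiples
#' of 3 (frame-preserving) and depressed elsewhere.
#'
#' @param effects Cohort effect calls (indels; SNPs ignored).
#' @return Tibble: `size`, `n_total`, `n_cds`, `pct_cds`.
#' @export
coding_fraction_by_size <- function(effects) {
  x <- effects[effects$kind != "snp", , drop = FALSE]
  if (!nrow(x)) {
    return(tibble::tibble(size = integer(0), n_total = integer(0),
                          n_cds = integer(0), pct_cds = numeric(0)))
  }
  x$abs_size <- abs(x$size)
  x$in_cds <- x$category %in% c("cds_frameshift", "cds_inframe")
  x |>
    dplyr::group_by(size = .data$abs_size) |>
    dplyr::summarise(n_total = dplyr::n(), n_cds = sum(.data$in_cds),
                     .groups = "drop") |>
    dplyr::mutate(pct_cds = 100 * .data$n_cds / .data$n_total) |>
    dplyr::arrange(.data$size)
}

#' Moving-window variant density profile
#'
#' Counts variants in sliding windows along one contig: total SNPs, SNPs
#' unique to their strain within the cohort, and indels, as separate series.
#' With `step = window` the profile reduces to disjoint binning and the
#' window counts sum to the per-contig totals.
#'
#' @param records Variant records (any number of strains; filter first if a
#'   single-strain profile is wanted) with `key` column or computable keys.
#' @param contig Contig to profile.
#' @param contig_length Contig length in bases.
#' @param window Window size in bases (default 10,000).
#' @param step Step between window starts (default 1,000).
#' @param unique_keys Character vector of cohort-unique keys (for the unique
#'   SNP series; omit for an all-zero series).
#' @return A tibble of class `window_profile`: `start`, `end`, `n_snps`,
#'   `n_unique_snps`, `n_indels`.
#' @export
window_density_profile <- function(records, contig, contig_length,
                                   window = 10000L, step = 1000L,
                                   unique_keys = character(0)) {
  stopifnot(window >= step, step >= 1L)
  if (!"key" %in% names(records)) records <- add_variant_keys(records)
  if (contig_length < window) {
    warning("contig shorter than window: single truncated window",
            call. = FALSE)
    starts <- 1L
    ends <- as.integer(contig_length)
  } else {
    n_win <- (contig_length - window) %/% step + 1L
    starts <- 1L + step * (seq_len(n_win) - 1L)
    ends <- starts + window - 1L
  }
  x <- records[records$contig == contig, , drop = FALSE]
  count_in <- function(pos) {
    if (!length(pos)) return(integer(length(starts)))
    vapply(seq_along(starts), function(i) {
      sum(pos >= starts[i] & pos <= ends[i])
    }, 1L)
  }
  snp_pos <- x$pos[x$kind == "snp"]
  uniq_pos <- x$pos[x$kind == "snp" & x$key %in% unique_keys]
  ind_pos <- x$pos[x$kind != "snp"]
  out <- tibble::tibble(start = starts, end = ends,
                        n_snps = count_in(snp_pos),
                        n_unique_snps = count_in(uniq_pos),
                        n_indels = count_in(ind_pos))
  attr(out, "contig") <- contig
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  class(out) <- c("window_profile", class(out))
  out
}

#' Segment a window profile into divergence blocks
#'
#' Two-state run-length segmentation with hysteresis, delimiting the
#' haplotype-like blocks visible as abrupt shifts between high and low
#' divergence from the reference: the state switches to `high` at the start
#' of the first run of `min_run` consecutive windows with counts at or above
#' `high_threshold`, and back to `low` at the start of a run of `min_run`
#' windows at or below `low_threshold`. Segments tile the profile.
#'
#' @param profile A `window_profile`.
#' @param high_threshold,low_threshold Hysteresis thresholds
#'   (`high_threshold > low_threshold >= 0`). Defaults are data-driven:
#'   the profile's 90th percentile and median (block boundaries are a
#'   qualitative feature, so thresholds adapt to the strain's divergence).
#' @param min_run Minimum run length, in windows, to switch state.
#' @param series Which count column to segment (default `"n_snps"`).
#' @return Tibble: `start_window`, `end_window`, `start`, `end`, `state`.
#' @export
detect_divergence_blocks <- function(profile,
                                     high_threshold = NULL,
                                     low_threshold = NULL,
                                     min_run = 3L, series = "n_snps") {
  x <- profile[[series]]
  n <- length(x)
  if (!n) stop("empty profile", call. = FALSE)
  if (is.null(high_threshold)) {
    high_threshold <- as.numeric(stats::quantile(x, 0.9))
  }
  if (is.null(low_threshold)) {
    low_threshold <- stats::median(as.numeric(x))
  }
  if (high_threshold <= low_threshold) {
    # degenerate (e.g. flat) profiles: keep the hysteresis well-formed
    high_threshold <- low_threshold + 1
  }
  stopifnot(high_threshold > low_threshold, low_threshold >= 0)
  run_ok <- function(i, thr, op) {
    j <- i + min_run - 1L
    j <= n && all(op(x[i:j], thr))
  }
  # initial state from the first window
  state <- if (x[1] >= high_threshold) "high" else "low"
  states <- character(n)
  for (i in seq_len(n)) {
    if (state == "low" && x[i] >= high_threshold &&
        run_ok(i, high_threshold, `>=`)) {
      state <- "high"
    } else if (state == "high" && x[i] <= low_threshold &&
               run_ok(i, low_threshold, `<=`)) {
      state <- "low"
    }
    states[i] <- state
  }
  r <- rle(states)
  endw <- cumsum(r$lengths)
  startw <- c(1L, utils::head(endw, -1L) + 1L)
  tibble::tibble(start_window = startw, end_window = endw,
                 start = profile$start[startw], end = profile$end[endw],
                 state = r$values)
}

#' Spontaneous mutation-rate estimate
#'
#' Upper-bound per-base mutation rate from the variants private to a strain:
#' `mu = (unique_snps + unique_indels) / genome_size`, reported to three
#' significant figures. For strains repeatedly backcrossed into the
#' reference background, private variants are an upper bound on the
#' mutations accumulated since divergence from the reference lineage.
#'
#' @param unique_snps Number of SNPs private to the strain.
#' @param genome_size Surveyed genome length in bases.
#' @param unique_indels Optional count of private indels to include.
#' @param strain Optional strain label.
#' @return Tibble: `strain`, `unique_snps`, `unique_indels`, `genome_size`,
#'   `mu`.
#' @export
mutation_rate <- function(unique_snps, genome_size, unique_indels = 0L,
                          strain = NA_character_) {
  if (genome_size <= 0) stop("genome_size must be positive", call. = FALSE)
  mu <- signif((unique_snps + unique_indels) / genome_size, 3)
  tibble::tibble(strain = strain, unique_snps = as.integer(unique_snps),
                 unique_indels = as.integer(unique_indels),
                 genome_size = genome_size, mu = mu)
}

#' Unique-variant density per kilobase
#'
#' `1000 * unique_count / genome_size`, rounded to one decimal when at least
#' 0.1 and to two decimals below that (the reporting convention of
#' per-strain divergence tables).
#'
#' @param unique_count Number of variants private to the strain.
#' @param genome_size Surveyed genome length in bases.
#' @return Density per kb (rounded as described).
#' @export
unique_density_per_kb <- function(unique_count, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive", call. = FALSE)
  d <- 1000 * unique_count / genome_size
  ifelse(d >= 0.1, round_half_up(d, 1), round_half_up(d, 2))
}

#' Transition/transversion ratio
#'
#' @param snps Variant records or effect calls restricted to SNPs (columns
#'   `ref` and `alt`).
#' @return Ratio of transitions to transversions; `NA` with a warning when
#'   no transversion is present.
#' @export
titv_ratio <- function(snps) {
  x <- snps[snps$kind == "snp", , drop = FALSE]
  if (!nrow(x)) stop("no SNPs supplied", call. = FALSE)
  type <- classify_substitution_type(x$ref, x$alt)
  ti <- sum(type == "transition")
  tv <- sum(type == "transversion")
  if (tv == 0L) {
    warning("no transversions: ti/tv ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  ti / tv
}

#' Annotation-class enrichment among nonsense-carrying ORFs
#'
#' Compares the annotation-class composition of ORFs carrying nonsense
#' mutations against the composition of all ORFs: `observed_pct` is the
#' percentage of nonsense mutations falling in each class, `background_pct`
#' the percentage of all genes in that class, and `ratio` their quotient.
#'
#' @param nonsense_classes Table (class, n) of nonsense mutations per
#'   annotation class, or a character vector of classes (one per mutation).
#' @param gene_classes Table (class, n) of genes per annotation class, or a
#'   character vector (one per gene).
#' @return Tibble: `class`, `n_nonsense`, `n_genes`, `observed_pct`,
#'   `background_pct`, `ratio`.
#' @export
annotation_class_enrichment <- function(nonsense_classes, gene_classes) {
  as_counts <- function(x, nm) {
    if (is.data.frame(x)) {
      stopifnot(ncol(x) >= 2)
      stats::setNames(as.integer(x[[2]]), as.character(x[[1]]))
    } else {
      tab <- table(x)
      stats::setNames(as.integer(tab), names(tab))
    }
  }
  obs <- as_counts(nonsense_classes)
  bg <- as_counts(gene_classes)
  if (!length(bg)) stop("empty gene class table", call. = FALSE)
  classes <- union(names(obs), names(bg))
  n_obs <- ifelse(classes %in% names(obs), obs[classes], 0L)
  n_bg <- ifelse(classes %in% names(bg), bg[classes], 0L)
  observed_pct <- 100 * n_obs / sum(obs)
  background_pct <- 100 * n_bg / sum(bg)
  tibble::tibble(class = classes,
                 n_nonsense = as.integer(n_obs),
                 n_genes = as.integer(n_bg),
                 observed_pct = observed_pct,
                 background_pct = background_pct,
                 ratio = ifelse(background_pct > 0,
                                observed_pct / background_pct, NA_real_))
}

#' Export a window profile as BedGraph tracks
#'
#' @param profile A `window_profile`.
#' @param path Output file.
#' @param series Count column to export.
#' @return `path`, invisibly.
#' @export
write_profile_bedgraph <- function(profile, path, series = "n_snps") {
  contig <- attr(profile, "contig")
  lines <- paste(contig, profile$start - 1L, profile$end, profile[[series]],
                 sep = "\t")
  writeLines(c(paste0("track type=bedGraph name=", series), lines), path)
  invisible(path)
}
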