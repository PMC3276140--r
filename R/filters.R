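#' Call-quality filter policy
#'
#' Record-level re-expression of the consensus-caller filters commonly applied
#' to short-read SNP/indel calls on haploid genomes: minimum read depth,
#' minimum phred-scaled consensus quality, minimum mapping quality, rejection
#' of SNPs adjacent to indels, and rejection of SNP clusters too dense to be
#' trusted within a short window.
#'
#' @param min_depth Minimum read depth (default 3).
#' @param min_consensus_quality Minimum consensus quality (default 40).
#' @param min_map_quality Minimum mapping quality (default 30).
#' @param indel_proximity_window Window in bases around an indel within which
#'   SNPs are rejected, and the span used for the SNP-density rule (default 5).
#' @param max_snps_in_window Maximum number of SNPs tolerated in any window of
#'   `indel_proximity_window` bases (default 2).
#'
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(min_depth = 3L, min_consensus_quality = 40L,
                          min_map_quality = 30L, indel_proximity_window = 5L,
                          max_snps_in_window = 2L) {
  p <- list(
    min_depth = as.integer(min_depth),
    min_consensus_quality = as.integer(min_consensus_quality),
    min_map_quality = as.integer(min_map_quality),
    indel_proximity_window = as.integer(indel_proximity_window),
    max_snps_in_window = as.integer(max_snps_in_window)
  )
  if (any(unlist(p) < 0L)) stop("filter thresholds must be >= 0", call. = FALSE)
  class(p) <- "filter_policy"
  p
}

#' Filter variant calls by quality and context
#'
#' Partitions the input into kept and rejected records. Quality thresholds are
#' applied per record; the indel-proximity and SNP-density rules are applied
#' per strain and contig. A SNP is rejected when it lies within
#' `indel_proximity_window` bases of any indel of the same strain, or when some
#' window of `indel_proximity_window` bases contains more than
#' `max_snps_in_window` SNPs (all SNPs of such a window are rejected).
#' Applying the filter a second time to the kept set is a no-op.
#'
#' @param records A `variant_records` tibble.
#' @param policy A [filter_policy()].
#' @return A list with elements `kept` (records passing all rules) and
#'   `rejected` (records with an added `reason` column; the first failed rule,
#'   in the order depth, consensus_quality, map_quality, indel_proximity,
#'   snp_density).
#' @export
filter_calls <- function(records, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (nrow(records) == 0L) {
    rej <- records
    rej$reason <- character(0)
    return(list(kept = records, rejected = rej))
  }
  reason <- rep(NA_character_, nrow(records))
  dp <- ifelse(is.na(records$dp), Inf, records$dp)
  cq <- ifelse(is.na(records$cq), Inf, records$cq)
  mq <- ifelse(is.na(records$mq), Inf, records$mq)
  reason[is.na(reason) & dp < policy$min_depth] <- "depth"
  reason[is.na(reason) & cq < policy$min_consensus_quality] <- "consensus_quality"
  reason[is.na(reason) & mq < policy$min_map_quality] <- "map_quality"

  w <- policy$indel_proximity_window
  nmax <- policy$max_snps_in_window
  groups <- paste(records$strain, records$contig, sep = "\r")
  for (g in unique(groups)) {
    in_g <- which(groups == g & is.na(reason))
    if (!length(in_g)) next
    snp_i <- in_g[records$kind[in_g] == "snp"]
    indel_i <- in_g[records$kind[in_g] != "snp"]
    if (length(snp_i) && length(indel_i)) {
      # an indel occupies [pos, pos + |size| - 1] for deletions, pos for others
      ist <- records$pos[indel_i]
      ien <- ifelse(records$kind[indel_i] == "sv_del", records$sv_end[indel_i],
                    ifelse(records$size[indel_i] < 0L,
                           records$pos[indel_i] - records$size[indel_i] - 1L,
                           records$pos[indel_i]))
      for (k in seq_along(snp_i)) {
        p <- records$pos[snp_i[k]]
        if (any(p >= ist - w & p <= ien + w)) reason[snp_i[k]] <- "indel_proximity"
      }
    }
    snp_i <- in_g[records$kind[in_g] == "snp" & is.na(reason[in_g])]
    if (length(snp_i) > nmax) {
      pos <- records$pos[snp_i]
      o <- order(pos)
      pos_s <- pos[o]
      dense <- logical(length(pos_s))
      j <- 1L
      for (i in seq_along(pos_s)) {
        while (pos_s[i] - pos_s[j] > w - 1L) j <- j + 1L
        if (i - j + 1L > nmax) dense[j:i] <- TRUE
      }
      reason[snp_i[o][dense]] <- "snp_density"
    }
  }
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(kept = kept, rejected = rejected)
}
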