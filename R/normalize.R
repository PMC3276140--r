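#' Left-normalize indels against the reference
#'
#' Shifts each insertion or deletion to its leftmost equivalent position so
#' that identical events called at different offsets in different strains
#' receive the same canonical key. A deletion of bases `[p, p+k-1]` may be
#' shifted left one base whenever the base at `p-1` equals the base at
#' `p+k-1`; an insertion may be shifted left whenever the base at `p-1`
#' equals the last inserted base (the inserted sequence is rotated
#' accordingly). SNPs and structural deletions pass through unchanged.
#'
#' @param records A `variant_records` tibble.
#' @param reference Named `DNAStringSet` covering the records' contigs.
#' @return The records with indel positions (and allele strings) normalized.
#' @export
left_normalize_indels <- function(records, reference) {
  idx <- which(records$kind == "indel")
  if (!length(idx)) return(records)
  seqs <- lapply(reference, as.character)
  for (i in idx) {
    contig <- records$contig[i]
    s <- seqs[[contig]]
    if (is.null(s)) next
    p <- records$pos[i]
    if (records$size[i] < 0L) {
      del <- records$ref[i]
      k <- nchar(del)
      while (p > 1L && substr(s, p - 1L, p - 1L) == substr(s, p + k - 1L, p + k - 1L)) {
        p <- p - 1L
      }
      records$pos[i] <- p
      records$ref[i] <- substr(s, p, p + k - 1L)
    } else {
      ins <- records$alt[i]
      k <- nchar(ins)
      while (p > 1L && substr(s, p - 1L, p - 1L) == substr(ins, k, k)) {
        ins <- paste0(substr(ins, k, k), substr(ins, 1L, k - 1L))
        p <- p - 1L
      }
      records$pos[i] <- p
      records$alt[i] <- ins
    }
  }
  records
}
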