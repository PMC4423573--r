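#' Pileup consensus over one read group
#'
#' Collapses the aligned bases of a read group into one majority-base call
#' per covered reference position. Deleted and skipped positions do not
#' contribute to depth. A position is called only when its depth reaches
#' `min_depth` and the majority base reaches `min_agreement` of the
#' covering bases; otherwise it is a no-call.
#'
#' @param aln an [alignment_table()] on one reference.
#' @param min_depth minimum covering bases for a call (>= 1).
#' @param min_agreement minimum majority fraction, in (0.5, 1].
#' @return a `data.table`: `chrom`, `pos`, `base` (`NA` for no-call),
#'   `depth`, `agreement`.
#' @export
pileup_consensus <- function(aln, min_depth = 4L, min_agreement = 0.8) {
  stopifnot(min_depth >= 1L, min_agreement > 0.5, min_agreement <= 1)
  bm <- base_map(aln)
  if (!nrow(bm))
    return(data.table(chrom = character(), pos = integer(),
                      base = character(), depth = integer(),
                      agreement = numeric()))
  cons <- bm[, {
    tab <- sort(table(base), decreasing = TRUE)
    .(base = names(tab)[1], depth = .N,
      agreement = as.numeric(tab[1]) / .N)
  }, by = .(chrom, pos)]
  cons[depth < min_depth | agreement < min_agreement, base := NA_character_]
  setkey(cons, chrom, pos)
  cons[]
}

#' Call homoeo-SNPs between two consensus tracks
#'
#' Emits an index record exactly where both consensus tracks have a call
#' and the called bases differ. The first track supplies `alleleA`, the
#' second `alleleB`, so swapping the tracks swaps the alleles.
#'
#' @param cons_a,cons_b consensus tables from [pileup_consensus()] over the
#'   same reference.
#' @return a [snp_index()].
#' @export
call_homoeo_snps <- function(cons_a, cons_b) {
  both <- merge(cons_a[!is.na(base)], cons_b[!is.na(base)],
                by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  snp_index(both[base_a != base_b,
                 .(chrom, pos, alleleA = base_a, alleleB = base_b)])
}

#' Iterative homoeo-SNP index refinement
#'
#' Starting from an initial index (for example one inferred from diploid
#' relatives), each round categorizes the allopolyploid reads with the
#' current index, splits them by assigned genome, builds a consensus pileup
#' per genome and re-calls homoeo-SNPs between the two consensuses. The
#' rebuilt index reflects the state of the polyploid itself rather than of
#' the diploids. No convergence rule is applied; per-round index sizes are
#' returned instead.
#'
#' @param aln an [alignment_table()] of allopolyploid reads on one
#'   reference.
#' @param initial_index a [snp_index()] to seed round 1.
#' @param rounds number of refinement rounds (>= 1).
#' @param threshold vote-majority threshold for the categorization step.
#' @param min_depth,min_agreement consensus thresholds, see
#'   [pileup_consensus()].
#' @return a list with `index` (the final [snp_index()]) and `sizes`
#'   (integer vector of index sizes after each round).
#' @export
iterate_index <- function(aln, initial_index, rounds = 1L,
                          threshold = 0.75, min_depth = 4L,
                          min_agreement = 0.8) {
  stopifnot(rounds >= 1L)
  idx <- initial_index
  sizes <- integer(rounds)
  for (k in seq_len(rounds)) {
    dec <- categorize_snpvote(aln, idx, threshold)$decisions
    qa <- dec[genome == "A", qname]
    qb <- dec[genome == "B", qname]
    cons_a <- pileup_consensus(aln[qname %in% qa], min_depth, min_agreement)
    cons_b <- pileup_consensus(aln[qname %in% qb], min_depth, min_agreement)
    idx <- call_homoeo_snps(cons_a, cons_b)
    sizes[k] <- nrow(idx)
  }
  list(index = idx, sizes = sizes)
}
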