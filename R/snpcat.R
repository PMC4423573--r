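#' Homoeo-SNP index I/O
#'
#' A homoeo-SNP index is a table of reference positions at which the two
#' subgenomes carry different, diagnostic bases. On disk it is
#' tab-separated with columns `chrom`, `pos` (1-based), `alleleA`,
#' `alleleB`; `#`-prefixed comment lines are allowed.
#'
#' @param path file to read or write.
#' @return `read_snp_index()` returns a validated `data.table` of class
#'   `snp_index`, sorted by `chrom` then `pos`.
#' @export
read_snp_index <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(snp_index())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 4L)
  if (length(bad))
    stop("malformed index line ", lineno[bad[1]], ": ", lines[bad[1]])
  idx <- data.table(chrom = vapply(f, `[`, "", 1L),
                    pos = suppressWarnings(as.integer(vapply(f, `[`, "", 2L))),
                    alleleA = toupper(vapply(f, `[`, "", 3L)),
                    alleleB = toupper(vapply(f, `[`, "", 4L)))
  if (anyNA(idx$pos))
    stop("non-numeric position on index line ",
         lineno[which(is.na(idx$pos))[1]])
  bad <- which(!(idx$alleleA %in% DNA_BASES) | !(idx$alleleB %in% DNA_BASES))
  if (length(bad))
    stop("non-ACGT allele on index line ", lineno[bad[1]])
  bad <- which(idx$alleleA == idx$alleleB)
  if (length(bad))
    stop("identical alleles on index line ", lineno[bad[1]])
  dup <- idx[, .(lines = list(lineno[.I]), n = .N), by = .(chrom, pos)][n > 1L]
  if (nrow(dup))
    stop("duplicate index position ", dup$chrom[1], ":", dup$pos[1],
         " on lines ", paste(dup$lines[[1]], collapse = " and "))
  snp_index(idx)
}

#' @rdname read_snp_index
#' @param idx a `snp_index` table (columns `chrom`, `pos`, `alleleA`,
#'   `alleleB`); for `snp_index()` the raw table to validate, defaulting to
#'   an empty index.
#' @export
write_snp_index <- function(idx, path) {
  writeLines(c("#chrom\tpos\talleleA\talleleB",
               sprintf("%s\t%d\t%s\t%s", idx$chrom, idx$pos,
                       idx$alleleA, idx$alleleB)), path)
  invisible(path)
}

#' @rdname read_snp_index
#' @export
snp_index <- function(idx = NULL) {
  if (is.null(idx))
    idx <- data.table(chrom = character(), pos = integer(),
                      alleleA = character(), alleleB = character())
  idx <- as.data.table(idx)[, .(chrom = as.character(chrom),
                                pos = as.integer(pos),
                                alleleA = as.character(alleleA),
                                alleleB = as.character(alleleB))]
  stopifnot(all(idx$alleleA %in% DNA_BASES), all(idx$alleleB %in% DNA_BASES),
            all(idx$alleleA != idx$alleleB))
  if (anyDuplicated(idx[, .(chrom, pos)]))
    stop("duplicate (chrom, pos) in SNP index")
  setkey(idx, chrom, pos)
  setattr(idx, "class", unique(c("snp_index", class(idx))))
  idx[]
}

#' Read base aligned to a reference position
#'
#' Walks one record's CIGAR to find the read base sitting on `ref_pos`.
#' Positions falling in a deletion or reference skip, or outside the
#' aligned span, return `NA` (absent), not an error.
#'
#' @param rec a single-row [alignment_table()] (mapped).
#' @param ref_pos 1-based reference coordinate.
#' @return a single base character, or `NA_character_` if absent.
#' @export
base_at <- function(rec, ref_pos) {
  stopifnot(nrow(rec) == 1L, is_mapped(rec))
  ops <- GenomicAlignments::explodeCigarOps(rec$cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar)[[1]]
  qpos <- 1L; rpos <- rec$pos
  for (j in seq_along(ops)) {
    op <- ops[j]; len <- lens[j]
    if (op %in% c("M", "=", "X")) {
      if (ref_pos >= rpos && ref_pos < rpos + len)
        return(substring(rec$seq, qpos + (ref_pos - rpos),
                         qpos + (ref_pos - rpos)))
      qpos <- qpos + len; rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (ref_pos >= rpos && ref_pos < rpos + len) return(NA_character_)
      rpos <- rpos + len
    }
  }
  NA_character_
}

# Expand mapped records into one row per aligned base:
# (qname, chrom, pos, base). Deletions/skips/insertions/clips contribute
# nothing. Backbone of SNP tallying and pileup consensus.
base_map <- function(aln) {
  aln <- validate_alignment_table(aln)
  aln <- aln[is_mapped(aln) & is_primary(aln)]
  if (!nrow(aln))
    return(data.table(qname = character(), chrom = character(),
                      pos = integer(), base = character()))
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos, ops = c("M", "=", "X"))
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(
    aln$cigar, ops = c("M", "=", "X"))
  nblk <- S4Vectors::elementNROWS(rr)
  rstart <- unlist(IRanges::start(rr), use.names = FALSE)
  qstart <- unlist(IRanges::start(qr), use.names = FALSE)
  blen <- unlist(IRanges::width(rr), use.names = FALSE)
  rec <- rep(seq_len(nrow(aln)), nblk)          # record of each block
  n <- rep(blen, blen)                           # then expand to bases
  off <- sequence(blen) - 1L
  data.table(
    qname = rep(aln$qname, nblk)[rep(seq_along(blen), blen)],
    chrom = rep(aln$rname, nblk)[rep(seq_along(blen), blen)],
    pos = rep(rstart, blen) + off,
    base = unlist(strsplit(substring(rep(aln$seq, nblk), qstart,
                                     qstart + blen - 1L), ""),
                  use.names = FALSE))
}

#' Tally homoeo-SNP votes for one fragment
#'
#' Pools the mapped mates of a fragment and, at every index position
#' overlapped by any mate, compares the read base to the two diagnostic
#' alleles. Bases equal to `alleleA` vote A, equal to `alleleB` vote B;
#' anything else (including gapped positions) is uninformative. Mates
#' covering the same SNP each vote independently.
#'
#' @param aln an [alignment_table()] with the fragment's records on the
#'   reference the index refers to.
#' @param idx a [snp_index()].
#' @return a list: `votes_a`, `votes_b`, `informative`, `uninformative`.
#' @export
tally_fragment <- function(aln, idx) {
  bm <- base_map(aln)
  hits <- merge(bm, idx, by = c("chrom", "pos"))
  list(votes_a = sum(hits$base == hits$alleleA),
       votes_b = sum(hits$base == hits$alleleB),
       informative = sum(hits$base == hits$alleleA |
                           hits$base == hits$alleleB),
       uninformative = sum(hits$base != hits$alleleA &
                             hits$base != hits$alleleB))
}

#' Vote-majority decision
#'
#' Categorizes a tally when at least the threshold fraction of informative
#' votes agree. The comparison is inclusive, so 3 of 4 votes categorize at
#' the default 0.75. Fragments with no informative votes are `N` with
#' criterion `NO_SNPS`; fragments failing the majority are `N` with
#' criterion `CONFLICT`.
#'
#' @param tally a tally from [tally_fragment()].
#' @param threshold minimum vote majority, in (0.5, 1].
#' @return a list with `genome` and `criterion` as in
#'   [categorize_fragment()] (criterion `MATCHES` when categorized).
#' @export
decide_category <- function(tally, threshold = 0.75) {
  check_threshold(threshold)
  inf <- tally$votes_a + tally$votes_b
  if (inf == 0L) return(list(genome = "N", criterion = "NO_SNPS"))
  if (max(tally$votes_a, tally$votes_b) / inf >= threshold)
    list(genome = if (tally$votes_a >= tally$votes_b) "A" else "B",
         criterion = "MATCHES")
  else list(genome = "N", criterion = "CONFLICT")
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0.5 || threshold > 1)
    stop("threshold must be a single value in (0.5, 1]")
  invisible(threshold)
}

#' SNP-vote categorization of an alignment stream
#'
#' Applies [tally_fragment()] + [decide_category()] to every fragment of a
#' single-reference mapping, fully vectorized. Fragments are read names;
#' mates are pooled.
#'
#' @param aln an [alignment_table()] of the read set mapped to one
#'   reference.
#' @param idx a [snp_index()] on that reference.
#' @param threshold minimum vote majority, in (0.5, 1].
#' @return a list with `decisions` (`qname`, `genome`, `criterion`,
#'   `votes_a`, `votes_b`) covering every read name in `aln`, and `summary`
#'   (`mapped`, `cat_a`, `cat_b`, `n`).
#' @export
categorize_snpvote <- function(aln, idx, threshold = 0.75) {
  check_threshold(threshold)
  aln <- validate_alignment_table(aln)
  aln <- aln[is_primary(aln)]
  frags <- aln[, .(mapped = sum(is_mapped(.SD))), by = qname]
  bm <- base_map(aln)
  hits <- merge(bm, idx, by = c("chrom", "pos"))
  votes <- hits[, .(votes_a = sum(base == alleleA),
                    votes_b = sum(base == alleleB)), by = qname]
  d <- merge(frags, votes, by = "qname", all.x = TRUE)
  for (col in c("votes_a", "votes_b"))
    set(d, which(is.na(d[[col]])), col, 0L)
  inf <- d$votes_a + d$votes_b
  top <- pmax(d$votes_a, d$votes_b)
  d[, genome := fcase(
    mapped == 0L, "UNMAPPED",
    inf == 0L, "N",
    top / inf >= threshold, fifelse(votes_a >= votes_b, "A", "B"),
    default = "N")]
  d[, criterion := fcase(
    mapped == 0L, "NONE_MAPPED",
    inf == 0L, "NO_SNPS",
    top / inf >= threshold, "MATCHES",
    default = "CONFLICT")]
  decisions <- d[, .(qname, genome, criterion, votes_a, votes_b)]
  summary <- list(mapped = sum(d$mapped > 0L),
                  cat_a = sum(d$genome == "A"),
                  cat_b = sum(d$genome == "B"),
                  n = sum(d$genome == "N"))
  list(decisions = decisions[], summary = summary)
}
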