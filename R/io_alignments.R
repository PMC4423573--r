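#' Alignment tables
#'
#' Alignments are held in a `data.table` with one row per SAM record and
#' columns `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`, `nm`,
#' `md`. Unmapped records have `rname`/`pos`/`cigar` set to `NA` and the
#' 0x4 flag bit set. Coordinates are 1-based fully closed, as in SAM.
#'
#' @param qname read names.
#' @param flag integer SAM flags.
#' @param rname reference sequence names (`NA` if unmapped).
#' @param pos 1-based leftmost mapping positions (`NA` if unmapped).
#' @param mapq mapping qualities (0-255).
#' @param cigar CIGAR strings (`NA` if unmapped).
#' @param seq read sequences.
#' @param nm edit distances (NM: mismatches + inserted + deleted bases), or
#'   `NA` when unknown.
#' @param md MD tags, or `NA` when unknown.
#' @return a `data.table` of class `alignment_table`.
#' @export
alignment_table <- function(qname = character(), flag = integer(),
                            rname = NA_character_, pos = NA_integer_,
                            mapq = 0L, cigar = NA_character_,
                            seq = character(), nm = NA_integer_,
                            md = NA_character_) {
  aln <- data.table(
    qname = as.character(qname), flag = as.integer(flag),
    rname = as.character(rname), pos = as.integer(pos),
    mapq = as.integer(mapq), cigar = as.character(cigar),
    seq = as.character(seq), nm = as.integer(nm), md = as.character(md)
  )
  validate_alignment_table(aln)
}

validate_alignment_table <- function(aln) {
  stopifnot(is.data.table(aln))
  need <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "nm", "md")
  miss <- setdiff(need, names(aln))
  if (length(miss))
    stop("alignment table is missing columns: ", paste(miss, collapse = ", "))
  mapped <- !has_flag(aln$flag, FLAG_UNMAPPED)
  if (any(mapped & (is.na(aln$rname) | is.na(aln$pos) | is.na(aln$cigar))))
    stop("mapped records must have rname, pos and cigar")
  if (nrow(aln)) {
    qw <- cigar_query_width(aln$cigar[mapped])
    bad <- which(qw != nchar(aln$seq[mapped]))
    if (length(bad))
      stop("CIGAR query width disagrees with sequence length for read(s): ",
           paste(head(aln$qname[mapped][bad], 3), collapse = ", "))
  }
  setattr(aln, "class", unique(c("alignment_table", class(aln))))
  aln[]
}

is_mapped <- function(aln) !has_flag(aln$flag, FLAG_UNMAPPED)

is_primary <- function(aln) {
  !has_flag(aln$flag, FLAG_SECONDARY) & !has_flag(aln$flag, FLAG_SUPPLEMENTARY)
}

# mate slot: 1, 2, or 0 for unpaired
mate_of <- function(aln) {
  fifelse(has_flag(aln$flag, FLAG_READ1), 1L,
          fifelse(has_flag(aln$flag, FLAG_READ2), 2L, 0L))
}

# query bases consumed by the CIGAR (M/=/X/I/S), vectorized
cigar_query_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar,
                                               after.soft.clipping = FALSE)
}

#' Per-alignment match statistics
#'
#' Computes, for each mapped record, the number of read bases aligned to the
#' reference (`aligned_bases`: bases under M/=/X operations; soft clips are
#' excluded) and the exact-match score `match_score = aligned_bases - NM`,
#' so that every mismatch, inserted base and deleted base is penalized as
#' one mismatch. The edit distance is taken from the NM tag when present,
#' recomputed from the MD tag otherwise, or recomputed against a supplied
#' reference as a last resort. When both NM and MD are present and
#' disagree, NM wins with a warning.
#'
#' @param aln an [alignment_table()].
#' @param reference optional named `DNAStringSet` for rescoring records that
#'   carry neither NM nor MD.
#' @return `aln` with columns `aligned_bases` and `match_score` added
#'   (`NA` for unmapped records).
#' @export
alignment_stats <- function(aln, reference = NULL) {
  aln <- copy(validate_alignment_table(aln))
  mapped <- is_mapped(aln)
  ab <- rep(NA_integer_, nrow(aln))
  if (any(mapped)) {
    ab[mapped] <- vapply(
      GenomicAlignments::explodeCigarOpLengths(aln$cigar[mapped],
                                               ops = c("M", "=", "X")),
      function(x) sum(x), integer(1))
  }
  nm <- aln$nm
  need <- mapped & is.na(nm) & !is.na(aln$md)
  if (any(need))
    nm[need] <- nm_from_md(aln$cigar[need], aln$md[need])
  check <- mapped & !is.na(aln$nm) & !is.na(aln$md)
  if (any(check)) {
    nm_md <- nm_from_md(aln$cigar[check], aln$md[check])
    bad <- which(nm_md != aln$nm[check])
    if (length(bad))
      warning("NM and MD disagree for read(s) ",
              paste(head(aln$qname[check][bad], 3), collapse = ", "),
              "; keeping NM")
  }
  need <- mapped & is.na(nm)
  if (any(need)) {
    if (is.null(reference))
      stop("cannot score read(s) ",
           paste(head(aln$qname[need], 3), collapse = ", "),
           ": no NM tag, no MD tag, and no reference supplied")
    nm[need] <- nm_from_reference(aln[need], reference)
  }
  set(aln, j = "nm", value = nm)
  set(aln, j = "aligned_bases", value = ab)
  set(aln, j = "match_score", value = fifelse(mapped, ab - nm, NA_integer_))
  aln[]
}

# NM from MD + CIGAR: mismatch letters in MD (outside ^-deletions) plus
# inserted and deleted bases from the CIGAR.
nm_from_md <- function(cigar, md) {
  indel <- vapply(
    GenomicAlignments::explodeCigarOpLengths(cigar, ops = c("I", "D")),
    function(x) sum(x), integer(1))
  mism <- vapply(md, function(m) {
    toks <- regmatches(m, gregexpr("\\^[ACGTN]+|[ACGTN]|[0-9]+", m))[[1]]
    sum(nchar(toks) == 1L & toks %in% c("A", "C", "G", "T", "N"))
  }, integer(1), USE.NAMES = FALSE)
  mism + indel
}

# NM by direct comparison against the reference, honoring the CIGAR
nm_from_reference <- function(aln, reference) {
  stopifnot(!is.null(names(reference)))
  vapply(seq_len(nrow(aln)), function(i) {
    r <- aln[i]
    refseq <- reference[[r$rname]]
    ops <- GenomicAlignments::explodeCigarOps(r$cigar)[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(r$cigar)[[1]]
    qpos <- 1L; rpos <- r$pos; nm <- 0L
    for (j in seq_along(ops)) {
      op <- ops[j]; len <- lens[j]
      if (op %in% c("M", "=", "X")) {
        rd <- substring(r$seq, qpos, qpos + len - 1L)
        rf <- as.character(Biostrings::subseq(refseq, rpos, rpos + len - 1L))
        nm <- nm + sum(strsplit(rd, "")[[1]] != strsplit(rf, "")[[1]])
        qpos <- qpos + len; rpos <- rpos + len
      } else if (op %in% c("I", "S")) {
        if (op == "I") nm <- nm + len
        qpos <- qpos + len
      } else if (op %in% c("D", "N")) {
        if (op == "D") nm <- nm + len
        rpos <- rpos + len
      } else if (op == "H") {
        # hard clip consumes nothing
      } else stop("unsupported CIGAR op: ", op)
    }
    nm
  }, integer(1))
}

#' Collate two mappings of the same read set into fragments
#'
#' Pairs up, by read name, the alignments of each read/fragment against two
#' references. Secondary and supplementary records are skipped; a read name
#' absent from one stream (its mapper may omit unmapped reads) yields a
#' fragment unmapped on that side. Mates of a pair are pooled: the fragment
#' stats on each reference are the sums over its mapped mates.
#'
#' @param aln_a,aln_b [alignment_table()]s of the same read set mapped to
#'   reference A and reference B. If `aligned_bases`/`match_score` are not
#'   yet present they are computed via [alignment_stats()].
#' @param reference_a,reference_b optional references forwarded to
#'   [alignment_stats()].
#' @return a `data.table` with one row per fragment: `qname`, and per side
#'   `mapped_a`/`mapped_b` (number of mapped mates), `mapq_a`, `len_a`,
#'   `score_a` (and `_b`): sums over mapped mates, 0 when unmapped.
#' @export
collate_fragments <- function(aln_a, aln_b,
                              reference_a = NULL, reference_b = NULL) {
  fa <- fragment_side(aln_a, reference_a)
  fb <- fragment_side(aln_b, reference_b)
  out <- merge(fa, fb, by = "qname", all = TRUE, suffixes = c("_a", "_b"))
  for (col in setdiff(names(out), "qname"))
    set(out, which(is.na(out[[col]])), col, 0L)
  setkey(out, qname)
  out[]
}

# per-reference fragment aggregation with duplicate-primary detection
fragment_side <- function(aln, reference = NULL) {
  aln <- validate_alignment_table(aln)
  aln <- aln[is_primary(aln)]
  dup <- aln[, .N, by = .(qname, mate = mate_of(aln))][N > 1L]
  if (nrow(dup))
    stop("duplicate primary records in one stream for read(s): ",
         paste(head(unique(dup$qname), 3), collapse = ", "),
         " (mapper must emit one primary per read)")
  if (!all(c("aligned_bases", "match_score") %in% names(aln)))
    aln <- alignment_stats(aln, reference)
  m <- is_mapped(aln)
  aln[, .(mapped = sum(m[.I]),
          mapq = sum(fifelse(m[.I], mapq, 0L)),
          len = sum(fifelse(m[.I], aligned_bases, 0L), na.rm = TRUE),
          score = sum(fifelse(m[.I], match_score, 0L), na.rm = TRUE)),
      by = qname]
}

#' Single-fragment view
#'
#' Builds the per-reference summary of one fragment from its (up to two)
#' primary alignment records, for use with [categorize_fragment()].
#'
#' @param aln an [alignment_table()] holding the records of one read name on
#'   one reference (possibly none).
#' @param reference optional reference for rescoring.
#' @return a list with `qname`, `any_mapped`, `mapped`, `mapq`, `len`,
#'   `score`.
#' @export
fragment_view <- function(aln, reference = NULL) {
  if (nrow(aln) == 0L)
    return(list(qname = NA_character_, any_mapped = FALSE, mapped = 0L,
                mapq = 0L, len = 0L, score = 0L))
  if (uniqueN(aln$qname) != 1L)
    stop("fragment_view expects records of a single read name")
  f <- fragment_side(aln, reference)
  list(qname = f$qname, any_mapped = f$mapped > 0L, mapped = f$mapped,
       mapq = f$mapq, len = f$len, score = f$score)
}

#' Write four-way categorized alignment files
#'
#' Splits the two input alignment streams by fragment decision and writes,
#' per reference, one file of A-fragment records, one of B-fragment
#' records, one N sink and one unmapped sink, i.e.
#' `<prefix>.<A|B|N>.on<A|B>.<ext>` plus `<prefix>.unmapped.on<A|B>.<ext>`.
#' Only records mapped on a given reference are written to that
#' reference's A/B/N files, so per reference the A/B/N record counts sum to
#' the mapped input record count.
#'
#' @param aln_a,aln_b the per-reference [alignment_table()]s.
#' @param decisions a decision table from [categorize_dualref()] (columns
#'   `qname`, `genome`, `criterion`).
#' @param prefix output path prefix.
#' @param sq_a,sq_b named integer vectors of reference sequence lengths for
#'   the SAM headers.
#' @param format `"sam"` or `"bam"`.
#' @return invisibly, a named character vector of the files written.
#' @export
write_categorized <- function(aln_a, aln_b, decisions, prefix,
                              sq_a, sq_b, format = c("sam", "bam")) {
  format <- match.arg(format)
  dec <- decisions[, .(qname, genome)]
  out <- character()
  for (side in c("A", "B")) {
    aln <- if (side == "A") aln_a else aln_b
    sq <- if (side == "A") sq_a else sq_b
    aln <- validate_alignment_table(aln)[is_primary(aln)]
    g <- dec[match(aln$qname, qname), genome]
    g[is.na(g)] <- "UNMAPPED"
    for (lab in c("A", "B", "N")) {
      path <- sprintf("%s.%s.on%s.%s", prefix, lab, side, format)
      write_alignments(aln[g == lab & is_mapped(aln)], path, sq)
      out[paste0(lab, ".on", side)] <- path
    }
    path <- sprintf("%s.unmapped.on%s.%s", prefix, side, format)
    write_alignments(aln[g == "UNMAPPED" | !is_mapped(aln)], path, sq)
    out[paste0("unmapped.on", side)] <- path
  }
  invisible(out)
}

#' Write an alignment table as SAM or BAM
#'
#' @param aln an [alignment_table()].
#' @param path output path; a `.bam` suffix triggers BAM conversion via
#'   Rsamtools.
#' @param sq named integer vector: reference sequence lengths.
#' @return invisibly, `path`.
#' @export
write_alignments <- function(aln, path, sq) {
  aln <- validate_alignment_table(aln)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)),
              "@PG\tID:homeoSort\tPN:homeoSort")
  m <- is_mapped(aln)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  aln$qname, aln$flag,
                  fifelse(m, aln$rname, "*"),
                  fifelse(m, aln$pos, 0L),
                  aln$mapq,
                  fifelse(m, aln$cigar, "*"),
                  aln$seq)
  tag <- fifelse(m & !is.na(aln$nm), sprintf("\tNM:i:%d", aln$nm), "")
  tag <- paste0(tag, fifelse(m & !is.na(aln$md),
                             sprintf("\tMD:Z:%s", aln$md), ""))
  body <- paste0(body, tag)
  if (grepl("\\.bam$", path)) {
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp))
    writeLines(c(header, body), tmp)
    Rsamtools::asBam(tmp, sub("\\.bam$", "", path), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' SAM text is parsed directly; BAM goes through [Rsamtools::scanBam()].
#' Only the fields the categorizers need are retained (see
#' [alignment_table()]); NM and MD tags are picked up when present.
#'
#' @param path a `.sam` or `.bam` file.
#' @return an [alignment_table()].
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path)) {
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
      tag = c("NM", "MD"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    return(alignment_table(
      qname = b$qname, flag = b$flag, rname = as.character(b$rname),
      pos = b$pos, mapq = fifelse(is.na(b$mapq), 0L, as.integer(b$mapq)),
      cigar = b$cigar, seq = as.character(b$seq),
      nm = as.integer(b$tag$NM %||% rep(NA_integer_, length(b$qname))),
      md = as.character(b$tag$MD %||% rep(NA_character_, length(b$qname)))))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(alignment_table())
  f <- strsplit(lines, "\t", fixed = TRUE)
  grab_tag <- function(x, key) {
    hit <- x[startsWith(x, key)]
    if (length(hit)) sub(key, "", hit[1]) else NA_character_
  }
  alignment_table(
    qname = vapply(f, `[`, "", 1L),
    flag = as.integer(vapply(f, `[`, "", 2L)),
    rname = {
      r <- vapply(f, `[`, "", 3L); r[r == "*"] <- NA; r
    },
    pos = {
      p <- as.integer(vapply(f, `[`, "", 4L)); p[p == 0L] <- NA; p
    },
    mapq = as.integer(vapply(f, `[`, "", 5L)),
    cigar = {
      cg <- vapply(f, `[`, "", 6L); cg[cg == "*"] <- NA; cg
    },
    seq = vapply(f, `[`, "", 10L),
    nm = as.integer(vapply(f, function(x) grab_tag(x, "NM:i:"), "")),
    md = vapply(f, function(x) grab_tag(x, "MD:Z:"), ""))
}
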