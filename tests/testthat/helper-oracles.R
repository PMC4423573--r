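# Brute-force reimplementations, deliberately simple and independent of
# the package internals: plain character walks, no Biostrings, no
# vectorization. Used to freeze expected values and for the randomized
# oracle-equivalence suites.

# per-alignment stats by walking the CIGAR against the reference strings
oracle_stats <- function(seq, cigar, pos, ref) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  qi <- 1L; ri <- pos
  aligned <- 0L; nm <- 0L
  for (t in toks) {
    len <- as.integer(sub("[A-Z=]$", "", t))
    op <- sub("^[0-9]+", "", t)
    if (op %in% c("M", "=", "X")) {
      for (j in seq_len(len)) {
        aligned <- aligned + 1L
        if (substring(seq, qi, qi) != substring(ref, ri, ri)) nm <- nm + 1L
        qi <- qi + 1L; ri <- ri + 1L
      }
    } else if (op == "I") {
      nm <- nm + len; qi <- qi + len
    } else if (op == "S") {
      qi <- qi + len
    } else if (op %in% c("D", "N")) {
      if (op == "D") nm <- nm + len
      ri <- ri + len
    }
  }
  list(aligned = aligned, nm = nm, score = aligned - nm)
}

# read base over a reference position, by explicit per-base walk
oracle_base_at <- function(seq, cigar, pos, ref_pos) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  qi <- 1L; ri <- pos
  for (t in toks) {
    len <- as.integer(sub("[A-Z=]$", "", t))
    op <- sub("^[0-9]+", "", t)
    if (op %in% c("M", "=", "X")) {
      for (j in seq_len(len)) {
        if (ri == ref_pos) return(substring(seq, qi, qi))
        qi <- qi + 1L; ri <- ri + 1L
      }
    } else if (op %in% c("I", "S")) {
      qi <- qi + len
    } else if (op %in% c("D", "N")) {
      for (j in seq_len(len)) {
        if (ri == ref_pos) return(NA_character_)
        ri <- ri + 1L
      }
    }
  }
  NA_character_
}

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(map[strsplit(x, "")[[1]]])), collapse = "")
}

# exhaustive gapless mapper: every start position, both strands
oracle_map <- function(read, ref, max_mm) {
  w <- nchar(read)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read else oracle_revcomp(read)
    sc <- strsplit(s, "")[[1]]
    for (p in seq_len(nchar(ref) - w + 1L)) {
      mm <- sum(sc != strsplit(substring(ref, p, p + w - 1L), "")[[1]])
      hits[[length(hits) + 1L]] <- list(pos = p, strand = strand, mm = mm)
    }
  }
  mms <- vapply(hits, `[[`, 0, "mm")
  mn <- min(mms)
  if (mn > max_mm || sum(mms == mn) > 1L) return(NULL)
  hits[[which(mms == mn)]]
}

# rebuild the reference window of a gapless alignment from seq + MD
nm_md_reconstruct <- function(seq, md) {
  toks <- regmatches(md, gregexpr("[0-9]+|[ACGTN]", md))[[1]]
  out <- character(0)
  qi <- 1L
  for (t in toks) {
    if (grepl("^[0-9]", t)) {
      n <- as.integer(t)
      if (n > 0L) {
        out <- c(out, substring(seq, qi, qi + n - 1L))
        qi <- qi + n
      }
    } else {
      out <- c(out, t)
      qi <- qi + 1L
    }
  }
  paste(out, collapse = "")
}

# the serial four-criterion rule, as a plain if/else chain
oracle_categorize <- function(va, vb) {
  if (!va$mapped && !vb$mapped)
    return(list(genome = "UNMAPPED", criterion = "NONE_MAPPED"))
  if (va$mapped && !vb$mapped)
    return(list(genome = "A", criterion = "UNIQUE_MAPPING"))
  if (!va$mapped && vb$mapped)
    return(list(genome = "B", criterion = "UNIQUE_MAPPING"))
  if (va$mapq != vb$mapq)
    return(list(genome = if (va$mapq > vb$mapq) "A" else "B",
                criterion = "MAPQ"))
  if (va$len != vb$len)
    return(list(genome = if (va$len > vb$len) "A" else "B",
                criterion = "ALIGN_LENGTH"))
  if (va$score != vb$score)
    return(list(genome = if (va$score > vb$score) "A" else "B",
                criterion = "MATCHES"))
  list(genome = "N", criterion = "TIE")
}
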