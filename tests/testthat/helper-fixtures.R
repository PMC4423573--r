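library(data.table)

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# one-row alignment table, mapped by default
rec <- function(qname = "r1", seq = "ACGT", cigar = paste0(nchar(seq), "M"),
                pos = 1L, rname = "chr1", mapq = 40L, nm = NA_integer_,
                md = NA_character_, flag = 0L, mapped = TRUE) {
  if (!mapped) flag <- bitwOr(as.integer(flag), 4L)
  alignment_table(qname = qname, flag = flag,
                  rname = if (mapped) rname else NA_character_,
                  pos = if (mapped) pos else NA_integer_,
                  mapq = mapq, cigar = if (mapped) cigar else NA_character_,
                  seq = seq, nm = nm, md = md)
}

# Random gapless-plus-indel alignment built by construction: returns the
# record, the reference it was built from, and the true per-op layout so
# oracles can verify stats and per-position bases independently.
random_alignment <- function(max_ref = 200L) {
  ref_len <- sample(60:max_ref, 1L)
  ref <- rand_seq(ref_len)
  pos <- sample(1:(ref_len - 50L), 1L)
  ops <- list()
  rpos <- pos
  n_blocks <- sample(1:3, 1L)
  for (b in seq_len(n_blocks)) {
    mlen <- sample(5:15, 1L)
    if (rpos + mlen - 1L > ref_len) break
    ops[[length(ops) + 1L]] <- list(op = "M", len = mlen)
    rpos <- rpos + mlen
    if (b < n_blocks) {
      if (runif(1) < 0.5) {
        dlen <- sample(1:3, 1L)
        if (rpos + dlen - 1L > ref_len) break
        ops[[length(ops) + 1L]] <- list(op = "D", len = dlen)
        rpos <- rpos + dlen
      } else {
        ops[[length(ops) + 1L]] <- list(op = "I", len = sample(1:3, 1L))
      }
    }
  }
  # assemble read: copy M blocks from ref (with random substitutions),
  # random bases for I; optionally soft-clip both ends
  seq <- character(0)
  rpos <- pos
  nm <- 0L
  for (o in ops) {
    if (o$op == "M") {
      block <- strsplit(substring(ref, rpos, rpos + o$len - 1L), "")[[1]]
      subs <- which(runif(o$len) < 0.1)
      for (s in subs) {
        old <- block[s]
        block[s] <- sample(setdiff(BASES, old), 1L)
        nm <- nm + 1L
      }
      seq <- c(seq, block)
      rpos <- rpos + o$len
    } else if (o$op == "D") {
      nm <- nm + o$len
      rpos <- rpos + o$len
    } else {
      seq <- c(seq, sample(BASES, o$len, replace = TRUE))
      nm <- nm + o$len
    }
  }
  sc_left <- sample(0:3, 1L)
  sc_right <- sample(0:3, 1L)
  cigar <- paste0(
    if (sc_left) paste0(sc_left, "S") else "",
    paste0(vapply(ops, function(o) paste0(o$len, o$op), ""), collapse = ""),
    if (sc_right) paste0(sc_right, "S") else "")
  seq <- paste(c(sample(BASES, sc_left, TRUE), seq,
                 sample(BASES, sc_right, TRUE)), collapse = "")
  list(rec = rec(seq = seq, cigar = cigar, pos = pos, nm = nm),
       ref = ref, ops = ops, pos = pos, nm = nm)
}

# small shared simulation for pipeline-level tests (computed once per run)
tiny_sim_cache <- new.env()
tiny_pipeline <- function() {
  if (!is.null(tiny_sim_cache$res)) return(tiny_sim_cache$res)
  cfg <- sim_config(ancestor_length = 20000L, n_fragments = 600L,
                    unique_segment_length = 1000L, error_rate = 0,
                    seed = 42L)
  sim <- evolve_genomes(cfg)
  rs <- simulate_reads(sim)
  aln_a <- naive_map(rs, sim$genome_a)
  aln_b <- naive_map(rs, sim$genome_b)
  frags <- collate_fragments(aln_a, aln_b)
  tiny_sim_cache$res <- list(cfg = cfg, sim = sim, rs = rs,
                             aln_a = aln_a, aln_b = aln_b, frags = frags)
  tiny_sim_cache$res
}
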