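#' Simulation configuration
#'
#' The generator models the setting the categorizers are built for: a
#' common ancestor sequence diverging into two genomes by substitutions and
#' small indels, with a fraction of each genome replaced by novel
#' genome-unique segments (mimicking the large species-specific tracts of
#' real subgenomes), then paired-end short reads drawn from the genomes
#' with uniform sequencing error and a truth label per fragment.
#'
#' `substitution_rate` is the expected pairwise substitution divergence
#' between the two genomes; each lineage mutates independently at half that
#' rate. The defaults are a desk-scale echo of a diverged-but-collinear
#' allotetraploid: 200 kb ancestor, 2% substitution divergence, 0.1%
#' indels, 5% unique segments, 100 bp paired reads.
#'
#' @param ancestor_length ancestor length in bp.
#' @param substitution_rate expected pairwise substitution divergence.
#' @param indel_rate per-base probability of initiating an indel event per
#'   lineage.
#' @param indel_max_len maximum indel length (lengths uniform on
#'   `1:indel_max_len`).
#' @param unique_fraction fraction of each genome replaced by novel
#'   genome-unique segments.
#' @param unique_segment_length length of each unique segment, bp.
#' @param n_fragments number of sequenced fragments.
#' @param read_length read length, bp.
#' @param insert_mean,insert_sd fragment (insert) size distribution, bp.
#' @param error_rate per-base sequencing error probability.
#' @param source which genome fragments are drawn from: `"both"`
#'   (length-proportional) or a single genome, for diploid-style error
#'   analysis.
#' @param seed integer seed; fully determines all outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(ancestor_length = 200000L, substitution_rate = 0.02,
                       indel_rate = 0.001, indel_max_len = 6L,
                       unique_fraction = 0.05, unique_segment_length = 2000L,
                       n_fragments = 2000L, read_length = 100L,
                       insert_mean = 300L, insert_sd = 30L,
                       error_rate = 0.001, source = c("both", "A", "B"),
                       seed = 1L) {
  source <- match.arg(source)
  cfg <- list(ancestor_length = as.integer(ancestor_length),
              substitution_rate = substitution_rate,
              indel_rate = indel_rate,
              indel_max_len = as.integer(indel_max_len),
              unique_fraction = unique_fraction,
              unique_segment_length = as.integer(unique_segment_length),
              n_fragments = as.integer(n_fragments),
              read_length = as.integer(read_length),
              insert_mean = as.integer(insert_mean),
              insert_sd = as.integer(insert_sd),
              error_rate = error_rate, source = source,
              seed = as.integer(seed))
  rates <- c(cfg$substitution_rate, cfg$indel_rate, cfg$unique_fraction,
             cfg$error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$substitution_rate / 2 + cfg$indel_rate > 1)
    stop("rates imply more than one expected mutation per base")
  if (cfg$read_length > cfg$insert_mean)
    stop("read_length must not exceed insert_mean")
  structure(cfg, class = "sim_config")
}

# mutate one lineage: substitutions at rate/2, indel events at indel_rate.
# Returns the genome string, the per-base ancestor->genome coordinate map
# (NA where deleted) and the post-substitution base vector.
evolve_lineage <- function(anc, cfg) {
  L <- length(anc)
  base <- anc
  sub_at <- which(runif(L) < cfg$substitution_rate / 2)
  if (length(sub_at)) {
    shift <- sample.int(3L, length(sub_at), replace = TRUE)
    cur <- match(anc[sub_at], DNA_BASES)
    base[sub_at] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  keep <- rep(TRUE, L)
  ins_after <- character(L)
  ev <- which(runif(L) < cfg$indel_rate)
  if (length(ev)) {
    lens <- sample.int(cfg$indel_max_len, length(ev), replace = TRUE)
    is_ins <- runif(length(ev)) < 0.5
    for (j in seq_along(ev)) {
      p <- ev[j]
      if (is_ins[j]) {
        ins_after[p] <- paste(sample(DNA_BASES, lens[j], TRUE), collapse = "")
      } else {
        keep[p:min(p + lens[j] - 1L, L)] <- FALSE
      }
    }
  }
  ins_len <- nchar(ins_after)
  coord <- cumsum(keep) + c(0L, head(cumsum(ins_len), -1L))
  coord[!keep] <- NA_integer_
  parts <- ifelse(keep, base, "")
  has_ins <- which(ins_len > 0L)
  parts[has_ins] <- paste0(parts[has_ins], ins_after[has_ins])
  list(genome = paste(parts, collapse = ""), coord = coord, base = base,
       keep = keep)
}

#' Evolve two genomes from a common ancestor
#'
#' Applies independent substitutions and indels to two copies of a random
#' ancestor, then overwrites disjoint segments of each genome with novel
#' random sequence (the genome-unique tracts). Every substitution
#' difference between the genomes that survives in the homoeologous
#' (non-unique, non-deleted) portion is reported with its coordinates
#' projected onto both genomes — the ground-truth homoeo-SNP table.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `homeo_sim`: `genome_a`/`genome_b` (named
#'   `DNAStringSet`s, single sequence `chr1`), `truth_snps` (a
#'   `data.table`: `anc_pos`, `pos_a`, `pos_b`, `allele_a`, `allele_b`),
#'   `unique_segments` (`genome`, `start`, `end` in that genome's
#'   coordinates), and `config`.
#' @export
evolve_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_fixed_seed(cfg$seed, {
    L <- cfg$ancestor_length
    anc <- sample(DNA_BASES, L, replace = TRUE)
    lin_a <- evolve_lineage(anc, cfg)
    lin_b <- evolve_lineage(anc, cfg)

    seg_len <- cfg$unique_segment_length
    n_seg <- round(cfg$unique_fraction * L / seg_len)
    seg <- data.table(genome = character(), start = integer(),
                      end = integer(), anc_start = integer(),
                      anc_end = integer())
    ga <- lin_a$genome
    gb <- lin_b$genome
    if (n_seg > 0L) {
      starts <- seq(1L, L - seg_len + 1L, by = seg_len)
      if (length(starts) < 2L * n_seg)
        stop("ancestor too short for the requested unique segments")
      picked <- sort(sample(starts, 2L * n_seg))
      owner <- sample(rep(c("A", "B"), n_seg))
      for (j in seq_along(picked)) {
        s <- picked[j]; e <- s + seg_len - 1L
        lin <- if (owner[j] == "A") lin_a else lin_b
        gpos <- lin$coord[s:e]
        gs <- min(gpos, na.rm = TRUE); ge <- max(gpos, na.rm = TRUE)
        novel <- paste(sample(DNA_BASES, ge - gs + 1L, TRUE), collapse = "")
        if (owner[j] == "A") substr(ga, gs, ge) <- novel
        else substr(gb, gs, ge) <- novel
        seg <- rbind(seg, data.table(genome = owner[j], start = gs,
                                     end = ge, anc_start = s, anc_end = e))
      }
    }

    in_unique <- rep(FALSE, L)
    for (j in seq_len(nrow(seg)))
      in_unique[seg$anc_start[j]:seg$anc_end[j]] <- TRUE
    diff_at <- which(lin_a$base != lin_b$base & lin_a$keep & lin_b$keep &
                       !in_unique)
    truth <- data.table(anc_pos = diff_at,
                        pos_a = lin_a$coord[diff_at],
                        pos_b = lin_b$coord[diff_at],
                        allele_a = lin_a$base[diff_at],
                        allele_b = lin_b$base[diff_at])

    genome_a <- Biostrings::DNAStringSet(ga); names(genome_a) <- "chr1"
    genome_b <- Biostrings::DNAStringSet(gb); names(genome_b) <- "chr1"
    structure(list(genome_a = genome_a, genome_b = genome_b,
                   truth_snps = truth,
                   unique_segments = seg[, .(genome, start, end)],
                   config = cfg),
              class = "homeo_sim")
  })
}

#' Ground-truth homoeo-SNP index on one reference
#'
#' Projects the simulator's true substitution differences onto the chosen
#' reference's coordinates as a [snp_index()] (`alleleA` is always the
#' genome-A base, `alleleB` the genome-B base).
#'
#' @param sim a `homeo_sim` from [evolve_genomes()].
#' @param reference which genome the index positions refer to.
#' @return a [snp_index()].
#' @export
truth_snp_index <- function(sim, reference = c("A", "B")) {
  reference <- match.arg(reference)
  pos <- if (reference == "A") sim$truth_snps$pos_a else sim$truth_snps$pos_b
  snp_index(data.table(chrom = "chr1", pos = pos,
                       alleleA = sim$truth_snps$allele_a,
                       alleleB = sim$truth_snps$allele_b))
}

#' Simulate labeled paired-end reads
#'
#' Draws fragments uniformly from the two genomes in proportion to their
#' lengths (or from a single genome), takes a read from each fragment end,
#' and applies uniform per-base substitution error. Read names carry no
#' information about the genome of origin; truth lives only in the
#' returned table.
#'
#' @param sim a `homeo_sim` from [evolve_genomes()].
#' @param cfg optional [sim_config()] overriding `sim$config` (read/insert
#'   geometry, error rate, fragment count, source genome).
#' @param seed seed for the read-level randomness; defaults to
#'   `config seed + 1` so genome evolution and sequencing draw independent
#'   streams.
#' @return a list of class `read_set`: `reads` (a `data.table`: `qname`,
#'   `mate`, `seq`) and `truth` (`qname`, `genome`, `start`, `insert`).
#' @export
simulate_reads <- function(sim, cfg = NULL, seed = NULL) {
  cfg <- cfg %||% sim$config
  seed <- seed %||% (cfg$seed + 1L)
  with_fixed_seed(seed, {
    rl <- cfg$read_length
    n <- cfg$n_fragments
    ga <- as.character(sim$genome_a[[1]])
    gb <- as.character(sim$genome_b[[1]])
    len <- c(A = nchar(ga), B = nchar(gb))
    genome <- switch(cfg$source,
                     both = sample(c("A", "B"), n, replace = TRUE,
                                   prob = len / sum(len)),
                     A = rep("A", n), B = rep("B", n))
    insert <- pmax(rl, as.integer(round(rnorm(n, cfg$insert_mean,
                                              cfg$insert_sd))))
    insert <- pmin(insert, len[genome])
    start <- as.integer(floor(runif(n) * (len[genome] - insert + 1))) + 1L
    src <- ifelse(genome == "A", ga, gb)
    r1 <- substring(src, start, start + rl - 1L)
    r2 <- revcomp_chr(substring(src, start + insert - rl, start + insert - 1L))
    reads <- c(r1, r2)
    if (cfg$error_rate > 0) {
      hit <- which(runif(2L * n * rl) < cfg$error_rate)
      for (h in hit) {
        i <- (h - 1L) %/% rl + 1L
        o <- (h - 1L) %% rl + 1L
        cur <- substr(reads[i], o, o)
        substr(reads[i], o, o) <-
          sample(setdiff(DNA_BASES, cur), 1L)
      }
    }
    qname <- sprintf("frag%06d", seq_len(n))
    structure(list(
      reads = data.table(qname = rep(qname, 2L),
                         mate = rep(c(1L, 2L), each = n),
                         seq = reads),
      truth = data.table(qname = qname, genome = genome,
                         start = start, insert = insert)),
      class = "read_set")
  })
}

#' Write a read set as FASTQ
#'
#' @param rs a `read_set` from [simulate_reads()].
#' @param r1_path,r2_path output FASTQ paths (uncompressed).
#' @return invisibly, the two paths.
#' @export
write_fastq <- function(rs, r1_path, r2_path) {
  for (m in 1:2) {
    rd <- rs$reads[mate == m]
    writeLines(paste0("@", rd$qname, "/", m, "\n", rd$seq, "\n+\n",
                      strrep("I", nchar(rd$seq))),
               if (m == 1L) r1_path else r2_path)
  }
  invisible(c(r1_path, r2_path))
}

#' Naive unique-best read mapper
#'
#' An exhaustive k-mer-seeded, gapless mapper for toy-scale references.
#' Every read is searched on both strands of every reference sequence; a
#' candidate locus is evaluated by its full-length mismatch count. The read
#' is reported only when a single candidate attains the minimum mismatch
#' count and that count is within `max_mismatches` — the unique-best policy
#' of the mappers the categorizers are designed to consume: a read fitting
#' two loci equally well stays unmapped. The default seed length
#' `floor(read_length / (max_mismatches + 1))` yields `max_mismatches + 1`
#' disjoint seeds, so by pigeonhole every gapless locus within
#' `max_mismatches` mismatches is found: for reporting purposes the seeded
#' search is equivalent to an exhaustive scan.
#'
#' @param reads a `read_set`, or a `data.table` with `qname`, `mate`
#'   (1/2/0), `seq`. All reads must share one length.
#' @param reference a named `DNAStringSet` or FASTA path; total length at
#'   most 2 Mbp (hard guard: this mapper is a test fixture, not a tool for
#'   real genomes).
#' @param max_mismatches maximum mismatches of a reported alignment.
#' @param k seed length; `NULL` (default) derives the exhaustive-equivalent
#'   length above.
#' @param mapq MAPQ assigned to every mapped record (the mapper does not
#'   grade its confidence, mirroring mappers that emit one constant score).
#' @return an [alignment_table()] with one record per input read (mapped
#'   records carry CIGAR `<len>M`, NM and MD; minus-strand records store
#'   the reverse-complemented sequence, as in SAM).
#' @export
naive_map <- function(reads, reference, max_mismatches = 6L, k = NULL,
                      mapq = 40L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  reference <- as_reference(reference)
  if (sum(Biostrings::width(reference)) > 2e6)
    stop("reference too large for the exhaustive naive mapper (> 2 Mbp)")
  w <- unique(nchar(reads$seq))
  if (length(w) != 1L)
    stop("naive_map requires equal-length reads")
  k <- k %||% max(4L, w %/% (as.integer(max_mismatches) + 1L))
  k <- min(as.integer(k), w)
  offsets <- unique(c(seq(1L, w - k + 1L, by = k), w - k + 1L))
  nr <- nrow(reads)

  cand <- list()
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") reads$seq else revcomp_chr(reads$seq)
    sset <- Biostrings::DNAStringSet(seqs)
    pat <- do.call(c, lapply(offsets, function(o)
      Biostrings::subseq(sset, o, o + k - 1L)))
    pat_read <- rep(seq_len(nr), times = length(offsets))
    pat_off <- rep(offsets, each = nr)
    ok <- !grepl("[^ACGT]", as.character(pat))
    pd <- Biostrings::PDict(pat[ok])
    for (ci in seq_along(reference)) {
      m <- Biostrings::matchPDict(pd, reference[[ci]])
      nh <- S4Vectors::elementNROWS(m)
      if (sum(nh) == 0L) next
      st <- unlist(Biostrings::startIndex(m), use.names = FALSE)
      pi <- which(ok)[rep(seq_along(nh), nh)]
      cp <- st - pat_off[pi] + 1L
      keep <- cp >= 1L & cp + w - 1L <= Biostrings::width(reference)[ci]
      if (!any(keep)) next
      cand[[length(cand) + 1L]] <- unique(data.table(
        read = pat_read[pi][keep], chrom_i = ci, strand = strand,
        pos = cp[keep]))
    }
  }
  if (length(cand)) {
    cand <- unique(rbindlist(cand))
    # full-length mismatch count per candidate, per (chrom, strand) batch
    cand[, mm := {
      refwin <- as.matrix(Biostrings::extractAt(
        reference[[chrom_i[1]]], IRanges::IRanges(pos, width = w)))
      rs <- if (strand[1] == "+") reads$seq[read]
            else revcomp_chr(reads$seq[read])
      rmat <- matrix(unlist(strsplit(rs, ""), use.names = FALSE),
                     ncol = w, byrow = TRUE)
      as.integer(rowSums(refwin != rmat))
    }, by = .(chrom_i, strand)]
    best <- cand[, {
      mn <- min(mm)
      .(pos = pos[mm == mn][1], chrom_i = chrom_i[mm == mn][1],
        strand = strand[mm == mn][1], mm = mn, n_best = sum(mm == mn))
    }, by = read]
    best <- best[mm <= max_mismatches & n_best == 1L]
  } else {
    best <- data.table(read = integer(), pos = integer(),
                       chrom_i = integer(), strand = character(),
                       mm = integer(), n_best = integer())
  }

  flag <- fifelse(reads$mate == 1L, FLAG_PAIRED + FLAG_READ1,
                  fifelse(reads$mate == 2L, FLAG_PAIRED + FLAG_READ2, 0L))
  out <- data.table(qname = reads$qname, flag = as.integer(flag),
                    rname = NA_character_, pos = NA_integer_, mapq = 0L,
                    cigar = NA_character_, seq = reads$seq,
                    nm = NA_integer_, md = NA_character_)
  mapq_val <- as.integer(mapq)
  if (nrow(best)) {
    i <- best$read
    out[i, `:=`(rname = names(reference)[best$chrom_i],
                pos = best$pos, mapq = mapq_val,
                cigar = paste0(w, "M"), nm = best$mm)]
    minus <- best$strand == "-"
    out[i[minus], flag := flag + FLAG_REVERSE]
    out[i[minus], seq := revcomp_chr(seq)]
    refwin <- character(nrow(best))
    for (ci in unique(best$chrom_i)) {
      j <- which(best$chrom_i == ci)
      refwin[j] <- as.character(Biostrings::extractAt(
        reference[[ci]], IRanges::IRanges(best$pos[j], width = w)))
    }
    out[i, md := md_tag(seq, refwin)]
  }
  out[is.na(rname), flag := flag + FLAG_UNMAPPED]
  validate_alignment_table(out)
}

# MD tag for gapless alignments: match-run lengths interleaved with the
# reference base at each mismatch
md_tag <- function(read, refwin) {
  vapply(seq_along(read), function(i) {
    rd <- strsplit(read[i], "")[[1]]
    rf <- strsplit(refwin[i], "")[[1]]
    mis <- which(rd != rf)
    if (!length(mis)) return(as.character(length(rd)))
    runs <- diff(c(0L, mis)) - 1L
    paste0(paste0(runs, rf[mis], collapse = ""),
           length(rd) - mis[length(mis)])
  }, character(1))
}
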