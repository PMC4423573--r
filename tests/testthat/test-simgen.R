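test_that("sim_config validates its rates and geometry", {
  expect_error(sim_config(substitution_rate = 1.5), "rates")
  expect_error(sim_config(read_length = 400L, insert_mean = 300L),
               "insert_mean")
  expect_s3_class(sim_config(seed = 7L), "sim_config")
})

test_that("zero-rate evolution is the identity", {
  cfg <- sim_config(ancestor_length = 5000L, substitution_rate = 0,
                    indel_rate = 0, unique_fraction = 0, seed = 2L)
  sim <- evolve_genomes(cfg)
  expect_equal(as.character(sim$genome_a), as.character(sim$genome_b),
               ignore_attr = TRUE)
  expect_equal(nrow(sim$truth_snps), 0L)
  expect_equal(nrow(sim$unique_segments), 0L)
})

test_that("a fixed seed reproduces every output byte-identically", {
  cfg <- sim_config(ancestor_length = 10000L, n_fragments = 50L, seed = 99L)
  s1 <- evolve_genomes(cfg); s2 <- evolve_genomes(cfg)
  expect_identical(as.character(s1$genome_a), as.character(s2$genome_a))
  expect_identical(as.character(s1$genome_b), as.character(s2$genome_b))
  expect_identical(s1$truth_snps, s2$truth_snps)
  r1 <- simulate_reads(s1); r2 <- simulate_reads(s2)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  # and the FASTQ bytes
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_fastq(r1, f1, g1); write_fastq(r2, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))
})

test_that("substitution divergence matches the binomial expectation", {
  cfg <- sim_config(ancestor_length = 100000L, substitution_rate = 0.01,
                    indel_rate = 0, unique_fraction = 0, seed = 31L)
  sim <- evolve_genomes(cfg)
  # each site differs when exactly one lineage hits it (or both hit it and
  # land on different bases); p ~= 2*(r/2)*(1-r/2) + (r/2)^2 * 2/3
  r2 <- cfg$substitution_rate / 2
  p <- 2 * r2 * (1 - r2) + r2^2 * 2 / 3
  expected <- cfg$ancestor_length * p
  sd <- sqrt(cfg$ancestor_length * p * (1 - p))
  expect_lt(abs(nrow(sim$truth_snps) - expected), 3 * sd)
  # truth projections index the right bases in each genome
  ga <- as.character(sim$genome_a[[1]]); gb <- as.character(sim$genome_b[[1]])
  with(sim$truth_snps[1:200], {
    expect_equal(substring(ga, pos_a, pos_a), allele_a)
    expect_equal(substring(gb, pos_b, pos_b), allele_b)
  })
})

test_that("unique segments are novel sequence present in one genome only", {
  cfg <- sim_config(ancestor_length = 50000L, unique_fraction = 0.08,
                    unique_segment_length = 1000L, seed = 13L)
  sim <- evolve_genomes(cfg)
  seg <- sim$unique_segments
  # 8% of 50 kb per genome in 1 kb segments: 4 segments in each genome
  expect_equal(unname(table(seg$genome)[c("A", "B")]), c(4L, 4L),
               ignore_attr = TRUE)
  # no true-SNP position falls inside a unique segment
  for (j in seq_len(nrow(seg))) {
    pcol <- if (seg$genome[j] == "A") "pos_a" else "pos_b"
    inside <- sim$truth_snps[[pcol]] >= seg$start[j] &
      sim$truth_snps[[pcol]] <= seg$end[j]
    expect_false(any(inside))
  }
})

test_that("error-free reads are exact substrings of their source genome", {
  cfg <- sim_config(ancestor_length = 20000L, n_fragments = 200L,
                    error_rate = 0, seed = 4L)
  sim <- evolve_genomes(cfg)
  rs <- simulate_reads(sim)
  expect_equal(nrow(rs$truth), 200L)
  expect_equal(nrow(rs$reads), 400L)
  ga <- as.character(sim$genome_a[[1]]); gb <- as.character(sim$genome_b[[1]])
  for (i in sample(nrow(rs$reads), 60L)) {
    rd <- rs$reads[i]
    src <- if (rs$truth[qname == rd$qname, genome] == "A") ga else gb
    hit <- grepl(rd$seq, src, fixed = TRUE) ||
      grepl(oracle_revcomp(rd$seq), src, fixed = TRUE)
    expect_true(hit)
  }
})

test_that("fragments are drawn in proportion to genome length", {
  cfg <- sim_config(ancestor_length = 30000L, n_fragments = 3000L, seed = 8L)
  sim <- evolve_genomes(cfg)
  # genome B twice as long: replace genome_a with its first half
  half <- Biostrings::subseq(sim$genome_a, 1, 15000)
  sim2 <- sim
  sim2$genome_a <- half
  rs <- simulate_reads(sim2)
  p <- 2 / 3
  frac_b <- mean(rs$truth$genome == "B")
  expect_lt(abs(frac_b - p),
            3 * sqrt(p * (1 - p) / cfg$n_fragments))
})

test_that("naive_map reports unique best hits with consistent NM and MD", {
  set.seed(21)
  ref <- Biostrings::DNAStringSet(c(chr1 = rand_seq(3000)))
  refstr <- as.character(ref[[1]])

  # exact substring maps at its locus with NM 0
  reads <- data.table(qname = "e1", mate = 0L,
                      seq = substring(refstr, 501, 560))
  aln <- naive_map(reads, ref, max_mismatches = 3L)
  expect_equal(aln$pos, 501L)
  expect_equal(aln$nm, 0L)
  expect_equal(aln$md, "60")

  # a read occurring identically at two loci stays unmapped
  dup_ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
    refstr, substring(refstr, 501, 560), rand_seq(50))))
  aln <- naive_map(reads, dup_ref, max_mismatches = 3L)
  expect_true(bitwAnd(aln$flag, 4L) > 0L)

  # one mismatch: NM 1, MD consistent with the oracle alignment
  sq <- strsplit(substring(refstr, 501, 560), "")[[1]]
  sq[20] <- sample(setdiff(BASES, sq[20]), 1L)
  aln <- naive_map(data.table(qname = "m1", mate = 0L,
                              seq = paste(sq, collapse = "")),
                   ref, max_mismatches = 3L)
  o <- oracle_map(paste(sq, collapse = ""), refstr, 3L)
  expect_equal(aln$pos, o$pos)
  expect_equal(aln$nm, 1L)
  expect_equal(aln$md, paste0("19", substring(refstr, 520, 520), "40"))

  # reverse-complement placement: stored sequence is reference-oriented
  rc <- oracle_revcomp(substring(refstr, 801, 860))
  aln <- naive_map(data.table(qname = "rc1", mate = 0L, seq = rc), ref,
                   max_mismatches = 3L)
  expect_equal(aln$pos, 801L)
  expect_true(bitwAnd(aln$flag, 16L) > 0L)
  expect_equal(aln$seq, substring(refstr, 801, 860))

  # guard against silently exhaustive runs on real-sized references
  expect_error(naive_map(reads, Biostrings::DNAStringSet(
    c(chr1 = strrep("ACGT", 600000)))), "too large")
})

test_that("mapped records reconstruct the read from the reference", {
  p <- tiny_pipeline()
  aln <- p$aln_a[bitwAnd(flag, 4L) == 0L]
  expect_true(all(aln$mapq == 40L))
  refstr <- as.character(p$sim$genome_a[[1]])
  for (i in sample(nrow(aln), 50L)) {
    r <- aln[i]
    w <- nchar(r$seq)
    window <- substring(refstr, r$pos, r$pos + w - 1L)
    # error-free simulation: NM must be the true mismatch count of the window
    mm <- sum(strsplit(window, "")[[1]] != strsplit(r$seq, "")[[1]])
    expect_equal(r$nm, mm)
    # and MD + seq reconstruct the reference window
    expect_equal(nm_md_reconstruct(r$seq, r$md), window)
  }
})
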