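test_that("SNP index round-trips and is validated with line numbers", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "chr1\t101\tA\tG", "chr2\t5\tC\tT"), path)
  idx <- read_snp_index(path)
  expect_s3_class(idx, "snp_index")
  expect_equal(nrow(idx), 2L)
  expect_equal(idx[chrom == "chr1", .(pos, alleleA, alleleB)],
               data.table(pos = 101L, alleleA = "A", alleleB = "G"),
               ignore_attr = TRUE)

  out <- tempfile(fileext = ".tsv")
  write_snp_index(idx, out)
  expect_equal(read_snp_index(out), idx)

  # duplicate position: error names both lines
  writeLines(c("chr1\t101\tA\tG", "chr1\t102\tC\tT", "chr1\t101\tA\tT"),
             path)
  expect_error(read_snp_index(path), "lines 1 and 3")

  writeLines("chr1\t7\tA\tA", path)
  expect_error(read_snp_index(path), "identical alleles")
  writeLines("chr1\t7\tA\tX", path)
  expect_error(read_snp_index(path), "non-ACGT")
  writeLines("chr1\tseven\tA\tC", path)
  expect_error(read_snp_index(path), "non-numeric")

  writeLines(character(), path)
  empty <- read_snp_index(path)
  expect_equal(nrow(empty), 0L)
  expect_s3_class(empty, "snp_index")
})

test_that("base_at walks M, D and I operations correctly", {
  # 10M starting at 101: direct offset
  r <- rec(seq = "ACGTACGTAC", cigar = "10M", pos = 101L, nm = 0L)
  expect_equal(base_at(r, 105L), "A")

  # deletion: ref positions 104-105 have no read base
  r <- rec(seq = "ACGTACGTAC", cigar = "3M2D7M", pos = 101L, nm = 2L)
  expect_equal(base_at(r, 104L), NA_character_)
  expect_equal(base_at(r, 103L), "G")
  expect_equal(base_at(r, 106L), "T")   # first base after the deletion

  # insertion shifts the read, not the reference
  r <- rec(seq = "ACGTTACGTACG", cigar = "3M2I7M", pos = 101L, nm = 2L)
  expect_equal(base_at(r, 104L), "A")   # read offset 6 after the insertion
  expect_equal(base_at(r, 106L), "G")   # read offset 8

  # outside the span: absent, not an error
  expect_equal(base_at(r, 99L), NA_character_)
  expect_equal(base_at(r, 500L), NA_character_)
})

test_that("base_at agrees with the brute-force walk on random alignments", {
  set.seed(77)
  for (i in 1:150) {
    a <- random_alignment()
    span <- (a$pos - 2L):(a$pos + 40L)
    for (rp in sample(span, 5L))
      expect_identical(base_at(a$rec, rp),
                       oracle_base_at(a$rec$seq, a$rec$cigar, a$pos, rp))
  }
})

test_that("tally_fragment pools mates and classifies bases", {
  idx <- snp_index(data.table(chrom = "chr1", pos = c(3L, 6L, 9L, 12L),
                              alleleA = c("A", "C", "G", "T"),
                              alleleB = c("G", "T", "A", "C")))
  # read covering 1-10 with A-alleles at 3, 6, 9
  r <- rec(seq = "GGAGGCGGGG", cigar = "10M", pos = 1L, nm = 0L)
  t <- tally_fragment(r, idx)
  expect_equal(t$votes_a, 3L)
  expect_equal(t$votes_b, 0L)

  # no overlap with any index position
  r2 <- rec(seq = "GGGG", cigar = "4M", pos = 100L, nm = 0L)
  expect_equal(tally_fragment(r2, idx)$informative, 0L)

  # a base matching neither allele is uninformative, not a vote
  r3 <- rec(seq = "GGAGGCGGTG", cigar = "10M", pos = 1L, nm = 0L)
  t <- tally_fragment(r3, idx)
  expect_equal(t$informative, 2L)
  expect_equal(t$uninformative, 1L)

  # mates pooled: each mate's base votes independently
  pair <- rbind(rec(seq = "GGAGGC", cigar = "6M", pos = 1L, nm = 0L,
                    flag = 0x41L),
                rec(seq = "CGGGGGT", cigar = "7M", pos = 6L, nm = 0L,
                    flag = 0x81L))
  t <- tally_fragment(pair, idx)
  expect_equal(t$votes_a, 5L)  # 3,6 from mate1; 6,9,12 from mate2
})

test_that("decide_category applies an inclusive threshold", {
  tl <- function(a, b) list(votes_a = a, votes_b = b)
  # 3 of 4 = 0.75 categorizes under the default (inclusive)
  expect_equal(decide_category(tl(3L, 1L))$genome, "A")
  expect_equal(decide_category(tl(1L, 3L))$genome, "B")
  # 2-2: no majority
  expect_equal(decide_category(tl(2L, 2L)),
               list(genome = "N", criterion = "CONFLICT"))
  # unanimous
  expect_equal(decide_category(tl(5L, 0L))$genome, "A")
  # no evidence is distinguishable from conflict via the criterion
  expect_equal(decide_category(tl(0L, 0L)),
               list(genome = "N", criterion = "NO_SNPS"))
  # 5 of 7 < 0.75 -> N
  expect_equal(decide_category(tl(5L, 2L))$genome, "N")
  expect_error(decide_category(tl(1L, 0L), threshold = 0.5), "threshold")
  expect_error(decide_category(tl(1L, 0L), threshold = 1.2), "threshold")
})

test_that("categorized set is monotone non-increasing in the threshold", {
  p <- tiny_pipeline()
  idx <- truth_snp_index(p$sim, "A")
  prev <- NULL
  for (th in c(0.6, 0.75, 0.9, 1.0)) {
    cat_set <- categorize_snpvote(p$aln_a, idx, th)$decisions[
      genome %in% c("A", "B"), sort(qname)]
    if (!is.null(prev)) expect_true(all(cat_set %in% prev))
    prev <- cat_set
  }
  # at threshold 1.0 only unanimous tallies are categorized
  d <- categorize_snpvote(p$aln_a, idx, 1.0)$decisions
  expect_true(all(d[genome == "A", votes_b == 0L]))
  expect_true(all(d[genome == "B", votes_a == 0L]))
})

test_that("stream decisions conserve fragments and match per-fragment calls", {
  p <- tiny_pipeline()
  idx <- truth_snp_index(p$sim, "A")
  res <- categorize_snpvote(p$aln_a, idx)
  s <- res$summary
  expect_equal(s$cat_a + s$cat_b + s$n, s$mapped)
  expect_equal(nrow(res$decisions), length(unique(p$aln_a$qname)))

  # spot-check stream against the per-fragment API
  set.seed(5)
  for (q in sample(res$decisions[genome != "UNMAPPED", qname], 25L)) {
    t <- tally_fragment(p$aln_a[qname == q], idx)
    d <- decide_category(t)
    expect_equal(res$decisions[qname == q, genome], d$genome)
  }

  # error-free reads with the truth index: wrong categorization rate is 0
  er <- error_rate(res$decisions, p$rs$truth)
  expect_equal(er$wrong, 0L)
})

test_that("decisions depend only on bases at index positions", {
  idx <- snp_index(data.table(chrom = "chr1", pos = c(20L, 40L),
                              alleleA = c("A", "A"), alleleB = c("C", "C")))
  set.seed(9)
  for (i in 1:40) {
    seq <- rand_seq(60)
    r <- rec(seq = seq, cigar = "60M", pos = 1L, nm = 0L)
    base_tally <- tally_fragment(r, idx)
    # mutate one random non-index base
    off <- sample(setdiff(1:60, c(20L, 40L)), 1L)
    mut <- seq
    substr(mut, off, off) <- sample(setdiff(BASES, substr(seq, off, off)), 1L)
    r2 <- rec(seq = mut, cigar = "60M", pos = 1L, nm = 1L)
    expect_identical(tally_fragment(r2, idx), base_tally)
  }
})
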