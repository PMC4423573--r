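---
title: "Categorizing allopolyploid reads by subgenome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorizing allopolyploid reads by subgenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

An allopolyploid nucleus carries two diverged ancestral genomes
(subgenomes). Short reads sequenced from such an organism are a mixture of
the two, and most downstream analyses — homoeolog expression, subgenome
phylogenetics, polyploid genome assembly QC — require each read (or read
pair, treated as one *fragment*) to be assigned to its subgenome of
origin: label A, label B, or N when no confident call is possible.

`homeoSort` implements three complementary strategies plus the scaffolding
to evaluate them:

1. **Dual-reference serial comparison** (`categorize_dualref()`): the same
   read set is mapped independently to the references of the two diploid
   relatives; each fragment's two alignments are compared through four
   criteria, consulted strictly in order: (1) did it map at all, and on
   how many references; (2) summed MAPQ; (3) summed aligned length (read
   bases under M/=/X CIGAR operations; soft clips excluded); (4) summed
   exact matches, computed as aligned length minus edit distance, so every
   inserted and deleted base is penalized like a mismatch. A later
   criterion is consulted only when all earlier ones tie; a fragment equal
   on all four is N (criterion `TIE`).
2. **Homoeo-SNP vote majority** (`categorize_snpvote()`): reads are mapped
   to a single reference; at every indexed homoeo-SNP position covered by
   a fragment, the read base votes for the genome whose diagnostic allele
   it matches. The fragment is categorized when at least a threshold
   fraction (default 0.75, *inclusive*, so 3-of-4 qualifies) of its
   informative votes agree.
3. **Concatenated-reference baseline** (`categorize_fullref()`): reads are
   mapped once to the concatenation of both references and labeled by the
   genome tag of the chromosome they land on; mates landing on different
   genomes are a conflict (N).

The dual-reference method exploits the homoeologous relationship between
the two references: a read may sit on one locus in *each* genome without
being a multi-mapper, whereas a unique-best mapper on the concatenated
reference must discard any read that fits both subgenome copies equally
well. The vote method is the most conservative: it can only speak where
homoeo-SNPs exist, i.e. in regions present and alignable in both genomes.

## Fragment semantics

Fragments are categorized as single units. On each reference the stats of
a fragment are the *sums* over its mapped mates (MAPQ, aligned length,
match score). The choice of sums is a design decision: the field's
sources state that pairs are handled as a unit but not how mates combine.
Summing rewards both longer alignments and doubly-mapped evidence, and it
gives a natural behavior in the crosswise case (mate 1 maps only on
reference A, mate 2 only on reference B): both views count as mapped, so
the decision falls through to the quantitative criteria instead of being
forced by step 1.

## Error measurement

With reads from a diploid relative, the genome of origin is known, so any
fragment categorized to the other genome is an error; the error rate is
wrong calls over mapped fragments (`error_rate()`, policy
`mapped_either`). N calls are never "wrong" and stay in the denominator; a
separate N rate keeps the conservativeness of a method visible. The
alternative policy `mapped_on_ref` conditions on fragments mapped to one
named reference — e.g. B-origin reads that mapped to the A reference and
were called A — which concentrates the denominator where errors live and
typically yields a higher, more cautious estimate.

## The synthetic world

`sim_config()` / `evolve_genomes()` / `simulate_reads()` generate a
deterministic toy allopolyploid setting:

* a random ancestor (default 200 kb) diverges into two genomes;
* `substitution_rate` (default 0.02) is the expected **pairwise**
  substitution divergence — each lineage independently mutates at half
  that rate, so the stated 2% profile is genuinely ~2% diverged;
* small indels (default rate 0.001/base/lineage, lengths 1–6 bp);
* a fraction of each genome (default 5%, in 2 kb segments) is replaced by
  novel random sequence — the genome-unique tracts that real subgenomes
  carry at hundreds-of-megabase scale; replacement is length-preserving so
  coordinates stay simple;
* paired 100 bp reads from fragments drawn length-proportionally from the
  two genomes (or from a single genome, for diploid-style error analysis),
  with insert sizes N(300, 30) and uniform per-base error (default 0.001;
  the error-analysis profiles use 0);
* the true substitution differences surviving in homoeologous regions are
  emitted with coordinates projected onto both genomes
  (`truth_snp_index()`), and every fragment carries a truth label.

`naive_map()` is the in-package stand-in for a unique-best short-read
mapper: a gapless, k-mer-seeded exhaustive search over both strands that
reports an alignment only when a single locus attains the minimum
mismatch count within `max_mismatches` (default 6). The default seed
length `floor(read_length/(max_mismatches+1))` gives `max_mismatches + 1`
disjoint seeds, so by pigeonhole the seeded search finds every reportable
gapless locus — it is provably equivalent to a full scan, which is what
makes the oracle-equivalence tests exact. MAPQ is a constant (real
mappers in this setting often emit indistinguishable MAPQs, so the MAPQ
criterion rarely decides; it is exercised in tests with synthetic
values).

What the generator does **not** emulate: transposable elements and other
repeat structure (so unique-mapping decides far fewer fragments than in
real repeat-rich genomes and the quantitative criteria decide more),
gapped alignment (reads spanning a simulated indel simply fail to map on
the diverged reference, slightly inflating aligned-length decisions),
base-quality profiles, GC bias, and structural variation beyond small
indels and unique segments. A green test therefore establishes algorithmic
correctness and the qualitative relationships between methods, not
performance on real data.

## Numerical and edge-case choices

* Edit-distance source priority: NM tag, else recomputation from the MD
  tag, else recomputation against a supplied reference FASTA; NM/MD
  disagreement warns and keeps NM. A mapped record with none of the three
  is a hard "cannot score" error naming the read.
* Coordinates are 1-based fully closed (SAM convention) everywhere.
* Secondary (0x100) and supplementary (0x800) records are skipped;
  duplicates are kept. Two primary records for the same read+mate in one
  stream are an error: upstream mapping is expected to emit unique best
  alignments.
* Vote threshold semantics are inclusive (`>=`); bases matching neither
  diagnostic allele are excluded from the vote denominator (they indicate
  sequencing error or allelic variation, not subgenome identity). N
  decisions record whether they stem from no evidence (`NO_SNPS`) or
  conflicting evidence (`CONFLICT`).
* Consensus calling for index building uses majority base with
  `min_depth = 4` and `min_agreement = 0.8` — strict enough for zero
  false homoeo-SNPs on clean simulations, exposed as arguments. Only
  substitutions are called; indel differences are out of scope.
* Index iteration has no convergence rule; per-round index sizes are
  reported so a user can watch growth/stabilization.
* `decide_category()` requires a threshold in (0.5, 1]: anything at or
  below 0.5 would not be a majority.

## Known limitations

* The naive mapper is deliberately gapless and capped at 2 Mbp of
  reference: it is a verifiable fixture, not a production mapper. Real
  data should be mapped with a unique-best short-read mapper and fed in
  as SAM/BAM. One measurable consequence: a read whose alignment crosses
  an indel difference between the genomes carries a systematically
  shifted tail, and where such misassigned pileups just clear the
  consensus depth threshold the index builder can emit a rare false
  homoeo-SNP adjacent to the indel (observed at ~0.7% of the index in an
  indel-bearing simulation; pinned by a dedicated test). A gapped mapper
  aligns through the indel and removes the artifact, so the
  parameter-recovery guarantee (zero false positions) is stated for
  indel-free alignments.
* Fragment collation is in-memory, hashed by read name; inputs need not
  be name-sorted, but the whole read-name universe must fit in memory.
* The vote method ignores base qualities (none of the upstream decisions
  use them); a minimum-quality filter would be a straightforward
  extension but is intentionally absent to keep behavior transparent.
* Cross-genome mate pairs in the baseline are N rather than split —
  fragments are units everywhere in this package.
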