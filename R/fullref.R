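#' Build a concatenated two-genome reference
#'
#' Prefixes every sequence name of each input genome with a genome tag and
#' combines the two into one reference, for the baseline strategy of
#' mapping to both genomes at once and categorizing reads by the genome of
#' the chromosome they land on. Prefixing must stay injective: name
#' collisions (including inputs that already carry a prefix) are errors.
#'
#' @param fasta_a,fasta_b named `DNAStringSet`s or FASTA paths.
#' @param prefixes length-2 character: tags for genome A and B. The `|`
#'   delimiter is legal in SAM reference names.
#' @param out_fasta optional path; when given the combined FASTA is
#'   written there.
#' @return a list with `reference` (combined `DNAStringSet`) and
#'   `name_map` (a `data.table`: `combined`, `genome`, `original`).
#' @export
concat_references <- function(fasta_a, fasta_b, prefixes = c("A|", "B|"),
                              out_fasta = NULL) {
  stopifnot(length(prefixes) == 2L, prefixes[1] != prefixes[2])
  ga <- as_reference(fasta_a)
  gb <- as_reference(fasta_b)
  if (anyDuplicated(names(ga)) || anyDuplicated(names(gb)))
    stop("duplicate sequence names within one input genome")
  for (p in prefixes) {
    hit <- c(names(ga), names(gb))[startsWith(c(names(ga), names(gb)), p)]
    if (length(hit))
      stop("input sequence name already carries prefix '", p, "': ", hit[1])
  }
  # paste0 recycles zero-length inputs to "", so guard empty genomes
  tag <- function(prefix, nms)
    if (length(nms)) paste0(prefix, nms) else character(0)
  na <- if (length(ga)) names(ga) else character(0)
  nb <- if (length(gb)) names(gb) else character(0)
  name_map <- data.table(
    combined = c(tag(prefixes[1], na), tag(prefixes[2], nb)),
    genome = rep(c("A", "B"), c(length(ga), length(gb))),
    original = c(na, nb))
  if (anyDuplicated(name_map$combined))
    stop("sequence name collision after prefixing")
  combined <- c(ga, gb)
  names(combined) <- name_map$combined
  if (!is.null(out_fasta))
    Biostrings::writeXStringSet(combined, out_fasta)
  list(reference = combined, name_map = name_map)
}

as_reference <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  stopifnot(methods::is(x, "DNAStringSet"),
            length(x) == 0L || !is.null(names(x)))
  x
}

#' Categorize fragments by chromosome of the combined reference
#'
#' Each fragment mapped to the concatenated reference is assigned the
#' genome tag of the chromosome(s) its mates mapped to. Mates landing on
#' chromosomes of different genomes are a conflict and yield `N`; the
#' fragment is treated as a unit, never split.
#'
#' @param aln an [alignment_table()] against the combined reference.
#' @param name_map the `name_map` from [concat_references()].
#' @return a list with `decisions` (`qname`, `genome`, `criterion`) and
#'   `summary` as in [categorize_snpvote()].
#' @export
categorize_fullref <- function(aln, name_map) {
  aln <- validate_alignment_table(aln)
  aln <- aln[is_primary(aln)]
  m <- is_mapped(aln)
  unknown <- setdiff(unique(aln$rname[m]), name_map$combined)
  if (length(unknown))
    stop("chromosome absent from name map: ", unknown[1])
  g <- name_map[match(aln$rname, combined), genome]
  d <- data.table(qname = aln$qname, mapped = m, g = g)[,
    .(mapped = sum(mapped),
      n_a = sum(g == "A" & mapped, na.rm = TRUE),
      n_b = sum(g == "B" & mapped, na.rm = TRUE)), by = qname]
  d[, genome := fcase(mapped == 0L, "UNMAPPED",
                      n_a > 0L & n_b > 0L, "N",
                      n_a > 0L, "A",
                      default = "B")]
  d[, criterion := fcase(mapped == 0L, "NONE_MAPPED",
                         n_a > 0L & n_b > 0L, "CONFLICT",
                         default = "UNIQUE_MAPPING")]
  decisions <- d[, .(qname, genome, criterion)]
  summary <- list(mapped = sum(d$mapped > 0L),
                  cat_a = sum(d$genome == "A"),
                  cat_b = sum(d$genome == "B"),
                  n = sum(d$genome == "N"))
  list(decisions = decisions[], summary = summary)
}
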