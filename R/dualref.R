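#' Serial-criteria decision between two fragment views
#'
#' The dual-reference categorizer compares a fragment's alignments to two
#' references through four criteria, consulted strictly in order and each
#' only when all earlier ones tie:
#'
#' 1. whether the fragment mapped (mapped on exactly one reference decides
#'    immediately: `UNIQUE_MAPPING`; mapped on neither: `UNMAPPED`);
#' 2. mapping quality (`MAPQ`, summed over mapped mates);
#' 3. aligned length (`ALIGN_LENGTH`, read bases under M/=/X);
#' 4. exact matches (`MATCHES`, aligned bases minus edit distance, so
#'    insertions and deletions are penalized as mismatches).
#'
#' A fragment equal on all four is reported as `N` with criterion `TIE`.
#' There are no margins: any strict inequality decides.
#'
#' @param view_a,view_b [fragment_view()]s of the same read name against
#'   reference A and reference B.
#' @return a list with `genome` (`"A"`, `"B"`, `"N"`, `"UNMAPPED"`) and
#'   `criterion` (`UNIQUE_MAPPING`, `MAPQ`, `ALIGN_LENGTH`, `MATCHES`,
#'   `TIE`, `NONE_MAPPED`).
#' @export
categorize_fragment <- function(view_a, view_b) {
  if (!identical(is.na(view_a$qname), is.na(view_b$qname)) ||
      (!is.na(view_a$qname) && view_a$qname != view_b$qname))
    stop("fragment views refer to different reads: ",
         view_a$qname, " vs ", view_b$qname)
  d <- decide_serial(view_a$mapped > 0L, view_b$mapped > 0L,
                     view_a$mapq, view_b$mapq,
                     view_a$len, view_b$len,
                     view_a$score, view_b$score)
  list(genome = d$genome, criterion = d$criterion)
}

# vectorized serial rule; the single-fragment API and the stream share it
decide_serial <- function(ma, mb, mqa, mqb, la, lb, sa, sb) {
  genome <- fcase(
    !ma & !mb, "UNMAPPED",
    ma & !mb, "A",
    !ma & mb, "B",
    mqa != mqb, fifelse(mqa > mqb, "A", "B"),
    la != lb, fifelse(la > lb, "A", "B"),
    sa != sb, fifelse(sa > sb, "A", "B"),
    default = "N")
  criterion <- fcase(
    !ma & !mb, "NONE_MAPPED",
    xor(ma, mb), "UNIQUE_MAPPING",
    mqa != mqb, "MAPQ",
    la != lb, "ALIGN_LENGTH",
    sa != sb, "MATCHES",
    default = "TIE")
  data.table(genome = genome, criterion = criterion)
}

#' Dual-reference categorization of a collated fragment stream
#'
#' Applies the serial criteria of [categorize_fragment()] to every fragment
#' of a collated table and reports per-criterion step attribution, with
#' fractions relative to the number of fragments mapped on at least one
#' reference.
#'
#' @param fragments a table from [collate_fragments()].
#' @return a list with `decisions` (a `data.table`: `qname`, `genome`,
#'   `criterion`, in input order) and `attribution` (a `data.table`:
#'   `criterion`, `n`, `fraction`; fractions are `NA` when no fragment
#'   mapped).
#' @export
categorize_dualref <- function(fragments) {
  d <- decide_serial(fragments$mapped_a > 0L, fragments$mapped_b > 0L,
                     fragments$mapq_a, fragments$mapq_b,
                     fragments$len_a, fragments$len_b,
                     fragments$score_a, fragments$score_b)
  decisions <- data.table(qname = fragments$qname,
                          genome = d$genome, criterion = d$criterion)
  n_mapped <- sum(decisions$genome != "UNMAPPED")
  attribution <- decisions[genome != "UNMAPPED", .N, by = criterion]
  setnames(attribution, "N", "n")
  attribution[, fraction := if (n_mapped > 0L) n / n_mapped else NA_real_]
  list(decisions = decisions[], attribution = attribution[],
       n_mapped = n_mapped)
}
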