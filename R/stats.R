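#' Categorization error rate against known truth
#'
#' When reads of known origin (e.g. from a diploid relative) are
#' categorized, every fragment assigned to the other genome is an error;
#' the fraction of mapped fragments so assigned approximates the method's
#' error rate. `N` and unmapped fragments are never counted as wrong, but
#' `N` stays in the mapped denominator; a separate N rate makes the
#' method's conservativeness visible.
#'
#' Two denominator policies are supported. `"mapped_either"` counts
#' fragments mapped on at least one reference (any decision other than
#' `UNMAPPED`). `"mapped_on_ref"` restricts both numerator and denominator
#' to fragments mapped on one named reference — e.g. reads of B origin that
#' mapped to the A reference and were categorized A — which typically
#' yields a higher, more conservative estimate.
#'
#' @param decisions a decision table (`qname`, `genome`, `criterion`).
#' @param truth a truth table (`qname`, `genome`) or a single genome label
#'   (`"A"`/`"B"`) when all reads share one origin.
#' @param policy denominator policy, see above.
#' @param fragments the [collate_fragments()] table; required for
#'   `policy = "mapped_on_ref"`.
#' @param ref which reference (`"A"`/`"B"`) defines the
#'   `"mapped_on_ref"` denominator.
#' @return a list of class `error_report`: `policy`, `mapped`, `wrong`,
#'   `n_uncalled`, `error_rate`, `n_rate`.
#' @export
error_rate <- function(decisions, truth,
                       policy = c("mapped_either", "mapped_on_ref"),
                       fragments = NULL, ref = c("A", "B")) {
  policy <- match.arg(policy)
  d <- as.data.table(decisions)[, .(qname, genome)]
  if (is.character(truth) && length(truth) == 1L) {
    stopifnot(truth %in% c("A", "B"))
    d[, true_genome := truth]
  } else {
    tt <- as.data.table(truth)
    d <- merge(d, tt[, .(qname, true_genome = genome)],
               by = "qname", all.x = TRUE)
    if (anyNA(d[genome %in% c("A", "B"), true_genome]))
      stop("decided fragment(s) without a truth label: ",
           paste(head(d[genome %in% c("A", "B") & is.na(true_genome),
                        qname], 3), collapse = ", "))
  }
  if (policy == "mapped_on_ref") {
    ref <- match.arg(ref)
    if (is.null(fragments))
      stop("policy 'mapped_on_ref' needs the collated fragment table")
    col <- if (ref == "A") "mapped_a" else "mapped_b"
    on_ref <- fragments[fragments[[col]] > 0L, qname]
    d <- d[qname %in% on_ref]
    mapped <- nrow(d)
  } else {
    d <- d[genome != "UNMAPPED"]
    mapped <- nrow(d)
  }
  wrong <- d[genome %in% c("A", "B") & genome != true_genome, .N]
  n_uncalled <- d[genome == "N", .N]
  structure(list(policy = policy, mapped = mapped, wrong = wrong,
                 n_uncalled = n_uncalled,
                 error_rate = if (mapped > 0L) wrong / mapped else 0,
                 n_rate = if (mapped > 0L) n_uncalled / mapped else 0),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "error report (%s): mapped %d, wrong %d (%.4f%%), N %d (%.2f%%)\n",
    x$policy, x$mapped, x$wrong, 100 * x$error_rate,
    x$n_uncalled, 100 * x$n_rate))
  invisible(x)
}

#' Cross-method comparison table
#'
#' Summarizes one or more categorization runs over the same read set:
#' mapped, categorized-per-genome and N counts, plus the error rate when a
#' truth table is given. Runs whose read universes differ are an error.
#'
#' @param runs a named list; each element is a decision table (`qname`,
#'   `genome`, `criterion`).
#' @param truth optional truth table or single genome label, forwarded to
#'   [error_rate()].
#' @return a `data.table` with one row per method.
#' @export
compare_methods <- function(runs, truth = NULL) {
  stopifnot(length(runs) >= 1L, !is.null(names(runs)))
  universes <- lapply(runs, function(d) sort(unique(d$qname)))
  if (length(runs) > 1L &&
      !all(vapply(universes[-1], identical, logical(1), universes[[1]])))
    stop("runs cover different read universes")
  out <- rbindlist(lapply(names(runs), function(nm) {
    d <- as.data.table(runs[[nm]])
    row <- data.table(method = nm, fragments = nrow(d),
                      mapped = d[genome != "UNMAPPED", .N],
                      cat_a = d[genome == "A", .N],
                      cat_b = d[genome == "B", .N],
                      n = d[genome == "N", .N])
    if (!is.null(truth)) {
      er <- error_rate(d, truth)
      row[, `:=`(error_rate = er$error_rate, n_rate = er$n_rate)]
    }
    row
  }))
  out[]
}

#' Write a comparison or attribution report
#'
#' @param x a `data.table` (e.g. from [compare_methods()] or the
#'   attribution of [categorize_dualref()]).
#' @param path output path; `.json` writes JSON (lossless round-trip via
#'   [jsonlite]), anything else tab-separated text.
#' @return invisibly, `path`.
#' @export
write_report <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, digits = NA, dataframe = "rows")
  } else {
    fwrite(x, path, sep = "\t")
  }
  invisible(path)
}
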