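# TSV input/output for offspring PMFs.
#
# Format: a header line `daughters<TAB>probability` (or
# `children<TAB>probability` for an unthinned completed-fertility table),
# then one row per support point with counts ascending.

#' Read an offspring PMF from a TSV file
#'
#' Accepts the two-column format `daughters<TAB>probability`; the variant
#' header `children<TAB>probability` marks a completed-fertility table that
#' must be thinned to daughters, so `p_daughter` becomes mandatory.
#' Probability columns that sum to 1 within 1e-6 are accepted as-is; sums
#' off by up to 1e-3 are renormalized with a warning; anything further off
#' is rejected.
#'
#' @param path Path to the TSV file.
#' @param p_daughter Probability a child is female; required when the file
#'   carries the `children` header, ignored otherwise.
#' @return An [offspring_distribution][make_empirical_pmf] of daughter
#'   counts.
#' @seealso [write_pmf_tsv()]
#' @export
read_pmf_tsv <- function(path, p_daughter = NULL) {
  if (!file.exists(path)) {
    abort_validation(sprintf("PMF file '%s' does not exist", path))
  }
  header <- readLines(path, n = 1L)
  if (!header %in% c("daughters\tprobability", "children\tprobability")) {
    abort_validation(sprintf(
      "malformed header '%s'; expected 'daughters<TAB>probability' or 'children<TAB>probability'",
      header))
  }
  is_children <- identical(header, "children\tprobability")
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  counts <- suppressWarnings(as.numeric(tab[[1L]]))
  probs <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(counts) || anyNA(probs)) {
    row <- which(is.na(counts) | is.na(probs))[1L]
    abort_validation(sprintf("non-numeric cell in data row %d of '%s'",
                             row, path))
  }
  dev <- abs(sum(probs) - 1)
  if (dev > 1e-3) {
    abort_validation(sprintf(
      "probabilities in '%s' sum to %.6g; more than 1e-3 from 1", path,
      sum(probs)))
  }
  if (dev > 1e-6) {
    warning(sprintf("probabilities in '%s' sum to %.6g; renormalizing",
                    path, sum(probs)), call. = FALSE)
  }
  dist <- make_empirical_pmf(counts, probs, label = basename(path))
  if (is_children) {
    if (is.null(p_daughter)) {
      abort_validation(sprintf(
        "'%s' holds a children-count table; supply 'p_daughter' to thin it to daughters",
        path))
    }
    dist <- thin_to_daughters(dist, p_daughter)
  }
  dist
}

#' Write an offspring PMF to a TSV file
#'
#' Probabilities are written with full double precision so that a write/read
#' round trip reproduces the distribution to 1e-12.
#'
#' @param dist An [offspring_distribution][make_empirical_pmf].
#' @param path Output path.
#' @param counts_are Header word for the count column: `"daughters"`
#'   (default) or `"children"`.
#' @return `path`, invisibly.
#' @seealso [read_pmf_tsv()]
#' @export
write_pmf_tsv <- function(dist, path, counts_are = c("daughters", "children")) {
  stopifnot(inherits(dist, "offspring_distribution"))
  counts_are <- match.arg(counts_are)
  lines <- c(paste(counts_are, "probability", sep = "\t"),
             paste(dist$support,
                   formatC(dist$probabilities, format = "g", digits = 17),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
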