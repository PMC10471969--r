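#' Compare exon retention estimates between replicate samples
#'
#' Inner-joins two exon-usage tables from the same donor on (allele, exon),
#' keeps rows where both replicates pass the read-count threshold and have
#' a defined retention rate, and reports the per-row Bland-Altman style
#' quantities (mean coverage, the two rates, their difference) plus
#' per-locus-class aggregates: mean absolute difference and the fraction of
#' rows within each tolerance (defaults 2% and 4%, the concordance margins
#' reported for class I and class II exons respectively).
#'
#' @param usage_rep1,usage_rep2 `hla_usage_table` data.frames for the two
#'   replicates; allele sets must overlap.
#' @param tolerances Numeric vector of tolerances (default `c(0.02, 0.04)`).
#' @return An `hla_concordance` object: list with `rows` (data.frame:
#'   `locus_class`, `allele`, `exon_index`, `mean_coverage`, `rate_rep1`,
#'   `rate_rep2`, `difference`) and `aggregates` (data.frame:
#'   `locus_class`, `n`, `mean_abs_diff`, one `frac_within_<tol>` column
#'   per tolerance).
#' @export
compare_replicates <- function(usage_rep1, usage_rep2,
                               tolerances = c(0.02, 0.04)) {
  shared <- intersect(unique(usage_rep1$allele), unique(usage_rep2$allele))
  if (length(shared) == 0L) {
    stop(sprintf(
      "replicate usage tables share no alleles (rep1: %s; rep2: %s)",
      paste(unique(usage_rep1$allele), collapse = ", "),
      paste(unique(usage_rep2$allele), collapse = ", ")), call. = FALSE)
  }
  j <- merge(usage_rep1, usage_rep2, by = c("allele", "exon_index"),
             suffixes = c("_rep1", "_rep2"))
  keep <- j$passes_threshold_rep1 & j$passes_threshold_rep2 &
    !is.na(j$retention_rate_rep1) & !is.na(j$retention_rate_rep2)
  j <- j[keep, , drop = FALSE]
  rows <- data.frame(
    locus_class = j$locus_class_rep1,
    allele = j$allele, exon_index = j$exon_index,
    mean_coverage = (j$n_reads_allele_rep1 + j$n_reads_allele_rep2) / 2,
    rate_rep1 = j$retention_rate_rep1,
    rate_rep2 = j$retention_rate_rep2,
    difference = j$retention_rate_rep1 - j$retention_rate_rep2,
    stringsAsFactors = FALSE)
  rows <- rows[order(rows$allele, rows$exon_index), , drop = FALSE]
  rownames(rows) <- NULL
  sp <- split(rows$difference, rows$locus_class)
  agg <- data.frame(locus_class = names(sp),
                    n = vapply(sp, length, integer(1)),
                    mean_abs_diff = vapply(sp, function(d) mean(abs(d)),
                                           numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (tol in tolerances) {
    agg[[sprintf("frac_within_%g", tol)]] <-
      vapply(sp, function(d) mean(abs(d) <= tol), numeric(1))
  }
  structure(list(rows = rows, aggregates = agg), class = "hla_concordance")
}

#' @export
print.hla_concordance <- function(x, ...) {
  cat(sprintf("<hla_concordance> %d (allele, exon) comparison(s)\n",
              nrow(x$rows)))
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}
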