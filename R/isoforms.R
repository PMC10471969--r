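#' Select full-span reads
#'
#' Keeps only callsets whose first and last exon are RETAINED, i.e. reads
#' spanning all known exons. By the flanking rule of [call_exons()] this
#' guarantees no internal exon remains UNASSESSED, so every internal 0 in
#' the resulting patterns reflects splicing, not truncation.
#'
#' @param callsets List of `hla_exon_calls`.
#' @return The full-span subset, same representation.
#' @export
select_full_span <- function(callsets) {
  Filter(function(cs) {
    n <- length(cs$calls)
    cs$calls[1L] == "RETAINED" && cs$calls[n] == "RETAINED"
  }, callsets)
}

#' Quantify exon-presence isoform patterns from full-span reads
#'
#' Counts, per allele, the distinct exon-presence bit patterns (1 retained,
#' 0 excluded) among full-span reads and normalizes to proportions. Rows
#' are ordered by allele, then descending count, ties broken by pattern
#' string.
#'
#' @param full_span Full-span callsets (see [select_full_span()]).
#' @param sample_id Sample identifier recorded in the table.
#' @return A data.frame of class `hla_isoform_table` with columns
#'   `sample_id`, `allele`, `pattern`, `n_reads`, `proportion`.
#' @export
quantify_isoforms <- function(full_span, sample_id) {
  if (length(full_span) == 0L) {
    out <- data.frame(sample_id = character(), allele = character(),
                      pattern = character(), n_reads = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("hla_isoform_table", "data.frame")
    return(out)
  }
  pat <- vapply(full_span, function(cs) {
    if (any(cs$calls == "UNASSESSED")) {
      stop(sprintf("read '%s' is not full-span (unassessed exon present)",
                   cs$read_id), call. = FALSE)
    }
    paste(as.integer(cs$calls == "RETAINED"), collapse = "")
  }, character(1))
  allele <- vapply(full_span, function(cs) cs$allele, character(1))
  tab <- as.data.frame(table(allele = allele, pattern = pat),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  totals <- tapply(tab$Freq, tab$allele, sum)
  out <- data.frame(sample_id = sample_id, allele = tab$allele,
                    pattern = tab$pattern, n_reads = as.integer(tab$Freq),
                    proportion = tab$Freq / as.numeric(totals[tab$allele]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$allele, -out$n_reads, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hla_isoform_table", "data.frame")
  out
}

#' Flag or remove rare isoform patterns
#'
#' Annotates patterns supported by fewer than `min_reads` reads (summed
#' across samples) or seen in fewer than `min_samples` samples as rare.
#' With `hard_filter = TRUE` rare rows are removed and proportions are
#' renormalized per (sample, allele).
#'
#' @param table An `hla_isoform_table`, possibly spanning several samples.
#' @param min_reads Minimum supporting reads (>= 1).
#' @param min_samples Minimum number of samples.
#' @param hard_filter Remove rare rows instead of annotating (default
#'   FALSE).
#' @return The table with an added logical `rare` column (and, under hard
#'   filtering, rare rows removed and proportions renormalized).
#' @export
filter_rare_isoforms <- function(table, min_reads = 1L, min_samples = 1L,
                                 hard_filter = FALSE) {
  stopifnot(min_reads >= 1L, min_samples >= 1L)
  key <- paste(table$allele, table$pattern, sep = "\r")
  reads_total <- tapply(table$n_reads, key, sum)
  samples_n <- tapply(table$sample_id, key, function(s) length(unique(s)))
  table$rare <- as.vector(reads_total[key] < min_reads |
                            samples_n[key] < min_samples)
  if (hard_filter) {
    table <- table[!table$rare, , drop = FALSE]
    grp <- paste(table$sample_id, table$allele, sep = "\r")
    totals <- tapply(table$n_reads, grp, sum)
    table$proportion <- table$n_reads / as.numeric(totals[grp])
    rownames(table) <- NULL
  }
  table
}

#' Write an isoform table as TSV
#' @param table An `hla_isoform_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isoform_tsv <- function(table, path) {
  out <- table
  out$proportion <- sprintf("%.6f", out$proportion)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
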