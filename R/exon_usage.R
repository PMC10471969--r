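EXON_STATUS <- c("RETAINED", "EXCLUDED", "UNASSESSED")

#' Call per-exon status for one aligned read
#'
#' For each annotated exon of the allele the read is aligned to, the exon is
#' RETAINED if any aligned block overlaps it by at least one base, EXCLUDED
#' if it has no overlap but at least one exon 5' of it and at least one exon
#' 3' of it are retained (evidence of splicing), and UNASSESSED otherwise
#' (5'/3' truncation is not evidence of splicing). Terminal exons can
#' therefore never be EXCLUDED.
#'
#' @param read An `hla_aligned_read` (see [load_alignments()]).
#' @param allele The matching `hla_allele_ref`.
#' @return An `hla_exon_calls` object: list with `read_id`, `allele`
#'   (character name), and `calls` (character vector over exons with values
#'   RETAINED / EXCLUDED / UNASSESSED).
#' @export
call_exons <- function(read, allele) {
  stopifnot(inherits(read, "hla_aligned_read"),
            inherits(allele, "hla_allele_ref"))
  if (read$allele != format(allele$name)) {
    stop(sprintf("read '%s' aligned to '%s', not to allele '%s'",
                 read$read_id, read$allele, format(allele$name)),
         call. = FALSE)
  }
  blocks <- read$blocks
  if (blocks[nrow(blocks), "end"] > nchar(allele$sequence)) {
    stop(sprintf("read '%s': blocks outside reference", read$read_id),
         call. = FALSE)
  }
  exons <- allele$exons
  n <- nrow(exons)
  overlaps <- logical(n)
  for (k in seq_len(n)) {
    overlaps[k] <- any(blocks[, "start"] < exons[k, "end"] &
                       blocks[, "end"] > exons[k, "start"])
  }
  calls <- rep("UNASSESSED", n)
  calls[overlaps] <- "RETAINED"
  if (any(overlaps)) {
    first_r <- which(overlaps)[1L]
    last_r <- which(overlaps)[sum(overlaps)]
    interior <- !overlaps & seq_len(n) > first_r & seq_len(n) < last_r
    calls[interior] <- "EXCLUDED"
  }
  structure(list(read_id = read$read_id, allele = read$allele, calls = calls),
            class = "hla_exon_calls")
}

#' Call exon status for a collection of reads
#'
#' @param reads List of `hla_aligned_read`.
#' @param bundle The `hla_ref_bundle` the reads were aligned to.
#' @return List of `hla_exon_calls`, one per read.
#' @export
call_exons_all <- function(reads, bundle) {
  stopifnot(inherits(bundle, "hla_ref_bundle"))
  lapply(reads, function(r) call_exons(r, bundle$alleles[[r$allele]]))
}

#' Aggregate per-read exon calls into an exon-usage table
#'
#' Produces one row per (allele, exon) with retained / excluded / unassessed
#' counts, the retention rate, and a pass flag for the class-specific
#' read-count threshold (>= 20 reads for class I alleles, >= 10 for class
#' II). The retention-rate denominator defaults to assessable reads
#' (retained + excluded), since unassessed (truncated) reads carry no
#' splicing information for that exon; `denominator = "all"` divides by all
#' reads assigned to the allele instead.
#'
#' @param callsets List of `hla_exon_calls`.
#' @param bundle The `hla_ref_bundle`.
#' @param sample_id Sample identifier recorded in the table.
#' @param denominator `"assessable"` (default) or `"all"`.
#' @param class1_min,class2_min Read-count thresholds (defaults 20 and 10).
#' @return A data.frame of class `hla_usage_table` with columns `sample_id`,
#'   `allele`, `locus_class`, `exon_index`, `n_retained`, `n_excluded`,
#'   `n_unassessed`, `retention_rate` (NA when the denominator is 0),
#'   `n_reads_allele`, `passes_threshold`.
#' @export
aggregate_usage <- function(callsets, bundle, sample_id,
                            denominator = c("assessable", "all"),
                            class1_min = 20L, class2_min = 10L) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(bundle, "hla_ref_bundle"))
  rows <- list()
  cs_allele <- vapply(callsets, function(cs) cs$allele, character(1))
  if (length(callsets) > 0L &&
      !all(cs_allele %in% names(bundle$alleles))) {
    stop("callsets reference alleles absent from the bundle", call. = FALSE)
  }
  for (aname in names(bundle$alleles)) {
    allele <- bundle$alleles[[aname]]
    n_ex <- nrow(allele$exons)
    sets <- callsets[cs_allele == aname]
    n_reads <- length(sets)
    thr <- if (allele$locus_class == "CLASS_I") class1_min else class2_min
    passes <- n_reads >= thr
    if (n_reads > 0L) {
      callmat <- do.call(rbind, lapply(sets, function(cs) {
        if (length(cs$calls) != n_ex) {
          stop(sprintf("callset for read '%s' has %d calls but allele has %d exons",
                       cs$read_id, length(cs$calls), n_ex), call. = FALSE)
        }
        cs$calls
      }))
      n_ret <- colSums(callmat == "RETAINED")
      n_exc <- colSums(callmat == "EXCLUDED")
      n_un <- colSums(callmat == "UNASSESSED")
    } else {
      n_ret <- n_exc <- n_un <- rep(0L, n_ex)
    }
    denom <- if (denominator == "assessable") n_ret + n_exc else
      rep(n_reads, n_ex)
    rate <- ifelse(denom > 0, n_ret / denom, NA_real_)
    rows[[aname]] <- data.frame(
      sample_id = sample_id, allele = aname,
      locus_class = allele$locus_class,
      exon_index = seq_len(n_ex),
      n_retained = as.integer(n_ret), n_excluded = as.integer(n_exc),
      n_unassessed = as.integer(n_un),
      retention_rate = rate,
      n_reads_allele = n_reads, passes_threshold = passes,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hla_usage_table", "data.frame")
  out
}

#' Partition exon retention rates by splice-site SNP genotype
#'
#' Groups per-allele retention rates for one exon by the allele's genotype
#' at a splice-site SNP (e.g. rs28688207, the intron-4 G>A substitution
#' that destroys the HLA-DQB1 exon-5 splice acceptor), and by donor
#' zygosity (e.g. AG vs AA). Only alleles passing the read threshold and
#' with a defined rate contribute. Alleles absent from the map go to an
#' `"ungrouped"` bucket with a warning.
#'
#' @param usage An `hla_usage_table`.
#' @param snp_map data.frame with columns `sample_id`, `allele`, `snp`
#'   (values `"G"` or `"A"`).
#' @param exon_index Which exon to partition (e.g. 5).
#' @return List with `groups` (data.frame: `snp`, `zygosity`, `sample_id`,
#'   `allele`, `retention_rate`), `medians` (data.frame: `snp`, `zygosity`,
#'   `median_rate`, `n`), and `ungrouped` (character vector of allele keys).
#' @export
partition_by_snp <- function(usage, snp_map, exon_index) {
  stopifnot(inherits(usage, "data.frame"), exon_index >= 1L)
  rows <- usage[usage$exon_index == exon_index & usage$passes_threshold &
                !is.na(usage$retention_rate), , drop = FALSE]
  key <- paste(rows$sample_id, rows$allele, sep = "\r")
  map_key <- paste(snp_map$sample_id, snp_map$allele, sep = "\r")
  idx <- match(key, map_key)
  ungrouped <- paste(rows$sample_id[is.na(idx)], rows$allele[is.na(idx)],
                     sep = "/")
  if (length(ungrouped) > 0L) {
    warning(sprintf("%d allele(s) missing from SNP map: %s",
                    length(ungrouped), paste(ungrouped, collapse = ", ")))
  }
  grouped <- rows[!is.na(idx), , drop = FALSE]
  snp <- snp_map$snp[idx[!is.na(idx)]]
  # donor zygosity from the mapped symbols of each sample's alleles
  zyg_by_sample <- vapply(split(snp, grouped$sample_id), function(s) {
    paste(sort(unique(s)), collapse = "")
  }, character(1))
  zyg_by_sample[nchar(zyg_by_sample) == 1L] <-
    strrep(zyg_by_sample[nchar(zyg_by_sample) == 1L], 2L)
  groups <- data.frame(
    snp = snp,
    zygosity = unname(zyg_by_sample[grouped$sample_id]),
    sample_id = grouped$sample_id, allele = grouped$allele,
    retention_rate = grouped$retention_rate,
    stringsAsFactors = FALSE)
  if (nrow(groups) > 0L) {
    sp <- split(groups$retention_rate,
                list(snp = groups$snp, zygosity = groups$zygosity),
                drop = TRUE)
    medians <- data.frame(
      snp = sub("\\..*$", "", names(sp)),
      zygosity = sub("^.*\\.", "", names(sp)),
      median_rate = vapply(sp, stats::median, numeric(1)),
      n = vapply(sp, length, integer(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    medians <- data.frame(snp = character(), zygosity = character(),
                          median_rate = numeric(), n = integer(),
                          stringsAsFactors = FALSE)
  }
  list(groups = groups, medians = medians, ungrouped = ungrouped)
}

#' Write an exon-usage table as TSV
#'
#' Fractions are written in fixed-point with 6 decimals so repeated runs
#' diff cleanly.
#'
#' @param usage An `hla_usage_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_usage_tsv <- function(usage, path) {
  out <- usage
  out$retention_rate <- ifelse(is.na(out$retention_rate), "NA",
                               sprintf("%.6f", out$retention_rate))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an exon-usage TSV written by [write_usage_tsv()]
#' @param path Input path.
#' @return An `hla_usage_table` data.frame.
#' @export
read_usage_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(retention_rate = "character"))
  out$retention_rate <- suppressWarnings(as.numeric(out$retention_rate))
  class(out) <- c("hla_usage_table", "data.frame")
  out
}
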