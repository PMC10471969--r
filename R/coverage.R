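#' Per-position depth over an allele reference
#'
#' @param reads List of `hla_aligned_read` aligned to `allele`.
#' @param allele An `hla_allele_ref`.
#' @return An `hla_coverage` object: list with `allele` (character name),
#'   `depth` (integer vector, one entry per reference position), `n_reads`.
#' @export
compute_depth <- function(reads, allele) {
  stopifnot(inherits(allele, "hla_allele_ref"))
  len <- nchar(allele$sequence)
  aname <- format(allele$name)
  delta <- integer(len + 1L)
  for (r in reads) {
    if (r$allele != aname) {
      stop(sprintf("read '%s' aligned to '%s', not '%s'", r$read_id,
                   r$allele, aname), call. = FALSE)
    }
    b <- r$blocks
    if (any(b[, "start"] < 0L) || any(b[, "end"] > len)) {
      stop(sprintf("read '%s': block outside reference", r$read_id),
           call. = FALSE)
    }
    delta[b[, "start"] + 1L] <- delta[b[, "start"] + 1L] + 1L
    delta[b[, "end"] + 1L] <- delta[b[, "end"] + 1L] - 1L
  }
  structure(list(allele = aname, depth = cumsum(delta[seq_len(len)]),
                 n_reads = length(reads)),
            class = "hla_coverage")
}

#' Breadth of coverage at depth thresholds
#'
#' For each threshold X, reports the fraction of reference positions with
#' depth >= X and whether that fraction meets the breadth cut (default
#' 90%), the per-allele criterion used for coverage summaries.
#'
#' @param profile An `hla_coverage`.
#' @param thresholds Depth thresholds (default `c(10, 25, 50, 75, 100)`).
#' @param breadth_cut Required fraction of positions (default 0.9).
#' @param sample_id Optional sample identifier for the output rows.
#' @return data.frame with columns `sample_id`, `allele`, `threshold`,
#'   `fraction_at_depth`, `meets_breadth`.
#' @export
breadth_at <- function(profile, thresholds = c(10L, 25L, 50L, 75L, 100L),
                       breadth_cut = 0.9, sample_id = NA_character_) {
  stopifnot(inherits(profile, "hla_coverage"), all(thresholds > 0))
  frac <- vapply(thresholds,
                 function(x) mean(profile$depth >= x), numeric(1))
  data.frame(sample_id = sample_id, allele = profile$allele,
             threshold = as.integer(thresholds),
             fraction_at_depth = frac,
             meets_breadth = frac >= breadth_cut,
             stringsAsFactors = FALSE)
}

#' Percentile-normalized gene-body coverage profile
#'
#' Each allele's depth vector is reduced to `n_bins` positional bins by
#' within-bin means, scaled to its own maximum (so alleles with different
#' expression levels are comparable), then summarized across alleles by the
#' per-bin median and the inner 50% and 90% bands. All-zero or empty
#' profiles are skipped with a warning.
#'
#' @param profiles List of `hla_coverage`.
#' @param n_bins Number of positional bins (default 100).
#' @return data.frame with columns `bin`, `median`, `p25`, `p75`, `p5`,
#'   `p95`.
#' @export
gene_body_profile <- function(profiles, n_bins = 100L) {
  stopifnot(n_bins >= 2L)
  binned <- list()
  for (p in profiles) {
    if (length(p$depth) == 0L || all(p$depth == 0)) {
      warning(sprintf("skipping allele '%s': empty or all-zero profile",
                      p$allele))
      next
    }
    idx <- ceiling(seq_along(p$depth) / length(p$depth) * n_bins)
    m <- tapply(p$depth, idx, mean)
    v <- numeric(n_bins)
    v[as.integer(names(m))] <- m
    binned[[length(binned) + 1L]] <- v / max(v)
  }
  if (length(binned) == 0L) {
    return(data.frame(bin = integer(), median = numeric(), p25 = numeric(),
                      p75 = numeric(), p5 = numeric(), p95 = numeric()))
  }
  mat <- do.call(rbind, binned)
  q <- apply(mat, 2L, stats::quantile,
             probs = c(0.5, 0.25, 0.75, 0.05, 0.95), names = FALSE)
  data.frame(bin = seq_len(n_bins), median = q[1, ], p25 = q[2, ],
             p75 = q[3, ], p5 = q[4, ], p95 = q[5, ])
}

#' 3'/5' coverage ratio
#'
#' Scalar diagnostic for 3' coverage bias: the mean depth over the 3'-most
#' `tail_fraction` of positions divided by the mean over the 5'-most
#' `tail_fraction`. Returns `NA` when the 5' mean is zero. Values above 1
#' indicate the 3' excess typical of oligo(dT)-primed cDNA with 5'-truncated
#' reads.
#'
#' @param profile An `hla_coverage`.
#' @param tail_fraction Fraction of positions in each tail (default 0.2).
#' @return Numeric ratio, or `NA` if undefined.
#' @export
three_prime_bias <- function(profile, tail_fraction = 0.2) {
  stopifnot(inherits(profile, "hla_coverage"),
            tail_fraction > 0, tail_fraction <= 0.5)
  len <- length(profile$depth)
  k <- max(1L, floor(len * tail_fraction))
  head_mean <- mean(profile$depth[seq_len(k)])
  tail_mean <- mean(profile$depth[seq.int(len - k + 1L, len)])
  if (head_mean == 0) return(NA_real_)
  tail_mean / head_mean
}
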