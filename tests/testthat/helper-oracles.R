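# Brute-force oracles and tiny fixture builders shared across tests.

# Per-base reference-consumption walk over a CIGAR: returns the sorted
# 0-based positions consumed inside blocks (M/=/X/D) so contiguous runs are
# the aligned blocks; N advances without consuming.
oracle_blocks <- function(ref_start, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub(".$", "", ops))
  chars <- sub("^\\d+", "", ops)
  pos <- ref_start
  covered <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] %in% c("M", "=", "X", "D")) {
      covered <- c(covered, seq.int(pos, length.out = lens[i]))
      pos <- pos + lens[i]
    } else if (chars[i] == "N") {
      pos <- pos + lens[i]
    }
  }
  if (length(covered) == 0L) return(cbind(start = integer(), end = integer()))
  covered <- sort(covered)
  breaks <- which(diff(covered) > 1L)
  starts <- covered[c(1L, breaks + 1L)]
  ends <- covered[c(breaks, length(covered))] + 1L
  cbind(start = starts, end = ends)
}

# Random CIGAR built from blocks of M/D/I/N/S ops with >=1 M.
random_cigar <- function() {
  n_ops <- sample(1:8, 1)
  chars <- sample(c("M", "D", "I", "N", "S"), n_ops, replace = TRUE,
                  prob = c(0.5, 0.15, 0.1, 0.15, 0.1))
  if (!"M" %in% chars) chars[sample(n_ops, 1)] <- "M"
  # soft clips only at the ends, no leading/trailing D or N
  chars <- chars[!(chars %in% c("D", "N") &
                   seq_along(chars) %in% c(1L, length(chars)))]
  if (!"M" %in% chars) chars <- c("M", chars)
  lens <- sample(1:30, length(chars), replace = TRUE)
  paste0(lens, chars, collapse = "")
}

# Per-base exon-call oracle: coverage vector from blocks; retained iff any
# covered base inside the exon; excluded iff uncovered and flanked by
# retained exons on both sides.
oracle_call_exons <- function(blocks, exons, ref_len) {
  cov <- logical(ref_len)
  for (i in seq_len(nrow(blocks))) {
    cov[seq.int(blocks[i, 1] + 1L, blocks[i, 2])] <- TRUE
  }
  n <- nrow(exons)
  retained <- vapply(seq_len(n), function(k) {
    any(cov[seq.int(exons[k, 1] + 1L, exons[k, 2])])
  }, logical(1))
  calls <- rep("UNASSESSED", n)
  calls[retained] <- "RETAINED"
  for (k in seq_len(n)) {
    if (!retained[k] && any(retained[seq_len(n) < k]) &&
        any(retained[seq_len(n) > k])) {
      calls[k] <- "EXCLUDED"
    }
  }
  calls
}

# Minimal allele reference built in code (random sequence, given exon map).
toy_allele <- function(name = "DQB1*05:03:01:01",
                       exon_lengths = c(100L, 270L, 282L, 111L, 24L, 200L),
                       intron_lengths = c(60L, 50L, 40L, 35L, 30L),
                       seed = 42L) {
  cfg <- sim_config(seed = seed,
                    alleles = list(list(name = name,
                                        exon_lengths = exon_lengths,
                                        intron_lengths = intron_lengths)),
                    isoform_mixtures = stats::setNames(
                      list(c(stats::setNames(1, strrep("1", length(exon_lengths))))),
                      name),
                    n_reads = stats::setNames(0L, name),
                    truncation_rate = 0, contamination_rate = 0,
                    per_base_error = 0, n_decoys = 0L)
  make_toy_db(cfg)[[1]]
}

# An aligned-read object from raw blocks, bypassing SAM I/O.
toy_read <- function(allele, blocks, read_id = "r1") {
  structure(list(read_id = read_id, allele = format(allele$name),
                 blocks = cbind(start = as.integer(blocks[, 1]),
                                end = as.integer(blocks[, 2])),
                 is_primary = TRUE, mapq = 60L),
            class = "hla_aligned_read")
}

# Exon-call set built directly from a status vector.
toy_callset <- function(allele_name, calls, read_id = "r1") {
  structure(list(read_id = read_id, allele = allele_name, calls = calls),
            class = "hla_exon_calls")
}

# Random small exon map on a short reference; returns list(exons, ref_len).
random_exon_map <- function() {
  n_ex <- sample(2:6, 1)
  lens <- sample(2:10, n_ex, replace = TRUE)
  gaps <- sample(1:8, n_ex - 1L, replace = TRUE)
  starts <- cumsum(c(sample(0:5, 1), lens[-n_ex] + gaps))
  exons <- cbind(start = starts, end = starts + lens)
  list(exons = exons, ref_len = max(exons[, 2]) + sample(0:5, 1))
}

# Random block set within a reference length.
random_blocks <- function(ref_len) {
  n_b <- sample(1:4, 1)
  pts <- sort(sample(0:ref_len, 2L * n_b, replace = TRUE))
  # enforce strictly increasing alternating starts/ends
  pts <- unique(pts)
  while (length(pts) < 2L) pts <- sort(unique(c(pts, sample(0:ref_len, 2))))
  n_b <- length(pts) %/% 2L
  cbind(start = pts[seq(1, 2 * n_b, by = 2)],
        end = pts[seq(2, 2 * n_b, by = 2)])
}

# Exact binomial central 99% interval for a proportion estimate at size n.
binom99 <- function(p, n) {
  c(lo = stats::qbinom(0.005, n, p) / n, hi = stats::qbinom(0.995, n, p) / n)
}
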