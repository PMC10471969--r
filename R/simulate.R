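#' Simulation configuration
#'
#' Describes a synthetic study: a toy allele database layout, per-allele
#' isoform mixtures, read counts, a 5'-truncation model producing 3'
#' coverage bias, cross-allele contamination, and a per-base error rate
#' applied to FASTQ output only.
#'
#' Defaults emulate the observed behaviour of nanopore cDNA sequencing of
#' HLA-DQB1 in peripheral blood lymphocytes: a six-exon gene with a 24-nt
#' exon 5, one allele with an intact exon-5 splice acceptor retaining exon
#' 5 in 72% of transcripts, one allele with the acceptor lost (exon 5
#' always spliced out), about 140 reads per class II allele, half the reads
#' 5'-truncated with mean retained length 500 nt, 4% of reads emitted under
#' the wrong same-locus allele, and a 10% per-base error rate.
#'
#' @param seed Integer seed driving all randomness.
#' @param alleles List of allele layouts, each a list with `name` (allele
#'   name string), `exon_lengths`, `intron_lengths` (length
#'   `length(exon_lengths) - 1`). Alleles at the same locus must share a
#'   layout (contaminated reads keep their coordinates).
#' @param isoform_mixtures Named list: allele name -> named numeric vector
#'   of pattern probabilities (patterns are bit strings over exons with
#'   terminal bits 1; probabilities sum to 1).
#' @param n_reads Named integer vector: allele name -> read count.
#' @param truncation_rate Probability a read is 5'-truncated.
#' @param truncation_keep_mean Mean retained exonic length (nt) of a
#'   truncated read; the retained length is geometric from the 3' end.
#' @param contamination_rate Probability a read is emitted under the other
#'   same-locus allele's name.
#' @param per_base_error Substitution rate applied to FASTQ sequences only;
#'   the emitted SAM coordinates are exact.
#' @param divergence Number of substitutions distinguishing same-locus
#'   alleles in the toy database.
#' @param n_decoys Number of non-HLA decoy reads (random sequence, FASTQ
#'   only).
#' @return An `hla_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       alleles = list(
                         list(name = "DQB1*05:03:01:01",
                              exon_lengths = c(100L, 270L, 282L, 111L, 24L, 200L),
                              intron_lengths = c(400L, 300L, 250L, 220L, 150L)),
                         list(name = "DQB1*05:01:01:01",
                              exon_lengths = c(100L, 270L, 282L, 111L, 24L, 200L),
                              intron_lengths = c(400L, 300L, 250L, 220L, 150L))),
                       isoform_mixtures = list(
                         "DQB1*05:03:01:01" = c("111111" = 0.72,
                                                "111101" = 0.28),
                         "DQB1*05:01:01:01" = c("111101" = 1)),
                       n_reads = c("DQB1*05:03:01:01" = 140L,
                                   "DQB1*05:01:01:01" = 140L),
                       truncation_rate = 0.5,
                       truncation_keep_mean = 500,
                       contamination_rate = 0.04,
                       per_base_error = 0.1,
                       divergence = 40L,
                       n_decoys = 0L) {
  cfg <- list(seed = as.integer(seed), alleles = alleles,
              isoform_mixtures = isoform_mixtures, n_reads = n_reads,
              truncation_rate = truncation_rate,
              truncation_keep_mean = truncation_keep_mean,
              contamination_rate = contamination_rate,
              per_base_error = per_base_error,
              divergence = as.integer(divergence),
              n_decoys = as.integer(n_decoys))
  validate_sim_config(cfg)
  structure(cfg, class = "hla_sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$alleles) == 0L) {
    stop("simulation requires at least one allele", call. = FALSE)
  }
  names_ <- vapply(cfg$alleles, `[[`, character(1), "name")
  for (a in cfg$alleles) {
    if (any(a$exon_lengths <= 0L) || any(a$intron_lengths <= 0L)) {
      stop(sprintf("allele '%s': exon/intron lengths must be positive",
                   a$name), call. = FALSE)
    }
    if (length(a$intron_lengths) != length(a$exon_lengths) - 1L) {
      stop(sprintf("allele '%s': need one intron fewer than exons", a$name),
           call. = FALSE)
    }
  }
  # same-locus alleles must share the exon/intron layout
  locus <- vapply(names_, function(n) parse_allele_name(n)$locus,
                  character(1))
  for (l in unique(locus)) {
    las <- cfg$alleles[locus == l]
    if (length(las) > 1L) {
      ref <- las[[1L]]
      for (a in las[-1L]) {
        if (!identical(as.integer(a$exon_lengths),
                       as.integer(ref$exon_lengths)) ||
            !identical(as.integer(a$intron_lengths),
                       as.integer(ref$intron_lengths))) {
          stop(sprintf("alleles at locus '%s' must share an exon/intron layout",
                       l), call. = FALSE)
        }
      }
    }
  }
  for (an in names(cfg$isoform_mixtures)) {
    mix <- cfg$isoform_mixtures[[an]]
    if (abs(sum(mix) - 1) > 1e-9) {
      stop(sprintf("isoform mixture for '%s' must sum to 1", an),
           call. = FALSE)
    }
    n_ex <- length(cfg$alleles[[match(an, names_)]]$exon_lengths)
    for (p in names(mix)) {
      if (nchar(p) != n_ex || !grepl("^[01]+$", p)) {
        stop(sprintf("pattern '%s' inconsistent with %d exons of '%s'",
                     p, n_ex, an), call. = FALSE)
      }
      if (substr(p, 1L, 1L) != "1" || substr(p, n_ex, n_ex) != "1") {
        stop(sprintf("pattern '%s' must retain the terminal exons", p),
             call. = FALSE)
      }
    }
  }
  rates <- c(cfg$truncation_rate, cfg$contamination_rate, cfg$per_base_error)
  if (any(rates < 0) || any(rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a toy allele database
#'
#' Builds seeded random genomic sequences with the configured exon/intron
#' layout. Alleles at the same locus share one base sequence and differ at
#' `divergence` randomly chosen positions, mimicking allelic polymorphism.
#'
#' @param config An `hla_sim_config`.
#' @param out_dir Optional directory; when given, `alleles.fa` and
#'   `exons.bed` are written there.
#' @return Named list of `hla_allele_ref` (invisibly carries attribute
#'   `paths` when `out_dir` is given).
#' @export
make_toy_db <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "hla_sim_config"))
  set.seed(config$seed)
  names_ <- vapply(config$alleles, `[[`, character(1), "name")
  locus <- vapply(names_, function(n) parse_allele_name(n)$locus,
                  character(1))
  db <- list()
  base_seq <- list()
  for (i in seq_along(config$alleles)) {
    a <- config$alleles[[i]]
    ex <- as.integer(a$exon_lengths)
    intr <- as.integer(a$intron_lengths)
    total <- sum(ex) + sum(intr)
    if (is.null(base_seq[[locus[i]]])) {
      s <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                 collapse = "")
      base_seq[[locus[i]]] <- s
    } else {
      s <- base_seq[[locus[i]]]
      pos <- sample.int(total, min(config$divergence, total))
      chars <- strsplit(s, "")[[1]]
      for (p in pos) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      s <- paste(chars, collapse = "")
    }
    starts <- integer(length(ex))
    pos <- 0L
    for (k in seq_along(ex)) {
      starts[k] <- pos
      pos <- pos + ex[k] + if (k < length(ex)) intr[k] else 0L
    }
    exons <- cbind(start = starts, end = starts + ex)
    db[[a$name]] <- new_allele_ref(parse_allele_name(a$name), s, exons)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(out_dir, "alleles.fa")
    bed <- file.path(out_dir, "exons.bed")
    seqs <- Biostrings::DNAStringSet(
      vapply(db, function(a) a$sequence, character(1)))
    names(seqs) <- names(db)
    Biostrings::writeXStringSet(seqs, fasta)
    rows <- do.call(rbind, lapply(db, function(a) {
      data.frame(chrom = format(a$name), start = a$exons[, "start"],
                 end = a$exons[, "end"],
                 name = sprintf("%s|exon_%d", format(a$name),
                                seq_len(nrow(a$exons))),
                 score = 0L, strand = "+", stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    attr(db, "paths") <- c(fasta = fasta, exon_bed = bed)
  }
  db
}

# Aligned blocks for a pattern on an allele, with optional 5' truncation
# keeping the 3'-most `keep` exonic bases.
pattern_blocks <- function(allele, pattern, keep = NULL) {
  bits <- as.integer(strsplit(pattern, "")[[1]])
  stopifnot(length(bits) == nrow(allele$exons))
  ex <- allele$exons[bits == 1L, , drop = FALSE]
  if (!is.null(keep)) {
    lens <- ex[, "end"] - ex[, "start"]
    total <- sum(lens)
    keep <- min(keep, total)
    drop5 <- total - keep
    k <- 1L
    while (drop5 >= lens[k]) {
      drop5 <- drop5 - lens[k]
      k <- k + 1L
    }
    ex <- ex[seq.int(k, nrow(ex)), , drop = FALSE]
    ex[1L, "start"] <- ex[1L, "start"] + drop5
  }
  ex
}

cigar_from_blocks <- function(blocks) {
  n <- nrow(blocks)
  ops <- sprintf("%dM", blocks[, "end"] - blocks[, "start"])
  if (n > 1L) {
    gaps <- sprintf("%dN", blocks[-1L, "start"] - blocks[-n, "end"])
    paste0(paste(as.vector(rbind(ops[-n], gaps)), collapse = ""), ops[n])
  } else {
    ops
  }
}

seq_from_blocks <- function(sequence, blocks) {
  paste(substring(sequence, blocks[, "start"] + 1L, blocks[, "end"]),
        collapse = "")
}

#' Simulate spliced long reads with a known truth table
#'
#' For each configured allele, reads draw an isoform pattern from the
#' allele's mixture; aligned blocks are the retained exon intervals, with N
#' operations spanning introns and excluded exons. With probability
#' `truncation_rate` a read keeps only its 3'-most geometric number of
#' exonic bases (mean `truncation_keep_mean`), producing the 3' coverage
#' bias of oligo(dT)-primed cDNA. With probability `contamination_rate` a
#' read is emitted under the other same-locus allele's name (coordinates
#' unchanged), emulating cross-allele misalignment. The SAM records exact
#' coordinates and error-free sequence; sequencing errors apply to the
#' FASTQ only. Identical configurations produce byte-identical outputs.
#'
#' @param config An `hla_sim_config`.
#' @param db Database from [make_toy_db()] (must match the config).
#' @param out_dir Output directory.
#' @return List with `sam`, `fastq`, `truth_tsv` (paths) and `truth`
#'   (data.frame: `read_id`, `true_allele`, `emitted_allele`,
#'   `true_pattern`, `truncation_keep` (NA when untruncated),
#'   `contaminated`).
#' @export
simulate_reads <- function(config, db, out_dir = tempfile("sim_")) {
  stopifnot(inherits(config, "hla_sim_config"))
  names_ <- vapply(config$alleles, `[[`, character(1), "name")
  if (!all(names_ %in% names(db))) {
    stop("database does not match the configured alleles", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed + 1L)
  locus <- vapply(names_, function(n) parse_allele_name(n)$locus,
                  character(1))

  recs <- list()
  truth <- list()
  fastq_lines <- character(0)
  counter <- 0L
  geom_p <- 1 / config$truncation_keep_mean
  for (an in names_) {
    allele <- db[[an]]
    n <- config$n_reads[[an]]
    if (is.null(n) || n == 0L) next
    mix <- config$isoform_mixtures[[an]]
    if (is.null(mix)) {
      stop(sprintf("no isoform mixture configured for allele '%s'", an),
           call. = FALSE)
    }
    patterns <- sample(names(mix), n, replace = TRUE, prob = mix)
    truncated <- stats::runif(n) < config$truncation_rate
    contaminated <- stats::runif(n) < config$contamination_rate
    others <- names_[locus == locus[[match(an, names_)]] & names_ != an]
    for (i in seq_len(n)) {
      counter <- counter + 1L
      rid <- sprintf("read_%06d", counter)
      keep <- NA_integer_
      if (truncated[i]) {
        keep <- 1L + stats::rgeom(1L, geom_p)
      }
      blocks <- pattern_blocks(allele, patterns[i],
                               keep = if (truncated[i]) keep else NULL)
      if (truncated[i]) {
        keep <- sum(blocks[, "end"] - blocks[, "start"])  # after capping
      }
      emit <- an
      if (contaminated[i] && length(others) > 0L) {
        emit <- sample(others, 1L)
      } else {
        contaminated[i] <- FALSE
      }
      readseq <- seq_from_blocks(db[[emit]]$sequence, blocks)
      recs[[counter]] <- list(qname = rid, rname = emit,
                              pos = blocks[1L, "start"] + 1L,
                              cigar = cigar_from_blocks(blocks),
                              seq = readseq)
      # FASTQ: same bases with substitution errors
      fq_seq <- readseq
      if (config$per_base_error > 0) {
        chars <- strsplit(fq_seq, "")[[1]]
        err <- which(stats::runif(length(chars)) < config$per_base_error)
        for (p in err) {
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
        }
        fq_seq <- paste(chars, collapse = "")
      }
      qual <- strrep("/", nchar(fq_seq))  # constant Q14
      fastq_lines <- c(fastq_lines,
                       paste0("@", rid), fq_seq, "+", qual)
      truth[[counter]] <- data.frame(
        read_id = rid, true_allele = an, emitted_allele = emit,
        true_pattern = patterns[i],
        truncation_keep = if (truncated[i]) keep else NA_integer_,
        contaminated = contaminated[i], stringsAsFactors = FALSE)
    }
  }

  if (config$n_decoys > 0L) {
    for (d in seq_len(config$n_decoys)) {
      s <- paste(sample(c("A", "C", "G", "T"), 600L, replace = TRUE),
                 collapse = "")
      fastq_lines <- c(fastq_lines, sprintf("@decoy_%04d", d), s, "+",
                       strrep("/", nchar(s)))
    }
  }

  sam_path <- file.path(out_dir, "reads.sam")
  fastq_path <- file.path(out_dir, "reads.fastq")
  truth_path <- file.path(out_dir, "truth.tsv")

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              vapply(names(db), function(a) {
                sprintf("@SQ\tSN:%s\tLN:%d", a, nchar(db[[a]]$sequence))
              }, character(1)))
  if (length(recs) > 0L) {
    rname <- vapply(recs, `[[`, character(1), "rname")
    pos <- vapply(recs, function(r) r$pos, numeric(1))
    ord <- order(match(rname, names(db)), pos)
    body <- vapply(recs[ord], function(r) {
      paste(r$qname, 0L, r$rname, r$pos, 60L, r$cigar, "*", 0L, 0L,
            r$seq, strrep("/", nchar(r$seq)), sep = "\t")
    }, character(1))
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), sam_path)
  writeLines(fastq_lines, fastq_path)
  truth_df <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(read_id = character(), true_allele = character(),
               emitted_allele = character(), true_pattern = character(),
               truncation_keep = integer(), contaminated = logical(),
               stringsAsFactors = FALSE)
  utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(sam = sam_path, fastq = fastq_path, truth_tsv = truth_path,
       truth = truth_df)
}
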