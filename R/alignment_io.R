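#' Reference-coordinate aligned blocks from a CIGAR string
#'
#' Walks a CIGAR string and returns the reference intervals covered by the
#' alignment, in 0-based half-open coordinates. Match operations (M/=/X) and
#' deletions (D) extend the current block -- a deletion of any length does
#' not split a block -- while reference skips (N, introns in spliced
#' alignments) close the current block and open a new one after the skip.
#' Insertions and clips (I/S/H/P) consume no reference.
#'
#' @param ref_start 0-based reference start of the alignment.
#' @param cigar CIGAR string, e.g. `"50M100N50M"`.
#' @return Integer matrix with columns `start`, `end`, one row per block,
#'   sorted ascending.
#' @examples
#' blocks_from_cigar(0, "50M100N50M")
#' @export
blocks_from_cigar <- function(ref_start, cigar) {
  stopifnot(ref_start >= 0)
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    stop("alignment has no CIGAR", call. = FALSE)
  }
  ops <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1]]
  if (sum(nchar(ops)) != nchar(cigar)) {
    stop(sprintf("invalid CIGAR string: '%s'", cigar), call. = FALSE)
  }
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  chars <- sub("^\\d+", "", ops)
  bad <- setdiff(chars, c("M", "=", "X", "D", "N", "I", "S", "H", "P"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid CIGAR operation(s): %s", paste(bad, collapse = "")),
         call. = FALSE)
  }
  starts <- integer(0)
  ends <- integer(0)
  pos <- as.integer(ref_start)
  block_start <- NA_integer_
  for (i in seq_along(chars)) {
    op <- chars[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(block_start)) block_start <- pos
      pos <- pos + lens[i]
    } else if (op == "N") {
      if (!is.na(block_start) && pos > block_start) {
        starts <- c(starts, block_start)
        ends <- c(ends, pos)
      }
      block_start <- NA_integer_
      pos <- pos + lens[i]
    }
    # I/S/H/P: no reference consumed
  }
  if (!is.na(block_start) && pos > block_start) {
    starts <- c(starts, block_start)
    ends <- c(ends, pos)
  }
  # merge blocks separated by zero-length skips
  if (length(starts) > 1L) {
    keep_start <- starts[1]
    ms <- integer(0); me <- integer(0)
    cur_s <- starts[1]; cur_e <- ends[1]
    for (i in 2:length(starts)) {
      if (starts[i] == cur_e) {
        cur_e <- ends[i]
      } else {
        ms <- c(ms, cur_s); me <- c(me, cur_e)
        cur_s <- starts[i]; cur_e <- ends[i]
      }
    }
    ms <- c(ms, cur_s); me <- c(me, cur_e)
    starts <- ms; ends <- me
  }
  cbind(start = starts, end = ends)
}

#' Load spliced alignments as per-read block sets
#'
#' Reads a SAM or BAM file and returns one aligned-read record per primary,
#' mapped, non-supplementary alignment whose reference is an allele of the
#' bundle. SAM input is converted through `Rsamtools::asBam()`. Reads
#' aligned to references absent from the bundle are dropped (a message
#' reports the count). No mapping-quality filter is applied by default.
#'
#' @param sam_path Path to a SAM (`.sam`) or BAM file.
#' @param bundle An `hla_ref_bundle`; reference names must match its allele
#'   names.
#' @param min_mapq Optional minimum MAPQ (default 0, i.e. no filter).
#' @return A list of `hla_aligned_read` objects: each a list with
#'   `read_id`, `allele` (character allele name), `blocks` (matrix as from
#'   [blocks_from_cigar()]), `is_primary`, `mapq`.
#' @export
load_alignments <- function(sam_path, bundle, min_mapq = 0L) {
  stopifnot(inherits(bundle, "hla_ref_bundle"))
  if (!file.exists(sam_path)) {
    stop(sprintf("alignment file not found: %s", sam_path), call. = FALSE)
  }
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(sam_path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "rname", "pos", "mapq", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  allele_names <- names(bundle$alleles)
  in_bundle <- as.character(rec$rname) %in% allele_names
  n_dropped <- sum(!in_bundle)
  if (n_dropped > 0L) {
    message(sprintf("dropped %d alignment(s) to references absent from bundle",
                    n_dropped))
  }
  keep <- which(in_bundle & !is.na(rec$mapq) & rec$mapq >= min_mapq |
                in_bundle & is.na(rec$mapq) & min_mapq == 0L)
  ref_len <- vapply(bundle$alleles, function(a) nchar(a$sequence), integer(1))
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    allele <- as.character(rec$rname[i])
    blocks <- blocks_from_cigar(rec$pos[i] - 1L, rec$cigar[i])
    if (blocks[nrow(blocks), "end"] > ref_len[[allele]]) {
      stop(sprintf("read '%s': aligned blocks exceed reference '%s' length",
                   rec$qname[i], allele), call. = FALSE)
    }
    out[[j]] <- structure(
      list(read_id = rec$qname[i], allele = allele, blocks = blocks,
           is_primary = TRUE, mapq = rec$mapq[i]),
      class = "hla_aligned_read")
  }
  out
}

#' Two-pass spliced alignment with an external aligner
#'
#' Thin wrapper around a minimap2-style spliced aligner implementing the
#' two-pass scheme: reads are first aligned to a set of coding sequences in
#' spliced mode with secondary alignments suppressed; read IDs with any
#' primary alignment become candidate HLA reads; only candidates are then
#' realigned to the donor-specific genomic reference bundle with splice
#' junction hints. All downstream logic works identically on externally
#' supplied SAM, so this wrapper is optional.
#'
#' @param reads_fastq Path to the input FASTQ.
#' @param cds_fasta Path to the coding-sequence FASTA used for candidate
#'   selection.
#' @param bundle An `hla_ref_bundle`.
#' @param out_dir Output directory.
#' @param aligner Aligner executable (default `"minimap2"`).
#' @param extra_args Extra arguments appended to both passes.
#' @return Path to the pass-2 SAM file.
#' @export
run_two_pass_alignment <- function(reads_fastq, cds_fasta, bundle,
                                   out_dir = tempfile("align_"),
                                   aligner = "minimap2",
                                   extra_args = character()) {
  stopifnot(inherits(bundle, "hla_ref_bundle"))
  if (Sys.which(aligner) == "") {
    stop(sprintf("spliced aligner '%s' not found on PATH", aligner),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reads <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(reads_fastq),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (length(reads) == 0L) {
    warning("empty FASTQ; emitting an empty SAM")
  }

  run_aligner <- function(args, out_sam) {
    log_file <- paste0(out_sam, ".log")
    status <- system2(aligner, args, stdout = out_sam, stderr = log_file)
    if (status != 0L) {
      stop(sprintf("aligner '%s' failed (exit %d):\n%s", aligner, status,
                   paste(readLines(log_file, warn = FALSE),
                         collapse = "\n")), call. = FALSE)
    }
    out_sam
  }

  pass1_sam <- file.path(out_dir, "pass1.sam")
  run_aligner(c("-a", "-x", "splice", "--secondary=no", extra_args,
                shQuote(cds_fasta), shQuote(reads_fastq)), pass1_sam)
  lines <- readLines(pass1_sam)
  body <- lines[!startsWith(lines, "@")]
  candidates <- character(0)
  if (length(body) > 0L) {
    f <- strsplit(body, "\t", fixed = TRUE)
    qn <- vapply(f, `[[`, character(1), 1L)
    flag <- as.integer(vapply(f, `[[`, character(1), 2L))
    mapped <- bitwAnd(flag, 4L) == 0L
    candidates <- unique(qn[mapped])
  }

  cand_fastq <- file.path(out_dir, "candidates.fastq")
  ids <- sub("\\s.*$", "", names(reads))
  sel <- reads[ids %in% candidates]
  Biostrings::writeQualityScaledXStringSet(sel, cand_fastq)

  paths <- write_bundle(bundle, out_dir)
  pass2_sam <- file.path(out_dir, "pass2.sam")
  run_aligner(c("-a", "-x", "splice", "--secondary=no",
                paste0("--junc-bed=", shQuote(paths[["junction_bed"]])),
                extra_args, shQuote(paths[["fasta"]]), shQuote(cand_fastq)),
              pass2_sam)
  pass2_sam
}
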