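#' Parse an allele database (FASTA + exon BED)
#'
#' Reads genomic allele sequences from a FASTA file whose record IDs are full
#' allele names, and attaches exon annotations from a BED file (0-based
#' half-open; the `name` column is ignored, intervals are grouped by their
#' `chrom` which must be a FASTA record ID). Exons are sorted and validated
#' against sequence bounds.
#'
#' @param fasta_path Path to the allele FASTA.
#' @param exon_bed_path Path to the exon BED (>= 3 columns, tab-separated).
#' @return A named list of `hla_allele_ref` objects, one per FASTA record.
#'   Each has `name` (an [parse_allele_name()] object), `sequence`
#'   (character), `exons` (integer matrix with columns `start`, `end`),
#'   and `locus_class`.
#' @export
parse_allele_db <- function(fasta_path, exon_bed_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  bed <- utils::read.table(exon_bed_path, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("exon BED needs at least 3 columns", call. = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  db <- vector("list", length(seqs))
  names(db) <- ids
  for (i in seq_along(seqs)) {
    id <- ids[i]
    nm <- tryCatch(parse_allele_name(id), error = function(e) {
      stop(sprintf("FASTA record %d: %s", i, conditionMessage(e)),
           call. = FALSE)
    })
    rows <- bed[bed$chrom == id, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop(sprintf("no exon annotations for FASTA record '%s'", id),
           call. = FALSE)
    }
    exons <- cbind(start = as.integer(rows$start), end = as.integer(rows$end))
    exons <- exons[order(exons[, "start"]), , drop = FALSE]
    db[[i]] <- new_allele_ref(nm, as.character(seqs[[i]]), exons)
  }
  orphan <- setdiff(unique(bed$chrom), ids)
  if (length(orphan) > 0L) {
    warning(sprintf("exon BED references %d sequence(s) absent from FASTA: %s",
                    length(orphan), paste(orphan, collapse = ", ")))
  }
  db
}

# Constructor with invariant checks shared by parser and simulator.
new_allele_ref <- function(name, sequence, exons) {
  stopifnot(inherits(name, "hla_allele_name"), is.character(sequence),
            is.matrix(exons), ncol(exons) == 2L, nrow(exons) >= 1L)
  len <- nchar(sequence)
  id <- format(name)
  if (any(exons[, 1] < 0L) || any(exons[, 2] > len)) {
    stop(sprintf("allele '%s': exon interval outside sequence bounds [0, %d)",
                 id, len), call. = FALSE)
  }
  if (any(exons[, 2] <= exons[, 1])) {
    stop(sprintf("allele '%s': empty or inverted exon interval", id),
         call. = FALSE)
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1] < exons[-nrow(exons), 2])) {
    stop(sprintf("allele '%s': overlapping exon intervals", id),
         call. = FALSE)
  }
  colnames(exons) <- c("start", "end")
  structure(list(name = name, sequence = sequence,
                 exons = exons, locus_class = locus_class(name)),
            class = "hla_allele_ref")
}

#' @export
print.hla_allele_ref <- function(x, ...) {
  cat(sprintf("<hla_allele_ref> %s (%s): %d nt, %d exons\n",
              format(x$name), x$locus_class, nchar(x$sequence),
              nrow(x$exons)))
  invisible(x)
}

#' Resolve a typed allele to its full-resolution reference allele
#'
#' Given a (possibly low-resolution) typed allele name, returns the database
#' allele with the lowest four-field nomenclature consistent with the type:
#' same locus, identical leading fields, minimal under field-wise numeric
#' ordering (field 1, then 2, 3, 4). Ties on all fields are broken by
#' preferring alleles without an expression suffix, then by suffix order.
#'
#' @param typed An `hla_allele_name` or a string parseable as one.
#' @param db A database as returned by [parse_allele_db()].
#' @return The matching `hla_allele_ref`.
#' @export
resolve_allele <- function(typed, db) {
  if (is.character(typed)) typed <- parse_allele_name(typed)
  stopifnot(length(db) > 0L)
  cand_names <- lapply(db, function(a) a$name)
  ok <- vapply(cand_names, function(full) allele_name_prefix(typed, full),
               logical(1))
  if (!any(ok)) {
    stop(sprintf("no database allele consistent with typed allele '%s'",
                 format(typed)), call. = FALSE)
  }
  cand <- db[ok]
  cand[[allele_name_order(lapply(cand, function(a) a$name))[1L]]]
}

#' Read a genotype table
#'
#' Reads a tab-separated genotype table with columns `sample_id`, `locus`,
#' `allele1`, `allele2` (allele2 may be empty or `NA` for hemizygous loci).
#'
#' @param path Path to the TSV.
#' @return A named list of `hla_genotype` objects (one per sample), each a
#'   list with `sample_id` and `calls` (locus -> list of typed allele names).
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "locus", "allele1", "allele2")
  if (!all(need %in% names(tab))) {
    stop(sprintf("genotype table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  out <- list()
  for (sid in unique(tab$sample_id)) {
    rows <- tab[tab$sample_id == sid, , drop = FALSE]
    calls <- list()
    for (j in seq_len(nrow(rows))) {
      a <- list(parse_allele_name(rows$allele1[j]))
      a2 <- rows$allele2[j]
      if (!is.na(a2) && nzchar(a2)) a <- c(a, list(parse_allele_name(a2)))
      calls[[rows$locus[j]]] <- a
    }
    out[[sid]] <- structure(list(sample_id = sid, calls = calls),
                            class = "hla_genotype")
  }
  out
}

#' Build a donor-specific reference bundle
#'
#' Resolves every typed allele in a genotype against the database and
#' collects the resulting reference alleles (deduplicated, so a homozygous
#' locus contributes a single reference and all its reads count toward it),
#' together with the splice junctions implied by consecutive exon
#' boundaries (donor = exon i end, acceptor = exon i+1 start).
#'
#' @param genotype An `hla_genotype` (see [read_genotypes()]).
#' @param db A database as returned by [parse_allele_db()].
#' @return An `hla_ref_bundle`: list with `sample_id`, `alleles` (named list
#'   of `hla_allele_ref`), and `junctions` (data.frame with columns
#'   `allele`, `donor`, `acceptor`).
#' @export
build_reference_bundle <- function(genotype, db) {
  stopifnot(inherits(genotype, "hla_genotype"))
  alleles <- list()
  for (locus in names(genotype$calls)) {
    for (typed in genotype$calls[[locus]]) {
      ref <- resolve_allele(typed, db)
      alleles[[format(ref$name)]] <- ref
    }
  }
  junctions <- do.call(rbind, lapply(alleles, function(a) {
    n <- nrow(a$exons)
    if (n < 2L) return(NULL)
    data.frame(allele = format(a$name),
               donor = a$exons[-n, "end"],
               acceptor = a$exons[-1L, "start"],
               stringsAsFactors = FALSE)
  }))
  if (is.null(junctions)) {
    junctions <- data.frame(allele = character(), donor = integer(),
                            acceptor = integer(), stringsAsFactors = FALSE)
  }
  rownames(junctions) <- NULL
  stopifnot(all(junctions$donor < junctions$acceptor))
  structure(list(sample_id = genotype$sample_id, alleles = alleles,
                 junctions = junctions),
            class = "hla_ref_bundle")
}

#' @export
print.hla_ref_bundle <- function(x, ...) {
  cat(sprintf("<hla_ref_bundle> sample %s: %d allele(s), %d junction(s)\n",
              x$sample_id, length(x$alleles), nrow(x$junctions)))
  invisible(x)
}

#' Write a reference bundle to disk
#'
#' Emits three files into `out_dir`: `<sample>.fa` (allele genomic
#' sequences), `<sample>.exons.bed` (BED6, name = `allele|exon_k`), and
#' `<sample>.junctions.bed` (one row per splice junction, usable as a
#' spliced aligner's junction-hint file). Reading the FASTA + exon BED back
#' with [parse_allele_db()] reproduces the bundle's alleles exactly.
#'
#' @param bundle An `hla_ref_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths
#'   (`fasta`, `exon_bed`, `junction_bed`).
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "hla_ref_bundle"))
  if (length(bundle$alleles) == 0L) {
    stop("cannot write an empty reference bundle", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(out_dir, bundle$sample_id)
  fasta <- paste0(base, ".fa")
  exon_bed <- paste0(base, ".exons.bed")
  junction_bed <- paste0(base, ".junctions.bed")

  seqs <- Biostrings::DNAStringSet(
    vapply(bundle$alleles, function(a) a$sequence, character(1)))
  names(seqs) <- vapply(bundle$alleles, function(a) format(a$name),
                        character(1))
  Biostrings::writeXStringSet(seqs, fasta)

  exon_rows <- do.call(rbind, lapply(bundle$alleles, function(a) {
    data.frame(chrom = format(a$name),
               start = a$exons[, "start"], end = a$exons[, "end"],
               name = sprintf("%s|exon_%d", format(a$name),
                              seq_len(nrow(a$exons))),
               score = 0L, strand = "+", stringsAsFactors = FALSE)
  }))
  utils::write.table(exon_rows, exon_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  jx <- bundle$junctions
  jx_rows <- data.frame(chrom = jx$allele, start = jx$donor, end = jx$acceptor,
                        name = sprintf("junc_%d", seq_len(nrow(jx))),
                        score = 0L, strand = "+", stringsAsFactors = FALSE)
  utils::write.table(jx_rows, junction_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  c(fasta = fasta, exon_bed = exon_bed, junction_bed = junction_bed)
}
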