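# Minimal --flag value parser; flags with no value become TRUE.
parse_cli_flags <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) {
      stop(sprintf("unexpected positional argument '%s'", a), call. = FALSE)
    }
    key <- sub("^--", "", a)
    if (grepl("=", key, fixed = TRUE)) {
      kv <- strsplit(key, "=", fixed = TRUE)[[1]]
      out[[kv[1]]] <- paste(kv[-1], collapse = "=")
      i <- i + 1L
    } else if (i < length(argv) && !startsWith(argv[i + 1L], "--")) {
      out[[key]] <- argv[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

require_flags <- function(flags, needed, usage) {
  missing <- setdiff(needed, names(flags))
  if (length(missing) > 0L) {
    stop(structure(class = c("cli_usage_error", "error", "condition"),
                   list(message = sprintf("missing required flag(s): %s\n%s",
                                          paste0("--", missing,
                                                 collapse = ", "), usage),
                        call = NULL)))
  }
}

#' Treat every database allele as one sample's reference bundle
#'
#' Convenience for simulated or single-donor data where the database
#' already contains exactly the donor's alleles.
#'
#' @param db Named list of `hla_allele_ref`.
#' @param sample_id Sample identifier.
#' @return An `hla_ref_bundle`.
#' @export
bundle_from_db <- function(db, sample_id) {
  stopifnot(length(db) > 0L)
  junctions <- do.call(rbind, lapply(db, function(a) {
    n <- nrow(a$exons)
    if (n < 2L) return(NULL)
    data.frame(allele = format(a$name), donor = a$exons[-n, "end"],
               acceptor = a$exons[-1L, "start"], stringsAsFactors = FALSE)
  }))
  if (is.null(junctions)) {
    junctions <- data.frame(allele = character(), donor = integer(),
                            acceptor = integer(), stringsAsFactors = FALSE)
  }
  rownames(junctions) <- NULL
  structure(list(sample_id = sample_id, alleles = db, junctions = junctions),
            class = "hla_ref_bundle")
}

#' Per-locus exon retention summary as JSON
#'
#' Writes, for every (locus, exon) over alleles passing the read-count
#' threshold, the median retention rate and the number of contributing
#' alleles.
#'
#' @param usage An `hla_usage_table` (may span samples).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_usage_summary_json <- function(usage, path) {
  rows <- usage[usage$passes_threshold & !is.na(usage$retention_rate), ,
                drop = FALSE]
  rows$locus <- vapply(rows$allele,
                       function(a) parse_allele_name(a)$locus, character(1))
  key <- interaction(rows$locus, rows$exon_index, drop = TRUE)
  sp <- split(rows$retention_rate, key)
  meta <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
  out <- data.frame(locus = meta[, 1],
                    exon_index = as.integer(meta[, 2]),
                    median_retention = vapply(sp, stats::median, numeric(1)),
                    n_alleles = vapply(sp, length, integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$locus, out$exon_index), , drop = FALSE]
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# Run log with package version, config hash, and input checksums.
write_run_log <- function(path, config_obj, inputs) {
  cfg_file <- tempfile()
  jsonlite::write_json(config_obj, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  files <- unlist(inputs)
  files <- files[file.exists(files)]
  sums <- tools::md5sum(files)
  lines <- c(sprintf("splicehla version: %s",
                     as.character(utils::packageVersion("splicehla"))),
             sprintf("config md5: %s", cfg_hash),
             sprintf("input %s: md5 %s", names(files), unname(sums)))
  writeLines(lines, path)
  invisible(path)
}
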