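# Recognized classical loci. Class I: A/B/C; the rest are class II.
HLA_LOCI <- c("A", "B", "C", "DPA1", "DPB1", "DQA1", "DQB1",
              "DRB1", "DRB3", "DRB4", "DRB5")
CLASS_I_LOCI <- c("A", "B", "C")
EXPRESSION_SUFFIXES <- c("N", "Q", "L", "S", "A", "C")

#' Parse an HLA allele name
#'
#' Parses colon-delimited IMGT/HLA nomenclature such as `"DQB1*05:03:01:01"`
#' into its locus, 1-4 numeric fields, and optional expression suffix
#' (N/Q/L/S/A/C). Field widths are normalized: fields are stored as integers
#' and re-printed zero-padded to two digits, the convention used by the
#' IPD-IMGT/HLA database, so formatting a parsed name reproduces the input.
#'
#' @param x Character scalar, e.g. `"A*24:02:01:01"` or `"DQB1*05:03"`.
#' @return An object of class `hla_allele_name`: a list with elements
#'   `locus` (character), `fields` (integer vector of length 1-4) and
#'   `suffix` (character, `""` when absent).
#' @examples
#' nm <- parse_allele_name("DQB1*05:03:01:01")
#' nm$locus
#' format(nm)
#' @export
parse_allele_name <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("allele name must be a single character string", call. = FALSE)
  }
  m <- regexec("^([A-Z][A-Z0-9]*)\\*([0-9]+(?::[0-9]+){0,3})([NQLSAC]?)$", x)
  g <- regmatches(x, m)[[1]]
  if (length(g) == 0L) {
    stop(sprintf("malformed allele name: '%s'", x), call. = FALSE)
  }
  locus <- g[2]
  if (!locus %in% HLA_LOCI) {
    stop(sprintf("unrecognized HLA locus '%s' in allele name '%s'", locus, x),
         call. = FALSE)
  }
  fields <- as.integer(strsplit(g[3], ":", fixed = TRUE)[[1]])
  if (any(fields <= 0L)) {
    stop(sprintf("allele name fields must be positive integers: '%s'", x),
         call. = FALSE)
  }
  structure(list(locus = locus, fields = fields, suffix = g[4]),
            class = "hla_allele_name")
}

#' @export
format.hla_allele_name <- function(x, ...) {
  paste0(x$locus, "*", paste(sprintf("%02d", x$fields), collapse = ":"),
         x$suffix)
}

#' @export
as.character.hla_allele_name <- function(x, ...) format(x)

#' @export
print.hla_allele_name <- function(x, ...) {
  cat("<hla_allele_name> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Locus class of an HLA locus or allele name
#'
#' @param x A locus string (e.g. `"DQB1"`) or an `hla_allele_name`.
#' @return `"CLASS_I"` for HLA-A/B/C, `"CLASS_II"` otherwise.
#' @export
locus_class <- function(x) {
  locus <- if (inherits(x, "hla_allele_name")) x$locus else x
  stopifnot(locus %in% HLA_LOCI)
  if (locus %in% CLASS_I_LOCI) "CLASS_I" else "CLASS_II"
}

# Is `typed` a field-prefix of `full` (same locus, same leading fields)?
allele_name_prefix <- function(typed, full) {
  if (typed$locus != full$locus) return(FALSE)
  k <- length(typed$fields)
  if (k > length(full$fields)) return(FALSE)
  all(typed$fields == full$fields[seq_len(k)])
}

# Ordering key for "lowest nomenclature": field-wise numeric comparison,
# then no-suffix before suffixed, then suffix character order.
allele_name_order <- function(names_list) {
  n <- length(names_list)
  f <- matrix(0L, nrow = n, ncol = 4L)
  for (i in seq_len(n)) {
    fl <- names_list[[i]]$fields
    f[i, seq_along(fl)] <- fl
  }
  sfx <- vapply(names_list, function(a) a$suffix, character(1))
  sfx_rank <- ifelse(sfx == "", 0L, match(sfx, EXPRESSION_SUFFIXES))
  order(f[, 1], f[, 2], f[, 3], f[, 4], sfx_rank)
}
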