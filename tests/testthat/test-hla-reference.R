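test_that("allele names parse, validate, and round-trip", {
  nm <- parse_allele_name("DQB1*05:03:01:01")
  expect_equal(nm$locus, "DQB1")
  expect_equal(nm$fields, c(5L, 3L, 1L, 1L))
  expect_equal(nm$suffix, "")
  expect_equal(format(nm), "DQB1*05:03:01:01")
  expect_equal(format(parse_allele_name("A*24:02")), "A*24:02")
  expect_equal(parse_allele_name("C*04:09N")$suffix, "N")
  expect_equal(format(parse_allele_name("C*04:09N")), "C*04:09N")
  expect_equal(format(parse_allele_name("DRB1*15:101")), "DRB1*15:101")
  expect_error(parse_allele_name("DQB1-05:03"), "malformed")
  expect_error(parse_allele_name("ZZ9*01:01"), "unrecognized HLA locus")
  expect_error(parse_allele_name("A*00:01"), "positive")
  expect_equal(locus_class("A"), "CLASS_I")
  expect_equal(locus_class(parse_allele_name("DQB1*05:03")), "CLASS_II")
})

write_toy_db_files <- function(dir, records) {
  # records: named list allele -> list(seq, exons matrix)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "db.fa")
  bed <- file.path(dir, "db.bed")
  writeLines(unlist(lapply(names(records), function(n) {
    c(paste0(">", n), records[[n]]$seq)
  })), fa)
  rows <- do.call(rbind, lapply(names(records), function(n) {
    e <- records[[n]]$exons
    data.frame(n, e[, 1], e[, 2])
  }))
  utils::write.table(rows, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(fa = fa, bed = bed)
}

test_that("allele database parses FASTA + exon BED with validation", {
  dir <- withr::local_tempdir()
  set.seed(11)
  seq600 <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  seq400 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  exons6 <- cbind(c(0, 110, 200, 300, 420, 500),
                  c(100, 180, 280, 400, 444, 600))
  paths <- write_toy_db_files(dir, list(
    "DQB1*05:03:01:01" = list(seq = seq600, exons = exons6),
    "A*24:02:01:01" = list(seq = seq400,
                           exons = cbind(c(0, 200), c(150, 380)))))
  db <- parse_allele_db(paths$fa, paths$bed)
  expect_length(db, 2)
  expect_equal(nrow(db[["DQB1*05:03:01:01"]]$exons), 6)
  expect_equal(db[["DQB1*05:03:01:01"]]$locus_class, "CLASS_II")
  expect_equal(db[["A*24:02:01:01"]]$locus_class, "CLASS_I")

  # exon beyond sequence bounds
  bad <- write_toy_db_files(file.path(dir, "bad"), list(
    "DQB1*05:03:01:01" = list(seq = seq600,
                              exons = cbind(c(0, 500), c(100, 700)))))
  expect_error(parse_allele_db(bad$fa, bad$bed), "bounds")

  # FASTA record with no exon rows
  bad2 <- write_toy_db_files(file.path(dir, "bad2"), list(
    "DQB1*05:03:01:01" = list(seq = seq600, exons = cbind(0, 100))))
  fa2 <- file.path(dir, "bad2", "two.fa")
  writeLines(c(readLines(bad2$fa), ">A*24:02:01:01", seq400), fa2)
  expect_error(parse_allele_db(fa2, bad2$bed), "no exon annotations")
})

test_that("typed alleles resolve to the lowest four-field reference", {
  dir <- withr::local_tempdir()
  mk <- function(names) {
    recs <- lapply(names, function(n) {
      list(seq = strrep("ACGT", 25), exons = cbind(0, 50))
    })
    names(recs) <- names
    p <- write_toy_db_files(dir, recs)
    parse_allele_db(p$fa, p$bed)
  }
  db <- mk(c("DQB1*05:03:01:01", "DQB1*05:03:08:01", "DQB1*05:01:01:01",
             "C*04:01:01:06", "C*04:01:01:01", "A*24:02:01:01"))
  expect_equal(format(resolve_allele("DQB1*05:03", db)$name),
               "DQB1*05:03:01:01")
  expect_equal(format(resolve_allele("A*24:02:01:01", db)$name),
               "A*24:02:01:01")
  expect_equal(format(resolve_allele("C*04:01", db)$name), "C*04:01:01:01")
  expect_error(resolve_allele("B*07:02", db), "no database allele")
})

test_that("resolution matches a brute-force minimum and prefers no suffix", {
  set.seed(202)
  for (rep in 1:50) {
    n <- sample(3:10, 1)
    fields <- cbind(sample(1:4, n, TRUE), sample(1:4, n, TRUE),
                    sample(1:3, n, TRUE), sample(1:3, n, TRUE))
    sfx <- sample(c("", "", "", "N", "Q"), n, TRUE)
    nm <- unique(sprintf("DQB1*%02d:%02d:%02d:%02d%s", fields[, 1],
                         fields[, 2], fields[, 3], fields[, 4], sfx))
    db <- lapply(nm, function(x) {
      structure(list(name = parse_allele_name(x), sequence = "ACGT",
                     exons = cbind(start = 0L, end = 4L),
                     locus_class = "CLASS_II"), class = "hla_allele_ref")
    })
    names(db) <- nm
    typed <- parse_allele_name(
      sprintf("DQB1*%02d:%02d", fields[1, 1], fields[1, 2]))
    # brute force: filter by string prefix on the two typed fields, then
    # sort on a padded sort key
    pref <- sprintf("DQB1*%02d:%02d", fields[1, 1], fields[1, 2])
    consistent <- nm[vapply(nm, function(x) {
      startsWith(x, paste0(pref, ":")) || x == pref ||
        grepl(paste0("^", gsub("\\*", "\\\\*", pref), "[NQ]?$"), x)
    }, logical(1))]
    key <- vapply(consistent, function(x) {
      a <- parse_allele_name(x)
      sprintf("%03d:%03d:%03d:%03d:%d", a$fields[1], a$fields[2],
              a$fields[3], a$fields[4],
              ifelse(a$suffix == "", 0L, match(a$suffix, c("N", "Q"))))
    }, character(1))
    expected <- consistent[order(key)][1]
    got <- resolve_allele(typed, db)
    expect_equal(format(got$name), expected)
    # prefix property + idempotence
    expect_true(startsWith(format(got$name), pref))
    expect_equal(format(resolve_allele(got$name, db)$name),
                 format(got$name))
  }
})

test_that("reference bundles collect resolved alleles and junctions", {
  cfg <- sim_config(seed = 5)
  db <- make_toy_db(cfg)
  gt <- structure(list(sample_id = "cDNA001",
                       calls = list(DQB1 = list(
                         parse_allele_name("DQB1*05:03"),
                         parse_allele_name("DQB1*05:01")))),
                  class = "hla_genotype")
  bundle <- build_reference_bundle(gt, db)
  expect_length(bundle$alleles, 2)
  expect_equal(nrow(bundle$junctions), 10)  # 5 junctions per 6-exon allele
  expect_true(all(bundle$junctions$donor < bundle$junctions$acceptor))
  jx <- bundle$junctions[bundle$junctions$allele == "DQB1*05:03:01:01", ]
  ex <- db[["DQB1*05:03:01:01"]]$exons
  expect_equal(jx$donor, unname(ex[-6, "end"]))
  expect_equal(jx$acceptor, unname(ex[-1, "start"]))

  # homozygous genotype collapses to a single reference allele
  gt_hom <- structure(list(sample_id = "s2",
                           calls = list(DQB1 = list(
                             parse_allele_name("DQB1*05:03"),
                             parse_allele_name("DQB1*05:03")))),
                      class = "hla_genotype")
  expect_length(build_reference_bundle(gt_hom, db)$alleles, 1)
})

test_that("bundle write/parse round-trip is exact", {
  cfg <- sim_config(seed = 9)
  db <- make_toy_db(cfg)
  bundle <- bundle_from_db(db, "cDNA001")
  dir <- withr::local_tempdir()
  paths <- write_bundle(bundle, dir)
  back <- parse_allele_db(paths[["fasta"]], paths[["exon_bed"]])
  expect_equal(names(back), names(bundle$alleles))
  for (n in names(back)) {
    expect_identical(back[[n]]$sequence, bundle$alleles[[n]]$sequence)
    expect_equal(unname(back[[n]]$exons), unname(bundle$alleles[[n]]$exons))
  }
  # junction file rows match junction count
  jx <- utils::read.table(paths[["junction_bed"]], sep = "\t")
  expect_equal(nrow(jx), nrow(bundle$junctions))
  # exon BED row count is the sum of exon counts
  eb <- utils::read.table(paths[["exon_bed"]], sep = "\t")
  expect_equal(nrow(eb), sum(vapply(db, function(a) nrow(a$exons),
                                    integer(1))))
  empty <- structure(list(sample_id = "e", alleles = list(),
                          junctions = bundle$junctions[0, ]),
                     class = "hla_ref_bundle")
  expect_error(write_bundle(empty, dir), "empty")
})

test_that("genotype tables read into per-sample calls", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "gt.tsv")
  writeLines(c("sample_id\tlocus\tallele1\tallele2",
               "cDNA001\tDQB1\tDQB1*05:03\tDQB1*05:01",
               "cDNA001\tA\tA*24:02\tA*24:02",
               "cDNA002\tDQB1\tDQB1*06:02\t"), tsv)
  gts <- read_genotypes(tsv)
  expect_length(gts, 2)
  expect_length(gts[["cDNA001"]]$calls$DQB1, 2)
  expect_length(gts[["cDNA002"]]$calls$DQB1, 1)
})
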