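test_that("TSV parsing handles both layouts, case, comments and grouping", {
  path <- withr::local_tempfile()
  writeLines(c("# comment line",
               "casp3\tDEVDGSAK",
               "casp3\tdevdgsak",
               "pepK\t--AKKEAA",
               paste(c("casp3", strsplit("DEVDAAAA", "")[[1]]),
                     collapse = "\t")),
             path)
  sets <- read_substrate_table(path)
  expect_named(sets, c("casp3", "pepK"))
  expect_equal(sets$casp3$windows, c("DEVDGSAK", "DEVDGSAK", "DEVDAAAA"))
  expect_equal(sets$pepK$windows, "--AKKEAA")
})

test_that("malformed rows are rejected with their line number", {
  bad <- list(
    short    = "x\tDEVDG",
    interior = "x\tDE-DGSAK",
    illegal  = "x\tDEVDGSAB",
    columns  = "x\tDEVD\tGSAK\tzz"
  )
  for (row in bad) {
    path <- withr::local_tempfile()
    writeLines(c("ok\tDEVDGSAK", row), path)
    expect_error(read_substrate_table(path), "line 2")
  }
  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_identical(read_substrate_table(empty), list())
})

test_that("FASTA dialect reads windows grouped by header token", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">casp3 record one", "DEVDGSAK",
               ">pepK", "--AKKEAA",
               ">casp3 another", "DEVDAAAA"), path)
  sets <- read_substrate_table(path, dialect = "fasta")
  expect_equal(sets$casp3$windows, c("DEVDGSAK", "DEVDAAAA"))
  expect_equal(sets$pepK$windows, "--AKKEAA")
})

test_that("write/read round-trips substrate sets bit-exactly", {
  sets <- list(random_set(20, 1, "alpha"), random_set(5, 2, "beta"),
               substrate_set("trunc", c("--AKKEAA", "DEVDGS--")))
  path <- withr::local_tempfile()
  write_substrate_table(sets, path)
  back <- read_substrate_table(path)
  expect_equal(unname(back), sets, ignore_attr = FALSE)
  # empty set writes nothing and vanishes on re-read
  path2 <- withr::local_tempfile()
  write_substrate_table(substrate_set("none"), path2)
  expect_identical(read_substrate_table(path2), list())
})

test_that("window validation enforces structure; drop_invalid spares symbol errors", {
  expect_error(substrate_set("", "DEVDGSAK"), "protease_id")
  expect_error(substrate_set("x", "DE-DGSAK"), "interior gap")
  expect_error(substrate_set("x", "DEVDGSAU"), "illegal symbol")
  expect_warning(s <- substrate_set("x", c("DEVDGSAK", "DEVDGSAB"),
                                    drop_invalid = TRUE), "dropping 1")
  expect_equal(s$windows, "DEVDGSAK")
  # structural problems are never droppable
  expect_error(substrate_set("x", "DE-DGSAK", drop_invalid = TRUE),
               "interior gap")
})

test_that("window_from_sequence pads termini and rejects out-of-range bonds", {
  expect_equal(window_from_sequence("MDEVDGSAKL", 5), "DEVDGSAK")
  expect_equal(window_from_sequence("AKFR", 2), "--AKFR--")
  expect_equal(window_from_sequence("AKFR", 1), "---AKFR-")
  expect_error(window_from_sequence("AK", 2), "out of range")
  expect_error(window_from_sequence("AK", 0), "out of range")
  # property: gap count follows the terminus-overhang formula, never interior
  set.seed(42)
  for (i in 1:50) {
    len <- sample(2:30, 1)
    prot <- paste0(sample(AAS, len, TRUE), collapse = "")
    ca <- sample(seq_len(len - 1), 1)
    w <- window_from_sequence(prot, ca)
    gaps <- sum(strsplit(w, "")[[1]] == "-")
    expect_identical(gaps, as.integer(max(0, 4 - ca) + max(0, ca + 4 - len)))
  }
})

test_that("PFM counts tally non-gap residues and column sums close the books", {
  s <- substrate_set("x", rep("DEVDGSAK", 3))
  pfm <- export_pfm(s)
  expect_equal(pfm["D", "P4"], 3L, ignore_attr = TRUE)
  expect_equal(pfm["E", "P3"], 3L, ignore_attr = TRUE)
  expect_equal(pfm["K", "P4'"], 3L, ignore_attr = TRUE)
  expect_equal(sum(pfm), 24L)
  expect_equal(sum(export_pfm(substrate_set("e"))), 0L)
  trunc <- export_pfm(substrate_set("t", "--AKKEAA"))
  expect_equal(unname(colSums(trunc)), c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L))
  # invariant: column sums + gap counts = window count, every position
  s2 <- substrate_set("m", c("--AKKEAA", "DEVDGSAK", "DEVDGS--"))
  pfm2 <- export_pfm(s2)
  gaps <- sapply(1:8, function(j)
    sum(substring(s2$windows, j, j) == "-"))
  expect_equal(unname(colSums(pfm2)) + gaps, rep(3, 8))
  path <- withr::local_tempfile()
  write_pfm(pfm, path)
  txt <- read.delim(path, row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(txt), unclass(pfm)[, ], ignore_attr = TRUE)
})
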