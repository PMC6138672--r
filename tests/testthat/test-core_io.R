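test_that("abundance table reader maps blanks, tokens and zeros to missing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ts1\ts2",
               "P1\t100\t",
               "P2\t0\t300",
               "P3\tNA\t400"), path)
  am <- read_abundance_table(path)
  expect_s3_class(am, "AbundanceMatrix")
  expect_identical(abundance_scale(am), "linear")
  expect_equal(sum(is.na(am)), 3L)           # blank, literal 0, "NA"
  expect_true(all(unclass(am) > 0, na.rm = TRUE))
  expect_equal(unclass(am)["P3", "s2"], 400)
})

test_that("abundance table reader rejects malformed input with coordinates", {
  bad_header <- withr::local_tempfile()
  writeLines(c("no tabs here", "P1\t1\t2"), bad_header)
  expect_error(read_abundance_table(bad_header), "malformed header",
               class = "parse_error")

  dup <- withr::local_tempfile()
  writeLines(c("id\ts1", "P1\t1", "P1\t2"), dup)
  expect_error(read_abundance_table(dup), "duplicate protein ids.*P1",
               class = "validation_error")

  nonnum <- withr::local_tempfile()
  writeLines(c("id\ts1\ts2", "P1\t1\t2", "P2\tabc\t4"), nonnum)
  expect_error(read_abundance_table(nonnum), "'abc' at line 3, column 's1'",
               class = "parse_error")
})

test_that("write/read round trip is the identity on values and missingness", {
  set.seed(42)
  v <- matrix(2^rnorm(60, 20, 2), 10, 6,
              dimnames = list(sprintf("P%02d", 1:10), sprintf("s%d", 1:6)))
  v[sample(60, 12)] <- NA
  am <- AbundanceMatrix(v)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(am, path)
  back <- read_abundance_table(path)
  expect_identical(rownames(back), rownames(am))
  expect_identical(colnames(back), colnames(am))
  expect_identical(is.na(back), is.na(am))
  expect_equal(unclass(back), unclass(am), tolerance = 1e-12)
})

test_that("sample design enforces control group and replicate structure", {
  d <- design_3x3()
  expect_identical(control_group(d), "control")
  expect_setequal(targeting_groups(d), c("siRNA1", "siRNA2"))
  expect_error(SampleDesign(c("a", "b"), c("g1", "g2"), control = "g3"),
               class = "validation_error")
  expect_error(SampleDesign(c("a", "b", "c"), c("g1", "g1", "g2"),
                            control = "g1"),
               ">= 2 replicates", class = "validation_error")
  expect_error(SampleDesign(c("a", "a"), c("g1", "g2"), control = "g1"),
               "duplicate", class = "validation_error")
})

test_that("sp table reader computes features and validates the alphabet", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tgene\tsequence\tkind\ttm\tnglyc",
               "Q9UM22\tEPDR1\tMPGRAPLRTVPGALGAWLLGGLWAWTLCGLCSLGAVG\tSP\tFALSE\tTRUE",
               "P23284\tPPIB\tMLRLSERNMKVLLAAALIAGSVFFLLLPGPSAA\tSP\tFALSE\tTRUE"),
             path)
  recs <- read_sp_table(path)
  expect_equal(nrow(recs), 2L)
  expect_equal(round_half_up(recs$gp_percent, 1), c(29.7, 12.1))
  expect_true(all(recs$hydrophobicity >= -4.5 & recs$hydrophobicity <= 4.5))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tgene\tsequence\tkind\ttm\tnglyc",
               "X1\tG1\tXLLL\tSP\tFALSE\tFALSE"), bad)
  expect_error(read_sp_table(bad), "non-standard residue",
               class = "validation_error")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("protein_id\tgene\tsequence\tkind\ttm\tnglyc", empty)
  expect_warning(out <- read_sp_table(empty), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("sp table reader accepts FASTA with metadata headers", {
  skip_if_not_installed("Biostrings")
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">Q9UM22|EPDR1|SP|-|+",
               "MPGRAPLRTVPGALGAWLLGGLWAWTLCGLCSLGAVG",
               ">P27797|CALR|SP|-|+",
               "MLLSVPLLLGLLGLAVA"), path)
  recs <- read_sp_table(path)
  expect_equal(recs$protein_id, c("Q9UM22", "P27797"))
  expect_equal(recs$nglyc_flag, c(TRUE, TRUE))
  expect_equal(recs$tm_flag, c(FALSE, FALSE))
  expect_equal(round_half_up(recs$gp_percent, 1), c(29.7, 17.6))
})

test_that("write_results emits deterministic tables and a correct manifest", {
  tbl <- data.frame(protein_id = sprintf("P%d", 1:5), value = (1:5) / 7)
  empty <- tbl[0, ]
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_results(list(res = tbl, none = empty), d1)
  m2 <- write_results(list(res = tbl, none = empty), d2)
  expect_equal(m1$rows, c(5L, 0L))
  expect_identical(m1$md5, m2$md5)      # byte-identical rerun
  hdr <- readLines(file.path(d1, "none.tsv"))
  expect_length(hdr, 1L)                # header only
})
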