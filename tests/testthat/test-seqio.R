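test_that("FASTA and FASTQ round-trip identically, with offset-33 qualities", {
  recs <- seq_records(c("c1_5p", "c1_3p", "t1"),
                      c("ACGTN", "GGGCCCA", "ATATATAT"),
                      qualities = list(c(40L, 40L, 2L, 0L, 20L),
                                       rep(30L, 7L), rep(40L, 8L)))
  fa <- tempfile(fileext = ".fa"); fq <- tempfile(fileext = ".fq")
  write_seq_records(recs, fa, "fasta")
  back <- read_seq_records(fa, "fasta")
  expect_identical(back$id, recs$id)
  expect_identical(back$residues, recs$residues)
  expect_true(all(vapply(back$qualities, is.null, logical(1))))

  write_seq_records(recs, fq, "fastq")
  back <- read_seq_records(fq, "fastq")
  expect_identical(back$id, recs$id)
  expect_identical(back$residues, recs$residues)
  expect_identical(back$qualities, recs$qualities)

  # direct offset-33 check
  writeLines(c("@c9_5p", "AC", "+", "II"), fq)
  expect_identical(read_seq_records(fq, "fastq")$qualities[[1]], c(40L, 40L))
})

test_that("sequence readers enforce the record contract", {
  fa <- tempfile(fileext = ".fa")
  writeLines(character(0), fa)
  expect_identical(nrow(read_seq_records(fa, "fasta")), 0L)

  writeLines(c(">a", "acgt"), fa)
  expect_identical(read_seq_records(fa, "fasta")$residues, "ACGT")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
  expect_error(read_seq_records(fa, "fasta"), "duplicate")

  writeLines(c(">a", "AC-T"), fa)
  expect_error(read_seq_records(fa, "fasta"), "invalid residues")
  writeLines(c(">a", "AC*T"), fa)
  expect_error(read_seq_records(fa, "fasta"), "invalid residues")

  fq <- tempfile(fileext = ".fq")
  writeLines(c("@a", "ACGT", "+", "IIII", "@b", "AC"), fq)
  expect_error(read_seq_records(fq, "fastq"), "line 5")

  recs <- seq_records("a", "ACGT")
  expect_error(write_seq_records(recs, fq, "fastq"), "qualities")
})

test_that("evidence tables normalise to 0-based forward-strand coordinates", {
  path <- tempfile(fileext = ".tsv")
  rows <- c(
    "r1\tp1\t98.5\t100\t1\t0\t1\t300\t1\t100\t3e-45\t180\tsome protein",
    "r2\tp2\t95.0\t100\t5\t0\t300\t1\t1\t100\t1e-30\t150\tantisense thing")
  writeLines(rows, path)
  ev <- read_evidence_table(path)
  expect_identical(ev$q_start, c(0L, 0L))
  expect_identical(ev$q_end, c(300L, 300L))
  expect_identical(ev$s_start, c(0L, 0L))
  expect_identical(ev$s_end, c(100L, 100L))
  expect_identical(ev$frame, c(1L, -1L))
  expect_equal(ev$e_value[1], 3e-45)
  # renormalising a normalised table is a no-op
  expect_identical(normalize_evidence(ev), ev)
  # write-read round trip
  out <- tempfile(fileext = ".tsv")
  write_evidence_table(ev, out)
  ev2 <- read_evidence_table(out)
  expect_identical(ev2[, c("q_start", "q_end", "s_start", "s_end", "frame")],
                   ev[, c("q_start", "q_end", "s_start", "s_end", "frame")])
  expect_equal(ev2$e_value, ev$e_value)
})

test_that("evidence tables reject malformed input", {
  path <- tempfile(fileext = ".tsv")
  writeLines("r1\tp1\t98.5\t100\t1\t0\t1\t300\t1\t100", path)
  expect_error(read_evidence_table(path), "13")
  writeLines(
    "r1\tp1\t98.5\t100\t1\t0\t1\t300\t1\t100\tnot-a-number\t180\tdesc", path)
  expect_error(read_evidence_table(path), "e-value")
})

test_that("report tables are deterministic and sorted by first column", {
  rows <- data.frame(id = c("b", "a", "c"), tissue = c("spleen", "gills", "tête"),
                     n = c(2L, 1L, 3L), stringsAsFactors = FALSE)
  p1 <- tempfile(); p2 <- tempfile()
  write_report_table(rows, p1)
  lines <- readLines(p1, encoding = "UTF-8")
  expect_length(lines, 4L)                   # header + 3 rows
  expect_match(lines[2], "^a\t")
  expect_match(lines[4], "tête")             # unicode preserved
  write_report_table(rows[c(3, 1, 2), ], p2) # different input order
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
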