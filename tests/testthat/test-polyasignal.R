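test_that("the canonical signal is called at its planted distance", {
  set.seed(60)
  body <- rand_dna(200)
  seq <- paste0(body, "AATAAA", rand_dna(12), strrep("A", 20))
  r <- scan_signal(seq, tail_start = 218L)
  expect_identical(r$signal, "AAUAAA")
  expect_identical(r$start, 200L)
  expect_identical(r$distance, 12L)
})

test_that("precedence beats proximity and the window bounds are inclusive", {
  set.seed(61)
  # ATTAAA nearer the tail than AATAAA: the canonical still wins
  body <- paste(rep("C", 150), collapse = "")
  seq <- paste0(body, "AATAAA", strrep("C", 11), "ATTAAA", strrep("C", 8),
                strrep("A", 15))
  tail_start <- nchar(body) + 6 + 11 + 6 + 8
  r <- scan_signal(seq, tail_start)
  expect_identical(r$signal, "AAUAAA")
  expect_identical(r$distance, 25L)

  # a signal only 3 bases before the tail is outside the window
  seq <- paste0(body, "AATAAA", "CCC", strrep("A", 15))
  r <- scan_signal(seq, nchar(body) + 9L)
  expect_identical(r$signal, "NOT_IDENTIFIABLE")

  # distances 5 and 30 are still legal
  for (gap in c(5L, 30L)) {
    seq <- paste0(body, "AATAAA", strrep("C", gap), strrep("A", 15))
    r <- scan_signal(seq, nchar(body) + 6L + gap)
    expect_identical(r$signal, "AAUAAA")
    expect_identical(r$distance, gap)
  }

  expect_error(scan_signal("ACGT", NA), "tail_start")
})

test_that("the scan equals the brute-force placement oracle on planted signals", {
  set.seed(62)
  hexes <- polya_signal_hexamers()
  for (i in 1:300) {
    body <- rand_dna(sample(80:200, 1))
    hx <- sample(hexes, 1)
    gap <- sample(5:30, 1)
    seq <- paste0(body, chartr("U", "T", hx), rand_dna(gap),
                  strrep("A", 15))
    tail_start <- nchar(body) + 6L + gap
    got <- scan_signal(seq, tail_start)
    want <- oracle_scan_signal(seq, tail_start)
    expect_identical(got$signal, want$signal)
    expect_identical(got$start, want$start)
  }
})

test_that("AAUAAA anywhere in the legal window always wins", {
  set.seed(63)
  for (i in 1:50) {
    body <- rand_dna(150)
    gap <- sample(5:30, 1)
    seq <- paste0(body, "AATAAA", rand_dna(gap), strrep("A", 12))
    r <- scan_signal(seq, nchar(body) + 6L + gap)
    expect_identical(r$signal, "AAUAAA")
  }
})

test_that("the call ignores sequence content downstream of the tail start", {
  set.seed(64)
  body <- rand_dna(120)
  seq1 <- paste0(body, "ATTAAA", rand_dna(10), strrep("A", 20))
  seq2 <- paste0(body, "ATTAAA", rand_dna(10), rand_dna(20))
  t0 <- nchar(body) + 16L
  expect_identical(scan_signal(seq1, t0), scan_signal(seq2, t0))
})

test_that("usage tables count per group with the stated denominators", {
  calls <- data.frame(
    transcript_id = sprintf("t%d", 1:10),
    signal = c(rep("AAUAAA", 6), rep("AUUAAA", 2), "UAUAAA",
               "NOT_IDENTIFIABLE"),
    stringsAsFactors = FALSE)
  tab <- usage_table(calls)
  expect_identical(tab$pct[tab$signal == "AAUAAA"], 60.0)
  expect_identical(tab$pct[tab$signal == "AUUAAA"], 20.0)
  expect_identical(tab$pct[tab$signal == "UAUAAA"], 10.0)
  expect_identical(tab$pct[tab$signal == "NOT_IDENTIFIABLE"], 10.0)
  expect_identical(sum(tab$n), 10L)

  none <- data.frame(transcript_id = "t1", signal = "NOT_IDENTIFIABLE",
                     stringsAsFactors = FALSE)
  tab <- usage_table(none)
  expect_identical(tab$pct[tab$signal == "NOT_IDENTIFIABLE"], 100.0)

  # counts conserve per group
  grp <- rep(c("coding", "noncoding"), 5)
  tab <- usage_table(calls, grp)
  for (g in c("coding", "noncoding"))
    expect_identical(sum(tab$n[tab$group == g]), 5L)
})
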