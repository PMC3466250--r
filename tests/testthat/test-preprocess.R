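test_that("quality trimming keeps everything above threshold and drops all-bad reads", {
  expect_identical(trim_quality(rep(40L, 100)), c(0L, 100L))
  expect_identical(trim_quality(rep(10L, 50)), c(0L, 0L))
  expect_error(trim_quality(NULL), "absent")
})

test_that("quality trimming matches the exhaustive best-window oracle", {
  set.seed(101)
  for (i in 1:300) {
    q <- sample(0:45, sample(20:120, 1), replace = TRUE)
    expect_identical(trim_quality(q), oracle_best_window(q))
  }
})

test_that("vector screening trims terminal matches and discards all-vector reads", {
  set.seed(7)
  vec <- rand_dna(300)
  insert <- rand_dna(200)
  read <- paste0(substr(vec, 1, 40), insert)
  res <- trim_vector(read, vec)
  expect_false(res$all_vector)
  expect_identical(res$interval[1], 40L)
  expect_identical(res$interval[2], nchar(read))

  res <- trim_vector(insert, vec)
  expect_identical(res$interval, c(0L, 200L))
  expect_false(res$all_vector)

  res <- trim_vector(substr(vec, 10, 250), vec)
  expect_true(res$all_vector)
})

test_that("cap-tag detection honours the mismatch budget and the SfiI remnant", {
  set.seed(8)
  insert <- rand_dna(300)
  tag <- CAP_TAG
  r <- detect_cap_tag(paste0(tag, insert))
  expect_true(r$cap_found)
  expect_identical(r$cap_end, 30L)

  tag1 <- paste0("T", substr(tag, 2, 30))  # one substitution
  expect_true(detect_cap_tag(paste0(tag1, insert))$cap_found)

  expect_false(detect_cap_tag(insert)$cap_found)

  # SfiI-digested remnant: only the tag suffix left
  r <- detect_cap_tag(paste0("CTACTGG", insert))
  expect_true(r$cap_found)
  expect_identical(r$cap_end, 7L)
})

test_that("3' reads are oriented to sense and the tail located", {
  set.seed(9)
  body <- rand_dna(200)
  sense <- paste0(body, strrep("A", 20))
  r <- orient_and_detect_polya(sense)
  expect_false(r$oriented_sense)
  expect_identical(r$tail_start, 200L)

  raw <- paste0(POLYT_PRIMER_HEAD, strrep("T", 20),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(body))))
  r <- orient_and_detect_polya(raw)
  expect_true(r$oriented_sense)
  expect_identical(substr(r$residues, 1, 200), body)
  expect_identical(r$tail_start, 200L)

  # A-run stranded 50 bp before the end is not a tail
  far <- paste0(body, strrep("A", 20), rand_dna(50))
  expect_true(is.na(orient_and_detect_polya(far)$tail_start))
})

test_that("poly(A) orientation is idempotent on sense reads", {
  set.seed(10)
  for (i in 1:25) {
    sense <- paste0(rand_dna(sample(150:400, 1)),
                    strrep("A", sample(10:40, 1)))
    once <- orient_and_detect_polya(sense)
    twice <- orient_and_detect_polya(once$residues)
    expect_identical(twice$residues, once$residues)
    expect_identical(twice$tail_start, once$tail_start)
  }
})

test_that("the length filter keeps exactly the reads of at least 150 bases", {
  expect_false(filter_length(149))
  expect_true(filter_length(150))
  expect_true(filter_length(151))
})

test_that("low-complexity flagging separates repeats from random sequence", {
  expect_true(flag_low_complexity(strrep("AT", 200)))
  set.seed(11)
  scores <- replicate(1000, {
    s <- rand_dna(400)
    ch <- strsplit(gsub("A{10,}|T{10,}", "", s), "")[[1]]
    max(vapply(seq(1, 337, by = 32), function(p)
      oligocap:::dust_score(ch[p:min(length(ch), p + 63)]), numeric(1)))
  })
  # random 50% GC sequence sits far below the threshold
  expect_lt(quantile(scores, 0.999), 2)
  set.seed(11)
  for (i in 1:20) expect_false(flag_low_complexity(rand_dna(400)))
  # an external mask covering 95% of the read flags it
  expect_true(flag_low_complexity(rand_dna(200),
                                  mask = cbind(0L, 190L)))
})

test_that("mitochondrial screening agrees with a Smith-Waterman oracle", {
  set.seed(12)
  mito <- rand_dna(2000)
  screen <- build_mito_screen(mito)

  sub <- substr(mito, 501, 700)
  expect_true(flag_mitochondrial(sub, screen))
  expect_true(oracle_has_local_hit(sub, mito))

  shuf <- paste(sample(strsplit(sub, "")[[1]]), collapse = "")
  expect_identical(flag_mitochondrial(shuf, screen),
                   oracle_has_local_hit(shuf, mito))
  expect_false(oracle_has_local_hit(shuf, mito))

  noisy <- mutate_dna(sub, 10)  # 5% substitutions, identity right at 0.95
  expect_true(flag_mitochondrial(noisy, screen))
})

test_that("every read gets exactly one disposition, in the fixed filter order", {
  set.seed(13)
  cfg <- sim_config(n_genes = 40, seed = 21)
  tx <- make_transcriptome(cfg)
  sim <- simulate_library(tx, cfg)
  pp <- preprocess_reads(sim$reads)
  expect_identical(nrow(pp$annotations), nrow(sim$reads))
  expect_true(all(pp$annotations$disposition %in%
    c("kept", "ALL_VECTOR", "TOO_SHORT", "LOW_COMPLEXITY", "MITOCHONDRIAL")))
  expect_setequal(pp$inserts$id,
                  pp$annotations$read_id[pp$annotations$disposition == "kept"])
})

test_that("with no errors and no truncation every 5' read carries the cap", {
  cfg <- sim_config(n_genes = 60, truncation_prob = 0, error_rate = 0,
                    seed = 5)
  sim <- simulate_library(make_transcriptome(cfg), cfg)
  pp <- preprocess_reads(sim$reads)
  ann5 <- pp$annotations[pp$annotations$end == "5p", ]
  expect_true(all(ann5$cap_found))
})
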