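mk_hit <- function(query_id = "r1", subject_id = "p1", q_start = 0L,
                   q_end = 300L, s_start = 0L, s_end = 100L, frame = 1L,
                   e_value = 1e-40, bitscore = 200,
                   subject_desc = "some protein") {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = 99, aln_len = s_end - s_start, mismatches = 0L,
             gap_opens = 0L, q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end, e_value = e_value,
             bitscore = bitscore, frame = frame,
             subject_desc = subject_desc, stringsAsFactors = FALSE)
}

test_that("truncation triage follows the cap/terminus rules", {
  slen <- c(p1 = 150L)
  # complete N-terminal coverage with cap: not truncated
  h <- mk_hit(s_start = 0L, s_end = 150L, q_end = 450L)
  expect_false(flag_truncated_coding("5p", TRUE, h, 500, slen))
  # hit starts deep into the subject while the read is already coding
  h <- mk_hit(q_start = 2L, q_end = 212L, s_start = 80L, s_end = 150L)
  expect_true(flag_truncated_coding("5p", TRUE, h, 500, slen))
  # missing cap alone is enough
  h <- mk_hit(s_start = 0L, s_end = 150L)
  expect_true(flag_truncated_coding("5p", FALSE, h, 500, slen))
  # no hit: never flagged here (continues to assembly)
  expect_false(flag_truncated_coding("5p", FALSE, NULL, 500, slen))
  # 3' read short of the C-terminus with the alignment running to the end
  h <- mk_hit(q_start = 100L, q_end = 400L, s_start = 0L, s_end = 100L)
  expect_true(flag_truncated_coding("3p", TRUE, h, 420, slen))
  # 3' read reaching the C-terminus: kept
  h <- mk_hit(q_start = 0L, q_end = 450L, s_start = 0L, s_end = 150L)
  expect_false(flag_truncated_coding("3p", TRUE, h, 600, slen))
})

test_that("full-length classification routes sense, antisense and RT hits", {
  r <- classify_full_length("t1", mk_hit(e_value = 1e-40))
  expect_identical(r$category, "FL_CODING")
  r <- classify_full_length("t1", mk_hit(frame = -2L, e_value = 1e-30))
  expect_identical(r$category, "FL_NONCODING")
  expect_identical(r$basis, "blast_hit_antisense")
  r <- classify_full_length("t1", NULL)
  expect_identical(r$category, "FL_NONCODING")
  expect_identical(r$basis, "no_hit")
  r <- classify_full_length(
    "t1", mk_hit(subject_desc = "pol-like Reverse Transcriptase"))
  expect_identical(r$category, "DISCARD_RT")
  # a weak sense hit above the threshold does not make it coding
  r <- classify_full_length("t1", mk_hit(e_value = 1e-3))
  expect_identical(r$category, "FL_NONCODING")
})

test_that("FL_CODING is never assigned from antisense-only hit tables", {
  set.seed(40)
  for (i in 1:50) {
    n <- sample(1:5, 1)
    hits <- do.call(rbind, lapply(seq_len(n), function(k)
      mk_hit(subject_id = paste0("p", k),
             frame = -sample(1:3, 1),
             e_value = 10^-runif(1, 5, 60),
             bitscore = runif(1, 50, 300))))
    expect_false(classify_full_length("t", hits)$category == "FL_CODING")
  }
})

test_that("walking candidates need both protein termini and rank by 5' length", {
  slen <- c(p1 = 200L, p2 = 300L)
  h5 <- rbind(mk_hit("c1_5p", "p1", s_start = 0L, s_end = 60L),
              mk_hit("c2_5p", "p1", s_start = 0L, s_end = 60L),
              mk_hit("c3_5p", "p2", s_start = 0L, s_end = 60L))
  h3 <- rbind(mk_hit("c1_3p", "p1", s_start = 140L, s_end = 200L),
              mk_hit("c2_3p", "p1", s_start = 140L, s_end = 200L),
              mk_hit("c3_3p", "p1", s_start = 140L, s_end = 200L))  # wrong subject
  lens <- c(c1_5p = 500, c2_5p = 650, c3_5p = 700,
            c1_3p = 400, c2_3p = 400, c3_3p = 400)
  got <- select_walking_candidates(h5, h3, lens, slen, n = 800)
  expect_identical(got, c("c2", "c1"))          # by 5'-read length, descending
  got <- select_walking_candidates(h5, h3, lens, slen, n = 1)
  expect_identical(got, "c2")
  # a 5' hit that misses the N-terminus disqualifies the clone
  h5b <- mk_hit("c1_5p", "p1", s_start = 50L, s_end = 110L)
  expect_length(select_walking_candidates(h5b, h3, lens, slen), 0L)
})

test_that("EST retention applies the 300-base boundary per end", {
  got <- retain_ests(c("a_5p", "b_3p", "c_5p"), c(299, 300, 301))
  expect_identical(got$category,
                   c("DISCARD_SHORT_EST", "EST3", "EST5"))
})

test_that("gene-loss categories follow group presence collapsed by OR", {
  presence <- data.frame(
    gene_id = rep(c("gA", "gB", "gC", "gD"), each = 4),
    group = rep(c("tetrapods", "tetrapods", "teleosts", "teleosts"), 4),
    present = c(TRUE, TRUE, FALSE, FALSE,    # gA: tetrapods only
                FALSE, FALSE, TRUE, FALSE,   # gB: teleosts only
                FALSE, FALSE, FALSE, FALSE,  # gC: nobody
                TRUE, FALSE, TRUE, TRUE),    # gD: both
    stringsAsFactors = FALSE)
  got <- categorize_gene_loss(presence)
  expect_identical(got$category[got$gene_id == "gA"], "LOST_IN_TELEOSTS")
  expect_identical(got$category[got$gene_id == "gB"], "LOST_IN_TETRAPODS")
  expect_identical(got$category[got$gene_id == "gC"],
                   "ABSENT_IN_BONY_VERTEBRATES")
  expect_identical(got$category[got$gene_id == "gD"], "SHARED")
})

test_that("every input read lands in exactly one terminal bucket", {
  cfg <- sim_config(n_genes = 50, seed = 77)
  s <- simulate_and_run(cfg)
  rc <- s$result$read_class
  expect_identical(nrow(rc), nrow(s$sim$reads))
  expect_identical(anyDuplicated(rc$read_id), 0L)
  expect_false(any(rc$category == "kept"))
  summ <- summarize_pipeline(s$result)
  expect_true(summ$conservation$ok)
})

test_that("with perfect evidence coding/noncoding assignment matches truth", {
  cfg <- sim_config(n_genes = 80, error_rate = 0, truncation_prob = 0,
                    seed = 13)
  s <- simulate_and_run(cfg)
  truth <- s$sim$truth
  fl <- s$result$fl_class
  coding <- setNames(truth$coding, truth$clone_id)
  for (i in seq_len(nrow(fl))) {
    expected <- if (coding[[fl$subject_id[i]]]) "FL_CODING" else "FL_NONCODING"
    expect_identical(fl$category[i], expected)
  }
})
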