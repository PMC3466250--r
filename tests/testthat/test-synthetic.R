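test_that("the simulator is byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 10, seed = 1)
  a <- make_transcriptome(cfg); b <- make_transcriptome(cfg)
  expect_identical(a, b)
  la <- simulate_library(a, cfg); lb <- simulate_library(b, cfg)
  expect_identical(la, lb)
  f1 <- tempfile(); f2 <- tempfile()
  write_seq_records(la$reads, f1, "fastq")
  write_seq_records(lb$reads, f2, "fastq")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a point-mass signal distribution plants only that signal", {
  cfg <- sim_config(n_genes = 30, seed = 2,
                    signal_distribution = c(AUUAAA = 1))
  tx <- make_transcriptome(cfg)
  expect_true(all(tx$genes$signal == "AUUAAA"))
})

test_that("config validation rejects bad signal distributions", {
  expect_error(sim_config(signal_distribution = c(AAUAAA = 0.5)), "sum to 1")
  expect_error(sim_config(signal_distribution = c(ZZZZZZ = 1)), "unknown")
})

test_that("mRNAs carry their planted signal at the planted distance", {
  cfg <- sim_config(n_genes = 50, seed = 3)
  tx <- make_transcriptome(cfg)
  for (i in seq_len(nrow(tx$genes))) {
    g <- tx$genes[i, ]
    tail_start <- g$mrna_len - g$tail_len
    sig_start <- tail_start - g$gap - 6L
    expect_identical(substr(tx$mrnas$residues[i], sig_start + 1L,
                            sig_start + 6L),
                     chartr("U", "T", g$signal))
  }
})

test_that("coding mRNAs translate to their recorded protein without stops", {
  cfg <- sim_config(n_genes = 40, seed = 4)
  tx <- make_transcriptome(cfg)
  cg <- tx$genes[tx$genes$coding, ]
  for (i in seq_len(nrow(cg))) {
    cds <- substr(tx$mrnas$residues[match(cg$gene_id[i], tx$genes$gene_id)],
                  cg$cds_start[i] + 1L, cg$cds_end[i])
    p <- translate_cds(cds, 1)
    expect_identical(substr(p, nchar(p), nchar(p)), "*")
    expect_identical(sub("\\*$", "", p), unname(tx$proteins[cg$gene_id[i]]))
    expect_false(grepl("\\*", sub("\\*$", "", p)))
  }
})

test_that("truncated molecules are uncapped and the rate is binomial", {
  cfg <- sim_config(n_genes = 600, truncation_prob = 0.3, error_rate = 0,
                    seed = 6)
  sim <- simulate_library(make_transcriptome(cfg), cfg)
  n <- nrow(sim$truth)
  frac <- mean(!sim$truth$full_length)
  sigma <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), 3 * sigma)
  # cap tag present on the 5' read exactly when the molecule is full length
  for (i in sample(n, 40)) {
    tr <- sim$truth[i, ]
    r5 <- sim$reads$residues[sim$reads$id == paste0(tr$clone_id, "_5p")]
    expect_identical(startsWith(r5, CAP_TAG), tr$full_length)
  }
})

test_that("size selection drops inserts outside the window", {
  cfg <- sim_config(n_genes = 40, seed = 7, truncation_prob = 0,
                    nc_len_dist = function(n) sample(c(200L, 1000L), n, TRUE),
                    noncoding_frac = 1)
  tx <- make_transcriptome(cfg)
  sim <- simulate_library(tx, cfg)
  expect_true(all(sim$truth$insert_len >= 500 & sim$truth$insert_len <= 3500))
  short_genes <- tx$genes$gene_id[tx$genes$mrna_len + 55 < 500]
  expect_length(intersect(short_genes, sim$truth$gene_id), 0L)
  expect_gt(length(short_genes), 0L)
})

test_that("truth-derived evidence respects the hit invariants", {
  cfg <- sim_config(n_genes = 60, seed = 8)
  tx <- make_transcriptome(cfg)
  sim <- simulate_library(tx, cfg)
  ev <- simulate_evidence(read_query_spans(sim$truth), tx$proteins,
                          noise = 0, seed = 99)
  expect_true(all(ev$q_start < ev$q_end))
  expect_true(all(ev$s_start < ev$s_end))
  expect_true(all(ev$e_value >= 0))
  expect_true(all(ev$frame %in% c(1L, 2L, 3L)))
  expect_true(all((ev$q_end - ev$q_start) %% 3L == 0L))
  # noise = 0: every hit points at the query's own gene
  truth5 <- sim$truth$gene_id[match(sub("_(5p|3p)$", "", ev$query_id),
                                    sim$truth$clone_id)]
  expect_identical(ev$subject_id, truth5)
})

test_that("reverse-transcriptase decoys at full noise discard all transcripts", {
  cfg <- sim_config(n_genes = 30, seed = 9, noncoding_frac = 1)
  tx <- make_transcriptome(cfg)
  sim <- simulate_library(tx, cfg)
  spans <- transcript_query_spans(sim$truth, sim$truth$clone_id)
  set.seed(1)
  repeat {  # decoys split between RT and antisense; find a seed giving RT
    ev <- simulate_evidence(spans, tx$proteins, noise = 1,
                            seed = sample.int(1e6, 1))
    if (any(ev$subject_id == "RT_decoy")) break
  }
  rt_queries <- unique(ev$query_id[ev$subject_id == "RT_decoy"])
  for (q in rt_queries) {
    r <- classify_full_length(q, ev[ev$query_id == q, , drop = FALSE])
    expect_identical(r$category, "DISCARD_RT")
  }
  as_only <- setdiff(unique(ev$query_id), rt_queries)
  for (q in as_only) {
    r <- classify_full_length(q, ev[ev$query_id == q, , drop = FALSE])
    expect_identical(r$category, "FL_NONCODING")
  }
})
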