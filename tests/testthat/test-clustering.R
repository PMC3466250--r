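test_that("greedy clustering groups identical sequences and splits divergent ones", {
  set.seed(50)
  s <- rand_dna(300)
  cl <- greedy_cluster(c(a = s, b = s), 0.99, 0.95, "nucleotide")
  expect_identical(length(cluster_reps(cl)), 1L)
  expect_identical(sort(cl$member_id), c("a", "b"))

  s2 <- mutate_dna(s, 30)  # 10% divergence
  cl <- greedy_cluster(c(a = s, b = s2), 0.99, 0.95, "nucleotide")
  expect_identical(length(cluster_reps(cl)), 2L)

  expect_identical(nrow(greedy_cluster(character(0), 0.99, 0.95)), 0L)
  expect_error(greedy_cluster(c(a = s), 1.2, 0.95), "identity")
})

test_that("originals pair with their lightly mutated copies at 98% identity", {
  set.seed(51)
  n <- 50L
  orig <- setNames(replicate(n, rand_dna(sample(250:400, 1))),
                   sprintf("o%02d", 1:n))
  copies <- setNames(vapply(orig, function(s)
    mutate_dna(s, max(1, round(0.005 * nchar(s)))), character(1)),
    sprintf("m%02d", 1:n))
  cl <- greedy_cluster(c(orig, copies), 0.98, 0.9, "nucleotide")
  expect_identical(length(cluster_reps(cl)), n)
  by_rep <- split(cl$member_id, cl$rep_id)
  for (members in by_rep) {
    expect_length(members, 2L)
    expect_identical(sub("^[om]", "", members[1]),
                     sub("^[om]", "", members[2]))
  }
})

test_that("cluster count is monotone in the identity threshold", {
  set.seed(52)
  base <- replicate(12, rand_dna(300))
  seqs <- setNames(c(base, vapply(base, function(s)
    mutate_dna(s, sample(2:25, 1)), character(1))), sprintf("s%02d", 1:24))
  counts <- vapply(c(0.85, 0.90, 0.95, 0.98, 0.99),
                   function(th) length(cluster_reps(
                     greedy_cluster(seqs, th, 0.9, "nucleotide"))),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the partition equals the all-pairs Biostrings oracle", {
  set.seed(53)
  base <- replicate(15, rand_dna(sample(200:350, 1)))
  seqs <- setNames(c(base,
                     vapply(sample(base, 15, TRUE), function(s)
                       mutate_dna(s, sample(1:12, 1)), character(1))),
                   sprintf("q%02d", 1:30))
  for (th in c(0.90, 0.98)) {
    got <- greedy_cluster(seqs, th, 0.9, "nucleotide")
    want <- oracle_greedy_cluster(seqs, th, 0.9)
    expect_identical(setNames(got$rep_id, got$member_id)[names(want)], want)
  }
})

test_that("the k-mer prefilter never changes the partition", {
  set.seed(54)
  seqs <- setNames(replicate(20, rand_dna(sample(150:300, 1))),
                   sprintf("p%02d", 1:20))
  a <- greedy_cluster(seqs, 0.95, 0.9, "nucleotide", prefilter = TRUE)
  b <- greedy_cluster(seqs, 0.95, 0.9, "nucleotide", prefilter = FALSE)
  expect_identical(a, b)
})

test_that("two-set clustering removes planted UTR fragments exactly", {
  set.seed(55)
  coding <- setNames(replicate(8, rand_dna(900)), sprintf("c%d", 1:8))
  utr_frags <- setNames(vapply(coding[1:4], function(s)
    substr(s, 600, 899), character(1)), sprintf("u%d", 1:4))
  free <- setNames(replicate(4, rand_dna(300)), sprintf("f%d", 1:4))
  res <- cluster_two_sets(c(utr_frags, free), coding)
  expect_setequal(res$removed, names(utr_frags))
  expect_setequal(res$retained, names(free))
})

test_that("clustering output is a partition of the input", {
  set.seed(56)
  seqs <- setNames(replicate(30, rand_dna(sample(100:250, 1))),
                   sprintf("x%02d", 1:30))
  cl <- greedy_cluster(seqs, 0.95, 0.9, "nucleotide")
  expect_setequal(cl$member_id, names(seqs))
  expect_identical(anyDuplicated(cl$member_id), 0L)
  expect_true(all(cl$rep_id %in% cl$member_id))
})
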