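# Independent oracles used across the suite.  Each recomputes a quantity by
# brute force or through Biostrings' aligners, never through the package's
# own code path.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# exhaustive best quality window: maximises sum(q - threshold) over all
# O(n^2) windows; ties broken earliest start, then longest
oracle_best_window <- function(q, threshold = 20) {
  n <- length(q)
  s <- as.numeric(q) - threshold
  best <- 0; bs <- 0L; be <- 0L
  for (i in 1:n) {
    acc <- 0
    for (j in i:n) {
      acc <- acc + s[j]
      better <- acc > best ||
        (acc == best && acc > 0 &&
           ((i - 1L) < bs || ((i - 1L) == bs && j > be)))
      if (better) { best <- acc; bs <- i - 1L; be <- j }
    }
  }
  if (best <= 0) c(0L, 0L) else c(bs, be)
}

# brute-force polyadenylation-signal call: every hexamer at every placement
# whose end lies 5..30 bases before the tail, first by precedence then by
# proximity to the tail
oracle_scan_signal <- function(seq, tail_start, min_gap = 5, max_gap = 30) {
  hexes <- polya_signal_hexamers()
  for (hx in hexes) {
    pat <- chartr("U", "T", hx)
    best <- NA_integer_
    for (s in 0:(nchar(seq) - 6L)) {
      gap <- tail_start - (s + 6L)
      if (gap < min_gap || gap > max_gap) next
      if (substr(seq, s + 1L, s + 6L) == pat &&
          (is.na(best) || s > best)) best <- s
    }
    if (!is.na(best)) return(list(signal = hx, start = best))
  }
  list(signal = "NOT_IDENTIFIABLE", start = NA_integer_)
}

# scoring shared with the package's aligners
oracle_submat <- function() {
  m <- matrix(-2, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  diag(m) <- 1
  m["N", ] <- -2; m[, "N"] <- -2
  m
}

# semi-global identity (shorter global, longer ends-free) via Biostrings
oracle_glocal_identity <- function(shorter, longer) {
  al <- Biostrings::pairwiseAlignment(
    shorter, longer, type = "global-local",
    substitutionMatrix = oracle_submat(), gapOpening = 0, gapExtension = 3)
  p <- as.character(Biostrings::alignedPattern(al))
  s <- as.character(Biostrings::alignedSubject(al))
  cols <- nchar(p)
  matches <- sum(strsplit(p, "")[[1]] == strsplit(s, "")[[1]] &
                   strsplit(p, "")[[1]] != "-")
  list(identity = matches / cols, aln_len = cols)
}

# greedy cd-hit-style clustering driven entirely by the Biostrings aligner
oracle_greedy_cluster <- function(seqs, identity, coverage) {
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  reps <- character(0)
  assign <- character(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (r in reps) {
      al <- oracle_glocal_identity(seqs[[i]], seqs[[r]])
      if (al$identity >= identity && al$aln_len >= coverage * nchar(seqs[[i]])) {
        assign[i] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, names(seqs)[i]); assign[i] <- names(seqs)[i] }
  }
  setNames(assign, names(seqs))
}

# full overlap DP (suffix of a vs prefix of b, trailing a free), vectorised
# row by row; returns the merge-decision quantities
oracle_overlap_decision <- function(a, b, match = 1, mismatch = -2,
                                    gap = -3) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  H[1, ] <- gap * (0:m)
  for (i in 1:n) {
    sc <- ifelse(bv == av[i] & av[i] != "N", match, mismatch)
    diag_up <- pmax(H[i, 1:m] + sc, H[i, 2:(m + 1)] + gap)
    # resolve left-gaps: H[i+1, j] = max(tmp[j], max_k<j H[i+1,k] + gap*(j-k))
    row <- c(0, diag_up)
    B <- row - gap * (0:m)
    B <- cummax(B)
    H[i + 1, ] <- pmax(row, B + gap * (0:m))
  }
  ends <- rbind(cbind(n + 1, 1:(m + 1)), cbind(1:(n + 1), m + 1))
  scores <- H[ends]
  k <- which.max(scores)
  ei <- ends[k, 1]; ej <- ends[k, 2]
  # traceback for matches / alignment length
  i <- ei - 1; j <- ej - 1; matches <- 0L; cols <- 0L
  while (j > 0) {
    sc <- if (i > 0 && bv[j] == av[i] && av[i] != "N") match else mismatch
    if (i > 0 && H[i + 1, j + 1] == H[i, j] + sc) {
      if (sc == match) matches <- matches + 1L
      i <- i - 1; j <- j - 1; cols <- cols + 1L
    } else if (i > 0 && H[i + 1, j + 1] == H[i, j + 1] + gap) {
      i <- i - 1; cols <- cols + 1L
    } else {
      j <- j - 1; cols <- cols + 1L
    }
  }
  list(score = max(scores), aln_len = cols, matches = matches)
}

oracle_merge_decision <- function(a, b, min_identity = 0.95,
                                  min_overlap_frac = 0.5) {
  d <- oracle_overlap_decision(a, b)
  if (d$aln_len == 0L) return(FALSE)
  idy <- d$matches / d$aln_len
  d$aln_len > min_overlap_frac * min(nchar(a), nchar(b)) && idy >= min_identity
}

# local-alignment (Smith-Waterman) qualifying-hit test via Biostrings
oracle_has_local_hit <- function(read, genome, min_len = 100,
                                 min_identity = 0.95) {
  for (g in c(genome, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome))))) {
    al <- Biostrings::pairwiseAlignment(
      read, g, type = "local",
      substitutionMatrix = oracle_submat(), gapOpening = 0, gapExtension = 3)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    cols <- length(p)
    matches <- sum(p == s & p != "-")
    if (cols >= min_len && matches / cols >= min_identity) return(TRUE)
  }
  FALSE
}

# substitution mutator for fixtures
mutate_dna <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
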