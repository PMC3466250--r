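#' Quality trimming by maximal-scoring window
#'
#' Mott-style trimming: each base scores `q - threshold` and the retained
#' interval is the contiguous window with the maximal score sum.  Ties are
#' broken deterministically: earliest start, then longest window.  A read
#' with no positive-scoring window yields the empty interval `[0, 0)`.
#'
#' @param qualities integer vector of PHRED scores.
#' @param threshold PHRED threshold; bases below it score negatively.
#' @return Integer vector `c(start, end)`, a 0-based half-open interval.
#' @export
trim_quality <- function(qualities, threshold = 20) {
  if (is.null(qualities) || length(qualities) == 0L)
    stop("qualities absent; skip quality trimming for this read")
  s <- as.numeric(qualities) - threshold
  n <- length(s)
  # prefix sums: window (i, j] has sum P[j+1] - P[i+1] (1-based P)
  P <- c(0, cumsum(s))
  best_sum <- 0; best_start <- 0L; best_end <- 0L
  min_pref <- P[1L]; min_idx <- 0L
  for (j in seq_len(n)) {
    w <- P[j + 1L] - min_pref
    if (w > best_sum ||
        (w == best_sum && w > 0 &&
         (min_idx < best_start || (min_idx == best_start && j > best_end)))) {
      best_sum <- w; best_start <- min_idx; best_end <- j
    }
    if (P[j + 1L] < min_pref) { min_pref <- P[j + 1L]; min_idx <- j }
  }
  if (best_sum <= 0) return(c(0L, 0L))
  c(best_start, best_end)
}

#' Vector screening of a read
#'
#' Finds approximate local matches (>= `min_match` aligned bases, mismatch
#' rate <= `max_mismatch_rate`) between the read and any supplied vector
#' sequence (either strand) and removes matches anchored at the read
#' termini.  A read whose qualifying matches cover more than `all_vector_cov`
#' of its length is discarded outright.
#'
#' @param residues read sequence (character scalar).
#' @param vector_seqs character vector of vector sequences (may be empty).
#' @param min_match minimum aligned length of a qualifying match.
#' @param max_mismatch_rate maximum fraction of non-matching columns.
#' @param terminal_slack bp from either read end within which a match is
#'   treated as terminal and trimmed.
#' @param all_vector_cov coverage fraction above which the read is all vector.
#' @return list with `interval` (0-based half-open retained span) and
#'   `all_vector` (logical).
#' @export
trim_vector <- function(residues, vector_seqs, min_match = 16,
                        max_mismatch_rate = 0.1, terminal_slack = 5,
                        all_vector_cov = 0.9) {
  len <- nchar(residues)
  cur <- c(0L, len)
  if (length(vector_seqs) == 0L || len == 0L)
    return(list(interval = cur, all_vector = FALSE))
  targets <- c(vector_seqs, revcomp(vector_seqs))
  covered <- logical(len)
  for (iter in seq_len(4L)) {
    frag <- substr(residues, cur[1L] + 1L, cur[2L])
    if (nchar(frag) < min_match) break
    best <- NULL
    for (v in targets) {
      al <- local_align_cpp(frag, v)
      if (al$aln_len >= min_match &&
          (al$aln_len - al$matches) / al$aln_len <= max_mismatch_rate) {
        if (is.null(best) || al$score > best$score) best <- al
      }
    }
    if (is.null(best)) break
    hs <- cur[1L] + best$a_start  # 0-based on full read
    he <- cur[1L] + best$a_end
    covered[(hs + 1L):he] <- TRUE
    if (hs <= cur[1L] + terminal_slack) {
      cur[1L] <- he
    } else if (he >= cur[2L] - terminal_slack) {
      cur[2L] <- hs
    } else break  # interior match: counted for coverage, not trimmed
    if (cur[2L] - cur[1L] < 1L) break
  }
  list(interval = cur, all_vector = mean(covered) > all_vector_cov)
}

# sliding mismatch counts of `pattern` against `subject` at starts 0..max_start
mismatch_scan <- function(subject, pattern, max_start) {
  plen <- nchar(pattern)
  slen <- nchar(subject)
  starts <- 0:max(0L, min(max_start, slen - plen))
  if (slen < plen) return(integer(0))
  pat <- strsplit(pattern, "")[[1L]]
  sub <- strsplit(subject, "")[[1L]]
  vapply(starts, function(s) sum(sub[(s + 1L):(s + plen)] != pat), integer(1))
}

#' Detect the oligo-cap tag at the start of a 5' read
#'
#' Searches the first `search_window` bases for the cap tag allowing up to
#' `max_mismatches` substitutions.  Because SfiI digestion during cloning can
#' truncate the tag, its terminal remnant (`suffix`, default the last 7
#' bases) is also accepted, with a tighter budget of one mismatch.
#'
#' @param residues vector-trimmed 5' read sequence.
#' @param cap_tag tag sequence (DNA alphabet).
#' @param max_mismatches substitution budget for the full tag.
#' @param search_window bases from the read start within which the tag must
#'   begin.
#' @param suffix SfiI-remnant suffix accepted in place of the full tag.
#' @return list with `cap_found` (logical) and `cap_end` (0-based position
#'   just past the tag; NA when not found).
#' @export
detect_cap_tag <- function(residues, cap_tag = CAP_TAG, max_mismatches = 2,
                           search_window = 60, suffix = CAP_TAG_SUFFIX) {
  mm <- mismatch_scan(residues, cap_tag, search_window - 1L)
  hit <- which(mm <= max_mismatches)
  if (length(hit)) {
    start <- hit[1L] - 1L
    return(list(cap_found = TRUE, cap_end = start + nchar(cap_tag)))
  }
  mm <- mismatch_scan(residues, suffix, search_window - 1L)
  hit <- which(mm <= 1L)
  if (length(hit)) {
    start <- hit[1L] - 1L
    return(list(cap_found = TRUE, cap_end = start + nchar(suffix)))
  }
  list(cap_found = FALSE, cap_end = NA_integer_)
}

# length of a cap-tag suffix anchored at the very start of a sense read
# (a read sequenced through the whole insert begins with the tag, possibly
# already shortened by quality trimming); mismatch budget scales with length
cap_remnant_length <- function(residues, cap_tag = CAP_TAG) {
  clen <- nchar(cap_tag)
  ch <- strsplit(substr(residues, 1L, clen), "")[[1L]]
  if (length(ch) < 7L) return(0L)
  for (k in min(clen, length(ch)):7L) {
    frag <- strsplit(substr(cap_tag, clen - k + 1L, clen), "")[[1L]]
    if (sum(ch[1:k] != frag) <= k %/% 10L) return(k)
  }
  0L
}

# longest terminal A-run: first index (0-based) of the maximal window of
# >= min_tail bases with A-fraction >= purity, starting on an A and ending
# within max_end_gap of the sequence end; NA if none.
find_polya_tail <- function(residues, min_tail = 8, max_end_gap = 3,
                            purity = 0.9) {
  n <- nchar(residues)
  if (n < min_tail) return(NA_integer_)
  ch <- strsplit(residues, "")[[1L]]
  isA <- ch == "A"
  best <- NA_integer_; best_len <- 0L
  for (e in n:max(min_tail, n - max_end_gap)) {
    a <- 0L
    lo <- max(1L, e - 400L)
    for (t in e:lo) {
      if (isA[t]) a <- a + 1L
      len <- e - t + 1L
      if (len >= min_tail && isA[t] && a / len >= purity && len > best_len) {
        best_len <- len; best <- t - 1L
      }
    }
  }
  best
}

#' Orient a 3' read to sense and locate its poly(A) tail
#'
#' Raw 3' reads are sequenced from the poly(T) primer and are therefore
#' antisense: they begin with the primer head followed by a T-run.  The read
#' is recognised as antisense by the primer head (<= 2 mismatches) or a
#' leading T-run, the primer head is removed, and the read is
#' reverse-complemented.  Reads already carrying a terminal A-run are
#' treated as sense and left unchanged, so the operation is idempotent on
#' sense reads.  The tail is the maximal terminal run of >= `min_tail`
#' bases with A-fraction >= `purity` ending within `max_end_gap` of the end.
#'
#' @param residues vector-trimmed 3' read sequence.
#' @param min_tail,max_end_gap,purity tail-run definition (see above).
#' @param primer_head constant head of the poly(T) primer.
#' @return list with `residues` (sense orientation), `tail_start` (0-based,
#'   NA when no tail), `oriented_sense` (TRUE when the read was flipped) and
#'   `trimmed_head` (bases removed from the raw read start).
#' @export
orient_and_detect_polya <- function(residues, min_tail = 8, max_end_gap = 3,
                                    purity = 0.9,
                                    primer_head = POLYT_PRIMER_HEAD) {
  flipped <- FALSE
  trimmed <- 0L
  sense_tail <- find_polya_tail(residues, min_tail, max_end_gap, purity)
  if (is.na(sense_tail)) {
    mm <- mismatch_scan(residues, primer_head, 5L)
    head_at <- which(mm <= 2L)
    if (length(head_at)) {
      cut <- (head_at[1L] - 1L) + nchar(primer_head)
      trimmed <- cut
      residues <- substr(residues, cut + 1L, nchar(residues))
      residues <- revcomp(residues)
      flipped <- TRUE
    } else {
      # a leading T-run marks an antisense read even without the primer
      # head; detected as a terminal A-run on the reverse complement so the
      # same gap/purity tolerances apply at this end too
      rc <- revcomp(residues)
      if (!is.na(find_polya_tail(rc, min_tail, max_end_gap, purity))) {
        residues <- rc
        flipped <- TRUE
      }
    }
    sense_tail <- find_polya_tail(residues, min_tail, max_end_gap, purity)
  }
  list(residues = residues, tail_start = sense_tail,
       oriented_sense = flipped, trimmed_head = trimmed)
}

#' Minimum-length filter
#'
#' Inserts shorter than `min_len` bases are low-quality short reads and are
#' discarded; the boundary is inclusive (exactly `min_len` is kept).
#'
#' @param insert_len insert length in bases (adapters excluded).
#' @param min_len minimum retained length.
#' @return TRUE to keep, FALSE to discard as too short.
#' @export
filter_length <- function(insert_len, min_len = 150) {
  insert_len >= min_len
}

# DUST-style score of one window: sum over triplet types of c*(c-1)/2,
# normalised by (window length - 3)
dust_score <- function(chars) {
  n <- length(chars)
  if (n < 4L) return(0)
  tri <- paste0(chars[1:(n - 2L)], chars[2:(n - 1L)], chars[3:n])
  cnt <- table(tri)
  sum(cnt * (cnt - 1) / 2) / (n - 3L)
}

#' Low-complexity flag
#'
#' A DUST-style triplet score is computed in sliding windows; the read is
#' flagged when any window exceeds `threshold` (classic DUST default 2).
#' Externally supplied mask intervals (e.g. from a dedicated repeat masker)
#' are honoured: the read is flagged when they cover more than
#' `mask_coverage` of its length.
#'
#' @param residues read sequence.
#' @param window window size in bases.
#' @param threshold score above which a window flags the read.
#' @param step window step (half-window overlap by default).
#' @param mask optional two-column matrix of 0-based half-open masked
#'   intervals from an external masker.
#' @param mask_coverage coverage fraction above which the mask flags the read.
#' @param exclude_polya_runs drop homopolymer A/T runs of 10+ bases before
#'   scoring, so genuine poly(A) tails (and poly(T) heads) do not flag
#'   otherwise complex transcript sequence.
#' @return TRUE when flagged as low complexity.
#' @export
flag_low_complexity <- function(residues, window = 64, threshold = 2,
                                step = window %/% 2L, mask = NULL,
                                mask_coverage = 0.9,
                                exclude_polya_runs = TRUE) {
  n <- nchar(residues)
  if (!is.null(mask) && nrow(mask) > 0L) {
    covered <- logical(n)
    for (i in seq_len(nrow(mask))) {
      lo <- max(1L, mask[i, 1L] + 1L); hi <- min(n, mask[i, 2L])
      if (hi >= lo) covered[lo:hi] <- TRUE
    }
    if (mean(covered) > mask_coverage) return(TRUE)
  }
  if (exclude_polya_runs)
    residues <- gsub("A{10,}|T{10,}", "", residues)
  n <- nchar(residues)
  if (n == 0L) return(FALSE)
  ch <- strsplit(residues, "")[[1L]]
  starts <- unique(c(seq(1L, max(1L, n - window + 1L), by = max(1L, step)),
                     max(1L, n - window + 1L)))
  for (s in starts) {
    w <- ch[s:min(n, s + window - 1L)]
    if (dust_score(w) > threshold) return(TRUE)
  }
  FALSE
}

# shared k-mer test between a read and a prebuilt k-mer set
kmer_set <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n >= k) out <- c(out, substring(s, 1:(n - k + 1L), k:n))
  }
  unique(out)
}

#' Mitochondrial-contamination flag
#'
#' Seed-and-extend screen against the mitochondrial genome: reads sharing a
#' 12-mer with either strand of the genome are locally aligned, and flagged
#' when an alignment of at least `min_aln_len` bases at identity >=
#' `min_identity` exists.  A qualifying alignment (100 bp at 95% identity)
#' always contains an exact 12-mer by the pigeonhole principle, so the seed
#' filter cannot miss one.
#'
#' @param residues read sequence.
#' @param mito_genome mitochondrial genome sequence, or a screen prebuilt
#'   with [build_mito_screen()].
#' @param min_aln_len minimum local-alignment length.
#' @param min_identity minimum alignment identity.
#' @return TRUE when flagged as mitochondrial.
#' @export
flag_mitochondrial <- function(residues, mito_genome, min_aln_len = 100,
                               min_identity = 0.95) {
  screen <- if (is.list(mito_genome)) mito_genome
            else build_mito_screen(mito_genome)
  n <- nchar(residues)
  if (n < screen$k) return(FALSE)
  rk <- substring(residues, 1:(n - screen$k + 1L), screen$k:n)
  if (!any(rk %in% screen$kmers)) return(FALSE)
  for (g in screen$strands) {
    al <- local_align_cpp(residues, g)
    if (al$aln_len >= min_aln_len && al$matches / al$aln_len >= min_identity)
      return(TRUE)
  }
  FALSE
}

#' Prebuild the mitochondrial k-mer screen
#'
#' @param mito_genome mitochondrial genome sequence(s).
#' @param k seed length.
#' @return screen object for [flag_mitochondrial()].
#' @export
build_mito_screen <- function(mito_genome, k = 12L) {
  strands <- c(mito_genome, revcomp(mito_genome))
  list(k = k, kmers = kmer_set(strands, k), strands = strands)
}

#' Per-read preprocessing
#'
#' Applies the full per-read QC chain in a fixed order -- quality trim,
#' vector trim, cap-tag detection (5' reads) or sense orientation and
#' poly(A) detection (3' reads), then the length, low-complexity and
#' mitochondrial filters.  Each read receives exactly one disposition:
#' `"kept"` or the first failing filter among `ALL_VECTOR`, `TOO_SHORT`,
#' `LOW_COMPLEXITY`, `MITOCHONDRIAL`.  Insert length excludes the cap-tag
#' and poly(T)-primer adapters but keeps the poly(A) tail (transcript
#' sequence).
#'
#' @param records a [seq_records] data.frame of raw reads (`<clone>_<end>`
#'   ids).
#' @param vector_seqs character vector of cloning-vector sequences.
#' @param mito_genome mitochondrial genome sequence (optional).
#' @param min_len minimum insert length.
#' @param quality_threshold PHRED trimming threshold.
#' @param cap_tag,max_cap_mismatches,cap_search_window cap-tag detection
#'   parameters (see [detect_cap_tag()]).
#' @param min_tail,max_end_gap,purity poly(A) tail definition.
#' @param lc_threshold DUST-style window score threshold.
#' @param mask optional named list of external mask interval matrices.
#' @return list with `annotations` (one row per read: clone, end,
#'   disposition, cap_found, cap_end, tail_start, trim_start, trim_end) and
#'   `inserts` (a [seq_records] of kept, adapter-free, sense-oriented
#'   inserts).
#' @export
preprocess_reads <- function(records, vector_seqs = character(0),
                             mito_genome = NULL, min_len = 150,
                             quality_threshold = 20, cap_tag = CAP_TAG,
                             max_cap_mismatches = 2, cap_search_window = 60,
                             min_tail = 8, max_end_gap = 3, purity = 0.9,
                             lc_threshold = 2, mask = NULL) {
  parsed <- parse_read_id(records$id)
  screen <- if (!is.null(mito_genome)) build_mito_screen(mito_genome) else NULL
  n <- nrow(records)
  ann <- data.frame(read_id = records$id, clone = parsed$clone,
                    end = parsed$end, tissue = records$tissue,
                    trim_start = 0L, trim_end = 0L,
                    cap_found = FALSE, cap_end = NA_integer_,
                    tail_start = NA_integer_, oriented_sense = FALSE,
                    disposition = "kept", stringsAsFactors = FALSE)
  keep_id <- character(0); keep_seq <- character(0)
  keep_qual <- list(); keep_tissue <- character(0)
  for (i in seq_len(n)) {
    seqi <- records$residues[i]
    qual <- records$qualities[[i]]
    span <- if (!is.null(qual)) trim_quality(qual, quality_threshold)
            else c(0L, nchar(seqi))
    trimmed <- substr(seqi, span[1L] + 1L, span[2L])
    tq <- if (!is.null(qual) && span[2L] > span[1L])
            qual[(span[1L] + 1L):span[2L]] else NULL
    vres <- trim_vector(trimmed, vector_seqs)
    if (vres$all_vector) {
      ann$disposition[i] <- "ALL_VECTOR"
      ann$trim_start[i] <- span[1L]; ann$trim_end[i] <- span[2L]
      next
    }
    vi <- vres$interval
    insert <- substr(trimmed, vi[1L] + 1L, vi[2L])
    iq <- if (!is.null(tq) && vi[2L] > vi[1L]) tq[(vi[1L] + 1L):vi[2L]] else NULL
    ann$trim_start[i] <- span[1L] + vi[1L]
    ann$trim_end[i] <- span[1L] + vi[2L]
    if (identical(parsed$end[i], "5p")) {
      cap <- detect_cap_tag(insert, cap_tag, max_cap_mismatches,
                            cap_search_window)
      ann$cap_found[i] <- cap$cap_found
      ann$cap_end[i] <- cap$cap_end
      if (cap$cap_found) {
        insert <- substr(insert, cap$cap_end + 1L, nchar(insert))
        if (!is.null(iq)) iq <- iq[-seq_len(cap$cap_end)]
      }
    } else if (identical(parsed$end[i], "3p")) {
      pol <- orient_and_detect_polya(insert, min_tail, max_end_gap, purity)
      insert <- pol$residues
      ann$oriented_sense[i] <- pol$oriented_sense
      if (pol$oriented_sense && !is.null(iq)) {
        if (pol$trimmed_head > 0L) iq <- iq[-seq_len(pol$trimmed_head)]
        iq <- rev(iq)
      }
      # a 3' read spanning the whole insert carries a cap-tag remnant at the
      # front of its sense orientation; remove it like any residual adapter
      k <- cap_remnant_length(insert, cap_tag)
      if (k > 0L) {
        insert <- substr(insert, k + 1L, nchar(insert))
        if (!is.null(iq)) iq <- iq[-seq_len(k)]
      }
      ann$tail_start[i] <- find_polya_tail(insert, min_tail, max_end_gap,
                                           purity)
    }
    if (!filter_length(nchar(insert), min_len)) {
      ann$disposition[i] <- "TOO_SHORT"; next
    }
    mmask <- if (!is.null(mask)) mask[[records$id[i]]] else NULL
    if (flag_low_complexity(insert, threshold = lc_threshold, mask = mmask)) {
      ann$disposition[i] <- "LOW_COMPLEXITY"; next
    }
    if (!is.null(screen) && flag_mitochondrial(insert, screen)) {
      ann$disposition[i] <- "MITOCHONDRIAL"; next
    }
    keep_id <- c(keep_id, records$id[i])
    keep_seq <- c(keep_seq, insert)
    keep_qual <- c(keep_qual, list(iq))
    keep_tissue <- c(keep_tissue, records$tissue[i])
  }
  inserts <- seq_records(keep_id, keep_seq, qualities = keep_qual,
                         tissue = keep_tissue)
  # recompute tail position on the final insert for 3' reads
  tails <- ann$tail_start[match(inserts$id, ann$read_id)]
  list(annotations = ann, inserts = inserts, tails = tails)
}
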