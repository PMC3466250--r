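#' Pair each clone's surviving 5' and 3' reads
#'
#' @param inserts a [seq_records] of preprocessed, sense-oriented inserts
#'   with `<clone>_<end>` identifiers.
#' @return list with `pairs` (data.frame: clone, id5, id3) and `orphans`
#'   (ids of reads whose mate did not survive preprocessing; they remain
#'   eligible for EST status).  Two reads with the same clone and end are an
#'   error.
#' @export
pair_clone_reads <- function(inserts) {
  parsed <- parse_read_id(inserts$id)
  if (anyNA(parsed$end))
    stop("read id not parseable as <clone>_<5p|3p>: ",
         inserts$id[which(is.na(parsed$end))[1L]])
  key <- paste(parsed$clone, parsed$end)
  if (anyDuplicated(key))
    stop("two reads with the same clone and end: ", key[duplicated(key)][1L])
  clones <- sort(unique(parsed$clone), method = "radix")
  id5 <- setNames(rep(NA_character_, length(clones)), clones)
  id3 <- id5
  id5[parsed$clone[parsed$end == "5p"]] <- inserts$id[parsed$end == "5p"]
  id3[parsed$clone[parsed$end == "3p"]] <- inserts$id[parsed$end == "3p"]
  both <- !is.na(id5) & !is.na(id3)
  pairs <- data.frame(clone = clones[both], id5 = unname(id5[both]),
                      id3 = unname(id3[both]), stringsAsFactors = FALSE)
  orphans <- c(unname(id5[!both & !is.na(id5)]), unname(id3[!both & !is.na(id3)]))
  list(pairs = pairs, orphans = sort(orphans, method = "radix"))
}

#' Merge a clone's 5' and 3' reads by overlap alignment
#'
#' The best alignment of a suffix of the 5' read against a prefix of the
#' (sense-oriented) 3' read is computed by overlap dynamic programming.  The
#' merge is accepted when the overlap exceeds `min_overlap_frac` of the
#' shorter read (strictly) and its identity is at least `min_identity`;
#' otherwise both reads continue unassembled.  At mismatching columns the
#' consensus takes the higher-quality base (the 5' base when qualities are
#' absent or tied).
#'
#' @param seq5,seq3 read sequences, both sense-oriented.
#' @param qual5,qual3 optional integer PHRED vectors.
#' @param min_identity minimum overlap identity.
#' @param min_overlap_frac overlap must exceed this fraction of the shorter
#'   read.
#' @return list with `merged` (logical); when merged also `residues`,
#'   `overlap_len` (alignment columns) and `overlap_identity`.
#' @export
merge_overlap <- function(seq5, seq3, qual5 = NULL, qual3 = NULL,
                          min_identity = 0.95, min_overlap_frac = 0.5) {
  al <- overlap_align_cpp(seq5, seq3)
  if (al$aln_len == 0L) return(list(merged = FALSE))
  identity <- al$matches / al$aln_len
  shorter <- min(nchar(seq5), nchar(seq3))
  if (!(al$aln_len > min_overlap_frac * shorter && identity >= min_identity))
    return(list(merged = FALSE))
  ch5 <- strsplit(seq5, "")[[1L]]
  ch3 <- strsplit(seq3, "")[[1L]]
  cons <- character(al$aln_len)
  for (k in seq_len(al$aln_len)) {
    ia <- al$ai[k]; ib <- al$bi[k]
    if (ia == 0L) {
      cons[k] <- ch3[ib]
    } else if (ib == 0L) {
      cons[k] <- ch5[ia]
    } else if (ch5[ia] == ch3[ib]) {
      cons[k] <- ch5[ia]
    } else {
      q5 <- if (!is.null(qual5)) qual5[ia] else -1L
      q3 <- if (!is.null(qual3)) qual3[ib] else -2L
      cons[k] <- if (q3 > q5) ch3[ib] else ch5[ia]  # tie goes to the 5' read
    }
  }
  # bases of the 5' read beyond the aligned end (adapter read-through past
  # the 3' read's terminus) are dropped
  merged <- paste0(substr(seq5, 1L, al$a_start),
                   paste(cons, collapse = ""),
                   substr(seq3, al$b_end + 1L, nchar(seq3)))
  list(merged = TRUE, residues = merged, overlap_len = al$aln_len,
       overlap_identity = identity)
}

#' Assemble all clone pairs
#'
#' @param inserts a [seq_records] of preprocessed inserts.
#' @param min_identity,min_overlap_frac merge acceptance thresholds (see
#'   [merge_overlap()]).
#' @return list with `transcripts` (a [seq_records] of merged transcripts,
#'   ids = clone ids), `report` (per-pair data.frame: clone, merged,
#'   overlap_len, identity), `orphans` (unmated read ids) and `unmerged`
#'   (read ids of pairs that failed to merge).
#' @export
assemble_pairs <- function(inserts, min_identity = 0.95,
                           min_overlap_frac = 0.5) {
  pr <- pair_clone_reads(inserts)
  idx <- setNames(seq_len(nrow(inserts)), inserts$id)
  n <- nrow(pr$pairs)
  merged_flag <- logical(n)
  ov_len <- rep(NA_integer_, n); ov_id <- rep(NA_real_, n)
  t_id <- character(0); t_seq <- character(0); t_tissue <- character(0)
  unmerged <- character(0)
  for (i in seq_len(n)) {
    i5 <- idx[[pr$pairs$id5[i]]]; i3 <- idx[[pr$pairs$id3[i]]]
    res <- merge_overlap(inserts$residues[i5], inserts$residues[i3],
                         inserts$qualities[[i5]], inserts$qualities[[i3]],
                         min_identity, min_overlap_frac)
    merged_flag[i] <- res$merged
    if (res$merged) {
      ov_len[i] <- res$overlap_len; ov_id[i] <- res$overlap_identity
      t_id <- c(t_id, pr$pairs$clone[i])
      t_seq <- c(t_seq, res$residues)
      t_tissue <- c(t_tissue, inserts$tissue[i5])
    } else {
      unmerged <- c(unmerged, pr$pairs$id5[i], pr$pairs$id3[i])
    }
  }
  transcripts <- seq_records(t_id, t_seq, tissue = t_tissue)
  report <- data.frame(clone = pr$pairs$clone, merged = merged_flag,
                       overlap_len = ov_len, identity = ov_id,
                       stringsAsFactors = FALSE)
  list(transcripts = transcripts, report = report,
       orphans = pr$orphans, unmerged = sort(unmerged, method = "radix"))
}
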