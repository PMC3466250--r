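#' Translate a sequence in a forward frame
#'
#' Standard genetic code, codon-by-codon; the trailing partial codon is
#' dropped; stop codons render as `*`; codons containing N (or any
#' ambiguity) render as `X`.
#'
#' @param residues DNA sequence.
#' @param frame 1, 2 or 3 (frame f starts at 0-based offset f - 1).
#' @return Amino-acid string.
#' @export
translate_cds <- function(residues, frame = 1) {
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3")
  off <- frame - 1L
  n <- nchar(residues)
  ncod <- (n - off) %/% 3L
  if (ncod <= 0L) return("")
  starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(residues, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

codon_at <- function(residues, pos0) substr(residues, pos0 + 1L, pos0 + 3L)
is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")
is_start <- function(codon) codon == "ATG"

#' Homology-guided open-reading-frame prediction
#'
#' The coding frame is taken from the best sense-strand protein hit; the
#' CDS is seeded by the hit's query interval (snapped to codon boundaries),
#' extended upstream codon-by-codon to the furthest in-frame ATG not
#' preceded (in frame) by a stop, and downstream to the first in-frame stop
#' codon (included in the CDS, excluded from the protein).  When the
#' upstream walk meets a stop before any ATG, the CDS begins at the first
#' in-frame codon after that stop and `has_start_codon` is FALSE; when no
#' in-frame stop exists downstream the CDS runs to the last complete codon
#' and `has_stop_codon` is FALSE.
#'
#' @param residues transcript sequence (sense orientation).
#' @param hit one-row evidence data.frame (sense strand: `frame > 0`,
#'   `e_value < e_max`).
#' @param e_max e-value threshold the hit must meet.
#' @return list: `frame`, `cds_start`, `cds_end` (0-based half-open),
#'   `has_start_codon`, `has_stop_codon`, `protein`.
#' @export
orf_from_evidence <- function(residues, hit, e_max = 1e-7) {
  if (is.null(hit) || nrow(hit) != 1L) stop("exactly one evidence hit required")
  if (hit$frame <= 0L) stop("antisense hit cannot seed an ORF on a sense transcript")
  if (hit$e_value >= e_max) stop("hit does not meet the e-value threshold")
  n <- nchar(residues)
  if (hit$q_start >= n || hit$q_end > n) stop("hit interval outside transcript")
  off <- hit$frame - 1L
  # snap the hit interval onto the frame's codon grid
  seed_start <- off + 3L * ((hit$q_start - off + 2L) %/% 3L)
  if (seed_start < off) seed_start <- off
  # upstream walk: furthest in-frame ATG not preceded in frame by a stop
  pos <- seed_start
  cds_start <- seed_start
  has_start <- is_start(codon_at(residues, seed_start))
  p <- seed_start - 3L
  furthest_atg <- if (has_start) seed_start else NA_integer_
  while (p >= off) {
    cod <- codon_at(residues, p)
    if (is_stop(cod)) break
    if (is_start(cod)) furthest_atg <- p
    p <- p - 3L
  }
  if (!is.na(furthest_atg)) {
    cds_start <- furthest_atg
    has_start <- TRUE
  } else {
    # no ATG upstream: start at the first in-frame codon after the stop
    cds_start <- p + 3L
    has_start <- FALSE
  }
  # downstream walk to the first in-frame stop
  q <- cds_start
  has_stop <- FALSE
  while (q + 3L <= n) {
    if (is_stop(codon_at(residues, q))) { has_stop <- TRUE; break }
    q <- q + 3L
  }
  cds_end <- if (has_stop) q + 3L else q
  cds <- substr(residues, cds_start + 1L, cds_end)
  protein <- translate_cds(cds, 1L)
  if (has_stop) protein <- substr(protein, 1L, nchar(protein) - 1L)
  list(frame = hit$frame, cds_start = cds_start, cds_end = cds_end,
       has_start_codon = has_start, has_stop_codon = has_stop,
       protein = protein)
}

#' Predict ORFs for a transcript set
#'
#' Each transcript is seeded by its single best sense hit (lowest e-value,
#' then highest bit score, then subject id).
#'
#' @param records a [seq_records] of sense transcripts.
#' @param hits evidence data.frame (`query_id` = transcript id).
#' @param e_max e-value threshold.
#' @return data.frame: `transcript_id`, `frame`, `cds_start`, `cds_end`,
#'   `has_start_codon`, `has_stop_codon`, `protein`; transcripts without a
#'   qualifying sense hit are omitted.
#' @export
predict_orfs <- function(records, hits, e_max = 1e-7) {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    h <- hits[hits$query_id == records$id[i], , drop = FALSE]
    bh <- best_hit(h, sense_only = TRUE)
    if (is.null(bh) || bh$e_value >= e_max) next
    o <- orf_from_evidence(records$residues[i], bh, e_max)
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = records$id[i], frame = o$frame,
      cds_start = o$cds_start, cds_end = o$cds_end,
      has_start_codon = o$has_start_codon, has_stop_codon = o$has_stop_codon,
      protein = o$protein, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      cds_start = integer(0), cds_end = integer(0),
                      has_start_codon = logical(0), has_stop_codon = logical(0),
                      protein = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
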