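#' Scan for the polyadenylation signal upstream of the tail
#'
#' Hexamers are tried in precedence order (see [polya_signal_hexamers()]):
#' for each, every placement whose end lies between `min_gap` and `max_gap`
#' bases (inclusive) upstream of the tail start is examined, and the first
#' hexamer in precedence order with any legal placement wins -- precedence
#' beats proximity.  Among placements of the winning hexamer the one closest
#' to the tail is reported.  Matching is on the DNA alphabet (U = T);
#' reported labels use the RNA alphabet.
#'
#' @param residues transcript sequence (sense orientation).
#' @param tail_start 0-based position of the first tail base; required.
#' @param min_gap,max_gap inclusive bounds on the gap (bases) between the
#'   hexamer end and the tail start.
#' @param hexamers candidate hexamers in precedence order (RNA alphabet).
#' @return list with `signal` (RNA-alphabet hexamer or
#'   `"NOT_IDENTIFIABLE"`), `start` (0-based, NA when not identifiable) and
#'   `distance` (bases between hexamer end and tail start).
#' @export
scan_signal <- function(residues, tail_start, min_gap = 5, max_gap = 30,
                        hexamers = polya_signal_hexamers()) {
  if (is.null(tail_start) || is.na(tail_start))
    stop("tail_start is required; filter transcripts without a tail first")
  if (tail_start < 0 || tail_start > nchar(residues))
    stop("tail_start outside the sequence")
  # hexamer end e (0-based, exclusive) must satisfy min_gap <= tail_start - e <= max_gap
  e_hi <- tail_start - min_gap
  e_lo <- max(6L, tail_start - max_gap)
  if (e_hi < e_lo)
    return(list(signal = "NOT_IDENTIFIABLE", start = NA_integer_,
                distance = NA_integer_))
  starts <- (e_lo - 6L):(e_hi - 6L)      # 0-based hexamer starts
  window_hex <- substring(residues, starts + 1L, starts + 6L)
  for (hx in hexamers) {
    hit <- which(window_hex == rna_to_dna(hx))
    if (length(hit)) {
      s <- starts[hit[length(hit)]]      # closest placement to the tail
      return(list(signal = hx, start = s,
                  distance = as.integer(tail_start - (s + 6L))))
    }
  }
  list(signal = "NOT_IDENTIFIABLE", start = NA_integer_,
       distance = NA_integer_)
}

#' Polyadenylation-signal usage table
#'
#' Counts and percentages of each signal per transcript group (e.g. coding
#' vs noncoding).  The denominator is all transcripts in the group;
#' transcripts with no identifiable signal form their own row.  Percentages
#' are rounded to one decimal.
#'
#' @param calls data.frame with columns `transcript_id`, `signal`.
#' @param group_labels character vector of group labels, parallel to
#'   `calls` rows (a single label is recycled).
#' @return data.frame: `signal`, `group`, `n`, `pct`, with one row per
#'   signal (in precedence order, then `NOT_IDENTIFIABLE`) per group.
#' @export
usage_table <- function(calls, group_labels = "all") {
  group_labels <- rep_len(group_labels, nrow(calls))
  levels_sig <- c(polya_signal_hexamers(), "NOT_IDENTIFIABLE")
  groups <- sort(unique(group_labels), method = "radix")
  out <- do.call(rbind, lapply(groups, function(g) {
    sigs <- calls$signal[group_labels == g]
    n <- vapply(levels_sig, function(s) sum(sigs == s), integer(1))
    denom <- length(sigs)
    pct <- if (denom > 0L) round(100 * n / denom, 1) else rep(0, length(n))
    data.frame(signal = levels_sig, group = g, n = unname(n),
               pct = unname(pct), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Call signals for a set of transcripts
#'
#' @param records a [seq_records] of sense transcripts.
#' @param tail_starts integer vector of 0-based tail positions (NA rows are
#'   skipped).
#' @param ... passed to [scan_signal()].
#' @return data.frame: `transcript_id`, `signal`, `start`, `distance`.
#' @export
scan_signals <- function(records, tail_starts, ...) {
  keep <- which(!is.na(tail_starts))
  rows <- lapply(keep, function(i) {
    sc <- scan_signal(records$residues[i], tail_starts[i], ...)
    data.frame(transcript_id = records$id[i], signal = sc$signal,
               start = sc$start, distance = sc$distance,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(transcript_id = character(0), signal = character(0),
                      start = integer(0), distance = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
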