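#' Sequence record container
#'
#' A light container for Sanger reads and assembled transcripts: a
#' data.frame with one row per record and columns `id`, `tissue`,
#' `residues` (uppercase DNA over A/C/G/T/N) and a `qualities` list-column
#' of integer PHRED scores (NULL elements when qualities are absent).
#'
#' @param id character vector of record identifiers; must be unique and
#'   non-empty.  Read identifiers follow the `<clone>_<end>` convention with
#'   end one of `5p`/`3p`; transcript identifiers are free-form.
#' @param residues character vector of DNA sequences.
#' @param qualities optional list of integer vectors (PHRED scale), one per
#'   record, each the same length as its sequence.
#' @param tissue optional character vector of tissue labels (recycled).
#' @return A `seq_records` data.frame.
#' @export
seq_records <- function(id, residues, qualities = NULL, tissue = NA_character_) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("id and residues must have the same length")
  if (any(!nzchar(id))) stop("record ids must be non-empty")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1L]
    stop("duplicate record id: ", dup)
  }
  bad <- grepl("[^ACGTN]", residues)
  if (any(bad))
    stop("invalid residues (allowed: A,C,G,T,N) in record ", id[which(bad)[1L]])
  if (is.null(qualities)) {
    qualities <- vector("list", length(id))
  } else {
    if (length(qualities) != length(id))
      stop("qualities must have one element per record")
    ok <- vapply(seq_along(id), function(i) {
      q <- qualities[[i]]
      is.null(q) || length(q) == nchar(residues[i])
    }, logical(1))
    if (!all(ok))
      stop("quality length differs from sequence length in record ",
           id[which(!ok)[1L]])
    qualities <- lapply(qualities, function(q) if (is.null(q)) NULL else as.integer(q))
  }
  out <- data.frame(id = id, tissue = rep_len(tissue, length(id)),
                    residues = residues, stringsAsFactors = FALSE)
  out$qualities <- qualities
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Parse clone and end from read identifiers
#'
#' Read identifiers encode the clone and the sequenced end as
#' `<clone>_<end>` with end `5p` or `3p`.  The pattern is an artifact
#' convention (the identifiers of a real run can be mapped via a sample
#' sheet before entering the pipeline).
#'
#' @param id character vector of read identifiers.
#' @return data.frame with columns `id`, `clone`, `end` (`"5p"`/`"3p"`,
#'   NA when the id does not match the pattern).
#' @export
parse_read_id <- function(id) {
  m <- regmatches(id, regexec("^(.*)_(5p|3p)$", id))
  clone <- vapply(m, function(x) if (length(x) == 3L) x[2L] else NA_character_,
                  character(1))
  end <- vapply(m, function(x) if (length(x) == 3L) x[3L] else NA_character_,
                character(1))
  data.frame(id = id, clone = clone, end = end, stringsAsFactors = FALSE)
}

#' Read sequence records from FASTA or FASTQ
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"` (FASTQ qualities Sanger-encoded,
#'   offset 33).
#' @return A [seq_records] data.frame in file order; lowercase residues are
#'   uppercased; `*` and `-` characters are rejected; duplicate identifiers
#'   are an error.
#' @export
read_seq_records <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    quals <- NULL
  } else {
    check_fastq_shape(path)
    qs <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    set <- Biostrings::BStringSet(qs)
    quals <- as(Biostrings::quality(qs), "IntegerList")
    quals <- lapply(seq_along(quals), function(i) as.integer(quals[[i]]))
  }
  ids <- sub("\\s.*$", "", names(set))
  seq_records(ids, as.character(set), qualities = quals)
}

# Minimal FASTQ structure check so malformed files fail with a line number.
check_fastq_shape <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(invisible(TRUE))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4); trailing record starts at line ",
         4L * (length(lines) %/% 4L) + 1L)
  heads <- seq(1L, length(lines), by = 4L)
  bad <- heads[!startsWith(lines[heads], "@")]
  if (length(bad)) stop("malformed FASTQ record header at line ", bad[1L])
  seps <- heads + 2L
  bad <- seps[!startsWith(lines[seps], "+")]
  if (length(bad)) stop("malformed FASTQ separator at line ", bad[1L])
  invisible(TRUE)
}

#' Write sequence records to FASTA or FASTQ
#'
#' Round-trips with [read_seq_records()]: reading a written file recovers
#' identical ids, residues and qualities.
#'
#' @param records a [seq_records] data.frame.
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`; FASTQ requires qualities on every
#'   record.
#' @return `path`, invisibly.
#' @export
write_seq_records <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  set <- Biostrings::DNAStringSet(records$residues)
  names(set) <- records$id
  if (format == "fasta") {
    Biostrings::writeXStringSet(set, path, format = "fasta")
  } else {
    missing_q <- vapply(records$qualities, is.null, logical(1))
    if (any(missing_q))
      stop("FASTQ output requires qualities; missing for record ",
           records$id[which(missing_q)[1L]])
    qual <- Biostrings::PhredQuality(vapply(seq_len(nrow(records)), function(i) {
      rawToChar(as.raw(records$qualities[[i]] + 33L))
    }, character(1)))
    Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  }
  invisible(path)
}

#' Read a 13-column translated-alignment evidence table
#'
#' The table is tab-separated in BLAST tabular ("outfmt 6") convention plus
#' a subject-description column: query id, subject id, percent identity,
#' alignment length, mismatches, gap opens, query start, query end, subject
#' start, subject end, e-value, bit score, subject description.  File
#' coordinates are 1-based inclusive; a minus-strand query hit is encoded by
#' `q_start > q_end`.
#'
#' On reading, coordinates are normalised to the internal convention:
#' 0-based half-open intervals on the forward query strand, with the strand
#' carried by the sign of `frame` (magnitude = 1 + (smaller query coordinate
#' - 1) mod 3).  Subject (amino-acid) coordinates are likewise 0-based
#' half-open.
#'
#' @param path file path.
#' @return data.frame of evidence hits with columns `query_id`,
#'   `subject_id`, `pct_identity`, `aln_len`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `e_value`, `bitscore`, `frame`,
#'   `subject_desc`.
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- c("query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
            "gap_opens", "q_start", "q_end", "s_start", "s_end", "e_value",
            "bitscore", "subject_desc")
  raw <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE)
    for (nm in c("pct_identity", "e_value", "bitscore")) out[[nm]] <- numeric(0)
    for (nm in c("aln_len", "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end")) out[[nm]] <- integer(0)
    out$frame <- integer(0)
    return(out[, c(cols[1:12], "frame", "subject_desc")])
  }
  if (ncol(raw) != 13L)
    stop("evidence table must have 13 tab-separated columns, found ", ncol(raw))
  names(raw) <- cols
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("non-numeric ", what, " in evidence table: ",
                       x[which(is.na(v))[1L]])
    v
  }
  out <- data.frame(
    query_id = raw$query_id, subject_id = raw$subject_id,
    pct_identity = num(raw$pct_identity, "percent identity"),
    aln_len = as.integer(num(raw$aln_len, "alignment length")),
    mismatches = as.integer(num(raw$mismatches, "mismatch count")),
    gap_opens = as.integer(num(raw$gap_opens, "gap-open count")),
    q_start = as.integer(num(raw$q_start, "query start")),
    q_end = as.integer(num(raw$q_end, "query end")),
    s_start = as.integer(num(raw$s_start, "subject start")),
    s_end = as.integer(num(raw$s_end, "subject end")),
    e_value = num(raw$e_value, "e-value"),
    bitscore = num(raw$bitscore, "bit score"),
    subject_desc = raw$subject_desc,
    stringsAsFactors = FALSE
  )
  minus <- out$q_start > out$q_end
  lo <- pmin(out$q_start, out$q_end)
  hi <- pmax(out$q_start, out$q_end)
  out$frame <- as.integer(ifelse(minus, -1L, 1L) * (1L + (lo - 1L) %% 3L))
  out$q_start <- lo - 1L
  out$q_end <- hi
  out$s_start <- out$s_start - 1L
  out[, c(cols[1:12], "frame", "subject_desc")]
}

#' Normalise evidence coordinates
#'
#' Idempotent on tables already in the internal convention (recognised by
#' the presence of a `frame` column): applying it twice equals applying it
#' once.  Tables straight from [read_evidence_table()] are already
#' normalised; this exists for evidence assembled in code.
#'
#' @param hits evidence data.frame.
#' @return The normalised table.
#' @export
normalize_evidence <- function(hits) {
  if (!is.null(hits$frame)) return(hits)
  stop("evidence table lacks a frame column; read it with read_evidence_table()")
}

#' Write evidence hits back to the 13-column file convention
#'
#' Inverse of [read_evidence_table()]: internal 0-based half-open
#' coordinates are converted to 1-based inclusive, with minus-strand hits
#' written as `q_start > q_end`.
#'
#' @param hits evidence data.frame (internal convention).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(hits, path) {
  qs <- hits$q_start + 1L
  qe <- hits$q_end
  minus <- hits$frame < 0L
  tmp <- qs[minus]; qs[minus] <- qe[minus]; qe[minus] <- tmp
  out <- data.frame(hits$query_id, hits$subject_id, hits$pct_identity,
                    hits$aln_len, hits$mismatches, hits$gap_opens,
                    qs, qe, hits$s_start + 1L, hits$s_end,
                    format(hits$e_value, scientific = TRUE, trim = TRUE),
                    hits$bitscore, hits$subject_desc,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tab-separated report table
#'
#' Deterministic output: rows are sorted by the first column (radix order),
#' so regenerating a report from the same rows is byte-identical.
#'
#' @param rows data.frame sharing a header.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(rows, path) {
  if (nrow(rows) > 0L)
    rows <- rows[order(as.character(rows[[1L]]), method = "radix"), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(rows, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n",
              fileEncoding = "UTF-8")
  invisible(path)
}
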