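#' Best evidence hit
#'
#' Deterministic best-hit selection: lowest e-value, then highest bit
#' score, then lexicographically smallest subject id.
#'
#' @param hits evidence data.frame (internal convention).
#' @param sense_only restrict to plus-frame hits.
#' @return One-row data.frame, or NULL when no hit qualifies.
#' @export
best_hit <- function(hits, sense_only = FALSE) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  if (sense_only) hits <- hits[hits$frame > 0L, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  ord <- order(hits$e_value, -hits$bitscore, hits$subject_id, method = "radix")
  hits[ord[1L], , drop = FALSE]
}

#' Flag a read as a truncated protein-coding transcript
#'
#' A read with a significant sense-strand protein hit is triaged as a
#' truncated coding EST (before assembly) when the evidence shows the
#' transcript cannot be full length: for a 5' read, the cap tag is absent,
#' or the hit starts deep into the subject (`s_start > margin_aa`) while the
#' read's 5' end is already in coding sequence (`q_start < 3 * margin_aa`)
#' -- a missing N-terminus; for a 3' read, the poly(A) tail is absent, or
#' the hit stops short of the subject C-terminus by more than `margin_aa`
#' residues while the query alignment runs to within `3 * margin_aa` of the
#' read end.  Reads without a qualifying hit are never flagged here (they
#' continue to assembly).
#'
#' @param end `"5p"` or `"3p"`.
#' @param has_anchor cap presence (5' reads) or tail presence (3' reads).
#' @param hits evidence hits for this read.
#' @param read_len read length in bases.
#' @param subject_lengths optional named vector of subject protein lengths
#'   (aa); without it the C-/N-terminal coverage clauses cannot fire.
#' @param e_max e-value threshold for a qualifying hit.
#' @param margin_aa terminal margin in amino acids.
#' @return TRUE when the read is a truncated coding EST.
#' @export
flag_truncated_coding <- function(end, has_anchor, hits, read_len,
                                  subject_lengths = NULL, e_max = 1e-7,
                                  margin_aa = 20) {
  bh <- best_hit(hits, sense_only = TRUE)
  if (is.null(bh) || bh$e_value >= e_max) return(FALSE)
  if (!isTRUE(has_anchor)) return(TRUE)
  if (identical(end, "5p")) {
    return(bh$s_start > margin_aa && bh$q_start < 3 * margin_aa)
  }
  slen <- if (!is.null(subject_lengths)) subject_lengths[[bh$subject_id]] else NULL
  if (is.null(slen) || is.na(slen)) return(FALSE)
  bh$s_end < slen - margin_aa && bh$q_end > read_len - 3 * margin_aa
}

#' Classify a merged full-length transcript
#'
#' Oligo-capped transcripts encode protein on the sense strand, so a
#' significant sense-frame hit makes the transcript full-length coding; a
#' best hit described as reverse transcriptase is discarded as a likely
#' retroelement; transcripts with only antisense hits, or none, are
#' full-length noncoding.
#'
#' @param transcript_id transcript (clone) identifier.
#' @param hits evidence hits for this transcript.
#' @param e_max e-value threshold.
#' @param rt_patterns case-insensitive substrings of subject descriptions
#'   that mark retroelement contamination.
#' @return One-row data.frame: `subject_id`, `category` (`FL_CODING`,
#'   `FL_NONCODING` or `DISCARD_RT`), `basis`, `evidence_subject`.
#' @export
classify_full_length <- function(transcript_id, hits, e_max = 1e-7,
                                 rt_patterns = "reverse transcriptase") {
  mk <- function(category, basis, ev = NA_character_)
    data.frame(subject_id = transcript_id, category = category, basis = basis,
               evidence_subject = ev, stringsAsFactors = FALSE)
  bh <- best_hit(hits)
  if (!is.null(bh)) {
    desc <- tolower(bh$subject_desc)
    if (any(vapply(tolower(rt_patterns), grepl, logical(1), x = desc,
                   fixed = TRUE)))
      return(mk("DISCARD_RT", "blast_hit_sense", bh$subject_id))
  }
  bs <- best_hit(hits, sense_only = TRUE)
  if (!is.null(bs) && bs$e_value < e_max)
    return(mk("FL_CODING", "blast_hit_sense", bs$subject_id))
  if (!is.null(bh) && bh$e_value < e_max)
    return(mk("FL_NONCODING", "blast_hit_antisense", bh$subject_id))
  mk("FL_NONCODING", "no_hit")
}

#' Select clones for full-length sequencing by primer walking
#'
#' Among unassembled clones, those whose 5' read hits the N-terminal region
#' of a protein (within `margin_aa` residues of the start) and whose 3' read
#' hits the C-terminal region of the same protein span the complete coding
#' sequence and can be finished by primer walking.  Qualifying clones are
#' ranked by 5'-read length (descending; ties by clone id) and the top `n`
#' returned.
#'
#' @param hits5,hits3 evidence for unmerged 5' and 3' reads (`query_id` =
#'   read id).
#' @param read_lens named vector of read lengths.
#' @param subject_lengths named vector of subject protein lengths (aa).
#' @param n number of clones to select.
#' @param margin_aa terminal margin in amino acids.
#' @param e_max e-value threshold.
#' @return character vector of selected clone ids, in rank order.
#' @export
select_walking_candidates <- function(hits5, hits3, read_lens,
                                      subject_lengths, n = 800,
                                      margin_aa = 20, e_max = 1e-7) {
  qual5 <- hits5[hits5$frame > 0L & hits5$e_value < e_max &
                   hits5$s_start <= margin_aa, , drop = FALSE]
  s_len <- subject_lengths[hits3$subject_id]
  qual3 <- hits3[hits3$frame > 0L & hits3$e_value < e_max &
                   !is.na(s_len) & hits3$s_end >= s_len - margin_aa, ,
                 drop = FALSE]
  if (nrow(qual5) == 0L || nrow(qual3) == 0L) return(character(0))
  p5 <- parse_read_id(qual5$query_id)
  p3 <- parse_read_id(qual3$query_id)
  key5 <- unique(paste(p5$clone, qual5$subject_id))
  key3 <- unique(paste(p3$clone, qual3$subject_id))
  shared <- intersect(key5, key3)
  if (length(shared) == 0L) return(character(0))
  clones <- unique(sub(" .*$", "", shared))
  len5 <- read_lens[paste0(clones, "_5p")]
  ord <- order(-len5, clones, method = "radix")
  head(clones[ord], n)
}

#' Retain unassembled reads as 5'- and 3'-ESTs
#'
#' Reads that were neither assembled nor selected for walking are kept as
#' single-pass ESTs when at least `min_len` bases long; shorter reads are
#' discarded.
#'
#' @param read_ids read identifiers (`<clone>_<end>`).
#' @param read_lens lengths of those reads.
#' @param min_len minimum retained length (inclusive boundary).
#' @return data.frame: `read_id`, `category` (`EST5`, `EST3` or
#'   `DISCARD_SHORT_EST`).
#' @export
retain_ests <- function(read_ids, read_lens, min_len = 300) {
  parsed <- parse_read_id(read_ids)
  category <- ifelse(read_lens < min_len, "DISCARD_SHORT_EST",
                     ifelse(parsed$end == "5p", "EST5", "EST3"))
  data.frame(read_id = read_ids, category = category, stringsAsFactors = FALSE)
}

#' Categorise genes by differential loss between tetrapods and teleosts
#'
#' Per-species homology presence is collapsed by OR within each group; a
#' gene with hits in tetrapods but none in teleosts was lost in teleosts
#' (and symmetrically), a gene with hits in both groups is shared, and a
#' gene with no hits in either group is absent from bony vertebrates.
#'
#' @param presence data.frame with columns `gene_id`, `group` (`"tetrapods"`
#'   or `"teleosts"`), `present` (logical), one row per gene x species.
#' @return data.frame: `gene_id`, `tetrapods`, `teleosts`, `category`.
#' @export
categorize_gene_loss <- function(presence) {
  stopifnot(all(c("gene_id", "group", "present") %in% names(presence)))
  if (!all(presence$group %in% c("tetrapods", "teleosts")))
    stop("groups must be 'tetrapods' and 'teleosts'")
  genes <- sort(unique(presence$gene_id), method = "radix")
  agg <- function(grp) vapply(genes, function(g)
    any(presence$present[presence$gene_id == g & presence$group == grp]),
    logical(1))
  tet <- agg("tetrapods"); tel <- agg("teleosts")
  category <- ifelse(tet & tel, "SHARED",
              ifelse(tet & !tel, "LOST_IN_TELEOSTS",
              ifelse(!tet & tel, "LOST_IN_TETRAPODS",
                     "ABSENT_IN_BONY_VERTEBRATES")))
  data.frame(gene_id = genes, tetrapods = unname(tet), teleosts = unname(tel),
             category = unname(category), stringsAsFactors = FALSE)
}
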