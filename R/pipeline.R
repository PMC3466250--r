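#' Run the full clone-classification pipeline
#'
#' Executes the decision tree over a set of paired raw reads:
#' preprocessing, truncated-coding triage, paired-read assembly,
#' full-length classification, unique-set clustering of unassembled reads,
#' walking-candidate selection, EST retention, non-redundant set
#' construction, polyadenylation-signal calling and ORF prediction.  Every
#' read receives exactly one terminal disposition.
#'
#' @param reads a [seq_records] of raw paired reads (`<clone>_<end>` ids).
#' @param read_hits evidence table for processed reads (query ids = read
#'   ids).
#' @param transcript_hits evidence table for merged transcripts (query ids
#'   = clone ids); rows for clones that do not merge are ignored.
#' @param subject_lengths named vector of subject protein lengths (aa).
#' @param vector_seqs,mito_genome contaminant screens for preprocessing;
#'   the poly(T)-primer head is always screened as a residual adapter.
#' @param e_max evidence e-value threshold.
#' @param margin_aa terminal margin (aa) for truncation/walking rules.
#' @param min_len minimum insert length at preprocessing.
#' @param est_min_len minimum retained EST length.
#' @param walking_n number of walking candidates to select.
#' @param merge_min_identity,merge_min_overlap_frac merge acceptance rules.
#' @param est_cluster_identity,est_cluster_coverage unique-set clustering
#'   thresholds for unassembled reads.
#' @param nr_protein_identity,nr_protein_coverage protein non-redundant set
#'   thresholds.
#' @param nr_noncoding_identity,nr_noncoding_coverage noncoding two-set
#'   clustering thresholds.
#' @return A list with the stage outputs: `preprocess`, `read_class` (one
#'   row per input read: read_id, clone, end, category), `assembly`,
#'   `fl_class`, `walking`, `orfs`, `proteins`, `nr_protein_clusters`,
#'   `nr_noncoding`, `est_clusters_5p`, `est_clusters_3p`, `signal_calls`,
#'   `signal_groups`, `clone_categories`.
#' @export
run_pipeline <- function(reads, read_hits, transcript_hits,
                         subject_lengths = NULL,
                         vector_seqs = character(0), mito_genome = NULL,
                         e_max = 1e-7, margin_aa = 20,
                         min_len = 150, est_min_len = 300, walking_n = 800,
                         merge_min_identity = 0.95,
                         merge_min_overlap_frac = 0.5,
                         est_cluster_identity = 0.99,
                         est_cluster_coverage = 0.95,
                         nr_protein_identity = 0.98,
                         nr_protein_coverage = 0.90,
                         nr_noncoding_identity = 0.98,
                         nr_noncoding_coverage = 0.95) {
  screens <- unique(c(vector_seqs, POLYT_PRIMER_HEAD))
  pp <- preprocess_reads(reads, vector_seqs = screens,
                         mito_genome = mito_genome, min_len = min_len)
  ann <- pp$annotations
  inserts <- pp$inserts

  read_class <- data.frame(read_id = ann$read_id, clone = ann$clone,
                           end = ann$end, category = ann$disposition,
                           stringsAsFactors = FALSE)
  kept <- read_class$category == "kept"

  # truncated-coding triage (before assembly, per read)
  hit_split <- split(seq_len(nrow(read_hits)), read_hits$query_id)
  get_hits <- function(id) {
    ix <- hit_split[[id]]
    if (is.null(ix)) NULL else read_hits[ix, , drop = FALSE]
  }
  ins_idx <- setNames(seq_len(nrow(inserts)), inserts$id)
  for (i in which(kept)) {
    id <- read_class$read_id[i]
    anchor <- if (ann$end[i] == "5p") ann$cap_found[i] else !is.na(ann$tail_start[i])
    rlen <- nchar(inserts$residues[ins_idx[[id]]])
    if (flag_truncated_coding(ann$end[i], anchor, get_hits(id), rlen,
                              subject_lengths, e_max, margin_aa))
      read_class$category[i] <- "EST_TRUNCATED"
  }

  # assembly of clones with both ends surviving and untriaged
  assemble_ids <- read_class$read_id[read_class$category == "kept"]
  asm <- assemble_pairs(inserts[inserts$id %in% assemble_ids, ],
                        min_identity = merge_min_identity,
                        min_overlap_frac = merge_min_overlap_frac)
  merged_clones <- asm$transcripts$id
  read_class$category[read_class$category == "kept" &
                        read_class$clone %in% merged_clones] <- "MERGED"

  # full-length classification of merged transcripts
  t_split <- split(seq_len(nrow(transcript_hits)), transcript_hits$query_id)
  fl_class <- do.call(rbind, lapply(merged_clones, function(cl) {
    ix <- t_split[[cl]]
    h <- if (is.null(ix)) NULL else transcript_hits[ix, , drop = FALSE]
    classify_full_length(cl, h, e_max)
  }))
  if (is.null(fl_class))
    fl_class <- data.frame(subject_id = character(0), category = character(0),
                           basis = character(0),
                           evidence_subject = character(0),
                           stringsAsFactors = FALSE)

  # unassembled reads: unique sets, walking candidates, ESTs
  loose_ids <- read_class$read_id[read_class$category == "kept"]
  loose <- inserts[inserts$id %in% loose_ids, ]
  loose_end <- parse_read_id(loose$id)$end
  est5_clusters <- greedy_cluster(loose[loose_end == "5p", ],
                                  est_cluster_identity, est_cluster_coverage,
                                  mode = "nucleotide")
  est3_clusters <- greedy_cluster(loose[loose_end == "3p", ],
                                  est_cluster_identity, est_cluster_coverage,
                                  mode = "nucleotide")
  read_lens <- setNames(nchar(loose$residues), loose$id)
  hits_loose <- read_hits[read_hits$query_id %in% loose$id, , drop = FALSE]
  p_loose <- parse_read_id(hits_loose$query_id)$end
  walking <- select_walking_candidates(
    hits_loose[p_loose == "5p", , drop = FALSE],
    hits_loose[p_loose == "3p", , drop = FALSE],
    read_lens, subject_lengths, n = walking_n, margin_aa = margin_aa,
    e_max = e_max)
  walk_reads <- read_class$category == "kept" & read_class$clone %in% walking
  read_class$category[walk_reads] <- "WALKING_CANDIDATE"

  still <- read_class$category == "kept"
  if (any(still)) {
    ests <- retain_ests(read_class$read_id[still],
                        read_lens[read_class$read_id[still]], est_min_len)
    read_class$category[still] <- ests$category
  }

  # ORFs and non-redundant sets
  coding_clones <- fl_class$subject_id[fl_class$category == "FL_CODING"]
  noncoding_clones <- fl_class$subject_id[fl_class$category == "FL_NONCODING"]
  coding_tx <- asm$transcripts[asm$transcripts$id %in% coding_clones, ]
  noncoding_tx <- asm$transcripts[asm$transcripts$id %in% noncoding_clones, ]
  orfs <- predict_orfs(coding_tx, transcript_hits, e_max)
  proteins <- setNames(orfs$protein, orfs$transcript_id)
  nr_protein_clusters <- greedy_cluster(proteins, nr_protein_identity,
                                        nr_protein_coverage, mode = "protein")
  nr_noncoding <- cluster_two_sets(noncoding_tx, coding_tx,
                                   nr_noncoding_identity,
                                   nr_noncoding_coverage)

  # polyadenylation signals on merged transcripts
  tails <- vapply(asm$transcripts$residues, find_polya_tail, integer(1),
                  USE.NAMES = FALSE)
  signal_calls <- scan_signals(asm$transcripts, tails)
  grp <- ifelse(signal_calls$transcript_id %in% coding_clones, "coding",
                ifelse(signal_calls$transcript_id %in% noncoding_clones,
                       "noncoding", "discarded"))
  signal_groups <- grp

  list(preprocess = pp, read_class = read_class, assembly = asm,
       fl_class = fl_class, walking = walking, orfs = orfs,
       proteins = proteins, nr_protein_clusters = nr_protein_clusters,
       nr_noncoding = nr_noncoding, est_clusters_5p = est5_clusters,
       est_clusters_3p = est3_clusters, signal_calls = signal_calls,
       signal_groups = signal_groups,
       clone_categories = clone_categories_from(read_class, fl_class))
}

# clone-level rollup of per-read categories; the same rules are applied to
# the ground truth by truth_clone_categories()
clone_categories_from <- function(read_class, fl_class) {
  clones <- sort(unique(read_class$clone), method = "radix")
  fl <- setNames(fl_class$category, fl_class$subject_id)
  vapply(clones, function(cl) {
    cats <- read_class$category[read_class$clone == cl]
    if (any(cats == "EST_TRUNCATED")) return("EST_TRUNCATED")
    if (any(cats == "MERGED")) return(unname(fl[cl]))
    if (any(cats == "WALKING_CANDIDATE")) return("WALKING_CANDIDATE")
    if (any(cats %in% c("EST5", "EST3", "DISCARD_SHORT_EST"))) return("EST_ONLY")
    "DROPPED"
  }, character(1))
}

#' Expected clone categories from simulator ground truth
#'
#' Derives, from the ground-truth geometry alone (read lengths, quality
#' tails, truncation cut, CDS coordinates, adapters), the terminal category
#' each sequenced clone is expected to reach: the same decision rules as
#' the pipeline, applied to noise-free arithmetic instead of alignments.
#'
#' @param truth truth table from [simulate_library()].
#' @param proteins named vector of true proteins.
#' @param min_aa minimum codon overlap for a hit (as in
#'   [simulate_evidence()]).
#' @param margin_aa,min_len,est_min_len,min_overlap_frac pipeline
#'   parameters being mirrored.
#' @return Named character vector: clone id -> expected category.
#' @export
truth_clone_categories <- function(truth, proteins, min_aa = 8L,
                                   margin_aa = 20, min_len = 150,
                                   est_min_len = 300,
                                   min_overlap_frac = 0.5) {
  primer <- nchar(POLYT_PRIMER_HEAD)
  out <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    capL <- tr$cap_len; L <- tr$insert_len
    plen <- if (tr$gene_id %in% names(proteins))
      nchar(proteins[[tr$gene_id]]) else NA_integer_
    i5a <- capL
    i5b <- min(tr$read5_len - tr$q10_5, L - primer)
    i3b <- L - primer
    i3a <- max(L - tr$read3_len + tr$q10_3, 0L)
    if (capL > 0L && i3a < capL) i3a <- capL  # cap remnant trimmed
    len5 <- max(0L, i5b - i5a); len3 <- max(0L, i3b - i3a)
    kept5 <- len5 >= min_len; kept3 <- len3 >= min_len
    ov5 <- cds_overlap_aa(tr$mcds_start - (i5a - capL),
                          tr$mcds_end - (i5a - capL), len5, plen)
    ov3 <- cds_overlap_aa(tr$mcds_start - (i3a - capL),
                          tr$mcds_end - (i3a - capL), len3, plen)
    hit5 <- kept5 && !is.na(ov5$aa_e) && ov5$aa_e - ov5$aa_s >= min_aa
    hit3 <- kept3 && !is.na(ov3$aa_e) && ov3$aa_e - ov3$aa_s >= min_aa
    trunc5 <- hit5 && (!tr$full_length ||
                         (ov5$aa_s > margin_aa && ov5$q_start < 3 * margin_aa))
    inter <- min(i5b, i3b) - max(i5a, i3a)
    merged <- kept5 && kept3 && !trunc5 &&
      inter > min_overlap_frac * min(len5, len3)
    ovt <- cds_overlap_aa(tr$mcds_start, tr$mcds_end, tr$mol_len, plen)
    t_hit <- !is.na(ovt$aa_e) && ovt$aa_e - ovt$aa_s >= min_aa
    out[i] <-
      if (!kept5 && !kept3) "DROPPED"
      else if (trunc5) "EST_TRUNCATED"
      else if (merged) { if (tr$coding && t_hit) "FL_CODING" else "FL_NONCODING" }
      else if (kept5 && kept3 && hit5 && hit3 && ov5$aa_s <= margin_aa)
        "WALKING_CANDIDATE"
      else "EST_ONLY"
  }
  setNames(out, truth$clone_id)
}

#' Simulate a library and run the pipeline over it
#'
#' Convenience wrapper tying the simulator to the pipeline with
#' truth-derived evidence: generates the transcriptome and the paired
#' reads, emits read- and transcript-level evidence, runs [run_pipeline()]
#' and compares clone categories against [truth_clone_categories()].
#'
#' @param config a [sim_config()].
#' @param noise decoy-evidence probability.
#' @return list: `sim` (reads + truth), `tx` (transcriptome), `result`
#'   (pipeline output), `truth_categories`, `agreement` (fraction of
#'   sequenced clones whose pipeline category equals the expected one).
#' @export
simulate_and_run <- function(config, noise = 0) {
  tx <- make_transcriptome(config)
  sim <- simulate_library(tx, config)
  spans_r <- read_query_spans(sim$truth)
  read_hits <- simulate_evidence(spans_r, tx$proteins, noise = noise,
                                 seed = config$seed + 7L)
  spans_t <- transcript_query_spans(sim$truth, sim$truth$clone_id)
  tx_hits <- simulate_evidence(spans_t, tx$proteins, noise = noise,
                               seed = config$seed + 11L)
  subject_lengths <- setNames(nchar(tx$proteins), names(tx$proteins))
  res <- run_pipeline(sim$reads, read_hits, tx_hits, subject_lengths)
  expected <- truth_clone_categories(sim$truth, tx$proteins)
  got <- res$clone_categories[names(expected)]
  agreement <- mean(got == expected, na.rm = FALSE)
  list(sim = sim, tx = tx, result = res, truth_categories = expected,
       agreement = agreement)
}
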