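#' Summarise a pipeline run
#'
#' Aggregates per-tissue counts of full-length coding and noncoding
#' transcripts and of retained 5'/3'-ESTs, the non-redundant set sizes, the
#' signal-usage table by class, and a read-count conservation check
#' (every input read in exactly one terminal bucket).
#'
#' @param result output of [run_pipeline()].
#' @return list: `fl_by_tissue`, `est_by_tissue`, `category_counts`,
#'   `nr_sizes`, `signal_usage`, `conservation` (list with `reads_in`,
#'   `reads_out`, `ok`).
#' @export
summarize_pipeline <- function(result) {
  rc <- result$read_class
  tiss <- result$preprocess$annotations$tissue[
    match(rc$read_id, result$preprocess$annotations$read_id)]
  tiss[is.na(tiss)] <- "unspecified"
  fl <- result$fl_class
  clone_tissue <- setNames(tiss, rc$clone)[!duplicated(rc$clone)]

  cat_counts <- table(rc$category)
  category_counts <- data.frame(category = names(cat_counts),
                                n = as.integer(cat_counts),
                                stringsAsFactors = FALSE)
  category_counts <- category_counts[
    order(category_counts$category, method = "radix"), ]
  rownames(category_counts) <- NULL

  tissues <- sort(unique(tiss), method = "radix")
  fl_by_tissue <- do.call(rbind, lapply(tissues, function(tt) {
    cl <- names(clone_tissue)[clone_tissue == tt]
    data.frame(tissue = tt,
               fl_coding = sum(fl$category == "FL_CODING" &
                                 fl$subject_id %in% cl),
               fl_noncoding = sum(fl$category == "FL_NONCODING" &
                                    fl$subject_id %in% cl),
               stringsAsFactors = FALSE)
  }))
  est_by_tissue <- do.call(rbind, lapply(tissues, function(tt) {
    sel <- tiss == tt
    data.frame(tissue = tt,
               est5 = sum(rc$category[sel] == "EST5"),
               est3 = sum(rc$category[sel] == "EST3"),
               stringsAsFactors = FALSE)
  }))

  nr_sizes <- data.frame(
    set = c("nr_protein", "nr_noncoding", "unique_5p", "unique_3p"),
    n = c(length(cluster_reps(result$nr_protein_clusters)),
          length(cluster_reps(result$nr_noncoding$clusters)),
          length(cluster_reps(result$est_clusters_5p)),
          length(cluster_reps(result$est_clusters_3p))),
    stringsAsFactors = FALSE)

  keep <- result$signal_groups %in% c("coding", "noncoding")
  signal_usage <- usage_table(result$signal_calls[keep, , drop = FALSE],
                              result$signal_groups[keep])

  reads_in <- nrow(rc)
  reads_out <- sum(cat_counts)
  list(fl_by_tissue = fl_by_tissue, est_by_tissue = est_by_tissue,
       category_counts = category_counts, nr_sizes = nr_sizes,
       signal_usage = signal_usage,
       conservation = list(reads_in = reads_in, reads_out = reads_out,
                           ok = reads_in == reads_out))
}

#' Write the report bundle to a directory
#'
#' Emits the summary tables as deterministic TSV files plus a short
#' human-readable summary; regenerating from the same run is
#' byte-identical.
#'
#' @param summary output of [summarize_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_report_table(summary$fl_by_tissue, file.path(dir, "fl_by_tissue.tsv"))
  write_report_table(summary$est_by_tissue, file.path(dir, "est_by_tissue.tsv"))
  write_report_table(summary$category_counts,
                     file.path(dir, "category_counts.tsv"))
  write_report_table(summary$nr_sizes, file.path(dir, "nr_sizes.tsv"))
  write_report_table(summary$signal_usage, file.path(dir, "signal_usage.tsv"))
  con <- file(file.path(dir, "summary.txt"), open = "wb")
  lines <- c(
    sprintf("reads in: %d", summary$conservation$reads_in),
    sprintf("reads in terminal buckets: %d", summary$conservation$reads_out),
    sprintf("conservation: %s",
            if (summary$conservation$ok) "OK" else "VIOLATED"),
    sprintf("%s: %d", summary$category_counts$category,
            summary$category_counts$n))
  writeLines(lines, con)
  close(con)
  invisible(dir)
}
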