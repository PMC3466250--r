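#!/usr/bin/env Rscript
# Per-read QC over the raw library: quality trim (PHRED < 20), residual
# adapter screening, cap-tag detection on 5' reads, sense orientation and
# poly(A) detection on 3' reads, then the length / low-complexity /
# mitochondrial filters.  Writes the per-read annotation table and the
# cleaned inserts.

suppressPackageStartupMessages(library(oligocap))

reads <- read_seq_records("results/data/reads.fastq", "fastq")
pp <- preprocess_reads(reads)

dir.create("results", showWarnings = FALSE)
write_report_table(pp$annotations[, c("read_id", "clone", "end", "tissue",
                                      "disposition", "cap_found",
                                      "tail_start", "trim_start", "trim_end")],
                   "results/read_annotations.tsv")
write_seq_records(pp$inserts, "results/inserts.fasta", "fasta")

cat("dispositions:\n")
print(table(pp$annotations$disposition))
ann5 <- pp$annotations[pp$annotations$end == "5p" &
                         pp$annotations$disposition == "kept", ]
cat(sprintf("cap tag found on %d / %d kept 5' reads (%.1f%%)\n",
            sum(ann5$cap_found), nrow(ann5),
            100 * mean(ann5$cap_found)))
ann3 <- pp$annotations[pp$annotations$end == "3p" &
                         pp$annotations$disposition == "kept", ]
cat(sprintf("poly(A) tail located on %d / %d kept 3' reads (%.1f%%)\n",
            sum(!is.na(ann3$tail_start)), nrow(ann3),
            100 * mean(!is.na(ann3$tail_start))))
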