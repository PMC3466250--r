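#!/usr/bin/env Rscript
# Build the synthetic oligo-capped library at the study conditions
# (200 genes, 20% 5'-truncated molecules, 0.5% read error, seed 42) and
# write the raw inputs every later step consumes: paired Sanger reads,
# the true transcriptome, and truth-derived translated-alignment evidence.

suppressPackageStartupMessages(library(oligocap))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_genes = 200, truncation_prob = 0.2, error_rate = 0.005,
                  seed = 42)
tx <- make_transcriptome(cfg)
sim <- simulate_library(tx, cfg)

write_seq_records(sim$reads, file.path(out, "reads.fastq"), "fastq")
# FASTQ carries no tissue labels; the sample sheet maps clones to tissues
write_report_table(sim$truth[, c("clone_id", "tissue")],
                   file.path(out, "sample_sheet.tsv"))
write_seq_records(tx$mrnas, file.path(out, "mrnas.fasta"), "fasta")
aa <- Biostrings::AAStringSet(tx$proteins)
Biostrings::writeXStringSet(aa, file.path(out, "true_proteins.fasta"))
write_report_table(sim$truth, file.path(out, "truth.tsv"))

read_ev <- simulate_evidence(read_query_spans(sim$truth), tx$proteins,
                             noise = 0, seed = 49)
tx_ev <- simulate_evidence(transcript_query_spans(sim$truth,
                                                  sim$truth$clone_id),
                           tx$proteins, noise = 0, seed = 53)
write_evidence_table(read_ev, file.path(out, "read_evidence.tsv"))
write_evidence_table(tx_ev, file.path(out, "transcript_evidence.tsv"))

cat(sprintf("genes: %d (%d coding, %d noncoding)\n", nrow(tx$genes),
            sum(tx$genes$coding), sum(!tx$genes$coding)))
cat(sprintf("clones surviving size selection: %d\n", nrow(sim$truth)))
cat(sprintf("of which 5'-truncated (uncapped): %d\n",
            sum(!sim$truth$full_length)))
cat(sprintf("reads written: %d\n", nrow(sim$reads)))
cat(sprintf("read-level evidence rows: %d, transcript-level: %d\n",
            nrow(read_ev), nrow(tx_ev)))
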