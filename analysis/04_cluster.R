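#!/usr/bin/env Rscript
# Non-redundant sets: cd-hit-style greedy clustering of the predicted
# proteins (98% identity, 90% coverage) and of the unassembled read sets
# (99% / 95%), plus two-set clustering of noncoding against coding
# transcripts (98% / 95%) to drop noncoding sequences that are really UTR
# fragments.

suppressPackageStartupMessages(library(oligocap))

res <- readRDS("scratch/pipeline_result.rds")

write_report_table(res$nr_protein_clusters, "results/nr_protein_clusters.tsv")
write_report_table(res$est_clusters_5p, "results/unique_5p_clusters.tsv")
write_report_table(res$est_clusters_3p, "results/unique_3p_clusters.tsv")
write_report_table(res$nr_noncoding$clusters,
                   "results/nr_noncoding_clusters.tsv")

cat(sprintf("proteins: %d -> %d non-redundant\n",
            nrow(res$orfs), length(cluster_reps(res$nr_protein_clusters))))
cat(sprintf("noncoding transcripts: %d, removed as coding-UTR fragments: %d, nr: %d\n",
            length(res$nr_noncoding$retained) + length(res$nr_noncoding$removed),
            length(res$nr_noncoding$removed),
            length(cluster_reps(res$nr_noncoding$clusters))))
cat(sprintf("unassembled unique sets: %d x 5', %d x 3'\n",
            length(cluster_reps(res$est_clusters_5p)),
            length(cluster_reps(res$est_clusters_3p))))
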