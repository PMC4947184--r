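#!/usr/bin/env Rscript
# Somatic structural-variant calling from the simulated tumour/normal
# read evidence: discordant-pair + soft-clip clustering, support filters,
# germline subtraction, and benchmarking against the planted truth.

suppressPackageStartupMessages(library(genomescars))
dir.create("results/sv", recursive = TRUE, showWarnings = FALSE)

tumour <- read.delim("results/sim/sv_evidence_tumour.tsv")
normal <- read.delim("results/sim/sv_evidence_normal.tsv")
truth_bedpe <- read.delim("results/sim/sv_truth.bedpe", header = FALSE)
truth <- data.frame(chrom1 = truth_bedpe$V1, pos1 = truth_bedpe$V3,
                    chrom2 = truth_bedpe$V4, pos2 = truth_bedpe$V6,
                    type = truth_bedpe$V7)

calls <- call_somatic_svs(cluster_evidence(tumour),
                          cluster_evidence(normal))
write_bedpe(calls, "results/sv/somatic_calls.bedpe")
cand <- attr(calls, "candidates")
write.table(cand, "results/sv/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d candidates -> %d somatic calls (%d germline, %d filtered)\n",
            nrow(cand), nrow(calls), sum(!cand$somatic),
            sum(cand$filtered)))
for (j in seq_len(nrow(calls))) {
  cat(sprintf("  %s %s:%d - %s:%d  (%d pairs, %d clips)\n",
              calls$type[j], calls$chrom1[j], calls$pos1[j],
              calls$chrom2[j], calls$pos2[j], calls$n_pairs[j],
              calls$n_clips[j]))
}

matched <- vapply(seq_len(nrow(calls)), function(j) {
  any(truth$type == calls$type[j] & truth$chrom1 == calls$chrom1[j] &
        abs(truth$pos1 - calls$pos1[j]) <= 300 &
        abs(truth$pos2 - calls$pos2[j]) <= 300)
}, TRUE)
cat(sprintf("precision %.0f%% against the planted truth\n",
            100 * mean(matched)))
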