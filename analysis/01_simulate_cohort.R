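#!/usr/bin/env Rscript
# Build the synthetic study inputs: a small cohort of tumour genomes at
# different contamination/ploidy settings, paired-end SV evidence, and an
# expression cohort with four planted groups. Everything downstream reads
# from results/sim/.

suppressPackageStartupMessages(library(genomescars))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

cohort <- data.frame(
  sample = c("T01", "T02", "T03", "T04"),
  alpha = c(0.0, 0.2, 0.3, 0.4),
  ploidy = c(2, 2, 3.4, 2),
  seed = c(101L, 102L, 103L, 104L))
write.table(cohort, "results/sim/cohort.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (i in seq_len(nrow(cohort))) {
  cfg <- sim_config(alpha = cohort$alpha[i], ploidy = cohort$ploidy[i],
                    seed = cohort$seed[i])
  sim <- simulate_cn_genome(cfg)
  write_binned_track(sim$track,
                     sprintf("results/sim/%s_track.tsv", cohort$sample[i]))
  write.table(sim$truth$segments,
              sprintf("results/sim/%s_truth.tsv", cohort$sample[i]),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d bins, alpha %.1f, ploidy %.1f\n", cohort$sample[i],
              nrow(sim$track), cohort$alpha[i], cohort$ploidy[i]))
}

# SV truth and read evidence for one tumour/normal pair
sv_truth <- data.frame(
  chrom1 = c("chr1", "chr1", "chr2", "chr1"),
  pos1 = c(1e6, 3e6, 2e6, 5e6),
  chrom2 = c("chr1", "chr1", "chr2", "chr2"),
  pos2 = c(1.05e6, 3.2e6, 2.4e6, 7e6),
  type = c("deletion", "duplication", "inversion", "inter_chromosomal"),
  germline = c(FALSE, FALSE, TRUE, FALSE))
genome <- data.frame(chrom = c("chr1", "chr2"), length = c(10e6, 10e6))
ev <- simulate_sv_read_evidence(sv_truth, depth = 8, seed = 301,
                                noise_rate = 1, genome = genome)
write_bedpe(sv_truth, "results/sim/sv_truth.bedpe")
write.table(ev$tumour, "results/sim/sv_evidence_tumour.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ev$normal, "results/sim/sv_evidence_normal.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("SV evidence: %d tumour / %d normal records for %d events\n",
            nrow(ev$tumour), nrow(ev$normal), nrow(sv_truth)))

# expression cohort (99 profiles, four groups)
expr <- simulate_expression_groups(seed = 401)
write_expression_tsv(round(expr$matrix, 4), "results/sim/expression.tsv")
write.table(data.frame(sample = colnames(expr$matrix),
                       label = expr$labels),
            "results/sim/expression_labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
gmt <- vapply(names(expr$gene_sets), function(nm) {
  paste(c(nm, "synthetic", expr$gene_sets[[nm]]), collapse = "\t")
}, "")
writeLines(gmt, "results/sim/signatures.gmt")
cat(sprintf("expression: %d genes x %d samples, groups %s\n",
            nrow(expr$matrix), ncol(expr$matrix),
            paste(table(expr$labels), collapse = "/")))
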