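#!/usr/bin/env Rscript
# Arm-level instability scores on the segmented cohort (firestorms and
# large-scale state transitions), and minimal-common-region refinement of
# the shared amplicon, including the worked GRCh37 coordinate arithmetic.

suppressPackageStartupMessages(library(genomescars))
dir.create("results/scars", recursive = TRUE, showWarnings = FALSE)

cohort <- read.delim("results/sim/cohort.tsv")
arm_bounds <- c(chrA = 12.5e6, chrB = 12.5e6)   # simulated centromeres
gaps <- data.frame(chrom = c("chrA", "chrB"),
                   start = c(12.4e6, 12.4e6), end = c(12.6e6, 12.6e6))

rows <- list()
gained <- list()
for (i in seq_len(nrow(cohort))) {
  id <- cohort$sample[i]
  seg <- read_segments_seg(sprintf("results/cnv/%s_segments.seg", id))
  seg$len <- seg$end - seg$start + 1
  arms <- split_by_arm(seg, arm_bounds)
  fs <- detect_firestorms(arms)
  lst <- lst_score(arms, gaps = gaps)
  rows[[i]] <- data.frame(sample = id,
                          n_firestorm = sum(fs$firestorm),
                          lst_total = lst$total)
  cat(sprintf("%s: %d firestorm arm(s), %d LST\n", id,
              sum(fs$firestorm), lst$total))
  g <- seg[seg$state %in% c("gain", "amplification") &
             seg$chrom == "chrA", c("start", "end")]
  if (nrow(g)) gained[[id]] <- g
}
write.table(do.call(rbind, rows), "results/scars/instability.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# shared amplified region across the simulated cohort
if (length(gained) == nrow(cohort)) {
  mcr <- minimal_common_region(gained)
  print(mcr)
} else {
  cat("no common gained region: only", length(gained),
      "samples carry a gain on chrA\n")
}

# worked example on printed GRCh37 coordinates: staggered per-sample
# amplified intervals whose common core is the ERBB2 amplicon
samples <- list(
  s1 = data.frame(start = c(37500000, 37818020),
                  end = c(37700000, 38100000)),
  s2 = data.frame(start = 37600000, end = 37924454),
  s3 = data.frame(start = c(37818020, 38200000),
                  end = c(37999999, 38300000)))
amplicon <- minimal_common_region(samples)
prior <- minimal_common_region(
  list(acgh = data.frame(start = 37725640, end = 37973561)))
cat(sprintf("refined amplicon: chr17:%d-%d (%.0f kbp; prior aCGH region %.0f kbp)\n",
            amplicon$start, amplicon$end, amplicon$length / 1000,
            prior$length / 1000))
jsonlite::write_json(
  list(amplicon = unclass(amplicon), prior_acgh = unclass(prior)),
  "results/scars/amplicon.json", auto_unbox = TRUE, digits = NA)
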