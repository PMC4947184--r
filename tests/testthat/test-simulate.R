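test_that("binned counts realize the tumour/normal mixture model", {
  # closed form: a c = 4 segment at alpha = 0.3, Q = 2 sits at relative
  # level (0.6 + 0.7 * 4) / (0.6 + 0.7 * 2) = 1.7
  cfg <- sim_config(chrom_lengths = c(chr1 = 20e6), alpha = 0.3,
                    ploidy = 2, depth = 100, gc_bias = gc_bias_flat(),
                    unmappable_fraction = 0, seed = 11)
  truth <- data.frame(chrom = "chr1",
                      start = c(1, 5e6 + 1, 15e6 + 1),
                      end = c(5e6, 15e6, 20e6),
                      cn = c(2, 4, 0))
  sim <- simulate_cn_genome(cfg, truth)
  tr <- sim$track
  lvl <- tapply(tr$count, tr$true_cn, mean)
  ratio <- lvl[["4"]] / lvl[["2"]]
  se <- ratio * sqrt(1 / (100 * 1.7 * 10000) + 1 / (100 * 5000))
  expect_lt(abs(ratio - 1.7), 3 * se)
  # homozygous deletion carries only normal-contamination signal
  expect_lt(lvl[["0"]], lvl[["2"]] / 2)
})

test_that("a homogeneous diploid genome has a flat expected profile", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 10e6), alpha = 0, ploidy = 2,
                    depth = 200, gc_bias = gc_bias_flat(),
                    unmappable_fraction = 0, seed = 5)
  truth <- data.frame(chrom = "chr1", start = c(1, 5e6 + 1),
                      end = c(5e6, 10e6), cn = c(2, 2))
  sim <- simulate_cn_genome(cfg, truth)
  halves <- tapply(sim$track$count, sim$track$start > 5e6, mean)
  se <- sqrt(200 / 5000) * sqrt(2)
  expect_lt(abs(diff(halves)), 3 * se)
})

test_that("empirical segment levels converge to the mixture prediction", {
  for (alpha in c(0, 0.4)) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 30e6), alpha = alpha,
                      ploidy = 2, depth = 100,
                      unmappable_fraction = 0, seed = 21)
    sim <- simulate_cn_genome(cfg)
    tr <- sim$track
    # remove GC bias using the generator's own curve, then compare
    expected_mu <- 100 * cfg$gc_bias(tr$gc) *
      genomescars:::mixture_level(tr$true_cn, alpha, 2)
    rel <- tr$count / expected_mu
    for (cn in unique(tr$true_cn)) {
      n <- sum(tr$true_cn == cn)
      m <- mean(rel[tr$true_cn == cn])
      se <- sd(rel[tr$true_cn == cn]) / sqrt(n)
      if (cn == 0 && alpha == 0) next  # zero-mean Poisson: rel undefined
      expect_lt(abs(m - 1), 3.5 * se + 1e-3)
    }
  }
})

test_that("overlapping or gapped truth segments are rejected by name", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 10e6), seed = 1)
  overlapping <- data.frame(chrom = "chr1", start = c(1, 4e6),
                            end = c(5e6, 10e6), cn = c(2, 3))
  expect_error(simulate_cn_genome(cfg, overlapping), "tile")
  gapped <- data.frame(chrom = "chr1", start = c(1, 6e6 + 2),
                       end = c(5e6, 10e6), cn = c(2, 3))
  expect_error(simulate_cn_genome(cfg, gapped), "tile")
})

test_that("all four generators are deterministic under a fixed seed", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e6), seed = 33)
  expect_identical(simulate_cn_genome(cfg), simulate_cn_genome(cfg))
  expect_identical(simulate_bfb_process(5, 4, seed = 9),
                   simulate_bfb_process(5, 4, seed = 9))
  tr <- sv_truth_fixture()
  expect_identical(
    simulate_sv_read_evidence(tr, depth = 5, seed = 2, noise_rate = 1,
                              genome = sv_genome_fixture()),
    simulate_sv_read_evidence(tr, depth = 5, seed = 2, noise_rate = 1,
                              genome = sv_genome_fixture()))
  expect_identical(
    simulate_expression_groups(n_genes = 2000, seed = 4),
    simulate_expression_groups(n_genes = 2000, seed = 4))
  # and sensitive to the seed
  expect_false(identical(simulate_bfb_process(5, 4, seed = 9)$counts,
                         simulate_bfb_process(5, 4, seed = 10)$counts) &&
               identical(simulate_bfb_process(5, 4, seed = 9)$history,
                         simulate_bfb_process(5, 4, seed = 10)$history))
})

test_that("BFB simulator honours its boundary conditions", {
  z <- simulate_bfb_process(4, 0, seed = 1)
  expect_identical(z$counts, rep(1L, 4))
  expect_identical(nrow(z$breakpoints), 0L)
  expect_length(z$history$cycles, 0)
  expect_error(simulate_bfb_process(0, 3), "positive")
})

test_that("emitted BFB breakpoints obey the fold/clip orientation rule", {
  # a left fold leaves reads aligned on their left part, clipped right;
  # a right fold conversely
  for (s in 1:40) {
    z <- simulate_bfb_process(sample(2:6, 1), sample(1:6, 1), seed = s)
    bp <- z$breakpoints
    if (!nrow(bp)) next
    expect_true(all((bp$fold == "left") == (bp$clip_side == "right")))
    expect_true(all((bp$fold == "right") == (bp$clip_side == "left")))
  }
})

test_that("SV evidence has type-specific orientations and germline sharing", {
  del <- data.frame(chrom1 = "chr1", pos1 = 2e6, chrom2 = "chr1",
                    pos2 = 2.1e6, type = "deletion", germline = FALSE)
  ev <- simulate_sv_read_evidence(del, depth = 10, seed = 3)
  pairs <- ev$tumour[ev$tumour$kind == "pair", ]
  clips <- ev$tumour[ev$tumour$kind == "clip", ]
  expect_identical(nrow(pairs), 10L)
  # FR orientation with a long insert spanning the deletion
  expect_true(all(pairs$strand == "+" & pairs$mate_strand == "-"))
  expect_true(all(pairs$insert > 350 + 4 * 50))
  # clip clusters at both ends with the configured clipped-base length
  expect_setequal(unique(clips$pos), c(2e6, 2.1e6))
  expect_true(all(clips$clip_bases >= 15))
  expect_identical(nrow(ev$normal), 0L)

  # germline_fraction = 1: every event's evidence appears in the normal
  tr <- sv_truth_fixture(); tr$germline <- NULL
  ev2 <- simulate_sv_read_evidence(tr, depth = 6, germline_fraction = 1,
                                   seed = 8)
  expect_true(all(ev2$truth$germline))
  expect_setequal(unique(ev2$normal$sv_id), seq_len(nrow(tr)))

  # zero supporting reads -> empty evidence
  ev3 <- simulate_sv_read_evidence(del, depth = 0, seed = 1)
  expect_identical(nrow(ev3$tumour), 0L)
  expect_error(simulate_sv_read_evidence(del, depth = -1), "non-negative")
})

test_that("expression generator plants four groups and opposing gradients", {
  sim <- simulate_expression_groups(n_per_group = c(10, 10, 10, 10),
                                    n_genes = 3000, n_informative = 80,
                                    effect_size = 4, seed = 6)
  expect_identical(dim(sim$matrix), c(3000L, 40L))
  expect_identical(nlevels(sim$labels), 4L)
  expect_length(intersect(sim$gene_sets$grad_up, sim$gene_sets$grad_down), 0)
  # the two sets run in opposite directions across A..D
  up_means <- tapply(colMeans(sim$matrix[sim$gene_sets$grad_up, ]),
                     sim$labels, mean)
  down_means <- tapply(colMeans(sim$matrix[sim$gene_sets$grad_down, ]),
                       sim$labels, mean)
  expect_true(all(diff(up_means) > 0))
  expect_true(all(diff(down_means) < 0))
  expect_error(simulate_expression_groups(n_genes = 100,
                                          n_informative = 200),
               "exceeds")
})

test_that("effect size controls whether clustering can recover groups", {
  null_sim <- simulate_expression_groups(n_per_group = c(12, 12, 12, 12),
                                         n_genes = 4000, effect_size = 0,
                                         seed = 13)
  f0 <- filter_probesets(null_sim$matrix)
  cl0 <- cluster_expression(f0, k = 4)
  expect_lt(abs(mclust::adjustedRandIndex(cl0, null_sim$labels)), 0.2)

  big <- simulate_expression_groups(n_per_group = c(12, 12, 12, 12),
                                    effect_size = 5, seed = 13)
  fb <- filter_probesets(big$matrix)
  clb <- cluster_expression(fb, k = 4)
  expect_gte(mclust::adjustedRandIndex(clb, big$labels), 0.9)
})
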