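test_that("GC model is flat when counts do not depend on GC", {
  set.seed(1)
  tr <- make_track(rpois(20000, 100), gc = runif(20000, 0.3, 0.6))
  gm <- build_gc_model(tr, seed = 1)
  pred <- predict_gc(gm, seq(0.3, 0.6, by = 0.01))
  expect_lt(max(pred) / min(pred), 1.05)
  expect_true(all(pred > 0))
})

test_that("GC model recovers a planted monotone bias", {
  set.seed(2)
  gc <- runif(30000, 0.3, 0.6)
  bias <- 0.5 + 1.5 * gc                  # strictly increasing
  tr <- make_track(rpois(30000, 100 * bias), gc = gc)
  gm <- build_gc_model(tr, seed = 1)
  pred <- predict_gc(gm, seq(0.32, 0.58, by = 0.02))
  expect_true(all(diff(pred) > 0))
})

test_that("extreme-count bins do not perturb the GC model", {
  set.seed(3)
  counts <- rpois(20000, 100)
  tr <- make_track(counts, gc = runif(20000, 0.3, 0.6))
  tr_out <- tr
  tr_out$count[7] <- 100 * median(counts)
  gm_clean <- build_gc_model(tr, seed = 1)
  gm_out <- build_gc_model(tr_out, seed = 1)
  grid <- seq(0.32, 0.58, by = 0.02)
  expect_lt(max(abs(predict_gc(gm_out, grid) / predict_gc(gm_clean, grid) - 1)),
            0.02)
  expect_error(build_gc_model(make_track(1:5, mappable = FALSE)),
               "mappable")
})

test_that("rRC is raw over predicted, on mappable bins only", {
  tr <- make_track(c(100, 150, 80), gc = 0.45)
  tr$mappable[3] <- FALSE
  gm <- structure(list(gc = c(0, 1), predicted = c(100, 100)),
                  class = "gc_model")
  rel <- compute_rrc(tr, gm)
  expect_equal(rel$rrc, c(1, 1.5, NA))
  gm0 <- structure(list(gc = c(0, 1), predicted = c(0, 0)),
                   class = "gc_model")
  expect_error(compute_rrc(tr, gm0), "chr1:1")
})

test_that("GC correction flattens a biased diploid genome within 2%", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 40e6), alpha = 0, ploidy = 2,
                    depth = 150, unmappable_fraction = 0, seed = 17)
  truth <- data.frame(chrom = "chr1", start = 1, end = 40e6, cn = 2)
  sim <- simulate_cn_genome(cfg, truth)
  gm <- build_gc_model(sim$track, seed = 1)
  rel <- compute_rrc(sim$track, gm)
  decile <- cut(rel$gc, quantile(rel$gc, 0:10 / 10), include.lowest = TRUE)
  per_decile <- tapply(rel$rrc, decile, mean)
  expect_lt(max(abs(per_decile / mean(rel$rrc) - 1)), 0.02)
})

test_that("Kalman smoothing preserves constants and chromosome bounds", {
  rel <- make_rel(rep(1.5, 50))
  out <- smooth_rrc(rel)
  expect_equal(out$smooth, rep(1.5, 50))
  # single-bin chromosome returned as-is
  rel1 <- make_rel(2.2)
  expect_equal(smooth_rrc(rel1)$smooth, 2.2)
  # two chromosomes at different constants stay exactly constant:
  # smoothing would blur the junction if it crossed the boundary
  rel2 <- rbind(make_rel(rep(1, 30), chrom = "chr1"),
                make_rel(rep(2, 30), chrom = "chr2"))
  out2 <- smooth_rrc(rel2)
  expect_equal(out2$smooth, rep(c(1, 2), each = 30))
})

test_that("Kalman smoothing reduces noise around a step signal", {
  set.seed(4)
  truth <- rep(c(1, 2), each = 200)
  rel <- make_rel(truth + rnorm(400, 0, 0.2))
  rel$smooth <- NULL
  out <- smooth_rrc(rel)
  expect_lt(var(out$smooth - truth), var(rel$rrc - truth) / 2)
})

test_that("comb fit recovers contamination and ploidy from levels", {
  # alpha = 0, Q = 2: spacing 1/Q = 0.5, baseline 0
  cfg <- sim_config(alpha = 0, ploidy = 2, seed = 42)
  sim <- simulate_cn_genome(cfg)
  rel <- smooth_rrc(compute_rrc(sim$track, build_gc_model(sim$track)))
  comb <- fit_gaussian_comb(rel)
  expect_lt(abs(comb$spacing - 0.5), 0.02)
  expect_lt(abs(comb$baseline - 0), 0.02)
  # alpha = 0.3, Q = 2: levels 0.30 + 0.35 c (closed-form mixture)
  cfg2 <- sim_config(alpha = 0.3, ploidy = 2, seed = 42)
  sim2 <- simulate_cn_genome(cfg2)
  rel2 <- smooth_rrc(compute_rrc(sim2$track, build_gc_model(sim2$track)))
  comb2 <- fit_gaussian_comb(rel2)
  expect_lt(abs(comb2$spacing - 0.35), 0.02)
  expect_lt(abs(comb2$baseline - 0.30), 0.02)
  expect_lt(abs(comb2$alpha - 0.3), 0.05)
  expect_lt(abs(comb2$ploidy - 2), 0.2)
  # comb levels are exactly evenly spaced
  lv <- comb_level(comb2, 0:20)
  expect_true(all(abs(diff(lv) - comb2$spacing) < 1e-9))
})

test_that("degenerate rRC distributions fail the comb fit explicitly", {
  expect_error(fit_gaussian_comb(make_rel(rep(1, 100))), "bins")
  set.seed(5)
  flat <- make_rel(rnorm(5000, 1, 0.005))
  expect_error(fit_gaussian_comb(flat), "identifiable")
})

test_that("rRC to aCN inversion applies the linear map with the tie rule", {
  comb <- make_comb(0, 2)       # levels 0.5 c
  expect_identical(rrc_to_acn(1.5, comb), 3L)
  expect_identical(rrc_to_acn(c(0, 0.49, 1.01), comb), c(0L, 1L, 2L))
  comb2 <- make_comb(0.3, 2)    # levels 0.30 + 0.35 c
  expect_identical(rrc_to_acn(0.30, comb2), 0L)
  # midway between two levels rounds away from the baseline
  expect_identical(rrc_to_acn(0.30 + 1.5 * 0.35, comb2), 2L)
  # below the baseline floors at 0
  expect_identical(rrc_to_acn(0.05, comb2), 0L)
  # round trip: on-grid values come back within half a spacing
  acn <- rrc_to_acn(comb_level(comb2, 0:12), comb2)
  expect_identical(acn, 0:12)
  expect_error(rrc_to_acn(1, make_comb(0, -1)), "spacing")
})

test_that("segment states follow the printed rCN scale", {
  seg <- data.frame(rcn = c(3.5, 3, 1.2, 1, 0.5, 0))
  out <- classify_segment_states(seg)
  expect_identical(as.character(out$state),
                   c("amplification", "gain", "gain", "neutral", "loss",
                     "homozygous_deletion"))
  expect_error(classify_segment_states(data.frame(rcn = -0.1)),
               "negative")
})

test_that("fraction of genome altered matches direct length accounting", {
  neutral <- data.frame(rcn = c(1, 1), len = c(5e6, 5e6))
  expect_equal(fraction_genome_altered(neutral), 0)
  half <- data.frame(rcn = c(1, 2), len = c(5e6, 5e6))
  expect_equal(fraction_genome_altered(half), 0.5)
  set.seed(6)
  for (i in 1:10) {
    seg <- data.frame(rcn = sample(c(0, 0.5, 1, 1.5, 2), 20, TRUE),
                      len = sample(1:100, 20) * 1e5)
    oracle <- sum(seg$len[seg$rcn != 1]) / sum(seg$len)
    expect_equal(fraction_genome_altered(seg), oracle)
  }
  expect_error(fraction_genome_altered(data.frame()), "empty")
})

test_that("HMM segmentation is exact on noiseless comb-level input", {
  comb <- make_comb(0, 2, sd = 0.02)
  truth_states <- rep(c(2, 4, 1, 2, 0), times = c(100, 50, 80, 60, 30))
  rel <- make_rel(comb_level(comb, truth_states))
  seg <- segment_copy_number(rel, comb)
  expect_identical(seg$acn, c(2L, 4L, 1L, 2L, 0L))
  expect_identical(seg$n_bins, c(100L, 50L, 80L, 60L, 30L))
  # constant input gives a single segment per chromosome
  rel2 <- rbind(make_rel(rep(1, 40), chrom = "chr1"),
                make_rel(rep(1, 40), chrom = "chr2"))
  seg2 <- segment_copy_number(rel2, comb)
  expect_identical(nrow(seg2), 2L)
  expect_error(segment_copy_number(rel, comb, c_max = 1), "c_max")
})

test_that("segmentation assigns every mappable bin exactly once", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 12e6, chr2 = 12e6),
                    alpha = 0.2, ploidy = 2, seed = 19)
  sim <- simulate_cn_genome(cfg)
  rel <- smooth_rrc(compute_rrc(sim$track, build_gc_model(sim$track)))
  comb <- fit_gaussian_comb(rel)
  seg <- segment_copy_number(rel, comb)
  for (ch in unique(seg$chrom)) {
    n_mappable <- sum(sim$track$mappable & sim$track$chrom == ch)
    expect_identical(sum(seg$n_bins[seg$chrom == ch]), n_mappable)
    expect_equal(sum(seg$len[seg$chrom == ch]),
                 n_mappable * cfg$bin_width)
  }
  # decoded states recover the truth for nearly all bins
  acc <- bin_state_accuracy(seg, sim$track)
  expect_gte(acc, 0.95)
})
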