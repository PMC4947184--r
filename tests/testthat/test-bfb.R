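test_that("aCN segments collapse with merging, shift and round trip", {
  seg <- data.frame(chrom = "chr17", start = c(1, 101, 201),
                    end = c(100, 200, 300), acn = c(3, 3, 5))
  cv <- collapse_acn_segments(seg)
  expect_identical(cv$counts, c(3L, 5L))
  expect_equal(cv$boundaries, 200)
  # the constant-shift case: two homologous copies subtracted
  seg2 <- data.frame(chrom = "chr17", start = c(1, 101, 201),
                     end = c(100, 200, 300), acn = c(4, 6, 4))
  cv2 <- collapse_acn_segments(seg2, baseline_shift = 2)
  expect_identical(cv2$counts, c(2L, 4L, 2L))
  expect_error(collapse_acn_segments(seg2, baseline_shift = 5),
               "negative")
  # collapse then expand by segment spans reproduces the input
  expand <- unlist(lapply(seq_along(cv$counts), function(i) {
    rep(cv$counts[i], sum(seg$start >= cv$starts[i] &
                            seg$end <= cv$ends[i]))
  }))
  expect_identical(expand, c(3L, 3L, 5L))
})

test_that("enumeration honours bounds, zero cycles and deduplication", {
  e0 <- enumerate_bfb_vectors(4, 0)
  expect_identical(e0, matrix(1L, 1, 4))
  e <- enumerate_bfb_vectors(3, 4, max_count = 6)
  expect_identical(anyDuplicated(apply(e, 1, paste, collapse = ",")), 0L)
  expect_error(enumerate_bfb_vectors(7, 2), "1..6")
  expect_error(enumerate_bfb_vectors(3, 9), "0..8")
})

test_that("capped enumeration equals literal replay of raw cycles", {
  # third, theory-free oracle: enumerate words by raw break-fusion
  # replay, uncapped, at tiny bounds
  for (n in 2:4) {
    for (cyc in 1:3) {
      raw <- raw_bfb_vectors(n, cyc)
      cap <- bfb_keys(enumerate_bfb_vectors(n, cyc, max_count = 60))
      expect_identical(cap, raw, info = sprintf("n=%d cycles=%d", n, cyc))
    }
  }
})

test_that("the decision handles canonical accept/reject examples", {
  expect_true(is_bfb_count_vector(1L))           # intact single segment
  expect_true(is_bfb_count_vector(c(1L, 1L, 1L)))
  # a positive count distal to a fully deleted segment is impossible
  expect_false(is_bfb_count_vector(c(2L, 0L, 3L)))
  expect_false(is_bfb_count_vector(c(2L, 0L, 3L),
                                   orientation = "unspecified"))
  # duplication must face the stable end: [2,1,1] only works reversed
  both <- is_bfb_count_vector(c(2L, 1L, 1L), orientation = "unspecified")
  expect_true(isTRUE(both))
  expect_identical(attr(both, "orientation"), "stable_right")
  expect_false(is_bfb_count_vector(c(2L, 1L, 1L)))
  expect_false(is_bfb_count_vector(c(0L, 0L)))
  expect_error(is_bfb_count_vector(integer()), "empty")
})

test_that("zero-propagation holds for random vectors with internal zeros", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(3:6, 1)
    v <- sample(1:5, n, TRUE)
    at <- sample(n - 1, 1)
    v[at] <- 0L                       # zero with a positive entry after it
    expect_false(is_bfb_count_vector(v))
  }
})

test_that("decision agrees with exhaustive enumeration on a bounded grid", {
  reach <- bfb_keys(enumerate_bfb_vectors(4, 6, max_count = 4))
  grid <- as.matrix(expand.grid(rep(list(0:4), 4)))
  dec <- apply(grid, 1, function(v) {
    isTRUE(is_bfb_count_vector(as.integer(v), max_cycles = 6))
  })
  in_set <- apply(grid, 1, paste, collapse = ",") %in% reach
  expect_identical(dec, in_set)
})

test_that("witnesses replay exactly to their count vectors", {
  set.seed(15)
  for (i in 1:200) {
    sim <- simulate_bfb_process(sample(2:6, 1), sample(0:6, 1), seed = i)
    res <- is_bfb_count_vector(sim$counts)
    expect_true(isTRUE(res), info = paste(sim$counts, collapse = ","))
    wit <- attr(res, "witness")
    expect_identical(genomescars:::replay_fold_pattern(wit),
                     sim$counts)
  }
})

test_that("longest compatible stretch matches the subvector oracle", {
  v <- c(1L, 1L, 2L)   # a fold-back duplication of the distal segment
  full <- longest_bfb_compatible(v)
  expect_identical(c(full$start, full$end), c(1L, 3L))
  # an invalid tail is excluded
  part <- longest_bfb_compatible(c(5L, 2L, 0L, 3L))
  oracle <- function(v) {
    n <- length(v)
    for (len in rev(seq_len(n))) {
      for (s in seq_len(n - len + 1)) {
        if (isTRUE(is_bfb_count_vector(v[s:(s + len - 1)]))) {
          return(c(s, s + len - 1))
        }
      }
    }
    c(NA, NA)
  }
  expect_identical(c(part$start, part$end),
                   as.integer(oracle(c(5L, 2L, 0L, 3L))))
  set.seed(16)
  for (i in 1:20) {
    v <- as.integer(sample(0:5, sample(2:5, 1), TRUE))
    got <- longest_bfb_compatible(v)
    expect_identical(c(got$start, got$end), as.integer(oracle(v)),
                     info = paste(v, collapse = ","))
  }
  one <- longest_bfb_compatible(2L)
  expect_identical(c(one$start, one$end), c(1L, 1L))
})

test_that("fold patterns derive from histories and carry clip sides", {
  z0 <- simulate_bfb_process(4, 0, seed = 2)
  expect_identical(nrow(derive_fold_pattern(z0$history)$folds), 0L)
  # a single cycle folds at the logged boundary
  z1 <- simulate_bfb_process(5, 1, seed = 3)
  pat1 <- derive_fold_pattern(z1$history)
  expect_identical(nrow(pat1$folds), 1L)
  expect_identical(pat1$folds$boundary, z1$history$cycles[[1]]$fold$boundary)
  # left folds imply right clips throughout
  set.seed(17)
  for (i in 1:50) {
    z <- simulate_bfb_process(sample(2:6, 1), sample(1:6, 1), seed = i)
    pat <- derive_fold_pattern(z$history)
    expect_true(all((pat$folds$fold == "left") ==
                      (pat$folds$clip_side == "right")))
  }
})

test_that("clip orientations verify against the folding pattern", {
  pat <- structure(list(
    folds = data.frame(order = 1L, boundary = 3L, fold = "left",
                       clip_side = "right"),
    n = 5, chain = NULL, observed_length = NULL), class = "fold_pattern")
  good <- data.frame(boundary = 3, clip_side = "right", support = 10)
  r <- check_clip_orientation_consistency(pat, good, tolerance_bp = 0)
  expect_identical(nrow(r$matched_consistent), 1L)
  expect_identical(nrow(r$matched_inconsistent), 0L)
  bad <- data.frame(boundary = 3, clip_side = "left", support = 10)
  r2 <- check_clip_orientation_consistency(pat, bad, tolerance_bp = 0)
  expect_identical(nrow(r2$matched_inconsistent), 1L)
  far <- data.frame(boundary = 10, clip_side = "right", support = 2)
  r3 <- check_clip_orientation_consistency(pat, far, tolerance_bp = 1)
  expect_identical(nrow(r3$unmatched), 1L)
  expect_identical(nrow(r3$missed), 1L)
})

test_that("simulated histories are fully clip-consistent end to end", {
  for (s in 1:60) {
    z <- simulate_bfb_process(sample(2:6, 1), sample(1:6, 1), seed = s + 100)
    pat <- derive_fold_pattern(z$history)
    if (!nrow(z$breakpoints)) next
    r <- check_clip_orientation_consistency(pat, z$breakpoints,
                                            tolerance_bp = 0)
    expect_identical(nrow(r$matched_inconsistent), 0L)
    expect_identical(nrow(r$unmatched), 0L)
    expect_equal(r$consistent_fraction, 1)
  }
})
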