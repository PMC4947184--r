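# Shared fixture builders; everything is generated in code.

# a minimal binned track built by hand
make_track <- function(counts, gc = 0.45, chrom = "chr1", bin = 1000,
                       mappable = TRUE) {
  n <- length(counts)
  data.frame(chrom = chrom,
             start = (seq_len(n) - 1) * bin + 1,
             end = seq_len(n) * bin,
             count = counts,
             gc = rep_len(gc, n),
             mappable = rep_len(mappable, n))
}

# a relative track with a prescribed (already smoothed) signal
make_rel <- function(smooth, chrom = "chr1", bin = 1000) {
  n <- length(smooth)
  data.frame(chrom = rep_len(chrom, n),
             start = (seq_len(n) - 1) * bin + 1,
             end = seq_len(n) * bin,
             rrc = smooth, smooth = smooth, mappable = TRUE)
}

# a comb fit with known parameters (bypassing the fit)
make_comb <- function(alpha, ploidy, sd = 0.02) {
  denom <- 2 * alpha + (1 - alpha) * ploidy
  structure(list(alpha = alpha, ploidy = ploidy,
                 spacing = (1 - alpha) / denom,
                 baseline = 2 * alpha / denom,
                 sd = sd, weights = NULL, gof = NA, n_bins = NA),
            class = "comb_fit")
}

# an arm segmentation from explicit integer copy states (ploidy 2 scale)
make_arm <- function(acn, len = 5e6, arm = "chr1p", start = NULL) {
  n <- length(acn)
  if (n == 0) {
    return(data.frame(arm = character(), chrom = character(),
                      start = numeric(), end = numeric(), len = numeric(),
                      acn = numeric(), rcn = numeric()))
  }
  len <- rep_len(len, n)
  end <- cumsum(len)
  data.frame(arm = arm, chrom = sub("[pq]$", "", arm),
             start = c(1, head(end, -1) + 1), end = end,
             len = len, acn = acn, rcn = acn / 2)
}

# uncapped literal brute-force enumeration of observable BFB count
# vectors (tiny bounds only): replays raw break-fusion cycles on words
raw_bfb_vectors <- function(n, max_cycles) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  note <- function(w) {
    cnt <- integer(n)
    for (x in w) {
      cnt[abs(x)] <- cnt[abs(x)] + 1L
      seen[[paste(cnt, collapse = ",")]] <- TRUE
    }
  }
  recurse <- function(w, d) {
    note(w)
    if (d >= max_cycles) return(invisible())
    ks <- if (d == 0L) seq_along(w) else seq_len(length(w) - 1L)
    for (k in ks) {
      p <- w[seq_len(k)]
      recurse(c(p, -rev(p)), d + 1L)
    }
    invisible()
  }
  recurse(seq_len(n), 0L)
  sort(ls(seen))
}

bfb_keys <- function(mat) {
  sort(apply(mat, 1, paste, collapse = ","))
}

# default SV truth table used across tests
sv_truth_fixture <- function() {
  data.frame(
    chrom1 = c("chr1", "chr1", "chr2", "chr1"),
    pos1 = c(1e6, 3e6, 2e6, 5e6),
    chrom2 = c("chr1", "chr1", "chr2", "chr2"),
    pos2 = c(1.05e6, 3.2e6, 2.4e6, 7e6),
    type = c("deletion", "duplication", "inversion", "inter_chromosomal"),
    germline = c(FALSE, FALSE, TRUE, FALSE))
}

sv_genome_fixture <- function() {
  data.frame(chrom = c("chr1", "chr2"), length = c(10e6, 10e6))
}

# match calls against truth within a breakpoint tolerance
sv_recall_precision <- function(calls, truth, tol = 300) {
  som <- truth[!truth$germline, , drop = FALSE]
  hit_truth <- vapply(seq_len(nrow(som)), function(i) {
    nrow(calls) > 0 && any(
      calls$type == som$type[i] & calls$chrom1 == som$chrom1[i] &
        abs(calls$pos1 - som$pos1[i]) <= tol &
        abs(calls$pos2 - som$pos2[i]) <= tol)
  }, TRUE)
  hit_call <- vapply(seq_len(nrow(calls)), function(j) {
    any(som$type == calls$type[j] & som$chrom1 == calls$chrom1[j] &
          abs(som$pos1 - calls$pos1[j]) <= tol &
          abs(som$pos2 - calls$pos2[j]) <= tol)
  }, TRUE)
  c(recall = mean(hit_truth),
    precision = if (nrow(calls)) mean(hit_call) else NA_real_)
}
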