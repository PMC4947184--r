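#' Segment relative read counts with a Gaussian hidden Markov model
#'
#' Decodes, per chromosome, the most likely integer copy-state path of the
#' smoothed rRC signal under a univariate Gaussian HMM whose state means
#' are fixed at the comb levels `level(c)` for `c = 0..c_max`, with a
#' shared emission variance estimated from the data and a uniform
#' self-transition probability `1 - epsilon`. Adjacent bins decoded to the
#' same state are merged into segments. The final state absorbs
#' amplifications beyond `c_max`.
#'
#' @param rel a [smooth_rrc()] result.
#' @param comb a [fit_gaussian_comb()] result.
#' @param c_max highest explicit copy state (>= 2; default 20).
#' @param epsilon per-bin probability of leaving the current state.
#' @param sample sample identifier stored in the output.
#' @return data.frame of segments: `sample`, `chrom`, `start`, `end`,
#'   `n_bins`, `len` (mappable extent, `n_bins * bin width`), `acn`
#'   (decoded state), `rcn` (`acn / Q`), `rrc_mean`, and `state` from
#'   [classify_segment_states()] with a neutral tolerance of half a copy.
#' @export
segment_copy_number <- function(rel, comb, c_max = 20, epsilon = 1e-5,
                                sample = "sample") {
  if (c_max < 2) stop("`c_max` must be >= 2", call. = FALSE)
  stopifnot(inherits(comb, "comb_fit"))
  x_col <- if ("smooth" %in% names(rel)) "smooth" else "rrc"
  means <- comb_level(comb, 0:c_max)
  sdev <- max(comb$sd, 1e-4)
  out <- list()
  for (ch in unique(rel$chrom)) {
    idx <- which(rel$chrom == ch & !is.na(rel[[x_col]]))
    if (!length(idx)) next
    x <- rel[[x_col]][idx]
    path <- viterbi_gaussian(x, means, sdev, epsilon)
    run <- rle(path)
    stop_i <- cumsum(run$lengths)
    start_i <- stop_i - run$lengths + 1L
    bw <- stats::median(rel$end[idx] - rel$start[idx] + 1)
    seg <- data.frame(
      sample = sample,
      chrom = ch,
      start = rel$start[idx][start_i],
      end = rel$end[idx][stop_i],
      n_bins = run$lengths,
      len = run$lengths * bw,
      acn = run$values - 1L,   # states are 1-based indices of 0..c_max
      rrc_mean = vapply(seq_along(run$values), function(j) {
        mean(x[start_i[j]:stop_i[j]])
      }, 0.0))
    out[[length(out) + 1L]] <- seg
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  seg$rcn <- seg$acn / comb$ploidy
  classify_segment_states(seg, neutral_tol = 0.5 / comb$ploidy)
}

# Viterbi decoding for a univariate Gaussian HMM with uniform
# off-diagonal transitions; returns 1-based state indices
viterbi_gaussian <- function(x, means, sdev, epsilon) {
  k <- length(means)
  n <- length(x)
  log_self <- log(1 - epsilon)
  log_switch <- log(epsilon / (k - 1))
  emis <- outer(x, means, function(xx, mm) dnorm(xx, mm, sdev, log = TRUE))
  delta <- emis[1, ] - log(k)
  psi <- matrix(0L, n, k)
  for (t in 2:n) {
    # transition: max over previous states (self vs best switch)
    best_prev <- which.max(delta)
    stay <- delta + log_self
    move <- delta[best_prev] + log_switch
    from <- ifelse(stay >= move, seq_len(k), best_prev)
    delta_new <- pmax(stay, move) + emis[t, ]
    psi[t, ] <- from
    delta <- delta_new
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Classify copy-number segment states on the rCN scale
#'
#' Applies the relative copy-number scale: `rCN > 3` amplification,
#' `3 >= rCN > 1` gain, `rCN = 1` neutral, `rCN < 1` loss, `rCN = 0`
#' homozygous deletion. `neutral_tol` widens the neutral band (and the
#' gain boundary) to `|rCN - 1| <= neutral_tol`, which decoded integer
#' states need when the mean ploidy is not integral.
#'
#' @param segments data.frame with an `rcn` column.
#' @param neutral_tol half-width of the neutral band around rCN = 1.
#' @return `segments` with a `state` factor column.
#' @export
classify_segment_states <- function(segments, neutral_tol = 0) {
  if (any(segments$rcn < 0)) {
    stop("negative rCN values", call. = FALSE)
  }
  rcn <- segments$rcn
  state <- ifelse(rcn <= 1e-9, "homozygous_deletion",
           ifelse(rcn > 3, "amplification",
           ifelse(rcn > 1 + neutral_tol, "gain",
           ifelse(abs(rcn - 1) <= neutral_tol, "neutral", "loss"))))
  segments$state <- factor(state,
    levels = c("homozygous_deletion", "loss", "neutral", "gain",
               "amplification"))
  segments
}

#' Fraction of the genome altered
#'
#' The summed length of segments whose relative copy number differs from
#' the reference state (rCN = 1, up to `neutral_tol`) divided by the
#' summed length of all segments.
#'
#' @param segments segment data.frame with `rcn` and a length column
#'   (`len`, else `end - start + 1`).
#' @param neutral_tol tolerance around rCN = 1 counted as unaltered.
#' @return fraction in \[0, 1\].
#' @export
fraction_genome_altered <- function(segments, neutral_tol = 0) {
  if (is.null(segments) || nrow(segments) == 0) {
    stop("empty segmentation", call. = FALSE)
  }
  len <- segments$len %||% (segments$end - segments$start + 1)
  altered <- abs(segments$rcn - 1) > neutral_tol
  sum(len[altered]) / sum(len)
}

#' Bin-level state accuracy of a segmentation against simulation truth
#'
#' Maps decoded segments back onto the bins of a simulated track and
#' returns the fraction of mappable bins whose decoded copy state equals
#' the generating copy number.
#'
#' @param segments a [segment_copy_number()] result.
#' @param track a simulated track carrying a `true_cn` column.
#' @return fraction of correctly decoded mappable bins.
#' @export
bin_state_accuracy <- function(segments, track) {
  stopifnot("true_cn" %in% names(track))
  dec <- rep(NA_integer_, nrow(track))
  for (i in seq_len(nrow(segments))) {
    sel <- track$chrom == segments$chrom[i] &
      track$start >= segments$start[i] & track$end <= segments$end[i]
    dec[sel] <- segments$acn[i]
  }
  m <- track$mappable & !is.na(dec)
  mean(dec[m] == track$true_cn[m])
}
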