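#' Simulation configuration for a binned tumour genome
#'
#' Describes the genome layout and the tumour/normal mixture from which
#' binned read counts are generated. The expected count of a bin with local
#' tumour copy number \eqn{c} is proportional to
#' \eqn{gc\_bias(GC) \times (2\alpha + (1-\alpha)c)}, i.e. a mixture of
#' diploid normal DNA at contamination \eqn{\alpha} and tumour DNA, scaled
#' so that a bin at the tumour mean ploidy \eqn{Q} has expected count
#' `depth`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param arm_boundaries optional named numeric vector: position of the
#'   p/q boundary (centromere) per chromosome. Defaults to the midpoint.
#' @param bin_width bin width in bp (> 0, default 1000).
#' @param alpha normal contamination, in \[0, 1\].
#' @param ploidy tumour mean ploidy Q (> 0). For a self-consistent profile
#'   the length-weighted mean of the true copy numbers should equal Q;
#'   [default_truth_segments()] guarantees this.
#' @param depth expected read count per bin at the tumour mean ploidy.
#' @param gc_bias function mapping GC fraction to a multiplicative bias;
#'   see [gc_bias_quadratic()] (default) and [gc_bias_flat()].
#' @param overdispersion negative-binomial overdispersion; 0 (default)
#'   gives Poisson counts, otherwise counts are NB with variance
#'   \eqn{\mu + overdispersion \cdot \mu^2}.
#' @param unmappable_fraction approximate fraction of bins masked as
#'   unmappable (placed in short runs, as real mappability gaps are).
#' @param seed integer seed; the same seed and configuration give
#'   bit-identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chrA = 25e6, chrB = 25e6),
                       arm_boundaries = NULL,
                       bin_width = 1000,
                       alpha = 0,
                       ploidy = 2,
                       depth = 100,
                       gc_bias = gc_bias_quadratic(),
                       overdispersion = 0,
                       unmappable_fraction = 0.03,
                       seed = 1L) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) >= 1)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("contamination `alpha` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(ploidy) || ploidy <= 0) {
    stop("tumour mean ploidy `ploidy` must be > 0", call. = FALSE)
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be > 0", call. = FALSE)
  }
  if (is.null(arm_boundaries)) {
    arm_boundaries <- round(chrom_lengths / 2)
  }
  structure(
    list(chrom_lengths = chrom_lengths,
         arm_boundaries = arm_boundaries,
         bin_width = bin_width,
         alpha = alpha,
         ploidy = ploidy,
         depth = depth,
         gc_bias = gc_bias,
         overdispersion = overdispersion,
         unmappable_fraction = unmappable_fraction,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Default GC-bias curves
#'
#' `gc_bias_quadratic()` is a unimodal quadratic in GC fraction peaking at
#' `gc_peak`, the qualitative shape empirical GC correction has to remove;
#' `gc_bias_flat()` is no bias.
#'
#' @param gc_peak GC fraction of maximal coverage.
#' @param strength curvature of the bias.
#' @return a function mapping GC fraction to a multiplicative bias.
#' @export
gc_bias_quadratic <- function(gc_peak = 0.45, strength = 3) {
  force(gc_peak); force(strength)
  function(gc) pmax(0.1, 1 - strength * (gc - gc_peak)^2)
}

#' @rdname gc_bias_quadratic
#' @export
gc_bias_flat <- function() function(gc) rep(1, length(gc))

# mixture level of copy number c relative to the tumour mean ploidy
mixture_level <- function(c, alpha, ploidy) {
  (2 * alpha + (1 - alpha) * c) / (2 * alpha + (1 - alpha) * ploidy)
}

#' Default truth segmentation for a simulated tumour genome
#'
#' Tiles each chromosome with `n_per_chrom` equal segments whose integer
#' copy numbers include a homozygous deletion, a single-copy loss and an
#' amplified level, and whose mean equals the configured tumour mean
#' ploidy exactly (so that the relative read-count scale is
#' self-consistent). Requires `10 * ploidy` to be an integer. Segment
#' order is shuffled deterministically from the configuration seed.
#'
#' @param config a [sim_config()].
#' @param n_per_chrom number of segments per chromosome (multiple of 10).
#' @return data.frame with columns `chrom`, `start`, `end`, `cn`
#'   (1-based inclusive coordinates).
#' @export
default_truth_segments <- function(config, n_per_chrom = 10) {
  stopifnot(inherits(config, "sim_config"))
  Q <- config$ploidy
  if (abs(10 * Q - round(10 * Q)) > 1e-9) {
    stop("default truth requires ploidy given to at most one decimal",
         call. = FALSE)
  }
  if (n_per_chrom %% 10 != 0) stop("`n_per_chrom` must be a multiple of 10")
  r <- round(Q)
  # ten copies summing to 10 Q: fixed low levels + filler at round(Q) +
  # one amplified remainder segment
  base <- c(0, 1, 2, 3, 4, r, r, r, r, 10 * Q - 10 - 4 * r)
  if (any(base < 0)) stop("ploidy too low for the default truth layout")
  copies <- rep(base, n_per_chrom / 10)
  with_seed(config$seed + 7L, {
    out <- lapply(names(config$chrom_lengths), function(ch) {
      len <- config$chrom_lengths[[ch]]
      bnd <- round(seq(0, len, length.out = n_per_chrom + 1))
      data.frame(chrom = ch,
                 start = bnd[-length(bnd)] + 1,
                 end = bnd[-1],
                 cn = sample(copies))
    })
    do.call(rbind, out)
  })
}

#' Simulate GC-biased binned read counts from an integer copy-number genome
#'
#' Realizes the tumour/normal read-count mixture model: each mappable bin
#' with local tumour copy number \eqn{c} has expected count
#' \eqn{depth \times gc\_bias(GC) \times
#' (2\alpha + (1-\alpha)c) / (2\alpha + (1-\alpha)Q)}, with Poisson (or
#' negative-binomial) noise. GC fractions vary smoothly along the genome
#' and unmappable bins are placed in runs.
#'
#' @param config a [sim_config()].
#' @param truth_segments data.frame (`chrom`, `start`, `end`, `cn`) of
#'   integer copy-number segments tiling every chromosome without gaps or
#'   overlaps (1-based inclusive). `NULL` uses
#'   [default_truth_segments()].
#' @return list with elements `track` (the binned track: `chrom`, `start`,
#'   `end`, `count`, `gc`, `mappable`, plus the generating `true_cn`) and
#'   `truth` (a truth set: `segments`, and the configuration used).
#' @export
simulate_cn_genome <- function(config, truth_segments = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth_segments)) truth_segments <- default_truth_segments(config)
  check_tiling(truth_segments, config$chrom_lengths)
  bw <- config$bin_width
  with_seed(config$seed, {
    tracks <- lapply(names(config$chrom_lengths), function(ch) {
      len <- config$chrom_lengths[[ch]]
      n <- floor(len / bw)
      start <- (seq_len(n) - 1) * bw + 1
      end <- start + bw - 1
      mid <- (start + end) / 2
      # smooth genome-like GC landscape
      phase <- runif(3, 0, 2 * pi)
      gc <- 0.42 +
        0.06 * sin(2 * pi * mid / 4.7e6 + phase[1]) +
        0.04 * sin(2 * pi * mid / 0.83e6 + phase[2]) +
        0.02 * sin(2 * pi * mid / 0.19e6 + phase[3])
      gc <- pmin(0.8, pmax(0.2, gc))
      # unmappable runs
      mappable <- rep(TRUE, n)
      n_gap_bins <- round(config$unmappable_fraction * n)
      while (n_gap_bins > 0) {
        run <- min(n_gap_bins, sample(5:50, 1))
        at <- sample(n - run, 1)
        mappable[at:(at + run - 1)] <- FALSE
        n_gap_bins <- n_gap_bins - run
      }
      segs <- truth_segments[truth_segments$chrom == ch, , drop = FALSE]
      segs <- segs[order(segs$start), , drop = FALSE]
      idx <- findInterval(mid, segs$start)
      cn <- segs$cn[idx]
      mu <- config$depth * config$gc_bias(gc) *
        mixture_level(cn, config$alpha, config$ploidy)
      count <- if (config$overdispersion > 0) {
        rnbinom(n, mu = mu, size = 1 / config$overdispersion)
      } else {
        rpois(n, mu)
      }
      data.frame(chrom = ch, start = start, end = end, count = count,
                 gc = gc, mappable = mappable, true_cn = cn)
    })
    track <- do.call(rbind, tracks)
    rownames(track) <- NULL
    list(track = track,
         truth = list(segments = truth_segments, config = config))
  })
}

# truth segments must tile each chromosome exactly
check_tiling <- function(segments, chrom_lengths) {
  need <- c("chrom", "start", "end", "cn")
  if (!all(need %in% names(segments))) {
    stop("truth segments need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    s <- s[order(s$start), ]
    bad_overlap <- which(s$start[-1] <= s$end[-nrow(s)])
    bad_gap <- which(s$start[-1] > s$end[-nrow(s)] + 1)
    if (length(c(bad_overlap, bad_gap))) {
      stop(sprintf(
        "truth segments do not tile %s: problem after segment(s) %s",
        ch, paste(rownames(s)[unique(c(bad_overlap, bad_gap))],
                  collapse = ", ")), call. = FALSE)
    }
    if (s$start[1] != 1) {
      stop(sprintf("truth segments on %s do not start at 1", ch),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
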