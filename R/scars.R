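#' Split a segmentation into chromosome arms
#'
#' Assigns each segment to the p or q arm from arm boundary positions and
#' truncates segments straddling the boundary.
#'
#' @param segments segment data.frame (`chrom`, `start`, `end`, plus copy
#'   columns, see [segment_copy_number()]).
#' @param arm_boundaries named vector: p/q boundary position per
#'   chromosome (as in [sim_config()]).
#' @return the segmentation with an added `arm` column (`"<chrom>p"` /
#'   `"<chrom>q"`), segments split at arm boundaries.
#' @export
split_by_arm <- function(segments, arm_boundaries) {
  out <- list()
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    bnd <- arm_boundaries[[ch]]
    if (is.null(bnd) || is.na(bnd)) {
      s$arm <- paste0(ch, "q")
      out[[length(out) + 1L]] <- s
      next
    }
    cross <- s$start <= bnd & s$end > bnd
    if (any(cross)) {
      left <- s[cross, , drop = FALSE]
      right <- s[cross, , drop = FALSE]
      scale_len <- !is.null(s$len)
      for (j in seq_len(nrow(left))) {
        frac <- (bnd - left$start[j] + 1) / (left$end[j] - left$start[j] + 1)
        left$end[j] <- bnd
        right$start[j] <- bnd + 1
        if (scale_len) {
          left$len[j] <- round(left$len[j] * frac)
          right$len[j] <- right$len[j] - left$len[j]
        }
      }
      s <- rbind(s[!cross, , drop = FALSE], left, right)
      s <- s[order(s$start), , drop = FALSE]
    }
    s$arm <- paste0(ch, ifelse(s$end <= bnd, "p", "q"))
    out[[length(out) + 1L]] <- s
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect firestorm chromosome arms
#'
#' A chromosome arm is in a state of firestorm when it harbours many
#' closely spaced amplicons: at least `min_segments` segments reaching at
#' least `min_levels` different copy-number levels, of which at least
#' `min_amplifications` are amplifications (rCN > 3). Levels are counted
#' on the decoded integer copy states.
#'
#' @param arms segmentation with an `arm` column ([split_by_arm()]), or a
#'   list of per-arm segment data.frames.
#' @param min_segments,min_levels,min_amplifications the firestorm rule.
#' @return data.frame with one row per arm: `arm`, `n_segments`,
#'   `n_levels`, `n_amplifications`, `firestorm`.
#' @export
detect_firestorms <- function(arms, min_segments = 20, min_levels = 10,
                              min_amplifications = 5) {
  arm_list <- as_arm_list(arms)
  rows <- lapply(names(arm_list), function(a) {
    s <- arm_list[[a]]
    lev <- if (!is.null(s$acn)) s$acn else s$rcn
    n_amp <- sum(s$rcn > 3)
    data.frame(arm = a,
               n_segments = nrow(s),
               n_levels = length(unique(lev)),
               n_amplifications = n_amp,
               firestorm = nrow(s) >= min_segments &&
                 length(unique(lev)) >= min_levels &&
                 n_amp >= min_amplifications)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_arm_list <- function(arms) {
  if (is.data.frame(arms)) {
    if (is.null(arms$arm)) stop("segments need an `arm` column",
                                call. = FALSE)
    split(arms, arms$arm)
  } else {
    if (is.null(names(arms))) names(arms) <- paste0("arm", seq_along(arms))
    arms
  }
}

#' Remove copy-number variation shorter than a minimum length
#'
#' Filtering and smoothing step preceding large-scale transition
#' counting: every segment shorter than `min_len` is absorbed into its
#' longer flanking neighbour (ties merge left), adjacent equal-level
#' segments are merged, and the procedure iterates to a fixed point.
#' Total arm coverage is conserved.
#'
#' @param arm one arm's segments, sorted (`start`, `end`, a length column
#'   `len` or coordinates, and `acn` or `rcn` as the copy level).
#' @param min_len minimum segment length kept, in bp (default 3 Mb).
#' @return the smoothed arm segmentation.
#' @export
smooth_segments_min_length <- function(arm, min_len = 3e6) {
  s <- arm[order(arm$start), , drop = FALSE]
  lev_col <- if (!is.null(s$acn)) "acn" else "rcn"
  if (is.null(s$len)) s$len <- s$end - s$start + 1
  s <- merge_equal_levels(s, lev_col)
  repeat {
    if (nrow(s) <= 1) break
    short <- which(s$len < min_len)
    if (!length(short)) break
    i <- short[which.min(s$len[short])]
    left_len <- if (i > 1) s$len[i - 1] else -Inf
    right_len <- if (i < nrow(s)) s$len[i + 1] else -Inf
    into <- if (left_len >= right_len) i - 1L else i + 1L
    s$len[into] <- s$len[into] + s$len[i]
    s$start[into] <- min(s$start[into], s$start[i])
    s$end[into] <- max(s$end[into], s$end[i])
    if (!is.null(s$n_bins)) s$n_bins[into] <- s$n_bins[into] + s$n_bins[i]
    s <- s[-i, , drop = FALSE]
    s <- merge_equal_levels(s, lev_col)
  }
  rownames(s) <- NULL
  s
}

merge_equal_levels <- function(s, lev_col) {
  if (nrow(s) <= 1) return(s)
  repeat {
    same <- which(diff(s[[lev_col]]) == 0)
    if (!length(same)) return(s)
    i <- same[1]
    s$end[i] <- s$end[i + 1]
    s$len[i] <- s$len[i] + s$len[i + 1]
    if (!is.null(s$n_bins)) s$n_bins[i] <- s$n_bins[i] + s$n_bins[i + 1]
    s <- s[-(i + 1), , drop = FALSE]
  }
}

#' Count large-scale state transitions on a chromosome arm
#'
#' A large-scale state transition (LST) is a copy-number break between
#' adjacent regions of at least `min_flank` each (measured on the
#' smoothed segmentation), not counting breaks at annotated centromeric
#' or unmappable gaps. The genome-wide LST count is a marker of
#' homologous-recombination deficiency.
#'
#' @param arm one arm's segments, already smoothed with
#'   [smooth_segments_min_length()].
#' @param min_flank minimum length of each flanking region (default
#'   10 Mb).
#' @param gaps optional data.frame (`chrom`, `start`, `end`) of
#'   centromere/unmappable gaps; junctions overlapping a gap are not
#'   counted.
#' @return integer LST count for the arm.
#' @export
count_lst <- function(arm, min_flank = 10e6, gaps = NULL) {
  s <- arm[order(arm$start), , drop = FALSE]
  if (nrow(s) < 2) return(0L)
  if (is.null(s$len)) s$len <- s$end - s$start + 1
  n_lst <- 0L
  for (i in seq_len(nrow(s) - 1)) {
    if (s$len[i] < min_flank || s$len[i + 1] < min_flank) next
    if (!is.null(gaps)) {
      g <- gaps
      if (!is.null(gaps$chrom) && !is.null(s$chrom)) {
        g <- gaps[gaps$chrom == s$chrom[i], , drop = FALSE]
      }
      junction <- c(s$end[i], s$start[i + 1])
      if (nrow(g) && any(g$start <= junction[2] & g$end >= junction[1])) {
        next
      }
    }
    n_lst <- n_lst + 1L
  }
  n_lst
}

#' Genome-wide LST score
#'
#' Applies [smooth_segments_min_length()] and [count_lst()] per arm and
#' totals the counts.
#'
#' @param arms segmentation with an `arm` column, or list of per-arm
#'   data.frames.
#' @inheritParams count_lst
#' @param min_len smoothing threshold passed to
#'   [smooth_segments_min_length()].
#' @return list with `per_arm` (named counts) and `total`.
#' @export
lst_score <- function(arms, min_flank = 10e6, min_len = 3e6, gaps = NULL) {
  arm_list <- as_arm_list(arms)
  counts <- vapply(arm_list, function(s) {
    count_lst(smooth_segments_min_length(s, min_len), min_flank, gaps)
  }, 0L)
  list(per_arm = counts, total = sum(counts))
}

#' Minimal common region across samples
#'
#' Returns the maximal genomic interval contained in at least one
#' qualifying interval of every sample: per sample the intervals are
#' merged (abutting/overlapping intervals are one region), the merged
#' sets are intersected across samples, and the longest resulting
#' interval is reported (leftmost on ties). Used to refine a minimal
#' common amplicon from per-sample gained/amplified segments.
#'
#' @param per_sample_intervals named list, one element per sample, each a
#'   data.frame with `start`, `end` (1-based inclusive, one chromosome).
#' @return list of class `mcr`: `found`, `start`, `end`, `length`
#'   (`end - start + 1`), and `n_samples`. A sample with no interval at
#'   all is an error naming the sample; an empty intersection is reported
#'   with `found = FALSE`.
#' @export
minimal_common_region <- function(per_sample_intervals) {
  if (!length(per_sample_intervals)) stop("no samples", call. = FALSE)
  if (is.null(names(per_sample_intervals))) {
    names(per_sample_intervals) <-
      paste0("sample", seq_along(per_sample_intervals))
  }
  sets <- lapply(names(per_sample_intervals), function(nm) {
    iv <- per_sample_intervals[[nm]]
    if (is.null(iv) || nrow(iv) == 0) {
      stop(sprintf("sample '%s' has no qualifying interval", nm),
           call. = FALSE)
    }
    IRanges::reduce(IRanges::IRanges(start = iv$start, end = iv$end))
  })
  common <- Reduce(IRanges::intersect, sets)
  if (length(common) == 0) {
    return(structure(list(found = FALSE, start = NA_real_, end = NA_real_,
                          length = 0,
                          n_samples = length(per_sample_intervals)),
                     class = "mcr"))
  }
  best <- which.max(IRanges::width(common))   # leftmost maximal on ties
  structure(list(found = TRUE,
                 start = IRanges::start(common)[best],
                 end = IRanges::end(common)[best],
                 length = IRanges::width(common)[best],
                 n_samples = length(per_sample_intervals)),
            class = "mcr")
}

#' @export
print.mcr <- function(x, ...) {
  if (x$found) {
    cat(sprintf("minimal common region: %s-%s (%d bp, %.0f kbp) in %d samples\n",
                format(x$start, big.mark = ","),
                format(x$end, big.mark = ","),
                x$length, round(x$length / 1000), x$n_samples))
  } else {
    cat("minimal common region: empty intersection across",
        x$n_samples, "samples\n")
  }
  invisible(x)
}
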