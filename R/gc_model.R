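#' Build an empirical GC-bias model from a binned track
#'
#' Fits the empirical dependency of read count on GC fraction: mappable
#' bins are sampled, bins with extreme counts are excluded, counts are
#' stratified by GC percent (101 strata), summarised by the per-stratum
#' median and smoothed across strata with loess. The resulting predictor
#' is calibrated so that the mean of raw/predicted over the sampled bins
#' is 1, which puts relative read counts on a genome-average scale.
#'
#' @param track binned track (`chrom`, `start`, `end`, `count`, `gc`,
#'   `mappable`).
#' @param n_positions number of mappable bins sampled to build the model.
#' @param seed integer seed for the sampling.
#' @param extreme quantile range of counts kept; bins outside it are the
#'   "extreme read counts" the model ignores.
#' @param span loess span for smoothing across GC strata.
#' @return object of class `gc_model`: the tabulated predictor (`gc`,
#'   `predicted`), the sampling size used and the exclusion range.
#' @export
build_gc_model <- function(track, n_positions = 1e5, seed = 1L,
                           extreme = c(0.01, 0.99), span = 0.3) {
  m <- track[track$mappable, , drop = FALSE]
  if (nrow(m) == 0) stop("no mappable bins in track", call. = FALSE)
  with_seed(seed, {
    if (nrow(m) > n_positions) {
      m <- m[sample.int(nrow(m), n_positions), , drop = FALSE]
    }
    lim <- quantile(m$count, extreme, names = FALSE)
    keep <- m$count >= lim[1] & m$count <= lim[2]
    m <- m[keep, , drop = FALSE]
    stratum <- round(m$gc * 100)
    med <- tapply(m$count, stratum, median)
    gc_grid <- as.numeric(names(med)) / 100
    pred <- as.numeric(med)
    if (length(gc_grid) >= 10) {
      fit <- loess(pred ~ gc_grid, span = span, degree = 2)
      pred <- predict(fit, gc_grid)
    }
    floor_val <- 0.5 * min(pred[pred > 0], Inf)
    if (!is.finite(floor_val)) {
      stop("GC model degenerate: no stratum with positive counts",
           call. = FALSE)
    }
    pred <- pmax(pred, floor_val)
    # calibrate to a genome-average scale: mean(raw/predicted) = 1
    p_at <- approx(gc_grid, pred, xout = m$gc, rule = 2)$y
    scale <- mean(m$count / p_at)
    structure(list(gc = gc_grid, predicted = pred * scale,
                   n_sampled = nrow(m), extreme_range = lim),
              class = "gc_model")
  })
}

#' Predicted count at given GC fractions
#'
#' @param model a [build_gc_model()] result.
#' @param gc numeric GC fractions.
#' @return predicted counts (strictly positive over the fitted range).
#' @export
predict_gc <- function(model, gc) {
  stopifnot(inherits(model, "gc_model"))
  approx(model$gc, model$predicted, xout = gc, rule = 2)$y
}

#' Compute GC-corrected relative read counts
#'
#' The relative read count (rRC) of a mappable bin is its raw count
#' divided by the GC-model prediction for its GC fraction; unmappable
#' bins carry no value.
#'
#' @param track binned track.
#' @param model a [build_gc_model()] result.
#' @return the track with an added `rrc` column (`NA` on unmappable
#'   bins); class `relative_track`.
#' @export
compute_rrc <- function(track, model) {
  pred <- rep(NA_real_, nrow(track))
  pred[track$mappable] <- predict_gc(model, track$gc[track$mappable])
  zero <- which(track$mappable & pred == 0)
  if (length(zero)) {
    stop(sprintf("predicted count is 0 at bin %s:%d",
                 track$chrom[zero[1]], track$start[zero[1]]),
         call. = FALSE)
  }
  track$rrc <- ifelse(track$mappable, track$count / pred, NA_real_)
  class(track) <- c("relative_track", class(track))
  track
}

#' Smooth relative read counts along chromosomes
#'
#' Applies a fixed-interval (local-level) Kalman smoother to the rRC
#' series of each chromosome independently, so that the distribution of
#' observed copy levels becomes well resolved. Smoothing never crosses
#' chromosome boundaries; a constant series (and a single-bin chromosome)
#' is returned unchanged. The observation variance is estimated robustly
#' from first differences and the process variance is
#' `ratio` times it.
#'
#' @param rel a [compute_rrc()] result.
#' @param ratio process-to-observation variance ratio of the local-level
#'   model (smaller = smoother).
#' @return `rel` with an added `smooth` column (`NA` on unmappable bins).
#' @export
smooth_rrc <- function(rel, ratio = 0.01) {
  stopifnot("rrc" %in% names(rel))
  rel$smooth <- NA_real_
  for (ch in unique(rel$chrom)) {
    i <- which(rel$chrom == ch & !is.na(rel$rrc))
    if (!length(i)) next
    rel$smooth[i] <- kalman_level(rel$rrc[i], ratio)
  }
  rel
}

# local-level Kalman filter + RTS smoother; y ordered, no NA
kalman_level <- function(y, ratio = 0.01) {
  n <- length(y)
  if (n <= 2) return(y)
  r_obs <- (mad(diff(y))^2) / 2
  if (!is.finite(r_obs) || r_obs <= 0) return(y)   # constant series
  q_proc <- ratio * r_obs
  a_f <- numeric(n)   # filtered mean
  p_f <- numeric(n)   # filtered variance
  a_p <- numeric(n)   # predicted mean
  p_p <- numeric(n)
  a_p[1] <- y[1]
  p_p[1] <- r_obs * 10
  for (t in seq_len(n)) {
    if (t > 1) {
      a_p[t] <- a_f[t - 1]
      p_p[t] <- p_f[t - 1] + q_proc
    }
    k <- p_p[t] / (p_p[t] + r_obs)
    a_f[t] <- a_p[t] + k * (y[t] - a_p[t])
    p_f[t] <- (1 - k) * p_p[t]
  }
  a_s <- a_f
  p_s <- p_f
  for (t in (n - 1):1) {
    g <- p_f[t] / p_p[t + 1]
    a_s[t] <- a_f[t] + g * (a_s[t + 1] - a_p[t + 1])
    p_s[t] <- p_f[t] + g^2 * (p_s[t + 1] - p_p[t + 1])
  }
  a_s
}
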