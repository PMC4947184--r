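#' Fit an evenly spaced Gaussian comb to the rRC distribution
#'
#' The smoothed relative read-count distribution of a tumour genome is a
#' mixture of evenly spaced peaks, one per integer copy number c, at
#' levels \eqn{level(c) = b_0 + s\,c} with
#' \eqn{level(c) = (2\alpha + (1-\alpha)c)/(2\alpha + (1-\alpha)Q)}.
#' The fit finds the peaks of a kernel density estimate, solves for the
#' spacing `s` and baseline `b0` by assigning integer copy numbers to
#' the peaks, refines (s, b0) by regressing all bins on their assigned
#' copies, and inverts the mixture model:
#' \eqn{\alpha = r/(r+2)} with \eqn{r = b_0/s}, and
#' \eqn{Q = (1-b_0)/s}.
#'
#' Peak positions alone cannot distinguish (\eqn{\alpha}, Q) from the
#' solution with every copy number shifted by one; the fit is anchored by
#' the assumption that the lowest observed peak corresponds to copy
#' `lowest_peak_copy` (default 0, i.e. the profile contains a homozygous
#' deletion level). Profiles without one should pass
#' `lowest_peak_copy = 1` (or whatever external evidence supports).
#'
#' @param rel a [smooth_rrc()] result (the `smooth` column is used).
#' @param lowest_peak_copy integer copy number of the lowest observed
#'   comb level.
#' @param bw kernel bandwidth, in rRC units.
#' @param min_peak_frac peaks below this fraction of the tallest peak are
#'   ignored.
#' @param min_spacing smallest admissible peak spacing, in rRC units;
#'   peaks closer than this are treated as one level.
#' @param min_bins minimum number of usable bins.
#' @return object of class `comb_fit`: `alpha`, `ploidy`, `spacing`,
#'   `baseline`, `sd` (within-peak standard deviation), `weights`
#'   (fraction of bins per copy state), `gof` (root-mean-square residual
#'   of bins to their assigned level), `n_bins`.
#' @export
fit_gaussian_comb <- function(rel, lowest_peak_copy = 0, bw = 0.02,
                              min_peak_frac = 0.05, min_spacing = 0.12,
                              min_bins = 500) {
  x <- if ("smooth" %in% names(rel)) rel$smooth else rel$rrc
  x <- x[!is.na(x)]
  if (length(x) < min_bins) {
    stop(sprintf("comb fit needs >= %d usable bins, got %d",
                 min_bins, length(x)), call. = FALSE)
  }
  d <- density(x, bw = bw, n = 2048, from = min(x) - 3 * bw,
               to = max(x) + 3 * bw)
  y <- d$y
  is_peak <- which(diff(sign(diff(y))) == -2) + 1L
  is_peak <- is_peak[y[is_peak] >= min_peak_frac * max(y)]
  peaks <- d$x[is_peak]
  heights <- y[is_peak]
  # sub-resolution structure (e.g. a wide amplified level splitting the
  # kernel estimate) is one level, not two
  merged <- merge_close_peaks(peaks, heights, min_spacing)
  peaks <- merged$peaks
  heights <- merged$heights
  if (length(peaks) < 2) {
    stop("comb fit is not identifiable: fewer than two peaks in the ",
         "smoothed rRC distribution", call. = FALSE)
  }
  s <- estimate_comb_spacing(peaks, heights, min_spacing)
  # assign integer copies to peaks, anchored at the lowest peak
  cc <- lowest_peak_copy + round((peaks - peaks[1]) / s)
  fit0 <- lm(peaks ~ cc, weights = heights)
  # refine on all bins: assign each to the nearest level, re-regress
  b0 <- coef(fit0)[1]
  s <- coef(fit0)[2]
  c_max_seen <- max(cc) + 2
  for (iter in 1:2) {
    cb <- pmin(c_max_seen, pmax(0, round((x - b0) / s)))
    fitb <- lm(x ~ cb)
    b0 <- coef(fitb)[1]
    s <- coef(fitb)[2]
  }
  if (!is.finite(s) || s <= 0) {
    stop("comb fit failed: non-positive peak spacing", call. = FALSE)
  }
  b0 <- max(0, b0)   # a slightly negative intercept means alpha = 0
  r <- b0 / s
  alpha <- r / (r + 2)
  ploidy <- (1 - b0) / s
  cb <- pmax(0, round((x - b0) / s))
  resid <- x - (b0 + s * cb)
  w <- table(factor(cb, levels = 0:max(cb))) / length(cb)
  structure(list(alpha = unname(alpha), ploidy = unname(ploidy),
                 spacing = unname(s), baseline = unname(b0),
                 sd = sd(resid), weights = as.numeric(w),
                 gof = sqrt(mean(resid^2)), n_bins = length(x)),
            class = "comb_fit")
}

merge_close_peaks <- function(peaks, heights, min_spacing) {
  repeat {
    if (length(peaks) < 2) break
    gaps <- diff(peaks)
    if (all(gaps >= min_spacing)) break
    i <- which.min(gaps)
    w <- heights[i] + heights[i + 1]
    peaks[i] <- (peaks[i] * heights[i] + peaks[i + 1] * heights[i + 1]) / w
    heights[i] <- w
    peaks <- peaks[-(i + 1)]
    heights <- heights[-(i + 1)]
  }
  list(peaks = peaks, heights = heights)
}

# Candidate spacings are integer fractions of the observed peak gaps.
# Each candidate is scored by the height-weighted squared fractional
# distance of the peaks to its grid; among candidates that fit
# comparably well, the largest spacing wins (any fit at spacing s is
# matched by s/2, never the reverse).
estimate_comb_spacing <- function(peaks, heights, min_spacing) {
  gaps <- diff(peaks)
  cand <- sort(unique(unlist(lapply(gaps, function(d) d / 1:4))))
  cand <- cand[cand >= min_spacing]
  if (!length(cand)) cand <- min(gaps)
  ratio <- vapply(cand, function(s) {
    z <- (peaks - peaks[1]) / s
    sum(heights * (z - round(z))^2) / sum(heights)
  }, 0.0)
  good <- cand[ratio <= max(2 * min(ratio), 1e-4)]
  max(good)
}

#' @export
print.comb_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Gaussian comb fit: alpha = %.3f, ploidy Q = %.2f\n",
    "  level(c) = %.4f + %.4f c  (rms residual %.4f over %d bins)\n"),
    x$alpha, x$ploidy, x$baseline, x$spacing, x$gof, x$n_bins))
  invisible(x)
}

#' rRC level of an integer copy number under a comb fit
#'
#' @param comb a `comb_fit`.
#' @param cn integer copy number(s).
#' @return rRC level `baseline + spacing * cn`.
#' @export
comb_level <- function(comb, cn) comb$baseline + comb$spacing * cn

#' Convert relative read counts to absolute integer copy numbers
#'
#' Inverts the contamination/ploidy linear map: `aCN` is the nearest
#' non-negative integer to `(rRC - b0)/s`. Values exactly midway between
#' two levels round away from the baseline (upwards).
#'
#' @param x numeric rRC values (or a data.frame with an `rrc` column).
#' @param comb a `comb_fit`.
#' @return integer aCN values (matching `x`'s shape).
#' @export
rrc_to_acn <- function(x, comb) {
  if (comb$spacing <= 0) stop("comb spacing must be > 0", call. = FALSE)
  if (is.data.frame(x)) {
    x$acn <- rrc_to_acn(x$rrc, comb)
    return(x)
  }
  z <- (x - comb$baseline) / comb$spacing
  # round() after the half-shift so that exact midpoints survive the
  # floating-point division and round away from the baseline
  as.integer(pmax(0, floor(round(z + 0.5, 9))))
}
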