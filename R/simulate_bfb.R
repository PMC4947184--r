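#' Simulate a breakage-fusion-bridge amplification history
#'
#' Runs `n_cycles` breakage-fusion-bridge cycles on a chromosome arm made
#' of `n_boundaries` segments (the stable, centromere-proximal end is
#' segment 1). Each cycle breaks the chromatid at a segment boundary chosen
#' uniformly (the first break may also lose only the telomere), keeps the
#' proximal part, and fuses the sister chromatids head to head, so that
#' DNA close to the breakpoint is duplicated in inverted orientation.
#'
#' @param n_boundaries number of breakable segments (>= 1).
#' @param n_cycles number of break-fusion cycles (>= 0); 0 returns the
#'   intact chromosome.
#' @param seed integer seed.
#' @param reads_per_fold supporting read count attached to each emitted
#'   fold breakpoint (per surviving junction copy).
#' @return list with elements
#'   \describe{
#'     \item{counts}{integer per-segment copy count of the final (fused)
#'       chromosome, stable end first.}
#'     \item{history}{class `bfb_history`: per-cycle break position and
#'       the fold it created (boundary index, fold direction, implied
#'       clip side), plus the final chromosome word.}
#'     \item{breakpoints}{data.frame of observable fold breakpoints
#'       (`boundary`, `fold`, `clip_side`, `support`): reads spanning a
#'       left fold align on their left part and are clipped on their
#'       right side, and conversely.}
#'   }
#' @export
simulate_bfb_process <- function(n_boundaries, n_cycles, seed = 1L,
                                 reads_per_fold = 10L) {
  if (!is.numeric(n_boundaries) || n_boundaries < 1) {
    stop("`n_boundaries` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_cycles) || n_cycles < 0) {
    stop("`n_cycles` must be a non-negative integer", call. = FALSE)
  }
  n <- as.integer(n_boundaries)
  if (n_cycles == 0) {
    return(list(counts = rep(1L, n),
                history = structure(list(n = n, cycles = list(),
                                         word = seq_len(n)),
                                    class = "bfb_history"),
                breakpoints = empty_breakpoints()))
  }
  with_seed(seed, {
    w <- seq_len(n)
    cycles <- vector("list", n_cycles)
    for (i in seq_len(n_cycles)) {
      # first break may keep the full run (telomere-only loss);
      # later breaks fall inside the fused bridge
      kmax <- if (i == 1L) length(w) else length(w) - 1L
      k <- sample.int(kmax, 1L)
      elt <- w[k]
      cycles[[i]] <- list(k = k, fold = fold_of_element(elt))
      p <- w[seq_len(k)]
      w <- c(p, -rev(p))
    }
    counts <- tabulate(abs(w), nbins = n)
    history <- structure(list(n = n, cycles = cycles, word = w),
                         class = "bfb_history")
    list(counts = counts,
         history = history,
         breakpoints = word_breakpoints(w, reads_per_fold))
  })
}

# fold created by breaking just distal to word element `elt`:
# a "+" copy runs left-to-right and folds back at the right edge of the
# segment (fold arm on the left => reads clipped right); a "-" copy
# conversely.
fold_of_element <- function(elt) {
  if (elt > 0) {
    list(boundary = elt, direction = "left", clip_side = "right")
  } else {
    list(boundary = -elt - 1L, direction = "right", clip_side = "left")
  }
}

empty_breakpoints <- function() {
  data.frame(boundary = integer(), fold = character(),
             clip_side = character(), support = integer())
}

# observable fold junctions of a chromosome word: adjacent head-to-head
# pairs (x, -x); mirrored copies of the same fold share boundary and clip
# side, so supports add up.
word_breakpoints <- function(w, reads_per_fold = 10L) {
  if (length(w) < 2) return(empty_breakpoints())
  x <- w[-length(w)]
  y <- w[-1]
  at <- which(y == -x)
  if (!length(at)) return(empty_breakpoints())
  folds <- lapply(at, function(i) fold_of_element(w[i]))
  df <- data.frame(boundary = vapply(folds, `[[`, 0L, "boundary"),
                   fold = vapply(folds, `[[`, "", "direction"),
                   clip_side = vapply(folds, `[[`, "", "clip_side"))
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          df[c("boundary", "fold", "clip_side")], sum)
  agg$support <- agg$n * as.integer(reads_per_fold)
  agg$n <- NULL
  agg[order(agg$boundary), , drop = FALSE]
}
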