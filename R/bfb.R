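#' Collapse an absolute copy-number segmentation into a count vector
#'
#' Merges adjacent segments with equal absolute copy number and optionally
#' subtracts a constant baseline shift (e.g. the copies contributed by an
#' intact homologous chromosome) from every count. The result is the
#' ordered segment copy-count vector on which breakage-fusion-bridge
#' compatibility is tested.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`, `acn`,
#'   sorted and non-overlapping over the analysed window.
#' @param baseline_shift integer subtracted from every count; a shift that
#'   would make any count negative is an error, not a clamp.
#' @param orientation which end of the window is the retained (stable)
#'   end: `"stable_left"`, `"stable_right"` or `"unspecified"`.
#' @return object of class `bfb_counts`: `counts` (integer), `starts`,
#'   `ends` (bp spans of the merged segments), `boundaries` (bp positions
#'   between consecutive merged segments), `orientation`, `shift`.
#' @export
collapse_acn_segments <- function(segments, baseline_shift = 0L,
                                  orientation = c("stable_left",
                                                  "stable_right",
                                                  "unspecified")) {
  orientation <- match.arg(orientation)
  stopifnot(all(c("start", "end", "acn") %in% names(segments)))
  if (nrow(segments) == 0) stop("empty segmentation", call. = FALSE)
  s <- segments[order(segments$start), , drop = FALSE]
  if (any(s$acn < 0)) stop("negative absolute copy numbers", call. = FALSE)
  keep <- c(TRUE, diff(s$acn) != 0)
  grp <- cumsum(keep)
  counts <- s$acn[keep]
  starts <- tapply(s$start, grp, min)
  ends <- tapply(s$end, grp, max)
  counts <- counts - as.integer(baseline_shift)
  if (any(counts < 0)) {
    stop(sprintf("baseline shift %d makes %d segment count(s) negative",
                 baseline_shift, sum(counts < 0)), call. = FALSE)
  }
  structure(list(counts = as.integer(counts),
                 starts = as.numeric(starts),
                 ends = as.numeric(ends),
                 boundaries = as.numeric(ends[-length(ends)]),
                 orientation = orientation,
                 shift = as.integer(baseline_shift)),
            class = "bfb_counts")
}

as_count_vector <- function(v) {
  if (inherits(v, "bfb_counts")) v$counts else as.integer(v)
}

mirror_word <- function(q) -rev(q)

# --- canonical-path search -------------------------------------------------
# A chromosome observable after breakage-fusion-bridge cycles is a proximal
# prefix of a word reachable by the chain
#   q_1 = (1..k),  q_{i+1} = q_i . mirror(q_i)[1..t],  t in 1..|q_i|-1,
# and any raw cycle path can be rewritten as such a chain with
# per-segment counts that never exceed those of the observed vector, so
# pruning on the target counts is sound and complete (see the methods
# vignette for the argument).

# BFS for a target vector u (all entries >= 1); returns NULL or the chain
bfb_chain_search <- function(u, max_cycles = Inf, max_states = 5e5) {
  n <- length(u)
  states <- list()
  parent <- integer()
  ext <- integer()        # 0 = start state, else mirrored-tail length
  depth <- integer()
  match_len <- NA_integer_
  match_idx <- NA_integer_
  visited <- new.env(hash = TRUE, parent = emptyenv())
  queue_add <- function(q, par, t, d) {
    key <- paste(q, collapse = ",")
    if (!is.null(visited[[key]])) return(invisible())
    visited[[key]] <- TRUE
    i <- length(states) + 1L
    states[[i]] <<- q
    parent[i] <<- par
    ext[i] <<- t
    depth[i] <<- d
    invisible()
  }
  for (k in seq_len(n)) if (all(tabulate(seq_len(k), n) <= u)) {
    queue_add(seq_len(k), 0L, 0L, 1L)
  }
  head <- 1L
  while (head <= length(states)) {
    if (length(states) > max_states) {
      stop("BFB search budget exceeded (", max_states, " states); ",
           "the count vector is too large for an exact decision",
           call. = FALSE)
    }
    q <- states[[head]]
    # does some proximal prefix of q . mirror(q) have exactly counts u?
    cnt <- integer(n)
    w <- c(q, mirror_word(q))
    for (j in seq_along(w)) {
      xi <- abs(w[j])
      cnt[xi] <- cnt[xi] + 1L
      if (cnt[xi] > u[xi]) break
      if (all(cnt == u)) {
        match_len <- j
        match_idx <- head
        break
      }
    }
    if (!is.na(match_idx)) break
    if (depth[head] < max_cycles && length(q) >= 2L) {
      m <- mirror_word(q)
      cnt <- tabulate(abs(q), nbins = n)
      for (t in seq_len(length(q) - 1L)) {
        xi <- abs(m[t])
        cnt[xi] <- cnt[xi] + 1L
        if (cnt[xi] > u[xi]) break
        queue_add(c(q, m[seq_len(t)]), head, t, depth[head] + 1L)
      }
    }
    head <- head + 1L
  }
  if (is.na(match_idx)) return(NULL)
  # reconstruct chain of half-words
  chain <- list()
  i <- match_idx
  while (i != 0L) {
    chain <- c(list(states[[i]]), chain)
    i <- parent[i]
  }
  list(chain = chain, observed_length = match_len)
}

#' Decide whether a copy-count vector is compatible with a BFB history
#'
#' Tests whether some breakage-fusion-bridge history over the window's
#' segments produces exactly the observed per-segment copy counts, in the
#' tagged orientation (both orientations when `"unspecified"`). The
#' decision is a memoized breadth-first search over canonical fold
#' histories with pruning on the target counts; when the vector is
#' compatible, a witness folding pattern that replays to it is attached.
#'
#' @param v integer vector of per-segment copy counts (entries >= 0), or a
#'   [collapse_acn_segments()] result.
#' @param orientation which end is the stable (retained) end; overridden
#'   by the tag of a `bfb_counts` input.
#' @param max_cycles maximum number of break-fusion cycles allowed.
#' @param max_states search budget; exceeding it is an error, never a
#'   silent wrong answer.
#' @return `TRUE` or `FALSE`; when `TRUE`, attributes `witness` (a
#'   `fold_pattern`, see [derive_fold_pattern()]) and `orientation` (the
#'   orientation that validated).
#' @export
is_bfb_count_vector <- function(v, orientation = NULL, max_cycles = Inf,
                                max_states = 5e5) {
  if (inherits(v, "bfb_counts")) {
    orientation <- orientation %||% v$orientation
  }
  orientation <- orientation %||% "stable_left"
  counts <- as_count_vector(v)
  if (length(counts) < 1) stop("empty count vector", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  orients <- switch(orientation,
                    stable_left = "stable_left",
                    stable_right = "stable_right",
                    unspecified = c("stable_left", "stable_right"),
                    stop("unknown orientation ", orientation, call. = FALSE))
  for (o in orients) {
    x <- if (o == "stable_right") rev(counts) else counts
    res <- bfb_decide_one(x, max_cycles, max_states)
    if (isTRUE(res$ok)) {
      out <- TRUE
      attr(out, "witness") <- res$witness
      attr(out, "orientation") <- o
      return(out)
    }
  }
  FALSE
}

# decision for a stable-left vector
bfb_decide_one <- function(counts, max_cycles, max_states) {
  n <- length(counts)
  nz <- which(counts > 0)
  if (length(nz) == 0) return(list(ok = FALSE))
  n_eff <- max(nz)
  u <- counts[seq_len(n_eff)]
  # every breakage truncates the distal end: a positive count distal to a
  # fully deleted segment is impossible
  if (any(u == 0)) return(list(ok = FALSE))
  if (n_eff == n && all(u == 1)) {
    return(list(ok = TRUE, witness = fold_pattern(list(), n, NULL)))
  }
  found <- bfb_chain_search(u, max_cycles, max_states)
  if (is.null(found)) return(list(ok = FALSE))
  # witness is expressed over the full window (trailing lost segments
  # keep count 0 on replay)
  list(ok = TRUE,
       witness = fold_pattern(found$chain, n, found$observed_length))
}

# build a fold_pattern from a canonical chain of half-words
fold_pattern <- function(chain, n, observed_length) {
  folds <- list()
  if (length(chain)) {
    lens <- vapply(chain, length, 0L)
    q_last <- chain[[length(chain)]]
    # junctions created by each fusion sit at the ends of the half-words
    fold_at <- lens[lens < (observed_length %||% Inf)]
    # the chain's own junctions (between q_i and its mirrored extension)
    # are at positions lens[1..m-1]; the final fusion's centre fold is at
    # lens[m], present only if the observed prefix extends beyond it
    word <- c(q_last, mirror_word(q_last))
    for (pos in fold_at) {
      folds[[length(folds) + 1L]] <- fold_of_element(word[pos])
    }
  }
  df <- if (length(folds)) {
    data.frame(order = seq_along(folds),
               boundary = vapply(folds, `[[`, 0L, "boundary"),
               fold = vapply(folds, `[[`, "", "direction"),
               clip_side = vapply(folds, `[[`, "", "clip_side"))
  } else {
    data.frame(order = integer(), boundary = integer(),
               fold = character(), clip_side = character())
  }
  structure(list(folds = df, n = n,
                 chain = chain, observed_length = observed_length),
            class = "fold_pattern")
}

#' @export
print.fold_pattern <- function(x, ...) {
  cat("BFB fold pattern:", nrow(x$folds), "fold(s) over", x$n,
      "segment(s)\n")
  if (nrow(x$folds)) print(x$folds, row.names = FALSE)
  invisible(x)
}

# replay a canonical chain and return the observed per-segment counts
replay_fold_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "fold_pattern"))
  if (!length(pattern$chain)) return(rep(1L, pattern$n))
  q <- pattern$chain[[length(pattern$chain)]]
  w <- c(q, mirror_word(q))
  o <- w[seq_len(pattern$observed_length)]
  tabulate(abs(o), nbins = pattern$n)
}

#' Derive (or verify) the folding pattern of a BFB history
#'
#' For a simulated history ([simulate_bfb_process()]) returns the folds it
#' actually performed; for a witness returned by [is_bfb_count_vector()]
#' verifies by replay that the pattern reproduces its count vector (an
#' internal-consistency failure is an error) and returns it.
#'
#' @param x a `bfb_history` or a `fold_pattern`.
#' @return a `fold_pattern` whose `folds` data.frame gives, in order, each
#'   fold's segment-boundary index, fold direction (`left`/`right`) and
#'   implied clip side (`right`/`left`).
#' @export
derive_fold_pattern <- function(x) {
  if (inherits(x, "bfb_history")) {
    folds <- lapply(x$cycles, `[[`, "fold")
    df <- if (length(folds)) {
      data.frame(order = seq_along(folds),
                 boundary = vapply(folds, `[[`, 0L, "boundary"),
                 fold = vapply(folds, `[[`, "", "direction"),
                 clip_side = vapply(folds, `[[`, "", "clip_side"))
    } else {
      data.frame(order = integer(), boundary = integer(),
                 fold = character(), clip_side = character())
    }
    return(structure(list(folds = df, n = x$n, word = x$word),
                     class = "fold_pattern"))
  }
  if (inherits(x, "fold_pattern")) {
    if (!is.null(x$chain)) {
      target <- replay_fold_pattern(x)
      # the witness must replay to a vector accepted by construction
      if (!isTRUE(all(target >= 0))) {
        stop("internal consistency failure: witness does not replay")
      }
    }
    return(x)
  }
  stop("`x` must be a bfb_history or fold_pattern", call. = FALSE)
}

#' Enumerate all count vectors reachable by bounded BFB histories
#'
#' Exhaustively enumerates the per-segment copy-count vectors reachable by
#' at most `max_cycles` breakage-fusion-bridge cycles over
#' `max_boundaries` segments, keeping vectors whose entries do not exceed
#' `max_count`. This is the brute-force oracle against which the decision
#' algorithm is checked.
#'
#' @param max_boundaries number of segments (<= 6, tractability bound).
#' @param max_cycles maximum cycles (<= 8, tractability bound).
#' @param max_count cap on reported per-segment counts.
#' @return integer matrix, one deduplicated count vector per row (stable
#'   end in column 1).
#' @export
enumerate_bfb_vectors <- function(max_boundaries, max_cycles,
                                  max_count = 8L) {
  if (max_boundaries < 1 || max_boundaries > 6) {
    stop("`max_boundaries` must be in 1..6", call. = FALSE)
  }
  if (max_cycles < 0 || max_cycles > 8) {
    stop("`max_cycles` must be in 0..8", call. = FALSE)
  }
  n <- as.integer(max_boundaries)
  out <- new.env(hash = TRUE, parent = emptyenv())
  emit_prefixes <- function(q) {
    cnt <- integer(n)
    for (x in c(q, mirror_word(q))) {
      xi <- abs(x)
      cnt[xi] <- cnt[xi] + 1L
      if (cnt[xi] > max_count) break
      out[[paste(cnt, collapse = ",")]] <- TRUE
    }
  }
  out[[paste(rep(1L, n), collapse = ",")]] <- TRUE   # intact chromosome
  if (max_cycles >= 1) {
    visited <- new.env(hash = TRUE, parent = emptyenv())
    states <- list()
    depth <- integer()
    add <- function(q, d) {
      key <- paste(q, collapse = ",")
      if (!is.null(visited[[key]])) return(invisible())
      visited[[key]] <- TRUE
      i <- length(states) + 1L
      states[[i]] <<- q
      depth[i] <<- d
      invisible()
    }
    for (k in seq_len(n)) add(seq_len(k), 1L)
    head <- 1L
    while (head <= length(states)) {
      q <- states[[head]]
      emit_prefixes(q)
      if (depth[head] < max_cycles && length(q) >= 2L) {
        m <- mirror_word(q)
        cnt <- tabulate(abs(q), nbins = n)
        for (t in seq_len(length(q) - 1L)) {
          xi <- abs(m[t])
          cnt[xi] <- cnt[xi] + 1L
          if (cnt[xi] > max_count) break
          add(c(q, m[seq_len(t)]), depth[head] + 1L)
        }
      }
      head <- head + 1L
    }
  }
  keys <- ls(out)
  mat <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  mat[do.call(order, as.data.frame(mat)), , drop = FALSE]
}

#' Longest contiguous subvector compatible with a BFB history
#'
#' Scans all contiguous windows of the count vector, longest first, and
#' returns the first (leftmost) window accepted by
#' [is_bfb_count_vector()]; the whole-vector span is returned when the
#' vector itself is valid. The window inherits the vector's orientation
#' tag (the stable side stays on the same side).
#'
#' @inheritParams is_bfb_count_vector
#' @return list with `start`, `end` (indices into `v`), `counts`, and the
#'   `witness`/`orientation` of the accepted window.
#' @export
longest_bfb_compatible <- function(v, orientation = NULL, max_cycles = Inf,
                                   max_states = 5e5) {
  if (inherits(v, "bfb_counts")) orientation <- orientation %||% v$orientation
  orientation <- orientation %||% "stable_left"
  counts <- as_count_vector(v)
  n <- length(counts)
  for (len in rev(seq_len(n))) {
    for (s in seq_len(n - len + 1L)) {
      sub <- counts[s:(s + len - 1L)]
      ok <- is_bfb_count_vector(sub, orientation = orientation,
                                max_cycles = max_cycles,
                                max_states = max_states)
      if (isTRUE(ok)) {
        return(list(start = s, end = s + len - 1L, counts = sub,
                    witness = attr(ok, "witness"),
                    orientation = attr(ok, "orientation")))
      }
    }
  }
  # a single all-zero entry window is never valid; report absence
  list(start = NA_integer_, end = NA_integer_, counts = integer(),
       witness = NULL, orientation = orientation)
}

#' Check clipped-read orientations against a BFB folding pattern
#'
#' Matches observed breakpoints (position, clip side) to the folds of a
#' pattern and applies the orientation rule: reads spanning a left fold
#' align on their left part and are clipped on their right (3') side, and
#' conversely for a right fold.
#'
#' @param pattern a `fold_pattern` (same coordinate frame as `observed`).
#' @param observed data.frame with columns `boundary` (or `position`),
#'   `clip_side` and optionally `support`.
#' @param tolerance_bp maximum distance between an observation and a fold
#'   for them to be matched.
#' @return list of class `clip_consistency`: counts and tables of
#'   `matched_consistent`, `matched_inconsistent`, `unmatched` observations
#'   and `missed` folds with no observation, plus `consistent_fraction`.
#' @export
check_clip_orientation_consistency <- function(pattern, observed,
                                               tolerance_bp = 0) {
  stopifnot(inherits(pattern, "fold_pattern"))
  pos_col <- if ("boundary" %in% names(observed)) "boundary" else "position"
  folds <- pattern$folds
  obs <- observed
  obs$matched <- NA_integer_
  obs$consistent <- NA
  if (nrow(obs) && nrow(folds)) {
    for (i in seq_len(nrow(obs))) {
      d <- abs(folds$boundary - obs[[pos_col]][i])
      near <- which(d <= tolerance_bp)
      if (!length(near)) next
      # boundaries can host folds of both directions; an observation is
      # consistent if any fold within tolerance matches its clip side
      good <- near[
        (folds$fold[near] == "left" & obs$clip_side[i] == "right") |
        (folds$fold[near] == "right" & obs$clip_side[i] == "left")]
      if (length(good)) {
        obs$matched[i] <- good[which.min(d[good])]
        obs$consistent[i] <- TRUE
      } else {
        obs$matched[i] <- near[which.min(d[near])]
        obs$consistent[i] <- FALSE
      }
    }
  }
  matched <- !is.na(obs$matched)
  # a fold is missed when no observation falls within tolerance of its
  # boundary (several cycles can fold at one boundary; one observed
  # breakpoint covers them all)
  missed <- if (nrow(folds)) {
    which(vapply(seq_len(nrow(folds)), function(j) {
      !nrow(obs) || all(abs(obs[[pos_col]] - folds$boundary[j]) >
                          tolerance_bp)
    }, TRUE))
  } else integer()
  structure(list(
    matched_consistent = obs[matched & obs$consistent %in% TRUE, ,
                             drop = FALSE],
    matched_inconsistent = obs[matched & obs$consistent %in% FALSE, ,
                               drop = FALSE],
    unmatched = obs[!matched, , drop = FALSE],
    missed = folds[missed, , drop = FALSE],
    consistent_fraction = if (any(matched)) {
      mean(obs$consistent[matched])
    } else NA_real_),
    class = "clip_consistency")
}

#' @export
print.clip_consistency <- function(x, ...) {
  cat("clip-orientation consistency:",
      nrow(x$matched_consistent), "consistent,",
      nrow(x$matched_inconsistent), "inconsistent,",
      nrow(x$unmatched), "unmatched observation(s),",
      nrow(x$missed), "missed fold(s)\n")
  invisible(x)
}
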