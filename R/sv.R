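#' Cluster discordant-pair and soft-clip read evidence
#'
#' Identifies discordant read pairs (wrong orientation for an FR library,
#' mates on different chromosomes, or insert size larger than
#' `insert_mean + k_insert * insert_sd`) and groups them into clusters
#' whose two ends each co-locate within a distance window; soft-clipped
#' reads are grouped by shared clip position and side.
#'
#' @param evidence read evidence data.frame (see
#'   [simulate_sv_read_evidence()] for the columns).
#' @param insert_mean,insert_sd library insert-size distribution.
#' @param k_insert inserts beyond `insert_mean + k_insert * insert_sd`
#'   are discordant.
#' @param pair_window co-location window for discordant-pair ends;
#'   defaults to `insert_mean + 3 * insert_sd`.
#' @param clip_window co-location window for clip positions (bp).
#' @return list of class `sv_clusters` with elements `discordant` (one
#'   row per cluster: regions of both ends, strands, size `n`, member
#'   ids) and `clip` (position, side, size, maximum aligned clipped
#'   bases).
#' @export
cluster_evidence <- function(evidence, insert_mean = 350, insert_sd = 50,
                             k_insert = 4,
                             pair_window = insert_mean + 3 * insert_sd,
                             clip_window = 5) {
  ev <- evidence
  pairs <- ev[ev$kind == "pair", , drop = FALSE]
  clips <- ev[ev$kind == "clip", , drop = FALSE]
  thr <- insert_mean + k_insert * insert_sd
  disc <- pairs[is_discordant(pairs, thr), , drop = FALSE]
  structure(list(discordant = cluster_pairs(disc, pair_window),
                 clip = cluster_clips(clips, clip_window)),
            class = "sv_clusters")
}

# FR library: a proper pair has both mates on one chromosome, leftmost
# read forward, mate reverse, insert within the expected range
is_discordant <- function(pairs, insert_threshold) {
  if (nrow(pairs) == 0) return(logical())
  inter <- pairs$chrom != pairs$mate_chrom
  wrong_orient <- !(pairs$strand == "+" & pairs$mate_strand == "-")
  long_insert <- !is.na(pairs$insert) & pairs$insert > insert_threshold
  inter | wrong_orient | long_insert
}

cluster_pairs <- function(disc, window) {
  empty <- data.frame(cluster_id = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), mate_chrom = character(),
                      mate_start = numeric(), mate_end = numeric(),
                      mate_strand = character(), n = integer())
  if (nrow(disc) == 0) {
    empty$members <- I(list())
    return(empty)
  }
  key <- paste(disc$chrom, disc$mate_chrom, disc$strand, disc$mate_strand)
  out <- list()
  for (k in unique(key)) {
    g <- disc[key == k, , drop = FALSE]
    g <- g[order(g$pos), , drop = FALSE]
    # chain on the left end, then split chains whose right ends scatter
    new_chain <- c(TRUE, diff(g$pos) > window)
    chain <- cumsum(new_chain)
    for (cid in unique(chain)) {
      h <- g[chain == cid, , drop = FALSE]
      h <- h[order(h$mate_pos), , drop = FALSE]
      sub <- cumsum(c(TRUE, diff(h$mate_pos) > window))
      for (sid in unique(sub)) {
        m <- h[sub == sid, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          cluster_id = length(out) + 1L,
          chrom = m$chrom[1], start = min(m$pos), end = max(m$pos),
          strand = m$strand[1],
          mate_chrom = m$mate_chrom[1],
          mate_start = min(m$mate_pos), mate_end = max(m$mate_pos),
          mate_strand = m$mate_strand[1],
          n = nrow(m),
          members = I(list(m$id)))
      }
    }
  }
  res <- do.call(rbind, out)
  res$cluster_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

cluster_clips <- function(clips, window) {
  empty <- data.frame(cluster_id = integer(), chrom = character(),
                      pos = numeric(), side = character(), n = integer(),
                      max_clip_bases = numeric())
  if (nrow(clips) == 0) {
    empty$members <- I(list())
    return(empty)
  }
  key <- paste(clips$chrom, clips$clip_side)
  out <- list()
  for (k in unique(key)) {
    g <- clips[key == k, , drop = FALSE]
    g <- g[order(g$pos), , drop = FALSE]
    chain <- cumsum(c(TRUE, diff(g$pos) > window))
    for (cid in unique(chain)) {
      m <- g[chain == cid, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = length(out) + 1L,
        chrom = m$chrom[1], pos = median(m$pos), side = m$clip_side[1],
        n = nrow(m), max_clip_bases = max(m$clip_bases),
        members = I(list(m$id)))
    }
  }
  res <- do.call(rbind, out)
  res$cluster_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Call somatic structural variants from clustered evidence
#'
#' Builds SV candidates from tumour discordant-pair clusters, types them
#' from the pair orientations (long-insert FR: deletion; everted RF:
#' duplication; same-strand: inversion; mates on different chromosomes:
#' inter-chromosomal), resolves breakpoints to the base pair from
#' attached soft-clip clusters, classifies candidates present in the
#' matched normal as germline, and enforces the support filters: at
#' least `min_pairs` discordant pairs, at least `min_clips` soft-clipped
#' reads per attached clip cluster, at least `min_clip_bases` aligned
#' clipped bases, and at least one breakpoint in a mappable region.
#'
#' @param tumour_clusters,normal_clusters [cluster_evidence()] results;
#'   the matched normal is required (somatic status is undefined without
#'   it).
#' @param mappable optional data.frame (`chrom`, `start`, `end`) of
#'   mappable regions; `NULL` treats the whole genome as mappable.
#' @param min_pairs,min_clips,min_clip_bases support filters.
#' @param attach_window maximum distance between a clip cluster and a
#'   discordant-cluster end region for attachment.
#' @param germline_window breakpoint distance within which a candidate
#'   matches a normal cluster of the same type.
#' @return data.frame of somatic calls: `type`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `n_pairs`, `n_clips`, `clip_side1`, `clip_side2`,
#'   `bp_resolved`. All candidates (with `somatic` and `filtered`
#'   columns) are attached as attribute `"candidates"`.
#' @export
call_somatic_svs <- function(tumour_clusters, normal_clusters,
                             mappable = NULL,
                             min_pairs = 2, min_clips = 2,
                             min_clip_bases = 15,
                             attach_window = 500,
                             germline_window = 300) {
  if (missing(normal_clusters) || is.null(normal_clusters)) {
    stop("a matched-normal cluster set is required: somatic status is ",
         "undefined without it", call. = FALSE)
  }
  stopifnot(inherits(tumour_clusters, "sv_clusters"),
            inherits(normal_clusters, "sv_clusters"))
  disc <- tumour_clusters$discordant
  clips <- tumour_clusters$clip
  if (nrow(disc) == 0) {
    out <- empty_sv_calls()
    attr(out, "candidates") <- out
    return(out)
  }
  cand <- do.call(rbind, lapply(seq_len(nrow(disc)), function(i) {
    typed <- type_candidate(disc[i, ], clips, attach_window)
  }))
  norm_cand <- if (nrow(normal_clusters$discordant)) {
    do.call(rbind, lapply(seq_len(nrow(normal_clusters$discordant)),
                          function(i) {
      type_candidate(normal_clusters$discordant[i, ],
                     normal_clusters$clip, attach_window)
    }))
  } else empty_sv_calls()
  cand$somatic <- !vapply(seq_len(nrow(cand)), function(i) {
    matches_normal(cand[i, ], norm_cand, germline_window)
  }, TRUE)
  cand$filtered <- !sv_passes_filters(cand, mappable, min_pairs,
                                      min_clips, min_clip_bases)
  out <- cand[cand$somatic & !cand$filtered, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "candidates") <- cand
  out
}

empty_sv_calls <- function() {
  data.frame(type = character(), chrom1 = character(), pos1 = numeric(),
             chrom2 = character(), pos2 = numeric(), n_pairs = integer(),
             n_clips = integer(), clip_n_min = integer(),
             clip_bases = numeric(), clip_side1 = character(),
             clip_side2 = character(), bp_resolved = logical())
}

# orientation-based typing and breakpoint resolution for one cluster
type_candidate <- function(cl, clips, attach_window) {
  inter <- cl$chrom != cl$mate_chrom
  type <- if (inter) {
    "inter_chromosomal"
  } else if (cl$strand == cl$mate_strand) {
    "inversion"
  } else if (cl$strand == "-" && cl$mate_strand == "+") {
    "duplication"
  } else {
    "deletion"
  }
  # breakpoint 1 lies just right of the left reads, breakpoint 2 just
  # left of the right reads (refined by clip clusters when present)
  bp1_guess <- cl$end
  bp2_guess <- cl$mate_start
  c1 <- nearest_clip(clips, cl$chrom, bp1_guess, attach_window)
  c2 <- nearest_clip(clips, cl$mate_chrom, bp2_guess, attach_window)
  data.frame(
    type = type,
    chrom1 = cl$chrom,
    pos1 = if (!is.null(c1)) c1$pos else bp1_guess,
    chrom2 = cl$mate_chrom,
    pos2 = if (!is.null(c2)) c2$pos else bp2_guess,
    n_pairs = cl$n,
    n_clips = sum(c(c1$n, c2$n)),
    clip_n_min = if (is.null(c1) && is.null(c2)) 0L else min(c(c1$n, c2$n)),
    clip_bases = max(c(c1$max_clip_bases, c2$max_clip_bases, 0)),
    clip_side1 = if (!is.null(c1)) c1$side else NA_character_,
    clip_side2 = if (!is.null(c2)) c2$side else NA_character_,
    bp_resolved = !is.null(c1) || !is.null(c2))
}

nearest_clip <- function(clips, chrom, pos, window) {
  g <- clips[clips$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  d <- abs(g$pos - pos)
  if (min(d) > window) return(NULL)
  g[which.min(d), , drop = FALSE]
}

matches_normal <- function(cand, norm_cand, window) {
  if (nrow(norm_cand) == 0) return(FALSE)
  same <- norm_cand$type == cand$type &
    norm_cand$chrom1 == cand$chrom1 & norm_cand$chrom2 == cand$chrom2 &
    abs(norm_cand$pos1 - cand$pos1) <= window &
    abs(norm_cand$pos2 - cand$pos2) <= window
  any(same)
}

# the four printed support filters; exported so tests can assert that no
# emitted call violates them
#' Check SV calls against the support filters
#'
#' @param calls candidate data.frame from [call_somatic_svs()].
#' @param mappable optional mappable-region data.frame.
#' @param min_pairs,min_clips,min_clip_bases filter thresholds.
#' @return logical vector, `TRUE` where a call passes all filters.
#' @export
sv_passes_filters <- function(calls, mappable = NULL, min_pairs = 2,
                              min_clips = 2, min_clip_bases = 15) {
  if (nrow(calls) == 0) return(logical())
  ok_pairs <- calls$n_pairs >= min_pairs
  ok_clips <- calls$bp_resolved & calls$clip_n_min >= min_clips
  ok_bases <- calls$clip_bases >= min_clip_bases
  ok_map <- if (is.null(mappable)) {
    rep(TRUE, nrow(calls))
  } else {
    in_map <- function(ch, p) {
      any(mappable$chrom == ch & mappable$start <= p & mappable$end >= p)
    }
    vapply(seq_len(nrow(calls)), function(i) {
      in_map(calls$chrom1[i], calls$pos1[i]) ||
        in_map(calls$chrom2[i], calls$pos2[i])
    }, TRUE)
  }
  ok_pairs & ok_clips & ok_bases & ok_map
}
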