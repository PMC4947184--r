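#' Simulate discordant-pair and soft-clip evidence for structural variants
#'
#' Emits, for each planted structural variant, `depth` discordant read
#' pairs whose orientations are characteristic of the variant type under
#' a forward-reverse (FR) paired-end library, plus soft-clipped reads at
#' both breakpoints, and uniform background noise pairs. Germline
#' variants contribute evidence to both the tumour and the matched
#' normal.
#'
#' Orientation conventions (records are stored with the leftmost read
#' first): deletion spans emit FR pairs with an insert longer than
#' expected; tandem duplications emit everted (RF) pairs; inversions emit
#' same-strand pairs; inter-chromosomal variants emit pairs with mates on
#' different chromosomes.
#'
#' @param truth_svs data.frame with columns `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `type` (`deletion`, `duplication`, `inversion`,
#'   `inter_chromosomal`) and optionally `germline` (logical).
#' @param depth supporting read pairs (and clipped reads per breakpoint)
#'   per variant; 0 gives empty evidence.
#' @param insert_mean,insert_sd insert-size distribution of the library.
#' @param germline_fraction if `truth_svs` has no `germline` column, the
#'   fraction of variants made germline (chosen deterministically from
#'   the seed).
#' @param seed integer seed.
#' @param read_len read length used to place reads and clips.
#' @param clip_bases aligned clipped-base count attached to clipped
#'   reads.
#' @param noise_rate background discordant pairs per Mb of genome span.
#' @param genome optional data.frame (`chrom`, `length`) for noise
#'   placement; defaults to the span of the planted variants plus 10%.
#' @return list with `tumour` and `normal` evidence data.frames (columns
#'   `id`, `kind` (`pair`/`clip`), `chrom`, `pos`, `strand`, `clip_side`,
#'   `clip_bases`, `mate_chrom`, `mate_pos`, `mate_strand`, `insert`,
#'   `sv_id` — the generating variant, `NA` for noise) and `truth` (the
#'   truth table with the germline flag resolved).
#' @export
simulate_sv_read_evidence <- function(truth_svs, depth = 10,
                                      insert_mean = 350, insert_sd = 50,
                                      germline_fraction = 0,
                                      seed = 1L,
                                      read_len = 100,
                                      clip_bases = 25,
                                      noise_rate = 0,
                                      genome = NULL) {
  if (depth < 0) stop("`depth` must be non-negative", call. = FALSE)
  need <- c("chrom1", "pos1", "chrom2", "pos2", "type")
  stopifnot(all(need %in% names(truth_svs)))
  bad <- !truth_svs$type %in% c("deletion", "duplication", "inversion",
                                "inter_chromosomal")
  if (any(bad)) stop("unknown SV type(s): ",
                     paste(unique(truth_svs$type[bad]), collapse = ", "),
                     call. = FALSE)
  with_seed(seed, {
    tr <- truth_svs
    if (is.null(tr$germline)) {
      tr$germline <- seq_len(nrow(tr)) %in%
        sample(nrow(tr), round(germline_fraction * nrow(tr)))
    }
    if (is.null(genome)) {
      genome <- local({
        ch <- unique(c(tr$chrom1, tr$chrom2))
        len <- vapply(ch, function(cc) {
          max(tr$pos1[tr$chrom1 == cc], tr$pos2[tr$chrom2 == cc], 1e6) * 1.1
        }, 0.0)
        data.frame(chrom = ch, length = len)
      })
    }
    tumour <- list()
    normal <- list()
    for (i in seq_len(nrow(tr))) {
      ev <- sv_supporting_evidence(tr[i, ], i, depth, insert_mean,
                                   insert_sd, read_len, clip_bases)
      tumour[[length(tumour) + 1L]] <- ev
      if (tr$germline[i]) {
        # fresh draws: the normal sees its own reads for the same event
        normal[[length(normal) + 1L]] <-
          sv_supporting_evidence(tr[i, ], i, depth, insert_mean,
                                 insert_sd, read_len, clip_bases)
      }
    }
    tumour[[length(tumour) + 1L]] <-
      sv_noise_evidence(genome, noise_rate, insert_mean, insert_sd)
    normal[[length(normal) + 1L]] <-
      sv_noise_evidence(genome, noise_rate, insert_mean, insert_sd)
    list(tumour = finish_evidence(tumour),
         normal = finish_evidence(normal),
         truth = tr)
  })
}

empty_evidence <- function() {
  data.frame(id = character(), kind = character(), chrom = character(),
             pos = numeric(), strand = character(), clip_side = character(),
             clip_bases = numeric(), mate_chrom = character(),
             mate_pos = numeric(), mate_strand = character(),
             insert = numeric(), sv_id = integer())
}

finish_evidence <- function(parts) {
  parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0,
                        TRUE)]
  if (!length(parts)) return(empty_evidence())
  ev <- do.call(rbind, parts)
  ev$id <- sprintf("r%06d", seq_len(nrow(ev)))
  rownames(ev) <- NULL
  ev
}

# evidence for one variant: `depth` discordant pairs + clips at each end
sv_supporting_evidence <- function(sv, sv_id, depth, insert_mean,
                                   insert_sd, read_len, clip_bases) {
  if (depth == 0) return(NULL)
  n <- depth
  gap <- pmax(20, round(runif(n, read_len + 10, insert_mean)))
  off1 <- sv$pos1 - gap              # read 1 aligns left of breakpoint 1
  off2 <- sv$pos2 + gap - read_len   # read 2 right of breakpoint 2
  conf <- switch(sv$type,
    deletion = list(s1 = "+", s2 = "-", c1 = "right", c2 = "left"),
    duplication = list(s1 = "-", s2 = "+", c1 = "left", c2 = "right"),
    inversion = list(s1 = "+", s2 = "+", c1 = "right", c2 = "right"),
    inter_chromosomal = list(s1 = "+", s2 = "-", c1 = "right", c2 = "left"))
  pairs <- data.frame(
    id = NA_character_, kind = "pair",
    chrom = sv$chrom1, pos = off1, strand = conf$s1,
    clip_side = "none", clip_bases = 0,
    mate_chrom = sv$chrom2, mate_pos = off2, mate_strand = conf$s2,
    insert = ifelse(sv$chrom1 == sv$chrom2,
                    abs(off2 + read_len - off1), NA_real_),
    sv_id = sv_id)
  clips <- rbind(
    data.frame(id = NA_character_, kind = "clip", chrom = sv$chrom1,
               pos = sv$pos1, strand = conf$s1, clip_side = conf$c1,
               clip_bases = clip_bases, mate_chrom = NA_character_,
               mate_pos = NA_real_, mate_strand = NA_character_,
               insert = NA_real_, sv_id = sv_id)[rep(1, depth), ],
    data.frame(id = NA_character_, kind = "clip", chrom = sv$chrom2,
               pos = sv$pos2, strand = conf$s2, clip_side = conf$c2,
               clip_bases = clip_bases, mate_chrom = NA_character_,
               mate_pos = NA_real_, mate_strand = NA_character_,
               insert = NA_real_, sv_id = sv_id)[rep(1, depth), ])
  rbind(pairs, clips)
}

# scattered discordant pairs with random partners (uniform background)
sv_noise_evidence <- function(genome, noise_rate, insert_mean, insert_sd) {
  n <- round(noise_rate * sum(genome$length) / 1e6)
  if (n == 0) return(NULL)
  ch1 <- sample(genome$chrom, n, replace = TRUE)
  ch2 <- sample(genome$chrom, n, replace = TRUE)
  len1 <- genome$length[match(ch1, genome$chrom)]
  len2 <- genome$length[match(ch2, genome$chrom)]
  data.frame(
    id = NA_character_, kind = "pair",
    chrom = ch1, pos = round(runif(n, 1, len1)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    clip_side = "none", clip_bases = 0,
    mate_chrom = ch2, mate_pos = round(runif(n, 1, len2)),
    mate_strand = sample(c("+", "-"), n, replace = TRUE),
    insert = round(runif(n, 3 * insert_mean, 50 * insert_mean)),
    sv_id = NA_integer_)
}
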