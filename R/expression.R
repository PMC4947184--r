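#' Simulate expression profiles with four planted sample groups
#'
#' Generates a probes-by-samples matrix with four sample groups. A block
#' of informative genes carries group-specific mean shifts of magnitude
#' `effect_size` (in noise standard deviations): group-marker genes are
#' elevated in one group each, and two disjoint gradient gene sets run in
#' opposite directions across the group order A < B < C < D (emulating
#' opposed luminal-differentiation signatures). The remaining genes are
#' exchangeable noise.
#'
#' @param n_per_group integer vector of 4 group sizes.
#' @param n_genes total number of genes.
#' @param n_informative number of informative genes (multiple of 8
#'   recommended; half are group markers, half gradient genes).
#' @param effect_size magnitude of the planted shifts, in units of the
#'   noise standard deviation; 0 removes all structure.
#' @param seed integer seed.
#' @param base_mean,base_sd distribution of per-gene baseline levels.
#' @param noise_sd within-group standard deviation.
#' @return list with `matrix` (genes x samples), `labels` (factor
#'   A/B/C/D per sample), `gene_sets` (list `grad_up`, `grad_down`:
#'   disjoint sets with opposing group gradients) and `informative`
#'   (all informative gene ids).
#' @export
simulate_expression_groups <- function(n_per_group = c(25, 25, 25, 24),
                                       n_genes = 20000,
                                       n_informative = 160,
                                       effect_size = 3,
                                       seed = 1L,
                                       base_mean = 7, base_sd = 0.5,
                                       noise_sd = 1) {
  if (length(n_per_group) != 4) {
    stop("`n_per_group` must have exactly 4 counts", call. = FALSE)
  }
  if (n_informative > n_genes) {
    stop("`n_informative` exceeds `n_genes`", call. = FALSE)
  }
  with_seed(seed, {
    n_samples <- sum(n_per_group)
    labels <- factor(rep(LETTERS[1:4], n_per_group))
    genes <- sprintf("g%05d", seq_len(n_genes))
    mu <- rnorm(n_genes, base_mean, base_sd)
    m <- matrix(rnorm(n_genes * n_samples, 0, noise_sd), n_genes,
                n_samples) + mu
    rownames(m) <- genes
    colnames(m) <- sprintf("s%03d", seq_len(n_samples))
    info <- sample(genes, n_informative)
    n_marker <- 4 * floor(n_informative * 3 / 16)   # 3/4 group markers
    markers <- split(info[seq_len(n_marker)],
                     rep(1:4, length.out = n_marker))
    grad <- info[(n_marker + 1):n_informative]
    grad_up <- grad[seq_len(floor(length(grad) / 2))]
    grad_down <- setdiff(grad, grad_up)
    shift <- effect_size * noise_sd
    for (g in 1:4) {
      m[markers[[g]], labels == LETTERS[g]] <-
        m[markers[[g]], labels == LETTERS[g]] + shift
    }
    gradient <- (as.integer(labels) - 2.5) / 1.5   # -1 .. 1 across A..D
    m[grad_up, ] <- m[grad_up, ] +
      matrix(shift * gradient, length(grad_up), n_samples, byrow = TRUE)
    m[grad_down, ] <- m[grad_down, ] -
      matrix(shift * gradient, length(grad_down), n_samples, byrow = TRUE)
    list(matrix = m, labels = labels,
         gene_sets = list(grad_up = grad_up, grad_down = grad_down),
         informative = info)
  })
}

#' Filter probesets by variance test and relative standard deviation
#'
#' Retains features that satisfy both criteria: (a) a variance test
#' against the median feature variance — the statistic
#' \eqn{(n-1) s_g^2 / s^2_{median}} is referred to the upper tail of a
#' chi-square distribution with \eqn{n-1} degrees of freedom and must
#' reach `var_p`; and (b) membership in the top `top_fraction` of
#' features ordered by relative standard deviation (sd/|mean|).
#'
#' @param m numeric matrix, features x samples.
#' @param var_p P-value threshold of the variance test.
#' @param top_fraction fraction of features retained by relative
#'   standard deviation (default 5 per mille).
#' @return the filtered matrix. If nothing passes (e.g. a constant
#'   matrix) a zero-row matrix is returned with attribute
#'   `status = "no features retained"`.
#' @export
filter_probesets <- function(m, var_p = 1e-3, top_fraction = 0.005) {
  if (ncol(m) < 2) stop("need >= 2 samples", call. = FALSE)
  n <- ncol(m)
  v <- apply(m, 1, var)
  med <- median(v)
  crit_a <- if (med > 0) {
    pchisq((n - 1) * v / med, df = n - 1, lower.tail = FALSE) < var_p
  } else {
    v > 0   # degenerate: only non-constant features can qualify
  }
  mu <- rowMeans(m)
  rel_sd <- ifelse(mu == 0, ifelse(v > 0, Inf, 0), sqrt(v) / abs(mu))
  n_top <- ceiling(top_fraction * nrow(m))
  crit_b <- rank(-rel_sd, ties.method = "first") <= n_top
  keep <- crit_a & crit_b
  out <- m[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    attr(out, "status") <- "no features retained"
  }
  out
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of samples with one minus the Pearson
#' correlation as dissimilarity and Ward's minimum-variance linkage,
#' cut into `k` clusters.
#'
#' @param m numeric matrix, features x samples (typically filtered with
#'   [filter_probesets()]).
#' @param k number of clusters (>= 2, <= number of samples).
#' @return integer cluster labels named by sample.
#' @export
cluster_expression <- function(m, k = 4) {
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (k > ncol(m)) stop("`k` exceeds the number of samples", call. = FALSE)
  d <- as.dist(1 - cor(m, method = "pearson"))
  cutree(hclust(d, method = "ward.D2"), k = k)
}

#' Per-group centroids on the centred-reduced matrix
#'
#' Centres and reduces each feature across samples (mean 0, sd 1) and
#' averages the standardized profiles within each group.
#'
#' @param m numeric matrix, features x samples.
#' @param labels group label per sample.
#' @return object of class `centroids`: matrix features x groups,
#'   with the group labels as column names.
#' @export
compute_group_centroids <- function(m, labels) {
  labels <- as.factor(labels)
  if (length(labels) != ncol(m)) {
    stop("one label per sample required", call. = FALSE)
  }
  if (any(table(labels) == 0)) {
    stop("empty group(s): ",
         paste(levels(labels)[table(labels) == 0], collapse = ", "),
         call. = FALSE)
  }
  sdv <- apply(m, 1, sd)
  z <- (m - rowMeans(m)) / ifelse(sdv == 0, 1, sdv)
  cen <- vapply(levels(labels), function(g) {
    rowMeans(z[, labels == g, drop = FALSE])
  }, numeric(nrow(m)))
  structure(cen, class = c("centroids", class(cen)))
}

#' Single-sample-predictor classification against group centroids
#'
#' Computes the Spearman rank correlation of a profile with each group
#' centroid and assigns the group with the largest coefficient, or no
#' group (`"O"`) when the largest coefficient is below `threshold`.
#' Ties break towards the first group in column order (A < B < C < D).
#'
#' @param profile named numeric vector (one sample) or features x
#'   samples matrix.
#' @param centroids a [compute_group_centroids()] result.
#' @param threshold minimum correlation for an assignment.
#' @return data.frame with `sample`, `label`, `rho` (correlation to the
#'   winning centroid).
#' @export
ssp_classify <- function(profile, centroids, threshold = 0.1) {
  if (is.matrix(profile) && !inherits(profile, "centroids")) {
    out <- do.call(rbind, lapply(seq_len(ncol(profile)), function(j) {
      ssp_classify(setNames(profile[, j], rownames(profile)), centroids,
                   threshold)
    }))
    out$sample <- colnames(profile) %||% paste0("s", seq_len(ncol(profile)))
    return(out)
  }
  feats <- intersect(names(profile), rownames(centroids))
  if (length(feats) == 0) {
    stop("no feature overlap between profile and centroids",
         call. = FALSE)
  }
  rho <- apply(centroids[feats, , drop = FALSE], 2, function(ctr) {
    cor(profile[feats], ctr, method = "spearman")
  })
  best <- which.max(rho)   # first maximum = fixed label-order tie-break
  data.frame(sample = NA_character_,
             label = if (rho[best] < threshold) "O" else names(rho)[best],
             rho = unname(rho[best]))
}

#' Cluster-label stability score
#'
#' Measures how well unsupervised clusters respect known labels: the
#' fraction of the most abundant label in each cluster, aggregated over
#' clusters weighted by cluster size — 1 when every cluster is composed
#' of a single label, about 1/k when labels are spread at random over k
#' equally sized clusters.
#'
#' @param assignments known labels per sample.
#' @param clusters cluster ids per sample.
#' @return fraction in \[0, 1\].
#' @export
cluster_stability <- function(assignments, clusters) {
  if (length(assignments) == 0 || length(assignments) != length(clusters)) {
    stop("`assignments` and `clusters` must be non-empty and aligned",
         call. = FALSE)
  }
  tab <- table(assignments, clusters)
  sum(apply(tab, 2, max)) / length(assignments)
}

#' Single-sample gene-set enrichment score
#'
#' Rank-normalizes the expression values of one sample and scores a gene
#' set as the summed difference between the empirical cumulative
#' distribution functions of the set genes and of the remaining genes
#' along the expression-ranked gene list. The score is positive when the
#' set genes concentrate at high expression.
#'
#' @param profile named numeric vector of expression values.
#' @param gene_set character vector of gene ids; must overlap the
#'   profile and must not cover all of it (the complement ECDF would be
#'   undefined).
#' @return numeric enrichment score.
#' @export
ssgsea_score <- function(profile, gene_set) {
  in_set <- names(profile) %in% gene_set
  if (!any(in_set)) stop("gene set does not overlap the profile",
                         call. = FALSE)
  if (all(in_set)) stop("gene set covers every gene in the profile",
                        call. = FALSE)
  r <- rank(profile, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  ind <- in_set[ord]
  p_in <- cumsum(ind) / sum(ind)
  p_out <- cumsum(!ind) / sum(!ind)
  sum(p_in - p_out)
}
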