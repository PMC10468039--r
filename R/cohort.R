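#' Compare PT curves between cohorts
#'
#' Per threshold tau, a Welch two-sample t-test compares the non-relapsing
#' and relapsing groups, separately on bar counts and on percentages. No
#' multiple-testing correction is applied by default, matching the pointwise
#' presentation of cohort PT-curve comparisons; Benjamini-Hochberg adjustment
#' is available behind `adjust = "BH"` and the report is labelled
#' accordingly. When both groups have zero variance at a tau, the test is
#' degenerate: p is set to 1 if the means agree and 0 otherwise, and the
#' position is flagged.
#'
#' @param nr list of `pt_curve` for the non-relapsing group (>= 2).
#' @param r list of `pt_curve` for the relapsing group (>= 2).
#' @param alpha significance level for the range-wise flag (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `cohort_comparison`: data frame with per-tau group means, sds and
#'   p-values (counts and percentages), plus attributes `alpha`,
#'   `significant_all` (all taus significant on counts), `adjust` and group
#'   sizes.
#' @export
compare_pt_curves <- function(nr, r, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(nr) < 2 || length(r) < 2)
    stop("need at least 2 patients per group")
  tau <- nr[[1]]$tau
  for (cv in c(nr, r))
    if (length(cv$tau) != length(tau) || any(cv$tau != tau))
      stop("tau grid mismatch across curves")
  mat <- function(curves, what)
    do.call(rbind, lapply(curves, `[[`, what))
  welch <- function(a, b) {
    # a, b: per-group vectors at one tau
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(list(p = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0,
                  degenerate = TRUE))
    list(p = stats::t.test(a, b)$p.value, degenerate = FALSE)
  }
  per_tau <- function(what) {
    A <- mat(nr, what); B <- mat(r, what)
    res <- lapply(seq_along(tau), function(j) welch(A[, j], B[, j]))
    list(p = vapply(res, `[[`, numeric(1), "p"),
         degenerate = vapply(res, `[[`, logical(1), "degenerate"),
         mean_nr = colMeans(A), mean_r = colMeans(B),
         sd_nr = apply(A, 2, stats::sd), sd_r = apply(B, 2, stats::sd))
  }
  cnt <- per_tau("count")
  pct <- per_tau("percentage")
  p_count <- cnt$p
  p_pct <- pct$p
  if (adjust == "BH") {
    p_count <- stats::p.adjust(p_count, "BH")
    p_pct <- stats::p.adjust(p_pct, "BH")
  }
  out <- data.frame(tau = tau,
                    mean_count_nr = cnt$mean_nr, mean_count_r = cnt$mean_r,
                    sd_count_nr = cnt$sd_nr, sd_count_r = cnt$sd_r,
                    p_count = p_count, degenerate_count = cnt$degenerate,
                    mean_pct_nr = pct$mean_nr, mean_pct_r = pct$mean_r,
                    p_pct = p_pct, degenerate_pct = pct$degenerate)
  structure(out, class = c("cohort_comparison", "data.frame"),
            alpha = alpha, adjust = adjust,
            n_nr = length(nr), n_r = length(r), dimension = nr[[1]]$dim,
            significant_all = all(p_count < alpha))
}

#' Cluster-count sanity check for dimension-0 persistence
#'
#' Connected components in dimension-0 persistent homology correspond to
#' clusters of cells in phenotype space. As an independent check, seeded
#' k-means is run for each k in `k_range` and the k maximising the mean
#' silhouette width is reported per cloud. (A self-organising-map clustering
#' step used in clinical workflows is deliberately not reimplemented; this is
#' a generic substitute.)
#'
#' Selection prefers parsimony: the smallest k whose mean silhouette is
#' within `margin` of the best is chosen, since the silhouette profile of a
#' single homogeneous cluster is nearly flat and its argmax is unstable.
#'
#' @param clouds list of rescaled [point_cloud()] objects.
#' @param k_range integer candidate cluster numbers (all >= 2).
#' @param seed RNG seed.
#' @param margin silhouette tolerance for the parsimony rule (default 0.05).
#' @return Integer vector of selected cluster counts, one per cloud.
#' @export
cluster_count_check <- function(clouds, k_range = 2:8, seed = 1L,
                                margin = 0.05) {
  k_range <- as.integer(k_range)
  if (length(k_range) < 1 || any(k_range < 2))
    stop("k_range must contain integers >= 2")
  vapply(seq_along(clouds), function(i) {
    cl <- clouds[[i]]
    assert_cloud(cl)
    v <- cl$values
    if (nrow(v) <= max(k_range)) stop("cloud too small for k_range")
    d <- as.matrix(stats::dist(v))
    scores <- vapply(k_range, function(k) {
      km <- with_seed(seed + i, stats::kmeans(v, centers = k, nstart = 5,
                                              iter.max = 50))
      mean_silhouette(d, km$cluster)
    }, numeric(1))
    k_range[which(scores >= max(scores) - margin)[1]]
  }, integer(1))
}

# mean silhouette width from a dense distance matrix and a cluster labelling
mean_silhouette <- function(d, cluster) {
  ks <- sort(unique(cluster))
  if (length(ks) < 2) return(-1)
  n <- nrow(d)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster[i]
    same <- which(cluster == own)
    a <- if (length(same) > 1) sum(d[i, same]) / (length(same) - 1) else 0
    b <- min(vapply(ks[ks != own], function(k) {
      mean(d[i, cluster == k])
    }, numeric(1)))
    sil[i] <- if (length(same) > 1) (b - a) / max(a, b) else 0
  }
  mean(sil)
}
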