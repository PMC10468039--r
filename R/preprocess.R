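#' Quantile rescaling of marker intensities
#'
#' Rescales every marker column so that its 0.001 quantile maps to 0 and its
#' 0.999 quantile maps to 1: `x' = (x - q_low) / (q_high - q_low)`. The
#' extreme quantiles (rather than min/max) damp the influence of outliers,
#' which would otherwise introduce spurious topological features. Values are
#' deliberately NOT clipped: points beyond the quantiles map outside \[0, 1\],
#' preserving the affine geometry that persistent homology sees. Quantiles
#' use linear interpolation between order statistics (R's default type 7).
#'
#' @param cloud a [point_cloud()].
#' @param params optional `rescale_params` from a previous call, to reuse the
#'   same affine map (e.g. on held-out data).
#' @return A list with elements `cloud` (rescaled) and `params`
#'   (`rescale_params`: per-marker `q_low`, `q_high`, and the quantile rule).
#' @export
quantile_rescale <- function(cloud, params = NULL) {
  assert_cloud(cloud)
  v <- cloud$values
  if (is.null(params)) {
    if (nrow(v) < 2) stop("need at least 2 cells to estimate quantiles")
    q <- apply(v, 2, stats::quantile, probs = c(0.001, 0.999),
               names = FALSE, type = 7)
    params <- structure(list(q_low = q[1, ], q_high = q[2, ],
                             markers = cloud$markers, quantile_type = 7L),
                        class = "rescale_params")
  }
  degenerate <- params$q_high <= params$q_low
  if (any(degenerate))
    stop("degenerate marker(s) (q0.999 <= q0.001): ",
         paste(cloud$markers[degenerate], collapse = ", "))
  scaled <- sweep(sweep(v, 2, params$q_low, "-"), 2,
                  params$q_high - params$q_low, "/")
  list(cloud = point_cloud(scaled, markers = cloud$markers,
                           patient_id = cloud$patient_id),
       params = params)
}

#' Gate on CD19 to select the B-cell subpopulation
#'
#' Keeps cells whose (rescaled) CD19 intensity is greater than or equal to
#' the threshold. The default threshold of 0.5 on rescaled intensities is a
#' documented placeholder for a laboratory-calibrated gate and triggers a
#' warning when relied upon.
#'
#' @param cloud a rescaled [point_cloud()] containing a `CD19` column.
#' @param threshold gate position on the rescaled CD19 axis.
#' @param marker gate marker name, default `"CD19"`.
#' @return The gated cloud; attribute `retained_fraction` records the fraction
#'   of cells kept.
#' @export
gate_cd19 <- function(cloud, threshold = 0.5, marker = "CD19") {
  assert_cloud(cloud)
  if (!marker %in% cloud$markers)
    stop("marker '", marker, "' not present; cannot gate")
  if (missing(threshold))
    warning("gate_cd19: using default placeholder threshold 0.5; ",
            "calibrate the CD19 gate for real data")
  keep <- cloud$values[, marker] >= threshold
  if (!any(keep)) stop("no cells pass gate: all ", marker, " < ", threshold)
  out <- point_cloud(cloud$values[keep, , drop = FALSE],
                     markers = cloud$markers, patient_id = cloud$patient_id)
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Uniform subsampling of a point cloud
#'
#' Draws `n` rows uniformly without replacement when the cloud is larger than
#' `n`, otherwise returns the cloud unchanged. Deterministic given `seed`.
#'
#' @param cloud a [point_cloud()].
#' @param n target number of cells (>= 1).
#' @param seed integer RNG seed.
#' @return The subsampled cloud.
#' @export
subsample_cells <- function(cloud, n, seed = 1L) {
  assert_cloud(cloud)
  if (n < 1) stop("n must be >= 1")
  if (n >= n_cells(cloud)) return(cloud)
  idx <- with_seed(seed, sample.int(n_cells(cloud), n))
  point_cloud(cloud$values[idx, , drop = FALSE], markers = cloud$markers,
              patient_id = cloud$patient_id)
}

#' Max-min (farthest-point) landmark selection
#'
#' Greedy k-center landmarking: starting from `start`, iteratively add the
#' point whose distance to the current landmark set is largest (ties broken
#' by lowest row index). The classic greedy rule guarantees a covering radius
#' within a factor 2 of the optimal k-center radius. Euclidean metric on all
#' marker columns.
#'
#' @param cloud a [point_cloud()].
#' @param k number of landmarks (`k <= n_cells`).
#' @param start starting row index (default 1 for determinism), or
#'   `"random"` with `seed` for a seeded random start.
#' @param seed RNG seed used when `start = "random"`.
#' @return A `landmark_set`: list with `indices` (ordered row indices),
#'   `covering_radius` (max over cloud points of distance to the nearest
#'   landmark) and `cloud` (the landmark sub-cloud).
#' @export
maxmin_landmarks <- function(cloud, k, start = 1L, seed = 1L) {
  assert_cloud(cloud)
  n <- n_cells(cloud)
  if (k > n) stop("k (", k, ") exceeds number of cells (", n, ")")
  if (k < 1) stop("k must be >= 1")
  if (identical(start, "random"))
    start <- with_seed(seed, sample.int(n, 1))
  start <- as.integer(start)
  if (start < 1 || start > n) stop("start index out of range")
  v <- cloud$values
  idx <- integer(k)
  idx[1] <- start
  # running min squared distance to the landmark set
  d2 <- rowSums(sweep(v, 2, v[start, ], "-")^2)
  if (k > 1) {
    for (i in 2:k) {
      nxt <- which.max(d2)  # ties: lowest index (which.max contract)
      idx[i] <- nxt
      d2 <- pmin(d2, rowSums(sweep(v, 2, v[nxt, ], "-")^2))
    }
  } else {
    d2 <- pmin(d2, d2)
  }
  structure(list(indices = idx,
                 covering_radius = sqrt(max(d2)),
                 cloud = point_cloud(v[idx, , drop = FALSE],
                                     markers = cloud$markers,
                                     patient_id = cloud$patient_id)),
            class = "landmark_set")
}

#' Project a cloud onto a pair of markers
#'
#' @param cloud a [point_cloud()].
#' @param m1,m2 marker names.
#' @return A two-column [point_cloud()] preserving row order.
#' @export
project_pair <- function(cloud, m1, m2) {
  assert_cloud(cloud)
  missing <- setdiff(c(m1, m2), cloud$markers)
  if (length(missing) > 0)
    stop("unknown marker(s): ", paste(missing, collapse = ", "))
  point_cloud(cloud$values[, c(m1, m2), drop = FALSE], markers = c(m1, m2),
              patient_id = cloud$patient_id)
}

#' Enumerate marker pairs in deterministic order
#'
#' All 2-subsets of the marker list, enumerated with the markers sorted
#' alphabetically, so that pair ordering is reproducible across runs.
#'
#' @param markers character vector of marker names.
#' @return A data frame with columns `m1`, `m2` and `pair` (label
#'   `"m1-m2"`).
#' @export
marker_pairs <- function(markers) {
  markers <- sort(unique(as.character(markers)))
  if (length(markers) < 2) stop("need at least two markers")
  cmb <- utils::combn(markers, 2)
  data.frame(m1 = cmb[1, ], m2 = cmb[2, ],
             pair = paste(cmb[1, ], cmb[2, ], sep = "-"),
             stringsAsFactors = FALSE)
}

#' Standard preprocessing pipeline
#'
#' Applies, in fixed order: quantile rescaling, CD19 gating, uniform
#' subsampling to `n_cells`, and max-min landmarking to `n_landmarks` on the
#' requested analysis markers (geometric markers FSC-A/SSC-A are always
#' excluded from the landmark metric).
#'
#' @param cloud raw [point_cloud()].
#' @param markers analysis markers for landmarking (default: all non-geometric
#'   markers except the gate marker).
#' @param n_cells subsample size (default 1e5).
#' @param n_landmarks number of landmarks (default 1e4).
#' @param cd19_threshold gate threshold (default 0.5; placeholder warning
#'   suppressed here because the caller states it explicitly).
#' @param seed RNG seed for the subsampling step.
#' @return A list with `landmarks` (a `landmark_set`), `cloud` (the gated,
#'   subsampled, rescaled full cloud) and `params` (`rescale_params`).
#' @export
preprocess_cloud <- function(cloud, markers = NULL, n_cells = 1e5,
                             n_landmarks = 1e4, cd19_threshold = 0.5,
                             seed = 1L) {
  rs <- quantile_rescale(cloud)
  gated <- gate_cd19(rs$cloud, threshold = cd19_threshold)
  sub <- subsample_cells(gated, n = n_cells, seed = seed)
  if (is.null(markers))
    markers <- setdiff(sub$markers, c("FSC-A", "SSC-A", "CD19"))
  markers <- setdiff(markers, c("FSC-A", "SSC-A"))
  analysis <- point_cloud(sub$values[, markers, drop = FALSE],
                          markers = markers, patient_id = sub$patient_id)
  lm <- maxmin_landmarks(analysis, k = min(n_landmarks, n_cells(analysis)))
  list(landmarks = lm, cloud = sub, params = rs$params)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
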