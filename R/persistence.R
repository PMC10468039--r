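new_barcode <- function(dimension, birth, death) {
  stopifnot(length(dimension) == length(birth), length(birth) == length(death))
  df <- data.frame(dimension = as.integer(dimension), birth = as.numeric(birth),
                   death = as.numeric(death))
  class(df) <- c("barcode", "data.frame")
  df
}

#' Extract the finite bars of a barcode in one homology dimension
#'
#' The essential (infinite-death) dimension-0 bar is retained in barcodes but
#' excluded from every downstream summary; this accessor is the single point
#' where that convention is applied.
#'
#' @param barcode a `barcode` data frame.
#' @param dim homology dimension.
#' @return Two-column matrix (`birth`, `death`) of finite bars.
#' @export
finite_bars <- function(barcode, dim) {
  sub <- barcode[barcode$dimension == dim & is.finite(barcode$death), ,
                 drop = FALSE]
  cbind(birth = sub$birth, death = sub$death)
}

#' Euclidean distance matrix of a point cloud
#'
#' @param cloud a finite [point_cloud()].
#' @return Symmetric dense matrix of pairwise Euclidean distances.
#' @export
distance_matrix <- function(cloud) {
  assert_cloud(cloud)
  if (n_cells(cloud) < 1) stop("cloud must contain at least one point")
  as.matrix(stats::dist(cloud$values))
}

#' Zero-dimensional persistence (connected components)
#'
#' All components are born at filtration value 0; finite deaths equal, as a
#' multiset, the edge weights of a minimum spanning tree of the complete
#' weighted graph on the points (single-linkage merge heights). Exactly one
#' essential bar `[0, Inf)` records the component that survives the whole
#' filtration. Zero-persistence bars (duplicate points) are dropped.
#'
#' @param dm distance matrix (as from [distance_matrix()]) or a
#'   [point_cloud()].
#' @return A `barcode` with dimension-0 rows only.
#' @export
persistence_dim0 <- function(dm) {
  dm <- as_distance_matrix(dm)
  res <- .vr_persistence_cpp(dm, 0L, Inf)
  bars_to_barcode(res)
}

#' Vietoris-Rips persistent homology
#'
#' Computes barcodes in dimensions 0..`maxdim` for the Vietoris-Rips
#' filtration: a simplex enters at the largest pairwise distance among its
#' vertices. Persistence pairing is the standard boundary-matrix column
#' reduction over Z/2 with simplices ordered by (filtration value, dimension,
#' lexicographic vertex order); zero-persistence pairs are dropped at source.
#' The dimension-0 block is computed by union-find and is identical to
#' [persistence_dim0()].
#'
#' The number of simplices `C(n,2) + C(n,3) [+ C(n,4)]` is checked against
#' `budget` before any allocation; oversize instances fail with an
#' instruction to reduce the landmark count rather than being silently
#' subsampled.
#'
#' @param dm distance matrix or [point_cloud()].
#' @param maxdim maximum homology dimension, 1 or 2.
#' @param budget simplex budget guard (default 2e7).
#' @return A `barcode` data frame with columns `dimension`, `birth`, `death`
#'   (death `Inf` for essential classes).
#' @export
persistence_vr <- function(dm, maxdim = 1L, budget = 2e7) {
  if (!maxdim %in% c(1L, 2L)) stop("maxdim must be 1 or 2")
  dm <- as_distance_matrix(dm)
  res <- .vr_persistence_cpp(dm, as.integer(maxdim), budget)
  bars_to_barcode(res)
}

as_distance_matrix <- function(dm) {
  if (inherits(dm, "point_cloud")) dm <- distance_matrix(dm)
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  storage.mode(dm) <- "double"
  dm
}

bars_to_barcode <- function(res) {
  dims <- seq_along(res) - 1L
  parts <- lapply(dims, function(d) {
    m <- res[[d + 1L]]
    new_barcode(rep(d, nrow(m)), m[, 1], m[, 2])
  })
  out <- do.call(rbind, parts)
  class(out) <- c("barcode", "data.frame")
  out
}

#' @export
print.barcode <- function(x, ...) {
  for (d in sort(unique(x$dimension))) {
    k <- sum(x$dimension == d)
    ki <- sum(x$dimension == d & is.infinite(x$death))
    cat("dim ", d, ": ", k, " bars (", ki, " essential)\n", sep = "")
  }
  invisible(x)
}
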