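#' Eight-dimensional barcode descriptor vector
#'
#' Summarises the finite bars of the dimension-0 and dimension-1 barcodes by
#' the maximum, minimum and mean persistence and the (population) standard
#' deviation, concatenated dimension 0 then dimension 1. An empty barcode in
#' a dimension yields an all-zero block with a warning.
#'
#' @param barcode a `barcode` data frame (dimensions 0 and 1 used).
#' @return Named numeric vector of length 8.
#' @export
descriptor_vector <- function(barcode) {
  block <- function(d) {
    bars <- finite_bars(barcode, d)
    p <- bars[, "death"] - bars[, "birth"]
    if (length(p) == 0) {
      warning("empty dimension-", d, " barcode: descriptor block set to zero")
      return(c(0, 0, 0, 0))
    }
    c(max(p), min(p), mean(p), sqrt(mean((p - mean(p))^2)))
  }
  out <- c(block(0L), block(1L))
  names(out) <- paste0(rep(c("dim0_", "dim1_"), each = 4),
                       c("max", "min", "mean", "sd"))
  out
}

#' Persistence-threshold (PT) curve
#'
#' For an evenly spaced grid of thresholds tau in `[tau_range[1],
#' tau_range[2]]` (inclusive endpoints), counts the finite bars whose
#' persistence (death - birth) is strictly greater than tau, together with
#' the percentage relative to the total number of finite bars in that
#' dimension (defined as 0 for an empty barcode).
#'
#' @param barcode a `barcode` data frame.
#' @param dim homology dimension the curve refers to.
#' @param tau_range length-2 numeric, `lo < hi`.
#' @param n_points number of grid points (default 20).
#' @return A `pt_curve`: list with `tau`, `count`, `percentage`, `dim`,
#'   `n_bars`.
#' @export
pt_curve <- function(barcode, dim, tau_range, n_points = 20L) {
  if (length(tau_range) != 2 || !(tau_range[1] < tau_range[2]))
    stop("tau_range must satisfy lo < hi")
  tau <- seq(tau_range[1], tau_range[2], length.out = n_points)
  bars <- finite_bars(barcode, dim)
  pers <- bars[, "death"] - bars[, "birth"]
  count <- vapply(tau, function(t) sum(pers > t), numeric(1))
  pct <- if (length(pers) == 0) rep(0, length(tau)) else count / length(pers)
  structure(list(tau = tau, count = count, percentage = pct,
                 dim = as.integer(dim), n_bars = length(pers)),
            class = "pt_curve")
}

#' Pointwise mean of PT curves
#'
#' @param curves list of `pt_curve` objects sharing the same tau grid.
#' @return A `pt_curve` with pointwise arithmetic means of counts and
#'   percentages (`n_bars` is the mean bar count).
#' @export
mean_pt_curve <- function(curves) {
  if (length(curves) == 0) stop("no curves supplied")
  tau <- curves[[1]]$tau
  for (cv in curves)
    if (length(cv$tau) != length(tau) || any(cv$tau != tau))
      stop("tau grid mismatch across curves")
  structure(list(tau = tau,
                 count = rowMeans(vapply(curves, `[[`, numeric(length(tau)), "count")),
                 percentage = rowMeans(vapply(curves, `[[`, numeric(length(tau)), "percentage")),
                 dim = curves[[1]]$dim,
                 n_bars = mean(vapply(curves, `[[`, numeric(1), "n_bars"))),
            class = "pt_curve")
}

#' Persistence image of a barcode
#'
#' Each finite bar `(b, d)` is mapped to birth-persistence coordinates
#' `(b, p = d - b)` and contributes an isotropic Gaussian of standard
#' deviation `spread`, weighted by the linear function `w(p) = p / p_max`
#' (vanishing at zero persistence, `p_max` = upper end of the persistence
#' axis of the domain). Pixel values are exact integrals of the weighted
#' Gaussian over each pixel, computed as products of one-dimensional Gaussian
#' CDF differences; the image is therefore additive in bars and stable under
#' small bar perturbations. The domain defaults to the unit square, making
#' images comparable across patients whose clouds were rescaled to \[0, 1\].
#'
#' @param barcode a `barcode` data frame.
#' @param dim homology dimension to image.
#' @param grid_size pixels per axis; one of 5, 10, 25, 50, 100.
#' @param spread Gaussian standard deviation (paper grid: 0.01 or 0.05).
#' @param domain list with `birth = c(lo, hi)` and `pers = c(lo, hi)` axis
#'   ranges; default unit square.
#' @return A `persistence_image`: list with `pixels` (grid_size x grid_size
#'   matrix, row = birth axis, column = persistence axis), `grid_size`,
#'   `spread`, `domain`, `weight`, `dim`.
#' @export
persistence_image <- function(barcode, dim, grid_size = 25L, spread = 0.05,
                              domain = list(birth = c(0, 1), pers = c(0, 1))) {
  if (spread <= 0) stop("spread must be positive")
  if (!grid_size %in% c(5L, 10L, 25L, 50L, 100L))
    stop("grid_size must be one of 5, 10, 25, 50, 100")
  bars <- finite_bars(barcode, dim)
  bx <- seq(domain$birth[1], domain$birth[2], length.out = grid_size + 1L)
  py <- seq(domain$pers[1], domain$pers[2], length.out = grid_size + 1L)
  pmax_domain <- domain$pers[2]
  img <- matrix(0, grid_size, grid_size)
  if (nrow(bars) > 0) {
    pers <- bars[, "death"] - bars[, "birth"]
    for (i in seq_len(nrow(bars))) {
      w <- pers[i] / pmax_domain
      if (w <= 0) next
      gx <- diff(stats::pnorm(bx, mean = bars[i, "birth"], sd = spread))
      gy <- diff(stats::pnorm(py, mean = pers[i], sd = spread))
      img <- img + w * outer(gx, gy)
    }
  }
  structure(list(pixels = img, grid_size = as.integer(grid_size),
                 spread = spread, domain = domain, weight = "linear",
                 dim = as.integer(dim)),
            class = "persistence_image")
}

#' Flatten persistence images into a feature vector
#'
#' Row-major flattening of each image, concatenated in increasing dimension
#' order (dim 0, then 1, then 2 when supplied). All images must share the
#' same grid size, spread and domain.
#'
#' @param images list of `persistence_image` objects (one per homology
#'   dimension).
#' @return Numeric feature vector of length `length(images) * grid_size^2`.
#' @export
pi_feature <- function(images) {
  if (length(images) == 0) stop("no images supplied")
  ref <- images[[1]]
  for (im in images) {
    if (im$grid_size != ref$grid_size || im$spread != ref$spread ||
        !identical(im$domain, ref$domain))
      stop("hyperparameter mismatch across persistence images")
  }
  ord <- order(vapply(images, `[[`, integer(1), "dim"))
  unlist(lapply(images[ord], function(im) as.vector(t(im$pixels))),
         use.names = FALSE)
}
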