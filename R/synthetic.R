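#' Specification for the synthetic cohort generator
#'
#' The generator emulates the qualitative relapse / non-relapse contrast seen
#' in diagnostic B-cell phenotype data: relapsing-like ("R") clouds are more
#' phenotypically diverse, with more isolated clusters and a wide persistent
#' loop (annulus) in the CD10-CD20 plane, while non-relapsing-like ("NR")
#' clouds are more homogeneous, their only loop structure being a narrow,
#' weakly persistent annulus in the CD38-CD45 plane. Cells are mixtures of
#' isotropic Gaussian blobs plus per-label annulus components embedded in a
#' named 2-marker plane (remaining coordinates blob-distributed), a small
#' uniform background-noise fraction, and a CD19 column in which a
#' configurable B-cell fraction sits above the gate. All values are clipped
#' to \[0, 1\].
#'
#' @param markers marker names; must include the ring-plane markers and
#'   `"CD19"`.
#' @param n_cells cells per patient (default 2000, the test profile).
#' @param n_clusters per-label integer vectors of candidate Gaussian-blob
#'   counts (NR fewer, R more).
#' @param rings per-label list of ring components; each has `plane` (two
#'   marker names), `centre`, `radius`, `sigma_r` (radial noise sd) and
#'   `fraction` (share of cells on the ring).
#' @param blob_sigma isotropic blob standard deviation.
#' @param noise_fraction uniform background fraction in `[0, 1)`.
#' @param bcell_fraction fraction of cells drawn above the CD19 gate.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(markers = c("CD10", "CD20", "CD38", "CD45", "CD19"),
                           n_cells = 2000L,
                           n_clusters = list(NR = 3:5, R = 4:6),
                           rings = list(
                             NR = list(list(plane = c("CD38", "CD45"),
                                            centre = c(0.5, 0.5),
                                            radius = 0.12, sigma_r = 0.02,
                                            fraction = 0.15)),
                             R = list(list(plane = c("CD10", "CD20"),
                                           centre = c(0.5, 0.5),
                                           radius = 0.25, sigma_r = 0.015,
                                           fraction = 0.35))),
                           blob_sigma = 0.03, noise_fraction = 0.005,
                           bcell_fraction = 0.95) {
  if (!"CD19" %in% markers) stop("markers must include CD19 (gate marker)")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("noise_fraction must be in [0, 1)")
  if (bcell_fraction <= 0 || bcell_fraction > 1)
    stop("bcell_fraction must be in (0, 1]")
  for (lab in names(rings)) for (rc in rings[[lab]]) {
    if (rc$radius <= 0) stop("ring radius must be positive")
    if (!all(rc$plane %in% markers))
      stop("ring plane markers missing from marker list: ",
           paste(rc$plane, collapse = ", "))
    room <- min(rc$centre, 1 - rc$centre)
    if (rc$radius + 3 * rc$sigma_r > room)
      stop("ring radius too large for the [0,1] domain (centre ",
           paste(rc$centre, collapse = ","), ", radius ", rc$radius, ")")
  }
  if (any(unlist(n_clusters) < 1)) stop("cluster counts must be >= 1")
  structure(list(markers = markers, n_cells = as.integer(n_cells),
                 n_clusters = n_clusters, rings = rings,
                 blob_sigma = blob_sigma, noise_fraction = noise_fraction,
                 bcell_fraction = bcell_fraction),
            class = "generator_spec")
}

#' Generate one synthetic patient point cloud
#'
#' @param spec a [generator_spec()].
#' @param label `"R"` or `"NR"`.
#' @param seed integer seed; the cloud is a deterministic function of
#'   `(spec, label, seed)`.
#' @param patient_id identifier for the cloud.
#' @return A [point_cloud()] with `spec$n_cells` rows, values in \[0, 1\].
#' @export
generate_patient <- function(spec, label = c("NR", "R"), seed = 1L,
                             patient_id = paste0(label, seed)) {
  label <- match.arg(label)
  stopifnot(inherits(spec, "generator_spec"))
  analysis <- setdiff(spec$markers, "CD19")
  d <- length(analysis)
  n <- spec$n_cells
  with_seed(seed, {
    rings <- spec$rings[[label]]
    if (is.null(rings)) rings <- list()
    n_ring <- vapply(rings, function(rc) round(rc$fraction * n), numeric(1))
    n_noise <- round(spec$noise_fraction * n)
    n_blob <- n - sum(n_ring) - n_noise
    if (n_blob < 0) stop("ring + noise fractions exceed 1")
    k <- if (length(spec$n_clusters[[label]]) == 1L)
      spec$n_clusters[[label]] else sample(spec$n_clusters[[label]], 1L)
    centres <- matrix(stats::runif(k * d, 0.15, 0.85), k, d)
    # keep each ring's hole empty in its own plane: a blob sitting inside the
    # annulus would fill the loop the generator is meant to create
    for (rc in rings) {
      i1 <- match(rc$plane[1], analysis)
      i2 <- match(rc$plane[2], analysis)
      clearance <- rc$radius + 3 * rc$sigma_r + 2 * spec$blob_sigma + 0.02
      for (ci in seq_len(k)) {
        tries <- 0
        while (sqrt((centres[ci, i1] - rc$centre[1])^2 +
                      (centres[ci, i2] - rc$centre[2])^2) < clearance &&
               tries < 100) {
          centres[ci, c(i1, i2)] <- stats::runif(2, 0.15, 0.85)
          tries <- tries + 1
        }
      }
    }
    rows <- vector("list", length(rings) + 2L)
    # Gaussian blobs
    assign_blob <- sample.int(k, n_blob, replace = TRUE)
    rows[[1]] <- centres[assign_blob, , drop = FALSE] +
      matrix(stats::rnorm(n_blob * d, 0, spec$blob_sigma), n_blob, d)
    # background noise
    rows[[2]] <- matrix(stats::runif(n_noise * d), n_noise, d)
    # annuli in named planes, other coordinates near a blob centre
    for (j in seq_along(rings)) {
      rc <- rings[[j]]
      m <- n_ring[j]
      theta <- stats::runif(m, 0, 2 * pi)
      rad <- stats::rnorm(m, rc$radius, rc$sigma_r)
      pts <- centres[rep(1L, m), , drop = FALSE] +
        matrix(stats::rnorm(m * d, 0, spec$blob_sigma), m, d)
      i1 <- match(rc$plane[1], analysis)
      i2 <- match(rc$plane[2], analysis)
      pts[, i1] <- rc$centre[1] + rad * cos(theta)
      pts[, i2] <- rc$centre[2] + rad * sin(theta)
      rows[[j + 2L]] <- pts
    }
    vals <- do.call(rbind, rows)
    colnames(vals) <- analysis
    # CD19: B cells above the gate, contaminants below
    is_b <- stats::runif(n) < spec$bcell_fraction
    cd19 <- ifelse(is_b, stats::rnorm(n, 0.8, 0.05), stats::rnorm(n, 0.2, 0.05))
    vals <- cbind(vals, CD19 = cd19)[, spec$markers, drop = FALSE]
    vals <- pmin(pmax(vals, 0), 1)
    point_cloud(vals, markers = spec$markers, patient_id = patient_id)
  })
}

#' Generate a labelled synthetic cohort
#'
#' Per-patient child seeds are drawn deterministically from the master seed.
#' Synthetic initial-risk groups are assigned so that about 85% of relapsing
#' patients carry a low or intermediate label (mirroring the clinical
#' observation that most relapses arise from the low-intermediate tier), and
#' a stratified discovery/validation split is recorded in the manifest.
#'
#' @param spec a [generator_spec()].
#' @param n_nr,n_r cohort sizes (defaults 80 and 16).
#' @param master_seed master RNG seed.
#' @param discovery_fraction share assigned to the discovery split (default
#'   0.52, mirroring a 50/46 split at n = 96).
#' @return A `synthetic_cohort`: list with `manifest` (a `cohort_manifest`
#'   without paths) and `clouds` (named list of [point_cloud()]).
#' @export
generate_cohort <- function(spec = generator_spec(), n_nr = 80L, n_r = 16L,
                            master_seed = 1L, discovery_fraction = 0.52) {
  if (n_nr < 1 || n_r < 1) stop("cohort counts must be >= 1")
  n <- n_nr + n_r
  labels <- c(rep("NR", n_nr), rep("R", n_r))
  ids <- sprintf("P%03d", seq_len(n))
  seeds <- with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
  risk <- with_seed(master_seed + 1L, {
    vapply(labels, function(lab) {
      if (lab == "R") {
        if (stats::runif(1) < 0.857)
          sample(c("low", "intermediate"), 1)
        else "high"
      } else {
        sample(c("low", "intermediate", "high"), 1, prob = c(0.5, 0.3, 0.2))
      }
    }, character(1))
  })
  disc <- stratified_split(labels, discovery_fraction,
                           seed = master_seed + 2L)
  manifest <- data.frame(patient_id = ids, label = labels, risk_group = risk,
                         split = ifelse(disc, "discovery", "validation"),
                         path = NA_character_, stringsAsFactors = FALSE)
  class(manifest) <- c("cohort_manifest", "data.frame")
  clouds <- lapply(seq_len(n), function(i) {
    generate_patient(spec, labels[i], seed = seeds[i], patient_id = ids[i])
  })
  names(clouds) <- ids
  structure(list(manifest = manifest, clouds = clouds, spec = spec,
                 master_seed = master_seed),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes one point-cloud file per patient (CSV by default, or FCS 3.0
#' fixtures) plus a `manifest.csv`, so the cohort can be consumed through the
#' file-based pipeline entry points.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"fcs"`.
#' @return Path to the written manifest, invisibly.
#' @export
save_cohort <- function(cohort, dir, format = c("csv", "fcs")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort$manifest
  ext <- if (format == "csv") ".csv" else ".fcs"
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$patient_id[i]
    fname <- paste0(id, ext)
    if (format == "csv")
      write_csv_cloud(cohort$clouds[[id]], file.path(dir, fname))
    else
      write_fcs_fixture(cohort$clouds[[id]], file.path(dir, fname))
    manifest$path[i] <- fname
  }
  mpath <- file.path(dir, "manifest.csv")
  write_manifest(manifest, mpath)
  invisible(mpath)
}
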