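#' Validated pipeline configuration
#'
#' Bundles every tunable of the end-to-end prognostic pipeline with two
#' profiles: `"test"` (2,000 cells / 200 landmarks; minutes on one CPU) and
#' `"paper"` (1e5 cells / 1e4 landmarks, 1e3 for dimension-2 work; this
#' reproduces the published scale and emits a compute-cost warning, as
#' full pairwise scans at that scale were reported to take about a week on
#' HPC hardware).
#'
#' @param profile `"test"` or `"paper"`.
#' @param markers analysis markers (default CD10, CD20, CD38, CD45).
#' @param n_cells,n_landmarks,n_landmarks_dim2 profile overrides.
#' @param maxdim maximum homology dimension for approach 3 (1 or 2).
#' @param pt_ranges named list of per-dimension threshold ranges; defaults
#'   `dim0 = c(0.03, 0.07)`, `dim1 = c(0.04, 0.05)`.
#' @param pt_points PT grid density (default 20).
#' @param pi_grid persistence-image grid size (5, 10, 25, 50 or 100).
#' @param pi_spread persistence-image Gaussian spread (> 0; 0.01 and 0.05
#'   were the studied values).
#' @param svm_C,svm_gamma fixed SVM hyperparameters (default 10 and 0.001).
#' @param folds cross-validation folds (default 6).
#' @param cd19_threshold CD19 gate threshold on rescaled intensity.
#' @param balance apply in-fold minority oversampling (default TRUE).
#' @param simplex_budget guard for the VR simplex count.
#' @param seed master seed.
#' @return A validated `run_config` list carrying its own `hash`.
#' @export
run_config <- function(profile = c("test", "paper"),
                       markers = c("CD10", "CD20", "CD38", "CD45"),
                       n_cells = NULL, n_landmarks = NULL,
                       n_landmarks_dim2 = NULL, maxdim = 1L,
                       pt_ranges = list(dim0 = c(0.03, 0.07),
                                        dim1 = c(0.04, 0.05)),
                       pt_points = 20L, pi_grid = 25L, pi_spread = 0.05,
                       svm_C = 10, svm_gamma = 0.001, folds = 6L,
                       cd19_threshold = 0.5, balance = TRUE,
                       simplex_budget = 2e7, seed = 1L) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper")
    list(n_cells = 1e5, n_landmarks = 1e4, n_landmarks_dim2 = 1e3)
  else
    list(n_cells = 2000L, n_landmarks = 200L, n_landmarks_dim2 = 100L)
  if (is.null(n_cells)) n_cells <- defaults$n_cells
  if (is.null(n_landmarks)) n_landmarks <- defaults$n_landmarks
  if (is.null(n_landmarks_dim2)) n_landmarks_dim2 <- defaults$n_landmarks_dim2
  if (profile == "paper")
    warning("paper profile selected: pairwise persistence scans at 1e4 ",
            "landmarks are extremely expensive (reported week-scale runtimes)")
  if (!pi_grid %in% c(5L, 10L, 25L, 50L, 100L))
    stop("invalid pi_grid ", pi_grid, " (allowed: 5, 10, 25, 50, 100)")
  if (pi_spread <= 0) stop("pi_spread must be positive")
  if (!maxdim %in% c(1L, 2L)) stop("maxdim must be 1 or 2")
  for (rng in pt_ranges)
    if (length(rng) != 2 || !(rng[1] < rng[2]))
      stop("each pt_range must satisfy lo < hi")
  if (svm_C <= 0 || svm_gamma <= 0) stop("svm_C and svm_gamma must be positive")
  cfg <- list(profile = profile, markers = markers, n_cells = n_cells,
              n_landmarks = as.integer(n_landmarks),
              n_landmarks_dim2 = as.integer(n_landmarks_dim2),
              maxdim = as.integer(maxdim), pt_ranges = pt_ranges,
              pt_points = as.integer(pt_points), pi_grid = as.integer(pi_grid),
              pi_spread = pi_spread, svm_C = svm_C, svm_gamma = svm_gamma,
              folds = as.integer(folds), cd19_threshold = cd19_threshold,
              balance = balance, simplex_budget = simplex_budget,
              seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# polynomial rolling hash over the JSON serialisation: cheap,
# dependency-free config fingerprint
config_hash <- function(cfg) {
  cfg$hash <- NULL
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                                   digits = NA)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# accept either a synthetic_cohort or a manifest with resolvable paths
resolve_cohort <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) return(cohort)
  if (inherits(cohort, "cohort_manifest") || is.data.frame(cohort)) {
    clouds <- lapply(seq_len(nrow(cohort)), function(i) {
      p <- cohort$path[i]
      if (grepl("\\.fcs$", p, ignore.case = TRUE))
        read_fcs(p, patient_id = cohort$patient_id[i])
      else read_csv_cloud(p, patient_id = cohort$patient_id[i])
    })
    names(clouds) <- cohort$patient_id
    return(list(manifest = cohort, clouds = clouds))
  }
  stop("cohort must be a synthetic_cohort or a cohort_manifest")
}

# shared preprocessing: rescale -> CD19 gate -> subsample, once per patient
prep_cohort <- function(cohort, config, markers_required = config$markers) {
  co <- resolve_cohort(cohort)
  out <- vector("list", nrow(co$manifest))
  for (i in seq_along(out)) {
    cl <- co$clouds[[co$manifest$patient_id[i]]]
    missing <- setdiff(c(markers_required, "CD19"), cl$markers)
    if (length(missing) > 0)
      stop("patient ", co$manifest$patient_id[i],
           " is missing required marker(s): ", paste(missing, collapse = ", "))
    rs <- quantile_rescale(cl)
    gated <- gate_cd19(rs$cloud, threshold = config$cd19_threshold)
    out[[i]] <- subsample_cells(gated, n = config$n_cells,
                                seed = config$seed + i)
  }
  names(out) <- co$manifest$patient_id
  list(manifest = co$manifest, clouds = out)
}

patient_pt_curves <- function(cloud, config, cache_dir = NULL) {
  pairs <- marker_pairs(config$markers)
  curves <- list()
  for (r in seq_len(nrow(pairs))) {
    key <- pairs$pair[r]
    bc <- NULL
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0(cloud$patient_id, ".", key, ".barcode.csv"))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      message("cache hit: ", basename(cache_file))
      bc <- load_barcode(cache_file)
    } else {
      proj <- project_pair(cloud, pairs$m1[r], pairs$m2[r])
      lm <- maxmin_landmarks(proj, k = min(config$n_landmarks, n_cells(proj)))
      bc <- persistence_vr(lm$cloud, maxdim = 1L,
                           budget = config$simplex_budget)
      if (!is.null(cache_file)) save_barcode(bc, cache_file)
    }
    for (d in 0:1) {
      rng <- config$pt_ranges[[paste0("dim", d)]]
      curves[[paste0(key, ".dim", d)]] <-
        pt_curve(bc, dim = d, tau_range = rng, n_points = config$pt_points)
    }
  }
  curves
}

#' Approach 2: PT-curve distance prognosis
#'
#' For every patient, Vietoris-Rips barcodes are computed on max-min
#' landmarks of each pairwise marker projection; PT curves are derived in
#' dimensions 0 and 1. Cohort mean curves are fitted on the discovery split
#' and held-out (validation) patients are scored by the PT-curve distance
#' ratio [pt_distance_score()]. Pointwise Welch tests compare the discovery
#' cohorts per pair and dimension.
#'
#' @param cohort a `synthetic_cohort` or `cohort_manifest`.
#' @param config a [run_config()].
#' @param cache_dir optional directory for barcode caching; reruns reuse
#'   cached barcodes and log each hit.
#' @return List with `scores` (per-patient data frame), `report`
#'   (validation-set metrics), `comparisons` (per pair/dimension
#'   `cohort_comparison` on the discovery split), `mean_nr`, `mean_r`,
#'   `curves`, and the config `hash`.
#' @export
run_approach2 <- function(cohort, config = run_config(), cache_dir = NULL) {
  pc <- prep_cohort(cohort, config)
  manifest <- pc$manifest
  if (!is.null(cache_dir))
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  all_curves <- lapply(pc$clouds, patient_pt_curves, config = config,
                       cache_dir = cache_dir)
  disc <- manifest$split == "discovery"
  lab <- manifest$label
  if (length(unique(lab[disc])) < 2)
    stop("cohort means require both R and NR patients in the discovery split")
  keys <- names(all_curves[[1]])
  mean_of <- function(sel) {
    out <- lapply(keys, function(k)
      mean_pt_curve(lapply(all_curves[sel], `[[`, k)))
    names(out) <- keys
    out
  }
  mean_nr <- mean_of(disc & lab == "NR")
  mean_r <- mean_of(disc & lab == "R")
  scores <- vapply(all_curves, pt_distance_score, numeric(1),
                   mean_nr = mean_nr, mean_r = mean_r)
  sc <- data.frame(patient_id = manifest$patient_id, label = lab,
                   split = manifest$split, score = as.numeric(scores),
                   stringsAsFactors = FALSE)
  val <- manifest$split == "validation"
  report <- if (any(val) && length(unique(lab[val])) == 2) {
    classification_report(lab[val], ifelse(sc$score[val] > 0.5, "R", "NR"),
                          sc$score[val], positive = "R")
  } else NULL
  comparisons <- if (sum(disc & lab == "NR") >= 2 && sum(disc & lab == "R") >= 2) {
    out <- lapply(keys, function(k)
      compare_pt_curves(lapply(all_curves[disc & lab == "NR"], `[[`, k),
                        lapply(all_curves[disc & lab == "R"], `[[`, k)))
    names(out) <- keys
    out
  } else NULL
  list(scores = sc, report = report, comparisons = comparisons,
       mean_nr = mean_nr, mean_r = mean_r, curves = all_curves,
       hash = config$hash)
}

#' Approach 3: persistence-image classification
#'
#' Vietoris-Rips persistence of the joint (4-marker) landmark cloud is
#' summarised as persistence images in dimensions 0 and 1 (and optionally 2,
#' computed on a reduced landmark set), flattened, concatenated and
#' classified with the RBF-SVM under stratified k-fold cross-validation with
#' in-fold minority oversampling; logistic regression is run alongside for
#' its interpretable coefficient image.
#'
#' @param cohort a `synthetic_cohort` or `cohort_manifest`.
#' @param config a [run_config()].
#' @param risk_subgroup restrict to patients whose initial risk group is low
#'   or intermediate (the clinically interesting reclassification tier).
#' @param methods any of `"svm"`, `"lr"`.
#' @return List with `svm` and/or `lr` results, the `features` matrix,
#'   `labels`, `n_patients`, and the config `hash`.
#' @export
run_approach3 <- function(cohort, config = run_config(),
                          risk_subgroup = FALSE, methods = c("svm", "lr")) {
  pc <- prep_cohort(cohort, config)
  manifest <- pc$manifest
  keep <- rep(TRUE, nrow(manifest))
  if (risk_subgroup) {
    keep <- manifest$risk_group %in% c("low", "intermediate")
    message("risk-subgroup mode: ", sum(keep), " of ", length(keep),
            " patients have low/intermediate initial risk")
  }
  manifest <- manifest[keep, , drop = FALSE]
  clouds <- pc$clouds[keep]
  dims <- 0:min(config$maxdim, 1L)
  feats <- lapply(clouds, function(cl) {
    analysis <- point_cloud(cl$values[, config$markers, drop = FALSE],
                            markers = config$markers,
                            patient_id = cl$patient_id)
    lm <- maxmin_landmarks(analysis, k = min(config$n_landmarks,
                                             n_cells(analysis)))
    bc <- persistence_vr(lm$cloud, maxdim = 1L, budget = config$simplex_budget)
    images <- lapply(dims, function(d)
      persistence_image(bc, dim = d, grid_size = config$pi_grid,
                        spread = config$pi_spread))
    if (config$maxdim >= 2L) {
      lm2 <- maxmin_landmarks(analysis, k = min(config$n_landmarks_dim2,
                                                n_cells(analysis)))
      bc2 <- persistence_vr(lm2$cloud, maxdim = 2L,
                            budget = config$simplex_budget)
      images <- c(images, list(
        persistence_image(bc2, dim = 2L, grid_size = config$pi_grid,
                          spread = config$pi_spread)))
    }
    pi_feature(images)
  })
  X <- do.call(rbind, feats)
  rownames(X) <- manifest$patient_id
  y <- manifest$label
  out <- list(features = X, labels = y, n_patients = nrow(manifest),
              hash = config$hash)
  if ("svm" %in% methods)
    out$svm <- svm_classify(X, y, folds = config$folds, C = config$svm_C,
                            gamma = config$svm_gamma,
                            balance = config$balance, positive = "R",
                            seed = config$seed)
  if ("lr" %in% methods)
    out$lr <- lr_classify(X, y, folds = config$folds,
                          grid_size = config$pi_grid, positive = "R",
                          seed = config$seed)
  out
}

#' Random-forest screening across a full marker panel
#'
#' Computes per-pair 8-dimensional barcode descriptor vectors for every
#' patient (landmarked pairwise projections, dimensions 0 and 1) and screens
#' all pairwise marker combinations with [rf_screen()].
#'
#' @param cohort a `synthetic_cohort` or `cohort_manifest`.
#' @param config a [run_config()]; `config$markers` is the panel to screen
#'   (geometric markers FSC-A/SSC-A and the CD19 gate marker are excluded
#'   from pairing).
#' @param ... passed to [rf_screen()].
#' @return A `screen_result` data frame ranked by mean AUC.
#' @export
run_screen <- function(cohort, config = run_config(), ...) {
  panel <- setdiff(config$markers, c("FSC-A", "SSC-A"))
  pc <- prep_cohort(cohort, config, markers_required = panel)
  pairs <- marker_pairs(panel)
  nP <- length(pc$clouds)
  features <- vector("list", nrow(pairs))
  names(features) <- pairs$pair
  for (r in seq_len(nrow(pairs))) {
    mat <- matrix(0, nP, 8)
    for (i in seq_len(nP)) {
      proj <- project_pair(pc$clouds[[i]], pairs$m1[r], pairs$m2[r])
      lm <- maxmin_landmarks(proj, k = min(config$n_landmarks, n_cells(proj)))
      bc <- persistence_vr(lm$cloud, maxdim = 1L,
                           budget = config$simplex_budget)
      mat[i, ] <- suppressWarnings(descriptor_vector(bc))
    }
    features[[r]] <- mat
  }
  rf_screen(features, pc$manifest$label, seed = config$seed, ...)
}
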