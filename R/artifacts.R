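VALID_LABELS <- c("R", "NR")
VALID_RISK <- c("low", "intermediate", "high", "unknown")
VALID_SPLIT <- c("discovery", "validation")

#' Load a cohort manifest
#'
#' The manifest is delimited text with five columns: `patient_id`, `label`
#' (`R` or `NR`), `risk_group` (`low`, `intermediate`, `high`, `unknown`),
#' `split` (`discovery` or `validation`) and `path` (the patient's point-cloud
#' file, resolved relative to the manifest's directory).
#'
#' @param path manifest CSV path.
#' @param check_paths verify that every referenced file exists (default TRUE).
#' @return A `cohort_manifest` data frame.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  required <- c("patient_id", "label", "risk_group", "split", "path")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient id(s): ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  bad <- setdiff(unique(df$label), VALID_LABELS)
  if (length(bad) > 0)
    stop("unknown label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed values: ", paste(VALID_LABELS, collapse = ", "))
  bad <- setdiff(unique(df$risk_group), VALID_RISK)
  if (length(bad) > 0)
    stop("unknown risk group(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed values: ", paste(VALID_RISK, collapse = ", "))
  bad <- setdiff(unique(df$split), VALID_SPLIT)
  if (length(bad) > 0)
    stop("unknown split value(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed values: ", paste(VALID_SPLIT, collapse = ", "))
  base <- dirname(normalizePath(path, mustWork = FALSE))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(base, df$path))
  if (check_paths) {
    gone <- !file.exists(abs)
    if (any(gone))
      stop("unresolvable path(s) in manifest: ",
           paste(df$path[gone], collapse = ", "))
  }
  df$path <- abs
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest
#'
#' @param manifest a `cohort_manifest` (or compatible data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' Save and load persistence barcodes as plain text
#'
#' Barcodes are persisted as three-column CSV (`dimension`, `birth`, `death`)
#' with infinite deaths spelled as the literal `inf`, so that the essential
#' dimension-0 bar survives a round trip exactly.
#'
#' @param barcode a `barcode` data frame as returned by [persistence_vr()].
#' @param path file path.
#' @return `save_barcode` returns `path` invisibly; `load_barcode` returns the
#'   barcode.
#' @export
save_barcode <- function(barcode, path) {
  stopifnot(is.data.frame(barcode))
  df <- data.frame(dimension = barcode$dimension,
                   birth = format(barcode$birth, digits = 17, trim = TRUE),
                   death = ifelse(is.infinite(barcode$death), "inf",
                                  format(barcode$death, digits = 17, trim = TRUE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_barcode
#' @export
load_barcode <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  death <- ifelse(df$death == "inf", Inf, as.numeric(df$death))
  new_barcode(as.integer(df$dimension), as.numeric(df$birth), death)
}

#' Save a numeric matrix artifact with a JSON sidecar
#'
#' Curves and persistence images are persisted as delimited matrices next to
#' a `<path>.json` sidecar recording the hyperparameters that produced them.
#'
#' @param mat numeric matrix.
#' @param path CSV path; the sidecar is written at `paste0(path, ".json")`.
#' @param meta named list of hyperparameters for the sidecar.
#' @return `path`, invisibly.
#' @export
save_matrix_artifact <- function(mat, path, meta = list()) {
  utils::write.csv(as.data.frame(mat), path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_matrix_artifact
#' @export
load_matrix_artifact <- function(path) {
  mat <- as.matrix(utils::read.csv(path, check.names = FALSE))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  attr(mat, "meta") <- meta
  mat
}
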