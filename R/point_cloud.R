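#' Point cloud of single-cell marker intensities
#'
#' A point cloud is the per-patient matrix of cells (rows) by named
#' immunophenotypic markers (columns), e.g. CD10, CD19, CD20, CD38, CD45.
#' Marker names must be unique and values finite; rows containing NA/NaN/Inf
#' are rejected by the constructor (readers drop and count them instead).
#'
#' @param values numeric matrix, one row per cell, one column per marker.
#' @param markers character vector of marker names; defaults to
#'   `colnames(values)`.
#' @param patient_id scalar identifier for the patient the cloud belongs to.
#' @return An object of class `point_cloud`: a list with elements
#'   `patient_id`, `markers` and `values`.
#' @export
point_cloud <- function(values, markers = colnames(values), patient_id = "unknown") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(markers)) stop("marker names are required")
  markers <- as.character(markers)
  if (length(markers) != ncol(values))
    stop("number of marker names (", length(markers),
         ") does not match number of columns (", ncol(values), ")")
  if (anyDuplicated(markers))
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  if (nrow(values) > 0 && !all(is.finite(values)))
    stop("point cloud contains non-finite values")
  colnames(values) <- markers
  structure(list(patient_id = as.character(patient_id)[1],
                 markers = markers, values = values),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("<point_cloud> patient ", x$patient_id, ": ", nrow(x$values), " cells x ",
      length(x$markers), " markers (", paste(x$markers, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' @export
dim.point_cloud <- function(x) dim(x$values)

n_cells <- function(cloud) nrow(cloud$values)

assert_cloud <- function(cloud) {
  if (!inherits(cloud, "point_cloud")) stop("expected a 'point_cloud' object")
  invisible(cloud)
}
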