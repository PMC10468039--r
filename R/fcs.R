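#' Read an FCS 3.0 list-mode file into a point cloud
#'
#' Minimal, auditable parser for the Flow Cytometry Standard 3.0: the 58-byte
#' header is read for the TEXT/DATA segment offsets, the TEXT segment is
#' parsed into keyword/value pairs, and the DATA segment is decoded according
#' to `$DATATYPE` (only `F` = float32 and `D` = float64 are supported),
#' `$BYTEORD`, `$PAR`, `$TOT` and the per-parameter `$PnB` widths. Column
#' names are taken from `$PnN`, falling back to `$PnS`. Only list mode
#' (`$MODE L`) single-dataset files are accepted; an ANALYSIS segment, if
#' declared, is ignored.
#'
#' @param path path to an FCS 3.0 file.
#' @param patient_id identifier for the returned cloud; defaults to the file
#'   name without extension.
#' @return A [point_cloud()] with `$TOT` rows and `$PAR` columns.
#' @export
read_fcs <- function(path, patient_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (nchar(header, type = "bytes") < 58 || substr(header, 1, 6) != "FCS3.0")
    stop("not an FCS 3.0 file (bad header): ", path)
  off <- function(k) {
    s <- trimws(substr(header, 11 + (k - 1) * 8, 10 + k * 8))
    if (s == "") 0 else as.numeric(s)
  }
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)
  if (text_start <= 0 || text_end < text_start)
    stop("invalid TEXT segment offsets in header")

  seek(con, text_start)
  raw_text <- readBin(con, "raw", n = text_end - text_start + 1)
  txt <- rawToChar(raw_text)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), by = 2)],
                        toupper(trimws(parts[seq(1, length(parts), by = 2)])))
  need <- function(key) {
    if (is.na(kw[key])) stop("required keyword missing: ", key)
    kw[[key]]
  }

  mode <- toupper(trimws(need("$MODE")))
  if (mode != "L") stop("unsupported $MODE '", mode, "': only list mode (L) is supported")
  datatype <- toupper(trimws(need("$DATATYPE")))
  if (!datatype %in% c("F", "D"))
    stop("unsupported datatype '$DATATYPE ", datatype,
         "': only F (float32) and D (float64) are supported")
  p <- as.integer(need("$PAR"))
  tot <- as.integer(need("$TOT"))
  byteord <- trimws(need("$BYTEORD"))
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
    else if (byteord %in% c("4,3,2,1", "2,1")) "big"
    else stop("unsupported $BYTEORD '", byteord, "'")

  word <- if (datatype == "F") 4L else 8L
  bits <- vapply(seq_len(p), function(i) {
    b <- kw[paste0("$P", i, "B")]
    if (is.na(b)) word * 8L else as.integer(b)
  }, integer(1))
  if (any(bits != word * 8L))
    stop("$PnB widths inconsistent with $DATATYPE ", datatype)

  if (data_start <= 0) data_start <- as.numeric(need("$BEGINDATA"))
  if (data_end <= 0) data_end <- as.numeric(need("$ENDDATA"))
  expected <- as.numeric(p) * tot * word
  avail <- data_end - data_start + 1
  if (tot > 0 && avail < expected)
    stop("segment length mismatch: DATA segment holds ", avail,
         " bytes but $PAR x $TOT x width requires ", expected)

  nms <- vapply(seq_len(p), function(i) {
    nm <- kw[paste0("$P", i, "N")]
    if (is.na(nm) || !nzchar(trimws(nm))) nm <- kw[paste0("$P", i, "S")]
    if (is.na(nm) || !nzchar(trimws(nm))) nm <- paste0("P", i)
    trimws(nm)
  }, character(1))

  if (tot == 0) {
    vals <- matrix(numeric(0), nrow = 0, ncol = p)
  } else {
    seek(con, data_start)
    x <- readBin(con, "numeric", n = p * tot, size = word, endian = endian)
    if (length(x) < p * tot) stop("segment length mismatch: DATA segment truncated")
    vals <- matrix(x, nrow = tot, ncol = p, byrow = TRUE)
  }
  point_cloud(vals, markers = nms, patient_id = patient_id)
}

#' Write a minimal FCS 3.0 fixture file
#'
#' Emits a valid single-dataset FCS 3.0 list-mode file (`$DATATYPE F`,
#' little-endian) that [read_fcs()] inverts exactly up to float32
#' quantisation. Intended for generating test fixtures and synthetic cohorts;
#' it is not a general-purpose FCS writer.
#'
#' @param cloud a finite [point_cloud()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fcs_fixture <- function(cloud, path) {
  assert_cloud(cloud)
  if (length(cloud$markers) == 0) stop("cannot write a cloud with no markers")
  if (nrow(cloud$values) > 0 && !all(is.finite(cloud$values)))
    stop("cloud contains non-finite values")
  p <- length(cloud$markers)
  tot <- nrow(cloud$values)
  nbytes <- 4L * p * tot

  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(tot))
  for (i in seq_len(p)) {
    kw <- c(kw, paste0("$P", i, "B"), "32",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), "262144",
            paste0("$P", i, "N"), cloud$markers[i])
  }
  delim <- "/"
  text <- paste0(delim, paste0(kw, collapse = delim), delim)
  text_start <- 58L
  text_len <- nchar(text, type = "bytes")  # placeholders are width-8, final too
  text <- sub("%BD%", sprintf("%08d", 0L), text, fixed = TRUE)
  text <- sub("%ED%", sprintf("%08d", 0L), text, fixed = TRUE)
  text_len <- nchar(text, type = "bytes")
  text_end <- text_start + text_len - 1L
  data_start <- text_end + 1L
  data_end <- if (tot > 0) data_start + nbytes - 1L else data_start
  text <- sub(sprintf("%08d", 0L), sprintf("%08d", data_start), text, fixed = TRUE)
  text <- sub(sprintf("%08d", 0L), sprintf("%08d", data_end), text, fixed = TRUE)

  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end,
                    if (tot > 0) data_start else 0L,
                    if (tot > 0) data_end else 0L, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (tot > 0)
    writeBin(as.vector(t(cloud$values)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a delimited-text point cloud
#'
#' Reads a CSV with a header row of marker names and a numeric body. Rows
#' containing any non-numeric, NA or non-finite cell are dropped; the drop
#' count is reported via a message and attached as attribute `n_dropped`.
#'
#' @param path CSV file path.
#' @param patient_id identifier for the returned cloud.
#' @return A [point_cloud()]; attribute `n_dropped` counts removed rows.
#' @export
read_csv_cloud <- function(path, patient_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  if (nrow(df) == 0 && ncol(df) == 0) stop("empty file: ", path)
  nms <- names(df)
  if (anyDuplicated(nms))
    stop("duplicate marker names in header: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  vals <- suppressWarnings(vapply(df, function(col) as.numeric(as.character(col)),
                                  numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), ncol = ncol(df))
  ok <- rowSums(!is.finite(vals)) == 0
  dropped <- sum(!ok)
  if (dropped > 0)
    message("read_csv_cloud: dropped ", dropped, " row(s) with non-finite cells")
  out <- point_cloud(vals[ok, , drop = FALSE], markers = nms,
                     patient_id = patient_id)
  attr(out, "n_dropped") <- dropped
  out
}

#' Write a point cloud as CSV
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_cloud <- function(cloud, path) {
  assert_cloud(cloud)
  utils::write.csv(as.data.frame(cloud$values), path, row.names = FALSE)
  invisible(path)
}
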