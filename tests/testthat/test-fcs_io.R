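test_that("FCS fixture round-trips exactly up to float32 quantisation", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(1:50, 1)
    p <- sample(1:6, 1)
    cl <- point_cloud(matrix(rnorm(n * p), n, p),
                      markers = paste0("CD", seq_len(p)),
                      patient_id = "rt")
    f <- withr::local_tempfile(fileext = ".fcs")
    write_fcs_fixture(cl, f)
    back <- read_fcs(f, patient_id = "rt")
    expect_identical(back$markers, cl$markers)
    expect_equal(back$values, cl$values, tolerance = 1e-6,
                 ignore_attr = TRUE)
    # float32 quantisation is exact: re-writing the re-read cloud is stable
    f2 <- withr::local_tempfile(fileext = ".fcs")
    write_fcs_fixture(back, f2)
    expect_identical(read_fcs(f2)$values, back$values)
  }
})

test_that("3-event 2-parameter fixture reproduces the exact matrix", {
  vals <- matrix(c(0.5, 1.25, -2, 0.75, 8, 0.0625), nrow = 3)  # dyadic: exact in f32
  cl <- point_cloud(vals, markers = c("CD10", "CD20"), patient_id = "p1")
  f <- withr::local_tempfile(fileext = ".fcs")
  write_fcs_fixture(cl, f)
  back <- read_fcs(f)
  expect_equal(dim(back$values), c(3L, 2L))
  expect_identical(back$markers, c("CD10", "CD20"))
  expect_identical(unname(back$values), unname(vals))
})

test_that("read_fcs rejects malformed inputs with specific errors", {
  cl <- point_cloud(matrix(1:6 / 2, 3, 2), markers = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".fcs")
  write_fcs_fixture(cl, f)

  # split the file at the end of the TEXT segment (header bytes 19-26)
  raw <- readBin(f, "raw", file.size(f))
  text_end <- as.integer(rawToChar(raw[19:26]))
  head_txt <- rawToChar(raw[seq_len(text_end + 1)])
  data_part <- raw[(text_end + 2):length(raw)]
  rewrite <- function(pattern, replacement) {
    f_bad <- tempfile(fileext = ".fcs")
    writeBin(c(charToRaw(sub(pattern, replacement, head_txt)), data_part),
             f_bad)
    f_bad
  }
  # unsupported datatype
  expect_error(read_fcs(rewrite("\\$DATATYPE/F", "$DATATYPE/A")),
               "unsupported datatype")
  # non-list mode
  expect_error(read_fcs(rewrite("\\$MODE/L", "$MODE/C")), "MODE")
  f_bad <- withr::local_tempfile(fileext = ".fcs")

  # truncated DATA segment
  writeBin(raw[1:(length(raw) - 5)], f_bad)
  expect_error(read_fcs(f_bad), "segment length mismatch")
})

test_that("zero-event FCS file yields 0 x p cloud without error", {
  cl <- point_cloud(matrix(numeric(0), 0, 2), markers = c("CD10", "CD20"))
  f <- withr::local_tempfile(fileext = ".fcs")
  write_fcs_fixture(cl, f)
  back <- read_fcs(f)
  expect_equal(dim(back$values), c(0L, 2L))
  expect_identical(back$markers, c("CD10", "CD20"))
})

test_that("write_fcs_fixture validates its input", {
  empty <- point_cloud(matrix(numeric(0), 1, 0), markers = character(0))
  expect_error(write_fcs_fixture(empty, withr::local_tempfile()),
               "no markers")
  cl <- point_cloud(matrix(1:4 / 4, 2, 2), markers = c("a", "b"))
  cl$values[1, 1] <- Inf
  expect_error(write_fcs_fixture(cl, withr::local_tempfile()), "non-finite")
})

test_that("read_csv_cloud keeps order, drops bad rows, rejects dup headers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD10,CD20", "0.1,0.2", "0.3,0.4", "0.5,0.6", "0.7,0.8"), f)
  cl <- read_csv_cloud(f, patient_id = "x")
  expect_equal(dim(cl$values), c(4L, 2L))
  expect_equal(cl$values[, "CD10"], c(0.1, 0.3, 0.5, 0.7), ignore_attr = TRUE)

  writeLines(c("CD10,CD20", "0.1,0.2", "NaN,0.4", "0.5,oops"), f)
  expect_message(cl <- read_csv_cloud(f), "dropped 2")
  expect_equal(nrow(cl$values), 1L)
  expect_identical(attr(cl, "n_dropped"), 2L)

  writeLines(c("CD10,CD10", "0.1,0.2"), f)
  expect_error(read_csv_cloud(f), "duplicate")
})

test_that("manifest loading validates labels, risk groups and uniqueness", {
  d <- withr::local_tempdir()
  writeLines("CD10,CD19\n0.1,0.9", file.path(d, "p1.csv"))
  writeLines("CD10,CD19\n0.2,0.8", file.path(d, "p2.csv"))
  mk <- function(rows) {
    f <- file.path(d, "manifest.csv")
    writeLines(c("patient_id,label,risk_group,split,path", rows), f)
    f
  }
  m <- load_manifest(mk(c("p1,R,low,discovery,p1.csv",
                          "p2,NR,high,validation,p2.csv")))
  expect_s3_class(m, "cohort_manifest")
  expect_identical(m$label, c("R", "NR"))

  expect_error(load_manifest(mk(c("p1,relapse,low,discovery,p1.csv"))),
               "allowed values: R, NR")
  expect_error(load_manifest(mk(c("p1,R,low,discovery,p1.csv",
                                  "p1,NR,low,discovery,p2.csv"))),
               "duplicate patient id")
  expect_error(load_manifest(mk(c("p1,R,low,discovery,missing.csv"))),
               "unresolvable")
})

test_that("barcode save/load round-trips intervals exactly, including Inf", {
  cl <- random_cloud(15, 2, seed = 9)
  bc <- persistence_vr(cl, maxdim = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  save_barcode(bc, f)
  expect_true(any(grepl("inf", readLines(f), fixed = TRUE)))
  back <- load_barcode(f)
  expect_identical(sort_barcode(back), sort_barcode(bc))
})

test_that("matrix artifacts round-trip with their JSON sidecar", {
  m <- matrix(runif(20), 4, 5)
  f <- withr::local_tempfile(fileext = ".csv")
  save_matrix_artifact(m, f, meta = list(grid_size = 5, spread = 0.05))
  back <- load_matrix_artifact(f)
  expect_equal(back, m, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(back, "meta")$grid_size, 5)
})
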