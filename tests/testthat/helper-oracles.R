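# Independent oracles used to validate the package's computational core.
# Everything here is deliberately naive (enumeration, dense reduction,
# brute force) and shares no code with the implementation under test.

# Naive VR persistence: enumerate all simplices up to maxdim+1, sort by
# (value, dim, lex), build the full Z/2 boundary matrix, run the textbook
# left-to-right column reduction, read pairs off the low function.
oracle_vr <- function(dm, maxdim) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  simplices <- list()
  for (d in 0:(maxdim + 1)) {
    if (n < d + 1) next
    combs <- utils::combn(n, d + 1)
    for (c_i in seq_len(ncol(combs))) {
      v <- combs[, c_i]
      val <- if (d == 0) 0 else max(dm[v, v][upper.tri(matrix(0, d + 1, d + 1))])
      simplices[[length(simplices) + 1]] <- list(v = v, val = val, dim = d)
    }
  }
  ord <- order(vapply(simplices, `[[`, numeric(1), "val"),
               vapply(simplices, `[[`, numeric(1), "dim"),
               vapply(simplices, function(s) paste(sprintf("%04d", s$v),
                                                   collapse = ""),
                      character(1)))
  simplices <- simplices[ord]
  key <- vapply(simplices, function(s) paste(s$v, collapse = ","), character(1))
  index <- stats::setNames(seq_along(simplices), key)
  ns <- length(simplices)
  cols <- vector("list", ns)
  for (j in seq_len(ns)) {
    s <- simplices[[j]]
    if (s$dim == 0) {
      cols[[j]] <- integer(0)
    } else {
      facets <- vapply(seq_along(s$v), function(drop_i)
        paste(s$v[-drop_i], collapse = ","), character(1))
      cols[[j]] <- sort(unname(index[facets]))
    }
  }
  lowinv <- integer(ns)  # 0 = unclaimed
  pair_of <- integer(ns)
  for (j in seq_len(ns)) {
    col <- cols[[j]]
    while (length(col) > 0) {
      low <- col[length(col)]
      j2 <- lowinv[low]
      if (j2 == 0) break
      col <- sort(setdiff(union(col, cols[[j2]]), intersect(col, cols[[j2]])))
      cols[[j]] <- col
    }
    if (length(col) > 0) {
      low <- col[length(col)]
      lowinv[low] <- j
      pair_of[low] <- j
    }
  }
  bars <- list()
  for (i in seq_len(ns)) {
    s <- simplices[[i]]
    if (length(cols[[i]]) == 0) {  # positive simplex
      j <- pair_of[i]
      death <- if (j == 0) Inf else simplices[[j]]$val
      if (s$dim <= maxdim && death > s$val)
        bars[[length(bars) + 1]] <- c(s$dim, s$val, death)
    }
  }
  if (length(bars) == 0)
    return(data.frame(dimension = integer(0), birth = numeric(0),
                      death = numeric(0)))
  m <- do.call(rbind, bars)
  df <- data.frame(dimension = as.integer(m[, 1]), birth = m[, 2],
                   death = m[, 3])
  df[order(df$dimension, df$birth, df$death), , drop = FALSE]
}

# canonical ordering for barcode comparison
sort_barcode <- function(bc) {
  df <- data.frame(dimension = bc$dimension, birth = bc$birth,
                   death = bc$death)
  df <- df[order(df$dimension, df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Brute-force optimal k-center radius over all k-subsets (tiny clouds only)
oracle_kcenter <- function(X, k) {
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  best <- Inf
  for (c_i in seq_len(ncol(sub <- utils::combn(n, k)))) {
    centers <- sub[, c_i]
    r <- max(apply(d[, centers, drop = FALSE], 1, min))
    best <- min(best, r)
  }
  best
}

# Closed-form power of the two-sample t-test (equal n, common sd)
oracle_t_power <- function(delta, sd, n_per_group, alpha = 0.05) {
  df <- 2 * n_per_group - 2
  ncp <- delta / (sd * sqrt(2 / n_per_group))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
}

random_cloud <- function(n, d, seed, markers = paste0("m", seq_len(d))) {
  set.seed(seed)
  topocyto::point_cloud(matrix(stats::runif(n * d), n, d), markers = markers)
}
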