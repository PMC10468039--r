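test_that("distance matrix is exact and matches a brute-force double loop", {
  cl <- point_cloud(rbind(c(0, 0), c(3, 4)), markers = c("x", "y"))
  expect_equal(distance_matrix(cl)[1, 2], 5)

  set.seed(8)
  X <- matrix(rnorm(60), 20, 3)
  dm <- distance_matrix(point_cloud(X, markers = letters[1:3]))
  brute <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) brute[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  expect_equal(unname(dm), brute, tolerance = 1e-12)

  # duplicate points are tolerated (zero off-diagonal)
  dup <- point_cloud(rbind(c(1, 1), c(1, 1)), markers = c("x", "y"))
  expect_equal(distance_matrix(dup)[1, 2], 0)
})

test_that("closed-form barcodes: square, collinear triple, equilateral triangle", {
  sq <- point_cloud(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                    markers = c("x", "y"))
  bc <- persistence_vr(sq, maxdim = 2)
  d1 <- finite_bars(bc, 1)
  expect_equal(nrow(d1), 1L)
  expect_equal(unname(d1[1, ]), c(1, sqrt(2)), tolerance = 1e-12)
  expect_equal(nrow(finite_bars(bc, 2)), 0L)

  tri <- point_cloud(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
                     markers = c("x", "y"))
  expect_equal(nrow(finite_bars(persistence_vr(tri, maxdim = 1), 1)), 0L)

  col3 <- point_cloud(cbind(x = c(0, 1, 3)))
  b0 <- persistence_dim0(col3)
  expect_equal(sort(finite_bars(b0, 0)[, "death"]), c(1, 2))
  expect_equal(sum(is.infinite(b0$death)), 1L)
  expect_true(all(b0$birth == 0))

  single <- point_cloud(cbind(x = 0))
  b <- persistence_dim0(single)
  expect_equal(nrow(b), 1L)
  expect_true(is.infinite(b$death))
})

test_that("dim-0 finite deaths equal the MST edge-weight multiset", {
  skip_if_not_installed("igraph")
  for (s in 1:10) {
    set.seed(s)
    n <- sample(10:60, 1)
    cl <- random_cloud(n, sample(2:4, 1), seed = s * 7)
    dm <- distance_matrix(cl)
    deaths <- sort(finite_bars(persistence_dim0(dm), 0)[, "death"])
    g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                             weighted = TRUE)
    mst_w <- sort(igraph::E(igraph::mst(g))$weight)
    expect_equal(deaths, mst_w[mst_w > 0], tolerance = 1e-12)
  }
})

test_that("barcodes equal the naive reduction oracle on random clouds", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(4:12, 1)
    cl <- random_cloud(n, sample(2:3, 1), seed = s + 500)
    dm <- distance_matrix(cl)
    got <- sort_barcode(persistence_vr(dm, maxdim = 2))
    want <- oracle_vr(dm, 2)
    rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
  # a couple of larger maxdim-1 instances
  for (s in 1:3) {
    cl <- random_cloud(25, 2, seed = s + 900)
    dm <- distance_matrix(cl)
    got <- sort_barcode(persistence_vr(dm, maxdim = 1))
    want <- oracle_vr(dm, 1)
    rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("persistence_vr dim-0 block equals persistence_dim0 exactly", {
  for (s in 1:5) {
    cl <- random_cloud(30, 2, seed = s)
    dm <- distance_matrix(cl)
    a <- persistence_vr(dm, maxdim = 1)
    expect_identical(sort_barcode(a[a$dimension == 0, ]),
                     sort_barcode(persistence_dim0(dm)))
  }
})

test_that("scale equivariance: scaling coordinates by c scales all endpoints by c", {
  cl <- random_cloud(20, 2, seed = 77)
  bc1 <- sort_barcode(persistence_vr(cl, maxdim = 1))
  cl2 <- point_cloud(cl$values * 2.5, markers = cl$markers)
  bc2 <- sort_barcode(persistence_vr(cl2, maxdim = 1))
  expect_equal(bc2$birth, 2.5 * bc1$birth, tolerance = 1e-12)
  expect_equal(bc2$death, 2.5 * bc1$death, tolerance = 1e-12)
})

test_that("bottleneck stability smoke test on tiny clouds", {
  # sup-norm perturbation by eps moves matched endpoints by <= 2*eps
  # (factor 2 covers the Euclidean diameter of an eps-box in 2D)
  set.seed(5)
  for (rep in 1:5) {
    X <- matrix(runif(16), 8, 2)
    eps <- 0.01
    Y <- X + matrix(runif(16, -eps, eps), 8, 2)
    b1 <- sort_barcode(persistence_vr(point_cloud(X, markers = c("x", "y")),
                                      maxdim = 1))
    b2 <- sort_barcode(persistence_vr(point_cloud(Y, markers = c("x", "y")),
                                      maxdim = 1))
    for (d in 0:1) {
      f1 <- b1[b1$dimension == d & is.finite(b1$death), ]
      f2 <- b2[b2$dimension == d & is.finite(b2$death), ]
      # greedy matching on these stable tiny inputs: sort by (birth, death)
      k <- min(nrow(f1), nrow(f2))
      if (k > 0) {
        long1 <- f1[order(-(f1$death - f1$birth)), ][seq_len(k), ]
        long2 <- f2[order(-(f2$death - f2$birth)), ][seq_len(k), ]
        expect_true(all(abs(long1$birth - long2$birth) <= 2 * eps * sqrt(2) + 1e-9 |
                          (long1$death - long1$birth) <= 4 * eps))
      }
    }
  }
})

test_that("Euler consistency: barcode ranks match brute-force Betti numbers", {
  # at any filtration value t, the number of bars alive at t in dim d equals
  # the rank of H_d of the complex at t, computed by naive reduction
  for (s in 1:4) {
    cl <- random_cloud(8, 2, seed = s + 40)
    dm <- distance_matrix(cl)
    bc <- persistence_vr(dm, maxdim = 2)
    want <- oracle_vr(dm, 2)
    ts <- quantile(dm[upper.tri(dm)], c(0.3, 0.6, 0.9))
    for (t in ts) for (d in 0:2) {
      alive <- sum(bc$dimension == d & bc$birth <= t & bc$death > t)
      alive_oracle <- sum(want$dimension == d & want$birth <= t & want$death > t)
      expect_identical(alive, alive_oracle)
    }
  }
})

test_that("simplex budget guard fails loudly with guidance", {
  cl <- random_cloud(50, 2, seed = 1)
  expect_error(persistence_vr(cl, maxdim = 1, budget = 1000),
               "simplex budget exceeded.*landmarks")
  expect_error(persistence_vr(cl, maxdim = 3), "maxdim")
})
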