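# small separable / null feature generators used across the ML tests
make_features <- function(n_nr, n_r, p = 8, shift = 0, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_nr * p), n_nr, p),
             matrix(rnorm(n_r * p, mean = shift), n_r, p))
  list(X = X, y = c(rep("NR", n_nr), rep("R", n_r)))
}

test_that("oversample equalises class counts by cyclic duplication", {
  X <- matrix(1:10, 5, 2)
  y <- c("NR", "NR", "NR", "NR", "R")
  os <- oversample(X, y)
  expect_equal(unname(table(os$y)["R"]), 4)
  expect_equal(unname(table(os$y)["NR"]), 4)
  expect_equal(os$X[6:8, ], X[c(5, 5, 5), ])  # exact duplicates

  bal <- oversample(X[1:4, ], c("NR", "R", "NR", "R"))
  expect_identical(bal$X, X[1:4, ])
  expect_error(oversample(X, rep("NR", 5)), "both classes")

  for (s in 1:5) {
    set.seed(s)
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    os <- oversample(matrix(rnorm((n1 + n2) * 2), ncol = 2),
                     c(rep("A", n1), rep("B", n2)))
    expect_equal(length(unique(table(os$y))), 1L)
  }
})

test_that("classification_report computes the textbook metrics", {
  # confusion TP=3, FP=1, FN=0, TN=4
  y_true <- c(rep("R", 3), rep("NR", 5))
  y_pred <- c(rep("R", 3), "R", rep("NR", 4))
  rep_ <- classification_report(y_true, y_pred)
  expect_equal(rep_$accuracy, 0.875)
  expect_equal(rep_$precision, 0.75)
  expect_equal(rep_$recall, 1)
  expect_equal(rep_$f1, 6 / 7)
  expect_equal(unname(rep_$confusion["R", "R"]), 3)

  # perfect scores give AUC 1; random scores give ~0.5
  perfect <- classification_report(y_true, y_pred,
                                   y_score = c(3, 2, 1, 0.4, -1, -2, -3, -4))
  expect_equal(perfect$auc, 1)
  set.seed(1)
  yy <- sample(c("R", "NR"), 4000, replace = TRUE)
  null_auc <- classification_report(yy, yy, y_score = runif(4000))$auc
  expect_lt(abs(null_auc - 0.5), 0.05)
  expect_warning(classification_report(rep("R", 3), rep("R", 3),
                                       y_score = 1:3), "single class")
})

test_that("SVM separates separable data and stays at chance on shuffled labels", {
  fx <- make_features(30, 30, shift = 3, seed = 2)
  res <- svm_classify(fx$X, fx$y, folds = 5, C = 10, gamma = 0.01, seed = 3)
  expect_gt(res$cv_accuracy, 0.95)
  expect_gt(res$report$auc, 0.95)

  set.seed(4)
  yshuf <- sample(fx$y)
  null <- svm_classify(fx$X, yshuf, folds = 5, C = 10, gamma = 0.01, seed = 3)
  expect_lt(abs(null$cv_accuracy - 0.5), 0.2)

  # duplicating every sample with the same seed gives identical fold metrics
  res2 <- svm_classify(fx$X, fx$y, folds = 5, C = 10, gamma = 0.01, seed = 3)
  expect_identical(res$fold_accuracy, res2$fold_accuracy)
})

test_that("SVM grid search stays inside training folds and selects sane values", {
  fx <- make_features(20, 20, shift = 2.5, seed = 6)
  res <- svm_classify(fx$X, fx$y, folds = 4,
                      grid = list(C = c(0.01, 1, 10), gamma = c(1e-3, 0.1)),
                      seed = 1)
  expect_gt(res$cv_accuracy, 0.85)
  expect_length(res$chosen, 4)
  expect_error(svm_classify(fx$X, fx$y, grid = list(C = numeric(0),
                                                    gamma = 1)),
               "degenerate")
})

test_that("fold count is reduced with a warning when the minority is small", {
  fx <- make_features(20, 4, shift = 3, seed = 7)
  expect_warning(res <- svm_classify(fx$X, fx$y, folds = 6, seed = 1),
                 "reducing folds")
  expect_equal(res$folds, 4L)
})

test_that("no leakage: oversampling before splitting inflates null accuracy, the shipped in-fold pipeline does not", {
  # canary: duplicate-then-split lets copies of one row land in train and test
  set.seed(11)
  fx <- make_features(40, 8, shift = 0, seed = 11)  # pure noise
  leaky <- oversample(fx$X, fx$y)
  res_leaky <- svm_classify(leaky$X, leaky$y, folds = 4, C = 10, gamma = 0.1,
                            seed = 2)
  res_clean <- svm_classify(fx$X, fx$y, folds = 4, C = 10, gamma = 0.1,
                            balance = TRUE, seed = 2)
  # leaked pipeline memorises duplicated minority rows; clean stays at chance
  expect_gt(res_leaky$report$auc, res_clean$report$auc + 0.15)
  expect_lt(abs(res_clean$report$auc - 0.5), 0.25)
})

test_that("logistic regression classifies separable PIs and shapes coefficients", {
  fx <- make_features(25, 25, p = 25, shift = 1.5, seed = 8)
  res <- lr_classify(fx$X, fx$y, folds = 5, grid_size = 5, seed = 1)
  expect_gt(res$cv_accuracy, 0.9)
  expect_length(res$coef_image, 1)
  expect_equal(dim(res$coef_image[[1]]), c(5L, 5L))

  # zero-variance pixel gets a (regularised) near-zero coefficient
  Xz <- fx$X; Xz[, 7] <- 0
  resz <- lr_classify(Xz, fx$y, folds = 5, seed = 1)
  expect_equal(resz$coefficients[7], 0)
})

test_that("rf_screen finds the informative pair and excludes noise", {
  set.seed(21)
  n <- 60
  y <- c(rep("NR", 45), rep("R", 15))
  informative <- rbind(matrix(rnorm(45 * 8, 0), 45, 8),
                       matrix(rnorm(15 * 8, 2.5), 15, 8))
  feats <- list("CD10-CD20" = informative,
                "CD38-CD45" = matrix(rnorm(n * 8), n, 8),
                "CD10-CD38" = matrix(rnorm(n * 8), n, 8))
  res <- rf_screen(feats, y, seed = 5)
  expect_s3_class(res, "screen_result")
  expect_identical(res$pair[1], "CD10-CD20")
  expect_gt(res$mean_accuracy[1], 0.95)
  expect_true(res$high_confidence[1])

  # same master seed twice -> identical results
  expect_identical(res, rf_screen(feats, y, seed = 5))

  # permuted labels: AUC near 0.5 for every pair
  set.seed(3)
  res_null <- rf_screen(feats, sample(y), seed = 5)
  expect_true(all(abs(res_null$mean_auc - 0.5) < 0.18))
})

test_that("screening monotonicity: adding noise pairs never flips an informative pair", {
  set.seed(31)
  y <- c(rep("NR", 30), rep("R", 10))
  informative <- rbind(matrix(rnorm(30 * 8), 30, 8),
                       matrix(rnorm(10 * 8, 2.5), 10, 8))
  base <- list("CD10-CD20" = informative)
  more <- c(base, list("N1" = matrix(rnorm(40 * 8), 40, 8),
                       "N2" = matrix(rnorm(40 * 8), 40, 8)))
  r1 <- rf_screen(base, y, seed = 9)
  r2 <- rf_screen(more, y, seed = 9)
  expect_identical(r1[r1$pair == "CD10-CD20", "included"],
                   r2[r2$pair == "CD10-CD20", "included"])
})

test_that("pt_distance_score implements the distance-ratio formula", {
  mk <- function(counts) structure(list(tau = seq_along(counts),
                                        count = counts,
                                        percentage = counts / 10,
                                        dim = 1L, n_bars = 10),
                                   class = "pt_curve")
  mean_nr <- list(a = mk(c(1, 1)), b = mk(c(2, 2)))
  mean_r <- list(a = mk(c(5, 5)), b = mk(c(6, 6)))

  # patient identical to the R mean -> probability 1
  expect_equal(as.numeric(pt_distance_score(mean_r, mean_nr, mean_r)), 1)
  # equidistant -> 0.5
  mid <- list(a = mk(c(3, 3)), b = mk(c(4, 4)))
  expect_equal(as.numeric(pt_distance_score(mid, mean_nr, mean_r)), 0.5)
  # both distances zero -> 0.5 by convention
  expect_equal(as.numeric(pt_distance_score(mean_nr, mean_nr, mean_nr)), 0.5)
  # grid mismatch detected
  bad <- list(a = mk(c(3, 3, 3)), b = mk(c(4, 4)))
  expect_error(pt_distance_score(bad, mean_nr, mean_r), "mismatch")
})
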