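#' Stratified fold assignment
#'
#' Deals the indices of each class round-robin into `k` folds after a seeded
#' shuffle, so every fold preserves the class proportions as closely as
#' integer counts allow.
#'
#' @param y class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.character(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

stratified_split <- function(y, train_frac, seed = 1L) {
  y <- as.character(y)
  train <- logical(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      n_tr <- max(1L, round(train_frac * length(idx)))
      train[idx[seq_len(n_tr)]] <- TRUE
    }
  })
  train
}

#' Balance classes by duplicating minority rows
#'
#' The minority class rows are repeated cyclically (exact duplicates, no
#' interpolation) until both classes have equal counts; the majority class is
#' untouched. Intended to be applied inside training folds only.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @return List with balanced `X` and `y`.
#' @export
oversample <- function(X, y) {
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) < 2) stop("oversample requires both classes present")
  if (length(tab) > 2) stop("oversample supports binary labels only")
  minority <- names(tab)[which.min(tab)]
  n_extra <- max(tab) - min(tab)
  if (n_extra == 0) return(list(X = X, y = y))
  idx <- which(y == minority)
  add <- rep(idx, length.out = n_extra)
  list(X = rbind(X, X[add, , drop = FALSE]), y = c(y, y[add]))
}

#' Fit / apply an RBF-kernel support vector machine
#'
#' Binary C-SVM with Gaussian kernel `K(x, x') = exp(-gamma ||x - x'||^2)`,
#' trained by a deterministic SMO solver. `svm_predict` returns decision
#' values (positive = `positive` class) and hard labels.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param C soft-margin penalty (> 0).
#' @param gamma kernel width (> 0).
#' @param positive label treated as the positive class (decision value > 0).
#' @return `svm_fit`: an `svm_model`; `svm_predict`: list with `decision` and
#'   `label`.
#' @export
svm_fit <- function(X, y, C = 10, gamma = 0.001, positive = "R") {
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive")
  X <- as.matrix(X)
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) != 2) stop("svm_fit requires exactly two classes")
  if (!positive %in% lev) positive <- lev[1]
  ypm <- ifelse(y == positive, 1, -1)
  fit <- .svm_smo_cpp(X, ypm, C, gamma, 1e-3, 5L)
  structure(list(X = X, ypm = ypm, alpha = fit$alpha, b = fit$b,
                 gamma = gamma, C = C, positive = positive,
                 negative = setdiff(lev, positive)),
            class = "svm_model")
}

#' @rdname svm_fit
#' @param model an `svm_model`.
#' @param newdata feature matrix to score.
#' @export
svm_predict <- function(model, newdata) {
  dec <- .svm_decision_cpp(model$X, model$ypm, model$alpha, model$b,
                           model$gamma, as.matrix(newdata))
  list(decision = dec,
       label = ifelse(dec > 0, model$positive, model$negative))
}

default_svm_grid <- function() {
  list(C = 10^seq(-2, 13), gamma = 10^seq(-9, 3))
}

#' Standard binary classification metrics
#'
#' Accuracy, balanced accuracy (mean of per-class recalls, whose chance
#' level is 0.5 regardless of class imbalance), precision, recall, F1 and
#' confusion matrix from hard labels; AUC from scores via the rank
#' (Mann-Whitney) statistic. If `y_true` contains a single class the AUC is
#' undefined and reported as `NA` with a warning.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels.
#' @param y_score real-valued scores (larger = more `positive`); optional.
#' @param positive positive-class label.
#' @return List of metrics (`accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `confusion`).
#' @export
classification_report <- function(y_true, y_pred, y_score = NULL,
                                  positive = "R") {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  acc <- (tp + tn) / length(y_true)
  rec_pos <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  rec_neg <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bal_acc <- mean(c(rec_pos, rec_neg), na.rm = TRUE)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  auc <- NA_real_
  if (!is.null(y_score)) {
    pos <- y_true == positive
    if (all(pos) || !any(pos)) {
      warning("AUC undefined: y_true contains a single class")
    } else {
      r <- rank(y_score)
      n1 <- sum(pos); n0 <- sum(!pos)
      auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(truth = c(positive, "other"),
                                      predicted = c(positive, "other")))
  list(accuracy = acc, balanced_accuracy = bal_acc, precision = prec,
       recall = rec, f1 = f1, auc = auc, confusion = confusion)
}

#' Cross-validated SVM classification of persistence-image features
#'
#' Outer stratified k-fold cross-validation. Within each training fold,
#' optionally: (i) minority oversampling (duplication), applied to training
#' data only, and (ii) hyperparameter selection over a logarithmic `(C,
#' gamma)` grid by inner stratified cross-validation. The default is the
#' fixed regime `C = 10`, `gamma = 0.001`. Test folds are never oversampled
#' and never seen by the grid search, so reported metrics are leakage-free.
#'
#' @param X feature matrix (rows = patients), e.g. from [pi_feature()].
#' @param y binary labels.
#' @param folds outer folds (default 6); reduced with a warning if the
#'   minority class has fewer members.
#' @param C,gamma fixed hyperparameters, used when `grid` is NULL.
#' @param grid optional list with vectors `C` and `gamma` to grid-search
#'   (see `default_svm_grid()` for the full logarithmic ranges).
#' @param inner_folds folds for the inner grid-search CV (default 3).
#' @param balance apply in-fold minority oversampling (default FALSE).
#' @param standardize z-score each feature on the training fold and apply the
#'   fitted scaling to the test fold (default TRUE). Persistence-image pixel
#'   masses are extensive in the grid size (they shrink as the grid refines),
#'   so a single fixed `(C, gamma)` regime is only meaningful across grid
#'   choices after per-feature scaling; constant features are left at zero.
#' @param positive positive-class label.
#' @param seed master RNG seed (folds and inner splits derive from it).
#' @return List: pooled `report` (from [classification_report()]),
#'   `fold_accuracy`, `cv_accuracy` (mean of fold accuracies), per-fold
#'   `chosen` hyperparameters, `prediction` data frame.
#' @export
svm_classify <- function(X, y, folds = 6L, C = 10, gamma = 0.001, grid = NULL,
                         inner_folds = 3L, balance = FALSE,
                         standardize = TRUE, positive = "R", seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (!all(is.finite(X))) stop("features must be finite")
  tab <- table(y)
  if (length(tab) != 2) stop("need exactly two classes")
  k <- min(folds, min(tab))
  if (k < folds)
    warning("reducing folds from ", folds, " to ", k,
            " (minority class has ", min(tab), " members)")
  if (k < 2) stop("minority class too small for cross-validation")
  if (!is.null(grid) && (length(grid$C) == 0 || length(grid$gamma) == 0))
    stop("degenerate hyperparameter grid")
  fold <- stratified_folds(y, k, seed = seed)
  dec <- numeric(length(y))
  pred <- character(length(y))
  fold_acc <- numeric(k)
  chosen <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]
    if (standardize) {
      sc <- fit_scaler(Xtr)
      Xtr <- apply_scaler(sc, Xtr)
      Xte <- apply_scaler(sc, Xte)
    }
    if (!is.null(grid)) {
      hp <- svm_grid_search(Xtr, ytr, grid, inner_folds, balance, positive,
                            seed = seed * 131L + f)
    } else {
      hp <- list(C = C, gamma = gamma)
    }
    if (balance) {
      os <- oversample(Xtr, ytr)
      Xtr <- os$X; ytr <- os$y
    }
    model <- svm_fit(Xtr, ytr, C = hp$C, gamma = hp$gamma, positive = positive)
    pr <- svm_predict(model, Xte)
    dec[!tr] <- pr$decision
    pred[!tr] <- pr$label
    fold_acc[f] <- mean(pr$label == y[!tr])
    chosen[[f]] <- hp
  }
  list(report = classification_report(y, pred, dec, positive = positive),
       fold_accuracy = fold_acc, cv_accuracy = mean(fold_acc),
       chosen = chosen, folds = k,
       prediction = data.frame(truth = y, predicted = pred, decision = dec))
}

# per-feature z-scoring fitted on training data; constant features stay 0
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- Inf  # constant -> scaled to 0
  list(mu = mu, sd = sd_)
}

apply_scaler <- function(sc, X) {
  sweep(sweep(X, 2, sc$mu, "-"), 2, sc$sd, "/")
}

svm_grid_search <- function(X, y, grid, inner_folds, balance, positive, seed) {
  k <- min(inner_folds, min(table(y)))
  if (k < 2) return(list(C = grid$C[1], gamma = grid$gamma[1]))
  fold <- stratified_folds(y, k, seed = seed)
  best <- NULL; best_acc <- -1
  for (C in grid$C) for (g in grid$gamma) {
    acc <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      if (balance) {
        os <- oversample(Xtr, ytr)
        Xtr <- os$X; ytr <- os$y
      }
      m <- svm_fit(Xtr, ytr, C = C, gamma = g, positive = positive)
      acc <- acc + mean(svm_predict(m, X[!tr, , drop = FALSE])$label == y[!tr])
    }
    acc <- acc / k
    if (acc > best_acc + 1e-12) {  # ties: first (smallest C, then gamma)
      best_acc <- acc
      best <- list(C = C, gamma = g)
    }
  }
  best
}

#' Cross-validated logistic-regression classification of persistence images
#'
#' Ridge-penalised logistic regression (small fixed penalty for numerical
#' stability on wide pixel matrices) with outer stratified k-fold CV, plus a
#' coefficient image: the decision-function coefficients of a full-data fit,
#' reshaped to the persistence-image grid for visual interpretation.
#'
#' @param X feature matrix of flattened persistence images.
#' @param y binary labels.
#' @param folds outer folds (default 6).
#' @param lambda ridge penalty (default 1e-3).
#' @param grid_size if supplied, coefficients are reshaped into
#'   `grid_size x grid_size` matrices (one per concatenated dimension block).
#' @param positive positive-class label.
#' @param seed RNG seed.
#' @return As [svm_classify()], plus `coefficients` and `coef_image` (list of
#'   matrices when `grid_size` is given).
#' @export
lr_classify <- function(X, y, folds = 6L, lambda = 1e-3, grid_size = NULL,
                        positive = "R", seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) != 2) stop("need exactly two classes")
  k <- min(folds, min(tab))
  if (k < folds)
    warning("reducing folds from ", folds, " to ", k)
  if (k < 2) stop("minority class too small for cross-validation")
  yf <- factor(y, levels = c(setdiff(names(tab), positive), positive))
  fold <- stratified_folds(y, k, seed = seed)
  prob <- numeric(length(y))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], yf[tr], family = "binomial",
                          alpha = 0, lambda = lambda, standardize = FALSE)
    prob[!tr] <- as.numeric(stats::predict(fit, X[!tr, , drop = FALSE],
                                           type = "response"))
    fold_acc[f] <- mean((prob[!tr] > 0.5) == (y[!tr] == positive))
  }
  pred <- ifelse(prob > 0.5, positive, setdiff(names(tab), positive))
  full <- glmnet::glmnet(X, yf, family = "binomial", alpha = 0,
                         lambda = lambda, standardize = FALSE)
  coefs <- as.numeric(full$beta)
  coef_image <- NULL
  if (!is.null(grid_size)) {
    g2 <- grid_size^2
    if (length(coefs) %% g2 != 0)
      stop("coefficient length not a multiple of grid_size^2")
    nblock <- length(coefs) / g2
    coef_image <- lapply(seq_len(nblock), function(b) {
      matrix(coefs[((b - 1) * g2 + 1):(b * g2)], grid_size, grid_size,
             byrow = TRUE)
    })
  }
  list(report = classification_report(y, pred, prob, positive = positive),
       fold_accuracy = fold_acc, cv_accuracy = mean(fold_acc), folds = k,
       coefficients = coefs, coef_image = coef_image,
       prediction = data.frame(truth = y, predicted = pred, prob = prob))
}

#' Random-forest fit-and-predict on descriptor features
#'
#' @param X training features; `y` binary labels; `Xtest` features to score.
#' @param ntree number of trees; `mtry` defaults to `floor(sqrt(p))`.
#' @param seed RNG seed (deterministic forest).
#' @param positive positive-class label.
#' @return List with `prob` (P(positive)) and `label`.
#' @keywords internal
rf_predict_prob <- function(X, y, Xtest, ntree = 50L, mtry = NULL, seed = 1L,
                            positive = "R") {
  X <- as.matrix(X); Xtest <- as.matrix(Xtest)
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("single-class training split")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  y01 <- as.integer(y == positive)
  prob <- .rf_fit_predict_cpp(X, y01, Xtest, as.integer(ntree),
                              as.integer(mtry), 2L, as.integer(seed))
  lev <- unique(y)
  list(prob = prob,
       label = ifelse(prob > 0.5, positive, setdiff(lev, positive)[1]))
}

#' Random-forest screening of pairwise marker combinations
#'
#' For each marker pair, a random forest is trained on the patients'
#' 8-dimensional barcode descriptor vectors over `n_iter` repetitions of a
#' stratified train/test split (default 60/40), with the number of trees
#' stepping through `n_estimators_range`. Pairs whose mean test AUC falls
#' below 0.5 are flagged as carrying very low information and excluded; pairs
#' with mean accuracy above `acc_threshold` (default 0.7) form the
#' high-confidence tier.
#'
#' @param features named list (one entry per marker pair) of matrices,
#'   patients x 8 descriptors.
#' @param labels binary patient labels, aligned with the feature rows.
#' @param n_estimators_range range of tree counts (default `c(20, 100)`).
#' @param n_iter repetitions (default 10).
#' @param split training fraction (default 0.6).
#' @param acc_threshold high-confidence accuracy cut (default 0.7).
#' @param positive positive-class label.
#' @param seed master seed; all splits and forests derive from it.
#' @return A `screen_result` data frame: `pair`, `mean_accuracy`, `mean_auc`,
#'   `included`, `high_confidence`, sorted by decreasing mean AUC.
#' @export
rf_screen <- function(features, labels, n_estimators_range = c(20L, 100L),
                      n_iter = 10L, split = 0.6, acc_threshold = 0.7,
                      positive = "R", seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2) stop("need exactly two classes")
  ntrees <- round(seq(n_estimators_range[1], n_estimators_range[2],
                      length.out = n_iter))
  rows <- lapply(seq_along(features), function(pi) {
    X <- as.matrix(features[[pi]])
    if (nrow(X) != length(labels)) stop("feature/label length mismatch")
    accs <- numeric(n_iter); aucs <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      s <- seed * 1009L + pi * 97L + it
      tr <- stratified_split(labels, split, seed = s)
      if (length(unique(labels[tr])) < 2 || length(unique(labels[!tr])) < 2)
        stop("single-class split; increase cohort size")
      pr <- rf_predict_prob(X[tr, , drop = FALSE], labels[tr],
                            X[!tr, , drop = FALSE], ntree = ntrees[it],
                            seed = s, positive = positive)
      rep_ <- classification_report(labels[!tr], pr$label, pr$prob,
                                    positive = positive)
      accs[it] <- rep_$accuracy
      aucs[it] <- rep_$auc
    }
    data.frame(pair = names(features)[pi], mean_accuracy = mean(accs),
               mean_auc = mean(aucs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$included <- out$mean_auc >= 0.5
  out$high_confidence <- out$mean_accuracy > acc_threshold
  out <- out[order(-out$mean_auc), ]
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' PT-curve distance prognostic score
#'
#' For each marker pair (and homology dimension supplied), the Euclidean
#' distance between the patient's PT curve (bar counts) and the cohort mean
#' curves of the non-relapsing and relapsing groups is computed; the per-pair
#' relapse score is `d_NR / (d_NR + d_R)` (1 when the patient sits exactly on
#' the relapsing mean, 0.5 when both distances vanish), and the final relapse
#' probability is the unweighted arithmetic mean over pairs.
#'
#' @param patient_curves named list of `pt_curve` for one patient (keys =
#'   pair/dimension identifiers).
#' @param mean_nr,mean_r named lists of cohort mean `pt_curve`s with the same
#'   keys and tau grids.
#' @return Relapse probability in \[0, 1\]; per-key scores in attribute
#'   `per_pair`.
#' @export
pt_distance_score <- function(patient_curves, mean_nr, mean_r) {
  keys <- names(patient_curves)
  if (length(keys) < 1) stop("need at least one marker pair")
  if (!setequal(keys, names(mean_nr)) || !setequal(keys, names(mean_r)))
    stop("curve keys mismatch across patient and cohort means")
  per <- vapply(keys, function(k) {
    pc <- patient_curves[[k]]; mnr <- mean_nr[[k]]; mr <- mean_r[[k]]
    if (length(pc$tau) != length(mnr$tau) || any(pc$tau != mnr$tau) ||
        any(pc$tau != mr$tau))
      stop("tau grid mismatch for key ", k)
    d_nr <- sqrt(sum((pc$count - mnr$count)^2))
    d_r <- sqrt(sum((pc$count - mr$count)^2))
    if (d_nr == 0 && d_r == 0) return(0.5)
    d_nr / (d_nr + d_r)
  }, numeric(1))
  structure(mean(per), per_pair = per)
}
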