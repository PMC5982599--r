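## helper: wrap a matrix as a standardized_matrix (bypassing z-scoring)
## for analytic SVD fixtures
as_std <- function(Y, classes = NULL) {
  structure(list(Y = Y, descriptors = paste0("d", seq_len(nrow(Y))),
                 lesion_ids = paste0("L", seq_len(ncol(Y))),
                 classes = classes, center = rep(0, nrow(Y)),
                 scale = rep(1, nrow(Y))),
            class = "standardized_matrix")
}

test_that("standardization z-scores rows with the population deviation", {
  tab <- fixture_table(stats::setNames(list(c(1, 3), c(10, 10.5)),
                                       c("VISNIR.414.R.mean",
                                         "VISNIR.477.R.mean")),
                       c("nevus", "melanoma"))
  m <- standardize(tab, c("VISNIR.414.R.mean", "VISNIR.477.R.mean"))
  expect_equal(m$Y[1, ], c(-1, 1))          # population sigma = 1
  expect_equal(unname(rowMeans(m$Y)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(m$Y^2))), c(1, 1), tolerance = 1e-12)

  ## idempotence: standardizing an already-standardized table is a no-op
  tab2 <- fixture_table(stats::setNames(list(m$Y[1, ], m$Y[2, ]),
                                        m$descriptors), tab$class)
  m2 <- standardize(tab2, m$descriptors)
  expect_equal(m2$Y, m$Y, tolerance = 1e-12)

  tabc <- fixture_table(stats::setNames(list(c(1, 1), c(1, 2)),
                                        c("VISNIR.414.R.mean",
                                          "VISNIR.477.R.mean")),
                        c("nevus", "melanoma"))
  expect_error(standardize(tabc, c("VISNIR.414.R.mean", "VISNIR.477.R.mean")),
               "zero variance descriptor: VISNIR.414.R.mean")
  expect_error(standardize(tab, "VISNIR.999.R.mean"), "not in table")
})

test_that("SVD of a diagonal matrix gives the hand-computed decomposition", {
  model <- pca_svd(as_std(matrix(c(3, 0, 0, 1), 2, 2)))
  expect_equal(model$d, c(3, 1))
  expect_equal(model$explained_variance, c(0.9, 0.1))
  expect_equal(pc_scores(model, 1), c(3, 0))
  expect_equal(pc_scores(model, 2), c(0, 1))
})

test_that("the SVD reconstructs, orders components, and conserves score energy", {
  set.seed(50)
  Y <- matrix(rnorm(5 * 12), 5, 12)
  Y <- (Y - rowMeans(Y)) / sqrt(rowMeans((Y - rowMeans(Y))^2))
  model <- pca_svd(as_std(Y))
  D <- matrix(0, 5, 12); diag(D) <- model$d
  expect_equal(model$U %*% D %*% t(model$V), Y, tolerance = 1e-8)
  expect_true(all(diff(model$d) <= 1e-12))
  expect_equal(sum(model$explained_variance), 1, tolerance = 1e-10)
  ## sign convention: largest-|entry| of each U column positive
  for (j in seq_len(ncol(model$U)))
    expect_gt(model$U[which.max(abs(model$U[, j])), j], 0)
  ## orthogonality and Parseval over scores
  scores <- sapply(seq_along(model$d), function(k) pc_scores(model, k))
  gram <- crossprod(scores)
  expect_equal(gram, diag(model$d^2), tolerance = 1e-8)
  expect_equal(sum(scores^2), sum(model$d^2), tolerance = 1e-8)

  rank1 <- pca_svd(as_std(outer(c(1, 2, 3), c(1, -1, 2, 0))))
  expect_equal(sum(rank1$d > 1e-10), 1)
  expect_error(pc_scores(model, 99), "out of range")
  expect_error(pca_svd(as_std(matrix(c(1, NA, 2, 3), 2, 2))), "non-finite")
})

test_that("a two-point SVM boundary is the perpendicular bisector", {
  pts <- rbind(c(0, 0), c(2, 2))
  bd <- train_svm(pts, c("melanoma", "nevus"), cost = 1e4)
  expect_equal(nrow(bd$support_vectors), 2)
  mid <- rbind(c(1, 1))
  expect_equal(abs(decision_values(bd, mid)), 0, tolerance = 1e-6)
  ## weight vector is parallel to the point difference
  wd <- bd$w / sqrt(sum(bd$w^2))
  expect_equal(abs(sum(wd * c(1, 1) / sqrt(2))), 1, tolerance = 1e-6)
  ## margin equals the inter-point distance
  expect_equal(bd$margin, sqrt(8), tolerance = 1e-3)
})

test_that("separable clouds are classified perfectly and label flips mirror the boundary", {
  set.seed(51)
  x <- rbind(matrix(rnorm(40, -2, 0.3), 20, 2),
             matrix(rnorm(40, 2, 0.3), 20, 2))
  y <- rep(c("melanoma", "nevus"), each = 20)
  bd <- train_svm(x, y)
  expect_gt(bd$margin, 0)
  rep_ <- evaluate(bd, x, y)
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$specificity, 1)

  ## flipping the labels leaves the boundary in place and mirrors the calls
  bd2 <- train_svm(x, rev(y))
  expect_equal(abs(decision_values(bd, x)), abs(decision_values(bd2, x)),
               tolerance = 1e-6)
  p1 <- stats::predict(bd$fit, x)
  p2 <- stats::predict(bd2$fit, x)
  expect_true(all(p1 != p2))

  expect_error(train_svm(x, rep("nevus", 40)), "both classes")
})

test_that("sensitivity and specificity follow their confusion-count definitions", {
  r <- classification_report(TP = 11, FN = 3, TN = 33, FP = 6)
  expect_equal(r$sensitivity_pct, 78.6)   # 11/14
  expect_equal(r$specificity_pct, 84.6)   # 33/39
  expect_equal(r$TP + r$FN + r$TN + r$FP, 53)
  perfect <- classification_report(TP = 14, FN = 0, TN = 39, FP = 0)
  expect_equal(perfect$sensitivity_pct, 100)
  expect_equal(perfect$specificity_pct, 100)
})

test_that("cross-validated evaluation pools held-out folds and is seed-stable", {
  set.seed(53)
  x <- rbind(matrix(rnorm(28, -2, 0.3), 14, 2),
             matrix(rnorm(44, 2, 0.3), 22, 2))
  y <- c(rep("melanoma", 14), rep("nevus", 22))
  r1 <- evaluate_cv(x, y, k = 5, seed = 9)
  r2 <- evaluate_cv(x, y, k = 5, seed = 9)
  expect_equal(r1, r2)
  expect_equal(r1$TP + r1$FN, 14)
  expect_equal(r1$TN + r1$FP, 22)
  expect_gte(r1$sensitivity, 0.9)   # well-separated clouds survive CV
  expect_gte(r1$specificity, 0.9)
  expect_error(evaluate_cv(x[1:15, ], y[1:15], k = 15), "single-class")
})

test_that("PC-pair selection finds the discriminating component", {
  set.seed(52)
  n <- 12
  classes <- rep(c("melanoma", "nevus"), each = n / 2)
  sep <- rep(c(1, -1), each = n / 2) + rnorm(n, 0, 0.05)
  ## orthonormal V with the class signal isolated in one column
  make_model <- function(signal_col) {
    Q <- qr.Q(qr(cbind(sep, matrix(rnorm(n * 2), n, 2))))
    cols <- switch(signal_col,
                   `1` = Q[, c(1, 2, 3)],
                   `3` = Q[, c(2, 3, 1)])
    structure(list(U = diag(3), d = c(5, 3, 2), V = cols,
                   explained_variance = c(25, 9, 4) / 38,
                   lesion_ids = paste0("L", 1:n), classes = classes,
                   rank = 3), class = "pca_model")
  }
  best3 <- select_pc_pair(make_model("3"))
  expect_true(3 %in% best3$pair)
  expect_equal(best3$report$sensitivity, 1)
  expect_equal(best3$report$specificity, 1)

  best1 <- select_pc_pair(make_model("1"))
  expect_true(1 %in% best1$pair)
  ## ties go to the first pair in enumeration order: only PC1 informs, so
  ## (1,2) and (1,3) tie and (1,2) wins
  expect_equal(best1$pair, c(1, 2))
})
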