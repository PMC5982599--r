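## Classification stage: z-score standardization of the selected
## descriptors, principal components via the singular value decomposition
## of the d x n standardized matrix, and a maximum-margin SVM boundary on
## a chosen pair of principal-component scores.

#' Standardize selected descriptor columns
#'
#' Builds the d x n matrix Y whose rows are the selected descriptors
#' z-scored across lesions: `(value - mean) / std`, with the population
#' standard deviation (divide by n).
#'
#' @param table descriptor table with `id` and `class` columns.
#' @param descriptors descriptor ids to include (rows of Y, in order).
#' @return A `standardized_matrix`: list with `Y` (d x n), `descriptors`,
#'   `lesion_ids`, `classes`, and the `center`/`scale` used per row.
#' @export
standardize <- function(table, descriptors) {
  missing <- setdiff(descriptors, names(table))
  if (length(missing))
    stop("descriptors not in table: ", paste(missing, collapse = ", "))
  X <- t(as.matrix(table[, descriptors, drop = FALSE]))
  n <- ncol(X)
  ctr <- rowMeans(X)
  scl <- sqrt(rowMeans((X - ctr)^2))
  if (any(scl < 1e-12))
    stop("zero variance descriptor: ",
         paste(descriptors[scl < 1e-12], collapse = ", "))
  structure(list(Y = (X - ctr) / scl, descriptors = descriptors,
                 lesion_ids = table$id, classes = table$class,
                 center = ctr, scale = scl),
            class = "standardized_matrix")
}

#' Principal components of a standardized matrix via SVD
#'
#' Full singular value decomposition `Y = U D V^t` of the d x n
#' standardized matrix. The explained-variance fraction of component k is
#' `D(k,k)^2 / sum_j D(j,j)^2`. Sign convention: each column of U has its
#' largest-magnitude entry positive (the matching V column is flipped
#' with it), so component scores are reproducible.
#'
#' @param m a [standardize()] result.
#' @return A `pca_model`: list with `U` (d x d), `d` (singular values),
#'   `V` (n x n), `explained_variance`, plus the lesion ids and classes
#'   carried through.
#' @export
pca_svd <- function(m) {
  stopifnot(inherits(m, "standardized_matrix"))
  Y <- m$Y
  if (!all(is.finite(Y))) stop("non-finite entries in standardized matrix")
  dd <- nrow(Y); n <- ncol(Y)
  if (dd < 2 || n < 2) stop("need at least 2 descriptors and 2 lesions")
  s <- svd(Y, nu = dd, nv = n)
  r <- length(s$d)
  for (j in seq_len(ncol(s$u))) {
    i_max <- which.max(abs(s$u[, j]))
    if (s$u[i_max, j] < 0) {
      s$u[, j] <- -s$u[, j]
      if (j <= ncol(s$v)) s$v[, j] <- -s$v[, j]
    }
  }
  ev <- s$d^2 / sum(s$d^2)
  structure(list(U = s$u, d = s$d, V = s$v, explained_variance = ev,
                 lesion_ids = m$lesion_ids, classes = m$classes,
                 rank = r), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %d components; explained variance %s%%>\n",
              length(x$d),
              paste(sprintf("%.1f", 100 * x$explained_variance[
                seq_len(min(3, length(x$d)))]), collapse = ", ")))
  invisible(x)
}

#' Principal-component scores
#'
#' Component k scores one lesion per entry: `D(k,k) * V(:,k)`.
#'
#' @param model a [pca_svd()] result.
#' @param k component index, `1 <= k <= min(d, n)`.
#' @return numeric vector of length n.
#' @export
pc_scores <- function(model, k) {
  stopifnot(inherits(model, "pca_model"))
  if (k < 1 || k > length(model$d)) stop("component index out of range")
  model$d[k] * model$V[, k]
}

#' Train a maximum-margin SVM boundary on a PC-score pair
#'
#' Soft-margin SVM (penalty `cost`) on 2-D points; linear kernel by
#' default, matching the maximum-margin hyperplane exposition (an RBF
#' kernel is available through `kernel`). Inputs are used as-is (no
#' internal rescaling), so the boundary lives in PC-score coordinates.
#'
#' @param scores n x 2 matrix of component scores.
#' @param labels per-point class labels (`"melanoma"` / `"nevus"`).
#' @param cost soft-margin penalty C (default 1).
#' @param kernel `"linear"` (default) or `"radial"`.
#' @return An `svm_boundary`: the fitted model plus, for the linear
#'   kernel, the weight vector `w`, offset `b` (decision value
#'   `w . x + b`) and geometric `margin = 2 / |w|`.
#' @export
train_svm <- function(scores, labels, cost = 1,
                      kernel = c("linear", "radial")) {
  kernel <- match.arg(kernel)
  scores <- as.matrix(scores)
  labels <- factor(labels, levels = c("melanoma", "nevus"))
  if (length(unique(labels[!is.na(labels)])) < 2)
    stop("both classes must be present to train an SVM")
  fit <- e1071::svm(x = scores, y = labels, kernel = kernel, cost = cost,
                    scale = FALSE)
  w <- NULL; b <- NULL; margin <- NULL
  if (kernel == "linear") {
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    margin <- 2 / sqrt(sum(w^2))
  }
  structure(list(fit = fit, kernel = kernel, cost = cost,
                 support_vectors = fit$SV, w = w, b = b, margin = margin),
            class = "svm_boundary")
}

#' Decision values of an SVM boundary
#'
#' @param boundary a [train_svm()] result.
#' @param scores n x 2 matrix.
#' @return numeric decision values (positive = melanoma side).
#' @export
decision_values <- function(boundary, scores) {
  p <- stats::predict(boundary$fit, as.matrix(scores), decision.values = TRUE)
  ## libsvm orients decision values by the order classes appear in the
  ## training data, so only |value| and the zero level set are
  ## orientation-free; class calls should go through predict()
  as.numeric(attr(p, "decision.values"))
}

#' Confusion counts, sensitivity and specificity
#'
#' Melanoma is the positive class: sensitivity = TP / (TP + FN) over
#' melanomas, specificity = TN / (TN + FP) over nevi. The percentage
#' fields are rounded to one decimal.
#'
#' @param boundary a [train_svm()] result.
#' @param scores n x 2 matrix of points to classify.
#' @param labels true labels.
#' @return A `classification_report`: list with `TP`, `FN`, `TN`, `FP`,
#'   `sensitivity`, `specificity` (fractions) and
#'   `sensitivity_pct`/`specificity_pct` (rounded percentages).
#' @export
evaluate <- function(boundary, scores, labels) {
  stopifnot(length(labels) == nrow(as.matrix(scores)))
  pred <- stats::predict(boundary$fit, as.matrix(scores))
  classification_report(
    TP = sum(pred == "melanoma" & labels == "melanoma"),
    FN = sum(pred == "nevus" & labels == "melanoma"),
    TN = sum(pred == "nevus" & labels == "nevus"),
    FP = sum(pred == "melanoma" & labels == "nevus"))
}

#' @rdname evaluate
#' @param TP,FN,TN,FP confusion counts (melanoma positive).
#' @export
classification_report <- function(TP, FN, TN, FP) {
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP,
                 sensitivity = sens, specificity = spec,
                 sensitivity_pct = round(100 * sens, 1),
                 specificity_pct = round(100 * spec, 1)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report: TP %d FN %d TN %d FP %d | sensitivity %.1f%%, specificity %.1f%%>\n",
    x$TP, x$FN, x$TN, x$FP, x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}

#' Cross-validated boundary evaluation
#'
#' The headline evaluation is resubstitution (train = test), matching the
#' pilot-study setting where the cohort was large enough to train but not
#' to hold lesions out. This helper provides the honest alternative:
#' stratified k-fold cross-validation of the SVM on a PC-score pair,
#' pooling the held-out confusion counts.
#'
#' @param scores n x 2 matrix of component scores.
#' @param labels class labels (`"melanoma"` / `"nevus"`).
#' @param k number of folds (default 5).
#' @param cost,kernel see [train_svm()].
#' @param seed RNG seed for the fold assignment.
#' @return A [classification_report()] pooled over held-out folds.
#' @export
evaluate_cv <- function(scores, labels, k = 5, cost = 1, kernel = "linear",
                        seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(length(labels) == n, k >= 2)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  pred <- character(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2)
      stop("fold ", f, " leaves a single-class training set; lower k")
    bd <- train_svm(scores[tr, , drop = FALSE], labels[tr],
                    cost = cost, kernel = kernel)
    pred[!tr] <- as.character(stats::predict(bd$fit,
                                             scores[!tr, , drop = FALSE]))
  }
  classification_report(
    TP = sum(pred == "melanoma" & labels == "melanoma"),
    FN = sum(pred == "nevus" & labels == "melanoma"),
    TN = sum(pred == "nevus" & labels == "nevus"),
    FP = sum(pred == "melanoma" & labels == "nevus"))
}

#' Pick the best principal-component pair
#'
#' Trains and evaluates (by resubstitution) one SVM per candidate PC
#' pair and returns the pair maximizing balanced accuracy
#' `(sensitivity + specificity) / 2`; ties go to the higher sensitivity,
#' then to the earlier pair in enumeration order.
#'
#' @param model a [pca_svd()] result carrying lesion classes.
#' @param labels class labels (default: the model's).
#' @param pairs list of 2-vectors of component indices.
#' @param cost,kernel see [train_svm()].
#' @return list with `pair`, `report`, `boundary`, `scores` and
#'   `all_reports` (one per candidate pair, named `"PCj vs PCk"`).
#' @export
select_pc_pair <- function(model, labels = model$classes,
                           pairs = list(c(1, 2), c(1, 3), c(2, 3)),
                           cost = 1, kernel = "linear") {
  stopifnot(length(model$d) >= max(unlist(pairs)))
  best <- NULL
  all_reports <- list()
  for (p in pairs) {
    sc <- cbind(pc_scores(model, p[1]), pc_scores(model, p[2]))
    colnames(sc) <- paste0("PC", p)
    bd <- train_svm(sc, labels, cost = cost, kernel = kernel)
    rep_ <- evaluate(bd, sc, labels)
    all_reports[[sprintf("PC%d vs PC%d", p[1], p[2])]] <- rep_
    bal <- (rep_$sensitivity + rep_$specificity) / 2
    if (is.null(best) || bal > best$bal + 1e-12 ||
        (abs(bal - best$bal) <= 1e-12 &&
         rep_$sensitivity > best$report$sensitivity + 1e-12)) {
      best <- list(pair = p, report = rep_, boundary = bd, scores = sc,
                   bal = bal)
    }
  }
  best$all_reports <- all_reports
  best$bal <- NULL
  best
}
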