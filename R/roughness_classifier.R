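# Per-sample Q feature vectors, the degree-2 polynomial-kernel SVM grader
# with stratified four-fold cross-validation, and confusion-matrix metrics.

#' Extract per-layer roughness features from a cone mesh
#'
#' Runs the full per-layer chain — [slice_mesh()], [fit_circle()],
#' [unwrap()], [spectrum()], [compute_Q()] and [layer_std()] — and returns
#' fixed-length feature vectors ordered bottom to top.  Layers whose slice
#' failed or produced fewer than 16 contour points are imputed with 0 (the
#' perfect-smoothness null) and flagged in `absent`.
#'
#' @param mesh a [triangle_mesh()].
#' @param n_layers number of slicing layers, default 40.
#' @param M resampling grid size, default 512.
#' @param lam_min,lam_max Q integration band; `NULL` (default) uses the
#'   per-layer default band of [compute_Q()].
#' @param sample_id optional sample name.
#' @param true_class optional known class (0..3) or `NA`.
#' @return an object of class `sample_features` with vectors `q`, `std`,
#'   `R`, `z`, logical `absent`, plus `sample_id` and `true_class`.
#' @export
extract_features <- function(mesh, n_layers = 40L, M = 512L,
                             lam_min = NULL, lam_max = NULL,
                             sample_id = NA_character_,
                             true_class = NA_integer_) {
  slices <- slice_mesh(mesh, n_layers)
  q <- numeric(n_layers)
  std <- numeric(n_layers)
  Rfit <- rep(NA_real_, n_layers)
  absent <- logical(n_layers)
  for (i in seq_len(n_layers)) {
    cs <- slices[[i]]
    if (is.null(cs) || nrow(cs$points) < 16L) {
      absent[i] <- TRUE
      next
    }
    ok <- tryCatch({
      fit <- fit_circle(cs)
      prof <- unwrap(cs, fit, M)
      spec <- spectrum(prof)
      q[i] <- compute_Q(spec, lam_min, lam_max)
      std[i] <- layer_std(prof)
      Rfit[i] <- fit$R
      TRUE
    }, error = function(e) FALSE)
    if (!ok) absent[i] <- TRUE
  }
  if (sum(!absent) < n_layers / 2)
    stop("fewer than half of the layers produced a valid contour")
  structure(list(sample_id = sample_id, true_class = true_class, q = q,
                 std = std, R = Rfit, z = attr(slices, "heights"),
                 absent = absent),
            class = "sample_features")
}

#' @export
print.sample_features <- function(x, ...) {
  cat(sprintf(
    "sample_features: %s (class %s), %d layers (%d absent), mean Q = %.4g\n",
    x$sample_id, ifelse(is.na(x$true_class), "?", x$true_class),
    length(x$q), sum(x$absent), mean(x$q)))
  invisible(x)
}

features_matrix <- function(features) {
  lens <- vapply(features, function(f) length(f$q), 0L)
  if (length(unique(lens)) != 1L)
    stop("feature vectors have inconsistent lengths")
  X <- do.call(rbind, lapply(features, `[[`, "q"))
  colnames(X) <- sprintf("q_%02d", seq_len(ncol(X)))
  X
}

#' Train the roughness-grade SVM
#'
#' Degree-2 polynomial-kernel SVM (one-vs-one multiclass) on per-layer Q
#' feature vectors.  Features are scaled using training data only and the
#' scaling is stored and re-applied at prediction.  The default
#' `scale = "global"` divides the whole feature matrix by its single
#' training-set standard deviation, preserving the relative magnitude of
#' the layers: near-apex layers carry almost no lumpiness signal, and
#' per-column standardisation (`scale = "columns"`) would inflate those
#' noise-only columns to unit variance, letting them swamp the kernel at
#' the small sample sizes this grader runs at.  Training is deterministic
#' for fixed input.
#'
#' @param features list of [extract_features()] results.
#' @param labels integer class labels (0..3), one per sample.
#' @param cost SVM box constraint C, default 10.
#' @param degree polynomial degree, default 2.
#' @param coef0 polynomial kernel offset, default 1 (inhomogeneous kernel,
#'   so linear terms participate).
#' @param gamma polynomial kernel scale, default 0.1.
#' @param scale `"global"` (default), `"columns"` (zero mean / unit
#'   variance per feature) or `"none"`.
#' @return an object of class `roughness_svm`.
#' @export
train_classifier <- function(features, labels, cost = 10, degree = 2L,
                             coef0 = 1, gamma = 0.1,
                             scale = c("global", "columns", "none")) {
  scale <- match.arg(scale)
  X <- features_matrix(features)
  if (nrow(X) != length(labels))
    stop("labels length does not match number of samples")
  if (nrow(X) < 2L) stop("need at least two samples")
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two distinct classes")
  s0 <- 1
  if (scale == "global") {
    s0 <- stats::sd(as.vector(X))
    if (!is.finite(s0) || s0 <= 0) s0 <- 1
    X <- X / s0
  }
  col_scale <- if (scale == "columns")
    !apply(X, 2L, function(col) diff(range(col)) == 0) else FALSE
  model <- suppressWarnings(
    e1071::svm(x = X, y = y, kernel = "polynomial", degree = degree,
               coef0 = coef0, cost = cost, gamma = gamma,
               scale = col_scale))
  structure(list(model = model, levels = levels(y), degree = degree,
                 cost = cost, coef0 = coef0, gamma = gamma,
                 scale = scale, s0 = s0),
            class = "roughness_svm")
}

#' Predict roughness classes
#'
#' @param object a [train_classifier()] model.
#' @param features list of [extract_features()] results (or a numeric
#'   matrix of Q vectors).
#' @param ... unused.
#' @return integer vector of predicted classes.
#' @export
predict.roughness_svm <- function(object, features, ...) {
  X <- if (is.matrix(features)) features else features_matrix(features)
  X <- X / object$s0
  as.integer(as.character(stats::predict(object$model, X)))
}

#' Stratified k-fold cross-validation of the roughness grader
#'
#' Splits the samples into `k` folds (default 4, i.e. 25% held out per
#' fold), stratified by class with seeded shuffling so every fold carries
#' a balanced class mix; trains on k-1 folds and predicts the held-out
#' fold; pools all held-out predictions into one confusion matrix.
#'
#' @param features list of [extract_features()] results.
#' @param labels integer class labels.
#' @param k number of folds, default 4.
#' @param seed integer seed for the stratified shuffle.
#' @param ... passed to [train_classifier()].
#' @return list with `confusion` (true x predicted count matrix),
#'   `accuracy`, `loss` (misclassification rate, 1 - accuracy),
#'   `predicted`, `folds`.
#' @export
cross_validate <- function(features, labels, k = 4L, seed = 1L, ...) {
  n <- length(labels)
  if (length(features) != n) stop("features/labels length mismatch")
  if (k < 2L) stop("k must be >= 2")
  counts <- table(labels)
  if (any(counts < k))
    stop("every class needs at least k samples for stratified k-fold CV")
  fold <- integer(n)
  with_seed(seed, {
    fold_load <- integer(k)
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      # send each class's remainder samples to the lightest folds so the
      # fold sizes stay equal overall (e.g. 24 = 4x6, k = 4 -> 6/6/6/6)
      ord <- order(fold_load)
      assign <- rep_len(ord, length(idx))
      fold[idx] <- assign
      fold_load <- fold_load + tabulate(assign, k)
    }
  })
  lev <- sort(unique(labels))
  pred <- integer(n)
  for (f in seq_len(k)) {
    te <- fold == f
    model <- train_classifier(features[!te], labels[!te], ...)
    pred[te] <- stats::predict(model, features[te])
  }
  cm <- confusion_matrix(labels, pred, levels = lev)
  acc <- sum(diag(cm)) / sum(cm)
  list(confusion = cm, accuracy = acc, loss = 1 - acc, predicted = pred,
       folds = fold)
}

#' Build a confusion matrix
#'
#' @param truth,predicted class label vectors of equal length.
#' @param levels class levels; default the sorted union.
#' @return square count matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels = levels),
              factor(predicted, levels = levels))
  m <- matrix(as.integer(cm), nrow = length(levels),
              dimnames = list(true = as.character(levels),
                              predicted = as.character(levels)))
  m
}

#' Confusion-matrix performance metrics
#'
#' Per-class sensitivity (recall: diagonal over true-class row total),
#' per-class positive predictive value (diagonal over predicted-class
#' column total) — the quantity that roughness-grading studies often
#' tabulate under the name "specificity", here reported as `ppv` — the
#' textbook specificity `TN / (TN + FP)`, and overall accuracy.  A zero
#' row or column makes the corresponding
#' metric undefined and it is reported as `NA`, not 0.
#'
#' @param cm square count matrix (rows = true, columns = predicted).
#' @return list with `sensitivity`, `ppv`,
#'   `specificity`, `accuracy` (all proportions in `[0, 1]`).
#' @export
matrix_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix must be nonnegative")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  d <- diag(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  sens <- ifelse(rs > 0, d / rs, NA_real_)
  ppv <- ifelse(cs > 0, d / cs, NA_real_)
  tn <- total - rs - cs + d
  fp <- cs - d
  spec <- ifelse((tn + fp) > 0, tn / (tn + fp), NA_real_)
  names(sens) <- names(ppv) <- names(spec) <- rownames(cm)
  list(sensitivity = sens, ppv = ppv,
       specificity = spec, accuracy = sum(d) / total)
}

#' Reference confusion matrix of the graded-milk-powder study
#'
#' The 24-cone benchmark outcome (6 samples per class: 3 replicates x 2
#' powder types): classes 0 and 3 fully correct; one class-1 sample
#' predicted as class 0; two class-2 samples predicted as class 0 and
#' class 1.  Serves as a worked example for [matrix_metrics()] — it yields
#' 87.5% overall accuracy, sensitivities 100/83.3/66.7/100% and
#' column-wise PPV 75/83.3/100/100%.
#'
#' @return 4x4 count matrix (rows = true class 0..3, columns = predicted).
#' @export
reference_confusion_matrix <- function() {
  m <- matrix(c(6L, 0L, 0L, 0L,
                1L, 5L, 0L, 0L,
                1L, 1L, 4L, 0L,
                0L, 0L, 0L, 6L),
              nrow = 4L, byrow = TRUE,
              dimnames = list(true = 0:3, predicted = 0:3))
  m
}
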