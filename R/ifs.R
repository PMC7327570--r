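#' Classifier settings for the IFS sweep
#'
#' @param kernel SVM kernel; the headline pipeline uses `"linear"`.
#' @param regularization SVM cost parameter C (> 0).
#' @param seed Integer seed (kept for interface symmetry; the linear SVM and
#'   LOOCV are deterministic).
#' @return A `classifier_params` list.
#' @export
classifier_params <- function(kernel = "linear", regularization = 1, seed = 1L) {
  if (regularization <= 0) stop_invalid("regularization must be positive")
  structure(list(kernel = kernel, regularization = regularization,
                 seed = as.integer(seed)),
            class = "classifier_params")
}

# One-vs-rest multiclass linear SVM: one binary machine per class, predict
# by decision-value argmax. e1071's native multiclass is one-vs-one, so the
# one-vs-rest scheme is assembled here.
fit_ovr_svm <- function(x, y, cp) {
  lapply(levels(y), function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x = x, y = yy, kernel = cp$kernel, cost = cp$regularization,
               scale = FALSE)
  })
}

predict_ovr_svm <- function(fits, classes, xnew) {
  scores <- vapply(fits, function(f) {
    pr <- stats::predict(f, xnew, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient so larger = more "pos", whatever order e1071 trained with
    if (colnames(dv)[1] == "pos/neg") dv[, 1] else -dv[, 1]
  }, numeric(nrow(xnew)))
  scores <- matrix(scores, nrow = nrow(xnew))
  classes[max.col(scores, ties.method = "first")]
}

#' Leave-one-out cross-validation of an SVM on a gene subset
#'
#' For each sample, a one-vs-rest linear SVM is trained on all other samples
#' and predicts the held-out one.  Genes are standardized (z-score) inside
#' each training fold and the held-out sample is transformed with the fold's
#' parameters, so no information leaks from the left-out sample.
#'
#' @param m Expression matrix restricted to the evaluated gene subset.
#' @param labels Class labels; every class needs >= 2 samples (a singleton
#'   class would have no same-class training example in its fold).
#' @param cp A [classifier_params()].
#' @return A list with `accuracy` (fraction of correct predictions) and
#'   `confusion` (a `confusion_matrix`: predicted classes in rows, actual in
#'   columns).
#' @export
loocv_evaluate <- function(m, labels, cp = classifier_params()) {
  assert_expression_matrix(m)
  labels <- assert_labels(labels, m)
  if (nlevels(labels) < 2) stop_invalid("need at least 2 classes")
  if (any(table(labels) < 2))
    stop_invalid("every class needs at least 2 samples for LOOCV")
  xt <- t(m)
  n <- nrow(xt)
  classes <- levels(labels)
  pred <- character(n)
  for (i in seq_len(n)) {
    xtr <- xt[-i, , drop = FALSE]
    mu <- colMeans(xtr)
    sg <- apply(xtr, 2, sd)
    sg[sg == 0] <- 1  # constant gene in fold: centering only
    xtr <- scale(xtr, center = mu, scale = sg)
    xte <- scale(xt[i, , drop = FALSE], center = mu, scale = sg)
    fits <- fit_ovr_svm(xtr, droplevels(labels[-i]), cp)
    pred[i] <- predict_ovr_svm(fits, levels(droplevels(labels[-i])), xte)
  }
  cm <- table(factor(pred, levels = classes), labels,
              dnn = c("predicted", "actual"))
  cm <- unclass(cm)
  class(cm) <- c("confusion_matrix", class(cm))
  list(accuracy = mean(pred == as.character(labels)), confusion = cm)
}

#' Sweep nested top-k subsets of a ranked gene list (IFS curve)
#'
#' Evaluates LOOCV accuracy for the top k genes at every k on a grid
#' (`step`, `2 step`, ..., `max_k`, with `max_k` always included), producing
#' the incremental-feature-selection curve whose peak defines the signature.
#'
#' @param ranked A `ranked_features` data frame.
#' @param m Full expression matrix (superset of the ranked genes).
#' @param labels Class labels.
#' @param cp A [classifier_params()].
#' @param max_k Largest subset size (`<= nrow(ranked)`).
#' @param step Grid stride (>= 1).
#' @return An `ifs_curve` data frame with columns `k` and `accuracy`; the
#'   confusion matrix of each k is kept in `attr(, "confusions")`.
#' @export
ifs_curve <- function(ranked, m, labels, cp = classifier_params(),
                      max_k = nrow(ranked), step = 1L) {
  if (max_k > nrow(ranked))
    stop_invalid("max_k (%d) exceeds the ranked list length (%d)",
                 max_k, nrow(ranked))
  if (step < 1) stop_invalid("step must be >= 1")
  ks <- unique(c(seq(step, max_k, by = step), max_k))
  res <- lapply(ks, function(k) {
    genes <- ranked$gene_id[seq_len(k)]
    loocv_evaluate(m[genes, , drop = FALSE], labels, cp)
  })
  out <- data.frame(k = as.integer(ks),
                    accuracy = vapply(res, `[[`, numeric(1), "accuracy"))
  structure(out, class = c("ifs_curve", "data.frame"),
            confusions = lapply(res, `[[`, "confusion"))
}

#' Pick the signature at the IFS accuracy peak
#'
#' @param curve An `ifs_curve`.
#' @param ranked The `ranked_features` the curve was swept over.
#' @return A list with `k_star` (smallest k attaining the maximum accuracy),
#'   `accuracy`, `genes` (the top-k_star gene IDs) and, when the curve
#'   retained them, `confusion` for k_star.
#' @export
select_signature <- function(curve, ranked) {
  if (nrow(curve) == 0) stop_invalid("the IFS curve is empty")
  i <- which.max(curve$accuracy)  # first index at the max -> smallest k
  k_star <- curve$k[i]
  conf <- attr(curve, "confusions")
  list(k_star = as.integer(k_star),
       accuracy = curve$accuracy[i],
       genes = ranked$gene_id[seq_len(k_star)],
       confusion = if (!is.null(conf)) conf[[i]] else NULL)
}

#' Per-class and overall accuracy of a confusion matrix
#'
#' The matrix holds predicted classes in rows and actual classes in columns;
#' per-class accuracy is the diagonal cell over its column sum (the class's
#' sample size) and overall accuracy the trace over the grand total.
#'
#' @param cm A square predicted x actual count matrix.
#' @return A list with `per_class` (named; `NA` for a class with no
#'   samples), `overall`, `sample_sizes` and `n`.
#' @export
confusion_stats <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop_invalid("confusion matrix must be square")
  if (any(cm < 0)) stop_invalid("confusion matrix has negative counts")
  sizes <- colSums(cm)
  per_class <- ifelse(sizes > 0, diag(cm) / sizes, NA_real_)
  names(per_class) <- colnames(cm)
  if (any(sizes == 0))
    warning("class(es) with zero samples: accuracy undefined (NA): ",
            paste(colnames(cm)[sizes == 0], collapse = ", "))
  list(per_class = per_class,
       overall = sum(diag(cm)) / sum(cm),
       sample_sizes = sizes,
       n = sum(cm))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  st <- suppressWarnings(confusion_stats(x))
  m <- rbind(format(unclass(x)),
             `Sample size` = format(st$sample_sizes),
             Accuracy = sprintf("%.3f", st$per_class))
  print(m, quote = FALSE, right = TRUE)
  cat(sprintf("Overall accuracy: %.3f (n = %d)\n", st$overall, st$n))
  invisible(x)
}

#' @export
print.ifs_curve <- function(x, ...) {
  best <- x$k[which.max(x$accuracy)]
  cat(sprintf("IFS curve over %d subset sizes; peak accuracy %.3f at k = %d\n",
              nrow(x), max(x$accuracy), best))
  invisible(x)
}
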