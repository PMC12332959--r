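#' Two-class soft-margin linear SVM
#'
#' Fits a linear C-SVC (hinge loss, cost `cost`) by sequential minimal
#' optimization on the dual problem.  The decision function is
#' `f(x) = w.x + b`; inputs are labeled 1 when `f(x) > 0`.
#'
#' @param x Numeric matrix of training vectors (rows = observations).
#' @param y Binary labels (0/1 or logical), length `nrow(x)`.
#' @param cost Soft-margin cost C, default 1.
#' @param class_weights Optional named vector `c("0" = w0, "1" = w1)`
#'   multiplying the cost per class (e.g. to reweight the 1:3 one-vs-rest
#'   imbalance).
#' @param eps SMO stopping tolerance on the KKT violation (default 1e-3).
#' @param max_iter Iteration cap.
#' @return An object of class `linear_svc` with elements `w`, `b`, `n_sv`,
#'   `converged`.
#' @export
linear_svc <- function(x, y, cost = 1, class_weights = NULL,
                       eps = 1e-3, max_iter = 200000L) {
  x <- as.matrix(x)
  y <- as.integer(as.logical(y))
  if (length(y) != nrow(x)) stop_user("length(y) must equal nrow(x)")
  if (length(unique(y)) < 2L) {
    stop_user("training set contains a single class")
  }
  w0 <- w1 <- 1
  if (!is.null(class_weights)) {
    if (!is.null(class_weights[["0"]])) w0 <- class_weights[["0"]]
    if (!is.null(class_weights[["1"]])) w1 <- class_weights[["1"]]
  }
  # degenerate input: identical vectors with mixed labels carry no signal
  # (cheap two-row pre-test guards the full scan in the common case)
  if (all(abs(x[1L, ] - x[nrow(x), ]) < 1e-12) &&
      all(abs(sweep(x, 2, x[1L, ])) < 1e-12)) {
    maj <- as.integer(mean(y) > 0.5)
    warning("all training vectors identical with mixed labels; ",
            "falling back to the majority label (", maj, ")")
    return(structure(list(w = numeric(ncol(x)),
                          b = if (maj == 1L) 1 else -1,
                          n_sv = 0L, converged = TRUE, majority = maj),
                     class = "linear_svc"))
  }
  yin <- ifelse(y == 1L, 1L, -1L)
  fit <- svc_train_linear_cpp(x, yin, cost * w1, cost * w0,
                              eps, as.integer(max_iter))
  structure(list(w = as.numeric(fit$w), b = fit$b, n_sv = fit$n_sv,
                 converged = fit$converged),
            class = "linear_svc")
}

#' @param object A `linear_svc` fit.
#' @param newdata Matrix of test vectors.
#' @param type `"class"` for 0/1 labels, `"decision"` for decision values.
#' @param ... Unused.
#' @rdname linear_svc
#' @export
predict.linear_svc <- function(object, newdata, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  dec <- drop(as.matrix(newdata) %*% object$w + object$b)
  if (type == "decision") dec else as.integer(dec > 0)
}

#' Train a one-vs-rest hyperplane for one target object
#'
#' Labels vectors of `target_object_id` as 1 and the other objects as 0,
#' then fits a linear SVM separating the target object from the rest at the
#' training viewing angle(s).
#'
#' @param train_vectors Matrix of population vectors (rows = pseudo-trials).
#' @param object_ids True object identity of each row.
#' @param target_object_id The object labeled 1.
#' @param ... Passed to [linear_svc()].
#' @return A `linear_svc` fit.
#' @export
train_hyperplane <- function(train_vectors, object_ids, target_object_id,
                             ...) {
  if (nrow(train_vectors) != length(object_ids)) {
    stop_user("object_ids must match rows of train_vectors")
  }
  linear_svc(train_vectors, object_ids == target_object_id, ...)
}

#' Confusion proportions of a one-vs-rest classifier
#'
#' True positive: the proportion of the target object's test vectors labeled
#' 1.  False positive: the proportion of the other objects' test vectors
#' labeled 1.
#'
#' @param classifier A `linear_svc` fit.
#' @param test_vectors Matrix of test population vectors (disjoint from the
#'   training set).
#' @param object_ids True object identity of each test row.
#' @param target_object_id The object the classifier was trained to label 1.
#' @return A list of class `confusion_proportions`: `tp`, `fp`, `n_pos`,
#'   `n_neg`.
#' @export
score <- function(classifier, test_vectors, object_ids, target_object_id) {
  if (nrow(test_vectors) == 0L) stop_user("empty test set")
  pred <- predict(classifier, test_vectors)
  pos <- object_ids == target_object_id
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos < 1L || n_neg < 1L) {
    stop_user("test set must contain target and non-target vectors")
  }
  structure(list(tp = mean(pred[pos] == 1L), fp = mean(pred[!pos] == 1L),
                 n_pos = n_pos, n_neg = n_neg),
            class = "confusion_proportions")
}

#' d-prime from confusion proportions
#'
#' `d' = z(tp) - z(fp)` with `z` the inverse standard normal CDF: a
#' proportion of 0.5 maps to a z-score of exactly 0, larger proportions to
#' positive and smaller to negative z-scores.  Proportions are clipped to
#' `[1/(2n), 1 - 1/(2n)]` (n = the relevant test count) before the
#' transform, so extreme proportions of 0 and 1 remain finite.
#'
#' @param cp A `confusion_proportions` object (or any list with `tp`, `fp`,
#'   `n_pos`, `n_neg`).
#' @return The d-prime value.
#' @export
dprime <- function(cp) {
  dprime_stat(cp$tp, cp$fp, cp$n_pos, cp$n_neg)
}

#' @param tp,fp True/false positive proportions (vectorized).
#' @param n_pos,n_neg Test-vector counts behind `tp` and `fp`.
#' @rdname dprime
#' @export
dprime_stat <- function(tp, fp, n_pos, n_neg) {
  if (any(tp < 0 | tp > 1 | fp < 0 | fp > 1)) {
    stop_user("proportions must lie in [0, 1]")
  }
  if (any(n_pos < 1 | n_neg < 1)) stop_user("test counts must be >= 1")
  tp <- pmin(pmax(tp, 1 / (2 * n_pos)), 1 - 1 / (2 * n_pos))
  fp <- pmin(pmax(fp, 1 / (2 * n_neg)), 1 - 1 / (2 * n_neg))
  qnorm(tp) - qnorm(fp)
}
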