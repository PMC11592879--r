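#' Fit a two-class linear discriminant
#'
#' Fisher / equal-covariance Gaussian discriminant with equal class
#' priors: `weight = S_pooled^-1 (m1 - m2)` and
#' `bias = -weight . (m1 + m2) / 2`, where `S_pooled` is the pooled
#' within-class covariance. A sample scores
#' `weight . x + bias`; positive scores classify as the first
#' (positive) class. When the pooled covariance is numerically singular a
#' small ridge (`ridge * mean(diag(S))` added to the diagonal) restores
#' invertibility; with `ridge = 0` singularity is an error.
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param y Class labels, exactly two distinct values, >= 2 samples each.
#' @param positive Which label is the positive class; default the first
#'   level encountered.
#' @param ridge Relative ridge for the singular-covariance fallback
#'   (default 1e-8).
#' @return An `lda_model`: `weight`, `bias`, `class_labels`
#'   (positive, negative), `means`.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 3), 10))
#' m <- lda_fit(x, rep(c("a", "b"), each = 10))
#' lda_classify(m, c(0, 0))
lda_fit <- function(x, y, positive = NULL, ridge = 1e-8) {
  x <- as.matrix(x)
  y <- as.character(y)
  cls <- unique(y)
  if (length(cls) != 2) stop("exactly two classes are required")
  if (is.null(positive)) positive <- cls[1]
  if (!positive %in% cls) stop("'positive' must be one of the class labels")
  negative <- setdiff(cls, positive)
  x1 <- x[y == positive, , drop = FALSE]
  x2 <- x[y == negative, , drop = FALSE]
  if (nrow(x1) < 2 || nrow(x2) < 2) stop("need >= 2 samples per class")
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  s <- (crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x2, 2, m2))) /
       (nrow(x1) + nrow(x2) - 2)
  w <- tryCatch(solve(s, m1 - m2), error = function(e) NULL)
  if (is.null(w)) {
    if (ridge <= 0) stop("pooled within-class covariance is singular")
    s <- s + diag(ridge * mean(diag(s)) + .Machine$double.eps, ncol(x))
    w <- solve(s, m1 - m2)
  }
  structure(list(weight = as.numeric(w),
                 bias = -sum(w * (m1 + m2) / 2),
                 class_labels = c(positive = positive, negative = negative),
                 means = rbind(positive = m1, negative = m2)),
            class = "lda_model")
}

#' Classify with a fitted linear discriminant
#'
#' @param model An `lda_model` from [lda_fit()].
#' @param x Feature vector, or matrix with samples in rows.
#' @return Character vector of class labels; a score of exactly 0 takes
#'   the negative class (documented tie-break).
#' @export
lda_classify <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(model$weight)) {
    stop("feature dimension mismatch: model has ", length(model$weight),
         ", input has ", ncol(x))
  }
  score <- as.numeric(x %*% model$weight) + model$bias
  ifelse(score > 0, model$class_labels[["positive"]],
         model$class_labels[["negative"]])
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model>", x$class_labels[["positive"]], "vs",
      x$class_labels[["negative"]], "| weight:",
      paste(signif(x$weight, 4), collapse = ", "), "| bias:",
      signif(x$bias, 4), "\n")
  invisible(x)
}

#' Leave-one-out LDA accuracy
#'
#' Refits the discriminant with each sample held out in turn and scores
#' the held-out prediction; the evaluation protocol for the small-cohort
#' LEFT-vs-RIGHT classifier.
#'
#' @inheritParams lda_fit
#' @return List with `accuracy` (fraction correct) and `predicted`.
#' @export
lda_loocv <- function(x, y, positive = NULL, ridge = 1e-8) {
  x <- as.matrix(x); y <- as.character(y)
  pred <- vapply(seq_len(nrow(x)), function(i) {
    m <- lda_fit(x[-i, , drop = FALSE], y[-i], positive = positive, ridge = ridge)
    lda_classify(m, x[i, ])
  }, character(1))
  list(accuracy = mean(pred == y), predicted = pred)
}

#' Lateralize a patient from hippocampal features (Analysis-1)
#'
#' Classifies LEFT vs RIGHT temporal lobe epilepsy with a linear
#' discriminant trained on reference cohort features. The default feature
#' set is the left/right hippocampus volumes, the combination with the
#' best reported discrimination; means and standard deviations can be
#' added via `features`.
#'
#' @param features A `morph_features` for the patient ([extract_features()]).
#' @param train_x,train_y Training features (matrix, same columns as
#'   selected) and LEFT/RIGHT labels.
#' @param feature_set Character subset of
#'   `c("volumes", "means", "sds")`; default `"volumes"`.
#' @return `"LEFT"` or `"RIGHT"`.
#' @export
hippo_lateralize <- function(features, train_x, train_y,
                             feature_set = "volumes") {
  fv <- morph_feature_vector(features, feature_set)
  model <- lda_fit(train_x, train_y, positive = "LEFT")
  unname(lda_classify(model, fv))
}

#' Flatten morphometric features into a feature vector
#'
#' @param features A `morph_features`.
#' @param feature_set Subset of `c("volumes", "means", "sds")`.
#' @return Named numeric vector.
#' @export
morph_feature_vector <- function(features, feature_set = "volumes") {
  stopifnot(all(feature_set %in% c("volumes", "means", "sds")))
  out <- c()
  if ("volumes" %in% feature_set)
    out <- c(out, vol_left = features$vol_left, vol_right = features$vol_right)
  if ("means" %in% feature_set)
    out <- c(out, mean_left = features$mean_left, mean_right = features$mean_right)
  if ("sds" %in% feature_set)
    out <- c(out, sd_left = features$sd_left, sd_right = features$sd_right)
  out
}
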