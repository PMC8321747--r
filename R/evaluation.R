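#' One-vs-rest confusion counts per class
#'
#' For every class c: TP = samples of c predicted c, FN = samples of c
#' predicted otherwise, FP = samples of other classes predicted c, TN = the
#' rest. For each class TP+FN+TN+FP = m, and the TPs summed over classes
#' equal the number of correctly classified samples.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param class_order classes in reporting order; labels outside it are an
#'   error.
#' @return a `confusion_counts` data.frame: class, TP, FN, TN, FP.
#' @export
confusion <- function(y_true, y_pred, class_order = sort(unique(y_true))) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad))
    stop("label(s) outside class_order: ", paste(bad, collapse = ", "))
  m <- length(y_true)
  out <- do.call(rbind, lapply(class_order, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    data.frame(class = cl, TP = tp, FN = fn, TN = m - tp - fn - fp, FP = fp)
  }))
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Per-class classification efficiency
#'
#' The geometric mean of sensitivity and specificity,
#' sqrt(TP/(TP+FN) x TN/(TN+FP)), in [0, 1]; 1 exactly for an error-free
#' class. Undefined (NA) when the positive or negative side of the class is
#' empty.
#'
#' @param counts a `confusion_counts` from [confusion()].
#' @param class class name; default computes all classes.
#' @return named numeric vector of efficiencies.
#' @export
efficiency <- function(counts, class = NULL) {
  rows <- if (is.null(class)) seq_len(nrow(counts)) else
    match(class, counts$class)
  out <- vapply(rows, function(i) {
    tp <- counts$TP[i]; fn <- counts$FN[i]
    tn <- counts$TN[i]; fp <- counts$FP[i]
    if (tp + fn == 0 || tn + fp == 0) return(NA_real_)
    sqrt((tp / (tp + fn)) * (tn / (tn + fp)))
  }, numeric(1))
  names(out) <- counts$class[rows]
  out
}

#' Total accuracy rate
#'
#' Percentage of correctly identified samples over all classes, reported to
#' 2 decimal places (e.g. 20 of 21 correct = 95.24).
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return accuracy in percent.
#' @export
total_accuracy <- function(y_true, y_pred) {
  if (!length(y_true)) stop("empty input")
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  round(100 * mean(as.character(y_true) == as.character(y_pred)), 2)
}

#' Permutation test of a PLS-DA model
#'
#' Guards against overfitting: class labels are permuted `n_iter` times
#' (permutations identical to the original labelling are redrawn), the
#' PLS-DA model is refitted with the same number of latent variables, and
#' R2/Q2 are recorded together with the correlation between the permuted
#' and original one-hot label matrices. A least-squares line of Q2 against
#' the label correlation (including the original model at correlation 1)
#' gives the Q2 intercept; an intercept at or below zero indicates the
#' model is not overfitting.
#'
#' @param X_cal calibration matrix.
#' @param y_cal class labels.
#' @param max_lv latent-variable search bound for the original fit.
#' @param n_iter number of permutations.
#' @param folds CV folds for Q2.
#' @param seed RNG seed.
#' @return a `permutation_result`: `n_iterations`, `permuted_r2q2`
#'   (data.frame: correlation, r2, q2), `original_r2q2`, `q2_intercept`,
#'   `not_overfitting`.
#' @export
permutation_test <- function(X_cal, y_cal, max_lv = 10, n_iter = 30,
                             folds = 7, seed = 1) {
  X_cal <- as.matrix(X_cal)
  y_cal <- as.character(y_cal)
  set.seed(seed)
  fit0 <- suppressWarnings(plsda_fit(X_cal, y_cal, max_lv, folds))
  nlv <- fit0$n_latent
  r2q2 <- function(fit, y) {
    Y <- one_hot(y, fit$class_order)
    Yhat <- plsda_predict_raw(fit, X_cal)
    r2 <- 1 - sum((Y - Yhat)^2) / sum(sweep(Y, 2, colMeans(Y))^2)
    c(r2 = r2, q2 = fit$cv_q2[fit$n_latent])
  }
  orig <- r2q2(fit0, y_cal)
  Y0 <- one_hot(y_cal, fit0$class_order)
  perm <- matrix(NA_real_, n_iter, 3,
                 dimnames = list(NULL, c("correlation", "r2", "q2")))
  for (i in seq_len(n_iter)) {
    repeat {
      yp <- sample(y_cal)
      if (!identical(yp, y_cal)) break
    }
    fit_p <- suppressWarnings(plsda_fit(X_cal, yp, nlv, folds))
    perm[i, ] <- c(stats::cor(as.vector(one_hot(yp, fit0$class_order)),
                              as.vector(Y0)),
                   r2q2(fit_p, yp))
  }
  pts <- rbind(data.frame(correlation = 1, r2 = orig["r2"],
                          q2 = orig["q2"]),
               as.data.frame(perm))
  line <- stats::lm(q2 ~ correlation, data = pts)
  icpt <- unname(stats::coef(line)[1])
  structure(list(n_iterations = n_iter,
                 permuted_r2q2 = as.data.frame(perm),
                 original_r2q2 = orig,
                 q2_intercept = icpt,
                 not_overfitting = icpt <= 0), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$n_iterations, " permutations; original R2 ",
      format(x$original_r2q2["r2"], digits = 3), ", Q2 ",
      format(x$original_r2q2["q2"], digits = 3), "; Q2 intercept ",
      format(x$q2_intercept, digits = 3),
      if (x$not_overfitting) " (not overfitting)" else " (overfitting risk)",
      "\n", sep = "")
  invisible(x)
}
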