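#' Candidate mtry values around the default
#'
#' The default mtry for classification is the (floored) square root of the
#' number of variables; the screening range is the default plus/minus
#' `span`, clipped to `[1, p]`. For p = 2387 this gives default 48 and
#' candidates 38..58.
#'
#' @param p number of variables.
#' @param span half-width of the candidate range.
#' @return list with `default` and `candidates`.
#' @export
rf_mtry_candidates <- function(p, span = 10) {
  default <- max(1L, as.integer(floor(sqrt(p))))
  candidates <- seq(max(1L, default - span), min(p, default + span))
  list(default = default, candidates = as.integer(candidates))
}

#' Screen random-forest n_tree and mtry by OOB error
#'
#' Two-stage screening on the calibration set:
#' 1. A forest of `ntree_init` trees is grown and the running out-of-bag
#'    (OOB) error recorded as trees accumulate. `n_tree` is the smallest
#'    tree count achieving the minimum overall OOB error while no class's
#'    running OOB error exceeds its value at the overall minimum (all
#'    classes are considered at the same time).
#' 2. With that `n_tree`, every mtry in the candidate range (see
#'    [rf_mtry_candidates()]) is evaluated; the lowest final OOB error wins,
#'    ties go to the value closest to the default, remaining ties to the
#'    smaller mtry.
#'
#' @param X_cal calibration matrix.
#' @param y_cal class labels (>= 2 classes).
#' @param ntree_init size of the screening forest.
#' @param mtry_span half-width of the mtry candidate range.
#' @param seed integer seed; the screen is bitwise reproducible under it.
#' @return an `rf_config`: `n_tree`, `mtry`, `oob_error_by_ntree` (vector),
#'   `oob_error_by_mtry` (data.frame), `seed`.
#' @export
rf_screen <- function(X_cal, y_cal, ntree_init = 2000, mtry_span = 10,
                      seed = 1) {
  X_cal <- as.matrix(X_cal)
  y <- factor(y_cal)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  set.seed(seed)
  fit0 <- randomForest::randomForest(X_cal, y, ntree = ntree_init)
  err <- fit0$err.rate                      # ntree x (OOB + classes)
  ok <- which(stats::complete.cases(err))
  overall <- err[, 1]
  emin <- min(overall[ok])
  t_star <- ok[which(overall[ok] <= emin + 1e-12)[1]]
  class_ref <- err[t_star, -1]
  cand <- ok[overall[ok] <= emin + 1e-12]
  feas <- cand[vapply(cand, function(t)
    all(err[t, -1] <= class_ref + 1e-12), logical(1))]
  n_tree <- as.integer(min(feas))

  mc <- rf_mtry_candidates(ncol(X_cal), mtry_span)
  oob <- vapply(seq_along(mc$candidates), function(i) {
    set.seed(seed + i)
    f <- randomForest::randomForest(X_cal, y, ntree = n_tree,
                                    mtry = mc$candidates[i])
    f$err.rate[n_tree, 1]
  }, numeric(1))
  structure(list(n_tree = n_tree,
                 mtry = choose_mtry(mc$candidates, oob, mc$default),
                 oob_error_by_ntree = overall,
                 oob_error_by_mtry = data.frame(mtry = mc$candidates,
                                                oob_error = oob),
                 mtry_default = mc$default, seed = seed),
            class = "rf_config")
}

# lowest OOB error wins; ties go to the mtry closest to the default,
# remaining ties to the smaller value
choose_mtry <- function(candidates, oob_errors, default) {
  ties <- candidates[oob_errors <= min(oob_errors) + 1e-12]
  as.integer(ties[order(abs(ties - default), ties)][1])
}

#' Fit a random forest classifier
#'
#' Bootstrap-aggregated classification trees ([randomForest::randomForest])
#' with the screened (or explicitly chosen) `n_tree` and `mtry`. Each tree
#' trains on a bootstrap sample (about two-thirds of the calibration set);
#' the remaining out-of-bag third yields the internal error estimate.
#'
#' @param X_cal calibration matrix.
#' @param y_cal class labels.
#' @param config an `rf_config` from [rf_screen()], or a list with
#'   `n_tree`, `mtry` and `seed`.
#' @return an `rf_model` wrapping the fitted forest.
#' @export
rf_fit <- function(X_cal, y_cal, config) {
  y <- factor(y_cal)
  set.seed(config$seed)
  forest <- randomForest::randomForest(as.matrix(X_cal), y,
                                       ntree = config$n_tree,
                                       mtry = config$mtry)
  structure(list(forest = forest, class_order = levels(y),
                 oob_error = forest$err.rate[config$n_tree, 1],
                 config = config), class = "rf_model")
}

#' Predict class memberships with a random forest
#'
#' Memberships are the fractions of trees voting for each class, so every
#' row sums to 1.
#'
#' @param model an `rf_model` from [rf_fit()].
#' @param X matrix with the training variables.
#' @return a [membership_matrix()].
#' @export
rf_predict <- function(model, X) {
  pr <- stats::predict(model$forest, as.matrix(X), type = "prob")
  membership_matrix(pr[, model$class_order, drop = FALSE],
                    model$class_order)
}

#' @export
print.rf_config <- function(x, ...) {
  cat("<rf_config> n_tree = ", x$n_tree, ", mtry = ", x$mtry,
      " (default ", x$mtry_default, ")\n", sep = "")
  invisible(x)
}
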