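#' Membership matrix: per-sample class membership degrees
#'
#' The common currency of high-level fusion: one row per sample, one column
#' per class, entries in [0, 1]. Random-forest memberships are vote
#' fractions (rows sum to 1); PLS-DA memberships are per-sample min-max
#' rescaled predicted dummy values.
#'
#' @param values numeric matrix in [0, 1].
#' @param class_order character vector naming the columns.
#' @return a `membership_matrix`.
#' @export
membership_matrix <- function(values, class_order) {
  values <- as.matrix(values)
  if (ncol(values) != length(class_order))
    stop("class_order length must match column count")
  if (any(values < -1e-9 | values > 1 + 1e-9))
    stop("membership degrees must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  colnames(values) <- class_order
  structure(list(values = values, class_order = as.character(class_order)),
            class = "membership_matrix")
}

#' Hard class assignment from memberships
#'
#' Argmax per row; ties resolved in favour of the earlier class in
#' `class_order`.
#'
#' @param m a [membership_matrix()].
#' @return character vector of predicted classes.
#' @export
membership_classes <- function(m) {
  m$class_order[apply(m$values, 1, which.max)]
}

one_hot <- function(y, class_order) {
  Y <- matrix(0, length(y), length(class_order))
  Y[cbind(seq_along(y), match(as.character(y), class_order))] <- 1
  colnames(Y) <- class_order
  Y
}

# NIPALS PLS2 on pre-scaled X and centred Y; returns weights/loadings for
# ncomp components (X-side weights are unit-norm)
nipals_pls2 <- function(X, Y, ncomp, tol = 1e-10, max_it = 500) {
  p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); Tm <- matrix(0, nrow(X), ncomp)
  ss <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    if (all(abs(u) < 1e-12)) u <- Y[, 1]
    t_old <- rep(Inf, nrow(X))
    for (iter in seq_len(max_it)) {
      w <- crossprod(X, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      tt <- X %*% w
      qv <- crossprod(Y, tt)[, 1] / sum(tt^2)
      u <- (Y %*% qv) / sum(qv^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    if (nw < 1e-14 || sum(tt^2) < 1e-14) { ncomp <- a - 1L; break }
    pv <- crossprod(X, tt)[, 1] / sum(tt^2)
    X <- X - tcrossprod(tt, pv)
    Y <- Y - tcrossprod(tt, qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- tt
    ss[a] <- sum(qv^2) * sum(tt^2)   # explained response sum of squares
  }
  keep <- seq_len(ncomp)
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       Q = Q[, keep, drop = FALSE], T = Tm[, keep, drop = FALSE],
       ss = ss[keep], ncomp = ncomp)
}

# per-component predictions for new (already scaled) X: list of Yhat by
# number of components 1..ncomp (centred scale)
pls2_predict_components <- function(fit, Xs) {
  ncomp <- fit$ncomp
  out <- vector("list", ncomp)
  Yhat <- matrix(0, nrow(Xs), nrow(fit$Q))
  Xd <- Xs
  for (a in seq_len(ncomp)) {
    tt <- Xd %*% fit$W[, a]
    Yhat <- Yhat + tcrossprod(tt, fit$Q[, a])
    Xd <- Xd - tcrossprod(tt, fit$P[, a])
    out[[a]] <- Yhat
  }
  out
}

#' Fit a PLS-DA model
#'
#' PLS2 regression (NIPALS) of the one-hot class indicator matrix on the
#' autoscaled calibration data. The number of latent variables maximizes the
#' 7-fold cross-validated Q2 over `1..max_lv` (contiguous folds; ties go to
#' fewer latent variables). Zero-variance columns are dropped with a
#' warning; `max_lv` beyond the data rank is capped with a warning record.
#'
#' @param X_cal calibration matrix.
#' @param y_cal class labels (>= 2 classes).
#' @param max_lv largest number of latent variables considered.
#' @param folds number of contiguous CV folds.
#' @return a `plsda_model`: weights/loadings, calibration scaling, chosen
#'   `n_latent`, per-candidate `cv_q2`, `class_order`, `warnings`.
#' @export
plsda_fit <- function(X_cal, y_cal, max_lv = 10, folds = 7) {
  X_cal <- as.matrix(X_cal)
  y_cal <- as.character(y_cal)
  class_order <- levels(factor(y_cal))
  if (length(class_order) < 2) stop("PLS-DA needs at least 2 classes")
  warn <- character(0)
  sds <- apply(X_cal, 2, stats::sd)
  keep <- which(sds > 0)
  if (length(keep) < ncol(X_cal)) {
    warn <- c(warn, sprintf("%d zero-variance column(s) dropped",
                            ncol(X_cal) - length(keep)))
    warning(warn[length(warn)])
  }
  Xk <- X_cal[, keep, drop = FALSE]
  cap <- min(nrow(Xk) - 1L, ncol(Xk))
  if (max_lv > cap) {
    warn <- c(warn, sprintf("max_lv capped at %d", cap))
    max_lv <- cap
  }
  Y <- one_hot(y_cal, class_order)

  # 7-fold CV of Q2 per candidate LV count
  m <- nrow(Xk)
  fold_id <- sort(rep_len(seq_len(folds), m))
  press <- numeric(max_lv); sstot <- 0
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    Xs_tr <- autoscale(Xk[tr, , drop = FALSE])
    Ytr <- Y[tr, , drop = FALSE]
    ybar <- colMeans(Ytr)
    fit_f <- nipals_pls2(Xs_tr, sweep(Ytr, 2, ybar),
                         min(max_lv, sum(tr) - 1L))
    Xs_te <- autoscale(Xk[!tr, , drop = FALSE],
                       center = attr(Xs_tr, "center"),
                       scale = attr(Xs_tr, "scale"))
    Yte_c <- sweep(Y[!tr, , drop = FALSE], 2, ybar)
    preds <- pls2_predict_components(fit_f, Xs_te)
    sstot <- sstot + sum(Yte_c^2)
    for (a in seq_len(max_lv)) {
      aa <- min(a, fit_f$ncomp)
      press[a] <- press[a] + sum((Yte_c - preds[[aa]])^2)
    }
  }
  cv_q2 <- 1 - press / sstot
  n_latent <- which.max(cv_q2)        # first maximum = fewest LVs on ties

  Xs <- autoscale(Xk)
  ybar <- colMeans(Y)
  fit <- nipals_pls2(Xs, sweep(Y, 2, ybar), n_latent)
  structure(list(
    n_latent = fit$ncomp,
    x_weights = fit$W, x_loadings = fit$P, y_loadings = fit$Q,
    ss_component = fit$ss,
    x_center = attr(Xs, "center"), x_scale = attr(Xs, "scale"),
    y_mean = ybar, keep = keep, p_all = ncol(X_cal),
    class_order = class_order,
    cv_q2 = cv_q2, warnings = warn), class = "plsda_model")
}

#' Predict class memberships with a PLS-DA model
#'
#' Predicted dummy values per class are rescaled affinely per sample onto
#' [0, 1] (row minimum to 0, row maximum to 1) so they can serve as fuzzy
#' membership degrees; the hard class is the argmax (see
#' [membership_classes()]).
#'
#' @param model a `plsda_model`.
#' @param X matrix with the same variables as the training data.
#' @return a [membership_matrix()].
#' @export
plsda_predict <- function(model, X) {
  raw <- plsda_predict_raw(model, X)
  membership_matrix(t(apply(raw, 1, minmax_row)), model$class_order)
}

# affine rescale of one row of predicted dummies onto [0,1]; a constant
# row (no preference) maps to all 0.5
minmax_row <- function(r) {
  d <- diff(range(r))
  if (d == 0) rep(0.5, length(r)) else (r - min(r)) / d
}

# predicted dummy values on the original (uncentred) scale
plsda_predict_raw <- function(model, X) {
  X <- as.matrix(X)
  Xk <- X[, model$keep, drop = FALSE]
  if (ncol(Xk) != nrow(model$x_weights))
    stop("dimension mismatch: model expects ",
         nrow(model$x_weights), " variables")
  Xs <- sweep(sweep(Xk, 2, model$x_center), 2, model$x_scale, "/")
  fit <- list(W = model$x_weights, P = model$x_loadings,
              Q = model$y_loadings, ncomp = model$n_latent)
  preds <- pls2_predict_components(fit, Xs)
  sweep(preds[[model$n_latent]], 2, model$y_mean, "+")
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP scores of a fitted PLS-DA model:
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}}
#' where \eqn{SS_a} is the response variance explained by component a.
#' The scores satisfy \eqn{\sum_j VIP_j^2 = p}; variables with VIP > 1
#' conventionally drive the class separation. Dropped (zero-variance)
#' columns receive VIP 0.
#'
#' @param model a `plsda_model`.
#' @return a `vip_vector`: list with non-negative `scores` per original
#'   variable.
#' @export
vip <- function(model) {
  W <- model$x_weights
  ss <- model$ss_component
  p <- nrow(W)
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  scores_kept <- sqrt(p * as.numeric(wn2 %*% ss) / sum(ss))
  scores <- numeric(model$p_all)
  scores[model$keep] <- scores_kept
  structure(list(scores = scores), class = "vip_vector")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("<plsda_model> ", length(x$class_order), " classes, ",
      x$n_latent, " latent variable(s); CV Q2 = ",
      format(x$cv_q2[x$n_latent], digits = 4), "\n", sep = "")
  invisible(x)
}
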