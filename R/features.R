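#' PCA feature extraction with cross-validated component count
#'
#' Principal components are fitted on the calibration set only (columns
#' mean-centred with calibration means); validation samples are projected
#' onto the calibration loadings. The number of components is chosen by
#' 7-fold cross-validation of the cumulative predictive fraction Q2_cum
#' (reconstruction PRESS on left-out rows, contiguous folds): components are
#' retained while adding one improves Q2_cum by at least `q2_gain` (0.01),
#' capped at `max_components` and at the calibration rank.
#'
#' @param X_cal,X_val calibration and validation matrices with equal column
#'   counts.
#' @param max_components upper bound on the number of components.
#' @param folds number of contiguous CV folds.
#' @param q2_gain minimum Q2_cum improvement to keep adding components.
#' @return a `pca_features` list: `n_components`, `cal_scores`,
#'   `val_scores`, `explained_fraction` (cumulative at `n_components`),
#'   `explained` (per-component cumulative vector), `loadings`, `cv_q2`.
#' @export
pca_extract <- function(X_cal, X_val, max_components, folds = 7,
                        q2_gain = 0.01) {
  X_cal <- as.matrix(X_cal); X_val <- as.matrix(X_val)
  if (ncol(X_cal) != ncol(X_val))
    stop("calibration and validation must have the same variables")
  mu <- colMeans(X_cal)
  Xc <- sweep(X_cal, 2, mu)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  kmax <- min(max_components, rank)

  # contiguous-fold CV of reconstruction PRESS
  m <- nrow(X_cal)
  fold_id <- sort(rep_len(seq_len(folds), m))  # contiguous folds
  press <- numeric(kmax + 1)
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    mu_f <- colMeans(X_cal[tr, , drop = FALSE])
    sv_f <- svd(sweep(X_cal[tr, , drop = FALSE], 2, mu_f))
    Xt <- sweep(X_cal[!tr, , drop = FALSE], 2, mu_f)
    press[1] <- press[1] + sum(Xt^2)
    kf <- min(kmax, ncol(sv_f$v))
    Tsc <- Xt %*% sv_f$v
    for (k in seq_len(kmax)) {
      kk <- min(k, kf)
      rec <- Tsc[, seq_len(kk), drop = FALSE] %*%
        t(sv_f$v[, seq_len(kk), drop = FALSE])
      press[k + 1] <- press[k + 1] + sum((Xt - rec)^2)
    }
  }
  q2 <- 1 - press[-1] / press[1]
  gains <- diff(c(0, q2))
  k <- if (any(gains < q2_gain)) max(1L, which(gains < q2_gain)[1] - 1L) else kmax

  V <- sv$v[, seq_len(kmax), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    s <- sign(V[which.max(abs(V[, j])), j]); if (s < 0) V[, j] <- -V[, j]
  }
  ev <- sv$d^2
  explained <- cumsum(ev)[seq_len(kmax)] / sum(ev)
  list_out <- list(
    n_components = as.integer(k),
    cal_scores = Xc %*% V[, seq_len(k), drop = FALSE],
    val_scores = sweep(X_val, 2, mu) %*% V[, seq_len(k), drop = FALSE],
    explained_fraction = explained[k],
    explained = explained,
    loadings = V[, seq_len(k), drop = FALSE],
    cv_q2 = q2,
    center = mu)
  structure(list_out, class = "pca_features")
}

#' Boruta all-relevant feature selection
#'
#' Random-forest-based wrapper that compares each variable's permutation
#' importance (mean decrease in accuracy, z-scored) against the maximum
#' importance among "shadow" variables — shuffled copies of the candidates
#' regenerated at every iteration. A variable beating the shadow maximum
#' registers a hit; two-sided binomial tests on the hit counts, Bonferroni
#' corrected over the variables still undecided, promote variables to
#' `confirmed` or demote them to `rejected` (rejected variables and their
#' shadows are dropped from later iterations). Variables still undecided at
#' `max_iter` are `tentative`. For fusion, `confirmed` and `tentative`
#' variables together are the extracted feature set (see
#' [boruta_selected_columns()]).
#'
#' @param X numeric matrix (>= 10 samples).
#' @param y class labels (>= 2 classes).
#' @param alpha significance level of the binomial tests.
#' @param max_iter maximum number of shadow iterations.
#' @param rf_trees trees per random forest fit.
#' @param seed optional integer; when given, results are bitwise
#'   reproducible.
#' @return a `feature_decision` list: `status` (per-variable factor
#'   confirmed/tentative/rejected), `hits`, `n_iterations`,
#'   `importance_history` (iterations x variables, NA once dropped).
#' @export
boruta_select <- function(X, y, alpha = 0.05, max_iter = 100,
                          rf_trees = 500, seed = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nrow(X) < 10) stop("Boruta needs at least 10 samples")
  if (nlevels(y) < 2) stop("Boruta needs at least 2 classes")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(X)
  status <- rep("undecided", p)
  hits <- integer(p)
  tested <- integer(p)
  history <- matrix(NA_real_, 0, p)
  it <- 0L
  while (it < max_iter && any(status == "undecided")) {
    active <- which(status != "rejected")
    if (length(active) < 5) break
    it <- it + 1L
    Xa <- X[, active, drop = FALSE]
    shadows <- apply(Xa, 2, sample)
    fit <- randomForest::randomForest(cbind(Xa, shadows), y,
                                      ntree = rf_trees, importance = TRUE)
    imp <- randomForest::importance(fit, type = 1)[, 1]
    real_imp <- imp[seq_along(active)]
    shadow_max <- max(imp[-seq_along(active)])
    hit <- real_imp > shadow_max
    hits[active] <- hits[active] + hit
    tested[active] <- tested[active] + 1L
    row <- rep(NA_real_, p); row[active] <- real_imp
    history <- rbind(history, row)
    und <- which(status == "undecided")
    n_test <- length(und)
    p_conf <- stats::pbinom(hits[und] - 1L, tested[und], 0.5,
                            lower.tail = FALSE)
    p_rej <- stats::pbinom(hits[und], tested[und], 0.5)
    status[und[p_conf < alpha / n_test]] <- "confirmed"
    und2 <- which(status == "undecided")
    p_rej <- p_rej[match(und2, und)]
    status[und2[p_rej < alpha / n_test]] <- "rejected"
  }
  status[status == "undecided"] <- "tentative"
  structure(list(
    status = factor(status, levels = c("confirmed", "tentative", "rejected")),
    hits = hits, n_iterations = it,
    importance_history = history), class = "feature_decision")
}

#' Columns extracted by a Boruta decision
#'
#' Confirmed and tentative variables are the important features carried
#' into mid- and high-level fusion.
#'
#' @param decision a `feature_decision` from [boruta_select()].
#' @return integer vector of column indices.
#' @export
boruta_selected_columns <- function(decision) {
  which(decision$status %in% c("confirmed", "tentative"))
}

#' @export
print.feature_decision <- function(x, ...) {
  tb <- table(x$status)
  cat("<feature_decision> ", x$n_iterations, " iterations; ",
      paste(names(tb), tb, sep = ": ", collapse = ", "), "\n", sep = "")
  invisible(x)
}
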