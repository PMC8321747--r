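test_that("separable two-class data are classified perfectly with 1 LV", {
  set.seed(1)
  y <- rep(c("A", "B"), each = 8)
  X <- cbind(c(rnorm(8, -2, 0.2), rnorm(8, 2, 0.2)),
             matrix(rnorm(16 * 4), 16))
  m <- plsda_fit(X, y, max_lv = 4)
  expect_gte(m$n_latent, 1)
  expect_equal(length(m$cv_q2), 4)
  pred <- membership_classes(plsda_predict(m, X))
  expect_equal(pred, y)
  expect_equal(total_accuracy(y, pred), 100)
})

test_that("full-LV PLS2 predictions equal the least-squares oracle", {
  set.seed(2)
  X <- matrix(rnorm(8 * 3), 8)
  y <- rep(c("A", "B"), 4)
  Y <- chemfuse:::one_hot(y, c("A", "B"))
  Xs <- autoscale(X)
  fit <- chemfuse:::nipals_pls2(Xs, sweep(Y, 2, colMeans(Y)), 3)
  Yhat <- chemfuse:::pls2_predict_components(fit, Xs)[[3]]
  Yhat <- sweep(Yhat, 2, colMeans(Y), "+")
  ls <- stats::lm.fit(cbind(1, Xs), Y)$fitted.values  # normal equations
  expect_equal(unname(Yhat), unname(ls), tolerance = 1e-8)
})

test_that("membership rescaling maps dummies onto [0,1] affinely", {
  expect_equal(chemfuse:::minmax_row(c(0.9, 0.3, -0.1)), c(1.0, 0.4, 0.0))
  expect_equal(chemfuse:::minmax_row(c(2, 2, 2)), c(0.5, 0.5, 0.5))
  expect_error(plsda_fit(matrix(rnorm(20), 10), rep("A", 10)), "2 classes")
})

test_that("VIP satisfies its normalization identity and flags signal", {
  # p = 1: VIP is exactly 1
  set.seed(3)
  y <- rep(c("A", "B"), each = 6)
  X1 <- matrix((y == "B") + rnorm(12, 0, 0.3), ncol = 1)
  m1 <- plsda_fit(X1, y, max_lv = 1, folds = 4)
  expect_equal(vip(m1)$scores, 1, tolerance = 1e-10)

  # one informative among 20 noise variables: max VIP, > 1
  set.seed(4)
  y <- rep(c("A", "B"), each = 15)
  X <- matrix(rnorm(30 * 21), 30)
  X[, 7] <- X[, 7] + 3 * (y == "B")
  m <- plsda_fit(X, y, max_lv = 3)
  v <- vip(m)$scores
  expect_equal(sum(v^2), 21, tolerance = 1e-8 * 21)
  expect_equal(which.max(v), 7)
  expect_gt(v[7], 1)
})

test_that("zero-variance columns are dropped with a warning, not an error", {
  set.seed(5)
  y <- rep(c("A", "B"), each = 8)
  X <- cbind(matrix(rnorm(16 * 3), 16), 0)
  X[, 1] <- X[, 1] + 6 * (y == "B")
  expect_warning(m <- plsda_fit(X, y, max_lv = 2), "zero-variance")
  expect_equal(length(vip(m)$scores), 4)
  expect_equal(vip(m)$scores[4], 0)
  expect_equal(membership_classes(plsda_predict(m, X)), y)
})

test_that("mtry defaults and tie-breaks follow the screening rules", {
  expect_equal(rf_mtry_candidates(2387)$default, 48L)
  expect_equal(range(rf_mtry_candidates(2387)$candidates), c(38L, 58L))
  expect_equal(rf_mtry_candidates(1097)$default, 33L)
  # equal OOB error at distances 2 and 5 from the default: closer wins
  expect_equal(chemfuse:::choose_mtry(c(43, 50), c(0.10, 0.10), 48), 50L)
  # remaining tie at equal distance: smaller mtry wins
  expect_equal(chemfuse:::choose_mtry(c(46, 50), c(0.10, 0.10), 48), 46L)
  expect_equal(chemfuse:::choose_mtry(c(40, 50), c(0.05, 0.10), 48), 40L)
})

test_that("random-forest memberships are vote fractions and OOB behaves", {
  set.seed(6)
  y <- rep(c("A", "B"), each = 20)
  X <- matrix(rnorm(40 * 10), 40)
  cfg <- list(n_tree = 200, mtry = 3, seed = 1)
  mem <- rf_predict(rf_fit(X, y, cfg), X)
  expect_equal(unname(rowSums(mem$values)), rep(1, 40), tolerance = 1e-12)

  # pure noise: OOB error near chance in nearly all seeds
  oob_null <- vapply(1:20, function(s) {
    set.seed(s + 300)
    Xn <- matrix(rnorm(40 * 20), 40)
    rf_fit(Xn, y, list(n_tree = 200, mtry = 4, seed = s))$oob_error
  }, numeric(1))
  expect_gte(sum(oob_null >= 0.3 & oob_null <= 0.7), 18)

  # one overwhelming predictor: OOB error < 0.1
  Xs <- matrix(rnorm(40 * 20), 40)
  Xs[, 5] <- 4 * (y == "B") + rnorm(40, 0, 0.2)
  expect_lt(rf_fit(Xs, y, list(n_tree = 200, mtry = 4, seed = 2))$oob_error,
            0.1)
})

test_that("the OOB screen is reproducible and respects both-stage rules", {
  set.seed(7)
  y <- rep(c("A", "B", "C"), each = 10)
  X <- matrix(rnorm(30 * 25), 30)
  X[, 1] <- X[, 1] + c(0, 2, 4)[as.integer(factor(y))]
  s1 <- rf_screen(X, y, ntree_init = 150, mtry_span = 2, seed = 42)
  s2 <- rf_screen(X, y, ntree_init = 150, mtry_span = 2, seed = 42)
  expect_identical(s1[c("n_tree", "mtry", "oob_error_by_ntree",
                        "oob_error_by_mtry")],
                   s2[c("n_tree", "mtry", "oob_error_by_ntree",
                        "oob_error_by_mtry")])
  expect_lte(s1$n_tree, 150)
  expect_true(s1$mtry %in% rf_mtry_candidates(25, 2)$candidates)
  # n_tree achieves the running minimum of the overall OOB curve
  err <- s1$oob_error_by_ntree
  expect_equal(err[s1$n_tree], min(err, na.rm = TRUE), tolerance = 1e-12)
})

test_that("NIPALS PLS2 agrees with an independent PLS-DA implementation", {
  set.seed(2)
  X <- matrix(rnorm(30 * 12), 30)
  colnames(X) <- paste0("v", 1:12)
  y <- rep(c("A", "B", "C"), each = 10)
  X[, 1] <- X[, 1] + c(0, 2, 4)[as.integer(factor(y))]
  X[, 2] <- X[, 2] + c(2, 0, -2)[as.integer(factor(y))]
  Y <- chemfuse:::one_hot(y, c("A", "B", "C"))
  Xs <- autoscale(X)
  fit <- chemfuse:::nipals_pls2(Xs, sweep(Y, 2, colMeans(Y)), 3)
  yh <- sweep(chemfuse:::pls2_predict_components(fit, Xs)[[3]], 2,
              colMeans(Y), "+")
  mo <- mixOmics::plsda(X, factor(y), ncomp = 3, scale = TRUE)
  pm <- stats::predict(mo, X)$predict[, , 3]
  expect_equal(unname(yh), unname(pm), tolerance = 1e-4)

  m <- structure(list(x_weights = fit$W, ss_component = fit$ss,
                      keep = 1:12, p_all = 12), class = "plsda_model")
  expect_equal(unname(vip(m)$scores), unname(mixOmics::vip(mo)[, 3]),
               tolerance = 1e-4)
})
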