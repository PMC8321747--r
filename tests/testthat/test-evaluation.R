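test_that("one-vs-rest confusion counts match direct enumeration", {
  y <- rep(c("C1", "C2", "C3"), c(4, 8, 9))
  cc <- confusion(y, y, c("C1", "C2", "C3"))
  expect_equal(cc$TP, c(4, 8, 9))
  expect_equal(cc$FN, c(0, 0, 0))
  expect_equal(cc$FP, c(0, 0, 0))
  expect_equal(cc$TN, c(17, 13, 12))

  all1 <- confusion(y, rep("C1", 21), c("C1", "C2", "C3"))
  expect_equal(all1$FP[1], 21 - 4)
  expect_equal(all1$TP[1], 4)

  set.seed(1)
  yt <- sample(c("A", "B", "C"), 30, replace = TRUE)
  yp <- sample(c("A", "B", "C"), 30, replace = TRUE)
  cc <- confusion(yt, yp, c("A", "B", "C"))
  for (i in 1:3) {
    cl <- cc$class[i]
    expect_equal(cc$TP[i], sum(yt == cl & yp == cl))
    expect_equal(cc$TN[i], sum(yt != cl & yp != cl))
    expect_equal(cc$TP[i] + cc$FN[i] + cc$TN[i] + cc$FP[i], 30)
  }
  expect_equal(sum(cc$TP), sum(yt == yp))
  expect_error(confusion(yt, yp, c("A", "B")), "outside")
})

test_that("efficiency is the geometric mean of sensitivity and specificity", {
  perfect <- confusion(rep(c("A", "B"), c(5, 10)), rep(c("A", "B"), c(5, 10)))
  expect_identical(unname(efficiency(perfect)), c(1, 1))

  # sensitivity 0.5, specificity 1 -> 0.7071
  cc <- data.frame(class = "A", TP = 1, FN = 1, TN = 19, FP = 0)
  expect_equal(unname(efficiency(cc)), sqrt(0.5), tolerance = 1e-4)
  cc2 <- data.frame(class = "A", TP = 1, FN = 1, TN = 16, FP = 4)
  expect_equal(unname(efficiency(cc2)), sqrt(0.5 * 0.8), tolerance = 1e-10)

  # converting a TP to an FN never increases efficiency
  cc3 <- data.frame(class = "A", TP = 3, FN = 1, TN = 16, FP = 4)
  cc4 <- data.frame(class = "A", TP = 2, FN = 2, TN = 16, FP = 4)
  expect_gt(unname(efficiency(cc3)), unname(efficiency(cc4)))

  empty <- data.frame(class = "A", TP = 0, FN = 0, TN = 10, FP = 2)
  expect_true(is.na(efficiency(empty)))
})

test_that("total accuracy reports two-decimal percentages", {
  expect_equal(total_accuracy(rep("A", 21), c(rep("A", 20), "B")), 95.24)
  expect_equal(total_accuracy(rep("A", 21), c(rep("A", 16), rep("B", 5))),
               76.19)
  expect_equal(total_accuracy(c("A", "B"), c("A", "B")), 100)
  expect_error(total_accuracy(character(0), character(0)), "empty")

  # identity with summed TP from the confusion counts
  set.seed(2)
  yt <- sample(c("A", "B", "C"), 40, replace = TRUE)
  yp <- sample(c("A", "B", "C"), 40, replace = TRUE)
  cc <- confusion(yt, yp, c("A", "B", "C"))
  expect_equal(total_accuracy(yt, yp), round(100 * sum(cc$TP) / 40, 2))
})

test_that("permutation test bookkeeping and reproducibility hold", {
  set.seed(3)
  y <- rep(paste0("C", 1:3), each = 8)
  X <- matrix(rnorm(24 * 10), 24)
  X[, 1] <- X[, 1] + c(0, 3, 6)[as.integer(factor(y))]
  X[, 2] <- X[, 2] + c(0, 3, -3)[as.integer(factor(y))]
  p1 <- permutation_test(X, y, max_lv = 4, n_iter = 10, seed = 11)
  expect_equal(nrow(p1$permuted_r2q2), 10)
  expect_true(all(p1$permuted_r2q2$correlation < 1))
  p2 <- permutation_test(X, y, max_lv = 4, n_iter = 10, seed = 11)
  expect_equal(p1$q2_intercept, p2$q2_intercept)
  expect_equal(p1$not_overfitting, p1$q2_intercept <= 0)
})
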