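mk_mem <- function(...) {
  membership_matrix(rbind(...), paste0("C", seq_len(length(c(...)) /
                                                      length(list(...)))))
}

test_that("low-level fusion concatenates variables with counts summing", {
  set.seed(1)
  mk <- function(n, kind = "retention_time")
    fingerprint_block(matrix(rnorm(3 * n), 3), seq_len(n), kind)
  fused <- low_level_fuse(list(mk(2387), mk(1097, "wavenumber")))
  expect_equal(ncol(fused$values), 3484)
  one <- mk(10)
  expect_identical(low_level_fuse(list(one)), one)
  blocks <- lapply(1:3, function(i)
    fingerprint_block(matrix(i, 3, i + 1), seq_len(i + 1), "retention_time"))
  f3 <- low_level_fuse(blocks, autoscale_blocks = FALSE)
  expect_equal(ncol(f3$values), 9)
  expect_equal(unname(f3$values[1, ]), rep(1:3, 2:4))   # order preserved
  b <- mk(4)
  mismatch <- fingerprint_block(matrix(rnorm(2 * 4), 2), 1:4,
                                "retention_time")
  expect_error(low_level_fuse(list(b, mismatch)), "differ")
})

test_that("mid-level fusion concatenates features and tolerates empties", {
  A <- matrix(rnorm(12), 4)
  B <- matrix(rnorm(8), 4)
  expect_equal(ncol(mid_level_fuse(list(A, B))), 5)
  expect_warning(out <- mid_level_fuse(list(A, matrix(0, 4, 0))),
                 "no features")
  expect_equal(out, A)
  expect_error(mid_level_fuse(list(A, matrix(0, 3, 2))), "row counts")
})

test_that("fuzzy connectives compute elementwise and stay in [0,1]", {
  m1 <- membership_matrix(rbind(c(0.9, 0.1)), c("C1", "C2"))
  m2 <- membership_matrix(rbind(c(0.8, 0.2)), c("C1", "C2"))
  expect_equal(fuzzy_aggregate(list(m1, m2), "product")$values[1, ],
               c(C1 = 0.72, C2 = 0.02))
  expect_equal(fuzzy_aggregate(list(m1, m2), "maximum")$values[1, ],
               c(C1 = 0.9, C2 = 0.2))
  expect_equal(fuzzy_aggregate(list(m1, m2), "average")$values[1, ],
               c(C1 = 0.85, C2 = 0.15))
  # identical inputs: max = min = average = input; product keeps the argmax
  for (op in c("maximum", "minimum", "average"))
    expect_equal(fuzzy_aggregate(list(m1, m1), op)$values, m1$values)
  expect_equal(which.max(fuzzy_aggregate(list(m1, m1), "product")$values),
               which.max(m1$values))
  # commutativity and closure on random memberships
  set.seed(2)
  r1 <- membership_matrix(matrix(runif(15), 5), paste0("C", 1:3))
  r2 <- membership_matrix(matrix(runif(15), 5), paste0("C", 1:3))
  for (op in c("maximum", "minimum", "average", "product")) {
    a <- fuzzy_aggregate(list(r1, r2), op)$values
    expect_equal(a, fuzzy_aggregate(list(r2, r1), op)$values)
    expect_true(all(a >= 0 & a <= 1))
  }
  bad <- membership_matrix(matrix(runif(15), 5), paste0("K", 1:3))
  expect_error(fuzzy_aggregate(list(r1, bad)), "class_order")
})

test_that("exact membership ties resolve deterministically", {
  m1 <- membership_matrix(rbind(c(1, 0)), c("C1", "C2"))
  m2 <- membership_matrix(rbind(c(0, 1)), c("C1", "C2"))
  d <- high_level_decide(list(m1, m2))
  # every operator aggregate is symmetric in the two classes, so each
  # operator vote and the final tie-break fall to the first class in order
  expect_equal(unname(d$per_operator_class[1, ]), rep("C1", 4))
  expect_equal(d$final_class, "C1")
  expect_error(high_level_decide(list(m1)), "2 blocks")
})
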