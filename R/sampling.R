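#' Kennard-Stone calibration/validation partitioning
#'
#' Deterministic max-min-distance selection: the first two calibration
#' samples are the pair at maximum Euclidean distance; each subsequent pick
#' maximizes its minimum distance to the samples already selected. Ties are
#' broken by the lowest sample index. The remaining samples form the
#' validation set.
#'
#' @param X numeric matrix (samples x variables).
#' @param n_cal number of calibration samples, `2 <= n_cal < nrow(X)`.
#' @return a `split_indices` list: `calibration` and `validation` index
#'   vectors (disjoint, covering all rows, both non-empty).
#' @export
kennard_stone <- function(X, n_cal) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (n_cal < 2 || n_cal >= m)
    stop("n_cal must satisfy 2 <= n_cal < ", m)
  D <- as.matrix(stats::dist(X))
  # farthest pair, lowest indices first on ties
  idx <- which(D == max(D), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sel <- c(idx[1, 1], idx[1, 2])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_cal) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)            # which.max takes the first maximum
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  structure(list(calibration = as.integer(sel),
                 validation = setdiff(seq_len(m), sel)),
            class = "split_indices")
}

#' Number of calibration samples for a cal:val ratio
#'
#' For the standard 2:1 ratio this is `floor(2m/3)`: 61 samples split
#' 40/21 and 62 split 41/21.
#'
#' @param m total number of samples.
#' @param ratio two numbers, calibration : validation proportions.
#' @return integer calibration count.
#' @export
calibration_size <- function(m, ratio = c(2, 1)) {
  as.integer(floor(m * ratio[1] / sum(ratio)))
}

#' Shared Kennard-Stone split across fingerprint blocks
#'
#' Data fusion requires the same samples on the same side of the split in
#' every block, so one split is computed on the column-wise concatenation of
#' the autoscaled blocks (autoscaling keeps a wide or high-variance block
#' from dominating the distance) and reused by every fusion strategy.
#'
#' @param blocks list of [fingerprint_block()]s with identical sample IDs in
#'   identical order.
#' @param ratio calibration : validation proportions.
#' @return a `split_indices` list (see [kennard_stone()]).
#' @export
shared_split <- function(blocks, ratio = c(2, 1)) {
  ids <- blocks[[1]]$sample_ids
  for (b in blocks[-1]) {
    bad <- which(b$sample_ids != ids)
    if (length(bad))
      stop("sample_ids differ across blocks at positions ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  Xs <- lapply(blocks, function(b) autoscale(b$values))
  X <- do.call(cbind, Xs)
  kennard_stone(X, calibration_size(length(ids), ratio))
}

#' @export
print.split_indices <- function(x, ...) {
  cat("<split_indices> calibration ", length(x$calibration),
      " / validation ", length(x$validation), "\n", sep = "")
  invisible(x)
}
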