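#' Low-level data fusion: concatenate fingerprint blocks
#'
#' Column-wise concatenation of the pretreated blocks; the fused variable
#' count is the sum of the block variable counts. Each block is autoscaled
#' before concatenation (switchable) so a wider or higher-variance block
#' does not dominate the subsequent model; samples must be in identical
#' order. The fused axis is a running variable index.
#'
#' @param blocks list of [fingerprint_block()]s.
#' @param autoscale_blocks autoscale each block before concatenation.
#' @return a [fingerprint_block()] with `axis_kind` of the first block.
#' @export
low_level_fuse <- function(blocks, autoscale_blocks = TRUE) {
  if (length(blocks) == 1) return(blocks[[1]])   # nothing to balance
  ids <- blocks[[1]]$sample_ids
  for (b in blocks[-1])
    if (!identical(b$sample_ids, ids))
      stop("sample rows differ across blocks")
  mats <- lapply(blocks, function(b)
    if (autoscale_blocks) autoscale(b$values) else b$values)
  X <- do.call(cbind, mats)
  fingerprint_block(X, seq_len(ncol(X)), blocks[[1]]$axis_kind,
                    ids, blocks[[1]]$labels)
}

#' Mid-level data fusion: concatenate extracted features
#'
#' Column-wise concatenation of per-block feature matrices (Boruta-selected
#' columns or PCA scores). An empty selection from one block passes the
#' others through with a warning.
#'
#' @param feature_blocks list of matrices with equal row counts.
#' @return the fused feature matrix.
#' @export
mid_level_fuse <- function(feature_blocks) {
  keep <- vapply(feature_blocks, function(f) ncol(as.matrix(f)) > 0,
                 logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " block(s) contributed no features")
    feature_blocks <- feature_blocks[keep]
  }
  if (!length(feature_blocks)) stop("no features from any block")
  m <- nrow(as.matrix(feature_blocks[[1]]))
  for (f in feature_blocks)
    if (nrow(as.matrix(f)) != m) stop("row counts differ across blocks")
  do.call(cbind, lapply(feature_blocks, as.matrix))
}

#' Fuzzy aggregation of membership matrices
#'
#' Combines per-block class membership degrees element-wise with one of the
#' four fuzzy connective operators: maximum, minimum, (arithmetic) average,
#' or product. All operators are commutative in the block list and map
#' [0,1] entries to [0,1].
#'
#' @param memberships list of [membership_matrix()]s with identical sample
#'   order and class order.
#' @param operator one of `"maximum"`, `"minimum"`, `"average"`,
#'   `"product"`.
#' @return the aggregated [membership_matrix()].
#' @export
fuzzy_aggregate <- function(memberships,
                            operator = c("maximum", "minimum", "average",
                                         "product")) {
  operator <- match.arg(operator)
  co <- memberships[[1]]$class_order
  for (mm in memberships[-1])
    if (!identical(mm$class_order, co))
      stop("class_order differs across membership matrices")
  arrs <- lapply(memberships, `[[`, "values")
  out <- switch(operator,
    maximum = Reduce(pmax, arrs),
    minimum = Reduce(pmin, arrs),
    average = Reduce(`+`, arrs) / length(arrs),
    product = Reduce(`*`, arrs))
  membership_matrix(out, co)
}

#' High-level decision fusion by majority vote of fuzzy connectives
#'
#' Each of the four operators (maximum, minimum, average, product)
#' aggregates the per-block memberships and casts an argmax vote per
#' sample; the final class is the one with the most operator votes. A vote
#' tie is broken by the average-operator aggregated membership (highest
#' wins), then by class order. When every block's own argmax agrees, the
#' final class is that class (unanimity preservation).
#'
#' @param memberships list of >= 2 [membership_matrix()]s (one per block).
#' @return a `fusion_decision`: `per_operator_class` (matrix samples x 4),
#'   `final_class`, `vote_detail` (aggregated memberships per operator).
#' @export
high_level_decide <- function(memberships) {
  if (length(memberships) < 2)
    stop("high-level fusion needs at least 2 blocks")
  ops <- c("maximum", "minimum", "average", "product")
  agg <- lapply(ops, function(op) fuzzy_aggregate(memberships, op))
  names(agg) <- ops
  votes <- vapply(agg, membership_classes,
                  character(nrow(memberships[[1]]$values)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1,
                                           dimnames = list(NULL, ops))
  co <- memberships[[1]]$class_order
  final <- vapply(seq_len(nrow(votes)), function(i) {
    tab <- table(factor(votes[i, ], levels = co))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) return(top)
    avg <- agg$average$values[i, top]
    top <- top[avg == max(avg)]
    top[1]                                 # class order breaks final ties
  }, character(1))
  structure(list(per_operator_class = votes, final_class = final,
                 vote_detail = agg, class_order = co),
            class = "fusion_decision")
}

#' Write a high-level fusion decision as CSV
#'
#' One row per sample: the four operator votes, the final class, and the
#' true class when available.
#'
#' @param decision a `fusion_decision`.
#' @param sample_ids sample identifiers.
#' @param y_true optional true classes.
#' @param path output file path.
#' @export
write_fusion_decision_csv <- function(decision, sample_ids, y_true = NULL,
                                      path) {
  dt <- data.table::data.table(sample_id = sample_ids)
  dt <- cbind(dt, data.table::as.data.table(decision$per_operator_class))
  dt[["final_class"]] <- decision$final_class
  if (!is.null(y_true)) dt[["true_class"]] <- as.character(y_true)
  data.table::fwrite(dt, path)
  invisible(path)
}
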