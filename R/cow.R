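#' Correlation-optimized warping (COW) of chromatograms
#'
#' Corrects sample-to-sample retention-time shifts by piecewise-linear
#' warping against a reference chromatogram. The reference axis is divided
#' into segments of approximately `segment_length` points; each internal
#' segment boundary in a sample may be displaced by up to `slack` points
#' from its reference position (signal ends stay fixed), and the warped
#' sample is the linear interpolation of each sample segment onto its
#' reference segment. Boundary positions are optimized jointly per sample
#' by exact dynamic programming, maximizing the summed Pearson correlation
#' of warped segments with the corresponding reference segments
#' (zero-variance segments contribute correlation 0).
#'
#' @param block a [fingerprint_block()] of chromatograms (rows = samples).
#' @param reference numeric vector of length `ncol(block$values)`; typically
#'   the column-wise mean of the calibration samples.
#' @param segment_length target segment length in points; must satisfy
#'   `segment_length >= 2 * slack + 3`.
#' @param slack maximum boundary displacement in points.
#' @return a `warping_result`: list with
#'   \describe{
#'     \item{aligned}{a [fingerprint_block()] of warped signals;}
#'     \item{node_map}{per-sample two-column matrices (source boundary in the
#'       sample, target boundary on the reference grid), 1-based, monotone,
#'       endpoints fixed;}
#'     \item{score}{per-sample summed segment correlation.}
#'   }
#' @export
cow_align <- function(block, reference, segment_length = 50, slack = 15) {
  X <- block$values
  n <- ncol(X)
  if (length(reference) != n)
    stop("reference length (", length(reference),
         ") must equal the number of variables (", n, ")")
  if (segment_length < 2 * slack + 3)
    stop("infeasible COW parameters: need segment_length >= 2*slack + 3 (",
         segment_length, " < ", 2 * slack + 3, ")")
  n_seg <- max(1L, as.integer(round((n - 1) / segment_length)))
  if ((n - 1) / n_seg < 2 * slack + 2)
    stop("infeasible COW parameters: segments of ", round((n - 1) / n_seg),
         " points cannot accommodate slack ", slack)
  # evenly spread boundaries, 0-based for the C++ core
  bounds <- as.integer(round(seq(0, n - 1, length.out = n_seg + 1)))
  res <- .cow_align_cpp(X, as.numeric(reference), bounds, as.integer(slack))
  node_map <- lapply(seq_len(nrow(X)), function(i) {
    cbind(source = bounds + 1L + res$offsets[i, ],
          target = bounds + 1L)
  })
  structure(list(
    aligned = block_with_values(block, res$aligned),
    node_map = node_map,
    score = as.numeric(res$scores)), class = "warping_result")
}

#' @export
print.warping_result <- function(x, ...) {
  cat("<warping_result> ", nrow(x$aligned$values), " samples, ",
      nrow(x$node_map[[1]]) - 1, " segments; mean segment-correlation sum ",
      format(mean(x$score), digits = 4), "\n", sep = "")
  invisible(x)
}
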