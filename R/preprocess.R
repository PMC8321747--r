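#' Keep one in every k variables
#'
#' Retains columns 1, 1+k, 1+2k, ... (the first point is always kept), the
#' standard data-reduction step for oversampled chromatograms.
#'
#' @param block a [fingerprint_block()].
#' @param k keep-every-k stride (k = 1 is the identity).
#' @return the reduced [fingerprint_block()].
#' @export
downsample_every_k <- function(block, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != as.integer(k))
    stop("k must be a positive integer")
  keep <- seq(1L, ncol(block$values), by = as.integer(k))
  block_subset_cols(block, keep)
}

# local least-squares filter weights for the d-th derivative, unit spacing:
# fit a polynomial of order p over 2h+1 points, differentiate at the centre
sg_coefficients <- function(window, polyorder, deriv) {
  h <- (window - 1L) / 2L
  A <- outer(seq(-h, h), 0:polyorder, "^")
  Cmat <- solve(crossprod(A), t(A))     # (p+1) x window
  factorial(deriv) * Cmat[deriv + 1L, ]
}

#' Savitzky-Golay second-derivative filter
#'
#' Applies a Savitzky-Golay polynomial second-derivative filter (default:
#' second-order polynomial, 15-point window) along each row. The derivative
#' is taken with respect to the point index (unit spacing). The
#' `(window-1)/2` columns at each edge, where the full window does not fit,
#' are discarded rather than padded, so the output has
#' `n - window + 1` columns and a correspondingly truncated axis.
#'
#' Removes constant offsets and linear baseline slopes exactly, and
#' sharpens overlapped bands, at the cost of the edge columns.
#'
#' @param block a [fingerprint_block()].
#' @param window odd filter window length (> polyorder).
#' @param polyorder polynomial order of the local fit.
#' @return the filtered [fingerprint_block()].
#' @export
sg_second_derivative <- function(block, window = 15, polyorder = 2) {
  n <- ncol(block$values)
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (n < window)
    stop("block has ", n, " variables; needs at least window = ", window)
  w <- sg_coefficients(window, polyorder, 2L)
  h <- (window - 1L) / 2L
  # valid-mode convolution: out[, j] = sum_s w[s] * X[, j + s - 1]
  nout <- n - window + 1L
  out <- matrix(0, nrow(block$values), nout)
  for (s in seq_len(window))
    out <- out + w[s] * block$values[, s:(s + nout - 1L), drop = FALSE]
  block_with_values(block, out, axis = block$axis[(h + 1L):(n - h)])
}

#' Delete variables inside axis bands
#'
#' Drops every column whose axis value lies inside any of the given closed
#' intervals (used to discard the noisy 4000-3700 and 2670-1750 cm^-1 FTIR
#' regions). Bands outside the axis range remove nothing; column order is
#' preserved; the operation is idempotent.
#'
#' @param block a [fingerprint_block()].
#' @param bands list of `c(low, high)` intervals in axis units.
#' @return the reduced [fingerprint_block()].
#' @export
remove_bands <- function(block, bands) {
  drop <- rep(FALSE, ncol(block$values))
  for (b in bands) {
    if (length(b) != 2 || b[1] >= b[2])
      stop("each band must be c(low, high) with low < high")
    drop <- drop | (block$axis >= b[1] & block$axis <= b[2])
  }
  block_subset_cols(block, which(!drop))
}

#' Full LC pretreatment chain
#'
#' COW retention-time correction against `reference` (defaulting to the
#' column-wise mean of the rows in `reference_rows`, intended to be the
#' calibration set), then 1-in-k data reduction, then the Savitzky-Golay
#' second-derivative filter. With the defaults a 7201-point chromatogram
#' block becomes 7201 -> 2401 -> 2387 variables.
#'
#' @param block LC [fingerprint_block()] (`axis_kind = "retention_time"`).
#' @param reference optional explicit COW reference signal.
#' @param reference_rows row indices used to build the default reference.
#' @param segment_length,slack COW parameters, see [cow_align()].
#' @param k downsampling stride.
#' @param window,polyorder Savitzky-Golay parameters.
#' @return the pretreated [fingerprint_block()].
#' @export
pretreat_lc <- function(block, reference = NULL,
                        reference_rows = seq_len(nrow(block$values)),
                        segment_length = 50, slack = 15, k = 3,
                        window = 15, polyorder = 2) {
  if (block$axis_kind != "retention_time")
    stop("pretreat_lc expects a retention_time block")
  if (is.null(reference))
    reference <- colMeans(block$values[reference_rows, , drop = FALSE])
  aligned <- cow_align(block, reference, segment_length, slack)$aligned
  sg_second_derivative(downsample_every_k(aligned, k), window, polyorder)
}

#' Full FTIR pretreatment chain
#'
#' Savitzky-Golay second-derivative filter first, then deletion of the noisy
#' spectral bands (band deletion is performed strictly after filtering so
#' the filter window never straddles a deletion gap).
#'
#' @param block FTIR [fingerprint_block()] (`axis_kind = "wavenumber"`).
#' @param bands wavenumber intervals to delete, cm^-1.
#' @param window,polyorder Savitzky-Golay parameters.
#' @return the pretreated [fingerprint_block()].
#' @export
pretreat_ftir <- function(block,
                          bands = list(c(1750, 2670), c(3700, 4000)),
                          window = 15, polyorder = 2) {
  if (block$axis_kind != "wavenumber")
    stop("pretreat_ftir expects a wavenumber block")
  remove_bands(sg_second_derivative(block, window, polyorder), bands)
}
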