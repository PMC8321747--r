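#' Fingerprint block: a sample-by-variable instrument response matrix
#'
#' The common container for one block of fingerprints: LC chromatograms
#' (intensity vs retention time in minutes) or ATR-FTIR spectra (absorbance
#' vs wavenumber in cm^-1). Rows are samples, columns are axis positions.
#'
#' @param values numeric matrix, m samples x n variables; no missing values.
#' @param axis numeric vector of length n; strictly monotone (ascending
#'   minutes for retention time; cm^-1 for wavenumber, either direction
#'   as exported, but strictly monotone).
#' @param axis_kind `"retention_time"` or `"wavenumber"`.
#' @param sample_ids character vector of m unique sample identifiers.
#' @param labels optional factor/character vector of m class labels.
#' @return An object of class `fingerprint_block`: a list with elements
#'   `values`, `axis`, `axis_kind`, `sample_ids`, `labels`.
#' @export
fingerprint_block <- function(values, axis,
                              axis_kind = c("retention_time", "wavenumber"),
                              sample_ids = NULL, labels = NULL) {
  axis_kind <- match.arg(axis_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  axis <- as.numeric(axis)
  if (length(axis) != ncol(values))
    stop("axis length (", length(axis), ") must equal column count (",
         ncol(values), ")")
  d <- diff(axis)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("axis must be strictly monotone")
  if (anyNA(values)) stop("values must not contain missing entries")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length must equal row count")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!is.null(labels)) {
    if (length(labels) != nrow(values))
      stop("labels length must equal row count")
    labels <- as.character(labels)
  }
  rownames(values) <- sample_ids
  structure(
    list(values = values, axis = axis, axis_kind = axis_kind,
         sample_ids = sample_ids, labels = labels),
    class = "fingerprint_block")
}

#' @export
print.fingerprint_block <- function(x, ...) {
  cat("<fingerprint_block> ", nrow(x$values), " samples x ",
      ncol(x$values), " variables (", x$axis_kind, ")\n", sep = "")
  cat("  axis: ", format(x$axis[1]), " .. ",
      format(x$axis[length(x$axis)]), "\n", sep = "")
  if (!is.null(x$labels))
    cat("  classes:", paste(names(table(x$labels)), table(x$labels),
                            sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.fingerprint_block <- function(x) dim(x$values)

# replace the value matrix / column subset, keeping metadata consistent
block_subset_cols <- function(block, keep) {
  fingerprint_block(block$values[, keep, drop = FALSE], block$axis[keep],
                    block$axis_kind, block$sample_ids, block$labels)
}

block_with_values <- function(block, values, axis = block$axis) {
  fingerprint_block(values, axis, block$axis_kind,
                    block$sample_ids, block$labels)
}

#' Autoscale a matrix (mean-centre, unit variance per column)
#'
#' Columns with zero variance are centred only (scale treated as 1) and
#' reported via the `"zero_variance"` attribute. When `center`/`scale` are
#' supplied (calibration statistics), they are applied as-is so validation
#' data are scaled into the calibration space.
#'
#' @param X numeric matrix.
#' @param center,scale optional vectors of pre-computed column statistics.
#' @return scaled matrix with attributes `center`, `scale`, `zero_variance`.
#' @export
autoscale <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
  }
  zv <- which(scale == 0 | !is.finite(scale))
  scale[zv] <- 1
  out <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  attr(out, "zero_variance") <- zv
  out
}
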