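#' Read a fingerprint block from CSV
#'
#' Expected layout: a header row whose entries after the identifier column(s)
#' are the numeric axis values; first column = sample IDs; an optional second
#' column named `label` (or `class`) carries class labels; remaining cells are
#' the response matrix.
#'
#' @param path file path.
#' @param axis_kind `"retention_time"` or `"wavenumber"`.
#' @return a [fingerprint_block()].
#' @export
read_fingerprint_csv <- function(path,
                                 axis_kind = c("retention_time", "wavenumber")) {
  axis_kind <- match.arg(axis_kind)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1)
    stop("ragged row at line ", which(nf != nf[1])[1])
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = 1), fill = FALSE)
  if (ncol(dt) < 2) stop("fingerprint CSV needs at least one data column")
  cols <- names(dt)
  has_label <- length(cols) >= 2 && tolower(cols[2]) %in% c("label", "class")
  first_data <- if (has_label) 3L else 2L
  axis <- suppressWarnings(as.numeric(cols[first_data:length(cols)]))
  if (anyNA(axis))
    stop("non-numeric axis value in header: ",
         cols[first_data:length(cols)][which(is.na(axis))[1]])
  ids <- dt[[1]]
  if (anyDuplicated(ids)) {
    ln <- which(duplicated(ids))[1] + 1L  # +1 for the header line
    stop("duplicate sample ID '", ids[duplicated(ids)][1], "' at line ", ln)
  }
  labels <- if (has_label) as.character(dt[[2]]) else NULL
  values <- as.matrix(dt[, first_data:length(cols), with = FALSE])
  dimnames(values) <- NULL
  if (!is.numeric(values)) {
    bad <- which(!apply(dt[, first_data:length(cols), with = FALSE], 1,
                        function(r) all(!is.na(suppressWarnings(as.numeric(r))))))[1]
    stop("non-numeric data value at line ", bad + 1L)
  }
  fingerprint_block(values, axis, axis_kind, sample_ids = ids, labels = labels)
}

#' Write a fingerprint block to CSV
#'
#' Inverse of [read_fingerprint_csv()]: axis values become the header,
#' sample IDs the first column, labels (when present) a `label` column.
#' Values are written with 12 significant digits so a write/read round trip
#' is lossless at that precision.
#'
#' @param block a [fingerprint_block()].
#' @param path output file path.
#' @export
write_fingerprint_csv <- function(block, path) {
  vals <- signif(block$values, 12)
  dt <- data.table::data.table(sample_id = block$sample_ids)
  if (!is.null(block$labels)) dt[["label"]] <- block$labels
  m <- data.table::as.data.table(vals)
  data.table::setnames(m, format(block$axis, digits = 12, trim = TRUE,
                                 scientific = FALSE))
  data.table::fwrite(cbind(dt, m), path)
  invisible(path)
}

#' Write a calibration/validation split as CSV
#'
#' Two columns: `sample_id` and `set` (`cal`/`val`).
#'
#' @param split a `split_indices` object from [kennard_stone()].
#' @param sample_ids character vector of all sample IDs (in row order).
#' @param path output file path.
#' @export
write_split_csv <- function(split, sample_ids, path) {
  set <- rep("val", length(sample_ids))
  set[split$calibration] <- "cal"
  data.table::fwrite(
    data.table::data.table(sample_id = sample_ids, set = set), path)
  invisible(path)
}

#' Write Boruta feature decisions as CSV
#'
#' Columns: variable index, axis value, status, hit count.
#'
#' @param decision a `feature_decision` from [boruta_select()].
#' @param axis axis values of the variables the decision refers to.
#' @param path output file path.
#' @export
write_feature_decision_csv <- function(decision, axis, path) {
  data.table::fwrite(
    data.table::data.table(variable = seq_along(decision$status),
                           axis = axis,
                           status = decision$status,
                           hits = decision$hits), path)
  invisible(path)
}
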