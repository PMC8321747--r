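#' Default peak table for the synthetic fingerprint design
#'
#' Gaussian peak positions (axis units), widths (Gaussian sd, axis units) and
#' per-class mean heights for a five-origin design measured by two blocks.
#' The design deliberately makes the first two origins confusable within
#' each single block but separable jointly: each block carries one weak
#' marker separating them (opposite class offsets in the two blocks), and
#' both markers additionally fluctuate with a shared specimen-level latent
#' abundance factor (`latent = 1` rows; sd `latent_sd` of the generator)
#' that masks the class offset within a block yet cancels in the cross-block
#' contrast. Origins 3-5 carry strong markers in both blocks. FTIR peaks
#' avoid the noisy 1750-2670 and 3700-4000 cm^-1 regions, which receive
#' noise only.
#'
#' @param n_classes number of origin classes (heights are defined for 5;
#'   fewer classes take the leading columns).
#' @return data.frame with columns `block`, `center`, `width`, `h1`..`h5`.
#' @export
default_peak_table <- function(n_classes = 5) {
  pt <- rbind(
    # block  center width  h1    h2    h3    h4    h5
    data.frame(block = "lc", center = 8,  width = 0.35,
               h1 = 0.80, h2 = 0.80, h3 = 0.80, h4 = 0.80, h5 = 0.80),
    data.frame(block = "lc", center = 14, width = 0.30,
               h1 = 0.55, h2 = 0.70, h3 = 0.55, h4 = 0.55, h5 = 0.95),
    data.frame(block = "lc", center = 22, width = 0.35,
               h1 = 0.60, h2 = 0.60, h3 = 1.00, h4 = 0.30, h5 = 0.60),
    data.frame(block = "lc", center = 31, width = 0.30,
               h1 = 0.50, h2 = 0.50, h3 = 0.50, h4 = 0.50, h5 = 0.50),
    data.frame(block = "lc", center = 38, width = 0.40,
               h1 = 0.70, h2 = 0.70, h3 = 0.40, h4 = 0.70, h5 = 0.70),
    data.frame(block = "lc", center = 47, width = 0.35,
               h1 = 0.90, h2 = 0.90, h3 = 0.90, h4 = 0.90, h5 = 0.90),
    data.frame(block = "lc", center = 53, width = 0.30,
               h1 = 0.30, h2 = 0.30, h3 = 0.30, h4 = 0.60, h5 = 0.30),
    data.frame(block = "ftir", center = 1030, width = 18,
               h1 = 0.90, h2 = 0.90, h3 = 0.90, h4 = 0.90, h5 = 0.90),
    data.frame(block = "ftir", center = 1145, width = 15,
               h1 = 0.52, h2 = 0.37, h3 = 0.52, h4 = 0.80, h5 = 0.52),
    data.frame(block = "ftir", center = 1310, width = 15,
               h1 = 0.60, h2 = 0.60, h3 = 0.90, h4 = 0.60, h5 = 0.30),
    data.frame(block = "ftir", center = 1450, width = 16,
               h1 = 0.50, h2 = 0.50, h3 = 0.50, h4 = 0.50, h5 = 0.50),
    data.frame(block = "ftir", center = 1640, width = 18,
               h1 = 0.70, h2 = 0.70, h3 = 0.50, h4 = 0.70, h5 = 1.00),
    data.frame(block = "ftir", center = 2900, width = 25,
               h1 = 0.80, h2 = 0.80, h3 = 0.80, h4 = 0.80, h5 = 0.80),
    data.frame(block = "ftir", center = 3400, width = 45,
               h1 = 0.60, h2 = 0.60, h3 = 0.60, h4 = 0.60, h5 = 0.60)
  )
  # the two weak origin-1/2 markers additionally carry the shared
  # specimen-level latent abundance factor (see generator_config)
  pt$latent <- 0
  pt$latent[pt$block == "lc" & pt$center == 14] <- 1
  pt$latent[pt$block == "ftir" & pt$center == 1145] <- 1
  if (n_classes < 5) pt <- pt[, c("block", "center", "width", "latent",
                                  paste0("h", seq_len(n_classes)))]
  pt
}

#' Configuration of the synthetic fingerprint generator
#'
#' Defaults emulate the study conditions: five geographic origins, LC
#' chromatograms recorded at 242 nm as 7201 points over a 60-min run, and
#' ATR-FTIR spectra of 1737 points spanning 650-4000 cm^-1, with
#' sample-specific retention-time shifts, per-sample baseline drift, and
#' noise-only FTIR regions at 1750-2670 and 3700-4000 cm^-1.
#'
#' @param n_per_class samples per origin class (>= 2).
#' @param n_classes number of origin classes.
#' @param lc_points,lc_minutes LC grid size and run length (minutes).
#' @param ftir_points,ftir_range FTIR grid size and wavenumber range (cm^-1).
#' @param peak_table data.frame as from [default_peak_table()].
#' @param shift_sd sd of the per-sample retention-time shift, in grid points
#'   (integer displacements are drawn from round(N(0, shift_sd))).
#' @param noise_sd sd of additive white noise (absorbance / intensity units).
#' @param height_sd sd of the per-sample, per-peak height fluctuation around
#'   the class mean (within-class biological variability).
#' @param latent_sd sd of the shared per-specimen latent abundance factor
#'   added to the heights of `latent = 1` peaks in both blocks (same draw
#'   per sample in LC and FTIR).
#' @param baseline_amp amplitude scale of the per-sample quadratic baseline.
#' @param noisy_bands list of FTIR wavenumber intervals that carry noise only.
#' @param noisy_band_factor noise-sd multiplier inside `noisy_bands`.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_per_class = 12, n_classes = 5,
                             lc_points = 7201, lc_minutes = 60,
                             ftir_points = 1737, ftir_range = c(650, 4000),
                             peak_table = default_peak_table(n_classes),
                             shift_sd = 5, noise_sd = 0.01, height_sd = 0.05,
                             latent_sd = 0.12, baseline_amp = 0.05,
                             noisy_bands = list(c(1750, 2670), c(3700, 4000)),
                             noisy_band_factor = 4, seed = 1) {
  stopifnot(n_per_class >= 2, n_classes >= 2, lc_points >= 2,
            ftir_points >= 2, shift_sd >= 0, noise_sd >= 0, height_sd >= 0,
            latent_sd >= 0)
  if (!all(peak_table$width > 0)) stop("all peak widths must be > 0")
  hcols <- paste0("h", seq_len(n_classes))
  if (!all(hcols %in% names(peak_table)))
    stop("peak_table must have one mean-height column per class (",
         paste(hcols, collapse = ", "), ")")
  structure(list(n_per_class = n_per_class, n_classes = n_classes,
                 lc_points = lc_points, lc_minutes = lc_minutes,
                 ftir_points = ftir_points, ftir_range = ftir_range,
                 peak_table = peak_table, shift_sd = shift_sd,
                 noise_sd = noise_sd, height_sd = height_sd,
                 latent_sd = latent_sd,
                 baseline_amp = baseline_amp, noisy_bands = noisy_bands,
                 noisy_band_factor = noisy_band_factor, seed = seed),
            class = "generator_config")
}

class_names <- function(n) paste0("Class", seq_len(n))

#' Generate one synthetic fingerprint block with ground truth
#'
#' Samples are Gaussian peak superpositions plus a per-sample quadratic
#' baseline and white noise. LC peaks are jointly displaced per sample by an
#' integer-point retention-time shift; FTIR peaks are not shifted and the
#' configured noisy wavenumber bands carry no class signal (inflated noise
#' only). Generation is fully determined by `config$seed` and `block_kind`.
#'
#' @param config a [generator_config()].
#' @param block_kind `"lc"` or `"ftir"`.
#' @return list with `block` (a [fingerprint_block()]) and `truth` (list:
#'   `informative` column indices carrying class signal, `true_shifts`
#'   per-sample shifts in points, `clean` the noise-free class-mean matrix).
#' @export
generate_block <- function(config, block_kind = c("lc", "ftir")) {
  block_kind <- match.arg(block_kind)
  k <- config$n_classes
  m <- config$n_per_class * k
  if (block_kind == "lc") {
    axis <- seq(0, config$lc_minutes, length.out = config$lc_points)
    axis_kind <- "retention_time"
  } else {
    axis <- seq(config$ftir_range[1], config$ftir_range[2],
                length.out = config$ftir_points)
    axis_kind <- "wavenumber"
  }
  pk <- config$peak_table[config$peak_table$block == block_kind, , drop = FALSE]
  if (nrow(pk) == 0) stop("no peaks configured for block '", block_kind, "'")
  bad <- which(pk$center < min(axis) | pk$center > max(axis))
  if (length(bad))
    stop("peak at ", pk$center[bad[1]], " (", block_kind,
         ") lies outside the axis range [", min(axis), ", ", max(axis), "]")
  heights <- as.matrix(pk[, paste0("h", seq_len(k)), drop = FALSE])

  labels <- rep(class_names(k), each = config$n_per_class)
  ids <- sprintf("s%02d", seq_len(m))
  spacing <- (max(axis) - min(axis)) / (length(axis) - 1)

  # the specimen-level latent factor is drawn from the same seed for both
  # block kinds, so the LC and FTIR fingerprints of a sample share it
  lat <- if (!is.null(config$latent_sd) && config$latent_sd > 0) {
    set.seed(config$seed + 500009L)
    stats::rnorm(m, 0, config$latent_sd)
  } else numeric(m)
  latent_pk <- if ("latent" %in% names(pk)) pk$latent > 0 else
    rep(FALSE, nrow(pk))

  # seed offset keeps the two blocks independent yet jointly reproducible
  set.seed(config$seed + ifelse(block_kind == "lc", 0L, 1000003L))
  shifts <- if (block_kind == "lc" && config$shift_sd > 0)
    as.integer(round(stats::rnorm(m, 0, config$shift_sd))) else integer(m)

  n <- length(axis)
  X <- matrix(0, m, n)
  for (i in seq_len(m)) {
    ci <- match(labels[i], class_names(k))
    h <- heights[, ci] + stats::rnorm(nrow(pk), 0, config$height_sd)
    h[latent_pk] <- h[latent_pk] + lat[i]
    centers <- pk$center + shifts[i] * spacing
    sig <- numeric(n)
    for (p in seq_len(nrow(pk)))
      sig <- sig + h[p] * exp(-(axis - centers[p])^2 / (2 * pk$width[p]^2))
    u <- (axis - min(axis)) / (max(axis) - min(axis))
    b <- stats::rnorm(3, 0, config$baseline_amp)
    sig <- sig + b[1] + b[2] * u + b[3] * u^2
    noise <- stats::rnorm(n, 0, config$noise_sd)
    if (block_kind == "ftir" && config$noise_sd > 0)
      for (bd in config$noisy_bands) {
        inb <- axis >= bd[1] & axis <= bd[2]
        noise[inb] <- noise[inb] * config$noisy_band_factor
      }
    X[i, ] <- sig + noise
  }

  # clean class-mean matrix (no shift, no noise, no baseline)
  clean <- matrix(0, k, n)
  for (ci in seq_len(k))
    for (p in seq_len(nrow(pk)))
      clean[ci, ] <- clean[ci, ] +
        heights[p, ci] * exp(-(axis - pk$center[p])^2 / (2 * pk$width[p]^2))

  # informative columns: within 1 sd of a peak whose class means differ
  disc <- apply(heights, 1, function(hh) diff(range(hh)) > 0)
  informative <- integer(0)
  for (p in which(disc))
    informative <- union(informative,
                         which(abs(axis - pk$center[p]) <= pk$width[p]))
  informative <- sort(informative)

  list(block = fingerprint_block(X, axis, axis_kind, ids, labels),
       truth = list(informative = informative, true_shifts = shifts,
                    clean = clean))
}

#' Generate the paired LC + FTIR dataset
#'
#' Convenience wrapper producing both blocks for the same cohort (identical
#' sample IDs, identical class labels).
#'
#' @param config a [generator_config()].
#' @return list `lc`, `ftir` (each as returned by [generate_block()]).
#' @export
generate_dataset <- function(config) {
  lc <- generate_block(config, "lc")
  ftir <- generate_block(config, "ftir")
  list(lc = lc, ftir = ftir)
}

#' Write generator ground truth as CSV
#'
#' One row per variable flagged informative: variable index, block,
#' informative flag.
#'
#' @param dataset output of [generate_dataset()].
#' @param path output file path.
#' @export
write_ground_truth_csv <- function(dataset, path) {
  rows <- do.call(rbind, lapply(c("lc", "ftir"), function(b) {
    n <- ncol(dataset[[b]]$block$values)
    data.table::data.table(variable = seq_len(n), block = b,
                           informative = seq_len(n) %in%
                             dataset[[b]]$truth$informative)
  }))
  data.table::fwrite(rows, path)
  invisible(path)
}
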