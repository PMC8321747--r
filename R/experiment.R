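#' Configuration of a full fusion experiment
#'
#' Collects the parameters of every stage with the standard defaults:
#' 1-in-3 data reduction, 15-point second-order SG window, 2:1
#' Kennard-Stone split, 7-fold cross-validation, 2000-tree RF screening,
#' FTIR deletion bands 1750-2670 and 3700-4000 cm^-1, 30-iteration
#' permutation test. Unknown arguments are errors (typo protection for
#' scientific parameters).
#'
#' @param generator a [generator_config()] describing the synthetic cohort
#'   (ignored when blocks are supplied to [run_experiment()] directly).
#' @param segment_length,slack COW parameters.
#' @param k downsampling stride.
#' @param window,polyorder Savitzky-Golay parameters.
#' @param bands FTIR deletion bands (cm^-1).
#' @param ratio calibration:validation proportions.
#' @param max_lv,folds PLS-DA latent-variable search bound and CV folds.
#' @param max_components PCA component search bound.
#' @param alpha,boruta_max_iter,boruta_trees Boruta parameters.
#' @param ntree_init,mtry_span RF screening parameters.
#' @param n_perm permutation-test iterations.
#' @param seed master seed; all stage seeds derive from it.
#' @param output_dir optional directory for per-stage CSV artifacts.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(generator = generator_config(),
                              segment_length = 50, slack = 15, k = 3,
                              window = 15, polyorder = 2,
                              bands = list(c(1750, 2670), c(3700, 4000)),
                              ratio = c(2, 1), max_lv = 10, folds = 7,
                              max_components = 10, alpha = 0.05,
                              boruta_max_iter = 100, boruta_trees = 500,
                              ntree_init = 2000, mtry_span = 10,
                              n_perm = 30, seed = 1, output_dir = NULL) {
  structure(as.list(environment()), class = "experiment_config")
}

# fit one classifier on a calibration matrix and return memberships for
# calibration and validation rows
fit_and_predict <- function(X_cal, X_val, y_cal, classifier, cfg, seed) {
  if (classifier == "plsda") {
    model <- suppressWarnings(plsda_fit(X_cal, y_cal, cfg$max_lv, cfg$folds))
    list(model = model,
         cal = plsda_predict(model, X_cal),
         val = plsda_predict(model, X_val))
  } else {
    screen <- rf_screen(X_cal, y_cal, ntree_init = cfg$ntree_init,
                        mtry_span = cfg$mtry_span, seed = seed)
    model <- rf_fit(X_cal, y_cal, screen)
    list(model = model,
         cal = rf_predict(model, X_cal),
         val = rf_predict(model, X_val))
  }
}

report_rows <- function(strategy, classifier, y_cal, y_val, pred_cal,
                        pred_val, class_order) {
  one <- function(set, yt, yp) {
    eff <- efficiency(confusion(yt, yp, class_order))
    row <- data.frame(strategy = strategy, classifier = classifier,
                      set = set, t(eff),
                      accuracy = total_accuracy(yt, yp),
                      check.names = FALSE)
    names(row)[4:(3 + length(eff))] <- paste0("eff_", class_order)
    row
  }
  rbind(one("cal", y_cal, pred_cal), one("val", y_val, pred_val))
}

#' Run the complete fusion experiment
#'
#' Executes the whole pipeline on a paired LC + FTIR dataset: one shared
#' Kennard-Stone split, per-block pretreatment (COW referenced on the
#' calibration mean, 1-in-k reduction and SG second derivative for LC; SG
#' second derivative then band deletion for FTIR), then fits and evaluates
#' PLS-DA and random forest for each strategy: the two single blocks,
#' low-level concatenation, mid-level PCA, mid-level Boruta, high-level PCA
#' and high-level Boruta (high-level trains one model per reduced block and
#' fuses the memberships by the four-connective majority vote). Reports
#' per-class efficiency and total accuracy for calibration and validation
#' sets — 4 single-block rows and 10 fusion rows per set.
#'
#' @param config an [experiment_config()].
#' @param blocks optional list `list(lc = , ftir = )` of
#'   [fingerprint_block()]s with labels; when NULL the synthetic generator
#'   in `config$generator` supplies them.
#' @return an `experiment_report`: `report` (data.frame), `split`,
#'   `boruta` (per-block feature decisions), `pca` (per-block features),
#'   `high_level` (fusion decisions), `models`.
#' @export
run_experiment <- function(config, blocks = NULL) {
  cfg <- config
  if (is.null(blocks)) {
    ds <- generate_dataset(cfg$generator)
    blocks <- list(lc = ds$lc$block, ftir = ds$ftir$block)
  }
  y <- blocks$lc$labels
  if (is.null(y) || !identical(y, blocks$ftir$labels))
    stop("blocks must carry identical class labels")
  class_order <- levels(factor(y))

  # one shared split, computed before warping (the COW reference is the
  # calibration mean, so the split must come first)
  split <- shared_split(list(blocks$lc, blocks$ftir), cfg$ratio)
  cal <- split$calibration; val <- split$validation
  y_cal <- y[cal]; y_val <- y[val]

  lc_p <- pretreat_lc(blocks$lc, reference_rows = cal,
                      segment_length = cfg$segment_length,
                      slack = cfg$slack, k = cfg$k,
                      window = cfg$window, polyorder = cfg$polyorder)
  ft_p <- pretreat_ftir(blocks$ftir, bands = cfg$bands,
                        window = cfg$window, polyorder = cfg$polyorder)

  pre <- list(lc = lc_p, ftir = ft_p)
  models <- list(); high_mem <- list()
  report <- list()

  # feature extraction per block (fit on calibration only)
  pca <- lapply(pre, function(b)
    pca_extract(b$values[cal, , drop = FALSE],
                b$values[val, , drop = FALSE],
                cfg$max_components, cfg$folds))
  boruta <- list(
    lc = boruta_select(lc_p$values[cal, , drop = FALSE], y_cal,
                       alpha = cfg$alpha, max_iter = cfg$boruta_max_iter,
                       rf_trees = cfg$boruta_trees, seed = cfg$seed + 11),
    ftir = boruta_select(ft_p$values[cal, , drop = FALSE], y_cal,
                         alpha = cfg$alpha, max_iter = cfg$boruta_max_iter,
                         rf_trees = cfg$boruta_trees, seed = cfg$seed + 13))
  bor_cols <- lapply(boruta, boruta_selected_columns)

  strat_seed <- cfg$seed + 100
  eval_strategy <- function(strategy, classifier, X_cal, X_val) {
    strat_seed <<- strat_seed + 1
    fp <- fit_and_predict(X_cal, X_val, y_cal, classifier, cfg, strat_seed)
    models[[paste(strategy, classifier, sep = ".")]] <<- fp$model
    report[[length(report) + 1]] <<- report_rows(
      strategy, classifier, y_cal, y_val,
      membership_classes(fp$cal), membership_classes(fp$val), class_order)
    fp
  }

  single_mem <- list()
  for (cls in c("plsda", "rf")) {
    # single blocks
    for (b in c("lc", "ftir"))
      single_mem[[paste(b, cls, sep = ".")]] <-
        eval_strategy(b, cls, pre[[b]]$values[cal, , drop = FALSE],
                      pre[[b]]$values[val, , drop = FALSE])
    # low-level
    fused <- low_level_fuse(pre)
    eval_strategy("low-level", cls, fused$values[cal, , drop = FALSE],
                  fused$values[val, , drop = FALSE])
    # mid-level PCA / Boruta
    eval_strategy("mid-level-pca", cls,
                  mid_level_fuse(lapply(pca, `[[`, "cal_scores")),
                  mid_level_fuse(lapply(pca, `[[`, "val_scores")))
    eval_strategy("mid-level-boruta", cls,
                  mid_level_fuse(list(
                    lc_p$values[cal, bor_cols$lc, drop = FALSE],
                    ft_p$values[cal, bor_cols$ftir, drop = FALSE])),
                  mid_level_fuse(list(
                    lc_p$values[val, bor_cols$lc, drop = FALSE],
                    ft_p$values[val, bor_cols$ftir, drop = FALSE])))
    # high-level: one model per reduced block, then fuzzy majority vote
    for (ex in c("pca", "boruta")) {
      feats <- if (ex == "pca") {
        list(lc = list(cal = pca$lc$cal_scores, val = pca$lc$val_scores),
             ftir = list(cal = pca$ftir$cal_scores,
                         val = pca$ftir$val_scores))
      } else {
        list(lc = list(cal = lc_p$values[cal, bor_cols$lc, drop = FALSE],
                       val = lc_p$values[val, bor_cols$lc, drop = FALSE]),
             ftir = list(cal = ft_p$values[cal, bor_cols$ftir, drop = FALSE],
                         val = ft_p$values[val, bor_cols$ftir, drop = FALSE]))
      }
      strat_seed <- strat_seed + 1
      fits <- lapply(feats, function(f)
        fit_and_predict(f$cal, f$val, y_cal, cls, cfg, strat_seed))
      dec_cal <- high_level_decide(lapply(fits, `[[`, "cal"))
      dec_val <- high_level_decide(lapply(fits, `[[`, "val"))
      strategy <- paste0("high-level-", ex)
      high_mem[[paste(strategy, cls, sep = ".")]] <-
        list(cal = dec_cal, val = dec_val)
      report[[length(report) + 1]] <- report_rows(
        strategy, cls, y_cal, y_val,
        dec_cal$final_class, dec_val$final_class, class_order)
    }
  }

  report <- do.call(rbind, report)
  rownames(report) <- NULL
  out <- structure(list(report = report, split = split, boruta = boruta,
                        pca = pca, high_level = high_mem, models = models,
                        pretreated = pre, labels = y, config = cfg),
                   class = "experiment_report")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(report, file.path(cfg$output_dir, "report.csv"))
    write_split_csv(split, blocks$lc$sample_ids,
                    file.path(cfg$output_dir, "split.csv"))
    for (b in c("lc", "ftir"))
      write_feature_decision_csv(boruta[[b]], pre[[b]]$axis,
        file.path(cfg$output_dir, paste0("boruta_", b, ".csv")))
  }
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> ", nrow(x$report), " rows (",
      length(unique(x$report$strategy)), " strategies x 2 classifiers x ",
      "cal/val)\n", sep = "")
  print(x$report[x$report$set == "val",
                 c("strategy", "classifier", "accuracy")],
        row.names = FALSE)
  invisible(x)
}
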