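#' Confusion counts over bag-level calls
#'
#' @param truth Vector of true labels in `{+1, -1}`.
#' @param pred Vector of predicted labels in `{+1, -1}`.
#' @return Named integer vector `c(TP, FP, FN, TN)` of class
#'   `confusion_counts`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  structure(c(TP = sum(truth > 0 & pred > 0),
              FP = sum(truth < 0 & pred > 0),
              FN = sum(truth > 0 & pred < 0),
              TN = sum(truth < 0 & pred < 0)),
            class = "confusion_counts")
}

#' Precision, sensitivity and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `sensitivity = TP/(TP+FN)`, `f1` their harmonic
#' mean. Degenerate `0/0` cases resolve to 0 (never `NaN`) so aggregation
#' over folds stays finite.
#'
#' @param counts A [confusion_counts()] vector, or any named vector/list with
#'   `TP`, `FP`, `FN` entries.
#' @return Named numeric vector `c(precision, sensitivity, f1)`.
#' @export
hrd_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]])
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  s <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(precision = p, sensitivity = s, f1 = f1_score(p, s))
}

#' Harmonic mean of precision and sensitivity
#'
#' @param precision,sensitivity Values in `[0, 1]`.
#' @return `2*P*S/(P+S)`, or 0 when `P + S == 0`.
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity > 0,
         2 * precision * sensitivity / (precision + sensitivity), 0)
}

# stratified fold ids (consumes the current RNG stream)
.stratified_folds <- function(labs, k) {
  fold <- integer(length(labs))
  for (cls in c(1L, -1L)) {
    idx <- sample(which(labs == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.eval_fold <- function(train_bags, test_bags, model_config, control) {
  model <- do.call(miln_train,
                   c(list(bags = train_bags, control = control),
                     model_config))
  pred <- predict(model, test_bags)
  confusion_counts(.bag_labels(test_bags), pred$hrd_status)
}

.report <- function(folds_df, mode, config, seed) {
  mean_row <- colMeans(folds_df[, c("precision", "sensitivity", "f1"),
                                drop = FALSE])
  structure(list(folds = folds_df, mean = mean_row,
                 var_f1 = stats::var(folds_df$f1),
                 mode = mode, config = config, seed = seed),
            class = "miln_eval")
}

#' @export
print.miln_eval <- function(x, ...) {
  cat(sprintf("<miln_eval> mode = %s, %d folds/replicates\n",
              x$mode, nrow(x$folds)))
  cat(sprintf("  mean precision %.2f, sensitivity %.2f, f1 %.2f (var of f1 %.5f)\n",
              x$mean["precision"], x$mean["sensitivity"], x$mean["f1"],
              x$var_f1))
  invisible(x)
}

#' Stratified k-fold cross-validation over bags
#'
#' Bags (samples) are the unit of splitting; a bag's instances always stay
#' together. Folds are stratified by HRD label. Per fold the model is trained
#' on the remaining bags (normalization bounds and threshold refit, so there
#' is no leakage) and evaluated on the held-out bags.
#'
#' @param bags List of labeled bags.
#' @param k_folds Number of folds (default 10).
#' @param model_config List of arguments for [miln_train()] (e.g. `K`,
#'   `pro`, `feature_names`).
#' @param seed Integer seed controlling the fold assignment.
#' @param control A [miln_control()] list.
#' @return A `miln_eval` report: per-fold counts and metrics, their means,
#'   and the variance of the fold F1 scores.
#' @export
kfold_cv <- function(bags, k_folds = 10L, model_config = list(K = 3L, pro = 0.9),
                     seed = 1L, control = miln_control()) {
  labs <- .bag_labels(bags)
  if (length(bags) < k_folds) stop("fewer bags than folds")
  if (!any(labs > 0) || !any(labs < 0)) stop("both classes required")
  set.seed(seed)
  fold <- .stratified_folds(labs, k_folds)
  rows <- lapply(seq_len(k_folds), function(f) {
    cc <- .eval_fold(bags[fold != f], bags[fold == f], model_config, control)
    data.frame(fold = f, TP = cc[["TP"]], FP = cc[["FP"]], FN = cc[["FN"]],
               TN = cc[["TN"]], t(hrd_metrics(cc)))
  })
  .report(do.call(rbind, rows), "kfold",
          c(model_config, list(k_folds = k_folds)), seed)
}

#' Nested cross-validation with (K, Pro) grid selection
#'
#' The inner loop selects the concept count `K` and reliability threshold
#' `Pro` by mean inner-fold F1; the outer loop reports unbiased scores for
#' the per-fold winners. Grid candidates whose inner evaluation fails (e.g.
#' a single-class inner fold) are skipped with a warning. The report also
#' carries the mean absolute metric difference against a plain k-fold run of
#' the modal chosen configuration.
#'
#' @param bags List of labeled bags.
#' @param outer_folds,inner_folds Fold counts (defaults 10 and 3).
#' @param K_grid,pro_grid Hyperparameter grids (non-empty).
#' @param seed Integer seed.
#' @param control A [miln_control()] list.
#' @return A `miln_eval` report with extra elements `chosen` (per outer fold)
#'   and `vs_plain_kfold` (mean absolute difference of the three metrics).
#' @export
nested_cv <- function(bags, outer_folds = 10L, inner_folds = 3L,
                      K_grid = c(1L, 2L, 3L, 4L), pro_grid = 0.9,
                      seed = 1L, control = miln_control()) {
  if (!length(K_grid) || !length(pro_grid)) stop("grids must be non-empty")
  labs <- .bag_labels(bags)
  if (length(bags) < outer_folds) stop("fewer bags than folds")
  set.seed(seed)
  fold <- .stratified_folds(labs, outer_folds)
  inner_seeds <- sample.int(.Machine$integer.max, outer_folds)
  grid <- expand.grid(K = K_grid, pro = pro_grid)
  rows <- list(); chosen <- list()
  for (f in seq_len(outer_folds)) {
    train <- bags[fold != f]
    inner_f1 <- apply(grid, 1, function(g) {
      tryCatch({
        r <- kfold_cv(train, inner_folds,
                      model_config = list(K = as.integer(g[["K"]]),
                                          pro = g[["pro"]]),
                      seed = inner_seeds[f], control = control)
        r$mean[["f1"]]
      }, error = function(e) {
        warning("inner-fold candidate K=", g[["K"]], " pro=", g[["pro"]],
                " skipped: ", conditionMessage(e))
        NA_real_
      })
    })
    if (all(is.na(inner_f1))) stop("no usable hyperparameter candidate")
    best <- which.max(inner_f1)          # ties -> first in grid order
    cfg <- list(K = as.integer(grid$K[best]), pro = grid$pro[best])
    cc <- .eval_fold(train, bags[fold == f], cfg, control)
    rows[[f]] <- data.frame(fold = f, TP = cc[["TP"]], FP = cc[["FP"]],
                            FN = cc[["FN"]], TN = cc[["TN"]],
                            t(hrd_metrics(cc)))
    chosen[[f]] <- data.frame(fold = f, K = cfg$K, pro = cfg$pro,
                              inner_f1 = inner_f1[best])
  }
  rep <- .report(do.call(rbind, rows), "nested",
                 list(K_grid = K_grid, pro_grid = pro_grid,
                      outer_folds = outer_folds, inner_folds = inner_folds),
                 seed)
  rep$chosen <- do.call(rbind, chosen)
  modal_K <- as.integer(names(which.max(table(rep$chosen$K))))
  modal_pro <- as.numeric(names(which.max(table(rep$chosen$pro))))
  plain <- kfold_cv(bags, outer_folds,
                    model_config = list(K = modal_K, pro = modal_pro),
                    seed = seed, control = control)
  rep$vs_plain_kfold <- mean(abs(rep$mean - plain$mean))
  rep
}

#' Bootstrap evaluation over bags
#'
#' Each replicate resamples bags with replacement, trains on the resample and
#' scores the out-of-bag samples. Replicates whose resample contains one
#' class (or leaves no out-of-bag bag) are redrawn up to `retry_limit` times,
#' then skipped with a warning.
#'
#' @param bags List of labeled bags.
#' @param replicates Number of bootstrap replicates (default 500).
#' @param model_config List of arguments for [miln_train()].
#' @param seed Integer seed.
#' @param control A [miln_control()] list.
#' @param retry_limit Redraw attempts per degenerate replicate (default 10).
#' @return A `miln_eval` report over replicates.
#' @export
bootstrap_eval <- function(bags, replicates = 500L,
                           model_config = list(K = 3L, pro = 0.9),
                           seed = 1L, control = miln_control(),
                           retry_limit = 10L) {
  labs <- .bag_labels(bags)
  if (!any(labs > 0) || !any(labs < 0)) stop("both classes required")
  set.seed(seed)
  n <- length(bags)
  rows <- list()
  for (r in seq_len(replicates)) {
    ok <- FALSE
    for (try in seq_len(retry_limit)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(unique(labs[idx])) == 2L && length(oob) > 0L) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      warning("replicate ", r, " skipped: degenerate resample")
      next
    }
    cc <- .eval_fold(bags[idx], bags[oob], model_config, control)
    rows[[length(rows) + 1L]] <-
      data.frame(fold = r, TP = cc[["TP"]], FP = cc[["FP"]], FN = cc[["FN"]],
                 TN = cc[["TN"]], t(hrd_metrics(cc)))
  }
  .report(do.call(rbind, rows), "bootstrap",
          c(model_config, list(replicates = replicates)), seed)
}

#' Write an evaluation report
#'
#' @param report A `miln_eval` object.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_eval_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report$folds, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(mode = report$mode,
                              mean = as.list(report$mean),
                              var_f1 = report$var_f1,
                              config = report$config, seed = report$seed,
                              folds = report$folds),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
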