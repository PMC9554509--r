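test_that("metrics handle worked examples and degenerate denominators", {
  expect_equal(hrd_metrics(c(TP = 1, FP = 3, FN = 1, TN = 0)),
               c(precision = 0.25, sensitivity = 0.5, f1 = 1 / 3))
  expect_equal(round(f1_score(0.25, 0.5), 2), 0.33)
  expect_equal(f1_score(1, 1), 1)
  # 0/0 cases resolve to 0, never NaN
  z <- hrd_metrics(c(TP = 0, FP = 0, FN = 0, TN = 5))
  expect_equal(unname(z), c(0, 0, 0))
  expect_equal(f1_score(0, 0), 0)
})

test_that("F1 property: symmetric, and between min and max of (P, S)", {
  set.seed(10)
  for (i in 1:50) {
    p <- runif(1); s <- runif(1)
    f <- f1_score(p, s)
    expect_equal(f, f1_score(s, p))
    expect_gte(f, min(p, s) - 1e-12)
    expect_lte(f, max(p, s) + 1e-12)
  }
})

test_that("confusion_counts partitions the evaluated bags", {
  set.seed(3)
  truth <- sample(c(1, -1), 30, replace = TRUE)
  pred <- sample(c(1, -1), 30, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  expect_equal(sum(cc), 30)
  expect_error(confusion_counts(truth, pred[-1]), "mismatch")
})

test_that("kfold_cv: folds partition bags, perfect world scores F1 = 1", {
  sim <- perfect_sim(seed = 7)
  cv <- kfold_cv(sim$bags, 4, list(K = 1, pro = 0.9), seed = 7,
                 control = fast_ctrl())
  # partition: every bag in exactly one test fold
  expect_equal(sum(cv$folds$TP + cv$folds$FP + cv$folds$FN + cv$folds$TN),
               length(sim$bags))
  expect_equal(cv$mean[["f1"]], 1)
  expect_equal(cv$var_f1, 0)
  # determinism
  cv2 <- kfold_cv(sim$bags, 4, list(K = 1, pro = 0.9), seed = 7,
                  control = fast_ctrl())
  expect_identical(cv$folds, cv2$folds)
  # different seed gives a different fold assignment but a valid partition
  cv3 <- kfold_cv(sim$bags, 4, list(K = 1, pro = 0.9), seed = 8,
                  control = fast_ctrl())
  expect_equal(sum(cv3$folds$TP + cv3$folds$FP + cv3$folds$FN + cv3$folds$TN),
               length(sim$bags))
  expect_error(kfold_cv(sim$bags, 99), "fewer bags")
})

test_that("null labels give chance-level precision", {
  # shuffled labels: precision pooled over folds approaches class prevalence
  # (fold-mean precision would be deflated by the 0/0 -> 0 convention on
  # folds that predict no positives, so pool the counts instead)
  precs <- vapply(1:8, function(s) {
    sim <- small_sim(seed = s, n_pos = 6, n_neg = 6)
    set.seed(s + 100)
    bags <- lapply(sim$bags, function(b) {
      b$label <- sample(c(1L, -1L), 1)
      b
    })
    labs <- vapply(bags, `[[`, 1L, "label")
    if (!any(labs > 0) || !any(labs < 0)) return(NA_real_)
    cv <- tryCatch(
      kfold_cv(bags, 3, list(K = 1, pro = 0.9), seed = s,
               control = miln_control(restarts = 1L, max_iter = 10L)),
      error = function(e) NULL)
    if (is.null(cv)) return(NA_real_)
    tp <- sum(cv$folds$TP); fp <- sum(cv$folds$FP)
    if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  }, 0)
  prevalence <- 0.5   # labels drawn fair-coin
  expect_lt(abs(mean(precs, na.rm = TRUE) - prevalence), 0.2)
})

test_that("nested_cv with a single-candidate grid reduces to plain kfold", {
  sim <- small_sim(seed = 1, n_pos = 8, n_neg = 8)
  ctrl <- fast_ctrl()
  nc <- nested_cv(sim$bags, outer_folds = 4, inner_folds = 2,
                  K_grid = 2, pro_grid = 0.9, seed = 5, control = ctrl)
  plain <- kfold_cv(sim$bags, 4, list(K = 2L, pro = 0.9), seed = 5,
                    control = ctrl)
  expect_equal(nc$mean, plain$mean)
  expect_equal(nc$vs_plain_kfold, 0)
  expect_true(all(nc$chosen$K == 2))
  expect_error(nested_cv(sim$bags, K_grid = integer(0)), "non-empty")
})

test_that("nested_cv recovers the planted concept count", {
  sim <- simulate_bags(sim_config(seed = 7))   # default K_true = 3 world
  nc <- nested_cv(sim$bags, outer_folds = 3, inner_folds = 2,
                  K_grid = c(1L, 3L), pro_grid = 0.9, seed = 7,
                  control = fast_ctrl())
  modal_K <- as.integer(names(which.max(table(nc$chosen$K))))
  expect_equal(modal_K, 3L)
})

test_that("bootstrap_eval is deterministic and scores the perfect world", {
  sim <- perfect_sim(seed = 7)
  b1 <- bootstrap_eval(sim$bags, replicates = 5,
                       model_config = list(K = 1, pro = 0.9), seed = 2,
                       control = fast_ctrl())
  b2 <- bootstrap_eval(sim$bags, replicates = 5,
                       model_config = list(K = 1, pro = 0.9), seed = 2,
                       control = fast_ctrl())
  expect_identical(b1$folds, b2$folds)
  expect_equal(nrow(b1$folds), 5)
  expect_gte(b1$mean[["f1"]], 0.9)
  # out-of-bag evaluation: every replicate evaluates a strict subset
  expect_true(all(b1$folds$TP + b1$folds$FP + b1$folds$FN + b1$folds$TN
                  < length(sim$bags)))
})

test_that("eval report writers emit TSV and JSON", {
  sim <- small_sim(seed = 6, n_pos = 6, n_neg = 6)
  cv <- kfold_cv(sim$bags, 3, list(K = 1, pro = 0.9), seed = 1,
                 control = fast_ctrl())
  tp <- file.path(withr::local_tempdir(), "rep.tsv")
  jp <- file.path(withr::local_tempdir(), "rep.json")
  write_eval_report(cv, tp, jp)
  expect_equal(nrow(utils::read.delim(tp)), 3)
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(j$mode, "kfold")
  expect_equal(j$mean$f1, cv$mean[["f1"]])
})
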