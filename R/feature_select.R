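# best decision stump for weights w: h(x) = sign * (2*(x > theta) - 1)
# maximizes sum_i w_i h(x_i); returns list(feature, threshold, sign, score)
.best_stump <- function(X, w, max_thresholds = 64L) {
  best <- list(score = -Inf)
  tot <- sum(w)
  for (d in seq_len(ncol(X))) {
    x <- X[, d]
    ux <- sort(unique(x))
    if (length(ux) < 2L) next
    if (length(ux) > max_thresholds) {
      ux <- unique(stats::quantile(x, probs = seq(0, 1,
                                                  length.out = max_thresholds),
                                   names = FALSE, type = 1))
    }
    thr <- (ux[-length(ux)] + ux[-1]) / 2
    ord <- order(x)
    cw <- cumsum(w[ord])
    # sum of w over x <= theta, via the sorted positions
    below <- cw[findInterval(thr, x[ord])]
    score_plus <- tot - 2 * below       # h = +1 above theta
    for (j in seq_along(thr)) {
      sc <- abs(score_plus[j])
      if (sc > best$score + 1e-12) {
        best <- list(feature = d, threshold = thr[j],
                     sign = if (score_plus[j] >= 0) 1 else -1, score = sc)
      }
    }
  }
  best
}

.stump_apply <- function(x, stump) {
  stump$sign * (2 * (x > stump$threshold) - 1)
}

# noisy-OR bag negative log likelihood given instance activations F
.milboost_loss <- function(F, bagid, y01, eps = 1e-9) {
  p <- stats::plogis(F)
  p <- pmin(pmax(p, eps), 1 - eps)
  log_not <- vapply(split(log1p(-p), bagid), sum, 0)
  P <- pmin(pmax(1 - exp(log_not), eps), 1 - eps)
  -sum(y01 * log(P) + (1 - y01) * log(1 - P))
}

#' MILBoost feature-importance ranking
#'
#' Boosts single-feature threshold stumps under the noisy-OR bag likelihood:
#' instance probabilities are logistic in the boosted score, a bag is
#' positive with probability `1 - prod_j (1 - p_ij)`, and per-round instance
#' weights are the gradient of the bag log-likelihood. Each round picks the
#' stump maximizing the weight-stump correlation and line-searches its
#' coefficient. A feature's importance is the normalized sum of absolute
#' stump coefficients over the rounds that used it.
#'
#' @param bags List of labeled bags (both classes present).
#' @param rounds Number of boosting rounds (>= 1; default 50).
#' @param seed Integer seed, recorded in the report (the fit itself is
#'   deterministic).
#' @return A `miln_importance` object: normalized `weights`, `ranking`,
#'   `rounds_used` and the per-round `stumps` table.
#' @export
milboost_fit <- function(bags, rounds = 50L, seed = 1L) {
  rounds <- as.integer(rounds)
  if (rounds < 1L) stop("rounds must be >= 1")
  labs <- .bag_labels(bags)
  if (!any(labs > 0) || !any(labs < 0)) {
    stop("both classes required for boosting")
  }
  st <- .stack_bags(bags)
  X <- st$X
  bagid <- st$bag
  y01 <- as.integer(labs > 0)
  m <- ncol(X)
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(m))
  eps <- 1e-9
  Fv <- numeric(nrow(X))
  stumps <- list()
  for (r in seq_len(rounds)) {
    p <- stats::plogis(Fv)
    p <- pmin(pmax(p, eps), 1 - eps)
    log_not <- vapply(split(log1p(-p), bagid), sum, 0)
    P <- pmin(pmax(1 - exp(log_not), eps), 1 - eps)
    # dL/dF per instance: positive bags pull their instances up in
    # proportion to how unexplained the bag is; negative bags push down
    w <- ifelse(y01[bagid] == 1L,
                p * (1 - P[bagid]) / P[bagid],
                -p)
    stump <- .best_stump(X, w)
    if (!is.finite(stump$score) || stump$score <= 1e-12) break
    h <- .stump_apply(X[, stump$feature], stump)
    loss0 <- .milboost_loss(Fv, bagid, y01, eps)
    ls <- stats::optimize(function(a) .milboost_loss(Fv + a * h, bagid,
                                                     y01, eps),
                          interval = c(0, 4))
    if (loss0 - ls$objective < 1e-10) break
    Fv <- Fv + ls$minimum * h
    stumps[[length(stumps) + 1L]] <-
      data.frame(round = r, feature = fn[stump$feature],
                 threshold = stump$threshold, sign = stump$sign,
                 alpha = ls$minimum)
  }
  weights <- stats::setNames(numeric(m), fn)
  if (length(stumps)) {
    sdf <- do.call(rbind, stumps)
    agg <- tapply(abs(sdf$alpha), sdf$feature, sum)
    weights[names(agg)] <- agg
    weights <- weights / sum(weights)
  }
  structure(list(weights = weights,
                 ranking = fn[order(-weights, seq_len(m))],
                 rounds_used = length(stumps),
                 stumps = if (length(stumps)) do.call(rbind, stumps) else NULL,
                 seed = as.integer(seed)),
            class = "miln_importance")
}

#' @export
print.miln_importance <- function(x, ...) {
  cat(sprintf("<miln_importance> %d boosting rounds used\n", x$rounds_used))
  print(round(sort(x$weights, decreasing = TRUE), 4))
  invisible(x)
}

#' Ablation curve over feature-set sizes
#'
#' For each candidate feature count, repeatedly draws random feature subsets,
#' evaluates the concept model by bag-level cross-validation on each subset,
#' and averages the F1 scores: each of `repeats` outer replicates is the mean
#' over `subsets_per_count` random-subset experiments, and the curve reports
#' the mean and dispersion of the outer replicates. The chosen count is the
#' smallest whose mean F1 is within one standard error of the global
#' maximum.
#'
#' @param bags List of labeled bags.
#' @param counts Feature counts to probe (default `1:m`).
#' @param subsets_per_count Random-subset experiments per replicate
#'   (default 50).
#' @param repeats Outer replicates per count (default 100).
#' @param seed Integer seed (all subset draws and CV splits flow from it).
#' @param model_config List of arguments for [miln_train()].
#' @param eval_folds Folds of the inner bag-level CV (default 3).
#' @param control A [miln_control()] list; the default is a lightened
#'   configuration (fewer restarts/iterations) because the curve needs many
#'   fits, not a polished single fit.
#' @return A `miln_ablation` object: `curve` (count, mean_f1, sd_f1, se_f1),
#'   `chosen`, and the per-experiment `detail` table (including the CV seed
#'   of every experiment, for exact reproduction).
#' @export
ablation_study <- function(bags, counts = NULL, subsets_per_count = 50L,
                           repeats = 100L, seed = 1L,
                           model_config = list(K = 3L, pro = 0.9),
                           eval_folds = 3L,
                           control = miln_control(restarts = 2L,
                                                  max_iter = 25L)) {
  m <- ncol(bags[[1]]$instances)
  fn <- colnames(bags[[1]]$instances)
  if (is.null(fn)) fn <- paste0("f", seq_len(m))
  if (is.null(counts)) counts <- seq_len(m)
  if (any(counts < 1L | counts > m)) stop("counts must lie in 1..", m)
  set.seed(seed)
  detail <- list()
  curve <- list()
  for (cc in counts) {
    reps_mean <- numeric(repeats)
    for (r in seq_len(repeats)) {
      f1s <- numeric(subsets_per_count)
      for (e in seq_len(subsets_per_count)) {
        sel <- sort(sample.int(m, cc))
        cv_seed <- sample.int(.Machine$integer.max, 1L)
        sub <- lapply(bags, function(b) {
          miln_bag(b$sample_id, b$instances[, sel, drop = FALSE], b$label)
        })
        res <- kfold_cv(sub, eval_folds, model_config, seed = cv_seed,
                        control = control)
        f1s[e] <- res$mean[["f1"]]
        detail[[length(detail) + 1L]] <-
          data.frame(count = cc, replicate = r, experiment = e,
                     cv_seed = cv_seed, f1 = f1s[e],
                     features = paste(fn[sel], collapse = ","))
      }
      reps_mean[r] <- mean(f1s)
    }
    curve[[length(curve) + 1L]] <-
      data.frame(count = cc, mean_f1 = mean(reps_mean),
                 sd_f1 = if (repeats > 1L) stats::sd(reps_mean) else 0,
                 se_f1 = if (repeats > 1L)
                   stats::sd(reps_mean) / sqrt(repeats) else 0)
  }
  curve <- do.call(rbind, curve)
  best <- which.max(curve$mean_f1)
  ok <- curve$mean_f1 >= curve$mean_f1[best] - curve$se_f1[best]
  chosen <- min(curve$count[ok])
  structure(list(curve = curve, chosen = chosen,
                 detail = do.call(rbind, detail), seed = as.integer(seed)),
            class = "miln_ablation")
}

#' @export
print.miln_ablation <- function(x, ...) {
  cat(sprintf("<miln_ablation> chosen feature count: %d\n", x$chosen))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Write feature-selection outputs as TSV
#'
#' @param importance A `miln_importance` object (or `NULL`).
#' @param ablation A `miln_ablation` object (or `NULL`).
#' @param importance_path,ablation_path Output paths.
#' @return Invisibly, `NULL`.
#' @export
write_feature_report <- function(importance = NULL, ablation = NULL,
                                 importance_path = NULL,
                                 ablation_path = NULL) {
  if (!is.null(importance) && !is.null(importance_path)) {
    utils::write.table(data.frame(feature = names(importance$weights),
                                  importance = importance$weights,
                                  rank = match(names(importance$weights),
                                               importance$ranking)),
                       importance_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(ablation) && !is.null(ablation_path)) {
    utils::write.table(ablation$curve, ablation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
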