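# mean-over-concepts similarity of every row of X (normalized space)
.instance_scores <- function(X, concepts) {
  acc <- numeric(nrow(X))
  for (k in seq_len(concepts$K)) {
    acc <- acc + .sims(X, concepts$concepts[k, ], concepts$scales)
  }
  acc / concepts$K
}

#' HRD score of a single LOH instance
#'
#' The average squared-exponential similarity of the instance to the K
#' learned concepts, `(1/K) * sum_k exp(-sum_d (s_d (x_d - t_kd))^2)`.
#' For `K = 1` this is exactly [instance_similarity()].
#'
#' @param x Feature vector (or matrix of instances), already normalized with
#'   the model's bounds.
#' @param model A `miln_model` from [miln_train()].
#' @return Score(s) in `(0, 1]`.
#' @export
instance_score <- function(x, model) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(model$concepts$concepts)) {
    stop("dimension mismatch: instance has ", ncol(x), " features, model has ",
         ncol(model$concepts$concepts))
  }
  drop(.instance_scores(x, model$concepts))
}

#' Classify a single instance score
#'
#' An instance is called HRD-driving when its score reaches the learned
#' threshold; the boundary resolves to positive.
#'
#' @param score Instance score(s) in `[0, 1]`.
#' @param threshold Decision threshold in `(0, 1)`.
#' @return `+1` or `-1` (vectorized).
#' @export
classify_instance <- function(score, threshold) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must lie in (0, 1)")
  ifelse(score >= threshold, 1L, -1L)
}

#' Score and classify one sample bag
#'
#' Scores every LOH instance of the bag against the learned concept set and
#' applies the existential rule: the sample is HRD-positive iff at least one
#' instance classifies positive. The continuous `hrd_score` (the maximum
#' per-instance score) is reported alongside the binary call so users can
#' re-threshold.
#'
#' @param bag A [miln_bag()] with raw (unnormalized) instance features.
#' @param model A `miln_model`.
#' @return A `miln_prediction` list: `sample_id`, `hrd_score`, `hrd_status`,
#'   `instance_scores`, `instance_calls`.
#' @export
classify_bag <- function(bag, model) {
  if (nrow(bag$instances) < 1L) stop("empty bag")
  X <- apply_minmax(bag$instances, model$bounds)
  sc <- .instance_scores(X, model$concepts)
  calls <- classify_instance(sc, model$threshold)
  structure(list(sample_id = bag$sample_id,
                 hrd_score = max(sc),
                 hrd_status = if (any(calls > 0)) 1L else -1L,
                 instance_scores = sc,
                 instance_calls = calls),
            class = "miln_prediction")
}

#' @export
print.miln_prediction <- function(x, ...) {
  cat(sprintf("<miln_prediction> %s: hrd_score %.4f, status %+d (%d/%d instances positive)\n",
              x$sample_id, x$hrd_score, x$hrd_status,
              sum(x$instance_calls > 0), length(x$instance_calls)))
  invisible(x)
}

#' Predict HRD status for a list of bags
#'
#' @param object A `miln_model`.
#' @param bags List of bags with raw instance features.
#' @param ... Unused.
#' @return A `data.frame` with columns `sample_id`, `hrd_score`,
#'   `hrd_status`.
#' @export
predict.miln_model <- function(object, bags, ...) {
  preds <- lapply(bags, classify_bag, model = object)
  data.frame(sample_id = vapply(preds, `[[`, "", "sample_id"),
             hrd_score = vapply(preds, `[[`, 0, "hrd_score"),
             hrd_status = vapply(preds, `[[`, 0L, "hrd_status"))
}

#' Write sample predictions as TSV
#'
#' Three columns, `sample_id<TAB>hrd_score<TAB>hrd_status`. A comment line
#' records that `hrd_score` is the maximum per-instance concept-proximity
#' score.
#'
#' @param predictions Data frame from [predict.miln_model()].
#' @param path Output path.
#' @param instance_detail Optional path; when given, also writes a
#'   per-instance TSV (`sample_id`, `seg`, `score`, `call`) for auditing
#'   which segments drove a positive call. Requires `bags` and `model`.
#' @param bags,model Needed only for `instance_detail`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, instance_detail = NULL,
                              bags = NULL, model = NULL) {
  con <- file(path, "w")
  writeLines("# hrd_score = max per-instance score (mean concept proximity)",
             con)
  utils::write.table(predictions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  if (!is.null(instance_detail)) {
    stopifnot(!is.null(bags), !is.null(model))
    rows <- do.call(rbind, lapply(bags, function(b) {
      p <- classify_bag(b, model)
      data.frame(sample_id = b$sample_id,
                 seg = seq_len(nrow(b$instances)),
                 score = p$instance_scores, call = p$instance_calls)
    }))
    utils::write.table(rows, instance_detail, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
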