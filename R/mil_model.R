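#' Squared-exponential instance-to-concept similarity
#'
#' The probability that instance `x` realizes the target concept `t`:
#' `exp(-sum_d (s_d * (x_d - t_d))^2)`, a weighted-Euclidean
#' squared-exponential affinity. Equals 1 iff `x == t` and decreases
#' strictly in every coordinate-wise distance.
#'
#' @param x Instance feature vector.
#' @param t Concept point, same length.
#' @param s Per-feature weights, strictly positive; default all 1.
#' @return A probability in `(0, 1]`.
#' @export
instance_similarity <- function(x, t, s = rep(1, length(x))) {
  if (length(x) != length(t) || length(t) != length(s)) {
    stop("dimension mismatch between instance, concept and scales")
  }
  if (any(s <= 0)) stop("scales must be strictly positive")
  exp(-sum((s * (x - t))^2))
}

# vectorized similarity of all rows of X to concept t
.sims <- function(X, t, s) {
  D <- sweep(X, 2, t, "-")
  if (!all(s == 1)) D <- sweep(D, 2, s, "*")
  exp(-rowSums(D * D))
}

#' Diverse-density likelihood of one labeled bag
#'
#' Most-likely-cause form: a positive bag is as likely as its best-matching
#' instance, `max_j Pr(t | B_ij)`; a negative bag contributes the complement
#' `1 - max_j Pr(t | B_ij)`.
#'
#' @param bag A labeled [miln_bag()].
#' @param t Concept point.
#' @param s Per-feature weights (default 1).
#' @return A probability in `[0, 1]`.
#' @export
bag_likelihood <- function(bag, t, s = rep(1, length(t))) {
  if (is.null(bag$label)) stop("bag '", bag$sample_id, "' is unlabeled")
  if (ncol(bag$instances) != length(t)) stop("dimension mismatch")
  m <- max(.sims(bag$instances, t, s))
  if (bag$label > 0) m else 1 - m
}

#' Construct a concept set
#'
#' The learned "LOHs cluster": `K` target concept points in feature space
#' plus one shared vector of per-feature weights.
#'
#' @param concepts Numeric matrix, one row per concept (a vector is taken as
#'   a single concept).
#' @param scales Per-feature weights, strictly positive; default all 1.
#' @return A `miln_concepts` object.
#' @export
miln_concepts <- function(concepts, scales = NULL) {
  if (is.null(dim(concepts))) concepts <- matrix(concepts, nrow = 1L)
  concepts <- as.matrix(concepts)
  if (nrow(concepts) < 1L) stop("need at least one concept")
  if (is.null(scales)) scales <- rep(1, ncol(concepts))
  if (length(scales) != ncol(concepts)) stop("scales dimension mismatch")
  if (any(scales <= 0)) stop("scales must be strictly positive")
  structure(list(concepts = concepts, scales = as.numeric(scales),
                 K = nrow(concepts)),
            class = "miln_concepts")
}

#' @export
print.miln_concepts <- function(x, ...) {
  cat(sprintf("<miln_concepts> K = %d, %d features\n", x$K, ncol(x$concepts)))
  print(round(x$concepts, 4))
  invisible(x)
}

#' Negative-log diverse density of a concept set
#'
#' The multi-target objective: the per-concept negative log bag likelihoods,
#' summed over bags and averaged over the `K` concepts,
#' `(1/K) * sum_k sum_i -log Pr(l_i | t_k, B_i)`. Lower is better; log
#' arguments are floored at `eps` so a single violated bag cannot produce an
#' infinite objective.
#'
#' @param concepts A [miln_concepts()] object.
#' @param bags List of labeled bags.
#' @param eps Floor inside logs (default 1e-12).
#' @return A non-negative scalar.
#' @export
nnldd <- function(concepts, bags, eps = 1e-12) {
  s <- concepts$scales
  tot <- 0
  for (k in seq_len(concepts$K)) {
    lik <- vapply(bags, bag_likelihood, 0, t = concepts$concepts[k, ], s = s)
    tot <- tot + sum(-log(pmax(lik, eps)))
  }
  tot / concepts$K
}

#' E-step: select one representative instance per bag per concept
#'
#' For each concept `t_k` and each bag, picks the instance with the highest
#' similarity to `t_k` (ties broken toward the lowest index) and records its
#' probability `p_k*`. Representatives with `p_k* > pro` are marked reliable
#' candidate target LOHs.
#'
#' @param concepts A [miln_concepts()] object.
#' @param bags List of bags.
#' @param pro Reliability threshold in `(0, 1)`, default 0.9.
#' @return A `miln_reps` object with `K x n` matrices `index`, `prob` and
#'   `reliable`.
#' @export
e_step <- function(concepts, bags, pro = 0.9) {
  if (!(pro > 0 && pro < 1)) stop("pro must lie in (0, 1)")
  K <- concepts$K
  n <- length(bags)
  idx <- prob <- matrix(0, K, n)
  for (k in seq_len(K)) {
    tk <- concepts$concepts[k, ]
    for (i in seq_len(n)) {
      sims <- .sims(bags[[i]]$instances, tk, concepts$scales)
      j <- which.max(sims)           # which.max = lowest index on ties
      idx[k, i] <- j
      prob[k, i] <- sims[j]
    }
  }
  structure(list(index = idx, prob = prob, reliable = prob > pro,
                 pro = pro, K = K, n_bags = n),
            class = "miln_reps")
}

# negative log DD of one concept on a reduced (one instance per bag) set
.nldd_reduced <- function(t, X, pos, s, eps) {
  D <- sweep(X, 2, t, "-")
  if (!all(s == 1)) D <- sweep(D, 2, s, "*")
  d2 <- rowSums(D * D)
  sum(d2[pos]) + sum(-log(pmax(1 - exp(-d2[!pos]), eps)))
}

.nldd_reduced_grad <- function(t, X, pos, s, eps) {
  D <- sweep(X, 2, t, "-")             # x_i - t
  s2 <- s * s
  d2 <- rowSums(sweep(D * D, 2, s2, "*"))
  # d(d2)/dt = -2 s^2 (x - t); negative-bag factor e^-d2 / (1 - e^-d2)
  w <- numeric(nrow(X))
  w[pos] <- 1
  e <- exp(-d2[!pos])
  w[!pos] <- -e / pmax(1 - e, eps)
  -2 * colSums(sweep(D * w, 2, s2, "*"))
}

# the reduced dataset a concept is optimized on: the representatives that
# are reliable candidates (p_k* > Pro), from positive and negative bags
# alike. Far-away negative representatives carry no information about where
# inside its cluster the concept belongs (negatives still act through
# candidate ranking, restart selection and thresholding, all of which use
# the full NNLDD); a negative representative inside the reliability radius
# is a concept-like LOH in an HRD-negative sample and repels strongly.
# If no positive representative is reliable the step falls back to the
# classical unfiltered reduced set so the concept can still move.
.reduced_set <- function(k, reps, bags, labs) {
  keep <- reps$reliable[k, ]
  if (!any(keep & labs > 0)) keep <- rep(TRUE, length(labs))
  X <- do.call(rbind, lapply(which(keep), function(i) {
    bags[[i]]$instances[reps$index[k, i], , drop = FALSE]
  }))
  list(X = X, pos = labs[keep] > 0)
}

#' M-step: re-optimize each concept on its reduced dataset
#'
#' Each concept is refit by quasi-Newton (L-BFGS-B) minimization of its
#' negative log diverse density over a reduced dataset of one representative
#' instance per bag, with box constraints `[-0.5, 1.5]` in normalized
#' feature units. This is where the reliability threshold bites: only
#' representatives that are reliable candidate target LOHs (`p_k* > Pro`)
#' enter a concept's reduced set, so each concept is refined on the samples
#' it actually explains instead of being dragged toward the centroid of all
#' positive bags or pushed off its cluster by the accumulated repulsion of
#' far-away negative bags (whose influence is exerted through candidate
#' ranking, restart selection and threshold learning instead). A negative
#' bag whose representative does fall inside the reliability radius repels
#' strongly. When no positive representative is reliable the step falls back
#' to the classical unfiltered reduced set.
#' Equivalent in direction to gradient ascent on the diverse density, but
#' numerically safer. If the optimizer fails, the input concept is kept and
#' a warning is raised; a concept is never replaced by one with a worse
#' reduced objective.
#'
#' @param concepts A [miln_concepts()] object.
#' @param reps Representatives from [e_step()] on the same concepts/bags.
#' @param bags List of labeled bags.
#' @param control A [miln_control()] list.
#' @return A new `miln_concepts` object.
#' @export
m_step <- function(concepts, reps, bags, control = miln_control()) {
  labs <- .bag_labels(bags)
  s <- concepts$scales
  eps <- control$eps
  out <- concepts$concepts
  for (k in seq_len(concepts$K)) {
    red <- .reduced_set(k, reps, bags, labs)
    X <- red$X
    pos <- red$pos
    t0 <- concepts$concepts[k, ]
    fit <- tryCatch(
      stats::optim(t0, .nldd_reduced, .nldd_reduced_grad,
                   X = X, pos = pos, s = s, eps = eps,
                   method = "L-BFGS-B", lower = -0.5, upper = 1.5,
                   control = list(maxit = 200L)),
      error = function(e) {
        warning("M-step optimizer failed for concept ", k, ": ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(fit) &&
        fit$value <= .nldd_reduced(t0, X, pos, s, eps) + 1e-10) {
      out[k, ] <- fit$par
    }
  }
  sc <- s
  if (isTRUE(control$optimize_scales)) {
    # shared-scale update: minimize the summed reduced objective over log s
    red_k <- lapply(seq_len(concepts$K), .reduced_set, reps = reps,
                    bags = bags, labs = labs)
    obj <- function(ls) {
      sv <- exp(ls)
      sum(vapply(seq_len(concepts$K), function(k) {
        .nldd_reduced(out[k, ], red_k[[k]]$X, red_k[[k]]$pos, sv, eps)
      }, 0))
    }
    fit <- tryCatch(stats::optim(log(s), obj, method = "L-BFGS-B",
                                 lower = log(1e-3), upper = log(1e3),
                                 control = list(maxit = 100L)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$value <= obj(log(s)) + 1e-10) sc <- exp(fit$par)
  }
  miln_concepts(out, sc)
}

#' Training control parameters
#'
#' @param tol Convergence tolerance on `max_k ||t_k - t_k'||_inf` in
#'   normalized feature units (default 1e-4).
#' @param max_iter Maximum EM iterations (default 100).
#' @param restarts Number of initialization restarts; the restart with the
#'   lowest final objective wins (default 5).
#' @param eps Floor inside logarithms (default 1e-12).
#' @param min_init_dist Minimum pairwise L2 distance between the K seed
#'   concepts at initialization (default 0.2).
#' @param optimize_scales Jointly optimize the shared per-feature weights
#'   `s_d` in the M-step (classical EMDD behaviour); off by default.
#' @param seed Integer seed recorded in the training log. Training itself is
#'   fully deterministic (initialization is a ranked, tie-broken search, not
#'   a random draw), so the seed only matters for downstream resampling.
#' @return A list of class `miln_control`.
#' @export
miln_control <- function(tol = 1e-4, max_iter = 100L, restarts = 5L,
                         eps = 1e-12, min_init_dist = 0.2,
                         optimize_scales = FALSE, seed = 1L) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts), eps = eps,
                 min_init_dist = min_init_dist,
                 optimize_scales = optimize_scales,
                 seed = as.integer(seed)),
            class = "miln_control")
}

# rank every positive-bag instance as a candidate concept by its one-concept
# negative log diverse density over all bags; order-invariant tie-breaking
# (lexicographic on the candidate's coordinates).
.rank_candidates <- function(bags, s, eps) {
  labs <- .bag_labels(bags)
  cand <- do.call(rbind, lapply(bags[labs > 0], `[[`, "instances"))
  cand <- unique(cand)
  st <- .stack_bags(bags)
  X <- st$X
  if (!all(s == 1)) {
    Xs <- sweep(X, 2, s, "*")
    Cs <- sweep(cand, 2, s, "*")
  } else {
    Xs <- X; Cs <- cand
  }
  # squared distances candidates x instances via one crossproduct
  d2 <- outer(rowSums(Cs * Cs), rowSums(Xs * Xs), "+") - 2 * tcrossprod(Cs, Xs)
  d2[d2 < 0] <- 0
  sims <- exp(-d2)
  nldd <- numeric(nrow(cand))
  for (i in seq_along(bags)) {
    mx <- apply(sims[, st$bag == i, drop = FALSE], 1, max)
    lik <- if (labs[i] > 0) mx else 1 - mx
    nldd <- nldd - log(pmax(lik, eps))
  }
  ord <- do.call(order, c(list(nldd), lapply(seq_len(ncol(cand)),
                                             function(j) cand[, j])))
  # per-bag best similarity of every candidate, kept for coverage seeding
  M <- matrix(0, nrow(cand), length(bags))
  for (i in seq_along(bags)) {
    M[, i] <- apply(sims[, st$bag == i, drop = FALSE], 1, max)
  }
  list(candidates = cand[ord, , drop = FALSE], nldd = nldd[ord],
       bagsim = M[ord, , drop = FALSE], labels = labs)
}

# coverage-greedy seed selection: the first seed is the candidate with the
# best overall one-concept NLDD (offset shifts this choice across restarts);
# each later seed is the candidate that best explains the positive bags not
# yet covered (no reliable representative under the seeds so far), subject
# to a minimum spacing so the K seeds are distinct hotspots. Spacing is
# relaxed if it cannot be met.
.seed_concepts <- function(ranked, K, offset, min_dist, pro, eps) {
  cand <- ranked$candidates
  n <- nrow(cand)
  pos <- ranked$labels > 0
  sel <- ((offset - 1L) %% n) + 1L
  while (length(sel) < K) {
    covered <- pos & (apply(ranked$bagsim[sel, , drop = FALSE], 2, max) > pro)
    tgt <- (pos & !covered)
    score <- if (any(tgt)) {
      -rowSums(log(pmax(ranked$bagsim[, tgt, drop = FALSE], eps))) +
        -rowSums(log(pmax(1 - ranked$bagsim[, !pos, drop = FALSE], eps)))
    } else {
      ranked$nldd
    }
    spaced <- vapply(seq_len(n), function(i) {
      !(i %in% sel) && all(vapply(sel, function(j) {
        sqrt(sum((cand[i, ] - cand[j, ])^2)) >= min_dist
      }, TRUE))
    }, TRUE)
    pool <- if (any(spaced)) which(spaced) else setdiff(seq_len(n), sel)
    if (!length(pool)) pool <- seq_len(n)   # fewer unique candidates than K
    sel <- c(sel, pool[which.min(score[pool])])
  }
  cand[sel, , drop = FALSE]
}

#' Train an HRD multi-instance concept model (modified EMDD)
#'
#' Learns `K` target concept points from labeled bags by alternating an
#' E-step (pick the most concept-like instance of every bag) and an M-step
#' (re-optimize each concept on its reduced dataset), from several ranked
#' diverse-density initializations; the restart with the lowest final
#' objective wins. Min-max normalization bounds are fitted on the training
#' bags (unless supplied) and frozen into the model; the decision threshold
#' is chosen by sweeping the training-bag HRD scores and maximizing training
#' F1 (ties resolved toward the higher threshold).
#'
#' @param bags List of labeled bags (both classes present).
#' @param K Number of target concepts (default 3).
#' @param pro Reliable-representative threshold in `(0,1)` (default 0.9).
#' @param control A [miln_control()] list.
#' @param feature_names Optional feature names (default: instance column
#'   names, else `f1..fm`).
#' @param bounds Optional pre-fitted [fit_minmax()] bounds; fitted on the
#'   training instances when `NULL`.
#' @return A `miln_model` with elements `concepts`, `threshold`, `pro`,
#'   `bounds`, `feature_names` and `training_log`.
#' @export
miln_train <- function(bags, K = 3L, pro = 0.9, control = miln_control(),
                       feature_names = NULL, bounds = NULL) {
  labs <- .bag_labels(bags)
  if (!any(labs > 0) || !any(labs < 0)) {
    stop("training requires at least one positive and one negative bag")
  }
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  n_pos_inst <- sum(vapply(bags[labs > 0],
                           function(b) nrow(b$instances), 1L))
  if (K > n_pos_inst) {
    stop("K (", K, ") exceeds the total number of positive-bag instances (",
         n_pos_inst, ")")
  }
  if (!(pro > 0 && pro < 1)) stop("pro must lie in (0, 1)")
  m <- ncol(bags[[1]]$instances)
  if (is.null(feature_names)) {
    feature_names <- colnames(bags[[1]]$instances)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(m))
  }
  if (is.null(bounds)) {
    bounds <- fit_minmax(lapply(bags, `[[`, "instances"))
  }
  nb <- .normalize_bags(bags, bounds)
  s <- rep(1, m)
  ranked <- .rank_candidates(nb, s, control$eps)
  n_cand <- nrow(ranked$candidates)
  best <- NULL
  iters <- integer(0)
  for (r in seq_len(max(1L, control$restarts))) {
    offset <- ((r - 1L) %% n_cand) + 1L
    seeds <- .seed_concepts(ranked, K, offset, control$min_init_dist,
                            pro, control$eps)
    cs <- miln_concepts(seeds, s)
    it <- 0L
    repeat {
      it <- it + 1L
      reps <- e_step(cs, nb, pro)
      new <- m_step(cs, reps, nb, control)
      delta <- max(abs(new$concepts - cs$concepts))
      cs <- new
      if (delta < control$tol || it >= control$max_iter) break
    }
    obj <- nnldd(cs, nb, control$eps)
    iters <- c(iters, it)
    if (is.null(best) || obj < best$obj - 1e-12) {
      best <- list(cs = cs, obj = obj, restart = r)
    }
  }
  cs <- best$cs
  # per-concept product of bag likelihoods (diagnostic for the reliability
  # rule; the product over many bags is almost always << pro)
  dd_prod <- vapply(seq_len(K), function(k) {
    prod(vapply(nb, bag_likelihood, 0, t = cs$concepts[k, ], s = cs$scales))
  }, 0)
  scores <- vapply(nb, function(b) max(.instance_scores(b$instances, cs)), 0)
  threshold <- .sweep_threshold(scores, labs)
  structure(list(
    concepts = cs,
    threshold = threshold,
    pro = pro,
    bounds = bounds,
    feature_names = feature_names,
    training_log = list(iterations = iters, nnldd = best$obj,
                        best_restart = best$restart,
                        restarts = control$restarts,
                        dd_product = dd_prod,
                        n_bags = length(bags), K = K,
                        seed = control$seed)),
    class = "miln_model")
}

# pick the score threshold maximizing training F1 (ties toward the higher,
# more conservative cut), then place the decision boundary at the midpoint
# between that score and the largest training score below it: a cut sitting
# exactly on the lowest positive training score has zero margin and turns
# borderline test positives into false negatives
.sweep_threshold <- function(scores, labs) {
  cand <- sort(unique(scores))
  best_f1 <- -1
  best_thr <- cand[length(cand)]
  for (thr in cand) {
    pred <- ifelse(scores >= thr, 1L, -1L)
    f1 <- unname(hrd_metrics(confusion_counts(labs, pred))["f1"])
    if (f1 > best_f1 || (f1 == best_f1 && thr > best_thr)) {
      best_f1 <- f1
      best_thr <- thr
    }
  }
  below <- cand[cand < best_thr]
  if (length(below)) best_thr <- (best_thr + max(below)) / 2
  min(max(best_thr, 1e-9), 1 - 1e-9)
}

#' @export
print.miln_model <- function(x, ...) {
  cat(sprintf("<miln_model> K = %d concepts, %d features, threshold %.4f, pro %.2f\n",
              x$concepts$K, length(x$feature_names), x$threshold, x$pro))
  cat(sprintf("  final objective (NNLDD): %.4f after %s EM iterations\n",
              x$training_log$nnldd,
              paste(x$training_log$iterations, collapse = "/")))
  invisible(x)
}

#' Learned concept locations
#'
#' @param model A `miln_model`.
#' @param scale `"normalized"` (training feature space, default) or `"raw"`
#'   (mapped back through the stored min-max bounds).
#' @return A `K x m` matrix of concept coordinates.
#' @export
concept_locations <- function(model, scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  C <- model$concepts$concepts
  colnames(C) <- model$feature_names
  if (scale == "raw") {
    rng <- model$bounds$max - model$bounds$min
    C <- sweep(sweep(C, 2, rng, "*"), 2, model$bounds$min, "+")
  }
  C
}
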