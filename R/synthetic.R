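#' Synthetic cohort configuration
#'
#' Describes the generated world: a balanced cohort of tumor samples (bags)
#' whose positive bags carry a few "signal" LOH segments drawn around
#' `K_true` planted target concepts in normalized 9-D feature space, on top
#' of uniform background segments present in every bag. Defaults mirror a
#' small clinical panel cohort: 28 positive and 28 negative samples with
#' 3-30 segments each.
#'
#' @param n_pos,n_neg Numbers of positive and negative bags (defaults 28/28).
#' @param K_true Number of planted concepts (default 3).
#' @param concept_locations `"random"` (drawn from `seed`: each coordinate
#'   sits in an extreme tail of its normalized range, uniform on
#'   `[0.05, 0.2]` or `[0.8, 0.95]` with a random side per dimension, and
#'   concepts must differ in side on at least 3 dimensions) or a
#'   `K_true x 9` matrix in `[0,1]`. Extremal placement mirrors what
#'   HRD-driving segments look like against typical background segments
#'   (e.g. lost lesser copy number, strong allelic imbalance) and is the
#'   regime in which background instances are genuinely unlikely under
#'   every concept.
#' @param concept_spread Within-concept standard deviation (default 0.03).
#' @param instances_per_bag Inclusive range of segments per bag
#'   (default `c(3, 30)`).
#' @param signal_per_bag Inclusive range of signal segments per positive bag
#'   (default `c(1, 3)`).
#' @param label_noise Fraction of bag labels flipped after generation
#'   (default 0).
#' @param seed Integer seed; everything is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pos = 28L, n_neg = 28L, K_true = 3L,
                       concept_locations = "random", concept_spread = 0.03,
                       instances_per_bag = c(3L, 30L),
                       signal_per_bag = c(1L, 3L),
                       label_noise = 0, seed = 7L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, K_true >= 1L, concept_spread > 0,
            length(instances_per_bag) == 2L,
            instances_per_bag[1] >= 1L,
            instances_per_bag[1] <= instances_per_bag[2],
            signal_per_bag[1] >= 1L,
            signal_per_bag[1] <= signal_per_bag[2],
            label_noise >= 0, label_noise <= 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 K_true = as.integer(K_true),
                 concept_locations = concept_locations,
                 concept_spread = concept_spread,
                 instances_per_bag = as.integer(instances_per_bag),
                 signal_per_bag = as.integer(signal_per_bag),
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "sim_config")
}

# K concept points with every coordinate in an extreme tail of [0,1];
# concepts must differ in tail side on >= 3 dimensions so they are
# distinguishable hotspots, not one smeared cluster
.random_concepts <- function(K, m = 9L) {
  sides <- matrix(NA, 0L, m)
  tries <- 0L
  while (nrow(sides) < K) {
    s <- stats::rbinom(m, 1L, 0.5)
    tries <- tries + 1L
    ok <- nrow(sides) == 0L ||
      all(rowSums(sides != rep(s, each = nrow(sides))) >= 3L)
    if (ok || tries > 5000L) sides <- rbind(sides, s)
  }
  lo <- matrix(stats::runif(K * m, 0.05, 0.20), K, m)
  hi <- matrix(stats::runif(K * m, 0.80, 0.95), K, m)
  ifelse(sides == 1L, hi, lo)
}

#' Simulate labeled bags with planted target concepts
#'
#' Positive bags contain background segments (uniform on `[0,1]^9`) plus
#' 1-3 signal segments drawn `Normal(concept, spread)` (clipped to `[0,1]`)
#' around randomly chosen planted concepts; negative bags contain background
#' only. Optionally flips a fraction of bag labels.
#'
#' @param config A [sim_config()].
#' @return A list with `bags` (list of [miln_bag()] with feature columns
#'   named per [miln_features()]) and `truth` (planted `concepts`, pre-noise
#'   `labels`, per-instance `provenance` flags and the `config`).
#' @export
simulate_bags <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- 9L
  C <- if (identical(config$concept_locations, "random")) {
    .random_concepts(config$K_true, m)
  } else {
    as.matrix(config$concept_locations)
  }
  if (nrow(C) != config$K_true || ncol(C) != m) {
    stop("concept_locations must be a K_true x 9 matrix")
  }
  n <- config$n_pos + config$n_neg
  labels <- c(rep(1L, config$n_pos), rep(-1L, config$n_neg))
  ids <- sprintf("SIM%03d", seq_len(n))
  bags <- vector("list", n)
  provenance <- vector("list", n)
  rng <- config$instances_per_bag
  srng <- config$signal_per_bag
  for (i in seq_len(n)) {
    ni <- if (rng[1] == rng[2]) rng[1] else
      sample(seq.int(rng[1], rng[2]), 1L)
    if (labels[i] > 0) {
      si <- if (srng[1] == srng[2]) srng[1] else
        sample(seq.int(srng[1], srng[2]), 1L)
      si <- min(si, ni)
      which_c <- sample.int(config$K_true, si, replace = TRUE)
      sig <- C[which_c, , drop = FALSE] +
        matrix(stats::rnorm(si * m, 0, config$concept_spread), si, m)
      sig <- pmin(pmax(sig, 0), 1)
      bg <- matrix(stats::runif((ni - si) * m), ni - si, m)
      X <- rbind(sig, bg)
      prov <- c(rep(TRUE, si), rep(FALSE, ni - si))
      ord <- sample.int(ni)              # hide signal position
      X <- X[ord, , drop = FALSE]
      prov <- prov[ord]
    } else {
      X <- matrix(stats::runif(ni * m), ni, m)
      prov <- rep(FALSE, ni)
    }
    colnames(X) <- miln_features()
    bags[[i]] <- miln_bag(ids[i], X, labels[i])
    provenance[[i]] <- prov
  }
  labels_prenoise <- labels
  if (config$label_noise > 0) {
    flip <- stats::runif(n) < config$label_noise
    for (i in which(flip)) bags[[i]]$label <- -bags[[i]]$label
    labels <- vapply(bags, `[[`, 1L, "label")
  }
  names(provenance) <- ids
  list(bags = bags,
       truth = list(concepts = C, labels = labels_prenoise,
                    labels_observed = labels, provenance = provenance,
                    config = config))
}

#' Plausible raw ranges for the nine LOH features
#'
#' The affine maps used by [bags_to_cncf()] to turn normalized features into
#' FACETS-like raw values. Integer-valued columns (`nhet`, `start`, `end`)
#' are rounded on write, which bounds the normalized round-trip error by
#' `0.5 / (max - min)` for those columns.
#'
#' @return A `data.frame` with `feature`, `min`, `max`, `integer`.
#' @export
raw_feature_ranges <- function() {
  data.frame(
    feature = miln_features(),
    min = c(0, -3, 0, 0, 1, 1.1e8, 0, 2, 0),
    max = c(5000, 3, 9, 9, 1e8, 2.4e8, 1, 8, 2),
    integer = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
}

#' Write bags as FACETS-dialect cncf tables
#'
#' Inverse-maps each bag's normalized 9-D features to plausible raw ranges
#' (heterozygous-SNP counts as integers, start < end base-pair coordinates,
#' `tcn_em >= lcn_em`, `cf_em` in `[0,1]`), fills the non-feature columns
#' deterministically, and writes one `<sample>_cncf.tsv` per bag plus a
#' `labels.tsv` and, when truth is given, a `truth.json`.
#'
#' @param bags List of bags with normalized 9-feature instances.
#' @param truth Optional truth list from [simulate_bags()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of cncf file paths.
#' @export
bags_to_cncf <- function(bags, truth = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rr <- raw_feature_ranges()
  paths <- character(length(bags))
  for (i in seq_along(bags)) {
    b <- bags[[i]]
    U <- b$instances[, miln_features(), drop = FALSE]
    raw <- sweep(sweep(U, 2, rr$max - rr$min, "*"), 2, rr$min, "+")
    raw[, rr$integer] <- round(raw[, rr$integer])
    ni <- nrow(raw)
    seg <- data.frame(chrom = 1 + (seq_len(ni) - 1L) %% 22L,
                      seg = seq_len(ni),
                      num_mark = raw[, "nhet"] + 37,
                      nhet = raw[, "nhet"],
                      cnlr_median = raw[, "cnlr_median"],
                      segclust = seq_len(ni),
                      cnlr_median_clust = raw[, "cnlr_median"],
                      start = raw[, "start"],
                      end = raw[, "end"],
                      mafR = raw[, "mafR"],
                      mafR_clust = raw[, "mafR_clust"],
                      cf_em = raw[, "cf_em"],
                      tcn_em = raw[, "tcn_em"],
                      lcn_em = raw[, "lcn_em"])
    paths[i] <- file.path(out_dir, paste0(b$sample_id, "_cncf.tsv"))
    write_cncf(seg, paths[i])
  }
  labeled <- !vapply(bags, function(b) is.null(b$label), TRUE)
  if (any(labeled)) {
    labs <- vapply(bags[labeled], `[[`, 1L, "label")
    names(labs) <- vapply(bags[labeled], `[[`, "", "sample_id")
    write_labels(labs, file.path(out_dir, "labels.tsv"))
  }
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(concepts = truth$concepts,
           labels = as.list(stats::setNames(truth$labels,
                                            vapply(bags, `[[`, "",
                                                   "sample_id"))),
           spread = truth$config$concept_spread,
           seed = truth$config$seed),
      file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(paths)
}

#' Load a simulated (or real) cohort directory into bags
#'
#' Reads every `*_cncf.tsv` in a directory plus its `labels.tsv`, extracts
#' the default nine features and assembles labeled bags. Raw features are
#' NOT normalized here; [miln_train()] fits and freezes its own bounds.
#'
#' @param dir Directory containing `<sample>_cncf.tsv` files and optionally
#'   `labels.tsv`.
#' @param feature_names Feature columns to extract (default
#'   [miln_features()]).
#' @return List of bags.
#' @export
read_cohort <- function(dir, feature_names = miln_features()) {
  files <- sort(list.files(dir, pattern = "_cncf\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no *_cncf.tsv files in ", dir)
  ids <- sub("_cncf\\.tsv$", "", basename(files))
  labels_path <- file.path(dir, "labels.tsv")
  labels <- if (file.exists(labels_path)) read_labels(labels_path)
  vecs <- stats::setNames(lapply(seq_along(files), function(i) {
    extract_features(read_cncf(files[i], ids[i]), feature_names)
  }), ids)
  assemble_bags(vecs, labels)
}

#' Greedy matching error between planted and learned concepts
#'
#' Matches each planted concept to its nearest unmatched learned concept
#' (greedy on L-infinity distance, smallest distance first) and returns the
#' per-planted-concept distances.
#'
#' @param planted,learned Matrices of concept coordinates in the same space.
#' @return Numeric vector of L-infinity matching distances, one per planted
#'   concept.
#' @export
match_concepts <- function(planted, learned) {
  planted <- as.matrix(planted)
  learned <- as.matrix(learned)
  D <- matrix(Inf, nrow(planted), nrow(learned))
  for (i in seq_len(nrow(planted))) {
    for (j in seq_len(nrow(learned))) {
      D[i, j] <- max(abs(planted[i, ] - learned[j, ]))
    }
  }
  out <- rep(NA_real_, nrow(planted))
  for (step in seq_len(min(dim(D)))) {
    ij <- arrayInd(which.min(D), dim(D))
    out[ij[1]] <- D[ij[1], ij[2]]
    D[ij[1], ] <- Inf
    D[, ij[2]] <- Inf
  }
  out
}
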