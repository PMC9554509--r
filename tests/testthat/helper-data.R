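# Fixtures are built in code; nothing is stored on disk.

identity_bounds <- function(m) {
  structure(list(min = rep(0, m), max = rep(1, m)), class = "miln_bounds")
}

# tiny 2-D world: positive cluster at (0.5, 0.5), negatives placed
# symmetrically around it so the diverse-density maximum sits exactly on
# the cluster (repulsions cancel)
toy_bags_symmetric <- function() {
  list(
    miln_bag("P1", rbind(c(0.50, 0.50), c(0.05, 0.95)), 1L),
    miln_bag("P2", rbind(c(0.52, 0.48), c(0.95, 0.95), c(0.10, 0.05)), 1L),
    miln_bag("N1", rbind(c(0.10, 0.10), c(0.90, 0.90)), -1L),
    miln_bag("N2", rbind(c(0.10, 0.90), c(0.90, 0.10)), -1L))
}

# asymmetric variant used for likelihood/e-step arithmetic
toy_bags_basic <- function() {
  list(
    miln_bag("P1", rbind(c(0.20, 0.80), c(0.90, 0.10)), 1L),
    miln_bag("P2", rbind(c(0.22, 0.78), c(0.55, 0.45)), 1L),
    miln_bag("N1", rbind(c(0.90, 0.15), c(0.60, 0.40)), -1L))
}

# brute-force K=1 diverse density over a lattice on [0,1]^2
grid_dd <- function(bags, step = 0.02) {
  g <- seq(0, 1, by = step)
  best <- list(dd = -Inf, t = NULL)
  for (x in g) for (y in g) {
    t <- c(x, y)
    dd <- prod(vapply(bags, bag_likelihood, 0, t = t))
    if (dd > best$dd) best <- list(dd = dd, t = t)
  }
  best
}

# a full 14-column cncf data frame with n synthetic-but-plausible rows
make_cncf_df <- function(n = 3) {
  data.frame(
    chrom = seq_len(n), seg = seq_len(n),
    num_mark = 10L * seq_len(n), nhet = 5L * seq_len(n),
    cnlr_median = round(seq(-0.5, 0.5, length.out = n), 3),
    segclust = seq_len(n),
    cnlr_median_clust = round(seq(-0.4, 0.4, length.out = n), 3),
    start = c(1e6, 2e6, 3e6)[seq_len(n)],
    end = c(1.5e6, 2.5e6, 3.5e6)[seq_len(n)],
    mafR = round(seq(0.1, 2, length.out = n), 3),
    mafR_clust = round(seq(0.2, 1.8, length.out = n), 3),
    cf_em = round(seq(0.3, 0.9, length.out = n), 3),
    tcn_em = c(2, 3, 4)[seq_len(n)],
    lcn_em = c(0, 1, 2)[seq_len(n)])
}

write_cncf_fixture <- function(n = 3, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "S1_cncf.tsv")
  write_cncf(make_cncf_df(n), path)
  path
}

# bags where only the first feature separates the classes
single_feature_bags <- function(n_pos = 8, n_neg = 8, m = 4, seed = 1) {
  set.seed(seed)
  bags <- list()
  for (i in seq_len(n_pos)) {
    ni <- sample(3:6, 1)
    X <- matrix(runif(ni * m), ni, m)
    X[sample(ni, 1), 1] <- runif(1, 0.9, 1)   # one high-signal instance
    X[-which.max(X[, 1]), 1] <- runif(ni - 1, 0, 0.5)
    bags[[length(bags) + 1]] <- miln_bag(paste0("P", i), X, 1L)
  }
  for (i in seq_len(n_neg)) {
    ni <- sample(3:6, 1)
    X <- matrix(runif(ni * m), ni, m)
    X[, 1] <- runif(ni, 0, 0.5)
    bags[[length(bags) + 1]] <- miln_bag(paste0("N", i), X, -1L)
  }
  bags
}

# small planted-concept cohort (scaled-down synthetic defaults)
small_sim <- function(seed = 7, n_pos = 10, n_neg = 10) {
  simulate_bags(sim_config(n_pos = n_pos, n_neg = n_neg,
                           instances_per_bag = c(3L, 10L), seed = seed))
}

fast_ctrl <- function(...) miln_control(restarts = 2L, max_iter = 25L, ...)

# a zero-noise, cleanly separable world: one concept in the far corner,
# tight spread, small bags -- background cannot reach the concept's score
perfect_sim <- function(seed = 7, n_pos = 8, n_neg = 8) {
  simulate_bags(sim_config(n_pos = n_pos, n_neg = n_neg, K_true = 1L,
                           concept_locations = matrix(0.95, 1, 9),
                           concept_spread = 0.01,
                           instances_per_bag = c(3L, 6L), seed = seed))
}
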