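test_that("instance_similarity closed forms and bounds", {
  x <- c(0.2, 0.4, 0.6)
  expect_equal(instance_similarity(x, x), 1.0)
  expect_equal(instance_similarity(c(0, 0), c(1, 0)), exp(-1))
  expect_equal(instance_similarity(c(0, 0), c(1, 0), s = c(2, 1)), exp(-4))
  expect_error(instance_similarity(c(0, 0), c(1, 0, 0)), "mismatch")
  expect_error(instance_similarity(c(0, 0), c(1, 0), s = c(1, 0)), "positive")
  # bounds and monotone decrease in |x_d - t_d|
  set.seed(1)
  for (i in 1:20) {
    a <- runif(4); b <- runif(4)
    v <- instance_similarity(a, b)
    expect_true(v > 0 && v <= 1)
    worse <- b + (b - a) * 0.5          # move further away along the gap
    expect_true(instance_similarity(a, worse) <= v)
  }
})

test_that("bag_likelihood uses most-likely-cause and label complement", {
  t <- c(0.2, 0.8)
  pos <- miln_bag("p", rbind(t, c(0.9, 0.1)), 1L)
  neg <- miln_bag("n", rbind(t, c(0.9, 0.1)), -1L)
  expect_equal(bag_likelihood(pos, t), 1.0)
  expect_equal(bag_likelihood(neg, t), 0.0)
  far <- miln_bag("p2", rbind(c(1.2, 0.8), c(0.2, 1.8)), 1L)
  expect_equal(bag_likelihood(far, t), exp(-1))   # best instance at distance 1
  expect_error(bag_likelihood(miln_bag("u", rbind(t)), t), "unlabeled")
})

test_that("nnldd averages per-concept sums and floors logs", {
  t <- c(0.2, 0.8)
  bags <- list(miln_bag("p", rbind(t), 1L),
               miln_bag("n", rbind(c(10, 10)), -1L))
  expect_equal(nnldd(miln_concepts(t), bags), 0, tolerance = 1e-8)
  bags2 <- list(miln_bag("p", rbind(c(1.2, 0.8)), 1L),   # lik exp(-1)
                miln_bag("n", rbind(c(10, 10)), -1L))    # lik ~ 1
  expect_equal(nnldd(miln_concepts(t), bags2), 1.0, tolerance = 1e-8)
  # K identical concepts average to the K=1 value
  expect_equal(nnldd(miln_concepts(rbind(t, t)), bags2),
               nnldd(miln_concepts(t), bags2))
  # a violated negative bag stays finite thanks to the eps floor
  bags3 <- list(miln_bag("p", rbind(t), 1L), miln_bag("n", rbind(t), -1L))
  v <- nnldd(miln_concepts(t), bags3)
  expect_true(is.finite(v) && v >= 0)
})

test_that("e_step picks argmax representatives, flags reliability, breaks ties low", {
  t <- c(0.2, 0.8)
  b1 <- miln_bag("b1", rbind(c(0.21, 0.81), c(0.9, 0.1)), 1L)   # sims ~.9996, low
  b2 <- miln_bag("b2", rbind(c(0.6, 0.4), c(0.7, 0.3)), -1L)    # both <= pro
  tie <- miln_bag("b3", rbind(c(0.3, 0.8), c(0.1, 0.8)), 1L)    # equal distance
  reps <- e_step(miln_concepts(t), list(b1, b2, tie), pro = 0.9)
  expect_equal(reps$index[1, ], c(1L, 1L, 1L))   # tie -> lowest index
  expect_true(reps$reliable[1, 1])
  expect_false(reps$reliable[1, 2])
  expect_equal(reps$prob[1, 1],
               instance_similarity(c(0.21, 0.81), t))
  expect_true(all(reps$prob >= 0 & reps$prob <= 1))
  expect_error(e_step(miln_concepts(t), list(b1), pro = 1.2), "(0, 1)")
})

test_that("m_step: single positive bag optimum is the representative itself", {
  x <- c(0.3, 0.6)
  bags <- list(miln_bag("p", rbind(x), 1L))
  cs <- miln_concepts(c(0.5, 0.5))
  reps <- e_step(cs, bags)
  out <- m_step(cs, reps, bags)
  expect_equal(drop(out$concepts), x, tolerance = 1e-5)
})

test_that("m_step: identical positive and negative representatives leave concept fixed", {
  x <- c(0.4, 0.4)
  bags <- list(miln_bag("p", rbind(x), 1L), miln_bag("n", rbind(x), -1L))
  cs <- miln_concepts(x)          # seeded exactly on the degenerate point
  reps <- e_step(cs, bags)
  out <- m_step(cs, reps, bags)
  expect_equal(out$concepts, cs$concepts)
})

test_that("m_step never worsens the reduced objective (monotone EM)", {
  sim <- small_sim(seed = 3)
  bounds <- fit_minmax(lapply(sim$bags, `[[`, "instances"))
  nb <- hrdmiln:::.normalize_bags(sim$bags, bounds)
  labs <- vapply(nb, `[[`, 1L, "label")
  ctrl <- miln_control()
  set.seed(11)
  cs <- miln_concepts(matrix(runif(18), 2, 9))
  for (it in 1:5) {
    reps <- e_step(cs, nb, 0.9)
    new <- m_step(cs, reps, nb, ctrl)
    for (k in 1:2) {
      red <- hrdmiln:::.reduced_set(k, reps, nb, labs)
      before <- hrdmiln:::.nldd_reduced(cs$concepts[k, ], red$X, red$pos,
                                        cs$scales, ctrl$eps)
      after <- hrdmiln:::.nldd_reduced(new$concepts[k, ], red$X, red$pos,
                                       new$scales, ctrl$eps)
      expect_lte(after, before + 1e-8)
    }
    cs <- new
  }
})

test_that("K=1 training matches the exhaustive grid-search DD oracle", {
  bags <- toy_bags_symmetric()
  oracle <- grid_dd(bags, step = 0.02)
  model <- miln_train(bags, K = 1, bounds = identity_bounds(2),
                      control = fast_ctrl())
  t_hat <- drop(model$concepts$concepts)
  dd_hat <- prod(vapply(bags, bag_likelihood, 0, t = t_hat))
  expect_lt(abs(dd_hat - oracle$dd), 1e-2)
  expect_equal(t_hat, oracle$t, tolerance = 0.05)
})

test_that("training validates inputs", {
  bags <- toy_bags_symmetric()
  expect_error(miln_train(bags[1:2], K = 1), "positive and.*negative")
  expect_error(miln_train(bags, K = 0), "K must be")
  expect_error(miln_train(bags, K = 99), "exceeds")
  expect_error(miln_train(bags, K = 1, pro = 1.5), "(0, 1)")
})

test_that("training is deterministic and permutation invariant", {
  sim <- small_sim(seed = 5)
  ctrl <- fast_ctrl()
  m1 <- miln_train(sim$bags, K = 2, control = ctrl)
  m2 <- miln_train(sim$bags, K = 2, control = ctrl)
  expect_identical(m1$concepts$concepts, m2$concepts$concepts)
  expect_identical(m1$threshold, m2$threshold)

  # shuffle bag order and instance order within bags
  set.seed(99)
  shuffled <- lapply(sample(sim$bags), function(b) {
    miln_bag(b$sample_id,
             b$instances[sample(nrow(b$instances)), , drop = FALSE],
             b$label)
  })
  m3 <- miln_train(shuffled, K = 2, control = ctrl)
  expect_equal(m3$concepts$concepts, m1$concepts$concepts, tolerance = 1e-8)
  expect_equal(m3$threshold, m1$threshold, tolerance = 1e-8)
})

test_that("trained model recovers planted concepts on a small cohort", {
  sim <- small_sim(seed = 7, n_pos = 14, n_neg = 14)
  model <- miln_train(sim$bags, K = 3)
  err <- match_concepts(sim$truth$concepts, concept_locations(model, "raw"))
  expect_true(all(err < 0.1))
})

test_that("scale optimization never worsens the objective and stays positive", {
  bags <- toy_bags_symmetric()
  ctrl <- fast_ctrl(optimize_scales = TRUE)
  model <- miln_train(bags, K = 1, bounds = identity_bounds(2),
                      control = ctrl)
  expect_true(all(model$concepts$scales > 0))
  base <- miln_train(bags, K = 1, bounds = identity_bounds(2),
                     control = fast_ctrl())
  expect_lte(model$training_log$nnldd, base$training_log$nnldd + 1e-6)
})

test_that("model JSON round-trip preserves predictions", {
  sim <- small_sim(seed = 2)
  model <- miln_train(sim$bags, K = 2, control = fast_ctrl())
  p <- file.path(withr::local_tempdir(), "model.json")
  save_model(model, p)
  back <- load_model(p)
  expect_equal(predict(back, sim$bags), predict(model, sim$bags))
  expect_equal(back$threshold, model$threshold)
  expect_equal(back$bounds$min, model$bounds$min)
})
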