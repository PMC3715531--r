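test_that("make_rf_mask produces the stated patch structure", {
  # global field
  expect_equal(make_rf_mask(c(6, 6), 9, NA), matrix(1, 36, 9))
  # singleton patches: each upper unit connects to exactly one lower unit
  m1 <- make_rf_mask(c(8, 8), 16, 1)
  expect_equal(colSums(m1), rep(1, 16))
  # full-extent patch = all ones
  mfull <- make_rf_mask(c(5, 5), 4, 5)
  expect_equal(mfull, matrix(1, 25, 4))
  # per-column count <= patch_side^2, with equality away from borders
  m <- make_rf_mask(c(12, 12), 16, 5)
  expect_true(all(colSums(m) <= 25))
  expect_true(any(colSums(m) == 25))
  expect_true(all(m %in% c(0, 1)))
  expect_error(make_rf_mask(c(4, 4), 4, 9), "exceeds")
  expect_error(make_rf_mask(c(8, 8), 10, 3), "perfect square")
})

test_that("init_network satisfies its initialization contract", {
  cfg <- train_config(init_bias = -3.5, weight_sd = 0.02, rng_seed = 8)
  net <- init_network(c(36, 16, 9), rf_spec(c(3, NA)), cfg, image_dim = c(6, 6))
  for (b in net$biases) expect_true(all(b == -3.5))
  for (l in 1:2) expect_true(all(net$weights[[l]][net$masks[[l]] == 0] == 0))
  net2 <- init_network(c(36, 16, 9), rf_spec(c(3, NA)), cfg, image_dim = c(6, 6))
  expect_identical(net$weights, net2$weights)
  expect_gt(sd(net$weights[[1]][net$masks[[1]] == 1]), 0)
})

test_that("cd_update conserves masks and has near-zero drift at the model's own distribution", {
  set.seed(21)
  nv <- 5; nh <- 3
  mask <- matrix(rbinom(nv * nh, 1, 0.8), nv, nh)
  W <- mask * matrix(rnorm(nv * nh, 0, 0.5), nv, nh)
  rbm <- structure(list(W = W, b_vis = rnorm(nv, 0, 0.3),
                        b_hid = rnorm(nh, 0, 0.3), mask = mask), class = "rbm")
  # sample minibatches exactly from the RBM's own equilibrium
  net <- layered_network(c(nv, nh), list(W), list(rbm$b_vis, rbm$b_hid), list(mask))
  d <- exact_distribution(net)
  cfg <- train_config(cd_steps = 3, learning_rate = 0.05, weight_decay = 0)
  drift <- matrix(0, nv, nh)
  n_batches <- 200
  set.seed(22)
  for (i in seq_len(n_batches)) {
    rows <- sample.int(nrow(d$states), 40, replace = TRUE, prob = d$prob)
    mb <- t(d$states[rows, seq_len(nv), drop = FALSE])
    upd <- cd_update(rbm, mb, cfg)
    drift <- drift + (upd$rbm$W - rbm$W) / cfg$learning_rate
    expect_true(all(upd$rbm$W[mask == 0] == 0))
  }
  mean_update <- drift / n_batches
  # model-equals-data null: mean update within MC error of zero
  expect_lt(max(abs(mean_update)), 3 * 0.5 / sqrt(40 * n_batches) * 3)
  expect_error(cd_update(rbm, matrix(0, nv + 1, 4), cfg), "match")
})

test_that("CD gradient direction agrees with the exact log-likelihood gradient", {
  set.seed(31)
  nv <- 6; nh <- 4
  mask <- matrix(1, nv, nh)
  W0 <- matrix(rnorm(nv * nh, 0, 0.7), nv, nh)
  rbm <- structure(list(W = W0, b_vis = rnorm(nv, 0, 0.4),
                        b_hid = rnorm(nh, 0, 0.4), mask = mask), class = "rbm")
  # data from a different small RBM so the gradient is nonzero
  gen <- random_net(c(nv, nh), seed = 32, w_sd = 1)
  d <- exact_distribution(gen)
  set.seed(33)
  rows <- sample.int(nrow(d$states), 600, replace = TRUE, prob = d$prob)
  data <- t(d$states[rows, seq_len(nv), drop = FALSE])
  exact <- rbm_exact_gradient(rbm, data)
  cfg <- train_config(cd_steps = 25, learning_rate = 1, weight_decay = 0)
  acc <- matrix(0, nv, nh)
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    upd <- cd_update(rbm, data[, sample.int(600, 100)], cfg)
    acc <- acc + (upd$rbm$W - rbm$W)
  }
  cd_grad <- as.vector(acc / n_rep)
  cos_sim <- sum(cd_grad * as.vector(exact$dW)) /
    sqrt(sum(cd_grad^2) * sum(exact$dW^2))
  expect_gt(cos_sim, 0.9)
})

test_that("exact log-likelihood increases over training on a tiny RBM", {
  set.seed(41)
  gen <- random_net(c(6, 4), seed = 42, w_sd = 1.2)
  d <- exact_distribution(gen)
  rows <- sample.int(nrow(d$states), 500, replace = TRUE, prob = d$prob)
  data <- t(d$states[rows, 1:6, drop = FALSE])
  mask <- matrix(1, 6, 4)
  rbm <- structure(list(W = mask * matrix(rnorm(24, 0, 0.01), 6, 4),
                        b_vis = rep(0, 6), b_hid = rep(0, 4), mask = mask),
                   class = "rbm")
  cfg <- train_config(cd_steps = 1, learning_rate = 0.02,
                      weight_decay = 0, minibatch_size = 50)
  ll0 <- rbm_exact_loglik(rbm, data)
  for (ep in 1:40) {
    ord <- sample.int(500)
    for (s in seq(1, 500, by = 50)) {
      upd <- cd_update(rbm, data[, ord[s:(s + 49)]], cfg)
      rbm <- upd$rbm
    }
  }
  ll1 <- rbm_exact_loglik(rbm, data)
  expect_gt(ll1, ll0)
})

test_that("layerwise_pretrain contracts: no-op at 0 epochs, mask/shape conservation", {
  enum <- enumerate_instances(c(8L, 8L), c(small = 3L, large = 5L))
  cfg0 <- train_config(epochs = 0, rng_seed = 5)
  net0 <- layerwise_pretrain(enum, c(64, 16, 9), rf_spec(c(3, NA)), cfg0)
  ref <- init_network(c(64, 16, 9), rf_spec(c(3, NA)), cfg0, image_dim = c(8, 8))
  expect_equal(net0$weights, ref$weights)
  expect_equal(net0$biases, ref$biases)
  cfg <- train_config(epochs = 3, rng_seed = 5)
  net <- layerwise_pretrain(enum, c(64, 16, 9), rf_spec(c(3, NA)), cfg)
  for (l in 1:2) expect_true(all(net$weights[[l]][net$masks[[l]] == 0] == 0))
  # reconstruction error decreases over epochs in the bottom pair
  errs <- net$meta$recon_error[[1]]
  expect_lt(errs[length(errs)], errs[1])
  expect_error(layerwise_pretrain(matrix(numeric(0), 64, 0), c(64, 16, 9),
                                  rf_spec(c(3, NA)), cfg), "empty")
})

test_that("checkpoints round-trip and reject version mismatches", {
  net <- random_net(c(6, 4, 2), seed = 61)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  expect_equal(back$weights, net$weights)
  expect_equal(back$biases, net$biases)
  expect_equal(back$layer_sizes, net$layer_sizes)
  bad <- readRDS(path)
  bad$format_version <- 99L
  saveRDS(bad, path)
  expect_error(load_checkpoint(path), "version")
})

test_that("trained shapes model autoencodes and generates (shared model)", {
  m <- acc_model()
  enum <- m$data
  set.seed(7)
  idx <- sample(ncol(enum$images), 60)
  imgs <- enum$images[, idx]
  st <- network_state(m$net, 60, visible = imgs)
  res <- run_trial(m$net, st, sampler_config())
  dec <- decode_layer(m$net, res$state$layers[[4]], 4)$pixels
  expect_gte(mean((dec > 0.5) == (imgs > 0.5)), 0.90)
  # free generation: Gibbs from random init, no clamping, decode visible
  st2 <- network_state(m$net, 60, init = "random")
  res2 <- run_trial(m$net, st2, sampler_config())
  q2 <- template_quality_batch(decode_layer(m$net, res2$state$layers[[4]], 4)$pixels,
                               m$bank)
  expect_gt(mean(pmax(q2$quality, 0)), 0.6)
})
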