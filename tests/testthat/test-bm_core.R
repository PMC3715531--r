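test_that("total_input matches the brute-force summation oracle", {
  net <- random_net(c(5, 4, 3), seed = 11)
  st <- random_state(net, seed = 12)
  for (layer in 1:3) {
    for (unit in seq_len(net$layer_sizes[layer])) {
      expect_equal(total_input(net, st, layer)[unit],
                   brute_total_input(net, st, layer, unit))
      expect_equal(total_input(net, st, layer, unit),
                   brute_total_input(net, st, layer, unit))
    }
  }
  expect_error(total_input(net, st, 4), "out of range")
  expect_error(total_input(net, st, 1, 99), "out of range")
})

test_that("total_input handles trivial cases", {
  net <- layered_network(c(1, 1), list(matrix(2, 1, 1)), list(-1, 0))
  st <- network_state(net, 1)
  st$layers[[2]][1, 1] <- 1
  expect_equal(total_input(net, st, 1, 1), 2 * 1 - 1)
  zero <- layered_network(c(2, 2), list(matrix(0, 2, 2)), list(rep(0, 2), rep(0, 2)))
  stz <- random_state(zero, seed = 3)
  expect_equal(total_input(zero, stz, 1), c(0, 0))
})

test_that("activation_prob is the logistic with correct limits", {
  expect_equal(activation_prob(0), 0.5)
  x <- c(-3.2, -0.5, 0.7, 4)
  expect_equal(activation_prob(x) + activation_prob(-x), rep(1, 4))
  expect_lt(abs(activation_prob(50) - 1), 1e-9)
  expect_true(all(diff(activation_prob(seq(-10, 10, 0.1))) > 0))
})

test_that("balanced_input interpolates feedforward and feedback", {
  net <- random_net(c(4, 3, 2), seed = 21)
  st <- random_state(net, seed = 22)
  expect_equal(balanced_input(net, st, 2, 0.5), total_input(net, st, 2))
  net0 <- net
  net0$biases[[2]][] <- 0
  bu <- drop(crossprod(net0$weights[[1]], st$layers[[1]]))
  td <- drop(net0$weights[[2]] %*% st$layers[[3]])
  expect_equal(balanced_input(net0, st, 2, 1), 2 * bu)
  expect_equal(balanced_input(net0, st, 2, 0), 2 * td)
  expect_error(balanced_input(net, st, 1, 0.5), "intermediate")
  expect_error(balanced_input(net, st, 3, 0.5), "intermediate")
})

test_that("gibbs_sweep respects clamping and samples at the right rate", {
  net <- random_net(c(3, 4), seed = 31)
  net$weights[[1]][] <- 0
  st <- network_state(net, 1, visible = c(1, 0, 1))
  # zero weights: hidden units are i.i.d. Bernoulli(sigmoid(bias))
  set.seed(99)
  n <- 1e4
  counts <- numeric(4)
  visible_untouched <- TRUE
  for (i in seq_len(n)) {
    out <- gibbs_sweep(net, st)
    counts <- counts + out$layers[[2]][, 1]
    visible_untouched <- visible_untouched &&
      identical(out$layers[[1]], st$layers[[1]])
  }
  expect_true(visible_untouched) # clamped layer bit-identical throughout
  p <- activation_prob(net$biases[[2]])
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(counts / n - p) < 3 * se + 1e-9))
  all_clamped <- network_state(net, 1, clamped = c(TRUE, TRUE))
  expect_error(gibbs_sweep(net, all_clamped), "clamped")
})

test_that("lambda = 0.5 reproduces the plain conditional trajectory", {
  net <- random_net(c(4, 3, 2), seed = 41)
  # reference sweep with no ACh machinery: plain total_input conditionals
  plain_sweep <- function(net, state) {
    for (l in 1:3) {
      if (state$clamped[l]) next
      p <- activation_prob(total_input(net, state, l))
      state$layers[[l]][, 1] <- (runif(length(p)) < p) + 0
    }
    state
  }
  st0 <- network_state(net, 1, visible = c(1, 0, 1, 1))
  set.seed(7)
  a <- st0
  for (i in 1:20) a <- gibbs_sweep(net, a, sampler_config(ach_lambda = 0.5))
  set.seed(7)
  b <- st0
  for (i in 1:20) b <- plain_sweep(net, b)
  expect_identical(a$layers, b$layers)
})

test_that("mean_field_sweep is deterministic and converges", {
  net <- random_net(c(4, 3, 2), seed = 51)
  st <- network_state(net, 1, visible = c(1, 0, 1, 0))
  a <- mean_field_sweep(net, st)
  b <- mean_field_sweep(net, st)
  expect_identical(a$layers, b$layers)
  # zero-weight network: fixed point sigmoid(bias) after one sweep
  net0 <- net
  for (l in 1:2) net0$weights[[l]][] <- 0
  s1 <- mean_field_sweep(net0, st)
  expect_equal(s1$layers[[2]][, 1], activation_prob(net0$biases[[2]]))
  s2 <- mean_field_sweep(net0, s1)
  expect_identical(s1$layers, s2$layers)
  # convergence on a 4-3-2 network
  s <- st
  deltas <- numeric(500)
  for (i in 1:500) {
    s_new <- mean_field_sweep(net, s)
    deltas[i] <- max(abs(unlist(s_new$layers) - unlist(s$layers)))
    s <- s_new
  }
  expect_lt(min(deltas), 1e-6)
  expect_true(all(diff(deltas[10:500]) <= 1e-12))
})

test_that("energy matches the double-loop oracle", {
  net <- random_net(c(3, 3, 2), seed = 61)
  st <- random_state(net, seed = 62)
  expect_equal(energy(net, st), brute_energy(net, st))
  zero_state <- network_state(net, 1)
  expect_equal(energy(net, zero_state), 0)
  pair <- layered_network(c(1, 1), list(matrix(1, 1, 1)), list(0, 0))
  stp <- network_state(pair, 1)
  stp$layers[[1]][] <- 1; stp$layers[[2]][] <- 1
  expect_equal(energy(pair, stp), -1)
})

test_that("exact_distribution is the Boltzmann table", {
  # all parameters zero: uniform
  net0 <- layered_network(c(2, 1), list(matrix(0, 2, 1)), list(c(0, 0), 0))
  d0 <- exact_distribution(net0)
  expect_equal(d0$prob, rep(1 / 8, 8))
  # single unit with bias b: P(on) = sigmoid(b)
  net1 <- layered_network(c(1, 1), list(matrix(0, 1, 1)), list(0.7, -50))
  d1 <- exact_distribution(net1)
  p_on <- sum(d1$prob[d1$states[, 1] == 1])
  expect_equal(p_on, activation_prob(0.7), tolerance = 1e-12)
  # probabilities proportional to exp(-energy) computed by the oracle
  net <- random_net(c(2, 2), seed = 71)
  d <- exact_distribution(net)
  e_oracle <- apply(d$states, 1, function(bits) {
    st <- network_state(net, 1)
    st$layers[[1]][, 1] <- bits[1:2]; st$layers[[2]][, 1] <- bits[3:4]
    brute_energy(net, st)
  })
  expect_equal(d$energy, e_oracle)
  expect_equal(d$prob, exp(-e_oracle) / sum(exp(-e_oracle)))
  big <- random_net(c(12, 10), seed = 72)
  expect_error(exact_distribution(big), "20 units")
})

test_that("long-run Gibbs frequencies match the exact distribution (2-2 net)", {
  net <- random_net(c(2, 2), seed = 81, w_sd = 1)
  d <- exact_distribution(net)
  set.seed(82)
  st <- network_state(net, 1)
  counts <- numeric(16)
  burn <- 200
  n <- 2e4
  for (i in seq_len(burn + n)) {
    st <- gibbs_sweep(net, st)
    if (i > burn) {
      k <- state_index(flatten_state(st))
      counts[k] <- counts[k] + 1
    }
  }
  tv <- 0.5 * sum(abs(counts / n - d$prob))
  expect_lt(tv, 0.05)
})

test_that("detailed balance holds for single-unit flips in a long run", {
  net <- random_net(c(2, 1), seed = 91, w_sd = 1)
  d <- exact_distribution(net)
  set.seed(92)
  st <- network_state(net, 1)
  counts <- numeric(8)
  for (i in 1:30000) {
    st <- gibbs_sweep(net, st)
    k <- state_index(flatten_state(st))
    counts[k] <- counts[k] + 1
  }
  freq <- counts / sum(counts)
  # states 1 (000) and 2 (100) differ in one unit
  for (pair in list(c(1, 2), c(1, 3), c(3, 4), c(5, 6))) {
    ratio <- freq[pair[1]] / freq[pair[2]]
    expected <- exp(-(d$energy[pair[1]] - d$energy[pair[2]]))
    expect_equal(ratio, expected, tolerance = 0.15)
  }
})

test_that("clamped layers are conserved under many sweeps of either mode", {
  net <- random_net(c(4, 3, 2), seed = 101)
  v <- c(1, 0, 1, 0)
  st <- network_state(net, 1, visible = v)
  set.seed(5)
  for (i in 1:50) st <- gibbs_sweep(net, st)
  expect_identical(st$layers[[1]][, 1], v)
  stm <- network_state(net, 1, visible = v)
  for (i in 1:50) stm <- mean_field_sweep(net, stm)
  expect_identical(stm$layers[[1]][, 1], v)
  # hidden clamp too
  sth <- network_state(net, 1, visible = v)
  sth <- clamp_layer(sth, 2, 0)
  set.seed(6)
  for (i in 1:20) sth <- gibbs_sweep(net, sth)
  expect_identical(sth$layers[[2]][, 1], rep(0, 3))
})

test_that("network invariants are enforced at construction", {
  expect_error(layered_network(c(2, 2), list(matrix(0, 3, 2)),
                               list(rep(0, 2), rep(0, 2))), "inconsistent")
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  w <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_error(layered_network(c(2, 2), list(w), list(rep(0, 2), rep(0, 2)),
                               list(m)), "mask")
  ok <- layered_network(c(2, 2), list(w * m), list(rep(0, 2), rep(0, 2)), list(m))
  expect_s3_class(ok, "layered_network")
})

test_that("run_trial records activity consistent with a manual sweep loop", {
  net <- random_net(c(3, 2, 2), seed = 111)
  v <- c(1, 1, 0)
  set.seed(7)
  res <- run_trial(net, network_state(net, 1, visible = v),
                   sampler_config(cycles = 30), record_activity = TRUE,
                   record_trace = TRUE)
  expect_length(res$trace, 30)
  expect_equal(dim(res$activity[[1]]), c(2, 1))
  expect_true(all(unlist(res$activity) >= 0 & unlist(res$activity) <= 1))
  # trace bookkeeping: final trace entry equals final state
  expect_identical(res$trace[[30]], res$state$layers)
})
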