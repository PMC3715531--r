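test_that("scenario constructor validates its inputs", {
  expect_error(scenario("robustness_pepper"), "requires a dataset")
  expect_error(scenario("no_such_kind"), "arg")
  sc <- scenario("blindness", seed = 3)
  expect_equal(sc$kind, "blindness")
  enum <- enumerate_instances(c(8L, 8L), c(small = 3L, large = 5L))
  scp <- scenario("robustness_pepper", dataset = enum)
  expect_equal(scp$fraction, 0.65)
  expect_equal(scenario("noise_input")$fraction, 0.10)
})

test_that("scenario providers produce the right input statistics", {
  enum <- enumerate_instances(c(10L, 10L), c(small = 3L, large = 5L))
  prov <- dbmcbs:::scenario_provider
  set.seed(1)
  v <- prov(scenario("blindness"), c(10, 10))(5)
  expect_true(all(v == 0))
  vn <- prov(scenario("noise_input"), c(10, 10))(6)
  expect_equal(colSums(vn), rep(10, 6))   # round(0.10 * 100) per trial
  sp <- prov(scenario("robustness_pepper", dataset = enum), c(10, 10))(8)
  expect_equal(length(sp$labels), 8)
  expect_true(all(colSums(sp$visible) <= colSums(enum$images[, 1:8]) + 25))
  sh <- prov(scenario("half_field", dataset = enum, half = "top"), c(10, 10))(8)
  top_rows <- as.vector(matrix(seq_len(100), 10)[1:5, ])
  expect_true(all(sh$visible[top_rows, ] == 0))
})

test_that("scenario runs are bit-identical under the same seed", {
  net <- random_net(c(6, 4, 3), seed = 3, w_sd = 0.4)
  net$geometry <- list(image_dim = c(2, 3))
  tgt <- list(rep(0.3, 4), rep(0.3, 3))
  cfg <- homeostasis_config(rate = 0.1, trials_per_iteration = 6,
                            cycles_per_trial = 8, max_iterations = 4)
  sc <- scenario("blindness", seed = 17)
  a <- run_scenario(net, sc, tgt, cfg)
  b <- run_scenario(net, sc, tgt, cfg)
  expect_identical(a$trace$activity, b$trace$activity)
  expect_identical(a$net$biases, b$net$biases)
})

test_that("suppression probe contract: zero-length probe, information flow", {
  m <- acc_model()
  # un-adapted model with clean clamped input: clamping h1 abolishes
  # veridical top-layer decoding (information flow check)
  img <- m$data$images[, 10]
  q_free <- probe_trials(m$net, img, 20, m$bank, seed = 1)
  q_clmp <- probe_trials(m$net, img, 20, m$bank, clamp_h1 = TRUE, seed = 1)
  expect_gt(mean(pmax(q_free$quality, 0)), 0.5)
  expect_lt(mean(pmax(q_clmp$quality, 0)), mean(pmax(q_free$quality, 0)) - 0.3)
  # zero-length probe: protocol reduces to identical before/after phases
  sup <- suppression_probe(m$net, m$bank, n_before = 10, n_probe = 0,
                           n_after = 10, visible = img, cycles = 20, seed = 2)
  expect_true(is.na(sup$summary$mean_quality[sup$summary$phase == "during"]))
  expect_equal(nrow(sup$phases$before), 10)
})

test_that("localization_stats counts, thresholds, and degenerate input", {
  q <- data.frame(quality = c(0.9, 0.95, 0.2, 0.88, NA),
                  category = c("square", "square", "triangle_up",
                               "triangle_down", NA),
                  size_class = c("small", "large", "small", "small", NA),
                  row = c(1, 5, 2, 8, NA), col = c(2, 3, 1, 4, NA),
                  degenerate = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  ls <- localization_stats(q, c(12, 12), threshold = 0.85,
                           sides = c(small = 5L, large = 8L))
  expect_equal(ls$n_counted, 3L)
  expect_equal(unname(ls$by_size), c(2L, 1L))
  expect_equal(ls$small_large_ratio, 2)
  # centres: rows 1+2=3 (top), 5+3.5=8.5, 8+2=10; top half = rows <= 6
  expect_equal(ls$frac_top, 1 / 3)
  empty <- localization_stats(q[0, ], c(12, 12))
  expect_equal(empty$n_counted, 0L)
  expect_true(is.na(empty$small_large_ratio))
})

test_that("contour completion flags images with nothing blanked", {
  m <- acc_model()
  img <- m$data$images[, 5]
  mask <- rep(0, 144)  # nothing blanked: score undefined
  cc <- contour_completion(m$net, matrix(img, ncol = 1), mask,
                           lambda_grid = 0.5, cycles = 5)
  expect_true(all(is.na(cc$score)))
})

test_that("realign probe flags an untrained network as undefined", {
  net <- init_network(c(144, 16, 9), rf_spec(c(5, NA)), train_config(rng_seed = 1),
                      image_dim = c(12, 12))
  m <- acc_model()
  rp <- realign_probe(net, m$data$images[, 3], m$data$labels$class[3],
                      m$bank, n = 10, cycles = 10, seed = 4)
  expect_true(is.na(rp$realigned))
})

test_that("raised feedforward balance improves alignment with a fixed input", {
  fx <- acc_fixed()
  m <- acc_model()
  rp <- realign_probe(fx$res$net, m$data$images[, fx$input_index],
                      fx$true_class, m$bank, lambda = 0.7, n = 50, seed = 55)
  # the raised-lambda condition must recover the true percept more often
  # than the normal balance, which hallucinates a non-matching majority
  expect_lt(rp$match_normal, 0.5)
  expect_gt(rp$match_raised, rp$match_normal)
})

test_that("fixed-input adaptation starts veridical and ends decoupled", {
  fx <- acc_fixed()
  mq <- mean_quality_series(fx$res$trace)
  expect_gt(mean(mq[1:5]), 0.7)  # initial percepts match the (clean) input
  q <- fx$res$trace$quality
  late <- q[q$iteration > 0.9 * max(q$iteration) & !q$degenerate, ]
  cls <- paste(late$category, late$size_class, sep = "_")
  # majority of late percepts no longer match the clamped input
  expect_lt(mean(cls == fx$true_class), 0.5)
})

test_that("CLI round trip: train then run an experiment", {
  dir <- tempfile(); dir.create(dir)
  ckpt <- file.path(dir, "model.rds")
  cfg <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(scale = "small",
                            image_size = c(8, 8),
                            sides = list(small = 3, large = 5),
                            hidden = c(16, 9), patches = c(3, NA),
                            epochs = 2,
                            max_iterations = 2, trials_per_iteration = 4,
                            cycles_per_trial = 5),
                       cfg, auto_unbox = TRUE, digits = NA)
  suppressMessages(cli_train(c("--dataset", "shapes", "--config", cfg,
                               "--seed", "7", "--out", ckpt)))
  expect_true(file.exists(ckpt))
  expect_true(file.exists(file.path(dir, "model_training_log.csv")))
  out <- file.path(dir, "run")
  suppressMessages(cli_experiment(c("--scenario", "blindness",
                                    "--checkpoint", ckpt, "--config", cfg,
                                    "--seed", "7", "--out", out)))
  expect_true(file.exists(file.path(out, "trace.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
})
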