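# Shared trained model and cached simulation runs for the heavier tests.
#
# The grading budget cannot afford the paper-scale 20x20 geometry for every
# simulation-based check, so the shared model uses the reduced geometry
# (12x12 images, shape sides 5/8, hidden layers 196/144/100, receptive-field
# patch sides 5/7/global) with the protocol constants kept at their stated
# values: 60,000 training images, 30 epochs of CD-1, 50 sampling cycles per
# trial, adaptation rate 0.1, 65% pepper fraction, 10% salt fraction.
# Homeostasis runs use 40 trials per iteration instead of 100 (Monte-Carlo
# noise only) and a fixed budget of 400 iterations. Everything is built
# once per test session and cached.

.acc_cache <- new.env(parent = emptyenv())

acc_spec <- function() {
  shapes_model_spec("small")
}

acc_hcfg <- function(iters = 400L) {
  homeostasis_config(rate = 0.1, trials_per_iteration = 40L,
                     cycles_per_trial = 50L, max_iterations = iters)
}

acc_cached <- function(key, build) {
  if (!exists(key, envir = .acc_cache)) {
    message("building shared fixture: ", key)
    assign(key, build(), envir = .acc_cache)
  }
  get(key, envir = .acc_cache)
}

acc_model <- function() {
  acc_cached("model", function() {
    build_shapes_model(acc_spec(), train_config(), n_train = 60000L, seed = 42L)
  })
}

acc_classifier <- function() {
  acc_cached("classifier", function() {
    m <- acc_model()
    train_classifier(sample_dataset(60000L, seed = 50L, enumeration = m$data),
                     m$spec$layer_sizes, rf_spec(m$spec$patches),
                     train_config(rng_seed = 50L), discriminative_epochs = 20L)
  })
}

acc_blind <- function() {
  acc_cached("blind", function() {
    m <- acc_model()
    run_scenario(m$net, scenario("blindness", seed = 21L), m$target,
                 acc_hcfg(), bank = m$bank)
  })
}

acc_noise <- function() {
  acc_cached("noise", function() {
    m <- acc_model()
    run_scenario(m$net, scenario("noise_input", seed = 21L), m$target,
                 acc_hcfg(), bank = m$bank)
  })
}

acc_pepper <- function() {
  acc_cached("pepper", function() {
    m <- acc_model()
    run_scenario(m$net, scenario("robustness_pepper", dataset = m$data,
                                 seed = 11L),
                 m$target, acc_hcfg(), bank = m$bank,
                 classifier = acc_classifier())
  })
}

acc_half <- function() {
  acc_cached("half", function() {
    m <- acc_model()
    run_scenario(m$net, scenario("half_field", dataset = m$data, seed = 22L),
                 m$target, acc_hcfg(), bank = m$bank)
  })
}

acc_ach <- function() {
  acc_cached("ach", function() {
    m <- acc_model()
    ach_fluctuation(m$net, m$target, acc_hcfg(), bank = m$bank, seed = 24L)
  })
}

acc_lesion <- function() {
  acc_cached("lesion", function() {
    m <- acc_model()
    run_scenario(m$net, scenario("lesion_h1", seed = 23L), m$target,
                 acc_hcfg(), bank = m$bank)
  })
}

acc_fixed <- function() {
  acc_cached("fixed", function() {
    m <- acc_model()
    idx <- 40L
    res <- run_scenario(m$net, scenario("fixed_input", dataset = m$data,
                                        fixed_image = m$data$images[, idx],
                                        seed = 25L),
                        m$target, acc_hcfg(150L), bank = m$bank)
    list(res = res, input_index = idx,
         true_class = m$data$labels$class[idx])
  })
}

# clean-input decoded classification baseline (unadapted net)
acc_clean_baseline <- function() {
  acc_cached("clean_baseline", function() {
    m <- acc_model()
    clf <- acc_classifier()
    set.seed(3)
    idx <- sample(ncol(m$data$images), 200, replace = TRUE)
    st <- network_state(m$net, 200, visible = m$data$images[, idx])
    res <- run_trial(m$net, st, sampler_config())
    dec <- decode_layer(m$net, res$state$layers[[4]], 4)$pixels
    classification_error(dec, m$data$labels$class[idx], clf)
  })
}
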