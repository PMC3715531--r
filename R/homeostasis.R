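#' Homeostasis configuration
#'
#' Parameters of the homeostatic adaptation protocol. Each iteration, the
#' current average activity of every hidden unit is measured over
#' `trials_per_iteration` trials of `cycles_per_trial` sampling cycles
#' (hidden states initialised to zero at the start of each trial), and each
#' hidden bias is then incremented by `rate * (target - current)`.
#' Parameters are fixed within trials and only updated gradually between
#' iterations. The adaptation rate is 0.1 for the shapes model (0.04 is the
#' value used for handwritten digits); the overall results do not depend on
#' its precise value. Convergence is by iteration budget, matching the
#' fixed-length simulation protocol.
#'
#' @param rate positive adaptation rate.
#' @param trials_per_iteration trials per iteration (default 100).
#' @param cycles_per_trial sampling cycles per trial (default 50).
#' @param max_iterations number of adaptation iterations.
#' @param n_score how many trials per iteration are decoded and scored for
#'   the sampled (dot-plot) quality record; the mean-quality series always
#'   uses all trials.
#' @return an object of class `homeostasis_config`.
#' @export
homeostasis_config <- function(rate = 0.1, trials_per_iteration = 100L,
                               cycles_per_trial = 50L, max_iterations = 100L,
                               n_score = 5L) {
  if (rate < 0) stop("rate must be non-negative")
  if (trials_per_iteration < 1L) stop("need at least one trial per iteration")
  structure(list(rate = rate,
                 trials_per_iteration = as.integer(trials_per_iteration),
                 cycles_per_trial = as.integer(cycles_per_trial),
                 max_iterations = as.integer(max_iterations),
                 n_score = as.integer(n_score)),
            class = "homeostasis_config")
}

#' Target activities from the training data
#'
#' The target activity of each hidden unit is its average activation
#' probability during inference over the training data, after training: one
#' trial per training image, visible layer clamped to the image, hidden
#' states initialised to zero, activities accumulated over
#' `cycles` sampling cycles and averaged over cycles and images.
#'
#' @param net a trained [layered_network()].
#' @param data `pixels x images` matrix or `shapes_dataset`.
#' @param cycles sampling cycles per trial.
#' @param seed optional integer seed.
#' @return list over hidden layers of per-unit target vectors.
#' @export
measure_target_activity <- function(net, data, cycles = 50L, seed = NULL) {
  if (inherits(data, "shapes_dataset")) data <- data$images
  if (is.null(dim(data)) || ncol(data) == 0L) stop("empty dataset")
  if (!is.null(seed)) set.seed(seed)
  st <- network_state(net, ncol(data), visible = data)
  res <- run_trial(net, st, sampler_config(cycles = cycles),
                   record_activity = TRUE)
  lapply(res$activity, rowMeans)
}

#' Current activities under a degraded-input scenario
#'
#' As [measure_target_activity()], but over scenario-provided inputs (blank,
#' corrupted, fixed, half-blanked, ...) for `trials_per_iteration` trials.
#'
#' @param net a [layered_network()].
#' @param input_provider function `(n)` returning a `pixels x n` visible
#'   matrix.
#' @param config a [homeostasis_config()].
#' @param lambda ACh balance factor for the trials.
#' @param clamp_h1 clamp the first hidden layer to zero (cortical lesion).
#' @param seed optional integer seed.
#' @return list over hidden layers of per-unit current-activity vectors.
#' @export
measure_current_activity <- function(net, input_provider, config,
                                     lambda = 0.5, clamp_h1 = FALSE,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$trials_per_iteration
  st <- network_state(net, n, visible = input_provider(n))
  if (clamp_h1) st <- clamp_layer(st, 2L, 0)
  res <- run_trial(net, st,
                   sampler_config(cycles = config$cycles_per_trial,
                                  ach_lambda = lambda),
                   record_activity = TRUE)
  lapply(res$activity, rowMeans)
}

#' One homeostatic excitability update
#'
#' Increments each hidden unit's bias by `rate * (target - current)`.
#' Weights and visible biases are untouched: the mechanism merely adapts
#' the local biases.
#'
#' @param net a [layered_network()].
#' @param target,current lists of per-unit activity vectors over hidden
#'   layers (as returned by the measurement functions).
#' @param rate adaptation rate.
#' @return the network with updated hidden biases.
#' @export
homeostatic_step <- function(net, target, current, rate) {
  L <- n_layers(net)
  if (length(target) != L - 1L || length(current) != L - 1L)
    stop("target/current must cover all hidden layers")
  for (l in 2:L)
    net$biases[[l]] <- net$biases[[l]] + rate * (target[[l - 1L]] - current[[l - 1L]])
  net
}

# internal: run one iteration's trials for one lambda block, returning
# accumulated per-unit activity sums, scored qualities of the decoded
# top-layer states and optional classifier predictions
run_trial_block <- function(net, visible, n, lambda, clamp_h1, cycles,
                            bank = NULL, classifier = NULL) {
  st <- network_state(net, n, visible = visible)
  if (clamp_h1) st <- clamp_layer(st, 2L, 0)
  res <- run_trial(net, st, sampler_config(cycles = cycles, ach_lambda = lambda),
                   record_activity = TRUE)
  L <- n_layers(net)
  out <- list(activity = res$activity, top = res$state$layers[[L]])
  if (!is.null(bank) || !is.null(classifier)) {
    dec <- decode_layer(net, out$top, L)$pixels
    # decoded percepts with no pixel above mid-grey are void, not content
    if (!is.null(bank)) out$quality <- template_quality_batch(dec, bank,
                                                              void_floor = 0.5)
    if (!is.null(classifier)) out$pred <- classifier_quality(dec, classifier)$class
  }
  out
}

#' Run homeostatic adaptation
#'
#' Alternates activity measurement and homeostatic bias updates for
#' `config$max_iterations` iterations, recording an adaptation trace:
#' per-iteration per-layer mean activity, mean absolute bias shift from the
#' initial values, decoded-state hallucination qualities, and (optionally)
#' classification error of the decoded top-layer states.
#'
#' @param net a trained [layered_network()].
#' @param input_provider function `(n)` returning a `pixels x n` visible
#'   matrix, or `(n)` returning a list with elements `visible` and `labels`
#'   (true class labels, enabling the classification-error series).
#' @param target list of per-unit target activities
#'   ([measure_target_activity()]).
#' @param config a [homeostasis_config()].
#' @param bank optional [template_bank()]; enables quality scoring.
#' @param classifier optional [train_classifier()] model; enables the
#'   classification-error series.
#' @param lambda_schedule ACh balance factor(s). A single value applies to
#'   all trials; a vector (e.g. `c(0.3, 0.7)`) splits each iteration's
#'   trials into equal blocks, one per value, with activities averaged over
#'   all blocks and qualities recorded separately per value.
#' @param clamp_h1 clamp the first hidden layer to zeros throughout
#'   (modelling a lesion of early cortex); the visible content is then
#'   irrelevant.
#' @param seed integer seed for the whole run (reproducible end to end).
#' @return an object of class `adaptation_trace`; the adapted network is in
#'   `$net`.
#' @export
run_adaptation <- function(net, input_provider, target,
                           config = homeostasis_config(), bank = NULL,
                           classifier = NULL, lambda_schedule = 0.5,
                           clamp_h1 = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- n_layers(net)
  b0 <- net$biases
  nlam <- length(lambda_schedule)
  ntr <- config$trials_per_iteration
  block_n <- rep(ntr %/% nlam, nlam)
  block_n[seq_len(ntr %% nlam)] <- block_n[seq_len(ntr %% nlam)] + 1L
  iters <- config$max_iterations
  activity <- matrix(NA_real_, iters, L - 1L)
  bias_shift <- numeric(iters)
  class_error <- rep(NA_real_, iters)
  qual <- list()
  for (it in seq_len(iters)) {
    cur <- lapply(2:L, function(l) numeric(net$layer_sizes[l]))
    preds <- character(0); truth <- character(0)
    for (j in seq_len(nlam)) {
      n <- block_n[j]
      inp <- input_provider(n)
      labels <- NULL
      if (is.list(inp)) { labels <- inp$labels; inp <- inp$visible }
      blk <- run_trial_block(net, inp, n, lambda_schedule[j], clamp_h1,
                             config$cycles_per_trial, bank, classifier)
      for (l in seq_len(L - 1L))
        cur[[l]] <- cur[[l]] + rowSums(blk$activity[[l]])
      if (!is.null(blk$quality)) {
        q <- blk$quality
        q$iteration <- it; q$trial <- seq_len(n); q$lambda <- lambda_schedule[j]
        qual[[length(qual) + 1L]] <- q
      }
      if (!is.null(blk$pred) && !is.null(labels)) {
        preds <- c(preds, blk$pred); truth <- c(truth, labels)
      }
    }
    cur <- lapply(cur, function(v) v / ntr)
    activity[it, ] <- vapply(cur, mean, numeric(1))
    if (length(preds)) class_error[it] <- mean(preds != truth)
    net <- homeostatic_step(net, target, cur, config$rate)
    bias_shift[it] <- mean(abs(unlist(net$biases[-1L]) - unlist(b0[-1L])))
  }
  structure(list(iterations = iters, activity = activity,
                 bias_shift = bias_shift,
                 quality = if (length(qual)) do.call(rbind, qual) else NULL,
                 class_error = class_error,
                 target_layer_means = vapply(target, mean, numeric(1)),
                 lambda_schedule = lambda_schedule,
                 config = config, net = net, initial_biases = b0),
            class = "adaptation_trace")
}

#' Per-iteration mean quality series
#'
#' Mean hallucination quality over all scored trials of each iteration
#' (negative correlations clamped at zero, the reported \[0, 1\] scale),
#' optionally restricted to one value of the ACh balance factor.
#'
#' @param trace an [run_adaptation()] result.
#' @param lambda optional balance-factor filter.
#' @return numeric vector of length `trace$iterations`.
#' @export
mean_quality_series <- function(trace, lambda = NULL) {
  q <- trace$quality
  if (is.null(q)) stop("trace was run without quality scoring")
  if (!is.null(lambda)) q <- q[abs(q$lambda - lambda) < 1e-12, ]
  out <- rep(NA_real_, trace$iterations)
  agg <- tapply(pmax(q$quality, 0), q$iteration, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' @export
print.adaptation_trace <- function(x, ...) {
  cat(sprintf("Adaptation trace: %d iterations, %d hidden layers\n",
              x$iterations, ncol(x$activity)))
  cat(sprintf("  final bias shift %.3f; final layer activities %s (targets %s)\n",
              x$bias_shift[x$iterations],
              paste(sprintf("%.3f", x$activity[x$iterations, ]), collapse = ", "),
              paste(sprintf("%.3f", x$target_layer_means), collapse = ", ")))
  if (!is.null(x$quality)) {
    mq <- mean_quality_series(x)
    cat(sprintf("  mean quality: first %.2f, last %.2f\n", mq[1], mq[length(mq)]))
  }
  invisible(x)
}

#' Persist an adaptation trace
#'
#' Writes the per-iteration per-layer series as CSV plus a JSON run
#' manifest (configuration, seeds, lambda schedule), and the quality table
#' as a second CSV.
#'
#' @param trace an [run_adaptation()] result.
#' @param dir output directory (created if needed).
#' @param seed the seed the run used (recorded in the manifest).
#' @return `dir`, invisibly.
#' @export
write_trace <- function(trace, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  act <- as.data.frame(trace$activity)
  names(act) <- paste0("layer", seq_len(ncol(act)) + 1L)
  act$iteration <- seq_len(trace$iterations)
  act$bias_shift <- trace$bias_shift
  act$class_error <- trace$class_error
  utils::write.csv(act, file.path(dir, "trace.csv"), row.names = FALSE)
  if (!is.null(trace$quality))
    utils::write.csv(trace$quality, file.path(dir, "quality.csv"),
                     row.names = FALSE)
  manifest <- list(iterations = trace$iterations,
                   lambda_schedule = trace$lambda_schedule,
                   rate = trace$config$rate,
                   trials_per_iteration = trace$config$trials_per_iteration,
                   cycles_per_trial = trace$config$cycles_per_trial,
                   seed = seed,
                   target_layer_means = trace$target_layer_means)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
plot.adaptation_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(x$activity, type = "l", lty = 1,
                    xlab = "iteration", ylab = "mean layer activity", ...)
  graphics::abline(h = x$target_layer_means, lty = 2,
                   col = seq_along(x$target_layer_means))
  if (!is.null(x$quality)) {
    mq <- mean_quality_series(x)
    graphics::plot(mq, type = "l", ylim = c(0, 1), xlab = "iteration",
                   ylab = "mean hallucination quality")
  }
  invisible(x)
}
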