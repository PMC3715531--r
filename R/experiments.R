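#' Experiment scenario
#'
#' Describes one of the in-scope experiments as a reproducible object. The
#' scenario determines the input provider (what the visible layer is clamped
#' to on each trial), any hidden-layer clamps, and the ACh balance schedule.
#'
#' Kinds: `robustness_pepper` (training images with a fraction of pixels
#' forced to black), `blindness` (permanently blank input), `noise_input`
#' (white pixels at random positions on a black background, resampled each
#' trial), `fixed_input` (a single fixed image every trial), `half_field`
#' (training images with one half blanked), `lesion_h1` (first hidden layer
#' clamped to zero; visible content irrelevant), `ach_fluctuation` (blank
#' input; half of each iteration's trials at a low and half at a high
#' balance factor).
#'
#' @param kind scenario kind (see Details).
#' @param dataset a `shapes_dataset` used to draw trial inputs (required for
#'   image-based scenarios).
#' @param fraction corruption fraction (pepper / salt scenarios).
#' @param half which half to blank for `half_field`.
#' @param fixed_image image for `fixed_input` (defaults to the dataset's
#'   first image).
#' @param lambda_low,lambda_high balance factors for `ach_fluctuation`.
#' @param seed integer seed recorded with the scenario.
#' @return an object of class `scenario`.
#' @export
scenario <- function(kind = c("robustness_pepper", "blindness", "noise_input",
                              "fixed_input", "half_field", "lesion_h1",
                              "ach_fluctuation"),
                     dataset = NULL, fraction = NULL,
                     half = "top", fixed_image = NULL,
                     lambda_low = 0.3, lambda_high = 0.7, seed = 1L) {
  kind <- match.arg(kind)
  needs_data <- kind %in% c("robustness_pepper", "fixed_input", "half_field")
  if (needs_data && is.null(dataset))
    stop(sprintf("scenario '%s' requires a dataset", kind))
  if (is.null(fraction))
    fraction <- switch(kind, robustness_pepper = 0.65, noise_input = 0.10, NA_real_)
  if (kind == "fixed_input" && is.null(fixed_image))
    fixed_image <- dataset$images[, 1L]
  structure(list(kind = kind, dataset = dataset, fraction = fraction,
                 half = half, fixed_image = fixed_image,
                 lambda_low = lambda_low, lambda_high = lambda_high,
                 seed = as.integer(seed)),
            class = "scenario")
}

# input provider for a scenario; providers draw from the current RNG stream
# so that a seeded run is reproducible end to end
scenario_provider <- function(sc, image_size) {
  npix <- prod(image_size)
  switch(sc$kind,
    blindness = ,
    lesion_h1 = ,
    ach_fluctuation = function(n) matrix(0, npix, n),
    noise_input = function(n) {
      k <- round(sc$fraction * npix)
      v <- matrix(0, npix, n)
      for (j in seq_len(n)) v[sample.int(npix, k), j] <- 1
      v
    },
    fixed_input = local({
      img <- as.vector(sc$fixed_image)
      function(n) matrix(img, npix, n)
    }),
    robustness_pepper = function(n) {
      idx <- sample.int(ncol(sc$dataset$images), n, replace = TRUE)
      v <- sc$dataset$images[, idx, drop = FALSE]
      k <- round(sc$fraction * npix)
      for (j in seq_len(n)) v[sample.int(npix, k), j] <- 0
      list(visible = v, labels = sc$dataset$labels$class[idx])
    },
    half_field = function(n) {
      idx <- sample.int(ncol(sc$dataset$images), n, replace = TRUE)
      v <- sc$dataset$images[, idx, drop = FALSE]
      H <- image_size[1]
      cut <- ceiling(H / 2)
      rows <- if (sc$half == "top") seq_len(cut) else (cut + 1L):H
      sel <- as.vector(matrix(seq_len(npix), image_size[1])[rows, ])
      v[sel, ] <- 0
      list(visible = v, labels = sc$dataset$labels$class[idx])
    },
    stop("unknown scenario kind"))
}

#' Run an experiment scenario
#'
#' Runs homeostatic adaptation under the scenario's input regime, scoring
#' the decoded top-layer states after the trial's sampling cycles.
#' Deterministic given the seed.
#'
#' @param net a trained [layered_network()].
#' @param sc a [scenario()].
#' @param target per-unit target activities ([measure_target_activity()]).
#' @param config a [homeostasis_config()].
#' @param bank a [template_bank()] for quality scoring (`NULL` to skip).
#' @param classifier optional [train_classifier()] model for the
#'   classification-error series (used by `robustness_pepper`).
#' @return an object of class `experiment_result`: the adaptation trace plus
#'   the scenario.
#' @export
run_scenario <- function(net, sc, target, config = homeostasis_config(),
                         bank = NULL, classifier = NULL) {
  lam <- if (sc$kind == "ach_fluctuation")
    c(sc$lambda_low, sc$lambda_high) else 0.5
  set.seed(sc$seed)
  provider <- scenario_provider(sc, net$geometry$image_dim)
  trace <- run_adaptation(net, provider, target, config, bank = bank,
                          classifier = classifier, lambda_schedule = lam,
                          clamp_h1 = identical(sc$kind, "lesion_h1"))
  structure(list(scenario = sc, trace = trace, net = trace$net),
            class = "experiment_result")
}

#' Probe trials on a (possibly adapted) network
#'
#' Runs `n` independent trials with the given input, without any further
#' adaptation, and scores the decoded top-layer states. Used for
#' blank-input probes of adapted models, suppression probes, and
#' realignment tests.
#'
#' @param net a [layered_network()].
#' @param visible `pixels x n` matrix, a single image, or `NULL` for blank
#'   input.
#' @param n number of trials.
#' @param bank a [template_bank()].
#' @param lambda ACh balance factor.
#' @param clamp_h1 clamp the first hidden layer to zeros during the trials.
#' @param cycles sampling cycles per trial.
#' @param seed optional integer seed.
#' @return the [template_quality_batch()] data frame, one row per trial.
#' @export
probe_trials <- function(net, visible = NULL, n = 100L, bank, lambda = 0.5,
                         clamp_h1 = FALSE, cycles = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  npix <- net$layer_sizes[1]
  v <- if (is.null(visible)) matrix(0, npix, n) else
    if (is.matrix(visible) && ncol(visible) == n) visible else
      matrix(as.vector(visible), npix, n)
  blk <- run_trial_block(net, v, n, lambda, clamp_h1, cycles, bank)
  blk$quality
}

#' TMS-like suppression probe
#'
#' On an adapted (hallucinating) model, temporarily clamps the first hidden
#' layer to zeros for a block of trials, modelling suppression of early
#' visual cortex by TMS, and compares mean hallucination quality before,
#' during, and after the probe.
#'
#' @param net an adapted [layered_network()] (e.g. from a blindness run).
#' @param bank a [template_bank()].
#' @param n_before,n_probe,n_after trial counts for the three phases
#'   (`n_probe = 0` yields an identical before/after protocol).
#' @param visible probe input (default blank).
#' @param cycles sampling cycles per trial.
#' @param seed integer seed.
#' @return list with per-phase quality tables and a `summary` data frame of
#'   phase mean qualities.
#' @export
suppression_probe <- function(net, bank, n_before = 50L, n_probe = 50L,
                              n_after = 50L, visible = NULL, cycles = 50L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phases <- list(before = c(n_before, FALSE), during = c(n_probe, TRUE),
                 after = c(n_after, FALSE))
  out <- stats::setNames(vector("list", 3L), names(phases))
  for (ph in names(phases)) {
    n <- phases[[ph]][1]
    if (n == 0) next
    out[[ph]] <- probe_trials(net, visible, n, bank,
                              clamp_h1 = as.logical(phases[[ph]][2]),
                              cycles = cycles)
  }
  means <- vapply(names(phases), function(ph)
    if (is.null(out[[ph]])) NA_real_ else mean(pmax(out[[ph]]$quality, 0)),
    numeric(1))
  list(phases = out,
       summary = data.frame(phase = names(means), mean_quality = unname(means),
                            stringsAsFactors = FALSE))
}

#' Hallucinations under fluctuating acetylcholine
#'
#' Runs the blindness adaptation experiment with each iteration's trials
#' split between a low and a high ACh balance factor (drowsiness vs.
#' vigilance); activities are averaged over both trial types, qualities are
#' recorded separately per factor.
#'
#' @inheritParams run_scenario
#' @param lambda_low,lambda_high the two balance factors.
#' @param seed integer seed.
#' @return an `experiment_result`; per-factor quality series are available
#'   via [mean_quality_series()] with the `lambda` filter.
#' @export
ach_fluctuation <- function(net, target, config = homeostasis_config(),
                            bank = NULL, lambda_low = 0.3, lambda_high = 0.7,
                            seed = 1L) {
  run_scenario(net, scenario("ach_fluctuation", lambda_low = lambda_low,
                             lambda_high = lambda_high, seed = seed),
               target, config, bank = bank)
}

#' Contour completion across layers and ACh levels
#'
#' Presents images in which part of the object has been blanked out, runs
#' deterministic mean-field inference with the visible layer permanently
#' clamped, decodes every hidden layer, and scores completion: the fraction
#' of blanked-out object pixels whose decoded value exceeds 0.5. Filling-in
#' is expected to increase with layer depth and to decrease with the
#' balance factor (increased ACh emphasises bottom-up flow).
#'
#' @param net a trained [layered_network()].
#' @param images `pixels x n` matrix of complete object images.
#' @param blank_mask logical/0-1 vector (or matrix) marking the pixels that
#'   are blanked before presentation; completion is scored on the object
#'   pixels inside this region.
#' Mean-field inference is initialised from the deterministic bottom-up
#' pass (standard variational practice) rather than from zeros: a cold
#' start at low balance factors would never activate the upper layers, and
#' there would be nothing to feed back.
#'
#' @param lambda_grid balance factors to test.
#' @param cycles mean-field sweeps per image.
#' @return data frame with columns `lambda`, `layer`, `score` (mean over
#'   images; `NA` when an image has no blanked object pixels) and attribute
#'   `per_image` holding the full array.
#' @export
contour_completion <- function(net, images, blank_mask,
                               lambda_grid = c(0.3, 0.5, 0.7), cycles = 50L) {
  images <- as.matrix(images)
  mask <- as.vector(blank_mask) > 0
  L <- n_layers(net)
  n <- ncol(images)
  blanked <- images
  blanked[mask, ] <- 0
  up <- upward_pass(net, blanked)
  scores <- array(NA_real_, c(length(lambda_grid), L - 1L, n),
                  dimnames = list(lambda = lambda_grid,
                                  layer = 2:L, image = NULL))
  for (i in seq_along(lambda_grid)) {
    st <- network_state(net, n, visible = blanked)
    for (l in 2:L) st$layers[[l]] <- up[[l]]
    cfgmf <- sampler_config(cycles = cycles, mode = "mean-field",
                            ach_lambda = lambda_grid[i])
    res <- run_trial(net, st, cfgmf)
    for (l in 2:L) {
      dec <- decode_layer(net, res$state$layers[[l]], l)$pixels
      for (j in seq_len(n)) {
        tgt <- mask & images[, j] > 0.5   # object pixels that were blanked
        scores[i, l - 1L, j] <- if (!any(tgt)) NA_real_ else
          mean(dec[tgt, j] > 0.5)
      }
    }
  }
  out <- expand.grid(lambda = lambda_grid, layer = 2:L)
  out$score <- apply(scores, c(1, 2), mean, na.rm = TRUE)[cbind(
    match(out$lambda, lambda_grid), out$layer - 1L)]
  attr(out, "per_image") <- scores
  out
}

#' Realignment of a decoupled percept by raised ACh
#'
#' On a model whose internal representations have decoupled from a fixed
#' input (after fixed-input adaptation), modestly increasing the impact of
#' feedforward processing (`lambda > 0.5`) should reliably realign the
#' decoded top-layer percept with the actual input image, whereas at the
#' normal balance the majority of trials hallucinate other content.
#'
#' @param net the adapted [layered_network()].
#' @param input_image the clamped input image.
#' @param true_class the input's true class label (e.g.
#'   `"square_small"`).
#' @param bank a [template_bank()].
#' @param lambda raised balance factor (default 0.7).
#' @param n trials per condition.
#' @param cycles sampling cycles per trial.
#' @param seed integer seed.
#' @param quality_floor decoded states below this quality are not counted
#'   as any category (untrained/contentless representations).
#' @return list with `match_raised`, `match_normal` (fraction of trials
#'   whose decoded category matches the input), `realigned` flag
#'   (`NA` when no trial reaches the quality floor), and the per-condition
#'   tables.
#' @export
realign_probe <- function(net, input_image, true_class, bank, lambda = 0.7,
                          n = 50L, cycles = 50L, seed = NULL,
                          quality_floor = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  q_raised <- probe_trials(net, input_image, n, bank, lambda = lambda,
                           cycles = cycles)
  q_normal <- probe_trials(net, input_image, n, bank, lambda = 0.5,
                           cycles = cycles)
  frac_match <- function(q) {
    cls <- paste(q$category, q$size_class, sep = "_")
    mean(q$quality >= quality_floor & cls == true_class)
  }
  mr <- frac_match(q_raised); mn <- frac_match(q_normal)
  realigned <- if (all(pmax(q_raised$quality, 0) < quality_floor) &&
                   all(pmax(q_normal$quality, 0) < quality_floor))
    NA else mr >= 0.8 && mr > mn
  list(match_raised = mr, match_normal = mn, realigned = realigned,
       raised = q_raised, normal = q_normal)
}

#' Localisation statistics of counted hallucinations
#'
#' Counts hallucinations above a quality threshold and summarises where
#' they occur (position histogram over the image halves and centre of the
#' matched template) and which size class they belong to.
#'
#' @param quality data frame from [template_quality_batch()],
#'   [probe_trials()] or an adaptation trace's `$quality`.
#' @param image_size `c(H, W)`.
#' @param threshold count only hallucinations with quality greater than
#'   this (default 0.85).
#' @param sides template side lengths per size class (to locate centres).
#' @return list with `n_counted`, `by_size` (small/large counts),
#'   `small_large_ratio`, `frac_top` (fraction of counted positions whose
#'   template centre lies in the top half), `positions` (data frame of
#'   centres), `by_category` counts.
#' @export
localization_stats <- function(quality, image_size, threshold = 0.85,
                               sides = c(small = 6L, large = 10L)) {
  q <- quality[!is.na(quality$quality) & !quality$degenerate &
                 quality$quality > threshold, , drop = FALSE]
  if (nrow(q) == 0L)
    return(list(n_counted = 0L, by_size = c(small = 0L, large = 0L),
                small_large_ratio = NA_real_, frac_top = NA_real_,
                positions = data.frame(), by_category = integer(0)))
  side <- sides[q$size_class]
  centre_row <- q$row + (side - 1) / 2
  centre_col <- q$col + (side - 1) / 2
  cut <- ceiling(image_size[1] / 2)
  by_size <- c(small = sum(q$size_class == "small"),
               large = sum(q$size_class == "large"))
  list(n_counted = nrow(q), by_size = by_size,
       small_large_ratio = unname(by_size["small"] / max(by_size["large"], 1L)),
       frac_top = mean(centre_row <= cut),
       positions = data.frame(row = centre_row, col = centre_col,
                              size_class = q$size_class,
                              category = q$category),
       by_category = table(paste(q$category, q$size_class, sep = "_")))
}
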