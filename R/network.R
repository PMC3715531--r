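#' Layered Boltzmann machine
#'
#' Container for an L-layer Boltzmann machine with connections only between
#' adjacent layers (no lateral connections within a layer). Weight matrix
#' `weights[[l]]` connects layer `l` to layer `l + 1` and is used
#' symmetrically; `masks[[l]]` is a congruent binary matrix encoding which
#' connections are permitted (receptive fields). Entries where the mask is 0
#' are exactly 0 and are kept at 0 by every operation in the package.
#'
#' @param layer_sizes integer vector of unit counts; index 1 is the visible
#'   layer.
#' @param weights list of `length(layer_sizes) - 1` numeric matrices, entry
#'   `l` of dimension `layer_sizes[l] x layer_sizes[l + 1]`.
#' @param biases list of numeric vectors, one per layer.
#' @param masks list of binary matrices congruent to `weights`; `NULL` means
#'   all connections permitted.
#' @param geometry optional list describing the 2-D interpretation of layers
#'   (e.g. `image_dim = c(H, W)` for the visible layer and per-layer grid
#'   dimensions); used by the decoder and mask builders.
#' @param meta optional named list of provenance metadata.
#' @return an object of class `layered_network`.
#' @export
layered_network <- function(layer_sizes, weights, biases, masks = NULL,
                            geometry = NULL, meta = list()) {
  layer_sizes <- as.integer(layer_sizes)
  if (any(layer_sizes <= 0L)) stop("layer_sizes must be positive")
  L <- length(layer_sizes)
  if (L < 2L) stop("need at least a visible and one hidden layer")
  if (length(weights) != L - 1L)
    stop("number of weight matrices must equal number of layers - 1")
  if (length(biases) != L) stop("need one bias vector per layer")
  if (is.null(masks))
    masks <- lapply(weights, function(w) matrix(1, nrow(w), ncol(w)))
  if (length(masks) != L - 1L) stop("need one mask per weight matrix")
  for (l in seq_len(L - 1L)) {
    w <- weights[[l]]
    if (!all(dim(w) == c(layer_sizes[l], layer_sizes[l + 1L])))
      stop(sprintf("weights[[%d]] has dimensions inconsistent with layer_sizes", l))
    if (!all(dim(masks[[l]]) == dim(w)))
      stop(sprintf("masks[[%d]] not congruent with weights[[%d]]", l, l))
    if (!all(masks[[l]] %in% c(0, 1)))
      stop("mask entries must be 0 or 1")
    if (any(w[masks[[l]] == 0] != 0))
      stop(sprintf("weights[[%d]] has nonzero entries where the mask is 0", l))
    if (length(biases[[l]]) != layer_sizes[l])
      stop(sprintf("biases[[%d]] has wrong length", l))
  }
  if (length(biases[[L]]) != layer_sizes[L]) stop("topmost bias has wrong length")
  structure(list(layer_sizes = layer_sizes,
                 weights = lapply(weights, unname),
                 biases = lapply(biases, unname),
                 masks = lapply(masks, unname),
                 geometry = geometry, meta = meta),
            class = "layered_network")
}

#' @export
print.layered_network <- function(x, ...) {
  cat("Layered Boltzmann machine\n")
  cat("  layers:", paste(x$layer_sizes, collapse = " - "), "\n")
  dens <- vapply(x$masks, mean, numeric(1))
  cat("  connection density:", paste(sprintf("%.2f", dens), collapse = ", "), "\n")
  if (!is.null(x$geometry$image_dim))
    cat("  image:", paste(x$geometry$image_dim, collapse = "x"), "\n")
  invisible(x)
}

n_layers <- function(net) length(net$layer_sizes)

n_hidden_units <- function(net) sum(net$layer_sizes[-1L])

#' Per-layer network state
#'
#' Holds the unit states of every layer, for one or more parallel chains
#' (trials), plus per-layer clamping flags. Each element of `layers` is a
#' `layer_sizes[l] x n_chains` matrix. Visible states may be real-valued in
#' \[0, 1\] when clamped to grey-scale input; hidden states are binary in
#' stochastic mode and probabilities in \[0, 1\] in mean-field mode. A layer
#' flagged as clamped is never altered by a sampling or mean-field sweep.
#'
#' @param net a [layered_network()].
#' @param n_chains number of parallel chains (trials).
#' @param visible optional visible-layer content: a vector (recycled across
#'   chains) or a `layer_sizes[1] x n_chains` matrix. Supplying it clamps the
#'   visible layer unless `clamp_visible = FALSE`.
#' @param clamp_visible whether the visible layer is clamped.
#' @param clamped optional full logical vector of per-layer clamping flags,
#'   overriding `clamp_visible`.
#' @param init initialisation rule for the remaining layers: `"zero"` (the
#'   default; trials start from all-zero hidden states) or `"random"`
#'   (i.i.d. Bernoulli(0.5)).
#' @return an object of class `network_state`.
#' @export
network_state <- function(net, n_chains = 1L, visible = NULL,
                          clamp_visible = !is.null(visible),
                          clamped = NULL, init = c("zero", "random")) {
  init <- match.arg(init)
  L <- n_layers(net)
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    n <- net$layer_sizes[l]
    layers[[l]] <- if (init == "zero") matrix(0, n, n_chains) else
      matrix(stats::rbinom(n * n_chains, 1L, 0.5), n, n_chains)
  }
  if (!is.null(visible)) {
    v <- if (is.matrix(visible)) visible else
      matrix(visible, net$layer_sizes[1L], n_chains)
    if (nrow(v) != net$layer_sizes[1L] || ncol(v) != n_chains)
      stop("visible has wrong dimensions")
    if (any(v < 0 | v > 1)) stop("visible values must lie in [0, 1]")
    layers[[1L]] <- v
  }
  if (is.null(clamped)) {
    clamped <- rep(FALSE, L)
    clamped[1L] <- isTRUE(clamp_visible)
  }
  if (length(clamped) != L) stop("clamped must have one flag per layer")
  structure(list(layers = layers, clamped = as.logical(clamped)),
            class = "network_state")
}

#' Clamp a layer of a network state
#'
#' Fixes a layer to given values (e.g. a hidden layer to zeros, modelling a
#' lesion or TMS-like suppression) so that sweeps leave it untouched.
#'
#' @param state a [network_state()].
#' @param layer layer index (1 = visible).
#' @param values vector or matrix of states; defaults to all zeros.
#' @return the modified state.
#' @export
clamp_layer <- function(state, layer, values = 0) {
  n <- nrow(state$layers[[layer]]); k <- ncol(state$layers[[layer]])
  state$layers[[layer]] <- if (is.matrix(values)) values else matrix(values, n, k)
  state$clamped[layer] <- TRUE
  state
}

#' Sampler configuration
#'
#' @param cycles number of sampling cycles per trial (default 50, the trial
#'   length used throughout the experiments).
#' @param init initialisation rule for unclamped layers at the start of a
#'   trial; hidden states are initialised to zero by default.
#' @param mode `"stochastic"` block Gibbs sampling or `"mean-field"`
#'   deterministic propagation of activation probabilities.
#' @param ach_lambda acetylcholine balance factor in \[0, 1\]; 0.5 is the
#'   normal level and recovers standard sampling, larger values emphasise
#'   feedforward (bottom-up) input at intermediate hidden layers.
#' @param rng_seed optional integer seed applied before a trial.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(cycles = 50L, init = c("zero", "random"),
                           mode = c("stochastic", "mean-field"),
                           ach_lambda = 0.5, rng_seed = NULL) {
  init <- match.arg(init); mode <- match.arg(mode)
  cycles <- as.integer(cycles)
  if (cycles < 1L) stop("cycles must be >= 1")
  if (ach_lambda < 0 || ach_lambda > 1) stop("ach_lambda must lie in [0, 1]")
  structure(list(cycles = cycles, init = init, mode = mode,
                 ach_lambda = ach_lambda, rng_seed = rng_seed),
            class = "sampler_config")
}

CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file container (RDS serialisation) holding the
#' layer sizes, weights, biases, masks, geometry, and a metadata block with a
#' format version and training provenance. `load_checkpoint()` rejects files
#' whose format version does not match the one this package writes.
#'
#' @param net a [layered_network()].
#' @param path file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the restored [layered_network()].
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "layered_network"))
  payload <- list(format_version = CHECKPOINT_VERSION,
                  layer_sizes = net$layer_sizes, weights = net$weights,
                  biases = net$biases, masks = net$masks,
                  geometry = net$geometry, meta = net$meta,
                  written = format(Sys.time(), tz = "UTC"))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (!identical(as.integer(payload$format_version), CHECKPOINT_VERSION))
    stop(sprintf("checkpoint format version %s not supported (expected %d)",
                 payload$format_version, CHECKPOINT_VERSION))
  layered_network(payload$layer_sizes, payload$weights, payload$biases,
                  payload$masks, geometry = payload$geometry,
                  meta = payload$meta)
}
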