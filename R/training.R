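#' Training configuration
#'
#' Hyper-parameters for layer-wise RBM training. Defaults follow standard
#' practice for binary RBMs at this scale: 30 epochs per layer, 1-step
#' contrastive divergence (5-step persistent CD is the setting used for
#' handwritten digits), learning rate 0.05, minibatches of 100, weight decay
#' 2e-4, and all biases initialised to a negative value (-4) before training
#' to encourage sparse representations.
#'
#' @param epochs passes through the training data per layer.
#' @param cd_steps number of alternating block-Gibbs steps in the negative
#'   phase (CD-k).
#' @param persistent use persistent chains for the negative phase (PCD).
#' @param learning_rate positive step size.
#' @param minibatch_size minibatch size.
#' @param weight_decay non-negative L2 penalty on weights.
#' @param init_bias negative initial bias for all units.
#' @param weight_sd standard deviation of the zero-mean Gaussian weight
#'   initialisation.
#' @param upper_input `"probs"` to train each upper RBM on the activation
#'   probabilities of the trained layer below (lower variance; the default)
#'   or `"samples"` for binary samples.
#' @param sparsity_target optional target activity for a homeostatic
#'   regulariser applied during training itself; `NULL` (the default)
#'   disables it, matching the main experiments, which adapt only after
#'   training.
#' @param sparsity_rate rate of the training-time homeostatic regulariser.
#' @param rng_seed optional integer seed.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, cd_steps = 1L, persistent = FALSE,
                         learning_rate = 0.05, minibatch_size = 100L,
                         weight_decay = 2e-4, init_bias = -4,
                         weight_sd = 0.01, upper_input = c("probs", "samples"),
                         sparsity_target = NULL, sparsity_rate = 0.01,
                         rng_seed = NULL) {
  upper_input <- match.arg(upper_input)
  if (epochs < 0L) stop("epochs must be >= 0")
  if (cd_steps < 1L) stop("cd_steps must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (weight_decay < 0) stop("weight_decay must be non-negative")
  structure(list(epochs = as.integer(epochs), cd_steps = as.integer(cd_steps),
                 persistent = isTRUE(persistent),
                 learning_rate = learning_rate,
                 minibatch_size = as.integer(minibatch_size),
                 weight_decay = weight_decay, init_bias = init_bias,
                 weight_sd = weight_sd, upper_input = upper_input,
                 sparsity_target = sparsity_target,
                 sparsity_rate = sparsity_rate, rng_seed = rng_seed),
            class = "train_config")
}

#' Receptive-field specification
#'
#' Square patch side length (in lower-layer grid units) for each hidden
#' layer; `NA` means a global (all-to-all) field. The topmost hidden layer
#' always receives a global field.
#'
#' @param patch_sides numeric vector, one entry per hidden layer; the last
#'   entry is coerced to `NA` (global).
#' @return an object of class `rf_spec`.
#' @export
rf_spec <- function(patch_sides) {
  patch_sides <- as.numeric(patch_sides)
  if (any(!is.na(patch_sides) & patch_sides < 1)) stop("patch sides must be >= 1")
  patch_sides[length(patch_sides)] <- NA_real_
  structure(list(patch_sides = patch_sides), class = "rf_spec")
}

#' Build a localised receptive-field mask
#'
#' Upper-layer units are laid out on an evenly spaced square grid over the
#' lower layer's 2-D grid; each connects to the square patch of side
#' `patch_side` centred at its grid position, clipped at the borders. The
#' upper unit count must be a perfect square so the grid layout is defined.
#'
#' @param lower_dim integer `c(rows, cols)` extent of the lower layer's grid;
#'   units are indexed column-major (R matrix order).
#' @param upper_count number of upper-layer units (a perfect square).
#' @param patch_side side of the square patch; `NA` yields a global
#'   (all-ones) mask.
#' @return a binary `prod(lower_dim) x upper_count` mask matrix.
#' @export
make_rf_mask <- function(lower_dim, upper_count, patch_side) {
  nl <- prod(lower_dim)
  if (is.na(patch_side)) return(matrix(1, nl, upper_count))
  if (patch_side > min(lower_dim))
    stop("patch_side exceeds the lower layer's grid extent")
  g <- sqrt(upper_count)
  if (g != round(g))
    stop("upper_count must be a perfect square for a grid layout")
  g <- as.integer(g)
  # grid centres evenly spaced over the lower extent
  centres_r <- (seq_len(g) - 0.5) / g * lower_dim[1] + 0.5
  centres_c <- (seq_len(g) - 0.5) / g * lower_dim[2] + 0.5
  half <- (patch_side - 1) / 2
  mask <- matrix(0, nl, upper_count)
  rows <- matrix(seq_len(lower_dim[1]), lower_dim[1], lower_dim[2])
  cols <- matrix(rep(seq_len(lower_dim[2]), each = lower_dim[1]),
                 lower_dim[1], lower_dim[2])
  u <- 0L
  for (jc in seq_len(g)) {
    for (ir in seq_len(g)) {
      u <- u + 1L
      r0 <- round(centres_r[ir] - half); c0 <- round(centres_c[jc] - half)
      r1 <- r0 + patch_side - 1; c1 <- c0 + patch_side - 1
      # clip at image borders, keeping the patch size where possible
      if (r0 < 1) { r1 <- r1 + (1 - r0); r0 <- 1 }
      if (c0 < 1) { c1 <- c1 + (1 - c0); c0 <- 1 }
      if (r1 > lower_dim[1]) { r0 <- r0 - (r1 - lower_dim[1]); r1 <- lower_dim[1] }
      if (c1 > lower_dim[2]) { c0 <- c0 - (c1 - lower_dim[2]); c1 <- lower_dim[2] }
      sel <- rows >= max(1, r0) & rows <= r1 & cols >= max(1, c0) & cols <= c1
      mask[as.vector(sel), u] <- 1
    }
  }
  mask
}

#' Initialise a layered network
#'
#' Weights are small zero-mean Gaussian values under the receptive-field
#' mask and exactly zero elsewhere; every bias equals `cfg$init_bias`
#' (negative before training, encouraging sparse representations).
#' Reproducible given `cfg$rng_seed`.
#'
#' @param layer_sizes unit counts, visible first.
#' @param rf an [rf_spec()] (one patch side per hidden layer).
#' @param cfg a [train_config()].
#' @param image_dim `c(H, W)` grid interpretation of the visible layer.
#' @return a [layered_network()].
#' @export
init_network <- function(layer_sizes, rf, cfg = train_config(),
                         image_dim = NULL) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  L <- length(layer_sizes)
  if (is.null(image_dim)) {
    side <- sqrt(layer_sizes[1])
    if (side != round(side)) stop("image_dim required for non-square visible layer")
    image_dim <- c(side, side)
  }
  if (length(rf$patch_sides) != L - 1L)
    stop("rf must give one patch side per hidden layer")
  grids <- vector("list", L)
  grids[[1L]] <- as.integer(image_dim)
  for (l in 2:L) {
    g <- sqrt(layer_sizes[l])
    grids[[l]] <- if (g == round(g)) c(g, g) else c(layer_sizes[l], 1L)
  }
  masks <- weights <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    masks[[l]] <- make_rf_mask(grids[[l]], layer_sizes[l + 1L],
                               rf$patch_sides[l])
    weights[[l]] <- masks[[l]] *
      matrix(stats::rnorm(layer_sizes[l] * layer_sizes[l + 1L], 0, cfg$weight_sd),
             layer_sizes[l], layer_sizes[l + 1L])
  }
  biases <- lapply(layer_sizes, function(n) rep(cfg$init_bias, n))
  layered_network(layer_sizes, weights, biases, masks,
                  geometry = list(image_dim = as.integer(image_dim),
                                  grids = grids),
                  meta = list(trained = FALSE))
}

#' A layer-pair (RBM) view
#'
#' Extracts the two-layer restricted Boltzmann machine formed by layers
#' `layer` and `layer + 1` of a network: weights, both bias vectors and the
#' mask. Used as the unit of layer-wise training.
#'
#' @param net a [layered_network()].
#' @param layer index of the lower layer of the pair.
#' @return an object of class `rbm`.
#' @export
rbm_view <- function(net, layer, f_vis = 1, f_hid = 1) {
  structure(list(W = net$weights[[layer]], b_vis = net$biases[[layer]],
                 b_hid = net$biases[[layer + 1L]], mask = net$masks[[layer]],
                 f_vis = f_vis, f_hid = f_hid),
            class = "rbm")
}

# input factors f_vis/f_hid implement the doubled-input pre-training
# correction for the end pairs of a stack: a layer that will receive both
# bottom-up and top-down drive in the composed machine is trained expecting
# twice the drive a single direction provides
rbm_hidden_probs <- function(rbm, v) {
  f <- if (is.null(rbm$f_hid)) 1 else rbm$f_hid
  activation_prob(f * crossprod(rbm$W, v) + rbm$b_hid)
}

rbm_visible_probs <- function(rbm, h) {
  f <- if (is.null(rbm$f_vis)) 1 else rbm$f_vis
  activation_prob(f * (rbm$W %*% h) + rbm$b_vis)
}

sample_bernoulli <- function(p) {
  (matrix(stats::runif(length(p)), nrow(p)) < p) + 0
}

#' One contrastive-divergence parameter update
#'
#' Positive phase: hidden activation probabilities given the data. Negative
#' phase: `cfg$cd_steps` alternating block-Gibbs steps starting from the
#' data (CD) or from the supplied persistent chains (PCD). The gradient is
#' the difference of positive- and negative-phase correlation averages,
#' applied with the learning rate and weight decay and re-masked so that
#' entries outside the receptive fields stay exactly zero.
#'
#' @param rbm an [rbm_view()] (list with `W`, `b_vis`, `b_hid`, `mask`).
#' @param minibatch `visible_units x batch` matrix (binary or probabilities).
#' @param cfg a [train_config()].
#' @param chains optional persistent negative-phase visible states.
#' @return a list with the updated `rbm` and the negative-phase `chains`.
#' @export
cd_update <- function(rbm, minibatch, cfg = train_config(), chains = NULL) {
  if (nrow(minibatch) != nrow(rbm$W))
    stop("minibatch rows do not match the visible size of the layer pair")
  nb <- ncol(minibatch)
  ph <- rbm_hidden_probs(rbm, minibatch)
  # negative phase
  if (cfg$persistent && !is.null(chains)) {
    v_neg <- chains
    h <- sample_bernoulli(rbm_hidden_probs(rbm, v_neg))
  } else {
    h <- sample_bernoulli(ph)
  }
  for (k in seq_len(cfg$cd_steps)) {
    v_neg <- sample_bernoulli(rbm_visible_probs(rbm, h))
    ph_neg <- rbm_hidden_probs(rbm, v_neg)
    h <- sample_bernoulli(ph_neg)
  }
  dW <- (minibatch %*% t(ph) - v_neg %*% t(ph_neg)) / nb
  db_vis <- rowMeans(minibatch) - rowMeans(v_neg)
  db_hid <- rowMeans(ph) - rowMeans(ph_neg)
  rbm$W <- rbm$mask * (rbm$W + cfg$learning_rate * (dW - cfg$weight_decay * rbm$W))
  rbm$b_vis <- rbm$b_vis + cfg$learning_rate * db_vis
  rbm$b_hid <- rbm$b_hid + cfg$learning_rate * db_hid
  if (!is.null(cfg$sparsity_target))
    rbm$b_hid <- rbm$b_hid + cfg$sparsity_rate * (cfg$sparsity_target - rowMeans(ph))
  list(rbm = rbm, chains = v_neg)
}

#' Exact log-likelihood of an RBM (enumeration oracle)
#'
#' Computes the average log-likelihood of a data matrix under a small RBM by
#' enumerating the partition function; feasible for a few dozen total units.
#'
#' @param rbm an [rbm_view()].
#' @param data `visible x n` matrix of binary data.
#' @return mean log-likelihood.
#' @export
rbm_exact_loglik <- function(rbm, data) {
  nh <- length(rbm$b_hid)
  if (nh > 20L) stop("enumeration limited to <= 20 hidden units")
  # free energy F(v) = -b_vis'v - sum_j softplus(b_hid_j + (W'v)_j)
  fe <- function(v) {
    -colSums(v * rbm$b_vis) - colSums(log1p(exp(crossprod(rbm$W, v) + rbm$b_hid)))
  }
  nv <- length(rbm$b_vis)
  if (nv > 20L) stop("enumeration limited to <= 20 visible units")
  M <- 2L^nv
  V <- matrix(0, nv, M)
  idx <- 0:(M - 1)
  for (j in seq_len(nv)) V[j, ] <- bitwAnd(idx %/% 2L^(j - 1L), 1L)
  fall <- fe(V)
  m <- max(-fall)
  logZ <- m + log(sum(exp(-fall - m)))
  mean(-fe(data)) - logZ
}

#' Exact log-likelihood gradient of an RBM (enumeration oracle)
#'
#' Data expectation minus model expectation of the sufficient statistics,
#' with the model expectation computed by full enumeration. Independent of
#' the sampler; used to validate contrastive-divergence updates.
#'
#' @inheritParams rbm_exact_loglik
#' @return list with `dW`, `db_vis`, `db_hid`.
#' @export
rbm_exact_gradient <- function(rbm, data) {
  nv <- length(rbm$b_vis)
  if (nv > 20L) stop("enumeration limited to <= 20 visible units")
  M <- 2L^nv
  V <- matrix(0, nv, M)
  idx <- 0:(M - 1)
  for (j in seq_len(nv)) V[j, ] <- bitwAnd(idx %/% 2L^(j - 1L), 1L)
  fall <- -colSums(V * rbm$b_vis) -
    colSums(log1p(exp(crossprod(rbm$W, V) + rbm$b_hid)))
  m <- max(-fall)
  p <- exp(-fall - m); p <- p / sum(p)
  ph_all <- rbm_hidden_probs(rbm, V)
  ph_dat <- rbm_hidden_probs(rbm, data)
  n <- ncol(data)
  list(dW = data %*% t(ph_dat) / n - V %*% (t(ph_all) * p),
       db_vis = rowMeans(data) - as.vector(V %*% p),
       db_hid = rowMeans(ph_dat) - as.vector(ph_all %*% p))
}

#' Layer-wise pre-training of the full network
#'
#' Treating each pair of adjacent layers as its own RBM, trains the bottom
#' RBM on the data and then each higher RBM on the activation probabilities
#' (or samples, per `cfg$upper_input`) of the trained layer below, composing
#' the stack into one network. No further joint training is performed after
#' the layer-wise pre-training.
#'
#' Each pair is trained with the doubled-input correction of the original
#' deep-Boltzmann-machine pre-training recipe: the bottom pair's hidden side
#' and the top pair's visible side are trained expecting doubled drive (those
#' layers will receive input from both directions in the composed machine),
#' and intermediate pairs are trained normally and composed with halved
#' weights. Without these corrections the composed machine over-drives its
#' units and inference fails to track the input.
#'
#' @param data `pixels x images` matrix (values in \[0, 1\]) or a
#'   [shapes_dataset].
#' @param layer_sizes unit counts, visible first.
#' @param rf an [rf_spec()].
#' @param cfg a single [train_config()] used for every layer, or a list with
#'   one config per layer pair.
#' @param image_dim `c(H, W)`; taken from a dataset argument if available.
#' @param verbose print per-epoch reconstruction error.
#' @return a trained [layered_network()]; per-layer reconstruction-error
#'   curves are attached as `meta$recon_error`.
#' @export
layerwise_pretrain <- function(data, layer_sizes, rf, cfg = train_config(),
                               image_dim = NULL, verbose = FALSE) {
  if (inherits(data, "shapes_dataset")) {
    image_dim <- data$image_size
    data <- data$images
  }
  if (is.null(dim(data)) || ncol(data) == 0L) stop("empty training data")
  if (nrow(data) != layer_sizes[1]) stop("data does not match the visible size")
  cfgs <- if (inherits(cfg, "train_config"))
    rep(list(cfg), length(layer_sizes) - 1L) else cfg
  net <- init_network(layer_sizes, rf, cfgs[[1L]], image_dim)
  input <- data
  np <- length(layer_sizes) - 1L
  recon <- vector("list", np)
  for (l in seq_len(np)) {
    cfg_l <- cfgs[[l]]
    f_hid <- if (np > 1L && l == 1L) 2 else 1
    f_vis <- if (np > 1L && l == np) 2 else 1
    rbm <- rbm_view(net, l, f_vis = f_vis, f_hid = f_hid)
    n <- ncol(input)
    chains <- NULL
    errs <- numeric(cfg_l$epochs)
    for (ep in seq_len(cfg_l$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg_l$minibatch_size)
      for (s in starts) {
        mb <- input[, ord[s:min(s + cfg_l$minibatch_size - 1L, n)], drop = FALSE]
        upd <- cd_update(rbm, mb, cfg_l, chains)
        rbm <- upd$rbm
        if (cfg_l$persistent) chains <- upd$chains
      }
      rec <- rbm_visible_probs(rbm, rbm_hidden_probs(rbm, input))
      errs[ep] <- mean((rec - input)^2)
      if (verbose)
        message(sprintf("layer %d epoch %d: reconstruction MSE %.5f", l, ep, errs[ep]))
    }
    recon[[l]] <- errs
    intermediate <- np > 1L && l > 1L && l < np
    net$weights[[l]] <- if (intermediate) rbm$W / 2 else rbm$W
    net$biases[[l]] <- rbm$b_vis
    net$biases[[l + 1L]] <- rbm$b_hid
    up <- rbm_hidden_probs(rbm, input)
    input <- if (cfg_l$upper_input == "probs") up else sample_bernoulli(up)
  }
  net$meta$trained <- TRUE
  net$meta$recon_error <- recon
  net
}

#' Deterministic bottom-up pass
#'
#' Propagates activation probabilities upward layer by layer, each layer
#' computed from the layer below only (the composition used when feeding a
#' trained layer's representation to the classifier). By default the
#' weights are doubled at every step except the one into the topmost layer,
#' compensating for the missing top-down input exactly as each layer pair
#' was trained (the topmost layer never receives top-down input, so its
#' step is not doubled).
#'
#' @param net a [layered_network()].
#' @param visible `pixels x n` matrix.
#' @param to_layer highest layer to compute (default: topmost).
#' @param double_weights apply the doubling compensation.
#' @return list of per-layer probability matrices (index = layer).
#' @export
upward_pass <- function(net, visible, to_layer = n_layers(net),
                        double_weights = TRUE) {
  acts <- vector("list", to_layer)
  acts[[1L]] <- as.matrix(visible)
  for (l in 2:to_layer) {
    f <- if (double_weights && l < n_layers(net)) 2 else 1
    acts[[l]] <- activation_prob(f * crossprod(net$weights[[l - 1L]], acts[[l - 1L]]) +
                                   net$biases[[l]])
  }
  acts
}
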