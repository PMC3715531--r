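#' Logistic activation probability
#'
#' Probability for a binary unit to switch on given its total input,
#' `1 / (1 + exp(-x))`. Saturates numerically for extreme inputs.
#'
#' @param total_input numeric vector/matrix of summed inputs.
#' @return values in \[0, 1\] of the same shape.
#' @export
activation_prob <- function(total_input) {
  1 / (1 + exp(-total_input))
}

#' Total input to units of a layer
#'
#' Sum over all connected units in the adjacent layers of weight times state,
#' plus the bias: the visible layer receives only top-down input, the topmost
#' layer only bottom-up input, and intermediate layers both.
#'
#' @param net a [layered_network()].
#' @param state a [network_state()].
#' @param layer layer index (1 = visible).
#' @param unit optional unit index; if `NULL` the inputs of all units in the
#'   layer are returned (a `units x chains` matrix, dropped to a vector for a
#'   single chain).
#' @return total input value(s).
#' @export
total_input <- function(net, state, layer, unit = NULL) {
  L <- n_layers(net)
  if (layer < 1L || layer > L) stop("layer index out of range")
  x <- matrix(net$biases[[layer]], net$layer_sizes[layer],
              ncol(state$layers[[layer]]))
  if (layer > 1L)
    x <- x + crossprod(net$weights[[layer - 1L]], state$layers[[layer - 1L]])
  if (layer < L)
    x <- x + net$weights[[layer]] %*% state$layers[[layer + 1L]]
  if (!is.null(unit)) {
    if (unit < 1L || unit > net$layer_sizes[layer]) stop("unit index out of range")
    x <- x[unit, , drop = TRUE]
  } else if (ncol(x) == 1L) {
    x <- drop(x)
  }
  x
}

#' Acetylcholine-balanced input to an intermediate hidden layer
#'
#' Interpolates between feedforward and feedback drive with a balance factor
#' `lam`: the input is `2 lam` times the bottom-up weighted sum plus
#' `2 (1 - lam)` times the top-down weighted sum, plus the bias. `lam = 0.5`
#' reduces exactly to [total_input()] (the normal sampling mode); `lam > 0.5`
#' models increased acetylcholine levels, i.e. increased feedforward flow of
#' information; at `lam = 1` inference becomes a doubled-weight feedforward
#' pass, as in a deep belief network.
#'
#' @inheritParams total_input
#' @param lam balance factor in \[0, 1\].
#' @return input value(s), shaped as in [total_input()].
#' @export
balanced_input <- function(net, state, layer, lam) {
  L <- n_layers(net)
  if (layer <= 1L || layer >= L)
    stop("balanced_input applies only to intermediate hidden layers")
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  bu <- crossprod(net$weights[[layer - 1L]], state$layers[[layer - 1L]])
  td <- net$weights[[layer]] %*% state$layers[[layer + 1L]]
  x <- 2 * lam * bu + 2 * (1 - lam) * td + net$biases[[layer]]
  if (ncol(x) == 1L) x <- drop(x)
  x
}

# Conditional input of a layer, routing intermediate hidden layers through the
# ACh balance. At lam = 0.5 this is algebraically identical to total_input for
# every layer, so the balanced path is the single code path used everywhere.
layer_conditional_input <- function(net, state, layer, lam) {
  L <- n_layers(net)
  b <- net$biases[[layer]]
  if (layer == 1L) {
    net$weights[[1L]] %*% state$layers[[2L]] + b
  } else if (layer == L) {
    crossprod(net$weights[[L - 1L]], state$layers[[L - 1L]]) + b
  } else {
    bu <- crossprod(net$weights[[layer - 1L]], state$layers[[layer - 1L]])
    td <- net$weights[[layer]] %*% state$layers[[layer + 1L]]
    if (lam == 0.5) bu + td + b else 2 * lam * bu + 2 * (1 - lam) * td + b
  }
}

#' One block-Gibbs sampling cycle
#'
#' Performs one full sampling cycle: every unclamped layer, visited in
#' bottom-up order (visible first if unclamped, then each hidden layer up to
#' the top), has all of its units sampled in parallel from their conditional
#' probabilities. Block updates are valid because there are no lateral
#' connections within a layer. Intermediate hidden layers use the
#' ACh-balanced conditional ([balanced_input()]); at `ach_lambda = 0.5` this
#' is exactly the standard conditional. Clamped layers are returned
#' unchanged.
#'
#' @inheritParams total_input
#' @param config a [sampler_config()].
#' @return the updated [network_state()].
#' @export
gibbs_sweep <- function(net, state, config = sampler_config()) {
  if (all(state$clamped)) stop("all layers are clamped; nothing to sample")
  lam <- config$ach_lambda
  for (l in seq_len(n_layers(net))) {
    if (state$clamped[l]) next
    p <- activation_prob(layer_conditional_input(net, state, l, lam))
    p <- as.matrix(p)
    state$layers[[l]] <- (matrix(stats::runif(length(p)), nrow(p)) < p) + 0
  }
  state
}

#' One deterministic mean-field cycle
#'
#' As [gibbs_sweep()], but each unclamped layer is set to its conditional
#' activation probabilities instead of binary samples, propagating activities
#' deterministically. On a fixed input, repeated sweeps converge to a fixed
#' point.
#'
#' @inheritParams gibbs_sweep
#' @return the updated [network_state()].
#' @export
mean_field_sweep <- function(net, state, config = sampler_config(mode = "mean-field")) {
  if (all(state$clamped)) stop("all layers are clamped; nothing to update")
  lam <- config$ach_lambda
  for (l in seq_len(n_layers(net))) {
    if (state$clamped[l]) next
    p <- activation_prob(layer_conditional_input(net, state, l, lam))
    state$layers[[l]] <- as.matrix(p)
  }
  state
}

#' Run a trial of repeated sampling cycles
#'
#' Runs `config$cycles` sweeps (stochastic or mean-field according to
#' `config$mode`) from the given state, optionally accumulating each hidden
#' unit's activation probability at every update (the per-unit "activity"
#' used by the homeostasis machinery) and optionally recording the state
#' after every cycle.
#'
#' @inheritParams gibbs_sweep
#' @param record_activity accumulate mean activation probabilities per hidden
#'   unit (averaged over cycles; one column per chain).
#' @param record_trace record per-cycle layer states (a list of length
#'   `cycles`, each a list of layer matrices).
#' @return a list with elements `state` (final state), `activity` (list over
#'   layers 2..L of `units x chains` mean-probability matrices, or `NULL`),
#'   and `trace` (or `NULL`).
#' @export
run_trial <- function(net, state, config = sampler_config(),
                      record_activity = FALSE, record_trace = FALSE) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  if (all(state$clamped)) stop("all layers are clamped; nothing to sample")
  L <- n_layers(net)
  lam <- config$ach_lambda
  stochastic <- config$mode == "stochastic"
  nc <- ncol(state$layers[[1L]])
  act <- NULL
  if (record_activity)
    act <- lapply(2:L, function(l) matrix(0, net$layer_sizes[l], nc))
  trace <- if (record_trace) vector("list", config$cycles) else NULL
  for (cyc in seq_len(config$cycles)) {
    for (l in seq_len(L)) {
      if (state$clamped[l]) next
      p <- as.matrix(activation_prob(layer_conditional_input(net, state, l, lam)))
      state$layers[[l]] <- if (stochastic)
        (matrix(stats::runif(length(p)), nrow(p)) < p) + 0 else p
      if (record_activity && l > 1L)
        act[[l - 1L]] <- act[[l - 1L]] + p
    }
    if (record_trace) trace[[cyc]] <- state$layers
  }
  if (record_activity) {
    # clamped hidden layers count their (fixed) states as their activity
    for (l in 2:L) {
      if (state$clamped[l]) act[[l - 1L]] <- state$layers[[l]] * config$cycles
      act[[l - 1L]] <- act[[l - 1L]] / config$cycles
    }
  }
  list(state = state, activity = act, trace = trace)
}

#' Energy of a joint network state
#'
#' The pairwise energy `-sum_l s_l' W_l s_{l+1} - sum_l b_l' s_l` over all
#' connected pairs and all units.
#'
#' @inheritParams total_input
#' @return a numeric value per chain.
#' @export
energy <- function(net, state) {
  L <- n_layers(net)
  e <- 0
  for (l in seq_len(L)) {
    s <- state$layers[[l]]
    e <- e - colSums(s * net$biases[[l]])
    if (l < L)
      e <- e - colSums((crossprod(net$weights[[l]], s)) * state$layers[[l + 1L]])
  }
  if (length(e) == 1L) e <- unname(e)
  e
}

#' Exact Boltzmann distribution of a small network
#'
#' Enumerates all joint binary states and returns the Boltzmann distribution
#' `P(s) = exp(-E(s)) / Z` at temperature 1. This is the package's exact
#' oracle for the Gibbs sampler and is feasible only for networks with at
#' most 20 units in total.
#'
#' @param net a [layered_network()] with `sum(layer_sizes) <= 20`.
#' @return a list with `states` (a `2^N x N` binary matrix, units ordered
#'   visible-first, layer by layer), `energy`, and `prob` (normalised to sum
#'   to 1).
#' @export
exact_distribution <- function(net) {
  N <- sum(net$layer_sizes)
  if (N > 20L)
    stop("exact enumeration is limited to networks with at most 20 units")
  M <- 2L^N
  # state matrix: row i = binary expansion of i - 1, unit 1 = least significant
  states <- matrix(0L, M, N)
  idx <- 0:(M - 1)
  for (j in seq_len(N)) states[, j] <- bitwAnd(idx %/% 2L^(j - 1L), 1L)
  offs <- c(0L, cumsum(net$layer_sizes))
  E <- numeric(M)
  for (l in seq_along(net$layer_sizes)) {
    S <- states[, (offs[l] + 1L):offs[l + 1L], drop = FALSE]
    E <- E - as.vector(S %*% net$biases[[l]])
    if (l < length(net$layer_sizes)) {
      S2 <- states[, (offs[l + 1L] + 1L):offs[l + 2L], drop = FALSE]
      E <- E - rowSums((S %*% net$weights[[l]]) * S2)
    }
  }
  w <- exp(-(E - min(E)))
  list(states = states, energy = E, prob = w / sum(w))
}
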