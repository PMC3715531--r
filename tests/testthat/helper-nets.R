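# Small random networks and brute-force oracles used across test files.

random_net <- function(layer_sizes, seed = 1, w_sd = 0.8, b_sd = 0.5,
                       masks = NULL) {
  set.seed(seed)
  L <- length(layer_sizes)
  weights <- lapply(seq_len(L - 1L), function(l)
    matrix(rnorm(layer_sizes[l] * layer_sizes[l + 1L], 0, w_sd),
           layer_sizes[l], layer_sizes[l + 1L]))
  if (!is.null(masks))
    weights <- Map(function(w, m) w * m, weights, masks)
  biases <- lapply(layer_sizes, function(n) rnorm(n, 0, b_sd))
  layered_network(layer_sizes, weights, biases, masks)
}

random_state <- function(net, seed = 1, n_chains = 1) {
  set.seed(seed)
  st <- network_state(net, n_chains)
  for (l in seq_along(st$layers))
    st$layers[[l]][] <- rbinom(length(st$layers[[l]]), 1, 0.5)
  st
}

# element-by-element summation oracle for the total input of one unit
brute_total_input <- function(net, state, layer, unit, chain = 1) {
  x <- net$biases[[layer]][unit]
  if (layer > 1) {
    for (i in seq_len(net$layer_sizes[layer - 1]))
      x <- x + net$weights[[layer - 1]][i, unit] * state$layers[[layer - 1]][i, chain]
  }
  if (layer < length(net$layer_sizes)) {
    for (j in seq_len(net$layer_sizes[layer + 1]))
      x <- x + net$weights[[layer]][unit, j] * state$layers[[layer + 1]][j, chain]
  }
  x
}

# double-loop energy oracle
brute_energy <- function(net, state, chain = 1) {
  e <- 0
  L <- length(net$layer_sizes)
  for (l in seq_len(L)) {
    s <- state$layers[[l]][, chain]
    e <- e - sum(net$biases[[l]] * s)
    if (l < L) {
      s2 <- state$layers[[l + 1]][, chain]
      for (i in seq_along(s)) for (j in seq_along(s2))
        e <- e - net$weights[[l]][i, j] * s[i] * s2[j]
    }
  }
  e
}

# index of a binary state vector in the exact_distribution enumeration
state_index <- function(bits) sum(bits * 2^(seq_along(bits) - 1)) + 1

# flatten a network_state (single chain) into the enumeration's unit order
flatten_state <- function(state) {
  unlist(lapply(state$layers, function(m) m[, 1]))
}
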