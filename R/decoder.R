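#' Decode hidden states into a reconstructed image
#'
#' A parameter copy of the network is used as a decoder: starting from the
#' given hidden layer's states, each successively lower layer's activation
#' probabilities are computed deterministically from the layer above only,
#' with the weights doubled to compensate for the lack of bottom-up input,
#' down to the visible layer. The visible activation probabilities are the
#' reconstructed grey-scale image. The decoder never mutates the inference
#' network.
#'
#' Doubling applies to every top-down step into a hidden layer (those
#' layers normally receive drive from both directions) but not to the final
#' step into the visible layer: the visible units only ever receive
#' top-down generative input, so their conditional needs no compensation.
#'
#' @param net a [layered_network()].
#' @param states the layer's states: a vector, or a `units x n` matrix to
#'   decode several states at once.
#' @param layer hidden layer index (>= 2; decoding the visible layer is
#'   meaningless).
#' @param cycle_index optional bookkeeping tag stored on the result.
#' @return an object of class `decoded_image`: list with `pixels` (an
#'   `H x W` matrix in \[0, 1\], or a `pixels x n` matrix for batch input),
#'   `source_layer`, `cycle_index`.
#' @export
decode_layer <- function(net, states, layer, cycle_index = NA_integer_) {
  if (layer <= 1L) stop("layer 0/1 is the visible layer; nothing to decode")
  if (layer > n_layers(net)) stop("layer index out of range")
  single <- !is.matrix(states)
  s <- if (single) matrix(states, ncol = 1L) else states
  if (nrow(s) != net$layer_sizes[layer]) stop("states do not match the layer size")
  for (l in seq(layer - 1L, 1L)) {
    f <- if (l > 1L) 2 else 1
    s <- activation_prob(f * (net$weights[[l]] %*% s) + net$biases[[l]])
  }
  pixels <- if (single && !is.null(net$geometry$image_dim))
    matrix(s, net$geometry$image_dim[1], net$geometry$image_dim[2]) else s
  structure(list(pixels = pixels, source_layer = layer,
                 cycle_index = cycle_index),
            class = "decoded_image")
}

#' Decode every recorded cycle of a trial
#'
#' Wraps [decode_layer()] over the per-cycle states recorded by
#' [run_trial()] with `record_trace = TRUE`, producing one reconstructed
#' image per cycle and per hidden layer. Deterministic given the recorded
#' states.
#'
#' @param net a [layered_network()].
#' @param trace the `trace` element of a [run_trial()] result.
#' @param chain which chain to decode when the trial ran several.
#' @return a list of [decode_layer()] results of length
#'   `cycles * (number of hidden layers)`, cycle-major.
#' @export
decode_trace <- function(net, trace, chain = 1L) {
  L <- n_layers(net)
  out <- vector("list", length(trace) * (L - 1L))
  i <- 0L
  for (cyc in seq_along(trace)) {
    for (l in 2:L) {
      i <- i + 1L
      out[[i]] <- decode_layer(net, trace[[cyc]][[l]][, chain], l,
                               cycle_index = cyc)
    }
  }
  out
}

#' Export decoded images
#'
#' `write_image_csv()` writes the pixel matrix as a plain CSV;
#' `write_montage_png()` arranges a list of images (matrices or
#' `decoded_image` objects) into a grid and writes a PNG.
#'
#' @param image a `decoded_image` or numeric matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_image_csv <- function(image, path) {
  px <- if (inherits(image, "decoded_image")) image$pixels else image
  utils::write.table(px, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_csv
#' @param images list of images for the montage.
#' @param ncol number of montage columns.
#' @export
write_montage_png <- function(images, path, ncol = ceiling(sqrt(length(images)))) {
  mats <- lapply(images, function(im)
    if (inherits(im, "decoded_image")) im$pixels else im)
  nrow_m <- ceiling(length(mats) / ncol)
  grDevices::png(path, width = 120 * ncol, height = 120 * nrow_m)
  op <- graphics::par(mfrow = c(nrow_m, ncol), mar = c(0.2, 0.2, 0.2, 0.2))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  for (m in mats)
    graphics::image(t(m[nrow(m):1, , drop = FALSE]), zlim = c(0, 1),
                    col = grDevices::gray.colors(64, 0, 1), axes = FALSE)
  invisible(path)
}
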