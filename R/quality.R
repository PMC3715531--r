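#' Shape templates
#'
#' The six class templates of the shapes corpus: the binary bounding-box
#' patch of each category at each size. Named list in the canonical class
#' order (small square, small triangle-up, small triangle-down, then the
#' large classes), the order used to break ties in template matching.
#'
#' @param sides named vector `c(small = ..., large = ...)`.
#' @return named list of binary matrices.
#' @export
shape_templates <- function(sides = c(small = 6L, large = 10L)) {
  out <- list()
  for (sc in names(sides))
    for (cat in SHAPE_CATEGORIES)
      out[[paste(cat, sc, sep = "_")]] <- shape_patch(cat, sides[[sc]])
  out
}

#' Precomputed template-matching bank
#'
#' Template matching slides every class template over the image
#' (convolution). Because the image is mean-subtracted and L2-normalised
#' once as a whole, the correlation of the image with a template placed at
#' offset p equals the inner product of the normalised image with the
#' normalised full-canvas image of that template at p. This bank precomputes
#' all placements as the rows of one matrix so that batches of images are
#' scored with a single matrix product.
#'
#' @param image_size `c(H, W)`.
#' @param templates named list of binary patch matrices ([shape_templates()]).
#' @return an object of class `template_bank`.
#' @export
template_bank <- function(image_size, templates = shape_templates()) {
  H <- image_size[1]; W <- image_size[2]; N <- H * W
  rows <- list(); meta <- list(); k <- 0L
  for (ci in seq_along(templates)) {
    patch <- templates[[ci]]
    h <- nrow(patch); w <- ncol(patch)
    if (h > H || w > W) stop("template larger than the image")
    area <- sum(patch)
    denom <- sqrt(area - area^2 / N)
    for (r0 in seq_len(H - h + 1L)) {        # row-major placement order
      for (c0 in seq_len(W - w + 1L)) {
        img <- matrix(0, H, W)
        img[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- patch
        k <- k + 1L
        rows[[k]] <- as.vector(img) / denom
        meta[[k]] <- c(ci, r0, c0)
      }
    }
  }
  meta <- do.call(rbind, meta)
  structure(list(B = matrix(unlist(rows), nrow = k, byrow = TRUE),
                 class_idx = meta[, 1], row = meta[, 2], col = meta[, 3],
                 classes = names(templates), image_size = as.integer(image_size)),
            class = "template_bank")
}

normalize_images <- function(images, eps = 1e-12) {
  x <- sweep(images, 2L, colMeans(images))
  nrm <- sqrt(colSums(x^2))
  ok <- nrm > eps
  x[, ok] <- sweep(x[, ok, drop = FALSE], 2L, nrm[ok], "/")
  list(x = x, ok = ok)
}

#' Template-matching hallucination quality
#'
#' Scores how well an image matches the learnt shape classes: the image and
#' each template are mean-subtracted and scaled to unit Euclidean norm, the
#' normalised cross-correlation is evaluated at every valid offset for every
#' template, and the overall maximum is the hallucination quality (a perfect
#' match scores exactly 1). Ties are broken by class order, then row-major
#' position. A zero-variance (constant) image has quality 0 by convention
#' and an undefined category.
#'
#' @param image numeric matrix (grey-scale values), or a `decoded_image`.
#' @param templates named list of binary patches, or a prebuilt
#'   [template_bank()].
#' @return an object of class `quality_result`: list with `quality`,
#'   `best_category` (`NA` for a degenerate image), `best_size_class`,
#'   `best_position` (`c(row, col)` of the maximising offset), `degenerate`.
#' @export
template_quality <- function(image, templates = shape_templates()) {
  if (inherits(image, "decoded_image")) image <- image$pixels
  bank <- if (inherits(templates, "template_bank")) templates else
    template_bank(dim(image), templates)
  res <- template_quality_batch(matrix(as.vector(image), ncol = 1L), bank)
  structure(list(quality = res$quality[1],
                 best_category = res$category[1],
                 best_size_class = res$size_class[1],
                 best_position = c(res$row[1], res$col[1]),
                 degenerate = res$degenerate[1]),
            class = "quality_result")
}

#' Batch template-matching quality
#'
#' Vectorised form of [template_quality()] for many images at once.
#'
#' @param images `pixels x n` matrix, one image per column.
#' @param bank a [template_bank()].
#' @param void_floor optional void-percept gate used when scoring decoded
#'   internal representations: an image none of whose grey values exceeds
#'   this floor contains no perceived content (nothing is "on"), and is
#'   scored 0 like a constant image. `NULL` (the default) disables the
#'   gate, leaving the pure contrast-invariant correlation measure.
#' @return data frame with columns `quality`, `category`, `size_class`,
#'   `row`, `col`, `degenerate`.
#' @export
template_quality_batch <- function(images, bank, void_floor = NULL) {
  nz <- normalize_images(images)
  if (!is.null(void_floor))
    nz$ok <- nz$ok & apply(images, 2L, max) > void_floor
  Q <- bank$B %*% nz$x
  best <- apply(Q, 2L, which.max)
  quality <- Q[cbind(best, seq_len(ncol(Q)))]
  cls <- bank$classes[bank$class_idx[best]]
  quality[!nz$ok] <- 0
  cls[!nz$ok] <- NA_character_
  parts <- strsplit(cls, "_(?=[^_]+$)", perl = TRUE)
  data.frame(quality = quality,
             category = vapply(parts, function(p) if (length(p)) p[1] else NA_character_,
                               character(1)),
             size_class = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                                 character(1)),
             row = ifelse(nz$ok, bank$row[best], NA_integer_),
             col = ifelse(nz$ok, bank$col[best], NA_integer_),
             degenerate = !nz$ok,
             stringsAsFactors = FALSE)
}

#' Train a label-augmented classifier model
#'
#' An independent instance of the layered model (never affected by
#' homeostasis) with a one-of-K classification unit group attached to the
#' topmost layer pair. Lower layer pairs are pre-trained layer-wise as
#' usual; the top pair is then trained jointly with the label group by
#' contrastive divergence. Classification of an image is the posterior over
#' the K labels given the representation obtained by a deterministic
#' bottom-up pass, computed exactly by free-energy enumeration over the K
#' classes.
#'
#' After the generative contrastive-divergence phase, the label pair is
#' fine-tuned for `discriminative_epochs` epochs on the exact conditional
#' log-likelihood `log P(y | pen)` (the classification-RBM gradient, which
#' is tractable because the posterior is an explicit softmax over the K
#' free energies), sharpening the posterior used as the quality measure.
#'
#' @param dataset a labelled `shapes_dataset` (or list with `images` and a
#'   `labels` data frame with a `class` column, or an integer/character
#'   label vector).
#' @param layer_sizes unit counts of the model instance, visible first.
#' @param rf an [rf_spec()].
#' @param cfg a [train_config()].
#' @param image_dim `c(H, W)`.
#' @param discriminative_epochs epochs of exact conditional-gradient
#'   fine-tuning of the label pair (0 disables).
#' @return an object of class `dbm_classifier`.
#' @export
train_classifier <- function(dataset, layer_sizes, rf, cfg = train_config(),
                             image_dim = NULL, discriminative_epochs = 10L) {
  images <- if (is.list(dataset)) dataset$images else dataset
  labels <- if (is.data.frame(dataset$labels)) dataset$labels$class else dataset$labels
  classes <- sort(unique(labels))
  K <- length(classes)
  if (K < 2L) stop("need at least two classes")
  if (inherits(dataset, "shapes_dataset")) image_dim <- dataset$image_size
  L <- length(layer_sizes)
  y <- matrix(0, K, ncol(images))
  y[cbind(match(labels, classes), seq_len(ncol(images)))] <- 1
  # feature stack: the layers below the label pair, pre-trained with the
  # usual stacking corrections; its own topmost layer is the penultimate
  # layer of the classifier
  feat_net <- layerwise_pretrain(images, layer_sizes[-L],
                                 rf_spec(utils::head(rf$patch_sides, -1L)),
                                 cfg, image_dim)
  pen <- upward_pass(feat_net, images)[[L - 1L]]
  # label-augmented top pair: [pen states; one-of-K labels] as the visible
  # side, the topmost layer as hidden, labels fully connected
  m <- layer_sizes[L - 1L]; n <- layer_sizes[L]
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed + 1L)
  mask_top <- make_rf_mask(c(m, 1L), n, NA)
  mask_aug <- rbind(mask_top, matrix(1, K, n))
  W_aug <- mask_aug * matrix(stats::rnorm((m + K) * n, 0, cfg$weight_sd), m + K, n)
  rbm <- structure(list(W = W_aug,
                        b_vis = c(rep(cfg$init_bias, m), rep(0, K)),
                        b_hid = rep(cfg$init_bias, n), mask = mask_aug),
                   class = "rbm")
  vis <- rbind(pen, y)
  nimg <- ncol(vis)
  chains <- NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(nimg)
    for (s in seq(1L, nimg, by = cfg$minibatch_size)) {
      mb <- vis[, ord[s:min(s + cfg$minibatch_size - 1L, nimg)], drop = FALSE]
      upd <- cd_update(rbm, mb, cfg, chains)
      rbm <- upd$rbm
      if (cfg$persistent) chains <- upd$chains
    }
  }
  clf <- structure(list(net = feat_net,
                        W_top = rbm$W[seq_len(m), , drop = FALSE],
                        b_top = rbm$b_hid,
                        W_lab = rbm$W[m + seq_len(K), , drop = FALSE],
                        b_lab = rbm$b_vis[m + seq_len(K)],
                        classes = classes),
                   class = "dbm_classifier")
  if (discriminative_epochs > 0L)
    clf <- discriminative_finetune(clf, pen, y, cfg, discriminative_epochs)
  clf
}

# exact conditional-gradient ascent on log P(y | pen) for the label pair
discriminative_finetune <- function(clf, pen, y, cfg, epochs) {
  K <- nrow(y); nimg <- ncol(pen)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nimg)
    for (s in seq(1L, nimg, by = cfg$minibatch_size)) {
      ix <- ord[s:min(s + cfg$minibatch_size - 1L, nimg)]
      x <- pen[, ix, drop = FALSE]; yy <- y[, ix, drop = FALSE]
      B <- ncol(x)
      base <- crossprod(clf$W_top, x) + clf$b_top
      S <- lapply(seq_len(K), function(k)
        activation_prob(base + clf$W_lab[k, ]))
      z <- do.call(rbind, lapply(seq_len(K), function(k)
        clf$b_lab[k] + colSums(log1p(exp(pmin(base + clf$W_lab[k, ], 30))) +
                                 pmax(base + clf$W_lab[k, ] - 30, 0))))
      z <- sweep(z, 2L, apply(z, 2L, max))
      P <- exp(z); P <- sweep(P, 2L, colSums(P), "/")
      D <- yy - P                           # K x B residuals
      M <- matrix(0, nrow(base), B)         # hidden-unit residual drive
      dW_lab <- matrix(0, K, nrow(base))
      for (k in seq_len(K)) {
        Mk <- S[[k]] * rep(D[k, ], each = nrow(base))
        M <- M + Mk
        dW_lab[k, ] <- rowSums(Mk) / B
      }
      lr <- cfg$learning_rate
      clf$W_lab <- clf$W_lab + lr * dW_lab
      clf$b_lab <- clf$b_lab + lr * rowMeans(D)
      clf$b_top <- clf$b_top + lr * rowSums(M) / B
      clf$W_top <- clf$W_top + lr * (x %*% t(M)) / B
    }
  }
  clf
}

#' Label posterior of the classifier
#'
#' Exact posterior over the K classes given an image: the image is
#' propagated bottom-up to the penultimate layer, and
#' `P(y = k | pen)` is computed by enumerating the K label configurations
#' of the top layer pair (free-energy softmax). Entries sum to 1.
#'
#' @param classifier a [train_classifier()] result.
#' @param images `pixels x n` matrix (or a single image matrix/vector).
#' @return `K x n` matrix of posterior probabilities.
#' @export
classifier_posterior <- function(classifier, images) {
  if (inherits(images, "decoded_image")) images <- images$pixels
  if (!is.matrix(images) || nrow(images) != classifier$net$layer_sizes[1])
    images <- matrix(as.vector(images), classifier$net$layer_sizes[1])
  pen <- upward_pass(classifier$net, images)[[n_layers(classifier$net)]]
  base <- crossprod(classifier$W_top, pen) + classifier$b_top
  K <- length(classifier$classes)
  z <- matrix(0, K, ncol(images))
  for (k in seq_len(K))
    z[k, ] <- classifier$b_lab[k] +
      colSums(log1p(exp(base + classifier$W_lab[k, ])))
  z <- sweep(z, 2L, apply(z, 2L, max))
  ez <- exp(z)
  sweep(ez, 2L, colSums(ez), "/")
}

#' Classifier-posterior quality
#'
#' The maximum of the label posterior (a measure with maximum value 1), and
#' the maximising class.
#'
#' @inheritParams classifier_posterior
#' @return data frame with `quality` and `class`, one row per image.
#' @export
classifier_quality <- function(images, classifier) {
  post <- classifier_posterior(classifier, images)
  best <- apply(post, 2L, which.max)
  data.frame(quality = post[cbind(best, seq_len(ncol(post)))],
             class = classifier$classes[best], stringsAsFactors = FALSE)
}

#' Classification error rate
#'
#' Fraction of images whose maximum-posterior class differs from the true
#' label.
#'
#' @inheritParams classifier_posterior
#' @param labels true class labels (character, matching the classifier's
#'   class names).
#' @return error rate in \[0, 1\].
#' @export
classification_error <- function(images, labels, classifier) {
  pred <- classifier_quality(images, classifier)$class
  mean(pred != labels)
}
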