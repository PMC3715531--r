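#' Shape specification
#'
#' One instance of the synthetic shapes corpus: a filled square or a filled
#' isoceles triangle (apex up or down), in one of two size classes, placed
#' at a pixel position. Category crossed with size class yields the six
#' object classes of the corpus.
#'
#' @param category `"square"`, `"triangle_up"` or `"triangle_down"`.
#' @param size_class `"small"` or `"large"`.
#' @param side bounding-box side length in pixels.
#' @param position 1-based `c(row, col)` of the bounding box's top-left
#'   corner.
#' @return an object of class `shape_spec`.
#' @export
shape_spec <- function(category = c("square", "triangle_up", "triangle_down"),
                       size_class = c("small", "large"), side,
                       position = c(1L, 1L)) {
  category <- match.arg(category)
  size_class <- match.arg(size_class)
  structure(list(category = category, size_class = size_class,
                 side = as.integer(side), position = as.integer(position)),
            class = "shape_spec")
}

SHAPE_CATEGORIES <- c("square", "triangle_up", "triangle_down")

# bounding-box patch of a shape; triangles are filled, apex up/down, with row
# width equal to the row's distance from the apex (width r at depth r)
shape_patch <- function(category, side) {
  s <- side
  patch <- matrix(0, s, s)
  if (category == "square") {
    patch[] <- 1
  } else {
    for (r in seq_len(s)) {
      w <- r
      c0 <- floor((s - w) / 2) + 1L
      patch[r, c0:(c0 + w - 1L)] <- 1
    }
    if (category == "triangle_down")
      patch <- patch[s:1, , drop = FALSE]
  }
  patch
}

#' Render a shape into a binary image
#'
#' Draws the filled shape at its position in an otherwise blank image.
#' Deterministic; errors if the shape does not lie fully inside the image.
#'
#' @param spec a [shape_spec()].
#' @param image_size `c(H, W)` in pixels.
#' @return a binary `H x W` matrix.
#' @export
render_shape <- function(spec, image_size) {
  r0 <- spec$position[1]; c0 <- spec$position[2]; s <- spec$side
  if (r0 < 1 || c0 < 1 || r0 + s - 1 > image_size[1] || c0 + s - 1 > image_size[2])
    stop("shape does not fit inside the image at that position")
  img <- matrix(0, image_size[1], image_size[2])
  img[r0:(r0 + s - 1L), c0:(c0 + s - 1L)] <- shape_patch(spec$category, s)
  img
}

new_shapes_dataset <- function(images, labels, image_size, sides) {
  structure(list(images = images, labels = labels,
                 image_size = as.integer(image_size), sides = sides),
            class = "shapes_dataset")
}

#' @export
print.shapes_dataset <- function(x, ...) {
  cat(sprintf("Shapes dataset: %d images of %dx%d pixels, %d classes\n",
              ncol(x$images), x$image_size[1], x$image_size[2],
              length(unique(x$labels$class))))
  invisible(x)
}

#' Enumerate every shape instance
#'
#' Renders every valid combination of category, size class and position
#' exactly once, covering all possible image instances of the corpus.
#' Images are stored as the columns of a `pixels x n` binary matrix
#' (column-major pixel order).
#'
#' @param image_size `c(H, W)`; the default 20 x 20 matches the package's
#'   default model geometry.
#' @param sides named vector `c(small = ..., large = ...)` of bounding-box
#'   side lengths for the two size classes.
#' @return a `shapes_dataset`: `images`, `labels` (data frame with
#'   `category`, `size_class`, `class`, `side`, `row`, `col`), `image_size`,
#'   `sides`.
#' @export
enumerate_instances <- function(image_size = c(20L, 20L),
                                sides = c(small = 6L, large = 10L)) {
  H <- image_size[1]; W <- image_size[2]
  imgs <- list(); labs <- list(); k <- 0L
  for (sc in names(sides)) {
    s <- sides[[sc]]
    for (cat in SHAPE_CATEGORIES) {
      patch <- shape_patch(cat, s)
      for (c0 in seq_len(W - s + 1L)) {
        for (r0 in seq_len(H - s + 1L)) {
          img <- matrix(0, H, W)
          img[r0:(r0 + s - 1L), c0:(c0 + s - 1L)] <- patch
          k <- k + 1L
          imgs[[k]] <- as.vector(img)
          labs[[k]] <- data.frame(category = cat, size_class = sc,
                                  class = paste(cat, sc, sep = "_"),
                                  side = s, row = r0, col = c0,
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  new_shapes_dataset(matrix(unlist(imgs), H * W, k),
                     do.call(rbind, labs), image_size, sides)
}

#' Sample a training set from the enumeration
#'
#' Draws `n` images with replacement from the full enumeration (the paper's
#' corpus covers all possible instances; a finite training set is a uniform
#' resample of them).
#'
#' @param n number of draws.
#' @param seed optional integer seed.
#' @param enumeration a pre-built [enumerate_instances()] result, or `NULL`
#'   to build one from `image_size`/`sides`.
#' @inheritParams enumerate_instances
#' @return a `shapes_dataset` of `n` images.
#' @export
sample_dataset <- function(n, seed = NULL, enumeration = NULL,
                           image_size = c(20L, 20L),
                           sides = c(small = 6L, large = 10L)) {
  if (is.null(enumeration))
    enumeration <- enumerate_instances(image_size, sides)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(ncol(enumeration$images), n, replace = TRUE)
  new_shapes_dataset(enumeration$images[, idx, drop = FALSE],
                     enumeration$labels[idx, , drop = FALSE],
                     enumeration$image_size, enumeration$sides)
}

#' Input-degradation operators
#'
#' Corruption operators modelling degraded visual input. All operators
#' preserve image dimensions and binarity. `corrupt_pepper()` forces a
#' uniformly chosen subset of `round(fraction * pixels)` pixel positions
#' (sampled without replacement, so the fraction is exact per image) to
#' black, never turning a black pixel white. `blank()` returns an all-zero
#' image. `salt_noise()` returns a fresh image with exactly
#' `round(fraction * pixels)` white pixels at uniform positions on a black
#' background. `half_blank()` zeroes the chosen half of the image; the top
#' half is rows `1 .. ceiling(H / 2)`.
#'
#' @param image binary matrix (or vector with `image_size` given).
#' @param fraction fraction of pixels affected.
#' @param seed optional integer seed.
#' @return a binary image of the same shape.
#' @export
corrupt_pepper <- function(image, fraction = 0.65, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(image)
  k <- round(fraction * n)
  if (k > 0) image[sample.int(n, k)] <- 0
  image
}

#' @rdname corrupt_pepper
#' @export
blank <- function(image) {
  image[] <- 0
  image
}

#' @rdname corrupt_pepper
#' @param image_size `c(H, W)` of the generated noise image.
#' @export
salt_noise <- function(image_size, fraction = 0.10, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(0, image_size[1], image_size[2])
  k <- round(fraction * length(img))
  if (k > 0) img[sample.int(length(img), k)] <- 1
  img
}

#' @rdname corrupt_pepper
#' @param half which half to blank, `"top"` or `"bottom"`.
#' @export
half_blank <- function(image, half = c("top", "bottom")) {
  half <- match.arg(half)
  H <- nrow(image)
  cut <- ceiling(H / 2)
  if (half == "top") image[seq_len(cut), ] <- 0
  else image[(cut + 1L):H, ] <- 0
  image
}

#' Provider returning the same image on every trial
#'
#' @param image the fixed image (matrix or vector).
#' @return a function `(n)` returning a `pixels x n` matrix of `n` copies.
#' @export
fixed_image_provider <- function(image) {
  v <- as.vector(image)
  function(n) matrix(v, length(v), n)
}

#' Load an MNIST-style IDX file pair
#'
#' Reads images and labels in the standard IDX binary format and binarises
#' pixel intensities at 0.5 (of the 0..255 range). Optional: no experiment
#' or test in the package requires these files.
#'
#' @param image_file path to an `idx3-ubyte` image file.
#' @param label_file path to an `idx1-ubyte` label file.
#' @param limit optional maximum number of images.
#' @return list with `images` (`pixels x n` binary matrix), `labels`
#'   (integer vector), `image_size`.
#' @export
load_mnist <- function(image_file, label_file, limit = NULL) {
  con <- file(image_file, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, integer(), 1, size = 4, endian = "big")
  if (magic != 2051L) stop("not an IDX image file")
  n <- readBin(con, integer(), 1, size = 4, endian = "big")
  h <- readBin(con, integer(), 1, size = 4, endian = "big")
  w <- readBin(con, integer(), 1, size = 4, endian = "big")
  if (!is.null(limit)) n <- min(n, limit)
  raw <- readBin(con, integer(), n * h * w, size = 1, signed = FALSE)
  imgs <- matrix(as.numeric(raw >= 128), h * w, n)
  con2 <- file(label_file, "rb"); on.exit(close(con2), add = TRUE)
  magic2 <- readBin(con2, integer(), 1, size = 4, endian = "big")
  if (magic2 != 2049L) stop("not an IDX label file")
  n2 <- readBin(con2, integer(), 1, size = 4, endian = "big")
  labels <- readBin(con2, integer(), min(n2, n), size = 1, signed = FALSE)
  list(images = imgs, labels = labels[seq_len(n)], image_size = c(h, w))
}
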