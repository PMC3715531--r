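#' Shapes model specification
#'
#' Geometry of the shapes model: image size, shape sizes, hidden layer
#' sizes and receptive-field patch sides. The defaults are 20 x 20 images,
#' small/large shape sides 6/10, three hidden layers of 256/196/64 units
#' with patch sides 7/7 and a global topmost field. (The corresponding
#' sizes printed in the original study are not recoverable; these are
#' declared stand-ins of the same character, and everything is
#' configurable.) `scale = "small"` gives a reduced geometry (12 x 12
#' images, sides 5/8, hidden 196/144/100, patches 5/7/global) used to keep
#' simulation-heavy checks affordable; the dynamics are the same.
#'
#' @param scale `"default"` or `"small"`.
#' @param image_size,sides,hidden,patches override individual fields.
#' @return a list with the five fields plus derived `layer_sizes`.
#' @export
shapes_model_spec <- function(scale = c("default", "small"),
                              image_size = NULL, sides = NULL,
                              hidden = NULL, patches = NULL) {
  scale <- match.arg(scale)
  def <- if (scale == "default")
    list(image_size = c(20L, 20L), sides = c(small = 6L, large = 10L),
         hidden = c(256L, 196L, 64L), patches = c(7, 7, NA))
  else
    list(image_size = c(12L, 12L), sides = c(small = 5L, large = 8L),
         hidden = c(196L, 144L, 100L), patches = c(5, 7, NA))
  if (!is.null(image_size)) def$image_size <- as.integer(unlist(image_size))
  if (!is.null(sides)) {
    sides <- unlist(sides)
    storage.mode(sides) <- "integer"
    def$sides <- sides
  }
  if (!is.null(hidden)) def$hidden <- as.integer(unlist(hidden))
  if (!is.null(patches))   # JSON configs encode the global field as null/"NA"
    def$patches <- suppressWarnings(as.numeric(unlist(lapply(patches,
      function(x) if (is.null(x) || identical(x, "NA")) NA_real_ else x))))
  def$layer_sizes <- c(prod(def$image_size), def$hidden)
  def
}

#' Build and train a complete shapes model
#'
#' One-call pipeline: enumerates the shapes corpus, draws a training set of
#' `n_train` images with replacement from it (all possible instances are
#' covered), trains the layered network layer-wise, measures per-unit
#' target activities over the enumeration (one trial per distinct image),
#' and prepares the template bank for quality scoring.
#'
#' @param spec a [shapes_model_spec()].
#' @param cfg a [train_config()].
#' @param n_train training-set size (default 60,000 images).
#' @param seed integer seed controlling training and target measurement.
#' @param target_cycles sampling cycles per trial when measuring targets.
#' @param verbose print per-epoch reconstruction error.
#' @return a list with `net`, `data` (the enumeration), `target`, `bank`,
#'   `templates`, `spec`.
#' @export
build_shapes_model <- function(spec = shapes_model_spec(),
                               cfg = train_config(), n_train = 60000L,
                               seed = 1L, target_cycles = 50L,
                               verbose = FALSE) {
  data <- enumerate_instances(spec$image_size, spec$sides)
  train <- sample_dataset(n_train, seed = seed, enumeration = data)
  cfg$rng_seed <- seed
  net <- layerwise_pretrain(train, spec$layer_sizes, rf_spec(spec$patches),
                            cfg, verbose = verbose)
  target <- measure_target_activity(net, data, cycles = target_cycles,
                                    seed = seed + 1L)
  templates <- shape_templates(spec$sides)
  bank <- template_bank(spec$image_size, templates)
  list(net = net, data = data, target = target, bank = bank,
       templates = templates, spec = spec)
}
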