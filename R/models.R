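# Model constructors: the simple baseline CNN, the parametric optimized-CNN
# family searched in stage 2, and a registry of reference architectures.

#' Architecture specification for the optimized-CNN family
#'
#' The five architecture hyperparameters tuned by the Bayesian search:
#' convolution kernel edge (integer 2–7), number of conv layers (integer
#' 2–6), feature maps in the first layer (integer 2–16), per-layer filter
#' growth factor (real in `[1, 2]`), and the dropout rate applied after the
#' fully connected head (one of 0.1, 0.2, ..., 0.9).
#'
#' @param filter_size,n_layers,base_filters,multiplier,dropout see above
#' @return object of class `arch_spec`
#' @export
arch_spec <- function(filter_size, n_layers, base_filters, multiplier,
                      dropout) {
  chk_int <- function(x, lo, hi, what) {
    if (length(x) != 1 || !is.finite(x) || x != round(x) || x < lo || x > hi) {
      stop_with("efastcnn_invalid_argument",
                sprintf("%s must be an integer in [%d, %d]", what, lo, hi))
    }
  }
  chk_int(filter_size, 2, 7, "filter_size")
  chk_int(n_layers, 2, 6, "n_layers")
  chk_int(base_filters, 2, 16, "base_filters")
  if (!is.finite(multiplier) || multiplier < 1 || multiplier > 2) {
    stop_with("efastcnn_invalid_argument", "multiplier must lie in [1, 2]")
  }
  lv <- round(dropout * 10)
  if (!is.finite(dropout) || lv < 1 || lv > 9 || abs(dropout * 10 - lv) > 1e-8) {
    stop_with("efastcnn_invalid_argument",
              "dropout must be one of 0.1, 0.2, ..., 0.9")
  }
  structure(list(filter_size = as.integer(filter_size),
                 n_layers = as.integer(n_layers),
                 base_filters = as.integer(base_filters),
                 multiplier = multiplier, dropout = lv / 10),
            class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf(
    "<arch_spec k=%d layers=%d base=%d mult=%.3f dropout=%.1f>\n",
    x$filter_size, x$n_layers, x$base_filters, x$multiplier, x$dropout))
  invisible(x)
}

#' Filter-count ladder of the optimized-CNN family
#'
#' `counts[l] = round(base * multiplier^(l-1))` with half-up rounding
#' (feature-map counts must be whole numbers), all at least 1. With base 16,
#' multiplier 2 and three layers this reproduces the simple CNN's 16/32/64
#' ladder.
#'
#' @param base feature maps in layer 1
#' @param multiplier growth factor per layer
#' @param n_layers number of conv layers
#' @return integer vector of length `n_layers`
#' @export
layer_filter_counts <- function(base, multiplier, n_layers) {
  raw <- base * multiplier^(seq_len(n_layers) - 1)
  pmax(1L, as.integer(floor(raw + 0.5)))  # round half up
}

#' Build the simple baseline CNN
#'
#' Three conv blocks (16, 32 and 64 filters, 3x3 kernels, each followed by
#' ReLU and 2x2 max pooling), a fully connected layer with two outputs, and
#' a selectable softmax or softplus final activation.
#'
#' @param activator "softmax" or "softplus"
#' @param input_size square input edge in pixels (default 512)
#' @param seed optional seed for weight initialization
#' @return a `cnn_model`
#' @export
build_simple_cnn <- function(activator = c("softmax", "softplus"),
                             input_size = 512, seed = NULL) {
  activator <- match.arg(activator)
  new_cnn_model("simple", filters = c(16L, 32L, 64L), filter_size = 3L,
                input_size = input_size, activator = activator, seed = seed)
}

#' Build a member of the optimized-CNN family
#'
#' `spec$n_layers` conv blocks (filters per [layer_filter_counts()], square
#' kernels of edge `spec$filter_size`, ReLU + 2x2 max pooling each), a
#' 2-output fully connected layer, dropout at `spec$dropout` on the logits
#' (training only), then the final activation.
#'
#' @param spec an [arch_spec()]
#' @inheritParams build_simple_cnn
#' @return a `cnn_model`
#' @export
build_custom_cnn <- function(spec, activator = c("softmax", "softplus"),
                             input_size = 512, seed = NULL) {
  activator <- match.arg(activator)
  if (!inherits(spec, "arch_spec")) {
    spec <- do.call(arch_spec, as.list(spec))
  }
  filters <- layer_filter_counts(spec$base_filters, spec$multiplier,
                                 spec$n_layers)
  new_cnn_model("optimized", filters = filters,
                filter_size = spec$filter_size, input_size = input_size,
                activator = activator, dropout = spec$dropout, spec = spec,
                seed = seed)
}

# ---- reference-architecture registry ---------------------------------------
# The published reference networks cannot be reproduced here at full
# fidelity (their topologies and ImageNet weights live outside this
# package), so the registry ships reduced-scale synthetic stand-in CNNs
# under the reference names: same role in the comparison (a light mobile
# model, a deep conventional model, a mid-depth ultrasound-tuned model),
# not the canonical layer graphs.  Users can register their own builders.

.model_registry <- new.env(parent = emptyenv())

#' Register a reference-model builder
#'
#' @param name model name used by [reference_model()]
#' @param builder `function(activator, input_size, seed)` returning a
#'   `cnn_model`
#' @export
register_reference_model <- function(name, builder) {
  assign(name, builder, envir = .model_registry)
  invisible(name)
}

#' List registered reference models
#' @export
registered_models <- function() sort(ls(.model_registry))

#' Build a reference architecture with a 2-output head
#'
#' Resolves `name` in the model registry. Pre-registered names are
#' MobileNetV2, DarkNet53 and ShrapML — shipped as reduced-scale synthetic
#' stand-ins (see the package vignette); registering a builder under the
#' same name replaces them. Pretrained weights are not distributed: with
#' `pretrained = TRUE` a warning is issued and random initialization is
#' used.
#'
#' @param name registered model name
#' @param pretrained request pretrained weights (falls back to random init
#'   with a warning)
#' @inheritParams build_simple_cnn
#' @return a `cnn_model`
#' @export
reference_model <- function(name, pretrained = FALSE,
                            activator = c("softmax", "softplus"),
                            input_size = 512, seed = NULL) {
  activator <- match.arg(activator)
  if (!exists(name, envir = .model_registry, inherits = FALSE)) {
    stop_with("efastcnn_unknown_model",
              sprintf("no model '%s' registered (known: %s)", name,
                      paste(registered_models(), collapse = ", ")))
  }
  if (isTRUE(pretrained)) {
    warning(sprintf(
      "pretrained weights for '%s' are not available; using random initialization",
      name))
  }
  get(name, envir = .model_registry)(activator, input_size, seed)
}

# stand-in builders (synthetic, reduced scale)
.register_builtin_models <- function() {
  register_reference_model("MobileNetV2", function(activator, input_size,
                                                   seed) {
    new_cnn_model("MobileNetV2", filters = c(8L, 16L, 32L, 64L),
                  filter_size = 3L, input_size = input_size,
                  activator = activator, seed = seed)
  })
  register_reference_model("DarkNet53", function(activator, input_size,
                                                 seed) {
    new_cnn_model("DarkNet53", filters = c(8L, 16L, 32L, 64L, 128L),
                  filter_size = 3L, input_size = input_size,
                  activator = activator, seed = seed)
  })
  register_reference_model("ShrapML", function(activator, input_size, seed) {
    new_cnn_model("ShrapML", filters = c(16L, 32L, 64L, 64L),
                  filter_size = 3L, input_size = input_size,
                  activator = activator, dropout = 0.3, seed = seed)
  })
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_models()
}

#' Architecture summary for export
#'
#' @param model a `cnn_model`
#' @return list (JSON-ready) with the layer ladder and parameter count
#' @export
model_summary <- function(model) {
  list(name = model$name, activator = model$activator,
       input_size = model$input_size, filter_size = model$filter_size,
       filters = model$filters, dropout = model$dropout,
       n_params = model$n_params)
}
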