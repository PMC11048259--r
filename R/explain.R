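# Grad-CAM saliency maps and confusion-category sampling for qualitative
# model auditing.

#' Grad-CAM heat map for one frame
#'
#' Channel weights are the spatial means of the gradient of the raw
#' target-class score with respect to the final conv block's (post-ReLU)
#' feature maps; the map is the rectified weighted sum of those feature
#' maps, min–max normalized to `[0, 1]` and bilinearly upsampled to the
#' frame's extents. A target score that is constant in the input yields an
#' all-zero map.
#'
#' @param model a `cnn_model`
#' @param frame a `us_frame` (or bare pixel matrix) at the model's input
#'   size
#' @param target class to explain: "positive" (default) or "negative"
#' @return object of class `heat_map` with `values` (matrix in `[0, 1]`),
#'   `target` and `model`
#' @export
gradcam <- function(model, frame, target = c("positive", "negative")) {
  target <- match.arg(target)
  if (!inherits(model, "cnn_model") || length(model$filters) == 0) {
    stop_with("efastcnn_unsupported_model",
              "Grad-CAM needs a model with at least one conv layer")
  }
  px <- if (inherits(frame, "us_frame")) frame$pixels else frame
  x <- array(px, dim = c(dim(px), 1, 1))
  fwd <- nn_forward(model, x, training = FALSE, retain = TRUE)
  L <- length(model$filters)
  A <- fwd$caches[[L]]$r  # (hL, wL, C, 1) post-ReLU feature maps
  t_idx <- match(target, .CLASS_LEVELS)
  # d(score_t)/d(pooled) is the fc row; route it back through the last pool
  dpool <- array(model$params$fc.W[t_idx, ], dim = fwd$pooled_dim)
  dA <- .maxpool_backward(fwd$caches[[L]]$idx, dpool, dim(A)[1], dim(A)[2])
  alpha <- apply(dA, 3, mean)
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (ch in seq_along(alpha)) cam <- cam + alpha[ch] * A[, , ch, 1]
  cam[cam < 0] <- 0
  rng <- range(cam)
  if (rng[2] > rng[1]) cam <- (cam - rng[1]) / (rng[2] - rng[1])
  up <- clamp01(resize_matrix(cam, nrow(px), ncol(px)))
  structure(list(values = up, target = target, model = model$name),
            class = "heat_map")
}

#' Sample frames from each confusion category
#'
#' Groups prediction records into TP/TN/FP/FN and samples up to
#' `n_per_category` of each without replacement (short categories return
#' all members). Uses the current RNG stream.
#'
#' @param predictions data.frame with columns `id` (or frame reference),
#'   `predicted` and `truth`
#' @param n_per_category per-category sample size (default 5, the study
#'   protocol)
#' @return named list of data.frame subsets for TP, TN, FP, FN
#' @export
sample_outcomes <- function(predictions, n_per_category = 5) {
  cat_of <- function(pred, truth) {
    ifelse(pred == "positive" & truth == "positive", "TP",
    ifelse(pred == "negative" & truth == "negative", "TN",
    ifelse(pred == "positive" & truth == "negative", "FP", "FN")))
  }
  cats <- cat_of(predictions$predicted, predictions$truth)
  out <- list()
  for (cc in c("TP", "TN", "FP", "FN")) {
    members <- which(cats == cc)
    take <- if (length(members) > n_per_category) {
      sample(members, n_per_category)
    } else members
    out[[cc]] <- predictions[take, , drop = FALSE]
  }
  out
}

#' Write a Grad-CAM overlay PNG
#'
#' Alpha-blends the heat map (red–yellow ramp: red fixed, green tracking
#' heat) over the grayscale frame.
#'
#' @param frame a `us_frame`
#' @param heatmap a [gradcam()] result
#' @param path output PNG path
#' @param alpha blend weight of the heat layer (default 0.4)
#' @return invisibly, `path`
#' @export
write_gradcam_overlay <- function(frame, heatmap, path, alpha = 0.4) {
  px <- frame$pixels
  h <- heatmap$values
  w <- alpha * h  # per-pixel blend strength follows the heat
  rgb <- array(0, dim = c(nrow(px), ncol(px), 3))
  rgb[, , 1] <- clamp01((1 - w) * px + w * 1)
  rgb[, , 2] <- clamp01((1 - w) * px + w * h)
  rgb[, , 3] <- clamp01((1 - w) * px)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(rgb, path)
  invisible(path)
}
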