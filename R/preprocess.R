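# Preprocessing: UI cropping, resizing, M-mode rolling-window splitting,
# datastore indexing, class-balanced sampling and image augmentation.

#' Augmentation policy
#'
#' Three independent random transforms applied in the fixed order
#' reflect -> rotate -> scale: y-axis reflection (coin flip), rotation
#' uniform in `[-max_rotation, +max_rotation]` degrees, and isotropic
#' rescaling uniform in `scale_range`. Exposed borders are filled with 0
#' (anechoic black). The optimization stages use 36 degrees and
#' `[0.90, 1.10]`; the LOSO stage uses 10 degrees and `[0.90, 1.10]`.
#'
#' @param reflect_y enable random y-axis reflection
#' @param max_rotation maximum rotation in degrees, either direction (>= 0)
#' @param scale_range length-2 multiplicative range, `0 < low <= high`
#' @return object of class `augment_policy`
#' @export
augment_policy <- function(reflect_y = TRUE, max_rotation = 36,
                           scale_range = c(0.90, 1.10)) {
  if (max_rotation < 0) {
    stop_with("efastcnn_invalid_argument", "max_rotation must be >= 0")
  }
  if (length(scale_range) != 2 || scale_range[1] <= 0 ||
      scale_range[1] > scale_range[2]) {
    stop_with("efastcnn_invalid_argument",
              "scale_range must satisfy 0 < low <= high")
  }
  structure(list(reflect_y = isTRUE(reflect_y), max_rotation = max_rotation,
                 scale_range = scale_range), class = "augment_policy")
}

#' LOSO-stage augmentation policy (10 degree rotation, 10 percent rescale)
#' @export
loso_policy <- function() augment_policy(TRUE, 10, c(0.90, 1.10))

#' Crop user-interface margins from a frame
#'
#' @param frame a `us_frame`
#' @param margins pixels to remove, in order top, bottom, left, right
#'   (recycled if length 1)
#' @return the cropped `us_frame`; provenance preserved
#' @export
crop_ui <- function(frame, margins) {
  m <- rep_len(as.integer(margins), 4)
  h <- nrow(frame$pixels)
  w <- ncol(frame$pixels)
  if (any(m < 0) || m[1] + m[2] >= h || m[3] + m[4] >= w) {
    stop_with("efastcnn_invalid_argument",
              "margins must be non-negative and leave a non-empty interior")
  }
  frame$pixels <- frame$pixels[(m[1] + 1):(h - m[2]), (m[3] + 1):(w - m[4]),
                               drop = FALSE]
  if (!is.null(frame$mask)) {
    frame$mask <- frame$mask[(m[1] + 1):(h - m[2]), (m[3] + 1):(w - m[4]),
                             drop = FALSE]
  }
  frame
}

#' Resize a frame to a square target with bilinear interpolation
#'
#' @param frame a `us_frame`
#' @param target output edge in pixels (default 512, the pipeline's native
#'   model input size)
#' @return resized `us_frame` with values clamped to `[0, 1]`
#' @export
resize_frame <- function(frame, target = 512) {
  if (target < 1) {
    stop_with("efastcnn_invalid_argument", "target must be >= 1")
  }
  frame$pixels <- clamp01(resize_matrix(frame$pixels, target, target))
  if (!is.null(frame$mask)) {
    frame$mask <- resize_matrix(frame$mask * 1, target, target) > 0.5
  }
  frame
}

#' Split an M-mode capture into rolling-window sections
#'
#' Splits a capture into `n_sections` frames each spanning `window` seconds.
#' For more than one section, start times are evenly spaced with stride
#' `(duration - window) / (n_sections - 1)` — the unique even tiling that
#' yields 25 overlapping one-second sections from a 5 s capture. A window
#' equal to the full duration yields exactly one section.
#'
#' @param capture an `mmode_capture`
#' @param window section length in seconds (<= capture duration)
#' @param n_sections number of sections (default 25)
#' @param target optional square resize applied to each section
#' @return list of `us_frame`s; the section index is appended to provenance
#' @export
split_mmode_windows <- function(capture, window = 1, n_sections = 25,
                                target = NULL) {
  if (window <= 0 || window > capture$duration) {
    stop_with("efastcnn_invalid_argument",
              "window must lie in (0, duration]")
  }
  if (n_sections < 1) {
    stop_with("efastcnn_invalid_argument", "n_sections must be >= 1")
  }
  cps <- capture$columns_per_second
  ncol_win <- max(1L, round(window * cps))
  starts <- if (n_sections == 1 || window == capture$duration) {
    0
  } else {
    (seq_len(n_sections) - 1) * (capture$duration - window) / (n_sections - 1)
  }
  lapply(seq_along(starts), function(i) {
    c0 <- round(starts[i] * cps) + 1L
    c1 <- min(ncol(capture$matrix), c0 + ncol_win - 1L)
    px <- capture$matrix[, c0:c1, drop = FALSE]
    msk <- if (!is.null(capture$mask)) {
      capture$mask[, c0:c1, drop = FALSE]
    }
    fr <- new_frame(px, capture$site, capture$subject_id, capture$label,
                    provenance = c(capture$provenance, i),
                    severity = capture$severity, mask = msk)
    if (!is.null(target)) fr <- resize_frame(fr, target)
    fr
  })
}

#' Build a datastore index over a cohort
#'
#' Flattens a cohort into a single indexed container keyed by
#' (site, subject, label). M-mode captures are indexed as captures; use
#' [split_mmode_windows()] beforehand (or [cohort_to_frames()]) when frames
#' are needed.
#'
#' @param cohort list of `subject_dataset`s, or a plain list of frames each
#'   carrying site/subject/label metadata
#' @return object of class `datastore` with elements `frames` (list) and
#'   `index` (data.frame: id, site, mode, subject, label, provenance)
#' @export
build_datastore <- function(cohort) {
  items <- list()
  if (length(cohort) > 0 && inherits(cohort[[1]], "subject_dataset")) {
    for (subj in cohort) items <- c(items, subj$items)
  } else {
    items <- cohort
  }
  if (length(items) == 0) {
    return(structure(list(frames = list(),
                          index = data.frame(id = integer(), site = character(),
                                             mode = character(),
                                             subject = character(),
                                             label = character(),
                                             provenance = character(),
                                             stringsAsFactors = FALSE)),
                     class = "datastore"))
  }
  index <- data.frame(
    id = seq_along(items),
    site = vapply(items, function(x) x$site, character(1)),
    mode = vapply(items, function(x) x$mode, character(1)),
    subject = vapply(items, function(x) x$subject_id, character(1)),
    label = vapply(items, function(x) x$label, character(1)),
    provenance = vapply(items, function(x) {
      paste(x$provenance, collapse = ":")
    }, character(1)),
    stringsAsFactors = FALSE)
  key <- paste(index$site, index$subject, index$label, index$provenance)
  if (anyDuplicated(key)) {
    stop_with("efastcnn_corrupt_input",
              "duplicate provenance within a subject/site/label")
  }
  structure(list(frames = items, index = index), class = "datastore")
}

#' Per-key counts of a datastore
#' @param store a `datastore`
#' @return data.frame of counts by site, subject and label
#' @export
datastore_counts <- function(store) {
  if (nrow(store$index) == 0) {
    return(data.frame(site = character(), subject = character(),
                      label = character(), n = integer()))
  }
  agg <- aggregate(list(n = store$index$id),
                   by = store$index[c("site", "subject", "label")], FUN = length)
  agg[order(agg$site, agg$subject, agg$label), , drop = FALSE]
}

#' Expand a cohort's M-mode captures into windowed frames
#'
#' Convenience wrapper: B-mode frames pass through unchanged; each M-mode
#' capture is split into rolling-window sections resized to `target`.
#'
#' @param cohort list of `subject_dataset`s
#' @param window,n_sections see [split_mmode_windows()]
#' @param target square resize applied to M-mode sections (default: capture
#'   depth)
#' @return list of `subject_dataset`s containing only `us_frame`s
#' @export
cohort_to_frames <- function(cohort, window = 1, n_sections = 25,
                             target = NULL) {
  lapply(cohort, function(subj) {
    items <- list()
    for (item in subj$items) {
      if (inherits(item, "mmode_capture")) {
        tgt <- target %||% nrow(item$matrix)
        items <- c(items, split_mmode_windows(item, window, n_sections, tgt))
      } else {
        items <- c(items, list(item))
      }
    }
    subj$items <- items
    subj
  })
}

#' Class-balanced sampling from a datastore
#'
#' Draws exactly `n_per_class` positive and `n_per_class` negative frames
#' without replacement for one scan site, restricted to the given subjects
#' (negatives are sampled to match the positives, mirroring how splits are
#' balanced). Uses the current RNG stream.
#'
#' @param store a `datastore`
#' @param site site code
#' @param subjects character vector of admissible subject ids
#' @param n_per_class frames per class
#' @return list of frames in shuffled order
#' @export
balanced_sample <- function(store, site, subjects, n_per_class) {
  if (n_per_class == 0) return(list())
  idx <- store$index
  pool <- idx[idx$site == site & idx$subject %in% subjects, , drop = FALSE]
  ids <- lapply(c("positive", "negative"), function(lab) {
    cand <- pool$id[pool$label == lab]
    if (length(cand) < n_per_class) {
      stop_with("efastcnn_insufficient_data",
                sprintf("site %s: need %d %s frames, have %d (deficit %d)",
                        site, n_per_class, lab, length(cand),
                        n_per_class - length(cand)),
                deficit = n_per_class - length(cand), label = lab)
    }
    sample(cand, n_per_class)
  })
  chosen <- sample(c(ids[[1]], ids[[2]]))
  store$frames[chosen]
}

# augmentation on a bare matrix (fast path used by the training loop)
augment_matrix <- function(px, policy) {
  if (policy$reflect_y && runif(1) < 0.5) px <- reflect_y(px)
  ang <- if (policy$max_rotation > 0) {
    runif(1, -policy$max_rotation, policy$max_rotation)
  } else 0
  sc <- if (policy$scale_range[1] < policy$scale_range[2]) {
    runif(1, policy$scale_range[1], policy$scale_range[2])
  } else policy$scale_range[1]
  clamp01(warp_rotate_scale(px, ang, sc, fill = 0))
}

#' Apply random augmentation to a frame
#'
#' Samples reflect / rotation / scale per the policy and applies them in
#' that order; output extents equal the input's, exposed regions are filled
#' with 0, and values stay in `[0, 1]`. Uses the current RNG stream.
#'
#' @param frame a `us_frame`
#' @param policy an [augment_policy()]
#' @return augmented `us_frame`
#' @export
apply_augment <- function(frame, policy) {
  frame$pixels <- augment_matrix(frame$pixels, policy)
  frame
}
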