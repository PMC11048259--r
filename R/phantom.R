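# Synthetic eFAST phantom generator.
#
# Six scan sites are emulated: RUQ (hepatorenal recess), BLD (bladder),
# PTX_B / HTX_B (thoracic B-mode) and PTX_M / HTX_M (thoracic M-mode).
# B-mode frames are fully-developed-speckle backgrounds (Rayleigh amplitude
# of a smoothed complex Gaussian field) with a per-site anatomical template;
# the positive injury state inserts an anechoic free-fluid signal whose
# strength and extent scale with a severity effect size in [0, 1].
# Severity 0 makes positive and negative renders identically distributed
# (and pixel-identical at matched RNG state): every random draw is consumed
# regardless of the label, and the injury modification is a deterministic
# function of those draws that vanishes at severity 0.

.SITE_CODES <- c("RUQ", "BLD", "PTX_B", "PTX_M", "HTX_B", "HTX_M")
.SITE_MODES <- c(RUQ = "B", BLD = "B", PTX_B = "B", PTX_M = "M",
                 HTX_B = "B", HTX_M = "M")

#' Scan-site table
#'
#' The six eFAST scan sites handled by the pipeline and their imaging mode.
#' Imaging mode is a pure function of the site code: thoracic M-mode sweeps
#' (`PTX_M`, `HTX_M`) are depth-versus-time captures, all other sites are
#' 2-D B-mode frames.
#'
#' @return data.frame with columns `code` and `mode`
#' @export
scan_sites <- function() {
  data.frame(code = .SITE_CODES, mode = unname(.SITE_MODES[.SITE_CODES]),
             stringsAsFactors = FALSE)
}

#' Imaging mode of a scan site
#' @param code one of RUQ, BLD, PTX_B, PTX_M, HTX_B, HTX_M
#' @return "B" or "M"
#' @export
site_mode <- function(code) {
  if (!code %in% .SITE_CODES) {
    stop_with("efastcnn_invalid_argument",
              paste0("unknown scan site: ", code))
  }
  unname(.SITE_MODES[code])
}

#' Phantom generator parameters
#'
#' Bundles the knobs of the synthetic generator. `severity` is the injury
#' effect size: 0 renders positive and negative states identically, 1 is the
#' overt injury the study's animal model produced. Subject-level standard
#' deviations control the inter-subject variability that makes
#' leave-one-subject-out evaluation meaningful.
#'
#' @param image_size native square render size in pixels (default 512)
#' @param severity injury effect size in `[0, 1]`
#' @param speckle_sigma Rayleigh scale of the speckle background
#' @param grain speckle correlation length in pixels
#' @param gain_sd sd of the per-subject additive brightness offset
#' @param grain_sd sd (log scale) of the per-subject speckle-grain factor
#' @param depth_jitter_sd sd of per-subject anatomy depth shift (fraction of
#'   image height)
#' @param geometry_jitter_sd sd of per-subject structure position/size jitter
#' @param mmode_duration M-mode capture length in seconds (default 5)
#' @param columns_per_second M-mode time-axis sampling rate
#' @param tick_spacing M-mode display tick spacing in seconds (default 0.2)
#' @param base_seed integer master seed; the whole cohort is a pure function
#'   of it
#' @return object of class `phantom_params`
#' @export
phantom_params <- function(image_size = 512, severity = 1,
                           speckle_sigma = 0.25, grain = 1.5,
                           gain_sd = 0.05, grain_sd = 0.15,
                           depth_jitter_sd = 0.025,
                           geometry_jitter_sd = 0.04,
                           mmode_duration = 5, columns_per_second = 100,
                           tick_spacing = 0.2, base_seed = 1L) {
  if (!is.numeric(severity) || severity < 0 || severity > 1) {
    stop_with("efastcnn_invalid_argument", "severity must lie in [0, 1]")
  }
  if (image_size < 8) {
    stop_with("efastcnn_invalid_argument", "image_size must be >= 8")
  }
  if (mmode_duration <= 0 || tick_spacing <= 0 || columns_per_second <= 0) {
    stop_with("efastcnn_invalid_argument",
              "M-mode duration, tick spacing and sampling rate must be > 0")
  }
  structure(list(
    image_size = as.integer(image_size), severity = severity,
    speckle_sigma = speckle_sigma, grain = grain,
    gain_sd = gain_sd, grain_sd = grain_sd,
    depth_jitter_sd = depth_jitter_sd,
    geometry_jitter_sd = geometry_jitter_sd,
    mmode_duration = mmode_duration,
    columns_per_second = columns_per_second,
    tick_spacing = tick_spacing,
    base_seed = as.integer(base_seed)
  ), class = "phantom_params")
}

#' Draw per-subject random effects
#'
#' A deterministic function of `(params, subject_seed)`: additive gain
#' offset, multiplicative speckle-grain factor, anatomy depth shift and
#' structure geometry jitter. Effects are bounded so rendered pixels always
#' remain clampable to `[0, 1]`.
#'
#' @param params a [phantom_params()] object
#' @param subject_seed non-negative integer identifying the subject
#' @return object of class `subject_effects`
#' @export
sample_subject_effects <- function(params, subject_seed) {
  if (subject_seed < 0) {
    stop_with("efastcnn_invalid_argument", "subject_seed must be >= 0")
  }
  with_seed(derive_seed(params$base_seed, 101L, subject_seed), {
    structure(list(
      gain_offset = max(-0.2, min(0.2, rnorm(1, 0, params$gain_sd))),
      grain_scale = max(0.5, min(2, exp(rnorm(1, 0, params$grain_sd)))),
      depth_jitter = max(-0.08, min(0.08, rnorm(1, 0, params$depth_jitter_sd))),
      geometry_jitter = pmax(-0.12, pmin(0.12,
                                         rnorm(3, 0, params$geometry_jitter_sd)))
    ), class = "subject_effects")
  })
}

neutral_effects <- function() {
  structure(list(gain_offset = 0, grain_scale = 1, depth_jitter = 0,
                 geometry_jitter = c(0, 0, 0)), class = "subject_effects")
}

#' Fully-developed speckle field
#'
#' Magnitude of a complex Gaussian field (Rayleigh-distributed amplitudes
#' with scale `sigma`). A positive `grain` Gaussian-smooths the complex
#' field before taking the magnitude (components are re-standardized after
#' smoothing so the marginal Rayleigh scale is preserved), producing the
#' laterally correlated granular texture of B-mode imaging. Uses the
#' current RNG stream.
#'
#' @param height,width grid extents in pixels (>= 1)
#' @param sigma Rayleigh scale (>= 0); 0 yields an all-zero grid
#' @param grain smoothing kernel sd in pixels (>= 0)
#' @param clamp clamp the output to `[0, 1]` (default TRUE)
#' @return `height x width` matrix
#' @export
speckle_field <- function(height, width, sigma, grain = 0, clamp = TRUE) {
  if (height < 1 || width < 1) {
    stop_with("efastcnn_invalid_argument", "grid extents must be >= 1")
  }
  if (sigma < 0 || grain < 0) {
    stop_with("efastcnn_invalid_argument", "sigma and grain must be >= 0")
  }
  if (sigma == 0) return(matrix(0, height, width))
  re <- matrix(rnorm(height * width), height, width)
  im <- matrix(rnorm(height * width), height, width)
  if (grain > 0) {
    re <- gauss_blur(re, grain)
    im <- gauss_blur(im, grain)
    re <- re / max(sd(as.vector(re)), 1e-12)
    im <- im / max(sd(as.vector(im)), 1e-12)
  }
  amp <- sigma * sqrt(re^2 + im^2)
  if (clamp) clamp01(amp) else amp
}

new_frame <- function(pixels, site, subject_id, label, provenance,
                      severity = NA_real_, mask = NULL) {
  stopifnot(all(pixels >= 0 & pixels <= 1))
  structure(list(pixels = pixels, site = site, mode = site_mode(site),
                 subject_id = subject_id, label = label,
                 provenance = provenance, severity = severity, mask = mask),
            class = "us_frame")
}

#' @export
print.us_frame <- function(x, ...) {
  cat(sprintf("<us_frame %s %s/%s %dx%d subject=%s prov=%s>\n",
              x$site, x$mode, x$label, nrow(x$pixels), ncol(x$pixels),
              x$subject_id, paste(x$provenance, collapse = ":")))
  invisible(x)
}

# ---- site geometry ---------------------------------------------------------
# All geometry is expressed in fractional image coordinates (depth = rows).
# `draws` carries the per-frame random numbers, drawn identically for both
# labels so matched-seed renders differ only through the severity term.

bmode_draws <- function(site) {
  # consume a fixed number of uniforms per site, label-independent
  switch(site,
    RUQ = list(curve = runif(1, -1, 1), shift = runif(1, -1, 1)),
    BLD = list(size = runif(1, 0.7, 1.3), cx = runif(1, -1, 1),
               side = runif(1)),
    PTX_B = ,
    HTX_B = list(rib = runif(2, -1, 1), wall = runif(1, -1, 1)),
    stop_with("efastcnn_invalid_argument", paste0("not a B-mode site: ", site))
  )
}

# fractional-coordinate grids
frac_grids <- function(n) {
  f <- (seq_len(n) - 0.5) / n
  list(rr = matrix(f, n, n), cc = matrix(f, n, n, byrow = TRUE))
}

#' Render a B-mode phantom frame
#'
#' Speckle background plus the site's anatomical template. RUQ carries a
#' bright curved hepatorenal interface; BLD an anechoic bladder ellipse with
#' randomized size and posterior enhancement; PTX_B/HTX_B vertical rib
#' shadows with a bright pleural line. The positive label inserts an
#' anechoic free-fluid region whose area and contrast scale with
#' `params$severity` (along the interface for RUQ, adjacent to the bladder
#' for BLD, below the pleural line for HTX_B). PTX_B carries a deliberately
#' weak positive signal: sub-pleural speckle texture is blended toward its
#' regional mean with no geometric cue, reflecting how hard pneumothorax is
#' to call from a single B-mode frame. The ground-truth injury region is
#' stored as `mask` alongside the frame; it is never shown to classifiers.
#'
#' @param site B-mode site code (RUQ, BLD, PTX_B, HTX_B)
#' @param label "positive" or "negative"
#' @param params [phantom_params()]
#' @param effects per-subject effects from [sample_subject_effects()]
#' @param subject_id,provenance provenance metadata carried on the frame
#' @return object of class `us_frame` with pixels in `[0, 1]`
#' @export
render_bmode <- function(site, label, params,
                         effects = neutral_effects(),
                         subject_id = "s1", provenance = 1L) {
  if (site_mode(site) != "B") {
    stop_with("efastcnn_invalid_argument",
              paste0(site, " is an M-mode site; use render_mmode()"))
  }
  if (!label %in% c("positive", "negative")) {
    stop_with("efastcnn_invalid_argument", "label must be positive/negative")
  }
  n <- params$image_size
  sev <- params$severity
  draws <- bmode_draws(site)
  bg <- speckle_field(n, n, params$speckle_sigma,
                      grain = params$grain * effects$grain_scale)
  g <- frac_grids(n)
  rr <- g$rr; cc <- g$cc
  gj <- effects$geometry_jitter
  gain <- matrix(0, n, n)      # additive template
  mult <- matrix(1, n, n)      # multiplicative template
  mask <- matrix(FALSE, n, n)  # injury truth region (geometry at any severity)
  injury_mult <- 1

  if (site == "RUQ") {
    d0 <- 0.55 + effects$depth_jitter + 0.02 * draws$shift
    depth <- d0 + (0.25 + 0.1 * draws$curve + gj[1]) * (cc - 0.5)^2
    gain <- gain + 0.35 * exp(-(rr - depth)^2 / (2 * 0.015^2))
    mult <- mult * ifelse(rr < depth, 1.08, 0.92)  # liver brighter, kidney darker
    half <- 0.10 + 0.15 * sev
    thick <- 0.015 + 0.06 * sev
    mask <- rr < depth & rr > depth - thick & abs(cc - (0.5 + 0.05 * gj[2])) < half
    injury_mult <- 1 - 0.85 * sev
  } else if (site == "BLD") {
    cy <- 0.45 + effects$depth_jitter
    cx <- 0.5 + 0.05 * draws$cx + gj[1]
    a <- 0.18 * draws$size * (1 + gj[2])   # lateral semi-axis
    b <- 0.12 * draws$size * (1 + gj[3])   # depth semi-axis
    inside <- ((rr - cy) / b)^2 + ((cc - cx) / a)^2 < 1
    mult[inside] <- 0.08
    post <- rr > cy + b & rr < cy + b + 0.12 & abs(cc - cx) < a
    gain[post] <- gain[post] + 0.18       # posterior acoustic enhancement
    off <- sign(draws$side - 0.5)
    fy <- cy + b + 0.06
    fx <- cx + off * (a + 0.05)
    fa <- 0.06 + 0.10 * sev
    fb <- 0.04 + 0.07 * sev
    mask <- ((rr - fy) / fb)^2 + ((cc - fx) / fa)^2 < 1
    injury_mult <- 1 - 0.9 * sev
  } else {  # PTX_B / HTX_B
    p <- 0.30 + effects$depth_jitter
    gain <- gain + 0.40 * exp(-(rr - p)^2 / (2 * 0.012^2))  # pleural line
    wall <- rr < p - 0.02
    gain[wall] <- gain[wall] +
      0.10 * (1 + sin(2 * pi * (rr[wall] * 6 + 0.3 * draws$wall)))
    rib1 <- 0.22 + 0.04 * draws$rib[1] + gj[1]
    rib2 <- 0.78 + 0.04 * draws$rib[2] + gj[2]
    shadow <- (abs(cc - rib1) < 0.06 | abs(cc - rib2) < 0.06) & rr > p - 0.06
    mult[shadow] <- mult[shadow] * 0.25
    between <- cc > rib1 + 0.08 & cc < rib2 - 0.08
    if (site == "HTX_B") {
      width <- 0.035 + 0.18 * sev
      mask <- between & rr > p + 0.02 & rr < p + 0.02 + width
      injury_mult <- 1 - 0.85 * sev
    } else {  # PTX_B: texture suppression only, deliberately low contrast
      mask <- between & rr > p + 0.02 & rr < p + 0.45
      injury_mult <- 1  # handled by blending, not darkening
    }
  }

  img <- clamp01(bg * mult + gain)
  if (label == "positive") {
    if (site == "PTX_B") {
      alpha <- 0.6 * sev
      if (alpha > 0 && any(mask)) {
        img[mask] <- (1 - alpha) * img[mask] + alpha * mean(img[mask])
      }
    } else if (injury_mult < 1 && any(mask)) {
      img[mask] <- img[mask] * injury_mult
    }
  }
  img <- clamp01(img + effects$gain_offset)
  new_frame(img, site, subject_id, label, provenance,
            severity = sev, mask = if (label == "positive") mask else NULL)
}

#' Render an M-mode phantom capture
#'
#' Depth-versus-time matrix over a `params$mmode_duration` second window
#' (default 5 s). The negative state shows the "seashore" appearance:
#' static layered chest wall above a bright pleural line and granular,
#' column-varying speckle below it (lung sliding). The PTX_M positive state
#' blends the sub-pleural region toward a temporally static, horizontally
#' striated "barcode" pattern (absent lung sliding), with blend weight equal
#' to severity. The HTX_M positive state inserts an anechoic band that
#' widens the pleural space, its width scaling with severity.
#'
#' @param site M-mode site code (PTX_M or HTX_M)
#' @inheritParams render_bmode
#' @return object of class `mmode_capture`
#' @export
render_mmode <- function(site, label, params,
                         effects = neutral_effects(),
                         subject_id = "s1", provenance = 1L) {
  if (site_mode(site) != "M") {
    stop_with("efastcnn_invalid_argument",
              paste0(site, " is a B-mode site; use render_bmode()"))
  }
  if (!label %in% c("positive", "negative")) {
    stop_with("efastcnn_invalid_argument", "label must be positive/negative")
  }
  n <- params$image_size
  tcols <- round(params$mmode_duration * params$columns_per_second)
  sev <- params$severity
  p_row <- max(2L, round(n * (0.30 + effects$depth_jitter)))
  below <- (p_row + 1):n
  nb <- length(below)

  # draws (label-independent, fixed order): wall profile, seashore texture,
  # barcode stripes
  wall_prof <- gauss_blur(matrix(rnorm(p_row), p_row, 1), 1.5)
  wall_prof <- 0.35 + 0.12 * wall_prof / max(sd(as.vector(wall_prof)), 1e-12)
  sea <- speckle_field(nb, tcols, params$speckle_sigma,
                       grain = params$grain * effects$grain_scale)
  stripes <- gauss_blur(matrix(rnorm(nb), nb, 1), 2)
  stripes <- clamp01(0.3 + 0.18 * stripes / max(sd(as.vector(stripes)), 1e-12))

  img <- matrix(0, n, tcols)
  img[seq_len(p_row), ] <- matrix(rep(clamp01(wall_prof), tcols), p_row, tcols)
  img[p_row, ] <- 0.9  # bright pleural line
  img[below, ] <- sea
  mask <- matrix(FALSE, n, tcols)

  if (site == "PTX_M") {
    mask[below, ] <- TRUE
    if (label == "positive" && sev > 0) {
      barcode <- matrix(rep(stripes, tcols), nb, tcols)
      img[below, ] <- (1 - sev) * img[below, ] + sev * barcode
    }
  } else {  # HTX_M
    width <- max(1L, round(n * (0.03 + 0.22 * sev)))
    band <- (p_row + 1):min(n, p_row + width)
    mask[band, ] <- TRUE
    if (label == "positive" && sev > 0) {
      img[band, ] <- img[band, ] * (1 - 0.9 * sev)
    }
  }
  img <- clamp01(img + effects$gain_offset)
  structure(list(matrix = img, duration = params$mmode_duration,
                 columns_per_second = params$columns_per_second,
                 tick_spacing = params$tick_spacing,
                 site = site, mode = "M", subject_id = subject_id,
                 label = label, provenance = provenance, severity = sev,
                 mask = if (label == "positive") mask else NULL),
            class = "mmode_capture")
}

#' @export
print.mmode_capture <- function(x, ...) {
  cat(sprintf("<mmode_capture %s/%s %dx%d (%.1f s @ %g col/s) subject=%s>\n",
              x$site, x$label, nrow(x$matrix), ncol(x$matrix), x$duration,
              x$columns_per_second, x$subject_id))
  invisible(x)
}

#' Canonical fluid region of a scan site
#'
#' The injury region geometry at severity 1 with neutral subject effects and
#' central per-frame draws; used as the fixed discriminant region in
#' effect-size calibration checks. Not available for PTX_B/PTX_M (their
#' positive signal is textural, not a darkened region).
#'
#' @param site site code
#' @param size image size in pixels
#' @return logical matrix
#' @export
canonical_fluid_region <- function(site, size) {
  n <- size
  g <- frac_grids(n)
  rr <- g$rr; cc <- g$cc
  if (site == "RUQ") {
    depth <- 0.55 + 0.25 * (cc - 0.5)^2
    rr < depth & rr > depth - (0.015 + 0.06) & abs(cc - 0.5) < 0.25
  } else if (site == "BLD") {
    # central draws: size 1.0, cx 0.5, fluid on the +side
    cy <- 0.45; a <- 0.18; b <- 0.12
    fy <- cy + b + 0.06; fx <- 0.5 + (a + 0.05)
    ((rr - fy) / 0.11)^2 + ((cc - fx) / 0.16)^2 < 1
  } else if (site == "HTX_B") {
    p <- 0.30
    cc > 0.30 & cc < 0.70 & rr > p + 0.02 & rr < p + 0.02 + 0.215
  } else if (site == "HTX_M") {
    p_row <- round(n * 0.30)
    m <- matrix(FALSE, n, n)
    m[(p_row + 1):min(n, p_row + max(1, round(n * 0.25))), ] <- TRUE
    m
  } else {
    stop_with("efastcnn_invalid_argument",
              paste0("no canonical anechoic region for site ", site))
  }
}

#' Generate a reproducible synthetic cohort
#'
#' Renders `n_subjects` subjects, each with `frames_per_class` positive and
#' negative frames (B-mode sites) or captures (M-mode sites) for every
#' requested site. Subject effects and every frame are seeded from
#' `params$base_seed`, so the whole cohort is a pure function of
#' `(params, base_seed)`.
#'
#' @param params [phantom_params()]
#' @param n_subjects number of subjects (>= 0); the study cohort is 27
#' @param frames_per_class frames (or captures) per site and label for each
#'   subject; either a single count or a named vector by site code
#' @param sites site codes to render (default: all six)
#' @return list of `subject_dataset` objects
#' @export
generate_cohort <- function(params, n_subjects,
                            frames_per_class = 5,
                            sites = .SITE_CODES) {
  if (n_subjects < 0) {
    stop_with("efastcnn_invalid_argument", "n_subjects must be >= 0")
  }
  if (any(frames_per_class < 0)) {
    stop_with("efastcnn_invalid_argument", "counts must be >= 0")
  }
  per_site <- if (length(frames_per_class) == 1) {
    setNames(rep(frames_per_class, length(sites)), sites)
  } else {
    frames_per_class[sites]
  }
  lapply(seq_len(n_subjects), function(i) {
    subject_id <- sprintf("subj%02d", i)
    effects <- sample_subject_effects(params, i)
    items <- list()
    for (s_idx in seq_along(sites)) {
      site <- sites[s_idx]
      for (lab_idx in 1:2) {
        label <- c("negative", "positive")[lab_idx]
        for (k in seq_len(per_site[[site]])) {
          seed <- derive_seed(params$base_seed, 7L, i, s_idx, lab_idx, k)
          item <- with_seed(seed, {
            if (site_mode(site) == "B") {
              render_bmode(site, label, params, effects,
                           subject_id = subject_id, provenance = k)
            } else {
              render_mmode(site, label, params, effects,
                           subject_id = subject_id, provenance = k)
            }
          })
          items[[length(items) + 1L]] <- item
        }
      }
    }
    structure(list(subject_id = subject_id, protocol_tag = "synthetic",
                   items = items), class = "subject_dataset")
  })
}

#' Export a cohort as 8-bit PNG files with a manifest
#'
#' Writes frames under `<root>/<site>/<subject>/<label>/<index>.png` (M-mode
#' captures are written as their full depth-by-time matrix) plus `manifest.csv`
#' and `manifest.json` with columns path, site, mode, subject, label,
#' severity.
#'
#' @param cohort list of subject datasets from [generate_cohort()]
#' @param root output directory
#' @return invisibly, the manifest data.frame
#' @export
export_cohort <- function(cohort, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (subj in cohort) {
    for (item in subj$items) {
      d <- file.path(root, item$site, subj$subject_id, item$label)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      path <- file.path(d, sprintf("%04d.png", item$provenance))
      px <- if (inherits(item, "mmode_capture")) item$matrix else item$pixels
      png::writePNG(px, path)
      rows[[length(rows) + 1L]] <- data.frame(
        path = path, site = item$site, mode = item$mode,
        subject = subj$subject_id, label = item$label,
        severity = item$severity, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}
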