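test_that("scan-site table has six codes and mode is a function of code", {
  tab <- scan_sites()
  expect_setequal(tab$code, c("RUQ", "BLD", "PTX_B", "PTX_M", "HTX_B",
                              "HTX_M"))
  expect_equal(nrow(tab), 6)
  for (i in seq_len(nrow(tab))) {
    expect_identical(site_mode(tab$code[i]), tab$mode[i])
  }
  expect_setequal(tab$mode[tab$code %in% c("PTX_M", "HTX_M")], "M")
  expect_error(site_mode("LUQ"), class = "efastcnn_invalid_argument")
})

test_that("subject effects are deterministic and respect degenerate SDs", {
  p0 <- phantom_params(gain_sd = 0, grain_sd = 0, depth_jitter_sd = 0,
                       geometry_jitter_sd = 0)
  e <- sample_subject_effects(p0, 7)
  expect_equal(e$gain_offset, 0)
  expect_equal(e$grain_scale, 1)
  expect_equal(e$depth_jitter, 0)
  expect_equal(e$geometry_jitter, c(0, 0, 0))

  p <- phantom_params(base_seed = 42)
  expect_identical(sample_subject_effects(p, 3), sample_subject_effects(p, 3))
  expect_false(identical(sample_subject_effects(p, 3),
                         sample_subject_effects(p, 4)))
})

test_that("gain-offset sample SD matches the configured SD (Monte Carlo)", {
  sd_cfg <- 0.05
  p <- phantom_params(gain_sd = sd_cfg, base_seed = 9)
  g <- vapply(1:100, function(s) sample_subject_effects(p, s)$gain_offset,
              numeric(1))
  # SE of a sample SD of n normal draws is approximately sd / sqrt(2(n-1))
  se <- sd_cfg / sqrt(2 * 99)
  expect_lt(abs(sd(g) - sd_cfg), 3 * se)
})

test_that("speckle field follows Rayleigh statistics", {
  expect_equal(speckle_field(10, 10, sigma = 0), matrix(0, 10, 10))
  set.seed(1)
  f <- speckle_field(256, 256, sigma = 0.2, grain = 0, clamp = FALSE)
  # Rayleigh mean is sigma * sqrt(pi/2); SE from the Rayleigh variance
  mu <- 0.2 * sqrt(pi / 2)
  se <- sqrt((2 - pi / 2) * 0.2^2 / (256 * 256))
  expect_lt(abs(mean(f) - mu), 3 * se)
  set.seed(5)
  a <- speckle_field(32, 32, 0.25, grain = 2)
  set.seed(5)
  b <- speckle_field(32, 32, 0.25, grain = 2)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_error(speckle_field(0, 10, 0.2), class = "efastcnn_invalid_argument")
  expect_error(speckle_field(10, 10, -1), class = "efastcnn_invalid_argument")
})

test_that("severity 0 renders positive and negative pixel-identically", {
  p0 <- phantom_params(image_size = 48, severity = 0, base_seed = 2)
  e <- sample_subject_effects(p0, 1)
  for (site in c("RUQ", "BLD", "PTX_B", "HTX_B")) {
    set.seed(31)
    pos <- render_bmode(site, "positive", p0, e)
    set.seed(31)
    neg <- render_bmode(site, "negative", p0, e)
    expect_identical(pos$pixels, neg$pixels, label = site)
  }
  for (site in c("PTX_M", "HTX_M")) {
    set.seed(32)
    pos <- render_mmode(site, "positive", p0, e)
    set.seed(32)
    neg <- render_mmode(site, "negative", p0, e)
    expect_identical(pos$matrix, neg$matrix, label = site)
  }
})

test_that("HTX_B fluid region is anechoic relative to tissue above the pleura", {
  p <- phantom_params(image_size = 64, severity = 1, base_seed = 4)
  inside <- outside <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    fr <- render_bmode("HTX_B", "positive", p)
    stopifnot(!is.null(fr$mask))
    # equal-area band above the pleural line, same columns as the fluid
    rows <- which(apply(fr$mask, 1, any))
    cols <- which(apply(fr$mask, 2, any))
    above <- fr$mask
    above[] <- FALSE
    shift <- max(rows) - min(rows) + round(0.08 * 64)
    above[rows - shift, cols] <- fr$mask[rows, cols]
    inside[s] <- mean(fr$pixels[fr$mask])
    outside[s] <- mean(fr$pixels[above])
  }
  expect_lt(mean(inside), 0.5 * mean(outside))
})

test_that("B-mode frames default to the configured 512-pixel render", {
  fr <- render_bmode("RUQ", "negative", phantom_params())
  expect_equal(dim(fr$pixels), c(512, 512))
  expect_true(all(fr$pixels >= 0 & fr$pixels <= 1))
  expect_error(render_bmode("PTX_M", "negative", phantom_params()),
               class = "efastcnn_invalid_argument")
})

test_that("M-mode captures span 5 s and PTX_M positives lose temporal variation", {
  p <- phantom_params(image_size = 48, base_seed = 6)
  cap <- render_mmode("PTX_M", "negative", p)
  expect_equal(cap$duration, 5)
  expect_equal(ncol(cap$matrix), round(5 * p$columns_per_second))
  expect_equal(cap$tick_spacing, 0.2)
  expect_error(render_mmode("RUQ", "negative", p),
               class = "efastcnn_invalid_argument")

  col_variation <- function(m, rows) {
    mean(abs(m[rows, -1] - m[rows, -ncol(m)]))
  }
  for (s in 1:5) {
    set.seed(s)
    pos <- render_mmode("PTX_M", "positive", p)
    set.seed(s)
    neg <- render_mmode("PTX_M", "negative", p)
    below <- which(apply(pos$mask, 1, any))
    expect_lt(col_variation(pos$matrix, below),
              col_variation(neg$matrix, below))
  }
})

test_that("HTX_M positives widen the pleural space with an anechoic band", {
  p <- phantom_params(image_size = 48, severity = 1, base_seed = 6)
  set.seed(3)
  pos <- render_mmode("HTX_M", "positive", p)
  set.seed(3)
  neg <- render_mmode("HTX_M", "negative", p)
  expect_lt(mean(pos$matrix[pos$mask]), 0.25 * mean(neg$matrix[pos$mask]))
})

test_that("cohort generation is reproducible and subject-distinct", {
  p <- phantom_params(image_size = 16, base_seed = 13)
  expect_equal(generate_cohort(p, 0), list())
  cohort <- generate_cohort(p, 27, frames_per_class = 1, sites = "RUQ")
  expect_length(unique(vapply(cohort, function(s) s$subject_id,
                              character(1))), 27)
  again <- generate_cohort(p, 27, frames_per_class = 1, sites = "RUQ")
  expect_identical(lapply(cohort, function(s) s$items[[1]]$pixels),
                   lapply(again, function(s) s$items[[1]]$pixels))
  for (s in cohort) {
    for (it in s$items) {
      expect_identical(it$subject_id, s$subject_id)
      expect_true(all(it$pixels >= 0 & it$pixels <= 1))
    }
  }
  expect_error(generate_cohort(p, -1), class = "efastcnn_invalid_argument")
})

test_that("a fixed anechoic-region discriminant separates classes more with severity", {
  # AUROC of mean intensity inside the canonical fluid region, HTX_B
  n_per_class <- 40
  region <- canonical_fluid_region("HTX_B", 48)
  auc <- vapply(c(0, 0.5, 1), function(sev) {
    p <- phantom_params(image_size = 48, severity = sev, base_seed = 21)
    scores <- labels <- character(0)
    vals <- numeric(0)
    for (i in seq_len(n_per_class)) {
      set.seed(1000 + i)
      vals <- c(vals, -mean(render_bmode("HTX_B", "positive", p)$pixels[region]))
      labels <- c(labels, "positive")
      set.seed(5000 + i)
      vals <- c(vals, -mean(render_bmode("HTX_B", "negative", p)$pixels[region]))
      labels <- c(labels, "negative")
    }
    compute_auroc(vals, labels)
  }, numeric(1))
  expect_true(all(diff(auc) >= 0))
  expect_gt(auc[3], 0.95)
  expect_lt(abs(auc[1] - 0.5), 0.2)
})

test_that("cohort export writes PNGs and a consistent manifest", {
  root <- withr::local_tempdir()
  p <- phantom_params(image_size = 16, base_seed = 3)
  cohort <- generate_cohort(p, 2, frames_per_class = 2, sites = "RUQ")
  manifest <- export_cohort(cohort, root)
  expect_equal(nrow(manifest), 2 * 2 * 2)
  expect_true(all(file.exists(manifest$path)))
  expect_true(file.exists(file.path(root, "manifest.csv")))
  px <- png::readPNG(manifest$path[1])
  expect_equal(dim(px), c(16, 16))
})
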