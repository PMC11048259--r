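# Experiment configuration and end-to-end pipeline orchestration:
# phantom -> preprocess -> stage-1 exhaustive grid -> stage-2 Bayesian
# architecture search -> LOSO evaluation -> Grad-CAM reporting.

#' Default experiment configuration
#'
#' Study-protocol defaults: 512-pixel frames, the full 54-run grid, a
#' 100-trial Bayesian budget, five LOSO clusters over 27 subjects, patience
#' 5 with at most 100 epochs, and the per-stage sample budgets (stage 1:
#' B-mode 2500/500/500 and M-mode 1250/250/250 train/val/test; LOSO:
#' B-mode 16000/2000/2000 and M-mode 4000/500/500). `scale` shrinks every
#' budget proportionally for desk-scale runs.
#'
#' @return a named list of defaults
#' @export
default_config <- function() {
  list(
    image_size = 512,
    sites = .SITE_CODES,
    severity = 1,
    n_subjects = 27,
    frames_per_class = 40,
    mmode_sections = 25,
    scale = 1,
    base_seed = 1,
    run_id = NULL,
    export_images = FALSE,
    stages = list(stage1 = TRUE, stage2 = TRUE, loso = TRUE, explain = TRUE),
    max_epochs = 100,
    patience = 5,
    batch_sizes = .BATCH_SIZES,
    optimizers = .OPTIMIZERS,
    learning_rates = .LEARNING_RATES,
    activators = .ACTIVATORS,
    stage1_budgets = list(B = list(train = 2500, val = 500, test = 500),
                          M = list(train = 1250, val = 250, test = 250)),
    stage2_budget = 100,
    stage2_objective = "blind",  # or "validation"
    k = 5,
    loso_budgets = list(B = list(train = 16000, val = 2000, test = 2000),
                        M = list(train = 4000, val = 500, test = 500)),
    loso_architectures = c("simple", "optimized", "MobileNetV2", "DarkNet53",
                           "ShrapML"),
    gradcam_per_category = 5,
    manual_train_config = NULL,  # used when stage1 is disabled
    out_root = "efastcnn-runs"
  )
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML file, fills unset fields with [default_config()] values,
#' and validates; every offending field is reported in one error message.
#'
#' @param path YAML file path
#' @return object of class `experiment_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_with("efastcnn_not_found", paste0("config file not found: ", path))
  }
  user <- yaml::read_yaml(path) %||% list()
  as_experiment_config(user)
}

#' Coerce a list of overrides into a validated experiment configuration
#'
#' @param overrides named list overriding [default_config()] fields
#' @return object of class `experiment_config`
#' @export
as_experiment_config <- function(overrides = list()) {
  config <- default_config()
  for (nm in names(overrides)) {
    if (!nm %in% names(config)) {
      stop_with("efastcnn_invalid_argument",
                paste0("unknown config field: ", nm))
    }
    if (is.list(config[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(config[[nm]]))) {
      for (sub in names(overrides[[nm]])) {
        config[[nm]][[sub]] <- overrides[[nm]][[sub]]
      }
    } else {
      config[[nm]] <- overrides[[nm]]
    }
  }
  problems <- character(0)
  note <- function(cond, msg) if (cond) problems <<- c(problems, msg)
  note(!all(config$sites %in% .SITE_CODES),
       "sites: unknown scan site code")
  note(config$severity < 0 || config$severity > 1,
       "severity: must lie in [0, 1]")
  note(config$scale <= 0, "scale: must be > 0")
  note(config$n_subjects < config$k,
       "n_subjects: need at least k subjects for LOSO")
  note(config$k < 2, "k: need at least 2 LOSO clusters")
  note(config$max_epochs < 1, "max_epochs: must be >= 1")
  note(config$patience < 1, "patience: must be >= 1")
  note(config$stage2_budget < 1, "stage2_budget: must be >= 1")
  note(!all(config$batch_sizes %in% .BATCH_SIZES),
       "batch_sizes: values must come from {16, 64, 128}")
  note(!all(config$optimizers %in% .OPTIMIZERS),
       "optimizers: values must come from {RMSprop, ADAM, SGDM}")
  note(!all(vapply(config$learning_rates,
                   function(x) any(abs(x - .LEARNING_RATES) < 1e-12),
                   logical(1))),
       "learning_rates: values must come from {0.001, 0.0005, 0.0001}")
  note(!all(config$activators %in% .ACTIVATORS),
       "activators: values must come from {softmax, softplus}")
  note(!config$stage2_objective %in% c("blind", "validation"),
       "stage2_objective: must be 'blind' or 'validation'")
  if (length(problems) > 0) {
    stop_with("efastcnn_invalid_config",
              paste0("invalid configuration:\n  ",
                     paste(problems, collapse = "\n  ")))
  }
  structure(config, class = c("experiment_config", "list"))
}

scaled_budget <- function(budgets, scale) {
  lapply(budgets, function(b) max(2L, 2L * ceiling(b * scale / 2)))
}

# balanced stage-1/2 datasets: subjects split into a fit pool and a blind
# pool; train/val sampled from the fit pool, blind test from the blind pool
stage_datasets <- function(store, site, subjects, budgets, input_size,
                           seed) {
  with_seed(derive_seed(seed, 201L), {
    n_fit <- max(2L, ceiling(length(subjects) * 2 / 3))
    fit_pool <- sample(subjects, n_fit)
    blind_pool <- setdiff(subjects, fit_pool)
    n_tr <- budgets$train %/% 2
    n_va <- budgets$val %/% 2
    both <- balanced_sample(store, site, fit_pool, n_tr + n_va)
    lab <- vapply(both, function(f) f$label, character(1))
    tr_idx <- c(which(lab == "positive")[seq_len(n_tr)],
                which(lab == "negative")[seq_len(n_tr)])
    test <- balanced_sample(store, site, blind_pool, budgets$test %/% 2)
    list(train = frames_to_tensor(both[tr_idx], target = input_size),
         val = frames_to_tensor(both[-tr_idx], target = input_size),
         test = frames_to_tensor(test, target = input_size))
  })
}

#' Run the full optimization and evaluation pipeline
#'
#' Executes the enabled stages in order phantom -> preprocess -> stage 1 ->
#' stage 2 -> LOSO -> Grad-CAM for every configured site, writing all
#' artifacts (frozen config, manifests, per-run CSVs, score-table and
#' aggregate JSONs, overlay PNGs) under one run directory. Every random
#' stream is seeded from `config$base_seed`. A stage failure aborts later
#' stages for that run; partial outputs are retained.
#'
#' @param config an `experiment_config` (see [as_experiment_config()])
#' @return list with `status` (0 on success), `run_dir`, and per-site
#'   results
#' @export
run_pipeline <- function(config) {
  config <- if (inherits(config, "experiment_config")) config else {
    as_experiment_config(config)
  }
  run_id <- config$run_id %||% format(Sys.time(), "run-%Y%m%d-%H%M%S")
  run_dir <- file.path(config$out_root, run_id)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(run_dir, "config.yaml"))
  status <- 0L
  site_results <- list()

  cohort <- generate_cohort(
    phantom_params(image_size = config$image_size,
                   severity = config$severity,
                   base_seed = config$base_seed),
    n_subjects = config$n_subjects,
    frames_per_class = config$frames_per_class,
    sites = config$sites)
  cohort <- cohort_to_frames(cohort, n_sections = config$mmode_sections,
                             target = config$image_size)
  store <- build_datastore(cohort)
  write.csv(store$index, file.path(run_dir, "datastore-index.csv"),
            row.names = FALSE)
  if (isTRUE(config$export_images)) {
    export_cohort(cohort, file.path(run_dir, "images"))
  }

  for (site in config$sites) {
    res <- tryCatch({
      site_dir <- file.path(run_dir, site)
      dir.create(site_dir, recursive = TRUE, showWarnings = FALSE)
      mode <- site_mode(site)
      subjects <- unique(store$index$subject[store$index$site == site])
      out <- list()

      budgets1 <- scaled_budget(config$stage1_budgets[[mode]], config$scale)
      ds <- stage_datasets(store, site, subjects, budgets1,
                           config$image_size,
                           derive_seed(config$base_seed, 11L,
                                       match(site, .SITE_CODES)))

      selected <- config$manual_train_config
      if (isTRUE(config$stages$stage1)) {
        grid <- enumerate_grid(config$batch_sizes, config$optimizers,
                               config$learning_rates, config$activators,
                               config$max_epochs, config$patience)
        s1 <- run_stage1(ds$train, ds$val, ds$test, grid,
                         augment = augment_policy(),
                         seed = derive_seed(config$base_seed, 12L,
                                            match(site, .SITE_CODES)),
                         input_size = config$image_size,
                         csv = file.path(site_dir, "stage1-runs.csv"))
        jsonlite::write_json(lapply(unclass(s1$table), as.list),
                             file.path(site_dir, "stage1-scores.json"),
                             auto_unbox = TRUE, digits = NA)
        selected <- s1$selected
        out$stage1 <- s1
      }
      if (is.null(selected)) {
        stop_with("efastcnn_invalid_config",
                  "stage1 disabled but no manual_train_config supplied")
      }
      selected$max_epochs <- as.integer(config$max_epochs)
      selected$patience <- as.integer(config$patience)
      out$selected <- selected

      top_specs <- NULL
      if (isTRUE(config$stages$stage2)) {
        objective <- function(spec) {
          run_seed <- derive_seed(config$base_seed, 13L,
                                  match(site, .SITE_CODES),
                                  spec$filter_size, spec$n_layers,
                                  spec$base_filters)
          model <- build_custom_cnn(spec, selected$activator,
                                    input_size = config$image_size,
                                    seed = run_seed)
          fit <- train_with_early_stopping(model, selected, ds$train, ds$val,
                                           augment = augment_policy(),
                                           seed = run_seed)
          if (fit$diverged) return(0)
          if (config$stage2_objective == "blind") {
            blind_accuracy(fit$model, ds$test)
          } else {
            blind_accuracy(fit$model, ds$val)
          }
        }
        history <- run_optimization(objective, default_space(),
                                    budget = config$stage2_budget,
                                    seed = derive_seed(config$base_seed, 14L,
                                                       match(site,
                                                             .SITE_CODES)))
        write.csv(history$df, file.path(site_dir, "stage2-history.csv"),
                  row.names = FALSE)
        top_specs <- select_top_k(history, 3)
        out$stage2 <- history
        out$top_specs <- top_specs
      }

      if (isTRUE(config$stages$loso)) {
        plan <- assign_clusters(subjects, k = config$k,
                                seed = derive_seed(config$base_seed, 15L))
        jsonlite::write_json(as.list(unclass(plan)),
                             file.path(site_dir, "loso-plan.json"),
                             auto_unbox = TRUE)
        builders <- list()
        for (arch in config$loso_architectures) {
          builders[[arch]] <- if (arch == "simple") {
            function(activator, input_size, seed) {
              build_simple_cnn(activator, input_size, seed)
            }
          } else if (arch == "optimized") {
            spec <- if (!is.null(top_specs)) top_specs[[1]] else {
              arch_spec(3, 3, 16, 2, 0.5)
            }
            local({
              spec <- spec
              function(activator, input_size, seed) {
                build_custom_cnn(spec, activator, input_size, seed)
              }
            })
          } else {
            local({
              nm <- arch
              function(activator, input_size, seed) {
                reference_model(nm, pretrained = FALSE,
                                activator = activator,
                                input_size = input_size, seed = seed)
              }
            })
          }
        }
        loso <- run_loso(builders, plan, store, site, selected,
                         budgets = config$loso_budgets[[mode]],
                         scale = config$scale, augment = loso_policy(),
                         input_size = config$image_size,
                         seed = derive_seed(config$base_seed, 16L,
                                            match(site, .SITE_CODES)))
        write.csv(loso$per_split, file.path(site_dir, "loso-per-split.csv"),
                  row.names = FALSE)
        jsonlite::write_json(loso$aggregate,
                             file.path(site_dir, "loso-aggregate.json"),
                             dataframe = "rows", auto_unbox = TRUE,
                             digits = NA)
        out$loso <- loso
      }

      if (isTRUE(config$stages$explain)) {
        # audit the last selected architecture on the stage-1 blind set
        seed_x <- derive_seed(config$base_seed, 17L,
                              match(site, .SITE_CODES))
        model <- build_simple_cnn(selected$activator,
                                  input_size = config$image_size,
                                  seed = seed_x)
        fit <- train_with_early_stopping(model, selected, ds$train, ds$val,
                                         augment = NULL, seed = seed_x)
        pred <- predict(fit$model, ds$test$x)
        records <- data.frame(id = seq_along(pred$labels),
                              predicted = pred$labels, truth = ds$test$y,
                              stringsAsFactors = FALSE)
        groups <- with_seed(derive_seed(config$base_seed, 18L),
                            sample_outcomes(records,
                                            config$gradcam_per_category))
        for (cc in names(groups)) {
          for (r in seq_len(nrow(groups[[cc]]))) {
            id <- groups[[cc]]$id[r]
            fr <- new_frame(ds$test$x[, , 1, id], site, "blind",
                            ds$test$y[id], id)
            hm <- gradcam(fit$model, fr, target = "positive")
            write_gradcam_overlay(fr, hm,
                                  file.path(site_dir, "gradcam", cc,
                                            sprintf("%02d.png", r)))
          }
        }
        out$explain <- lapply(groups, nrow)
      }
      out
    }, error = function(e) {
      warning(sprintf("site %s failed: %s", site, conditionMessage(e)))
      status <<- 1L
      list(error = conditionMessage(e))
    })
    site_results[[site]] <- res
  }
  list(status = status, run_dir = run_dir, sites = site_results)
}
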