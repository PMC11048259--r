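# Leave-one-subject-out (LOSO) protocol: balanced subject clustering,
# per-split dataset construction with a hard no-leakage guarantee, training
# of every candidate architecture on every split, and cross-split metric
# aggregation.

#' Assign subjects to balanced LOSO clusters
#'
#' Random balanced partition of the subjects into `k` clusters whose sizes
#' differ by at most one (27 subjects into the default 5 clusters gives
#' sizes 6,6,5,5,5). Each cluster plays the role of one held-out "subject".
#' Deterministic under a fixed seed.
#'
#' @param subject_ids character vector of subject identifiers
#' @param k number of clusters (default 5; must not exceed the number of
#'   subjects)
#' @param seed integer seed
#' @return named integer vector (class `loso_plan`) mapping subject id to
#'   cluster index in `1..k`
#' @export
assign_clusters <- function(subject_ids, k = 5, seed = 1L) {
  n <- length(subject_ids)
  if (k < 2 || n < k) {
    stop_with("efastcnn_invalid_argument",
              "need k >= 2 and at least k subjects")
  }
  with_seed(derive_seed(seed, 501L), {
    shuffled <- sample(subject_ids)
    plan <- setNames(rep(seq_len(k), length.out = n), shuffled)
    structure(plan[subject_ids], k = k, class = "loso_plan")
  })
}

#' Build one LOSO split
#'
#' Training and validation frames are drawn (class-balanced, without
#' replacement and without overlap) exclusively from the non-holdout
#' clusters; blind-test frames exclusively from the holdout cluster. The
#' default budgets are the study protocol's: B-mode 16,000 train / 2,000
#' val / 2,000 test total frames, M-mode 4,000 / 500 / 500, each split
#' evenly between classes and scalable with `scale`.
#'
#' @param plan a [assign_clusters()] plan
#' @param holdout cluster index in `1..k` to hold out
#' @param store a `datastore` of frames
#' @param site site code
#' @param budgets list with total counts `train`, `val`, `test` (default:
#'   study budgets for the site's mode)
#' @param scale multiplier applied to the budgets (counts are rounded up to
#'   an even total)
#' @param seed integer seed
#' @return list with `train`, `val`, `test` frame lists and a `subjects`
#'   audit list
#' @export
build_split <- function(plan, holdout, store, site, budgets = NULL,
                        scale = 1, seed = 1L) {
  k <- attr(plan, "k")
  if (!holdout %in% seq_len(k)) {
    stop_with("efastcnn_invalid_argument", "holdout must lie in 1..k")
  }
  if (is.null(budgets)) {
    budgets <- if (site_mode(site) == "B") {
      list(train = 16000, val = 2000, test = 2000)
    } else {
      list(train = 4000, val = 500, test = 500)
    }
  }
  per_class <- lapply(budgets, function(b) max(1L, ceiling(b * scale / 2)))
  subjects <- names(plan)
  test_subjects <- subjects[plan == holdout]
  fit_subjects <- subjects[plan != holdout]
  with_seed(derive_seed(seed, 601L, holdout), {
    # train and val drawn jointly so they never share a frame
    both <- balanced_sample(store, site, fit_subjects,
                            per_class$train + per_class$val)
    lab <- vapply(both, function(f) f$label, character(1))
    tr <- c(which(lab == "positive")[seq_len(per_class$train)],
            which(lab == "negative")[seq_len(per_class$train)])
    train <- both[tr]
    val <- both[-tr]
    test <- balanced_sample(store, site, test_subjects, per_class$test)
    list(train = train[sample.int(length(train))], val = val, test = test,
         subjects = list(fit = fit_subjects, test = test_subjects))
  })
}

# audit helper: subjects actually present in a frame list
split_subjects <- function(frames) {
  unique(vapply(frames, function(f) f$subject_id, character(1)))
}

metric_row <- function(ms) {
  data.frame(accuracy = ms$accuracy, precision = ms$precision,
             recall = ms$recall, specificity = ms$specificity, f1 = ms$f1,
             auroc = ms$auroc)
}

#' Evaluate a trained model on a blind test tensor
#'
#' Computes the full confusion-derived metric set plus AUROC from the
#' positive-class probability (softmax probability, or L1-normalized
#' softplus outputs).
#'
#' @param model a trained `cnn_model`
#' @param test tensor dataset (see [frames_to_tensor()])
#' @return a `metric_set`
#' @export
evaluate_model <- function(model, test) {
  pred <- predict(model, test$x)
  ms <- compute_metrics(confusion(pred$labels, test$y))
  ms$auroc <- compute_auroc(pred$probs["positive", ], test$y)
  ms
}

#' Run the LOSO cross-validation comparison
#'
#' For every architecture builder and every holdout cluster: build the
#' split, train with validation-patience early stopping, and evaluate the
#' blind-test metric suite and split-validation accuracy. Leakage is
#' asserted on every split (train/val and test subject sets must be
#' disjoint). Metrics are aggregated as mean and sample (n-1) standard
#' deviation over the k splits. A failed split is recorded with a warning
#' and aggregation proceeds over the completed splits.
#'
#' @param builders named list of `function(activator, input_size, seed)`
#'   returning a `cnn_model`
#' @param plan a [assign_clusters()] plan
#' @param store a `datastore`
#' @param site site code
#' @param config a [train_config()] (the stage-1 selection)
#' @param budgets,scale see [build_split()]
#' @param augment augmentation policy (default [loso_policy()])
#' @param input_size model input edge; frames are resized to it
#' @param seed integer seed
#' @return list with `per_split` (data.frame: architecture, split, metrics,
#'   val_accuracy) and `aggregate` (data.frame of means and sds)
#' @export
run_loso <- function(builders, plan, store, site, config,
                     budgets = NULL, scale = 1, augment = loso_policy(),
                     input_size = 64, seed = 1L) {
  k <- attr(plan, "k")
  rows <- list()
  for (arch in names(builders)) {
    for (split in seq_len(k)) {
      row <- tryCatch({
        sp <- build_split(plan, split, store, site, budgets, scale,
                          seed = derive_seed(seed, 701L, split))
        fit_subj <- unique(c(split_subjects(sp$train), split_subjects(sp$val)))
        stopifnot(length(intersect(fit_subj, split_subjects(sp$test))) == 0)
        run_seed <- derive_seed(seed, 702L, match(arch, names(builders)),
                                split)
        model <- builders[[arch]](config$activator, input_size, run_seed)
        tr <- frames_to_tensor(sp$train, target = input_size)
        va <- frames_to_tensor(sp$val, target = input_size)
        te <- frames_to_tensor(sp$test, target = input_size)
        fit <- train_with_early_stopping(model, config, tr, va,
                                         augment = augment, seed = run_seed)
        ms <- evaluate_model(fit$model, te)
        val_acc <- blind_accuracy(fit$model, va)
        cbind(data.frame(site = site, architecture = arch, split = split,
                         val_accuracy = val_acc, epochs_run = fit$epochs_run,
                         stringsAsFactors = FALSE),
              metric_row(ms))
      }, error = function(e) {
        warning(sprintf("LOSO split %d for %s failed: %s", split, arch,
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  per_split <- do.call(rbind, rows)
  metrics <- c("val_accuracy", "accuracy", "precision", "recall",
               "specificity", "f1", "auroc")
  agg <- do.call(rbind, lapply(split(per_split, per_split$architecture),
    function(d) {
      out <- data.frame(site = d$site[1], architecture = d$architecture[1],
                        n_splits = nrow(d))
      for (m in metrics) {
        out[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
        out[[paste0(m, "_sd")]] <- sd(d[[m]], na.rm = TRUE)
      }
      out
    }))
  rownames(agg) <- NULL
  list(per_split = per_split, aggregate = agg)
}
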