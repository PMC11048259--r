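test_that("confusion counts enumerate the four outcomes", {
  allpos <- confusion(rep("positive", 10), rep("positive", 10))
  expect_equal(c(allpos$TP, allpos$TN, allpos$FP, allpos$FN), c(10, 0, 0, 0))
  mixed <- confusion(c("positive", "positive", "negative", "negative"),
                     c("positive", "negative", "positive", "negative"))
  expect_equal(c(mixed$TP, mixed$FP, mixed$FN, mixed$TN), c(1, 1, 1, 1))
  expect_equal(mixed$TP + mixed$TN + mixed$FP + mixed$FN, 4)
  expect_error(confusion("positive", c("positive", "negative")),
               class = "efastcnn_invalid_argument")
})

test_that("metrics match their hand-evaluated definitions", {
  ms <- compute_metrics(list(TP = 8, TN = 6, FP = 2, FN = 4))
  expect_equal(ms$accuracy, 0.70)
  expect_equal(ms$precision, 0.80)
  expect_equal(ms$recall, 0.6667, tolerance = 1e-4)
  expect_equal(ms$specificity, 0.75)
  expect_equal(ms$f1, 0.7273, tolerance = 1e-4)

  perfect <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall",
                                "specificity", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, specificity = 1,
                 f1 = 1))

  degen <- compute_metrics(list(TP = 0, TN = 7, FP = 0, FN = 3))
  expect_true(is.na(degen$precision))
  expect_equal(degen$accuracy, 0.7)
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               class = "efastcnn_invalid_argument")
})

test_that("accuracy identity holds on random confusion tables", {
  set.seed(7)
  for (i in 1:50) {
    cc <- list(TP = sample(0:30, 1), TN = sample(0:30, 1),
               FP = sample(0:30, 1), FN = sample(1:30, 1))
    ms <- compute_metrics(cc)
    P <- cc$TP + cc$FN
    N <- cc$TN + cc$FP
    lhs <- ms$accuracy
    rec <- if (P > 0) cc$TP / P else 0
    spec <- if (N > 0) cc$TN / N else 0
    expect_equal(lhs, (rec * P + spec * N) / (P + N))
  }
})

test_that("AUROC equals brute-force pair ordering and the pROC oracle", {
  expect_equal(compute_auroc(c(0.9, 0.8, 0.2, 0.1),
                             c("positive", "positive", "negative",
                               "negative")), 1.0)
  expect_equal(compute_auroc(rep(0.5, 6),
                             rep(c("positive", "negative"), 3)), 0.5)
  expect_equal(compute_auroc(c(0.9, 0.8, 0.4, 0.3),
                             c("positive", "negative", "positive",
                               "negative")), 0.75)
  expect_error(compute_auroc(1:3, rep("positive", 3)),
               class = "efastcnn_invalid_argument")

  brute <- function(scores, truth) {
    p <- scores[truth == "positive"]
    n <- scores[truth == "negative"]
    tot <- 0
    for (a in p) for (b in n) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(p) * length(n))
  }
  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    truth <- c("positive", "negative",
               sample(c("positive", "negative"), n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # ties likely
    got <- compute_auroc(scores, truth)
    expect_equal(got, brute(scores, truth))
    if (requireNamespace("pROC", quietly = TRUE)) {
      oracle <- as.numeric(pROC::auc(pROC::roc(
        response = truth, predictor = scores, levels = c("negative",
                                                         "positive"),
        direction = "<", quiet = TRUE)))
      expect_equal(got, oracle)
    }
  }
})

test_that("cluster assignment is balanced, deterministic, and validated", {
  ids <- subject_ids(5)
  plan <- assign_clusters(ids, k = 5, seed = 1)
  expect_equal(sort(unname(plan)), 1:5)

  plan27 <- assign_clusters(subject_ids(27), seed = 4)
  expect_equal(attr(plan27, "k"), 5)
  expect_equal(sort(unname(table(plan27)), decreasing = TRUE),
               c(6, 6, 5, 5, 5), ignore_attr = TRUE)
  expect_identical(unclass(plan27),
                   unclass(assign_clusters(subject_ids(27), seed = 4)))
  expect_error(assign_clusters(subject_ids(3), k = 5),
               class = "efastcnn_invalid_argument")
})

test_that("LOSO splits are balanced and leak-free for every holdout", {
  store <- make_tiny_store(site = "HTX_B", n_subjects = 6, per_class = 8,
                           size = 12, seed = 51)
  plan <- assign_clusters(subject_ids(6), k = 3, seed = 2)
  budgets <- list(train = 12, val = 4, test = 6)
  for (holdout in 1:3) {
    sp <- build_split(plan, holdout, store, "HTX_B", budgets, seed = 7)
    test_subj <- unique(vapply(sp$test, function(f) f$subject_id,
                               character(1)))
    fit_subj <- unique(vapply(c(sp$train, sp$val), function(f) f$subject_id,
                              character(1)))
    expect_length(intersect(test_subj, fit_subj), 0)
    expect_true(all(test_subj %in% names(plan)[plan == holdout]))
    labs <- vapply(sp$train, function(f) f$label, character(1))
    expect_equal(sum(labs == "positive"), sum(labs == "negative"))
    expect_length(sp$train, 12)
    expect_length(sp$val, 4)
    expect_length(sp$test, 6)
    # train and val never share a frame
    key <- function(f) paste(f$subject_id, f$label,
                             paste(f$provenance, collapse = ":"))
    expect_length(intersect(vapply(sp$train, key, character(1)),
                            vapply(sp$val, key, character(1))), 0)
  }
  expect_error(build_split(plan, 9, store, "HTX_B", budgets),
               class = "efastcnn_invalid_argument")
})

test_that("run_loso produces one metric set per split and a cross-split aggregate", {
  store <- make_tiny_store(site = "HTX_B", n_subjects = 6, per_class = 8,
                           size = 16, seed = 61)
  plan <- assign_clusters(subject_ids(6), k = 3, seed = 3)
  cfg <- train_config(16, "ADAM", 0.001, "softmax", max_epochs = 3,
                      patience = 5)
  builders <- list(simple = function(activator, input_size, seed) {
    build_simple_cnn(activator, input_size, seed)
  })
  res <- run_loso(builders, plan, store, "HTX_B", cfg,
                  budgets = list(train = 16, val = 8, test = 8),
                  augment = NULL, input_size = 16, seed = 5)
  expect_equal(nrow(res$per_split), 3)
  expect_equal(res$aggregate$n_splits, 3)
  expect_true(all(res$per_split$accuracy >= 0 & res$per_split$accuracy <= 1))
  expect_equal(res$aggregate$accuracy_mean, mean(res$per_split$accuracy))
  expect_equal(res$aggregate$accuracy_sd, sd(res$per_split$accuracy))
})
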