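test_that("validation patience fires on the scripted loss sequence", {
  tr <- early_stop_trace(c(1.0, 0.9, 0.95, 0.96, 0.97, 0.98, 0.99),
                         patience = 5)
  expect_equal(tr$stop_epoch, 7)
  expect_equal(tr$best_epoch, 2)
  expect_true(tr$stopped_early)

  dec <- early_stop_trace(seq(1, 0.1, length.out = 20), patience = 5)
  expect_equal(dec$stop_epoch, 20)
  expect_false(dec$stopped_early)
  expect_equal(dec$best_epoch, 20)
})

test_that("the stopping rule matches a reference simulator on random sequences", {
  # independent oracle: explicit state machine over best-so-far and a
  # consecutive non-improvement counter
  oracle <- function(losses, patience) {
    best <- Inf; best_e <- 0; run <- 0
    for (e in seq_along(losses)) {
      if (losses[e] < best) {
        best <- losses[e]; best_e <- e; run <- 0
      } else {
        run <- run + 1
        if (run == patience) return(c(e, best_e))
      }
    }
    c(length(losses), best_e)
  }
  set.seed(99)
  for (i in 1:100) {
    losses <- round(runif(sample(3:30, 1), 0, 2), 2)  # ties occur often
    patience <- sample(1:6, 1)
    got <- early_stop_trace(losses, patience)
    exp <- oracle(losses, patience)
    expect_equal(c(got$stop_epoch, got$best_epoch), exp)
  }
})

test_that("training configs carry the protocol defaults", {
  cfg <- train_config(16, "RMSprop", 0.001, "softmax")
  expect_equal(cfg$max_epochs, 100L)
  expect_equal(cfg$patience, 5L)
  expect_error(train_config(32, "ADAM", 0.001, "softmax"),
               class = "efastcnn_invalid_argument")
  expect_error(train_config(16, "AdaGrad", 0.001, "softmax"),
               class = "efastcnn_invalid_argument")
})

test_that("training reduces loss, respects patience, and restores best weights", {
  store <- make_tiny_store(site = "HTX_B", n_subjects = 3, per_class = 12,
                           size = 16, seed = 31)
  set.seed(8)
  tr <- frames_to_tensor(balanced_sample(store, "HTX_B", subject_ids(2), 20))
  va <- frames_to_tensor(balanced_sample(store, "HTX_B", "subj03", 8))
  cfg <- train_config(16, "ADAM", 0.001, "softmax", max_epochs = 8,
                      patience = 2)
  model <- build_simple_cnn("softmax", input_size = 16, seed = 5)
  fit <- train_with_early_stopping(model, cfg, tr, va, seed = 9)
  expect_false(fit$diverged)
  expect_lte(fit$epochs_run, 8)
  expect_lte(fit$epochs_run, fit$best_epoch + cfg$patience)
  expect_lt(fit$history$train_loss[fit$epochs_run],
            fit$history$train_loss[1])
  # restored weights reproduce the recorded best validation loss
  expect_equal(efastcnn:::nn_eval_loss(fit$model, va$x,
                                       efastcnn:::label_index(va$y)),
               fit$best_val_loss)
  # determinism: identical seed, identical history
  model2 <- build_simple_cnn("softmax", input_size = 16, seed = 5)
  fit2 <- train_with_early_stopping(model2, cfg, tr, va, seed = 9)
  expect_equal(fit2$history, fit$history)

  expect_error(
    train_with_early_stopping(model, cfg,
                              list(x = array(0, c(16, 16, 1, 0)),
                                   y = character(0)), va),
    class = "efastcnn_insufficient_data")
})

test_that("each optimizer takes a finite descent step", {
  store <- make_tiny_store(site = "HTX_B", n_subjects = 2, per_class = 6,
                           size = 16, seed = 17)
  set.seed(4)
  tr <- frames_to_tensor(balanced_sample(store, "HTX_B", subject_ids(2), 10))
  for (opt in c("RMSprop", "ADAM", "SGDM")) {
    cfg <- train_config(16, opt, 0.001, "softmax", max_epochs = 2,
                        patience = 5)
    model <- build_simple_cnn("softmax", input_size = 16, seed = 2)
    fit <- train_with_early_stopping(model, cfg, tr, tr, seed = 3)
    expect_false(fit$diverged)
    expect_true(all(is.finite(fit$history$val_loss)))
  }
})

test_that("softplus-head training works end to end", {
  store <- make_tiny_store(site = "HTX_B", n_subjects = 2, per_class = 8,
                           size = 16, seed = 23)
  set.seed(6)
  tr <- frames_to_tensor(balanced_sample(store, "HTX_B", subject_ids(2), 12))
  cfg <- train_config(16, "ADAM", 0.001, "softplus", max_epochs = 4,
                      patience = 5)
  model <- build_simple_cnn("softplus", input_size = 16, seed = 7)
  fit <- train_with_early_stopping(model, cfg, tr, tr, seed = 8)
  expect_false(fit$diverged)
  expect_lt(fit$history$train_loss[4], fit$history$train_loss[1])
  probs <- predict(fit$model, tr$x)$probs
  expect_equal(unname(colSums(probs)), rep(1, ncol(probs)))
})
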