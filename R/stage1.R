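# Stage 1: exhaustive grid over training hyperparameters with the
# score-aggregation selection rule.

.BATCH_SIZES <- c(16L, 64L, 128L)
.OPTIMIZERS <- c("RMSprop", "ADAM", "SGDM")
.LEARNING_RATES <- c(0.001, 0.0005, 0.0001)
.ACTIVATORS <- c("softmax", "softplus")

#' Stage-1 training configuration
#'
#' @param batch_size one of 16, 64, 128
#' @param optimizer one of RMSprop, ADAM, SGDM
#' @param learning_rate one of 0.001, 0.0005, 0.0001
#' @param activator one of softmax, softplus
#' @param max_epochs epoch cap (study protocol: 100)
#' @param patience validation-patience epochs (study protocol: 5)
#' @return object of class `train_config`
#' @export
train_config <- function(batch_size, optimizer, learning_rate, activator,
                         max_epochs = 100, patience = 5) {
  if (!batch_size %in% .BATCH_SIZES ||
      !optimizer %in% .OPTIMIZERS ||
      !any(abs(learning_rate - .LEARNING_RATES) < 1e-12) ||
      !activator %in% .ACTIVATORS) {
    stop_with("efastcnn_invalid_argument",
              "config fields must be drawn from the stage-1 grid values")
  }
  structure(list(batch_size = as.integer(batch_size), optimizer = optimizer,
                 learning_rate = learning_rate, activator = activator,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf("<train_config batch=%d opt=%s lr=%g act=%s>\n",
              x$batch_size, x$optimizer, x$learning_rate, x$activator))
  invisible(x)
}

#' Enumerate the exhaustive training grid
#'
#' Full Cartesian product of batch size, optimizer, learning rate and final
#' activator in deterministic order (batch varies slowest, then optimizer,
#' learning rate, activator). The full grid has 3 x 3 x 3 x 2 = 54 unique
#' configurations; passing subsets of the value lists produces the
#' scaled-down sub-grids used for desk-scale runs.
#'
#' @param batch_sizes,optimizers,learning_rates,activators value subsets
#'   (defaults: the full grids)
#' @param max_epochs,patience carried onto every configuration
#' @return list of [train_config()] objects
#' @export
enumerate_grid <- function(batch_sizes = .BATCH_SIZES,
                           optimizers = .OPTIMIZERS,
                           learning_rates = .LEARNING_RATES,
                           activators = .ACTIVATORS,
                           max_epochs = 100, patience = 5) {
  out <- list()
  for (b in batch_sizes) {
    for (o in optimizers) {
      for (lr in learning_rates) {
        for (a in activators) {
          out[[length(out) + 1L]] <-
            train_config(b, o, lr, a, max_epochs, patience)
        }
      }
    }
  }
  out
}

#' Score a model from its blind-test accuracy
#'
#' Models at or above 0.5 accuracy contribute `accuracy - 0.5`; models below
#' 0.5 contribute 0. A 0.74-accuracy run therefore adds 0.24 to the score of
#' each of its four parameter values.
#'
#' @param blind_accuracy fraction in `[0, 1]`
#' @return non-negative score
#' @export
score_model <- function(blind_accuracy) {
  if (!is.finite(blind_accuracy) || blind_accuracy < 0 || blind_accuracy > 1) {
    stop_with("efastcnn_invalid_argument", "accuracy must lie in [0, 1]")
  }
  if (blind_accuracy >= 0.5) blind_accuracy - 0.5 else 0
}

#' Stage-1 run result
#'
#' @param config a [train_config()]
#' @param blind_accuracy blind-test accuracy in `[0, 1]`
#' @param epochs_run epochs actually trained
#' @param best_val_loss best validation loss reached
#' @return object of class `run_result`
#' @export
run_result <- function(config, blind_accuracy, epochs_run = NA_integer_,
                       best_val_loss = NA_real_) {
  if (!is.finite(blind_accuracy) || blind_accuracy < 0 || blind_accuracy > 1) {
    stop_with("efastcnn_invalid_argument", "accuracy must lie in [0, 1]")
  }
  structure(list(config = config, blind_accuracy = blind_accuracy,
                 epochs_run = epochs_run, best_val_loss = best_val_loss),
            class = "run_result")
}

empty_score_table <- function() {
  structure(list(
    batch_size = setNames(rep(0, 3), as.character(.BATCH_SIZES)),
    optimizer = setNames(rep(0, 3), .OPTIMIZERS),
    learning_rate = setNames(rep(0, 3), format(.LEARNING_RATES)),
    activator = setNames(rep(0, 2), .ACTIVATORS)
  ), class = "score_table")
}

#' Aggregate run scores into a per-parameter score table
#'
#' Each run's score ([score_model()] of its blind accuracy) is added to the
#' entry of its value for every one of the four hyperparameters, so every
#' parameter's column sums to the same grand total.
#'
#' @param results list of [run_result()]s
#' @return object of class `score_table`
#' @export
aggregate_scores <- function(results) {
  tab <- empty_score_table()
  for (r in results) {
    s <- score_model(r$blind_accuracy)
    cfg <- r$config
    tab$batch_size[as.character(cfg$batch_size)] <-
      tab$batch_size[as.character(cfg$batch_size)] + s
    tab$optimizer[cfg$optimizer] <- tab$optimizer[cfg$optimizer] + s
    lr_key <- format(.LEARNING_RATES)[which.min(abs(.LEARNING_RATES -
                                                      cfg$learning_rate))]
    tab$learning_rate[lr_key] <- tab$learning_rate[lr_key] + s
    tab$activator[cfg$activator] <- tab$activator[cfg$activator] + s
  }
  tab
}

#' Select the optimal value of each hyperparameter
#'
#' Per-parameter argmax over the accumulated scores; ties are broken in
#' favour of the first value in the declared enumeration order (and logged
#' with a message).
#'
#' @param table a [aggregate_scores()] score table
#' @param max_epochs,patience carried onto the selected configuration
#' @return a [train_config()] with the winning value of each parameter
#' @export
select_parameters <- function(table, max_epochs = 100, patience = 5) {
  pick <- function(scores, what) {
    w <- which(scores == max(scores))
    if (length(w) > 1) {
      message(sprintf("tie on %s between {%s}; keeping '%s'", what,
                      paste(names(scores)[w], collapse = ", "),
                      names(scores)[w[1]]))
    }
    w[1]
  }
  train_config(
    .BATCH_SIZES[pick(table$batch_size, "batch_size")],
    .OPTIMIZERS[pick(table$optimizer, "optimizer")],
    .LEARNING_RATES[pick(table$learning_rate, "learning_rate")],
    .ACTIVATORS[pick(table$activator, "activator")],
    max_epochs, patience)
}

#' Run the stage-1 exhaustive optimization
#'
#' Trains a fresh simple CNN for every configuration in the grid (with
#' early stopping), measures blind-test accuracy, aggregates scores, and
#' selects the per-parameter winners. Per-run seeds are derived from
#' `seed` and the configuration index.
#'
#' @param train,val,test tensor datasets (see [frames_to_tensor()])
#' @param grid list of configurations (default: the full 54-run grid)
#' @param augment an [augment_policy()] or NULL
#' @param seed base seed
#' @param input_size model input edge (inferred from `train$x` by default)
#' @param csv optional path for the per-run results CSV
#' @return list with `results` (run_result list), `table` (score table),
#'   `selected` (the winning [train_config()]), and `runs` (data.frame)
#' @export
run_stage1 <- function(train, val, test, grid = enumerate_grid(),
                       augment = augment_policy(), seed = 1L,
                       input_size = NULL, csv = NULL) {
  input_size <- input_size %||% dim(train$x)[1]
  results <- vector("list", length(grid))
  rows <- list()
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    run_seed <- derive_seed(seed, 301L, i)
    model <- build_simple_cnn(cfg$activator, input_size = input_size,
                              seed = run_seed)
    fit <- train_with_early_stopping(model, cfg, train, val,
                                     augment = augment, seed = run_seed)
    acc <- if (fit$diverged) 0 else blind_accuracy(fit$model, test)
    results[[i]] <- run_result(cfg, acc, fit$epochs_run, fit$best_val_loss)
    rows[[i]] <- data.frame(
      run = i, batch_size = cfg$batch_size, optimizer = cfg$optimizer,
      learning_rate = cfg$learning_rate, activator = cfg$activator,
      epochs_run = fit$epochs_run, best_val_loss = fit$best_val_loss,
      blind_accuracy = acc, score = score_model(acc),
      diverged = fit$diverged, stringsAsFactors = FALSE)
  }
  runs <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(runs, csv, row.names = FALSE)
  table <- aggregate_scores(results)
  list(results = results, table = table,
       selected = select_parameters(table,
                                    max_epochs = grid[[1]]$max_epochs,
                                    patience = grid[[1]]$patience),
       runs = runs)
}
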