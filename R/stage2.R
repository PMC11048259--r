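# Stage 2: Bayesian optimization over the CNN architecture space.
# Surrogate: Gaussian process with a Matern-5/2 kernel on the unit-cube
# scaled parameters; acquisition: expected improvement, maximized over a
# random candidate set; integers by continuous relaxation + rounding.

#' Default architecture search space
#'
#' Filter size 2–7, layers 2–6, base filters 2–16 (integers), multiplier in
#' `[1, 2]` (real), dropout on the nine-level grid 0.1–0.9.
#'
#' @return object of class `search_space`
#' @export
default_space <- function() {
  structure(list(
    filter_size = list(type = "int", lo = 2, hi = 7),
    n_layers = list(type = "int", lo = 2, hi = 6),
    base_filters = list(type = "int", lo = 2, hi = 16),
    multiplier = list(type = "real", lo = 1, hi = 2),
    dropout = list(type = "grid", levels = seq(0.1, 0.9, by = 0.1))
  ), class = "search_space")
}

space_bounds <- function(space) {
  t(vapply(space, function(f) {
    if (f$type == "grid") c(min(f$levels), max(f$levels)) else c(f$lo, f$hi)
  }, numeric(2)))
}

# continuous unit-cube point -> valid arch_spec
point_to_spec <- function(u, space) {
  b <- space_bounds(space)
  vals <- b[, 1] + u * (b[, 2] - b[, 1])
  snap <- function(name, v) {
    f <- space[[name]]
    if (f$type == "int") {
      as.integer(min(f$hi, max(f$lo, round(v))))
    } else if (f$type == "grid") {
      f$levels[which.min(abs(f$levels - v))]
    } else {
      min(f$hi, max(f$lo, v))
    }
  }
  arch_spec(snap("filter_size", vals[1]), snap("n_layers", vals[2]),
            snap("base_filters", vals[3]), snap("multiplier", vals[4]),
            snap("dropout", vals[5]))
}

spec_to_row <- function(spec) {
  c(filter_size = spec$filter_size, n_layers = spec$n_layers,
    base_filters = spec$base_filters, multiplier = spec$multiplier,
    dropout = spec$dropout)
}

spec_key <- function(spec) {
  paste(spec$filter_size, spec$n_layers, spec$base_filters,
        sprintf("%.6f", spec$multiplier), sprintf("%.1f", spec$dropout),
        sep = "|")
}

# unit-cube coordinates of evaluated specs
history_matrix <- function(history, space) {
  b <- space_bounds(space)
  X <- do.call(rbind, lapply(history$specs, spec_to_row))
  sweep(sweep(X, 2, b[, 1]), 2, b[, 2] - b[, 1], "/")
}

# ---- Gaussian-process surrogate -------------------------------------------

matern52 <- function(D, ls) {
  r <- sqrt(5) * D / ls
  (1 + r + r^2 / 3) * exp(-r)
}

dist_mat <- function(A, B) {
  # Euclidean distances between rows of A and rows of B
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

gp_fit <- function(X, y, noise = 1e-4) {
  mu <- mean(y)
  s <- sd(y)
  if (!is.finite(s) || s < 1e-12) {
    return(list(flat = TRUE, mu = mu))
  }
  ys <- (y - mu) / s
  D <- dist_mat(X, X)
  best <- NULL
  for (ls in c(0.1, 0.2, 0.3, 0.5, 1.0)) {
    K <- matern52(D, ls) + diag(noise + 1e-8, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    # marginal log-likelihood up to constants
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, ls = ls, chol = ch, alpha = alpha)
    }
  }
  if (is.null(best)) return(list(flat = TRUE, mu = mu))
  c(best, list(flat = FALSE, X = X, mu = mu, s = s))
}

gp_predict <- function(fit, Xs) {
  if (fit$flat) {
    return(list(mean = rep(fit$mu, nrow(Xs)), sd = rep(0, nrow(Xs))))
  }
  Ks <- matern52(dist_mat(Xs, fit$X), fit$ls)
  mean_s <- as.vector(Ks %*% fit$alpha)
  V <- forwardsolve(t(fit$chol), t(Ks))
  var_s <- pmax(1 - colSums(V^2), 0)
  list(mean = fit$mu + fit$s * mean_s, sd = fit$s * sqrt(var_s))
}

expected_improvement <- function(mu, s, best) {
  z <- ifelse(s > 0, (mu - best) / s, 0)
  ei <- (mu - best) * pnorm(z) + s * dnorm(z)
  ifelse(s > 0, pmax(ei, 0), pmax(mu - best, 0))
}

# perturb a spec until it no longer collides with evaluated keys
dedup_spec <- function(spec, space, seen) {
  tries <- 0
  while (spec_key(spec) %in% seen && tries < 200) {
    u <- pmin(pmax((spec_to_row(spec) - space_bounds(space)[, 1]) /
                     (space_bounds(space)[, 2] - space_bounds(space)[, 1]) +
                     rnorm(5, 0, 0.15), 0), 1)
    spec <- point_to_spec(u, space)
    tries <- tries + 1
  }
  if (spec_key(spec) %in% seen) {
    # fall back to uniform draws; the discrete space is large enough
    repeat {
      spec <- point_to_spec(runif(5), space)
      if (!spec_key(spec) %in% seen) break
    }
  }
  spec
}

new_trial_history <- function() {
  structure(list(specs = list(),
                 df = data.frame(trial = integer(), filter_size = integer(),
                                 n_layers = integer(),
                                 base_filters = integer(),
                                 multiplier = double(), dropout = double(),
                                 objective = double(),
                                 incumbent = double())),
            class = "trial_history")
}

history_append <- function(history, spec, objective) {
  inc <- if (nrow(history$df) == 0) objective else {
    max(objective, history$df$incumbent[nrow(history$df)])
  }
  history$specs[[length(history$specs) + 1L]] <- spec
  history$df <- rbind(history$df, data.frame(
    trial = nrow(history$df) + 1L, filter_size = spec$filter_size,
    n_layers = spec$n_layers, base_filters = spec$base_filters,
    multiplier = spec$multiplier, dropout = spec$dropout,
    objective = objective, incumbent = inc))
  history
}

#' Propose the next architecture to evaluate
#'
#' The first `n_init` proposals are uniform over the space; afterwards a
#' Gaussian-process surrogate is fit to the history and the proposal
#' maximizes expected improvement over a random candidate set (plus local
#' perturbations of the incumbent). An already-evaluated point is never
#' re-proposed. Uses the current RNG stream.
#'
#' @param history a `trial_history` (possibly empty)
#' @param space a [default_space()]
#' @param n_init number of initial random proposals (default 8)
#' @return an [arch_spec()]
#' @export
suggest <- function(history, space = default_space(), n_init = 8) {
  seen <- vapply(history$specs, spec_key, character(1))
  if (nrow(history$df) < n_init) {
    return(dedup_spec(point_to_spec(runif(5), space), space, seen))
  }
  X <- history_matrix(history, space)
  y <- history$df$objective
  fit <- gp_fit(X, y)
  U <- matrix(runif(512 * 5), ncol = 5)
  inc_u <- X[which.max(y), , drop = FALSE]
  loc <- matrix(pmin(pmax(rep(inc_u, each = 128) +
                            rnorm(128 * 5, 0, 0.1), 0), 1), ncol = 5)
  cand <- rbind(U, loc)
  pr <- gp_predict(fit, cand)
  ei <- expected_improvement(pr$mean, pr$sd, max(y))
  ord <- order(ei, decreasing = TRUE)
  for (i in ord[seq_len(min(50, length(ord)))]) {
    spec <- point_to_spec(cand[i, ], space)
    if (!spec_key(spec) %in% seen) return(spec)
  }
  dedup_spec(point_to_spec(cand[ord[1], ], space), space, seen)
}

#' Run the Bayesian architecture optimization
#'
#' Evaluates `budget` unique architecture specifications (default 100, the
#' study protocol), recording each trial's objective and the running
#' incumbent. An objective that throws is recorded as 0 and the search
#' continues.
#'
#' @param objective `function(arch_spec) -> fraction`, e.g. blind-test
#'   accuracy of the trained architecture
#' @param space a [default_space()]
#' @param budget number of unique trials (>= 1)
#' @param seed integer seed
#' @param n_init initial uniform-random trials before the surrogate kicks in
#' @return a `trial_history`; `$df` has one row per trial with the spec
#'   fields, objective, and incumbent-so-far
#' @export
run_optimization <- function(objective, space = default_space(), budget = 100,
                             seed = 1L, n_init = 8) {
  if (budget < 1) {
    stop_with("efastcnn_invalid_argument", "budget must be >= 1")
  }
  history <- new_trial_history()
  with_seed(derive_seed(seed, 401L), {
    for (t in seq_len(budget)) {
      spec <- suggest(history, space, n_init)
      val <- tryCatch(objective(spec), error = function(e) {
        warning(sprintf("trial %d failed (%s); recording objective 0", t,
                        conditionMessage(e)))
        0
      })
      history <- history_append(history, spec, val)
    }
  })
  history
}

#' Select the top-k architectures from a trial history
#'
#' Highest objective first; ties broken by earlier trial index. Requests
#' beyond the history length return the whole history sorted.
#'
#' @param history a `trial_history`
#' @param k number of architectures (default 3, the study protocol)
#' @return list of [arch_spec()]s
#' @export
select_top_k <- function(history, k = 3) {
  if (k < 1) stop_with("efastcnn_invalid_argument", "k must be >= 1")
  ord <- order(-history$df$objective, history$df$trial)
  history$specs[ord[seq_len(min(k, length(ord)))]]
}
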