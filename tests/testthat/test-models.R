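test_that("filter ladders follow round(base * multiplier^(l-1)) with half-up rounding", {
  expect_equal(layer_filter_counts(16, 2, 3), c(16L, 32L, 64L))
  expect_equal(layer_filter_counts(7, 1, 4), rep(7L, 4))
  # hand-evaluated: 5, 7.5, 11.25, 16.875 -> 5, 8, 11, 17
  expect_equal(layer_filter_counts(5, 1.5, 4), c(5L, 8L, 11L, 17L))
})

test_that("the simple CNN has the 16/32/64 ladder and a 2-output head", {
  m <- build_simple_cnn("softmax", input_size = 64, seed = 1)
  expect_equal(m$filters, c(16L, 32L, 64L))
  expect_equal(m$filter_size, 3L)
  expect_equal(nrow(m$params$fc.W), 2)
  for (size in c(16, 24, 64)) {
    mm <- build_simple_cnn("softmax", input_size = size, seed = 1)
    out <- predict(mm, array(0, dim = c(size, size, 1, 1)))
    expect_length(out$scores, 2)
    expect_true(all(is.finite(out$scores)))
  }
})

test_that("arch_spec validates the search ranges", {
  s <- arch_spec(3, 3, 16, 2, 0.5)
  expect_s3_class(s, "arch_spec")
  expect_error(arch_spec(8, 3, 16, 2, 0.5), class = "efastcnn_invalid_argument")
  expect_error(arch_spec(3, 1, 16, 2, 0.5), class = "efastcnn_invalid_argument")
  expect_error(arch_spec(3, 3, 17, 2, 0.5), class = "efastcnn_invalid_argument")
  expect_error(arch_spec(3, 3, 16, 2.5, 0.5),
               class = "efastcnn_invalid_argument")
  expect_error(arch_spec(3, 3, 16, 2, 0.95),
               class = "efastcnn_invalid_argument")
})

test_that("custom CNNs realize their spec and are deterministic at inference", {
  spec <- arch_spec(3, 3, 16, 2, 0.5)
  m <- build_custom_cnn(spec, "softmax", input_size = 64, seed = 2)
  expect_equal(m$filters, c(16L, 32L, 64L))
  expect_equal(m$filter_size, 3L)
  expect_equal(m$dropout, 0.5)
  x <- array(runif(64 * 64), dim = c(64, 64, 1, 1))
  expect_identical(predict(m, x)$scores, predict(m, x)$scores)

  m2 <- build_custom_cnn(arch_spec(2, 2, 4, 1.3, 0.1), "softplus",
                         input_size = 64, seed = 3)
  out <- predict(m2, array(0.5, dim = c(64, 64, 1, 2)))
  expect_equal(dim(out$scores), c(2L, 2L))
})

test_that("parameter count strictly increases with base_filters", {
  counts <- vapply(c(4, 8, 12, 16), function(b) {
    build_custom_cnn(arch_spec(3, 3, b, 1.5, 0.2), "softmax",
                     input_size = 32, seed = 1)$n_params
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("final activations match their closed forms", {
  expect_equal(final_activation(c(0, 0), "softmax"), c(0.5, 0.5))
  expect_equal(final_activation(c(log(2), 0), "softmax"), c(2 / 3, 1 / 3))
  expect_equal(final_activation(c(0, 0), "softplus"), c(log(2), log(2)))
  expect_error(final_activation(c(Inf, 0), "softmax"),
               class = "efastcnn_invalid_argument")
})

test_that("softmax sums to one and is shift-invariant; softplus approaches identity", {
  set.seed(4)
  for (i in 1:25) {
    a <- rnorm(2, sd = 5)
    y <- final_activation(a, "softmax")
    expect_equal(sum(y), 1)
    expect_true(all(y > 0 & y < 1))
    expect_equal(final_activation(a + 3.7, "softmax"), y)
  }
  xs <- seq(-5, 5, by = 0.5)
  sp <- final_activation(rbind(xs, xs)[1, , drop = FALSE], "softplus")
  expect_true(all(sp > 0))
  expect_true(all(diff(as.vector(sp)) > 0))
  expect_lt(abs(final_activation(c(30, 30), "softplus")[1] - 30), 1e-9)
})

test_that("the reference registry resolves known names and rejects others", {
  for (nm in c("MobileNetV2", "DarkNet53", "ShrapML")) {
    m <- reference_model(nm, pretrained = FALSE, input_size = 64, seed = 1)
    expect_equal(nrow(m$params$fc.W), 2)
    out <- predict(m, array(0.1, dim = c(64, 64, 1, 1)))
    expect_length(out$labels, 1)
  }
  expect_error(reference_model("ResNet50"), class = "efastcnn_unknown_model")
  expect_warning(reference_model("MobileNetV2", pretrained = TRUE,
                                 input_size = 32, seed = 1),
                 "random initialization")
  register_reference_model("custom-test", function(activator, input_size,
                                                   seed) {
    build_simple_cnn(activator, input_size, seed)
  })
  expect_true("custom-test" %in% registered_models())
})

test_that("model summaries expose the architecture and parameter count", {
  m <- build_simple_cnn("softplus", input_size = 32, seed = 1)
  s <- model_summary(m)
  expect_equal(s$filters, c(16L, 32L, 64L))
  expect_equal(s$n_params, m$n_params)
  expect_equal(s$activator, "softplus")
})
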