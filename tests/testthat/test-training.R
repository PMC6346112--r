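test_that("cross-entropy evaluates the textbook cases", {
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0, tolerance = 1e-9)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(cross_entropy(c(0, 1), c(0.9, 0.1)), -log(0.1))
  # clipping keeps a confident wrong prediction finite
  expect_true(is.finite(cross_entropy(c(1, 0), c(0, 1))))
  expect_gte(cross_entropy(c(0.3, 0.7), c(0.6, 0.4)), 0)
})

test_that("cross-entropy validates its inputs", {
  expect_error(cross_entropy(c(1, 0), c(1, 0, 0)), "equal length")
  expect_error(cross_entropy(1, 1), "length >= 2")
  expect_error(cross_entropy(c(0.5, 0.2), c(0.5, 0.5)),
               "not a probability distribution")
  expect_error(cross_entropy(c(1, 0), c(0.9, 0.2)),
               "not a probability distribution")
})

test_that("backprop gradients match central finite differences", {
  spec <- tiny_spec(input_length = 6) # 38 trainable parameters
  d <- toy_dataset(3, 1, seq_len = 6, seed = 8)
  enc <- encode_dataset(d, max_len = 6)
  prepared <- mirtroncnn:::prepare_inputs(spec, enc$x)
  y_idx <- as.integer(enc$y)
  # hand-built weights with positive biases so relu units are alive and the
  # loss is locally smooth (no argmax or relu kinks within the probe step)
  w <- withr::with_seed(2, list(
    conv = list(list(W = matrix(stats::runif(24, -0.5, 0.5), 12, 2),
                     b = c(0.2, 0.3))),
    W1 = matrix(stats::runif(4, -0.5, 0.5), 2, 2), b1 = c(0.3, 0.4),
    W2 = matrix(stats::runif(4, -0.5, 0.5), 2, 2), b2 = c(0.05, -0.05)
  ))

  loss_at <- function(flat) {
    wi <- utils::relist(flat, w)
    fwd <- mirtroncnn:::nn_forward(spec, wi, prepared)
    mirtroncnn:::mean_nll(fwd$probs, y_idx)
  }
  fwd <- mirtroncnn:::nn_forward(spec, w, prepared, keep_argmax = TRUE)
  grads <- mirtroncnn:::nn_backward(spec, w, prepared, fwd, y_idx, NULL)
  g_ana <- unlist(grads, use.names = FALSE)

  flat <- unlist(w, use.names = FALSE)
  eps <- 1e-6
  g_num <- vapply(seq_along(flat), function(i) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    (loss_at(up) - loss_at(dn)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(g_num - g_ana)) / max(abs(g_num)), 1e-4)
})

test_that("a zero-iteration budget returns the initial weights, no history", {
  spec <- tiny_spec()
  d <- toy_dataset(6, 6, seq_len = 6)
  fit <- train_cnn(spec, d, config = training_config(max_iterations = 0,
                                                     seed = 9),
                   monitor_fraction = 0)
  expect_equal(nrow(fit$history), 0)
  expect_equal(fit$steps_run, 0)
  expect_equal(fit$weights, init_cnn_weights(spec, seed = 9))
})

test_that("early stopping walks the held-out trace as specified", {
  dec <- early_stop_decision(c(0.6, 0.5, 0.55, 0.56, 0.57), patience = 2)
  expect_true(dec$stop)
  expect_equal(dec$stop_index, 4) # second consecutive non-improvement
  expect_equal(dec$best_index, 2)

  # monotone improvement never stops
  dec2 <- early_stop_decision(seq(1, 0.1, by = -0.1), patience = 1)
  expect_false(dec2$stop)
  expect_equal(dec2$best_index, 10)

  # patience 0 stops at the first non-improving evaluation
  dec3 <- early_stop_decision(c(0.5, 0.5), patience = 0)
  expect_true(dec3$stop)
  expect_equal(dec3$stop_index, 2)
  expect_equal(dec3$best_index, 1) # earliest on ties

  # improvements below tolerance do not count as progress
  dec4 <- early_stop_decision(c(0.5, 0.49999, 0.49998), patience = 2,
                              tol = 1e-4)
  expect_true(dec4$stop)
  expect_error(early_stop_decision(numeric(0), patience = 1),
               "at least one")
})

test_that("training histories are well-formed and losses finite", {
  spec <- tiny_spec()
  d <- toy_dataset(10, 10, seq_len = 6, seed = 3)
  fit <- train_cnn(spec, d, config = training_config(
    max_iterations = 40, eval_every = 10, seed = 4, batch_size = 8),
    monitor_fraction = 0.2)
  expect_equal(fit$history$step, seq_len(fit$steps_run))
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(fit$history$train_loss >= 0))
  evals <- fit$history$heldout_loss[!is.na(fit$history$heldout_loss)]
  expect_gte(length(evals), 1)
  expect_true(all(evals >= 0))
  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(glance(fit)$total_parameters,
               attr(count_parameters(spec), "total"))
  expect_equal(tidy(fit), count_parameters(spec), ignore_attr = TRUE)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("identical seeds reproduce training bitwise", {
  spec <- tiny_spec()
  d <- toy_dataset(8, 8, seq_len = 6, seed = 5)
  cfg <- training_config(max_iterations = 30, eval_every = 10, seed = 11,
                         batch_size = 4)
  f1 <- train_cnn(spec, d, config = cfg)
  f2 <- train_cnn(spec, d, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  m1 <- evaluate_model(f1, d)
  m2 <- evaluate_model(f2, d)
  expect_identical(m1, m2)
})

test_that("prediction refuses sequences longer than the trained input", {
  spec <- tiny_spec(input_length = 10)
  d <- toy_dataset(6, 6, seq_len = 10, seed = 6)
  fit <- train_cnn(spec, d, config = training_config(max_iterations = 5,
                                                     seed = 1),
                   monitor_fraction = 0)
  long <- tibble::tibble(id = "x", sequence = strrep("ACGU", 5))
  expect_error(predict(fit, long), "refusing to truncate")
  ok <- predict(fit, tibble::tibble(id = c("a", "b"),
                                    sequence = c("ACGUA", "GGCU")))
  expect_equal(nrow(ok), 2)
  expect_equal(ok$p_canonical + ok$p_mirtron, rep(1, 2), tolerance = 1e-6)
})

test_that("checkpoints round-trip through disk", {
  spec <- tiny_spec()
  d <- toy_dataset(6, 6, seq_len = 6, seed = 7)
  fit <- train_cnn(spec, d, config = training_config(max_iterations = 10,
                                                     seed = 2),
                   monitor_fraction = 0)
  dir <- withr::local_tempdir()
  save_checkpoint(fit, dir)
  back <- load_checkpoint(dir)
  expect_equal(back$weights, fit$weights)
  enc <- encode_dataset(d, max_len = 6)
  expect_equal(predict(back, enc), predict(fit, enc))
})
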