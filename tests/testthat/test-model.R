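test_that("valid-convolution output lengths follow L - h + 1", {
  expect_equal(conv_output_length(164, 3), 162L)
  expect_equal(conv_output_length(164, 4), 161L)
  expect_equal(conv_output_length(164, 5), 160L)
  expect_equal(conv_output_length(164, 6), 159L)
  for (L in c(1, 7, 50)) expect_equal(conv_output_length(L, 1), L)
  expect_equal(conv_output_length(3, 3), 1L) # boundary: single window
  expect_error(conv_output_length(4, 5), "exceeds input length")
})

test_that("one-kernel specs have one 128-filter branch", {
  spec <- build_one_kernel_spec(6)
  expect_equal(spec$name, "CNN-filter6-128")
  expect_length(spec$branches, 1)
  expect_equal(spec$branches[[1]]$out_channels, 128L)
  expect_equal(spec$branches[[1]]$filter_width, 4L)
  expect_equal(spec$dense_width, 128L)
  expect_equal(spec$n_classes, 2L)

  # height-5 variant: concatenated feature length is the 128 of one branch
  p5 <- count_parameters(build_one_kernel_spec(5))
  expect_equal(p5$params[p5$layer == "dense_1"], 128L * 128L + 128L)

  # boundary: filter as tall as the input is valid, taller is not
  expect_silent(build_one_kernel_spec(3, input_length = 3))
  expect_error(build_one_kernel_spec(7, input_length = 6), "exceeds")
})

test_that("concat specs get one 32-filter branch per height", {
  spec <- build_concat_spec()
  expect_length(spec$branches, 4)
  expect_equal(vapply(spec$branches, `[[`, integer(1), "filter_height"),
               3:6)
  expect_true(all(vapply(spec$branches, `[[`, integer(1),
                         "out_channels") == 32L))
  # default four heights -> 128-long concatenated feature vector
  p <- count_parameters(spec)
  expect_equal(p$output_shape[p$layer == "global_max_pool + concat"],
               "(128)")

  one <- build_concat_spec(filter_heights = 3)
  expect_length(one$branches, 1)
  expect_equal(one$branches[[1]]$out_channels, 32L)

  two <- build_concat_spec(filter_heights = c(2, 2))
  p2 <- count_parameters(two)
  expect_equal(p2$output_shape[p2$layer == "global_max_pool + concat"],
               "(64)")
  expect_error(build_concat_spec(filter_heights = integer(0)), "nonempty")
})

test_that("per-layer parameter accounting matches the reference accounting", {
  p <- count_parameters(build_concat_spec())
  get <- function(layer) p$params[p$layer == layer]
  expect_equal(get("Conv3_32"), 416L)
  expect_equal(get("Conv4_32"), 544L)
  expect_equal(get("Conv5_32"), 672L)
  expect_equal(get("Conv6_32"), 800L)
  expect_equal(get("dense_1"), 16512L)
  expect_equal(get("dense_2"), 258L)
  expect_equal(attr(p, "total"), 19202L)
  expect_equal(attr(p, "total"), sum(p$params))
})

test_that("parameter accounting equals the instantiated weight count", {
  # dual route: spec formulas vs the sizes of the actually allocated arrays
  variants <- list(build_one_kernel_spec(3), build_one_kernel_spec(4),
                   build_one_kernel_spec(5), build_one_kernel_spec(6),
                   build_concat_spec())
  for (spec in variants) {
    w <- init_cnn_weights(spec, seed = 1)
    allocated <- sum(vapply(w$conv, function(cw) {
      length(cw$W) + length(cw$b)
    }, numeric(1))) + length(w$W1) + length(w$b1) +
      length(w$W2) + length(w$b2)
    expect_equal(allocated, attr(count_parameters(spec), "total"))
  }
})

test_that("model variant names resolve and unknown names fail", {
  expect_equal(model_variant("filter4")$name, "CNN-filter4-128")
  expect_equal(model_variant("concat")$name, "CNN-concat-filters")
  expect_error(model_variant("filter7"), "unknown model variant")
})

test_that("softmax outputs are probabilities for any weights", {
  spec <- build_concat_spec(input_length = 30)
  w <- init_cnn_weights(spec, seed = 3)
  enc <- encode_dataset(toy_dataset(3, 3, seq_len = 25), max_len = 30)
  probs <- cnn_forward(spec, w, enc)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, 6), tolerance = 1e-6)
})

test_that("all-zero weights yield (0.5, 0.5) for every input", {
  spec <- tiny_spec(input_length = 8)
  w <- init_cnn_weights(spec, seed = 1)
  zero <- function(x) x * 0
  w$conv <- lapply(w$conv, function(cw) lapply(cw, zero))
  w$W1 <- zero(w$W1); w$b1 <- zero(w$b1)
  w$W2 <- zero(w$W2); w$b2 <- zero(w$b2)
  enc <- encode_dataset(toy_dataset(2, 2, seq_len = 8), max_len = 8)
  probs <- cnn_forward(spec, w, enc)
  expect_equal(unname(probs), matrix(0.5, 4, 2))
})

test_that("forward agrees with a pencil-and-paper single-branch oracle", {
  # 1 branch, height 3, 1 filter, dense width 1, input ACGU at length 4
  spec <- build_concat_spec(filter_heights = 3, input_length = 4,
                            dropout_rate = 0)
  spec$branches[[1]]$out_channels <- 1L
  spec$dense_width <- 1L
  w <- list(
    conv = list(list(W = matrix((1:12) / 10, ncol = 1), b = 0.05)),
    W1 = matrix(0.5, 1, 1), b1 = -0.2,
    W2 = matrix(c(0.3, -0.4), 1, 2), b2 = c(0.1, 0.2)
  )
  # window ACG = rows (A,C,G): responds at offsets 1,8,11 of the filter
  r1 <- 0.1 * 1 + 0.8 * 1 + 1.1 * 1 + 0.05
  # window CGU = rows (C,G,U): offsets 4, 7, 10
  r2 <- 0.4 * 1 + 0.7 * 1 + 1.0 * 1 + 0.05
  pooled <- max(max(r1, 0), max(r2, 0))
  h1 <- max(pooled * 0.5 - 0.2, 0)
  z2 <- c(h1 * 0.3 + 0.1, h1 * -0.4 + 0.2)
  expected <- exp(z2) / sum(exp(z2))
  probs <- cnn_forward(spec, w, list(encode_sequence("ACGU", 4)))
  expect_equal(unname(probs[1, ]), expected, tolerance = 1e-6)
})

test_that("extra zero-padding rows never change pooled features", {
  # once the encoding is long enough to contain a fully-zero window, every
  # additional padding row only adds more fully-zero windows, whose response
  # (the bias) is already represented in the max — so growing max_len from
  # 20 to 40 leaves the forward pass of 12-nt sequences untouched
  seqs <- toy_dataset(3, 3, seq_len = 12)
  spec_short <- build_concat_spec(input_length = 20)
  spec_long <- build_concat_spec(input_length = 40)
  w <- init_cnn_weights(spec_short, seed = 5)
  p_short <- cnn_forward(spec_short, w,
                         encode_dataset(seqs, max_len = 20))
  p_long <- cnn_forward(spec_long, w,
                        encode_dataset(seqs, max_len = 40))
  expect_equal(p_short, p_long, tolerance = 1e-12)
})

test_that("interior motif shifts leave pooled features unchanged", {
  spec <- build_concat_spec(input_length = 30)
  w <- init_cnn_weights(spec, seed = 6)
  w$conv <- lapply(w$conv, function(cw) { cw$b <- cw$b * 0; cw })
  shifted <- function(at) {
    s <- strrep("A", 30)
    substr(s, at, at + 5) <- "GUCGGC"
    cnn_forward(spec, w, list(encode_sequence(s, 30)))
  }
  base <- shifted(8)
  for (at in c(10, 14, 19)) {
    expect_equal(shifted(at), base, tolerance = 1e-12)
  }
})

test_that("shape mismatches and non-finite weights are rejected", {
  spec <- build_concat_spec(input_length = 20)
  w <- init_cnn_weights(spec, seed = 1)
  expect_error(cnn_forward(spec, w, list(encode_sequence("ACGU", 10))),
               "does not match model input")
  w$W1[1, 1] <- NaN
  expect_error(cnn_forward(spec, w, list(encode_sequence("ACGU", 20))),
               "non-finite weights")
})

test_that("model specs survive a JSON round trip", {
  spec <- build_concat_spec(filter_heights = c(3, 5), input_length = 80,
                            dropout_rate = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back$input_length, spec$input_length)
  expect_equal(back$dropout_rate, spec$dropout_rate)
  expect_equal(count_parameters(back), count_parameters(spec),
               ignore_attr = TRUE)
})
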