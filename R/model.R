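#' Feature-map length of a valid convolution
#'
#' For stride 1 and valid (no) padding, a filter of height `filter_height`
#' sliding over an input of `input_length` rows produces
#' `input_length - filter_height + 1` positions. With the corpus-scale input
#' of 164 nt this gives 162/161/160/159 for heights 3/4/5/6.
#'
#' @param input_length Input length in nt.
#' @param filter_height Filter height in nt; must be `<= input_length`.
#' @param stride Convolution stride (only 1 is supported).
#' @param padding_mode Only `"valid"` is supported.
#' @return The feature-map length (integer).
#' @export
conv_output_length <- function(input_length, filter_height, stride = 1,
                               padding_mode = "valid") {
  stopifnot(stride == 1, identical(padding_mode, "valid"))
  if (filter_height > input_length) {
    stop("filter height ", filter_height, " exceeds input length ",
         input_length, call. = FALSE)
  }
  if (filter_height < 1) stop("filter height must be >= 1", call. = FALSE)
  as.integer(input_length - filter_height + 1)
}

new_model_spec <- function(branches, input_length, dense_width = 128L,
                           n_classes = 2L, dropout_rate = 0.5,
                           name = "cnn") {
  stopifnot(length(branches) >= 1, input_length >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  for (b in branches) {
    conv_output_length(input_length, b$filter_height) # validates height
  }
  structure(
    list(
      name = name,
      input_length = as.integer(input_length),
      branches = branches,
      dense_width = as.integer(dense_width),
      n_classes = as.integer(n_classes),
      dropout_rate = dropout_rate
    ),
    class = "cnn_model_spec"
  )
}

conv_branch <- function(filter_height, out_channels) {
  list(filter_height = as.integer(filter_height),
       filter_width = 4L, in_channels = 1L,
       out_channels = as.integer(out_channels),
       stride = 1L, padding_mode = "valid", activation = "relu")
}

#' One-kernel model specification
#'
#' A single convolution branch (128 filters of one height, spanning the full
#' one-hot width of 4), relu, global max-pooling over the feature map, a
#' 128-unit dense layer with relu and dropout, and a 2-class softmax output.
#' Heights 3-6 give the four one-kernel variants (`CNN-filter3-128` ...
#' `CNN-filter6-128`); height 6 is the best-performing variant on the
#' pre-miRNA corpus.
#'
#' @param filter_height Filter height in nt (3-6 in the standard variants;
#'   any height `<= input_length` is accepted).
#' @param input_length Model input length in nt (default 164, the maximum
#'   pre-miRNA length in the merged corpus).
#' @param dropout_rate Dropout probability on the dense layer during
#'   training.
#' @return A `cnn_model_spec`.
#' @seealso [build_concat_spec()], [count_parameters()]
#' @export
build_one_kernel_spec <- function(filter_height, input_length = 164,
                                  dropout_rate = 0.5) {
  new_model_spec(
    branches = list(conv_branch(filter_height, 128L)),
    input_length = input_length,
    dropout_rate = dropout_rate,
    name = sprintf("CNN-filter%d-128", as.integer(filter_height))
  )
}

#' Mixed (concat-filters) model specification
#'
#' One convolution branch per filter height, 32 filters each; the pooled
#' features of all branches are concatenated before the dense layers. With
#' the default heights (3, 4, 5, 6) the concatenated feature vector is
#' 128-long, matching the one-kernel variants' dense fan-in.
#'
#' @param filter_heights Ordered integer vector of filter heights.
#' @inheritParams build_one_kernel_spec
#' @return A `cnn_model_spec`.
#' @export
build_concat_spec <- function(filter_heights = c(3L, 4L, 5L, 6L),
                              input_length = 164, dropout_rate = 0.5) {
  if (length(filter_heights) == 0) {
    stop("filter_heights must be nonempty", call. = FALSE)
  }
  new_model_spec(
    branches = lapply(filter_heights, conv_branch, out_channels = 32L),
    input_length = input_length,
    dropout_rate = dropout_rate,
    name = "CNN-concat-filters"
  )
}

#' Resolve a model variant name to its specification
#'
#' @param variant One of `"filter3"`, `"filter4"`, `"filter5"`, `"filter6"`,
#'   `"concat"`.
#' @inheritParams build_one_kernel_spec
#' @return A `cnn_model_spec`.
#' @export
model_variant <- function(variant, input_length = 164, dropout_rate = 0.5) {
  switch(variant,
    filter3 = build_one_kernel_spec(3, input_length, dropout_rate),
    filter4 = build_one_kernel_spec(4, input_length, dropout_rate),
    filter5 = build_one_kernel_spec(5, input_length, dropout_rate),
    filter6 = build_one_kernel_spec(6, input_length, dropout_rate),
    concat = build_concat_spec(input_length = input_length,
                               dropout_rate = dropout_rate),
    stop("unknown model variant '", variant,
         "' (expected filter3/filter4/filter5/filter6/concat)",
         call. = FALSE)
  )
}

feature_length <- function(spec) {
  sum(vapply(spec$branches, function(b) b$out_channels, integer(1)))
}

#' @export
print.cnn_model_spec <- function(x, ...) {
  cat(x$name, ": input (", x$input_length, ", 4, 1 )\n", sep = "")
  for (b in x$branches) {
    cat(sprintf("  conv %dx%d, %d filters, valid, relu -> global max pool\n",
                b$filter_height, b$filter_width, b$out_channels))
  }
  cat(sprintf("  concat (%d) -> dense %d (relu, dropout %.2f) -> dense %d (softmax)\n",
              feature_length(x), x$dense_width, x$dropout_rate, x$n_classes))
  invisible(x)
}

#' Per-layer trainable parameter counts
#'
#' Convolution layers contribute
#' `height * width * in_channels * out_channels + out_channels` parameters
#' (weights + biases); dense layers contribute `fan_in * fan_out + fan_out`;
#' pooling, concatenation, flatten and dropout contribute none. For the mixed
#' model this reproduces the reference per-layer accounting: 416, 544, 672
#' and 800 for the four convolution branches, 16512 and 258 for the two dense
#' layers, 19202 in total.
#'
#' @param spec A `cnn_model_spec`.
#' @return A tibble with columns `layer`, `output_shape`, `params`; the total
#'   is `sum(out$params)` and is also stored as attribute `"total"`.
#' @examples
#' count_parameters(build_concat_spec())
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "cnn_model_spec"))
  rows <- list(tibble::tibble(
    layer = "input", output_shape = sprintf("(%d, 4, 1)", spec$input_length),
    params = 0L))
  for (b in spec$branches) {
    L <- conv_output_length(spec$input_length, b$filter_height)
    rows <- c(rows, list(tibble::tibble(
      layer = sprintf("Conv%d_%d", b$filter_height, b$out_channels),
      output_shape = sprintf("(%d, 1, %d)", L, b$out_channels),
      params = b$filter_height * b$filter_width * b$in_channels *
        b$out_channels + b$out_channels
    )))
  }
  nf <- feature_length(spec)
  rows <- c(rows, list(
    tibble::tibble(layer = "global_max_pool + concat",
                   output_shape = sprintf("(%d)", nf), params = 0L),
    tibble::tibble(layer = "dense_1",
                   output_shape = sprintf("(%d)", spec$dense_width),
                   params = nf * spec$dense_width + spec$dense_width),
    tibble::tibble(layer = "dropout",
                   output_shape = sprintf("(%d)", spec$dense_width),
                   params = 0L),
    tibble::tibble(layer = "dense_2",
                   output_shape = sprintf("(%d)", spec$n_classes),
                   params = spec$dense_width * spec$n_classes + spec$n_classes)
  ))
  out <- dplyr::bind_rows(rows)
  out$params <- as.integer(out$params)
  attr(out, "total") <- sum(out$params)
  out
}

#' Serialize / deserialize a model specification
#'
#' @param spec A `cnn_model_spec`.
#' @param path Output (input) JSON path.
#' @return `path` invisibly; `read_model_spec()` returns the spec.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  branches <- raw$branches
  if (is.data.frame(branches)) {
    branches <- lapply(seq_len(nrow(branches)), function(i) {
      conv_branch(branches$filter_height[i], branches$out_channels[i])
    })
  } else {
    branches <- lapply(branches, function(b) {
      conv_branch(b$filter_height, b$out_channels)
    })
  }
  new_model_spec(branches, raw$input_length, raw$dense_width, raw$n_classes,
                 raw$dropout_rate, raw$name)
}
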