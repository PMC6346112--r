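#' Cross-entropy between two label distributions
#'
#' `-sum(y * log(s))` with natural log; predicted probabilities are clipped
#' to `[1e-12, 1 - 1e-12]` before the log so a confident wrong prediction
#' yields a large finite loss rather than `Inf`. Zero exactly when the
#' prediction puts all mass on the true label.
#'
#' @param true_dist,pred_dist Probability vectors of equal length `>= 2`,
#'   entries in `[0, 1]`, each summing to 1 (tolerance 1e-6).
#' @return A single nonnegative loss value.
#' @examples
#' cross_entropy(c(1, 0), c(0.5, 0.5)) # log(2)
#' @export
cross_entropy <- function(true_dist, pred_dist) {
  if (length(true_dist) != length(pred_dist)) {
    stop("true_dist and pred_dist must have equal length", call. = FALSE)
  }
  if (length(true_dist) < 2) {
    stop("distributions must have length >= 2", call. = FALSE)
  }
  check_dist <- function(p, what) {
    if (any(p < -1e-9) || any(p > 1 + 1e-9) || abs(sum(p) - 1) > 1e-6) {
      stop(what, " is not a probability distribution", call. = FALSE)
    }
  }
  check_dist(true_dist, "true_dist")
  check_dist(pred_dist, "pred_dist")
  s <- pmin(pmax(pred_dist, 1e-12), 1 - 1e-12)
  -sum(true_dist * log(s))
}

#' Training configuration
#'
#' @param batch_size Records per gradient update (default 32).
#' @param max_iterations Maximum number of update steps (default 2000; 0 is
#'   allowed and returns the initial weights untouched).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param learning_rate Step size (default 2e-3; see the methods vignette
#'   for why this suits the 2000-step default budget).
#' @param eval_every Steps between held-out loss evaluations (default 50).
#' @param early_stop_patience Number of consecutive held-out evaluations
#'   without improvement (by more than `improvement_tol`) before training
#'   stops (default 10; set to `Inf` to disable).
#' @param improvement_tol Absolute held-out-loss improvement below which an
#'   evaluation does not count as progress (default 1e-4).
#' @param seed Integer seed for shuffling, dropout and weight
#'   initialization.
#' @return A list of class `training_config`.
#' @export
training_config <- function(batch_size = 32L, max_iterations = 2000L,
                            optimizer = c("adam", "sgd"),
                            learning_rate = 2e-3, eval_every = 50L,
                            early_stop_patience = 10L,
                            improvement_tol = 1e-4, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(batch_size >= 1, max_iterations >= 0, learning_rate > 0,
            eval_every >= 1, early_stop_patience >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 optimizer = optimizer, learning_rate = learning_rate,
                 eval_every = as.integer(eval_every),
                 early_stop_patience = early_stop_patience,
                 improvement_tol = improvement_tol,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Early-stopping decision on a held-out loss trace
#'
#' Walks the held-out losses in order, counting consecutive evaluations that
#' fail to improve on the best loss so far by more than `tol`. The stop flag
#' is raised at the first evaluation where the count reaches `patience`
#' (`patience = 0` stops at the first non-improving evaluation). The best
#' checkpoint is the argmin of the trace, earliest on ties.
#'
#' @param heldout_loss Numeric vector of held-out losses (or a history tibble
#'   with a `heldout_loss` column; `NA` entries are dropped).
#' @param patience Consecutive non-improving evaluations tolerated.
#' @param tol Absolute improvement threshold (default 1e-4).
#' @return A list with `stop` (logical), `stop_index` (evaluation at which
#'   the rule fires, `NA` if it never does) and `best_index` (1-based argmin).
#' @examples
#' early_stop_decision(c(0.6, 0.5, 0.55, 0.56, 0.57), patience = 2)
#' @export
early_stop_decision <- function(heldout_loss, patience, tol = 1e-4) {
  if (is.data.frame(heldout_loss)) {
    heldout_loss <- heldout_loss$heldout_loss
  }
  heldout_loss <- heldout_loss[!is.na(heldout_loss)]
  if (length(heldout_loss) < 1) {
    stop("need at least one held-out evaluation", call. = FALSE)
  }
  best <- Inf
  best_index <- NA_integer_
  bad <- 0L
  stop_index <- NA_integer_
  for (i in seq_along(heldout_loss)) {
    if (heldout_loss[i] < best - tol) {
      best <- heldout_loss[i]
      best_index <- i
      bad <- 0L
    } else {
      if (heldout_loss[i] < best) { # improvement below tol: keep best, no reset
        best <- heldout_loss[i]
        best_index <- i
      }
      bad <- bad + 1L
      if (bad >= patience && is.na(stop_index)) stop_index <- i
    }
  }
  # argmin, earliest on ties (scan above keeps the first strict minimum)
  best_index <- which.min(heldout_loss)
  list(stop = !is.na(stop_index), stop_index = stop_index,
       best_index = as.integer(best_index))
}

as_encoded <- function(data, max_len, strict = TRUE) {
  if (inherits(data, "encoded_dataset")) {
    if (data$max_len != max_len) {
      stop("encoded data max_len ", data$max_len,
           " does not match model input length ", max_len, call. = FALSE)
    }
    return(data)
  }
  encode_dataset(data, max_len = max_len, strict = strict)
}

#' Train a CNN classifier
#'
#' Minimizes mean cross-entropy by mini-batch back-propagation. Each step
#' draws a random batch (without replacement within a shuffled epoch); the
#' held-out loss is evaluated every `config$eval_every` steps and training
#' stops early when it has not improved for `config$early_stop_patience`
#' evaluations. The returned fit carries the weights of the best held-out
#' checkpoint, not the last step.
#'
#' By default a stratified monitoring subset (`monitor_fraction`) is carved
#' out of the training data, so the test partition is never seen during
#' training. Passing `monitor_data` explicitly (e.g. the test set, as in the
#' original protocol) overrides this; monitoring on the test set is
#' leakage-prone and only appropriate for reproducing that protocol.
#'
#' @param spec A `cnn_model_spec`.
#' @param train_data A labeled dataset tibble or an `encoded_dataset`.
#' @param monitor_data Optional held-out set for early stopping (same types).
#' @param config A [training_config()].
#' @param monitor_fraction Fraction of training records carved out for
#'   monitoring when `monitor_data` is not given (default 0.15).
#' @return An object of class `cnn_fit`: `spec`, `weights` (best checkpoint),
#'   `history` (tibble: `step`, `train_loss`, `heldout_loss` with `NA` between
#'   evaluations), `config`, `best_step`, `best_heldout_loss`,
#'   `stopped_early`, `steps_run`, `n_train`.
#' @examples
#' \donttest{
#' d <- generate_dataset(60, 60, signal_model(plant_probability = 1), seed = 1)
#' fit <- train_cnn(build_concat_spec(input_length = 164), d,
#'                  config = training_config(max_iterations = 200, seed = 1))
#' glance(fit)
#' }
#' @export
train_cnn <- function(spec, train_data, monitor_data = NULL,
                      config = training_config(), monitor_fraction = 0.15) {
  stopifnot(inherits(spec, "cnn_model_spec"))
  if (is.null(monitor_data) && !inherits(train_data, "encoded_dataset") &&
      monitor_fraction > 0 && nrow(train_data) >= 10) {
    sp <- stratified_split(train_data, test_fraction = monitor_fraction,
                           seed = config$seed)
    train_data <- sp$train
    monitor_data <- sp$test
  }
  train_enc <- as_encoded(train_data, spec$input_length)
  monitor_enc <- if (is.null(monitor_data)) {
    train_enc # degenerate but explicit: monitor on the training data itself
  } else {
    as_encoded(monitor_data, spec$input_length)
  }
  if (length(train_enc$x) == 0) stop("training set is empty", call. = FALSE)
  if (length(monitor_enc$x) == 0) stop("monitor set is empty", call. = FALSE)

  prepared <- prepare_inputs(spec, train_enc$x)
  prepared_mon <- prepare_inputs(spec, monitor_enc$x)
  y_idx <- as.integer(train_enc$y)
  y_mon <- as.integer(monitor_enc$y)
  if (anyNA(y_idx) || anyNA(y_mon)) {
    stop("all records must carry a canonical/mirtron label", call. = FALSE)
  }

  weights <- init_cnn_weights(spec, seed = config$seed)
  n <- length(prepared)
  hist_step <- integer(0)
  hist_train <- numeric(0)
  hist_heldout <- numeric(0)
  eval_losses <- numeric(0)
  best_loss <- Inf
  best_weights <- weights
  best_step <- 0L
  stopped_early <- FALSE
  steps_run <- 0L

  if (config$max_iterations > 0) {
    withr::with_seed(config$seed, {
      state <- adam_init(weights)
      order_pool <- integer(0)
      for (step in seq_len(config$max_iterations)) {
        if (length(order_pool) < config$batch_size) {
          order_pool <- c(order_pool, sample.int(n))
        }
        take <- min(config$batch_size, n)
        batch <- order_pool[seq_len(take)]
        order_pool <- order_pool[-seq_len(take)]

        mask <- NULL
        if (spec$dropout_rate > 0) {
          keep <- stats::runif(take * spec$dense_width) >= spec$dropout_rate
          mask <- matrix(keep / (1 - spec$dropout_rate), nrow = take)
        }
        fwd <- nn_forward(spec, weights, prepared[batch],
                          dropout_mask = mask, keep_argmax = TRUE)
        loss <- mean_nll(fwd$probs, y_idx[batch])
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at step ", step,
               call. = FALSE)
        }
        grads <- nn_backward(spec, weights, prepared[batch], fwd,
                             y_idx[batch], mask)
        if (config$optimizer == "adam") {
          st <- adam_step(weights, grads, state, lr = config$learning_rate)
          weights <- st$weights
          state <- st$state
        } else {
          weights <- sgd_step(weights, grads, config$learning_rate)
        }
        steps_run <- step
        hist_step <- c(hist_step, step)
        hist_train <- c(hist_train, loss)

        if (step %% config$eval_every == 0 ||
            step == config$max_iterations) {
          mon_fwd <- nn_forward(spec, weights, prepared_mon)
          mon_loss <- mean_nll(mon_fwd$probs, y_mon)
          hist_heldout <- c(hist_heldout,
                            rep(NA_real_, length(hist_step) -
                                  length(hist_heldout) - 1L),
                            mon_loss)
          eval_losses <- c(eval_losses, mon_loss)
          if (mon_loss < best_loss) {
            best_weights <- weights
            best_step <- step
            best_loss <- mon_loss
          }
          dec <- early_stop_decision(eval_losses,
                                     patience = config$early_stop_patience,
                                     tol = config$improvement_tol)
          if (dec$stop) {
            stopped_early <- TRUE
            break
          }
        }
      }
    })
  }
  hist_heldout <- c(hist_heldout,
                    rep(NA_real_, length(hist_step) - length(hist_heldout)))
  if (config$max_iterations == 0 || best_step == 0L) {
    best_weights <- weights
  }
  structure(
    list(spec = spec, weights = best_weights,
         history = tibble::tibble(step = hist_step, train_loss = hist_train,
                                  heldout_loss = hist_heldout),
         config = config,
         best_step = best_step,
         best_heldout_loss = if (is.finite(best_loss)) best_loss else NA_real_,
         stopped_early = stopped_early,
         steps_run = steps_run,
         n_train = length(train_enc$x)),
    class = "cnn_fit"
  )
}

sgd_step <- function(weights, grads, lr) {
  walk <- function(w, g) {
    if (is.list(w)) Map(walk, w, g) else w - lr * g
  }
  walk(weights, grads)
}

#' Forward pass: per-record class probabilities
#'
#' Applies the trained (or freshly initialized) network to a batch of encoded
#' records: per branch a valid convolution with relu, global max-pooling over
#' the feature map, concatenation, a relu dense layer (dropout inactive at
#' inference) and a softmax output. Each output row is nonnegative and sums
#' to 1.
#'
#' @param spec A `cnn_model_spec`.
#' @param weights A weight list (see [init_cnn_weights()]).
#' @param batch An `encoded_dataset` or a list of encoded matrices matching
#'   `spec$input_length`.
#' @return A numeric matrix with one row per record and columns `canonical`,
#'   `mirtron`.
#' @export
cnn_forward <- function(spec, weights, batch) {
  x_list <- if (inherits(batch, "encoded_dataset")) batch$x else batch
  if (!all(vapply(weights$conv, function(cw) all(is.finite(cw$W)),
                  logical(1))) ||
      !all(is.finite(weights$W1)) || !all(is.finite(weights$W2))) {
    stop("non-finite weights", call. = FALSE)
  }
  prepared <- prepare_inputs(spec, x_list)
  probs <- nn_forward(spec, weights, prepared)$probs
  colnames(probs) <- class_levels()
  probs
}

#' Predict classes or probabilities for new sequences
#'
#' @param object A `cnn_fit`.
#' @param new_data A labeled or unlabeled dataset tibble (columns `id`,
#'   `sequence`) or an `encoded_dataset`. Sequences longer than the trained
#'   input length are an error.
#' @param type `"prob"` (default) or `"class"`.
#' @param ... Unused.
#' @return A tibble: `id`, `p_canonical`, `p_mirtron`, and `.pred_class` when
#'   `type = "class"`.
#' @export
predict.cnn_fit <- function(object, new_data, type = c("prob", "class"),
                            ...) {
  type <- match.arg(type)
  if (inherits(new_data, "encoded_dataset")) {
    enc <- new_data
  } else {
    x <- lapply(new_data$sequence, encode_sequence,
                max_len = object$spec$input_length)
    enc <- structure(list(x = x, y = NULL, id = new_data$id,
                          max_len = object$spec$input_length),
                     class = "encoded_dataset")
  }
  probs <- cnn_forward(object$spec, object$weights, enc)
  out <- tibble::tibble(id = enc$id,
                        p_canonical = probs[, "canonical"],
                        p_mirtron = probs[, "mirtron"])
  if (type == "class") {
    out$.pred_class <- factor(
      class_levels()[max.col(probs, ties.method = "first")],
      levels = class_levels())
  }
  out
}

#' Evaluate a fit on a labeled dataset
#'
#' Predicts the class with the larger softmax probability for every record
#' and scores the result with the five confusion-matrix measures (mirtron =
#' positive class).
#'
#' @param fit A `cnn_fit`.
#' @param test_data A labeled dataset tibble or `encoded_dataset`.
#' @return A one-row metrics tibble (see [compute_metrics()]).
#' @export
evaluate_model <- function(fit, test_data) {
  enc <- as_encoded(test_data, fit$spec$input_length)
  pred <- predict(fit, enc, type = "class")
  compute_metrics(confusion(enc$y, pred$.pred_class))
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat("Trained", x$spec$name, "-", x$steps_run, "steps on", x$n_train,
      "records\n")
  cat("best held-out loss", format(x$best_heldout_loss, digits = 4),
      "at step", x$best_step,
      if (x$stopped_early) "(early stop)\n" else "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CNN fit: per-layer parameter accounting
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return The [count_parameters()] tibble of the fit's architecture.
#' @method tidy cnn_fit
#' @export
tidy.cnn_fit <- function(x, ...) count_parameters(x$spec)

#' One-row summary of a CNN fit
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `n_train`, `steps_run`, `best_step`,
#'   `best_heldout_loss`, `final_train_loss`, `stopped_early`,
#'   `total_parameters`.
#' @method glance cnn_fit
#' @export
glance.cnn_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$name,
    n_train = x$n_train,
    steps_run = x$steps_run,
    best_step = x$best_step,
    best_heldout_loss = x$best_heldout_loss,
    final_train_loss = if (nrow(x$history) > 0) {
      x$history$train_loss[nrow(x$history)]
    } else {
      NA_real_
    },
    stopped_early = x$stopped_early,
    total_parameters = attr(count_parameters(x$spec), "total")
  )
}

#' Loss-curve plot for a CNN fit
#'
#' Training loss per step and held-out loss at evaluation points, on one
#' panel; the classic picture is a training loss that tends to zero while
#' the held-out loss flattens (overfitting), which is what early stopping
#' acts on.
#'
#' @param object A `cnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnn_fit
#' @export
autoplot.cnn_fit <- function(object, ...) {
  h <- object$history
  df <- dplyr::bind_rows(
    tibble::tibble(step = h$step, loss = h$train_loss, set = "training"),
    tibble::tibble(step = h$step[!is.na(h$heldout_loss)],
                   loss = h$heldout_loss[!is.na(h$heldout_loss)],
                   set = "held-out")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "cross-entropy loss",
                  colour = NULL, title = object$spec$name) +
    ggplot2::theme_minimal()
}

#' Export a loss history as TSV
#'
#' @param fit A `cnn_fit`.
#' @param path Output path (columns `step`, `train_loss`, `heldout_loss`).
#' @return `path`, invisibly.
#' @export
write_loss_history <- function(fit, path) {
  utils::write.table(fit$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Save / load a self-describing checkpoint
#'
#' A checkpoint directory holds `weights.rds` (the fitted weights and
#' history) and a `spec.json` sidecar so the checkpoint can be reloaded
#' without the originating script.
#'
#' @param fit A `cnn_fit`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir` invisibly; `load_checkpoint()` returns the `cnn_fit`.
#' @export
save_checkpoint <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_model_spec(fit$spec, file.path(dir, "spec.json"))
  saveRDS(fit[setdiff(names(fit), "spec")], file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  spec <- read_model_spec(file.path(dir, "spec.json"))
  rest <- readRDS(file.path(dir, "weights.rds"))
  structure(c(list(spec = spec), rest), class = "cnn_fit")
}
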