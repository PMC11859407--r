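#' Classifier configuration
#'
#' Hyperparameters of the 9-class intent classifiers and their admissible
#' ranges (the same ranges the hyperparameter search explores):
#' `learning_rate` in `[1e-5, 1e-2]`, `num_filters_1` in `[10, 128]`,
#' `num_filters_2` in `[20, 256]`, `dropout_rate` in `[0.1, 0.5]`,
#' `dense_units` in `[64, 512]`, `batch_size` in `[32, 128]`, `l2_reg` in
#' `[1e-7, 1e-3]` (or exactly 0 for no regularization, the default).
#'
#' @param architecture `"cnn"` (alternating convolution/pooling stack) or
#'   `"mlcnn"` (three parallel convolution streams with kernel sizes 3/9/27
#'   and pooling window 15, concatenated).
#' @param learning_rate Adam learning rate.
#' @param num_filters_1 Filters in the first convolution (and in each mlcnn
#'   stream).
#' @param num_filters_2 Filters in the second cnn convolution.
#' @param dropout_rate Dropout probability before the dense head.
#' @param dense_units Width of the fully connected layer.
#' @param batch_size Minibatch size.
#' @param l2_reg L2 weight-penalty coefficient.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation accuracy.
#' @param seed Integer seed for weight initialization, shuffling and dropout.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(architecture = c("mlcnn", "cnn"),
                              learning_rate = 1e-3, num_filters_1 = 32,
                              num_filters_2 = 64, dropout_rate = 0.5,
                              dense_units = 128, batch_size = 64,
                              l2_reg = 0, epochs = 30, patience = 5,
                              seed = 1L) {
  architecture <- match.arg(architecture)
  cfg <- list(
    architecture = architecture, learning_rate = learning_rate,
    num_filters_1 = as.integer(num_filters_1),
    num_filters_2 = as.integer(num_filters_2),
    dropout_rate = dropout_rate, dense_units = as.integer(dense_units),
    batch_size = as.integer(batch_size), l2_reg = l2_reg,
    epochs = as.integer(epochs), patience = as.integer(patience),
    seed = as.integer(seed)
  )
  validate_classifier_config(cfg)
  structure(cfg, class = "classifier_config")
}

hyperparameter_space <- function() {
  list(
    learning_rate = c(1e-5, 1e-2),
    num_filters_1 = c(10, 128),
    num_filters_2 = c(20, 256),
    dropout_rate = c(0.1, 0.5),
    dense_units = c(64, 512),
    batch_size = c(32, 128),
    l2_reg = c(1e-7, 1e-3)
  )
}

validate_classifier_config <- function(cfg) {
  sp <- hyperparameter_space()
  chk <- function(name, allow_zero = FALSE) {
    v <- cfg[[name]]
    lo <- sp[[name]][1]; hi <- sp[[name]][2]
    ok <- (v >= lo && v <= hi) || (allow_zero && v == 0)
    if (!ok) {
      rlang::abort(sprintf("`%s` = %g is outside its admissible range [%g, %g].",
                           name, v, lo, hi))
    }
  }
  chk("learning_rate"); chk("num_filters_1"); chk("num_filters_2")
  chk("dropout_rate"); chk("dense_units"); chk("batch_size")
  chk("l2_reg", allow_zero = TRUE)
  if (cfg$epochs < 1) rlang::abort("`epochs` must be >= 1.")
  invisible(cfg)
}

#' Build an (untrained) intent classifier
#'
#' Instantiates the network for a 450 x channels input window:
#' * `cnn`: conv(k = 7, `num_filters_1`) -> maxpool 4 -> conv(k = 5,
#'   `num_filters_2`) -> maxpool 4 -> dropout -> dense -> softmax over the 9
#'   intent classes;
#' * `mlcnn`: three parallel streams conv(k in 3/9/27, `num_filters_1`) ->
#'   maxpool 15, concatenated -> dropout -> dense -> softmax.
#'
#' Weight initialization is seeded, so identical config + seed gives
#' identical parameters.
#'
#' @param config A [classifier_config()].
#' @param input_shape `c(window_length, n_channels)`.
#' @return An object of class `intent_model` (untrained).
#' @export
build_model <- function(config, input_shape = c(450, 11)) {
  stopifnot(inherits(config, "classifier_config"))
  validate_classifier_config(config)
  net <- withr::with_seed(config$seed, nn_build(config, input_shape))
  structure(
    list(
      config = config, input_shape = as.integer(input_shape),
      classes = 0:8, plan = net$plan, params = net$params,
      history = NULL, trained = FALSE
    ),
    class = "intent_model"
  )
}

#' @export
print.intent_model <- function(x, ...) {
  cat(sprintf(
    "<intent_model> %s, input %d x %d, %d parameters%s\n",
    x$config$architecture, x$input_shape[1], x$input_shape[2],
    n_parameters(x), if (x$trained) " (trained)" else " (untrained)"
  ))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model An `intent_model`.
#' @param convolutional_only Count only convolution weights/biases.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model, convolutional_only = FALSE) {
  stopifnot(inherits(model, "intent_model"))
  net <- list(plan = model$plan, params = model$params)
  as.integer(if (convolutional_only) nn_conv_params(net) else nn_n_params(net))
}

check_windows <- function(windows) {
  if (!inherits(windows, "data.frame") ||
      !all(c("samples", "label") %in% names(windows))) {
    rlang::abort("`windows` must be a labeled_windows tibble with `samples` and `label`.")
  }
  if (nrow(windows) == 0) rlang::abort("`windows` is empty.")
  invisible(windows)
}

#' Train an intent classifier
#'
#' Minibatch Adam on softmax cross-entropy (plus the configured L2 penalty),
#' with a seeded train/validation split, per-epoch history and early stopping
#' on validation accuracy (the best-epoch weights are restored).
#'
#' @param model An `intent_model` from [build_model()].
#' @param windows A `labeled_windows` tibble.
#' @param validation_fraction Fraction held out for validation (0 disables
#'   early stopping).
#' @param epochs Override of the configured epoch count.
#' @param seed Override of the configured seed.
#' @return The trained `intent_model`, with `history` (tibble of `epoch`,
#'   `loss`, `accuracy`, `val_loss`, `val_accuracy`).
#' @export
train_model <- function(model, windows, validation_fraction = 0.2,
                        epochs = NULL, seed = NULL) {
  stopifnot(inherits(model, "intent_model"))
  check_windows(windows)
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  seed <- seed %||% cfg$seed
  labels <- as.integer(windows$label)
  present <- sort(unique(labels))
  if (length(setdiff(0:8, present)) > 0) {
    rlang::warn(sprintf("Classes absent from training data: %s",
                        paste(setdiff(0:8, present), collapse = ", ")))
  }
  X <- windows_to_array(windows$samples)
  if (!all(dim(X)[1:2] == model$input_shape)) {
    rlang::abort("Window shape does not match the model input shape.")
  }
  n <- length(labels)

  withr::with_seed(seed, {
    idx <- sample.int(n)
    n_val <- floor(validation_fraction * n)
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[setdiff(seq_len(n), seq_len(n_val))]
    Xtr <- X[, , tr_idx, drop = FALSE]; ytr <- labels[tr_idx]
    Xval <- if (n_val > 0) X[, , val_idx, drop = FALSE] else NULL
    yval <- labels[val_idx]

    net <- list(plan = model$plan, params = model$params)
    opt <- adam_init(net$params)
    hist <- vector("list", epochs)
    # early stopping monitors validation loss (accuracy saturates long before
    # the decision margins stop improving); best-epoch weights are restored
    best <- list(loss = Inf, acc = -Inf, params = net$params, epoch = 0L)
    wait <- 0L
    n_tr <- length(ytr)
    bs <- min(cfg$batch_size, n_tr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      tot_loss <- 0; tot_correct <- 0
      for (start in seq(1, n_tr, by = bs)) {
        take <- ord[start:min(start + bs - 1, n_tr)]
        Xb <- Xtr[, , take, drop = FALSE]
        yb <- ytr[take]
        fw <- nn_forward(net, Xb, train = TRUE)
        p <- fw$probs
        ll <- -mean(log(pmax(p[cbind(seq_along(yb), yb + 1L)], 1e-12)))
        tot_loss <- tot_loss + ll * length(yb)
        tot_correct <- tot_correct + sum(max.col(p, "first") - 1L == yb)
        grads <- nn_backward(net, Xb, yb, p, fw$cache)
        stepped <- adam_step(net$params, grads, opt, cfg$learning_rate)
        net$params <- stepped$params
        opt <- stepped$state
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (n_val > 0) {
        pv <- nn_predict_probs(net, Xval, bs)
        val_loss <- -mean(log(pmax(pv[cbind(seq_along(yval), yval + 1L)], 1e-12)))
        val_acc <- mean(max.col(pv, "first") - 1L == yval)
      }
      hist[[ep]] <- tibble::tibble(
        epoch = ep, loss = tot_loss / n_tr, accuracy = tot_correct / n_tr,
        val_loss = val_loss, val_accuracy = val_acc
      )
      monitor <- if (n_val > 0) val_loss else tot_loss / n_tr
      if (monitor < best$loss - 1e-12) {
        best <- list(loss = monitor,
                     acc = if (n_val > 0) val_acc else tot_correct / n_tr,
                     params = net$params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (n_val > 0 && wait >= cfg$patience) break
      }
    }
    model$params <- best$params
    model$history <- dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))])
    model$trained <- TRUE
    model$best_epoch <- best$epoch
    model$validation_accuracy <- if (n_val > 0) best$acc else NA_real_
  })
  model
}

# Batched inference without dropout.
nn_predict_probs <- function(net, X, batch_size = 128) {
  B <- dim(X)[3]
  out <- matrix(0, B, 9)
  for (start in seq(1, B, by = batch_size)) {
    take <- start:min(start + batch_size - 1, B)
    out[take, ] <- nn_forward(net, X[, , take, drop = FALSE], train = FALSE)$probs
  }
  out
}

#' Predict intent codes for windows
#'
#' @param object A trained `intent_model`.
#' @param windows A `labeled_windows` tibble (or anything with a `samples`
#'   list-column of window matrices).
#' @param ... Unused.
#' @return A tibble with predicted `code`, `prob` (probability of the argmax,
#'   ties broken toward the lowest code) and columns `p0` ... `p8`.
#' @export
predict.intent_model <- function(object, windows, ...) {
  check_windows_shape <- function(s) {
    if (!all(dim(s) == object$input_shape)) {
      rlang::abort("Window shape does not match the model input shape.")
    }
  }
  samples <- if (inherits(windows, "data.frame")) windows$samples else windows
  lapply(samples, check_windows_shape)
  X <- windows_to_array(samples)
  net <- list(plan = object$plan, params = object$params)
  p <- nn_predict_probs(net, X)
  colnames(p) <- paste0("p", 0:8)
  code <- max.col(p, ties.method = "first") - 1L
  dplyr::bind_cols(
    tibble::tibble(code = code, prob = p[cbind(seq_len(nrow(p)), code + 1L)]),
    tibble::as_tibble(p)
  )
}

#' Confusion matrix over the nine intent classes
#'
#' @param truth,predicted Integer class codes (0--8).
#' @return A 9 x 9 integer matrix of class `intent_confusion`; rows are true
#'   classes, columns predictions, `accuracy(cm) = trace / total`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:8), all(predicted %in% 0:8))
  cm <- table(factor(truth, levels = 0:8), factor(predicted, levels = 0:8))
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(truth = 0:8, predicted = 0:8)
  structure(cm, class = c("intent_confusion", class(cm)))
}

#' Classification accuracy of a confusion matrix
#'
#' @param cm An `intent_confusion` matrix.
#' @return `sum(diag(cm)) / sum(cm)`.
#' @export
accuracy <- function(cm) {
  sum(diag(cm)) / sum(cm)
}

#' Group-wise cross-validation
#'
#' One fold per group id: the held-out group is the external test set and
#' never appears in training or validation; the remaining groups are split
#' 80/20 into train and validation.  Reported per fold: internal (validation)
#' accuracy, external accuracy and the external confusion matrix.
#'
#' @param windows A `labeled_windows` tibble with a `group` column (>= 2
#'   distinct groups).
#' @param config A [classifier_config()].
#' @param seed Integer seed; per-fold seeds derive from it.
#' @param epochs Optional epoch override.
#' @return A tibble of class `intent_crossval`: one row per fold with
#'   `fold`, `group`, `n_train`, `n_external`, `internal_accuracy`,
#'   `external_accuracy`, and list-columns `confusion` and `model`.
#' @export
crossval_groups <- function(windows, config = classifier_config(), seed = 1L,
                            epochs = NULL) {
  check_windows(windows)
  if (!"group" %in% names(windows)) rlang::abort("`windows` needs a `group` column.")
  groups <- sort(unique(windows$group))
  if (length(groups) < 2) rlang::abort("Need at least 2 distinct groups.")
  input_shape <- dim(windows$samples[[1]])
  fold_seeds <- withr::with_seed(seed,
                                 sample.int(.Machine$integer.max - 1, length(groups)))
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    ext <- windows[windows$group == g, ]
    int <- windows[windows$group != g, ]
    if (nrow(ext) == 0) {
      rlang::warn(sprintf("Group %s has no windows; fold skipped.", format(g)))
      next
    }
    cfg <- config
    cfg$seed <- fold_seeds[i]
    model <- build_model(cfg, input_shape)
    model <- train_model(model, int, validation_fraction = 0.2,
                         epochs = epochs, seed = fold_seeds[i])
    pred <- predict(model, ext)
    cm <- confusion_matrix(ext$label, pred$code)
    rows[[i]] <- tibble::tibble(
      fold = i, group = g, n_train = nrow(int), n_external = nrow(ext),
      internal_accuracy = model$validation_accuracy,
      external_accuracy = accuracy(cm),
      confusion = list(cm), model = list(model)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("intent_crossval", class(out))
  out
}

#' Random hyperparameter search over the admissible space
#'
#' Draws `n_trials` seeded configurations -- log-uniform for `learning_rate`
#' and `l2_reg`, uniform (integer) for the filter counts, dense width and
#' batch size, uniform for `dropout_rate` -- trains each on the supplied
#' windows and scores it by validation accuracy.  Hyperparameter importances
#' are estimated from the trial log with a random-forest variance
#' decomposition.
#'
#' @param windows A `labeled_windows` tibble.
#' @param n_trials Number of trials (>= 1).
#' @param architecture Architecture tag for all trials.
#' @param epochs Training epochs per trial (kept small; the search ranks
#'   configurations, it does not produce the final fit).
#' @param validation_fraction Held-out fraction used as the objective.
#' @param seed Integer seed.
#' @return A list of class `hyper_search`: `best_config`, `best_accuracy`,
#'   `trials` (tibble log) and `importance` (named numeric, sums to 1).
#' @export
search_hyperparameters <- function(windows, n_trials = 50,
                                   architecture = "mlcnn", epochs = 3,
                                   validation_fraction = 0.2, seed = 1L) {
  check_windows(windows)
  if (n_trials < 1) rlang::abort("`n_trials` must be >= 1.")
  sp <- hyperparameter_space()
  input_shape <- dim(windows$samples[[1]])
  draws <- withr::with_seed(seed, {
    tibble::tibble(
      trial = seq_len(n_trials),
      learning_rate = exp(runif(n_trials, log(sp$learning_rate[1]),
                                log(sp$learning_rate[2]))),
      num_filters_1 = sample(sp$num_filters_1[1]:sp$num_filters_1[2],
                             n_trials, replace = TRUE),
      num_filters_2 = sample(sp$num_filters_2[1]:sp$num_filters_2[2],
                             n_trials, replace = TRUE),
      dropout_rate = runif(n_trials, sp$dropout_rate[1], sp$dropout_rate[2]),
      dense_units = sample(sp$dense_units[1]:sp$dense_units[2],
                           n_trials, replace = TRUE),
      batch_size = sample(sp$batch_size[1]:sp$batch_size[2],
                          n_trials, replace = TRUE),
      l2_reg = exp(runif(n_trials, log(sp$l2_reg[1]), log(sp$l2_reg[2]))),
      seed = sample.int(.Machine$integer.max - 1, n_trials)
    )
  })
  acc <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    d <- draws[i, ]
    cfg <- classifier_config(
      architecture = architecture, learning_rate = d$learning_rate,
      num_filters_1 = d$num_filters_1, num_filters_2 = d$num_filters_2,
      dropout_rate = d$dropout_rate, dense_units = d$dense_units,
      batch_size = d$batch_size, l2_reg = d$l2_reg, epochs = epochs,
      seed = d$seed
    )
    m <- build_model(cfg, input_shape)
    m <- train_model(m, windows, validation_fraction = validation_fraction)
    acc[i] <- m$validation_accuracy
  }
  trials <- dplyr::mutate(draws, accuracy = acc)
  best_i <- which.max(acc)
  d <- draws[best_i, ]
  best_config <- classifier_config(
    architecture = architecture, learning_rate = d$learning_rate,
    num_filters_1 = d$num_filters_1, num_filters_2 = d$num_filters_2,
    dropout_rate = d$dropout_rate, dense_units = d$dense_units,
    batch_size = d$batch_size, l2_reg = d$l2_reg, seed = d$seed
  )
  importance <- hyper_importance(trials)
  structure(
    list(best_config = best_config, best_accuracy = acc[best_i],
         trials = trials, importance = importance),
    class = "hyper_search"
  )
}

hyper_importance <- function(trials, seed = 1L) {
  vars <- c("learning_rate", "num_filters_1", "num_filters_2", "dropout_rate",
            "dense_units", "batch_size", "l2_reg")
  df <- as.data.frame(trials[, c(vars, "accuracy")])
  rf <- withr::with_seed(seed, {
    randomForest::randomForest(accuracy ~ ., data = df, ntree = 300,
                               importance = TRUE)
  })
  imp <- randomForest::importance(rf, type = 2)[, 1]
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) imp[] <- 1
  imp / sum(imp)
}

#' @export
print.hyper_search <- function(x, ...) {
  cat(sprintf("<hyper_search> %d trials, best validation accuracy %.4f\n",
              nrow(x$trials), x$best_accuracy))
  invisible(x)
}
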