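#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained intent model's training history
#'
#' @param x An `intent_model`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `loss`, `accuracy`,
#'   `val_loss`, `val_accuracy`).
#' @export
tidy.intent_model <- function(x, ...) {
  if (is.null(x$history)) {
    rlang::abort("Model has no training history; train it first.")
  }
  x$history
}

#' One-row summary of a trained intent model
#'
#' @param x An `intent_model`.
#' @param ... Unused.
#' @return Tibble with `architecture`, `n_parameters`, `epochs_run`,
#'   `best_epoch`, `validation_accuracy`.
#' @export
glance.intent_model <- function(x, ...) {
  tibble::tibble(
    architecture = x$config$architecture,
    n_parameters = n_parameters(x),
    epochs_run = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    validation_accuracy = x$validation_accuracy %||% NA_real_
  )
}

#' Tidy a group-wise cross-validation result
#'
#' @param x An `intent_crossval` tibble.
#' @param ... Unused.
#' @return Per-fold tibble without the model/confusion list-columns.
#' @export
tidy.intent_crossval <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -dplyr::any_of(c("confusion", "model")))
}

#' Summary accuracies of a group-wise cross-validation
#'
#' @param x An `intent_crossval` tibble.
#' @param ... Unused.
#' @return One-row tibble with `n_folds`, `mean_internal_accuracy`,
#'   `mean_external_accuracy`.
#' @export
glance.intent_crossval <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x),
    mean_internal_accuracy = mean(x$internal_accuracy, na.rm = TRUE),
    mean_external_accuracy = mean(x$external_accuracy, na.rm = TRUE)
  )
}

#' Tidy a confusion matrix into long form
#'
#' @param x An `intent_confusion` matrix.
#' @param ... Unused.
#' @return Tibble with `truth`, `predicted`, `n`.
#' @export
tidy.intent_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)))
  names(df) <- c("truth", "predicted", "n")
  tibble::as_tibble(dplyr::mutate(
    df,
    truth = as.integer(as.character(.data$truth)),
    predicted = as.integer(as.character(.data$predicted)),
    n = as.integer(.data$n)
  ))
}

#' Tidy a hyperparameter search (trial log)
#'
#' @param x A `hyper_search`.
#' @param ... Unused.
#' @return The trial tibble (one row per trial with the sampled
#'   hyperparameters and the achieved validation accuracy).
#' @export
tidy.hyper_search <- function(x, ...) {
  x$trials
}

#' One-row summary of a hyperparameter search
#'
#' @param x A `hyper_search`.
#' @param ... Unused.
#' @return Tibble with `n_trials`, `best_accuracy` and the importance of the
#'   two dominant hyperparameters.
#' @export
glance.hyper_search <- function(x, ...) {
  imp <- sort(x$importance, decreasing = TRUE)
  tibble::tibble(
    n_trials = nrow(x$trials),
    best_accuracy = x$best_accuracy,
    top_importance = names(imp)[1],
    top_importance_share = unname(imp[1])
  )
}
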