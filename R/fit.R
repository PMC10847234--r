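#' Train a spiking network on encoded samples
#'
#' Online (per-sample) training of an SRM network with joint weight and
#' delay plasticity.  Each epoch shuffles the data (seeded), then for every
#' sample runs one forward pass, one backward pass and one parameter
#' update via [fit_one_sample()].  The history records, per epoch, the mean
#' pre-update loss and the online training accuracy (each sample classified
#' by its pre-update forward pass).  Fully deterministic given
#' `tc$seed`.
#'
#' @param data Tibble of encoded samples: list-columns `input_times`,
#'   `desired_times` and integer `label` (as produced by
#'   [encode_features()] or the synthetic generators).  Rows with a
#'   `split` column are *not* filtered here; subset before calling.
#' @param layer_sizes Network architecture (input size must match the
#'   encoded input width).
#' @param config A [neuron_config()].
#' @param sg A [surrogate_config()].
#' @param tc A [train_config()].
#' @param grid A [time_grid()].
#' @param decoder Function `record -> class index`; defaults to
#'   [classify_record()].  Use [decoder_nearest_time()] for single-output
#'   tasks.
#' @param params Optional starting [network_params()]; defaults to
#'   [init_network()] seeded with `tc$seed`.
#' @param stop_at_accuracy Optional early stop: end training after the
#'   first epoch whose training accuracy reaches this fraction (e.g. 1.0).
#' @return An object of class `srm_fit`: the final `params`, the `history`
#'   tibble (`epoch`, `mean_loss`, `train_accuracy`), and the
#'   configurations used.
#' @export
srm_fit <- function(data, layer_sizes, config = neuron_config(),
                    sg = surrogate_config(), tc = train_config(),
                    grid = time_grid(), decoder = NULL, params = NULL,
                    stop_at_accuracy = NULL) {
  n <- nrow(data)
  if (is.null(n) || n == 0) abort("`data` must contain at least one sample.")
  if (length(data$input_times[[1]]) != layer_sizes[1]) {
    abort(sprintf("encoded input width %d does not match input layer size %d.",
                  length(data$input_times[[1]]), layer_sizes[1]))
  }
  if (is.null(params)) params <- init_network(layer_sizes, config, tc$seed)
  if (is.null(decoder)) decoder <- classify_record

  history <- tibble::tibble(epoch = integer(), mean_loss = numeric(),
                            train_accuracy = numeric())
  set.seed(tc$seed)
  tc_epoch <- tc
  if (tc$epochs > 0) {
    for (epoch in seq_len(tc$epochs)) {
      if (!is.null(tc$eta_decay) && tc$eta_decay < 1 && epoch > 1) {
        tc_epoch$eta_w <- tc_epoch$eta_w * tc$eta_decay
        tc_epoch$eta_d <- tc_epoch$eta_d * tc$eta_decay
      }
      ord <- sample.int(n)
      losses <- numeric(n)
      correct <- logical(n)
      for (s in seq_len(n)) {
        r <- ord[s]
        res <- fit_one_sample(data$input_times[[r]], data$desired_times[[r]],
                              params, config, sg, tc_epoch, grid)
        params <- res$params
        losses[s] <- res$loss
        correct[s] <- decoder(res$record) == data$label[r]
      }
      acc <- mean(correct)
      history <- dplyr::bind_rows(history, tibble::tibble(
        epoch = epoch, mean_loss = mean(losses), train_accuracy = acc
      ))
      if (!is.null(stop_at_accuracy) && acc >= stop_at_accuracy) break
    }
  }
  structure(
    list(params = params, history = history, config = config, sg = sg,
         tc = tc, grid = grid, decoder = decoder,
         layer_sizes = as.integer(layer_sizes)),
    class = "srm_fit"
  )
}

#' @export
print.srm_fit <- function(x, ...) {
  cat(sprintf("<srm_fit> architecture %s, %s mode%s\n",
              paste(x$layer_sizes, collapse = "-"), x$sg$mode,
              if (x$tc$weight_only) " (weight-only)" else ""))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epoch(s); final mean loss %.4f, train accuracy %.1f%%\n",
                nrow(x$history), last$mean_loss, 100 * last$train_accuracy))
  } else {
    cat("  untrained (0 epochs)\n")
  }
  invisible(x)
}

#' Predict class labels for encoded samples
#'
#' @param object An `srm_fit`.
#' @param new_data Tibble of encoded samples (`input_times`, optionally
#'   `label`).
#' @param ... Unused.
#' @return A tibble with one row per sample: `.pred_class`, list-column
#'   `.pred_times` (output spike times), and `decided_by` (`"spikes"` when
#'   at least one output fired, `"potential"` when the decision fell back
#'   to the silent-case membrane-potential rule).
#' @export
predict.srm_fit <- function(object, new_data, ...) {
  n <- nrow(new_data)
  pred <- integer(n)
  times <- vector("list", n)
  decided <- character(n)
  for (r in seq_len(n)) {
    rec <- simulate_forward(new_data$input_times[[r]], object$params,
                            object$config, object$grid)
    pred[r] <- object$decoder(rec)
    t_o <- output_times(rec)
    times[[r]] <- t_o
    decided[r] <- if (any(!is.na(t_o))) "spikes" else "potential"
  }
  tibble::tibble(.pred_class = pred, .pred_times = times,
                 decided_by = decided)
}

#' Accuracy of a fitted network on labeled samples
#'
#' @param object An `srm_fit`.
#' @param new_data Tibble of encoded samples with a `label` column; must be
#'   non-empty (an empty evaluation set is an error, never 0%).
#' @return A one-row tibble: `accuracy_pct`, `n`, `n_silent_decided`
#'   (samples decided by the membrane-potential fallback).
#' @export
srm_evaluate <- function(object, new_data) {
  if (is.null(nrow(new_data)) || nrow(new_data) == 0) {
    abort("evaluation set is empty; refusing to report an accuracy.")
  }
  preds <- predict(object, new_data)
  tibble::tibble(
    accuracy_pct = 100 * mean(preds$.pred_class == new_data$label),
    n = nrow(new_data),
    n_silent_decided = sum(preds$decided_by == "potential")
  )
}

#' @exportS3Method generics::tidy
tidy.srm_fit <- function(x, ...) {
  rows <- lapply(seq_along(x$params$weights), function(l) {
    W <- x$params$weights[[l]]
    D <- x$params$delays[[l]]
    idx <- expand.grid(pre = seq_len(nrow(W)), post = seq_len(ncol(W)))
    tibble::tibble(layer = l + 1L, pre = idx$pre, post = idx$post,
                   weight = W[cbind(idx$pre, idx$post)],
                   delay = D[cbind(idx$pre, idx$post)])
  })
  dplyr::bind_rows(rows)
}

#' @exportS3Method generics::glance
glance.srm_fit <- function(x, ...) {
  n_par <- sum(vapply(x$params$weights, length, integer(1)))
  last <- if (nrow(x$history)) x$history[nrow(x$history), ] else
    tibble::tibble(mean_loss = NA_real_, train_accuracy = NA_real_)
  tibble::tibble(
    architecture = paste(x$layer_sizes, collapse = "-"),
    epochs = nrow(x$history),
    final_loss = last$mean_loss,
    final_train_accuracy_pct = 100 * last$train_accuracy,
    n_weights = n_par,
    n_delays = n_par,
    mode = x$sg$mode,
    weight_only = x$tc$weight_only
  )
}

#' Training-history curves
#'
#' @param object An `srm_fit`.
#' @param ... Unused.
#' @return A ggplot of mean loss and training accuracy against epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.srm_fit <- function(object, ...) {
  h <- object$history
  if (!nrow(h)) abort("no history to plot (0 epochs).")
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, metric = "mean loss",
                   value = h$mean_loss),
    tibble::tibble(epoch = h$epoch, metric = "train accuracy",
                   value = h$train_accuracy)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Spiking-network training history") +
    ggplot2::theme_minimal()
}

#' Membrane-potential traces of a simulated sample
#'
#' @param record An `srm_record`.
#' @param layer Layer to plot (default: output layer).
#' @param theta Optional threshold to mark as a horizontal line.
#' @return A ggplot of each neuron's potential over the window, with
#'   detected spike times marked.
#' @export
plot_potentials <- function(record, layer = length(record$times),
                            theta = NULL) {
  if (layer < 2) abort("the input layer has no membrane potential.")
  V <- record$v_trace[[layer]]
  tg <- record$grid$times
  long <- dplyr::bind_rows(lapply(seq_len(ncol(V)), function(j) {
    tibble::tibble(t = tg, v = V[, j], neuron = factor(j))
  }))
  spikes <- tibble::tibble(
    t = record$times[[layer]],
    neuron = factor(seq_len(ncol(V)))
  )
  spikes <- spikes[!is.na(spikes$t), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$v,
                                     color = .data$neuron)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = spikes,
                        ggplot2::aes(xintercept = .data$t,
                                     color = .data$neuron),
                        linetype = "dashed", alpha = 0.6) +
    (if (!is.null(theta)) {
      ggplot2::geom_hline(yintercept = theta, linetype = "dotted")
    }) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential",
                  title = sprintf("Layer %d membrane potentials", layer)) +
    ggplot2::theme_minimal()
}
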