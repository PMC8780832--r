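#' Network architecture for the sequence classifier
#'
#' Describes the stacked-LSTM binary classifier operating on 3-second,
#' 12-channel windows: a sequence-output LSTM, batch normalization over the
#' channel axis, a second LSTM emitting its last hidden state, two dropout /
#' dense(ReLU) stages and a single sigmoid output unit.
#'
#' @param input_timesteps timesteps per window (default 300 = 3 s at 100 Hz).
#' @param input_channels feature channels per timestep (default 12).
#' @param lstm_units sizes of the two recurrent layers (default `c(200, 50)`).
#' @param dense_units sizes of the two ReLU dense layers (default `c(50, 15)`).
#' @param dropout_p dropout probability (default 0.2).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_timesteps = 300, input_channels = 12,
                         lstm_units = c(200, 50), dense_units = c(50, 15),
                         dropout_p = 0.2) {
  stopifnot(length(lstm_units) == 2, length(dense_units) == 2,
            dropout_p >= 0, dropout_p < 1)
  structure(list(input_timesteps = as.integer(input_timesteps),
                 input_channels = as.integer(input_channels),
                 lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 dropout_p = dropout_p),
            class = "network_spec")
}

#' Analytic per-layer parameter counts
#'
#' Counts trainable-plus-tracked parameters per layer without building the
#' network: an LSTM layer with `u` units on `d` inputs has
#' `4 (u (u + d) + u)` weights (four gates, each with input and recurrent
#' kernels and a bias); batch normalization tracks `4 c` values per channel
#' (scale, shift and the two running statistics); a dense layer mapping `d`
#' to `u` has `(d + 1) u`; dropout has none.
#'
#' @param spec a [network_spec()].
#' @return Named integer vector of per-layer counts, in network order.
#' @export
count_parameters <- function(spec = network_spec()) {
  d <- spec$input_channels
  u1 <- spec$lstm_units[1]; u2 <- spec$lstm_units[2]
  d1 <- spec$dense_units[1]; d2 <- spec$dense_units[2]
  c(lstm_1 = 4L * (u1 * (u1 + d) + u1),
    batch_norm = 4L * u1,
    lstm_2 = 4L * (u2 * (u2 + u1) + u2),
    dropout_1 = 0L,
    dense_relu_1 = (u2 + 1L) * d1,
    dropout_2 = 0L,
    dense_relu_2 = (d1 + 1L) * d2,
    dense_sigmoid = (d2 + 1L) * 1L)
}

#' @export
print.network_spec <- function(x, ...) {
  cnt <- count_parameters(x)
  layers <- c(
    sprintf("LSTM (None,%d,%d)", x$input_timesteps, x$lstm_units[1]),
    sprintf("BatchNorm (None,%d,%d)", x$input_timesteps, x$lstm_units[1]),
    sprintf("LSTM (None,%d)", x$lstm_units[2]),
    sprintf("Dropout (None,%d)", x$lstm_units[2]),
    sprintf("Dense ReLU (None,%d)", x$dense_units[1]),
    sprintf("Dropout (None,%d)", x$dense_units[1]),
    sprintf("Dense ReLU (None,%d)", x$dense_units[2]),
    "Dense Sigmoid (None,1)")
  cat("<network_spec> input (None,", x$input_timesteps, ",",
      x$input_channels, ")\n", sep = "")
  for (k in seq_along(layers))
    cat(sprintf("  %-28s %10s\n", layers[k], format(cnt[k], big.mark = ",")))
  cat(sprintf("  %-28s %10s\n", "total",
              format(sum(cnt), big.mark = ",")))
  invisible(x)
}

label_to_binary <- function(label) {
  if (is.numeric(label) || is.logical(label)) {
    y <- as.numeric(label)
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(list(y = y, levels = c("0", "1")))
  }
  lv <- sort(unique(as.character(label)))
  if (length(lv) > 2) stop("labels must be binary", call. = FALSE)
  # convention: "stroke" (or the second level alphabetically) is the
  # positive class
  if (all(c("healthy", "stroke") %in% lv)) lv <- c("healthy", "stroke")
  list(y = as.numeric(as.character(label) == lv[length(lv)]), levels = lv)
}

window_matrix <- function(x) {
  if (inherits(x, "window_set")) x$features else x
}

#' Fit the stacked-LSTM window classifier
#'
#' Trains the [network_spec()] architecture with binary cross-entropy and
#' Adam on 3-D window arrays (`n x timesteps x channels`). Inputs are
#' z-scored per channel with statistics computed on the training set only;
#' the same statistics are applied at prediction time. Training is
#' deterministic for a fixed seed under single-threaded numerics: parameter
#' initialization, shuffling and dropout all draw from one seeded stream.
#'
#' @param x a `window_set` or an `n x timesteps x channels` array.
#' @param y binary labels (0/1, logical, or two-level character/factor such
#'   as healthy/stroke); defaults to the window-set labels.
#' @param spec a [network_spec()].
#' @param epochs training epochs (default 20).
#' @param batch_size minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param clip_norm global-norm gradient clipping threshold (default 1;
#'   0 disables).
#' @param validation optional `list(x =, y =)` (or a `window_set`) scored
#'   after every epoch.
#' @param seed integer seed.
#' @param standardize z-score channels on training statistics (default TRUE).
#' @param verbose print per-epoch progress.
#' @return An object of class `lstm_classifier` with `history`, the fitted
#'   `weights`, the batch-norm running statistics and the channel scaling.
#' @export
fit_lstm <- function(x, y = NULL, spec = network_spec(), epochs = 20,
                     batch_size = 64, learning_rate = 1e-3, clip_norm = 1,
                     validation = NULL, seed = 1L, standardize = TRUE,
                     verbose = FALSE) {
  arr <- window_matrix(x)
  if (is.null(y)) {
    if (!inherits(x, "window_set")) stop("`y` required for array input",
                                         call. = FALSE)
    y <- x$label
  }
  lab <- label_to_binary(y)
  if (length(unique(lab$y)) < 2)
    stop("training set has a single class", call. = FALSE)
  dm <- dim(arr)
  if (dm[2] != spec$input_timesteps || dm[3] != spec$input_channels)
    stop("window shape ", dm[2], "x", dm[3], " does not match spec ",
         spec$input_timesteps, "x", spec$input_channels, call. = FALSE)
  if (standardize) {
    mu <- apply(arr, 3, mean)
    sdv <- apply(arr, 3, sd)
    sdv[sdv == 0] <- 1
    arr <- scale_channels(arr, mu, sdv)
  } else {
    mu <- rep(0, dm[3]); sdv <- rep(1, dm[3])
  }
  xv <- numeric(0); yv <- numeric(0)
  if (!is.null(validation)) {
    if (inherits(validation, "window_set"))
      validation <- list(x = validation$features,
                         y = validation$label)
    xv <- scale_channels(window_matrix(validation$x), mu, sdv)
    yv <- label_to_binary(validation$y)$y
  }
  dims <- list(timesteps = dm[2], channels = dm[3],
               lstm1 = spec$lstm_units[1], lstm2 = spec$lstm_units[2],
               dense1 = spec$dense_units[1], dense2 = spec$dense_units[2])
  fit <- .lstm_train_cpp(arr, lab$y, xv, yv, dims, as.integer(epochs),
                         as.integer(batch_size), learning_rate,
                         spec$dropout_p, clip_norm, as.integer(seed), verbose)
  structure(
    list(spec = spec, weights = fit$weights,
         running_mean = fit$running_mean, running_var = fit$running_var,
         history = fit$history, levels = lab$levels,
         channel_mean = mu, channel_sd = sdv, seed = seed,
         config = list(epochs = epochs, batch_size = batch_size,
                       learning_rate = learning_rate, clip_norm = clip_norm,
                       dropout_p = spec$dropout_p)),
    class = "lstm_classifier")
}

scale_channels <- function(arr, mu, sdv) {
  for (c in seq_along(mu)) arr[, , c] <- (arr[, , c] - mu[c]) / sdv[c]
  arr
}

#' @export
print.lstm_classifier <- function(x, ...) {
  h <- x$history
  cat("<lstm_classifier> ", sum(count_parameters(x$spec)), " parameters, ",
      nrow(h), " epochs\n", sep = "")
  last <- h[nrow(h), ]
  cat(sprintf("  final loss %.4f, accuracy %.3f", last$loss, last$accuracy))
  if (!is.na(last$val_accuracy))
    cat(sprintf(", val accuracy %.3f", last$val_accuracy))
  cat("\n  positive class:", x$levels[length(x$levels)], "\n")
  invisible(x)
}

#' @export
summary.lstm_classifier <- function(object, ...) {
  print(object$spec)
  print(object)
  invisible(object)
}

#' @describeIn fit_lstm training-history curves (loss and accuracy by epoch).
#' @param ... ignored.
#' @export
plot.lstm_classifier <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "loss",
       main = "training loss")
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, type = "b", col = 2)
  plot(h$epoch, h$accuracy, type = "b", xlab = "epoch", ylab = "accuracy",
       ylim = c(0, 1), main = "accuracy")
  if (!all(is.na(h$val_accuracy)))
    graphics::lines(h$epoch, h$val_accuracy, type = "b", col = 2)
  invisible(x)
}

#' Predict window class probabilities
#'
#' @param object an [fit_lstm()] model.
#' @param newdata a `window_set` or 3-D window array.
#' @param type `"prob"` for positive-class probabilities, `"class"` for hard
#'   labels at threshold 0.5.
#' @param ... ignored.
#' @export
predict.lstm_classifier <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  arr <- scale_channels(window_matrix(newdata), object$channel_mean,
                        object$channel_sd)
  dims <- list(timesteps = object$spec$input_timesteps,
               channels = object$spec$input_channels,
               lstm1 = object$spec$lstm_units[1],
               lstm2 = object$spec$lstm_units[2],
               dense1 = object$spec$dense_units[1],
               dense2 = object$spec$dense_units[2])
  p <- .lstm_predict_cpp(arr, object$weights, object$running_mean,
                         object$running_var, dims)
  if (type == "prob") return(p)
  object$levels[1L + (p > 0.5)]
}

#' ROC evaluation by threshold sweep
#'
#' Sweeps every distinct predicted score as a decision threshold, records
#' the (FPR, TPR) operating points and integrates the curve trapezoidally.
#' The area is invariant under strictly monotone transforms of the scores.
#'
#' @param scores predicted positive-class scores, or an `lstm_classifier`
#'   (then `windows` supplies the data).
#' @param labels binary labels aligned with `scores`.
#' @param windows a `window_set` scored with the model when `scores` is a
#'   model.
#' @return An object of class `roc_eval`: data.frame `points`
#'   (threshold/fpr/tpr) and scalar `auc`.
#' @export
evaluate_roc <- function(scores, labels = NULL, windows = NULL) {
  if (inherits(scores, "lstm_classifier")) {
    if (is.null(windows)) stop("`windows` required with a model", call. = FALSE)
    labels <- if (is.null(labels)) windows$label else labels
    scores <- predict(scores, windows)
  }
  y <- label_to_binary(labels)$y
  if (length(unique(y)) < 2)
    stop("ROC needs both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  np <- sum(ys); nn <- length(ys) - np
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  # collapse tied scores to one operating point
  last_of_tie <- c(diff(scores[ord]) != 0, TRUE)
  pts <- data.frame(threshold = scores[ord][last_of_tie],
                    fpr = fp[last_of_tie] / nn, tpr = tp[last_of_tie] / np)
  pts <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), pts)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_eval")
}

#' @export
print.roc_eval <- function(x, ...) {
  cat("<roc_eval> AUC =", sprintf("%.4f", x$auc), "over",
      nrow(x$points) - 1, "operating points\n")
  invisible(x)
}

#' @describeIn evaluate_roc draw the ROC curve.
#' @param x a `roc_eval`.
#' @param ... passed to [plot()].
#' @export
plot.roc_eval <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Smallest threshold achieving a requested sensitivity
#'
#' Scans the ROC operating points for the largest threshold whose true
#' positive rate meets `target` — the operating point a screening
#' application would choose to keep sensitivity high while minimising
#' false positives.
#'
#' @param roc an [evaluate_roc()] result.
#' @param target required sensitivity in (0, 1].
#' @return List with `threshold`, `tpr`, `fpr` at the chosen point.
#' @export
threshold_for_sensitivity <- function(roc, target) {
  pts <- roc$points[roc$points$tpr >= target & is.finite(roc$points$threshold), ]
  if (nrow(pts) == 0) stop("requested sensitivity not attainable", call. = FALSE)
  best <- pts[which.max(pts$threshold), ]
  list(threshold = best$threshold, tpr = best$tpr, fpr = best$fpr)
}

#' Save / load a fitted classifier
#'
#' The checkpoint holds the weights, the batch-norm running statistics, the
#' channel scaling and the training history; a JSON mirror of the
#' architecture is written alongside.
#'
#' @param model an `lstm_classifier`.
#' @param path checkpoint path.
#' @export
write_lstm_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  jsonlite::write_json(unclass(model$spec), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lstm_checkpoint
#' @export
read_lstm_checkpoint <- function(path) {
  m <- readRDS(path)
  m$spec <- structure(m$spec, class = "network_spec")
  structure(m, class = "lstm_classifier")
}
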