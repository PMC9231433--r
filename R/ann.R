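# The gesture classifier: a two-layer feed-forward network (10 tanh hidden
# units, 4 softmax outputs) trained by full-batch gradient descent on
# cross-entropy. Features are the concatenated filtered window samples,
# standardized per feature with training-set statistics that travel with
# the model.

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)            # shift for numerical stability
  e <- exp(z)
  e / rowSums(e)
}

#' Construct an ANN gesture classifier object
#'
#' Normally produced by [train_gesture_ann()]; exposed so models can be
#' rebuilt from serialized weights.
#'
#' @param hidden_weights `n_hidden x n_features` matrix.
#' @param hidden_biases length-`n_hidden` vector.
#' @param output_weights `n_labels x n_hidden` matrix.
#' @param output_biases length-`n_labels` vector.
#' @param feat_mean,feat_sd per-feature standardization constants.
#' @param label_order classifier output order (fixed to [gesture_labels()]).
#' @param train_seed seed the model was trained with.
#' @param holdout_accuracy held-out accuracy recorded at training time.
#' @return an `ann_model` object.
#' @export
ann_model <- function(hidden_weights, hidden_biases, output_weights,
                      output_biases, feat_mean, feat_sd,
                      label_order = gesture_labels(),
                      train_seed = NA_integer_, holdout_accuracy = NA_real_) {
  hidden_weights <- as.matrix(hidden_weights)
  output_weights <- as.matrix(output_weights)
  stopifnot(nrow(hidden_weights) == length(hidden_biases),
            nrow(output_weights) == length(output_biases),
            ncol(output_weights) == nrow(hidden_weights),
            length(feat_mean) == ncol(hidden_weights),
            length(feat_sd) == ncol(hidden_weights),
            length(label_order) == length(output_biases))
  structure(
    list(hidden_weights = hidden_weights,
         hidden_biases = as.numeric(hidden_biases),
         output_weights = output_weights,
         output_biases = as.numeric(output_biases),
         feat_mean = as.numeric(feat_mean),
         feat_sd = as.numeric(feat_sd),
         label_order = label_order,
         hidden_activation = "tanh",
         output_activation = "softmax",
         train_seed = train_seed,
         holdout_accuracy = holdout_accuracy),
    class = "ann_model"
  )
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf(
    "Feed-forward gesture classifier: %d features -> %d tanh -> %d softmax\n",
    ncol(x$hidden_weights), nrow(x$hidden_weights), nrow(x$output_weights)))
  cat(sprintf("  labels: %s\n", paste(x$label_order, collapse = ", ")))
  if (!is.na(x$holdout_accuracy)) {
    cat(sprintf("  held-out accuracy at training: %.3f\n", x$holdout_accuracy))
  }
  invisible(x)
}

# Forward pass on a standardized feature matrix (rows = examples).
ann_forward <- function(model, x_std) {
  h <- tanh(x_std %*% t(model$hidden_weights) +
              matrix(model$hidden_biases, nrow(x_std),
                     length(model$hidden_biases), byrow = TRUE))
  z <- h %*% t(model$output_weights) +
    matrix(model$output_biases, nrow(x_std),
           length(model$output_biases), byrow = TRUE)
  softmax_rows(z)
}

standardize_features <- function(x, mu, sd) {
  sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}

# Stratified holdout split: same fraction held out from every class.
stratified_split <- function(labels, holdout_fraction) {
  test_idx <- integer(0)
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    n_test <- floor(length(idx) * holdout_fraction)
    if (n_test > 0) test_idx <- c(test_idx, sample(idx, n_test))
  }
  sort(test_idx)
}

#' Train the eye-gesture neural network
#'
#' Fits the two-layer architecture (10 hidden neurons, 4 output neurons) to
#' a labelled collection of gesture windows. Features are the concatenated
#' filtered samples of both channels, standardized per feature using
#' training-split statistics (stored in the model). Training minimises
#' cross-entropy by full-batch gradient descent with a fixed step size and a
#' maximum epoch count; identical seed and dataset give an identical model.
#'
#' @param windows list of [gesture_window()] objects, each carrying a label.
#' @param train_seed integer seed controlling the holdout split and weight
#'   initialisation.
#' @param holdout_fraction fraction of each class held out for the accuracy
#'   estimate (default 0.2).
#' @param n_hidden hidden-layer width (default 10).
#' @param learning_rate fixed gradient-descent step (default 0.3).
#' @param max_epochs full-batch epochs (default 500).
#' @return an `ann_model` with `holdout_accuracy` filled in.
#' @export
train_gesture_ann <- function(windows, train_seed = 0,
                              holdout_fraction = 0.2,
                              n_hidden = 10,
                              learning_rate = 0.3,
                              max_epochs = 500) {
  if (length(windows) == 0) {
    hf_stop("empty training dataset", "hf_validation_error")
  }
  labels <- vapply(windows, function(w) w$label %||% NA_character_,
                   character(1))
  if (anyNA(labels)) {
    hf_stop("every training window must carry a label", "hf_validation_error")
  }
  if (length(unique(labels)) < 2) {
    hf_stop("training needs at least two distinct gesture classes",
            "hf_validation_error")
  }
  stopifnot(holdout_fraction >= 0, holdout_fraction < 1)

  x <- t(vapply(windows, window_to_features,
                numeric(2 * windows[[1]]$window_len)))
  label_order <- GESTURE_LABELS
  y_idx <- match(labels, label_order)
  n_out <- length(label_order)

  with_preserved_seed(train_seed, {
    test_idx <- if (holdout_fraction > 0) {
      stratified_split(labels, holdout_fraction)
    } else integer(0)
    train_idx <- setdiff(seq_along(labels), test_idx)

    x_tr <- x[train_idx, , drop = FALSE]
    mu <- colMeans(x_tr)
    sd <- apply(x_tr, 2, stats::sd)
    sd[sd < 1e-12] <- 1                 # constant features pass through
    x_tr <- standardize_features(x_tr, mu, sd)
    y_tr <- y_idx[train_idx]
    n_tr <- length(train_idx)
    n_feat <- ncol(x_tr)

    y_onehot <- matrix(0, n_tr, n_out)
    y_onehot[cbind(seq_len(n_tr), y_tr)] <- 1

    w1 <- matrix(stats::rnorm(n_hidden * n_feat, sd = 0.1), n_hidden, n_feat)
    b1 <- numeric(n_hidden)
    w2 <- matrix(stats::rnorm(n_out * n_hidden, sd = 0.1), n_out, n_hidden)
    b2 <- numeric(n_out)

    for (epoch in seq_len(max_epochs)) {
      h <- tanh(x_tr %*% t(w1) + matrix(b1, n_tr, n_hidden, byrow = TRUE))
      p <- softmax_rows(h %*% t(w2) + matrix(b2, n_tr, n_out, byrow = TRUE))
      dz2 <- (p - y_onehot) / n_tr
      dw2 <- t(dz2) %*% h
      db2 <- colSums(dz2)
      dh <- dz2 %*% w2
      dz1 <- dh * (1 - h^2)
      dw1 <- t(dz1) %*% x_tr
      db1 <- colSums(dz1)
      w2 <- w2 - learning_rate * dw2
      b2 <- b2 - learning_rate * db2
      w1 <- w1 - learning_rate * dw1
      b1 <- b1 - learning_rate * db1
    }

    model <- ann_model(w1, b1, w2, b2, mu, sd,
                       label_order = label_order, train_seed = train_seed)
    acc <- NA_real_
    if (length(test_idx) > 0) {
      x_te <- standardize_features(x[test_idx, , drop = FALSE], mu, sd)
      p_te <- ann_forward(model, x_te)
      pred <- max.col(p_te, ties.method = "first")
      acc <- mean(pred == y_idx[test_idx])
    }
    model$holdout_accuracy <- acc
    model
  })
}

#' Classify one gesture window
#'
#' Runs the forward pass and returns the winning label and the full score
#' vector. Scores are a softmax output: nonnegative and summing to 1. Exact
#' score ties resolve to the earliest label in the model's `label_order`.
#'
#' @param model an [ann_model()].
#' @param window a [gesture_window()] whose feature length matches the model.
#' @return a list with elements `label` and `scores` (named numeric vector).
#' @export
classify_gesture <- function(model, window) {
  stopifnot(inherits(model, "ann_model"))
  feats <- window_to_features(window)
  if (length(feats) != ncol(model$hidden_weights)) {
    hf_stop(sprintf("feature length %d does not match model input size %d",
                    length(feats), ncol(model$hidden_weights)),
            "hf_shape_error")
  }
  x_std <- standardize_features(matrix(feats, nrow = 1),
                                model$feat_mean, model$feat_sd)
  scores <- drop(ann_forward(model, x_std))
  names(scores) <- model$label_order
  list(label = model$label_order[which.max(scores)], scores = scores)
}

#' Serialize an ANN model to JSON
#'
#' Weights are written row-major with their shapes, together with the label
#' order, standardization constants and training seed, so a model round-trips
#' exactly through [read_ann_json()].
#'
#' @param model an [ann_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ann_json <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  payload <- list(
    format = "handsfree-ann-1",
    n_features = ncol(model$hidden_weights),
    n_hidden = nrow(model$hidden_weights),
    n_outputs = nrow(model$output_weights),
    hidden_activation = model$hidden_activation,
    output_activation = model$output_activation,
    label_order = model$label_order,
    train_seed = model$train_seed,
    holdout_accuracy = model$holdout_accuracy,
    hidden_weights = as.numeric(t(model$hidden_weights)),  # row-major
    hidden_biases = model$hidden_biases,
    output_weights = as.numeric(t(model$output_weights)),
    output_biases = model$output_biases,
    feat_mean = model$feat_mean,
    feat_sd = model$feat_sd
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ANN model from JSON
#'
#' @param path file written by [write_ann_json()].
#' @return an `ann_model`.
#' @export
read_ann_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "handsfree-ann-1")) {
    hf_stop("not a handsfree ANN model file", "hf_validation_error")
  }
  ann_model(
    matrix(p$hidden_weights, p$n_hidden, p$n_features, byrow = TRUE),
    p$hidden_biases,
    matrix(p$output_weights, p$n_outputs, p$n_hidden, byrow = TRUE),
    p$output_biases,
    p$feat_mean, p$feat_sd,
    label_order = p$label_order,
    train_seed = p$train_seed,
    holdout_accuracy = p$holdout_accuracy %||% NA_real_
  )
}
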