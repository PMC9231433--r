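# Independent oracles and fixture builders shared across the suite.

# EMA oracle: the same recursion expressed through stats::filter's
# recursive engine (independent of the package's explicit loop).
oracle_ema <- function(x, w, y_init = 0) {
  as.numeric(stats::filter(w * x, 1 - w, method = "recursive",
                           init = y_init))
}

# DC-blocker oracle: first-difference input fed to a recursive pole.
oracle_dc_blocker <- function(x, alpha, x_init, y_init = 0) {
  d <- x - c(x_init, x[-length(x)])
  as.numeric(stats::filter(d, alpha, method = "recursive", init = y_init))
}

# Brute-force ANN forward pass: naively looped matrix evaluation, no
# vectorized algebra shared with the implementation.
oracle_classify <- function(model, window) {
  feats <- c(window$left_channel, window$right_channel)
  x <- (feats - model$feat_mean) / model$feat_sd
  n_hidden <- nrow(model$hidden_weights)
  h <- numeric(n_hidden)
  for (j in seq_len(n_hidden)) {
    s <- model$hidden_biases[j]
    for (k in seq_along(x)) s <- s + model$hidden_weights[j, k] * x[k]
    h[j] <- tanh(s)
  }
  n_out <- nrow(model$output_weights)
  z <- numeric(n_out)
  for (j in seq_len(n_out)) {
    s <- model$output_biases[j]
    for (k in seq_len(n_hidden)) s <- s + model$output_weights[j, k] * h[k]
    z[j] <- s
  }
  p <- exp(z - max(z))
  p <- p / sum(p)
  list(label = model$label_order[which.max(p)], scores = p)
}

# Small filtered, labelled dataset for classifier tests.
make_filtered_dataset <- function(n_per_class = 50, seed = 0) {
  raw <- gen_gesture_dataset(n_per_class,
                             gesture_template_params(seed = seed))
  lapply(raw, function(w) {
    condition_and_window(w$left_channel, w$right_channel,
                         label = w$label, window_len = w$window_len)
  })
}
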