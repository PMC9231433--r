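# Synthetic signal generators: scripted IMU traces, gesture waveforms,
# voice streams; seeding contracts and round trips.

test_that("a neutral script with zero noise gives pure gravity on z", {
  sc <- head_motion_script(data.frame(duration_s = 1, theta_x = 0,
                                      theta_y = 0), noise_sigma = 0)
  tr <- gen_accel_trace(sc)
  expect_equal(nrow(tr), 50)
  expect_equal(tr$ax, rep(0, 50))
  expect_equal(tr$ay, rep(0, 50))
  expect_equal(tr$az, rep(1, 50))
})

test_that("noiseless traces round-trip through the tilt estimator", {
  sc <- head_motion_script(
    data.frame(duration_s = c(0.5, 0.5, 0.5),
               theta_x = c(30, -45, 10), theta_y = c(0, 20, -60)),
    noise_sigma = 0)
  tr <- gen_accel_trace(sc)
  ang <- tilt_from_accel(tr)
  # after each 0.2 s ramp the pose holds the scripted target
  expect_equal(ang$theta_x[20], 30, tolerance = 1e-6)
  expect_equal(ang$theta_y[20], 0, tolerance = 1e-6)
  expect_equal(ang$theta_x[50], -45, tolerance = 1e-6)
  expect_equal(ang$theta_y[50], 20, tolerance = 1e-6)
  expect_equal(ang$theta_x[75], 10, tolerance = 1e-6)
  expect_equal(ang$theta_y[75], -60, tolerance = 1e-6)
  # static poses keep unit magnitude
  expect_equal(sqrt(tr$ax^2 + tr$ay^2 + tr$az^2), rep(1, nrow(tr)),
               tolerance = 1e-9)
})

test_that("accel generation is seeded and validates its script", {
  seg <- data.frame(duration_s = 1, theta_x = 20, theta_y = 5)
  a <- gen_accel_trace(head_motion_script(seg, noise_sigma = 0.05, seed = 9))
  b <- gen_accel_trace(head_motion_script(seg, noise_sigma = 0.05, seed = 9))
  c <- gen_accel_trace(head_motion_script(seg, noise_sigma = 0.05, seed = 10))
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(head_motion_script(data.frame(duration_s = 0, theta_x = 0,
                                             theta_y = 0)),
               class = "hf_range_error")
  expect_error(head_motion_script(data.frame(duration_s = 1, theta_x = 95,
                                             theta_y = 0)),
               class = "hf_range_error")
})

test_that("gesture templates encode the four classes as documented", {
  quiet <- gesture_template_params(noise_sigma = 0, drift_slope = 0)
  open <- gen_gesture_window("open", quiet)
  expect_equal(open$left_channel, rep(2, 75))
  expect_equal(open$right_channel, rep(2, 75))
  left <- gen_gesture_window("left", quiet)
  centre <- quiet$pulse_center
  expect_gt(left$left_channel[centre], quiet$baseline_dc)
  expect_lt(left$right_channel[centre], quiet$baseline_dc)
  close <- gen_gesture_window("close", quiet)
  expect_gt(close$left_channel[centre], quiet$baseline_dc)
  expect_gt(close$right_channel[centre], quiet$baseline_dc)
  expect_error(gen_gesture_window("wink", quiet),
               class = "hf_vocabulary_error")
  # seeding contract
  p <- gesture_template_params(seed = 3)
  expect_identical(window_to_features(gen_gesture_window("left", p)),
                   window_to_features(gen_gesture_window("left", p)))
})

test_that("the dataset is balanced, sized per protocol, and seeded", {
  ds <- gen_gesture_dataset(50, gesture_template_params(seed = 1))
  expect_length(ds, 200)
  labels <- vapply(ds, `[[`, character(1), "label")
  expect_equal(unname(table(labels)[gesture_labels()]),
               rep(50L, 4), ignore_attr = TRUE)
  expect_true(all(vapply(ds, function(w) w$window_len, numeric(1)) == 75))
  # distinct per-window sub-seeds: replicate windows differ within a class
  expect_false(identical(ds[[1]]$left_channel, ds[[2]]$left_channel))
  # different master seeds change noise, not labels
  ds2 <- gen_gesture_dataset(50, gesture_template_params(seed = 2))
  expect_identical(labels, vapply(ds2, `[[`, character(1), "label"))
  expect_false(identical(ds[[1]]$left_channel, ds2[[1]]$left_channel))
  tiny <- gen_gesture_dataset(1, gesture_template_params(seed = 1))
  expect_length(tiny, 4)
})

test_that("class-mean windows are separable well above the noise floor", {
  p <- gesture_template_params(seed = 7)
  ds <- gen_gesture_dataset(20, p)
  labels <- vapply(ds, `[[`, character(1), "label")
  feats <- t(vapply(ds, window_to_features, numeric(150)))
  means <- lapply(gesture_labels(), function(l) {
    colMeans(feats[labels == l, , drop = FALSE])
  })
  floor_dist <- 10 * p$noise_sigma * sqrt(p$window_len)
  pairs <- utils::combn(4, 2)
  dists <- vapply(seq_len(ncol(pairs)), function(k) {
    sqrt(sum((means[[pairs[1, k]]] - means[[pairs[2, k]]])^2))
  }, numeric(1))
  # mean pairwise separation comfortably above the noise floor, and every
  # individual pair at least near it
  expect_gt(mean(dists), floor_dist)
  expect_true(all(dists > 0.9 * floor_dist))
})

test_that("voice streams drop and confuse tokens as specified", {
  script <- data.frame(t = 0:4,
                       word = c("move", "right", "go", "left", "stop"))
  expect_identical(gen_voice_stream(script, 0, 0, seed = 1), script)
  expect_equal(nrow(gen_voice_stream(script, drop_prob = 1, seed = 1)), 0)
  # binomial survival count within 3 sigma of expectation
  big <- data.frame(t = seq_len(1000) - 1,
                    word = rep(c("move", "forward"), 500))
  kept <- nrow(gen_voice_stream(big, drop_prob = 0.3, seed = 5))
  expect_lt(abs(kept - 700), 3 * sqrt(1000 * 0.3 * 0.7))
  # confusion keeps tokens in vocabulary and is seeded
  conf <- gen_voice_stream(big, confusion_prob = 0.5, seed = 6)
  vocab <- unlist(voice_vocabulary())
  expect_true(all(conf$word %in% vocab))
  expect_identical(conf, gen_voice_stream(big, confusion_prob = 0.5,
                                          seed = 6))
  expect_error(gen_voice_stream(data.frame(t = 0, word = "banana")),
               class = "hf_vocabulary_error")
})
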