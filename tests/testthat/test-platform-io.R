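# Configuration loading, file-format round trips, and the command-line
# dispatcher.

test_that("configuration defaults, merging and validation behave", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(load_config(empty), default_config())
  expect_equal(load_config(NULL), default_config())

  pick <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("interface: voice", "head:", "  m: 4.0"), pick)
  cfg <- load_config(pick)
  expect_equal(cfg$interface, "voice")
  expect_equal(cfg$head$m, 4.0)
  expect_equal(cfg$head$n, 2.5)   # untouched defaults survive

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"interface": "eye", "eye": {"w": 0.5}}', js)
  expect_equal(load_config(js)$eye$w, 0.5)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("head:", "  slope: 1"), bad)
  expect_error(load_config(bad), regexp = "head.slope",
               class = "hf_config_error")

  two <- withr::local_tempfile(fileext = ".yaml")
  writeLines("interface: [head, voice]", two)
  expect_error(load_config(two), class = "hf_config_error")
  expect_error(load_config("/nonexistent.yaml"), class = "hf_config_error")
  pars <- config_params(load_config(NULL))
  expect_s3_class(pars$cubic_map, "cubic_map_params")
  expect_s3_class(pars$drive, "drive_params")
})

test_that("every trace format round-trips through its reader", {
  dir <- withr::local_tempdir()
  accel <- gen_accel_trace(head_motion_script(
    data.frame(duration_s = 0.5, theta_x = 10, theta_y = -5),
    noise_sigma = 0.01, seed = 1))
  write_accel_csv(accel, file.path(dir, "a.csv"))
  expect_equal(read_accel_csv(file.path(dir, "a.csv")), accel,
               tolerance = 1e-12)

  volts <- head_run(accel)[, c("t", "vx", "vy")]
  write_voltage_csv(volts, file.path(dir, "v.csv"))
  expect_equal(read_voltage_csv(file.path(dir, "v.csv")), volts,
               tolerance = 1e-12)

  w <- gen_gesture_window("right", gesture_template_params(seed = 2))
  write_gesture_window_csv(w, file.path(dir, "w.csv"))
  tr <- read_ir_trace_csv(file.path(dir, "w.csv"))
  expect_equal(tr$ch_left, w$left_channel, tolerance = 1e-12)

  ds <- gen_gesture_dataset(2, gesture_template_params(seed = 3))
  write_gesture_dataset(ds, file.path(dir, "ds"))
  back <- read_gesture_dataset(file.path(dir, "ds"))
  expect_length(back, 8)
  expect_equal(vapply(back, `[[`, character(1), "label"),
               vapply(ds, `[[`, character(1), "label"))
  expect_equal(back[[5]]$left_channel, ds[[5]]$left_channel,
               tolerance = 1e-12)

  tokens <- data.frame(t = c(0, 1.5, 3), word = c("move", "right", "stop"))
  write_tokens(tokens, file.path(dir, "tok.jsonl"))
  expect_equal(read_tokens(file.path(dir, "tok.jsonl")), tokens)
  writeLines(c("move", "right"), file.path(dir, "tok.txt"))
  plain <- read_tokens(file.path(dir, "tok.txt"))
  expect_equal(plain$word, c("move", "right"))
  expect_equal(plain$t, c(0, 1))

  course <- list(start = list(x = 1, y = 2, heading = 0.5), dt = 0.05,
                 obstacles = data.frame(x = 3, y = 0, radius = 0.4))
  write_course_json(course, file.path(dir, "c.json"))
  back_course <- read_course_json(file.path(dir, "c.json"))
  expect_equal(back_course$start$x, 1)
  expect_equal(back_course$dt, 0.05)
  expect_equal(back_course$obstacles$radius, 0.4)

  traj <- run_closed_loop(data.frame(vx = rep(3, 5), vy = rep(2.5, 5)))
  write_trajectory_csv(traj, file.path(dir, "t.csv"))
  expect_equal(read_trajectory_csv(file.path(dir, "t.csv"))$x, traj$x,
               tolerance = 1e-12)
})

test_that("fixtures are byte-identical for the same master seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  expect_equal(cli_dispatch(c("fixtures", "--out", d1, "--seed", "4"),
                            quiet = TRUE), 0L, ignore_attr = TRUE)
  expect_equal(cli_dispatch(c("fixtures", "--out", d2, "--seed", "4"),
                            quiet = TRUE), 0L, ignore_attr = TRUE)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
})

test_that("subcommands chain: fixtures -> head-run -> course -> wst-score", {
  dir <- withr::local_tempdir()
  fx <- file.path(dir, "fx")
  expect_equal(cli_dispatch(c("fixtures", "--out", fx, "--seed", "1"),
                            quiet = TRUE), 0L, ignore_attr = TRUE)
  volts <- file.path(dir, "volts.csv")
  expect_equal(cli_dispatch(c("head-run", "--input",
                              file.path(fx, "head_demo.csv"),
                              "--output", volts), quiet = TRUE), 0L,
               ignore_attr = TRUE)
  expect_true(file.exists(volts))
  traj <- file.path(dir, "traj.csv")
  expect_equal(cli_dispatch(c("course", "--voltages", volts,
                              "--course", file.path(fx, "course_demo.json"),
                              "--output", traj), quiet = TRUE), 0L,
               ignore_attr = TRUE)
  expect_gt(nrow(read_trajectory_csv(traj)), 1)
  out <- capture.output(
    status <- cli_dispatch(c("wst-score", "--input",
                             file.path(fx, "wst_demo.csv")), quiet = TRUE))
  expect_equal(status, 0L, ignore_attr = TRUE)
  expect_match(out, "100.0", all = FALSE)
})

test_that("eye subcommands train on a dataset directory and decode a trace", {
  dir <- withr::local_tempdir()
  ds <- gen_gesture_dataset(10, gesture_template_params(seed = 5))
  write_gesture_dataset(ds, file.path(dir, "ds"))
  model_path <- file.path(dir, "model.json")
  expect_equal(cli_dispatch(c("eye-train", "--data", file.path(dir, "ds"),
                              "--output", model_path, "--seed", "2"),
                            quiet = TRUE), 0L, ignore_attr = TRUE)
  expect_true(file.exists(model_path))
  # two "left" windows back to back decode to a move-left action
  w1 <- gen_gesture_window("left", gesture_template_params(seed = 31))
  w2 <- gen_gesture_window("left", gesture_template_params(seed = 32))
  trace <- data.frame(t = (0:149) / 50,
                      ch_left = c(w1$left_channel, w2$left_channel),
                      ch_right = c(w1$right_channel, w2$right_channel))
  write_ir_trace_csv(trace, file.path(dir, "trace.csv"))
  actions_path <- file.path(dir, "actions.json")
  expect_equal(cli_dispatch(c("eye-run", "--model", model_path,
                              "--input", file.path(dir, "trace.csv"),
                              "--output", actions_path), quiet = TRUE), 0L,
               ignore_attr = TRUE)
  res <- jsonlite::read_json(actions_path, simplifyVector = TRUE)
  expect_equal(res$window_labels, c("left", "left"))
  expect_equal(res$actions$action, "left")
})

test_that("voice-run writes the session timeline", {
  dir <- withr::local_tempdir()
  write_tokens(data.frame(t = c(0, 1, 4), word = c("go", "forward", "stop")),
               file.path(dir, "tok.jsonl"))
  out <- file.path(dir, "timeline.json")
  expect_equal(cli_dispatch(c("voice-run", "--input",
                              file.path(dir, "tok.jsonl"),
                              "--output", out), quiet = TRUE), 0L,
               ignore_attr = TRUE)
  tl <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(tl$direction, "forward")
  expect_equal(tl$t_on, 1)
  expect_equal(tl$t_off, 3)
})

test_that("usage errors exit nonzero without touching files", {
  expect_equal(suppressMessages(cli_dispatch("no-such-command",
                                             quiet = TRUE)), 2L,
               ignore_attr = TRUE)
  expect_equal(suppressMessages(cli_dispatch(c("wst-score", "--bogus", "x"),
                                             quiet = TRUE)), 2L,
               ignore_attr = TRUE)
  expect_equal(suppressMessages(cli_dispatch(c("wst-score"), quiet = TRUE)),
               2L, ignore_attr = TRUE)
})
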