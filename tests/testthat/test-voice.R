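# Voice-command grammar: token parsing, the attention/orientation state
# machine, and timed session playback.

test_that("token parsing normalizes case and whitespace and rejects strays", {
  expect_equal(parse_voice_token("stop"),
               list(word = "stop", category = "attention"))
  expect_equal(parse_voice_token("RUN "),
               list(word = "run", category = "attention"))
  expect_equal(parse_voice_token("  Left"),
               list(word = "left", category = "orientation"))
  expect_error(parse_voice_token("banana"), class = "hf_vocabulary_error")
})

test_that("all 16 attention-orientation pairs follow the command table", {
  modes <- list(move = list(mode = "timed", duration_s = 1),
                go   = list(mode = "timed", duration_s = 2),
                run  = list(mode = "continuous", duration_s = NA_real_))
  for (att in c("stop", "move", "go", "run")) {
    for (ori in c("forward", "backward", "left", "right")) {
      st <- grammar_step(grammar_state(), att)$state
      res <- grammar_step(st, ori)
      if (att == "stop") {
        # stop does not arm a motion mode: the orientation is ignored
        expect_null(res$command, info = paste(att, ori))
      } else {
        expect_equal(res$command$direction, ori, info = paste(att, ori))
        expect_equal(res$command$mode, modes[[att]]$mode,
                     info = paste(att, ori))
        expect_equal(res$command$duration_s, modes[[att]]$duration_s,
                     info = paste(att, ori))
      }
    }
  }
})

test_that("orientation words without a pending attention are ignored", {
  for (ori in c("forward", "backward", "left", "right")) {
    res <- grammar_step(grammar_state(), ori)
    expect_null(res$command, info = ori)
    expect_null(res$state$pending_attention, info = ori)
  }
})

test_that("a second attention word replaces the pending one", {
  st <- grammar_step(grammar_state(), "move")$state
  st <- grammar_step(st, "run")$state
  res <- grammar_step(st, "forward")
  expect_equal(res$command$mode, "continuous")
})

test_that("stop halts everything and emits the halt command", {
  st <- grammar_step(grammar_state(), "run")$state
  st <- grammar_step(st, "forward")$state
  expect_false(st$halted)
  res <- grammar_step(st, "stop")
  expect_equal(res$command$mode, "halt")
  expect_true(res$state$halted)
  expect_null(res$state$active_command)
  expect_null(res$state$pending_attention)
})

test_that("session playback times commands per their attention word", {
  # move + right: active on [1, 2)
  tl <- run_voice_session(data.frame(t = c(0, 1),
                                     word = c("move", "right")))
  expect_equal(nrow(tl), 1)
  expect_equal(tl$direction, "right")
  expect_equal(tl$t_on, 1)
  expect_equal(tl$t_off, 2)
  # run + forward runs until the stop timestamp
  tl <- run_voice_session(data.frame(t = c(0, 1, 5),
                                     word = c("run", "forward", "stop")))
  expect_equal(tl$mode, "continuous")
  expect_equal(tl$t_on, 1)
  expect_equal(tl$t_off, 5)
  # empty stream: empty timeline
  expect_equal(nrow(run_voice_session(
    data.frame(t = numeric(0), word = character(0)))), 0)
})

test_that("new commands supersede the active one; timed ones expire", {
  # continuous forward superseded by a timed left turn
  tl <- run_voice_session(data.frame(
    t = c(0, 1, 3, 4),
    word = c("run", "forward", "move", "left")))
  expect_equal(tl$direction, c("forward", "left"))
  expect_equal(tl$t_off, c(4, 5))
  # a timed command expires on its own before the next one starts
  tl <- run_voice_session(data.frame(
    t = c(0, 1, 10, 11),
    word = c("go", "right", "go", "left")))
  expect_equal(tl$t_off, c(3, 13))
})

test_that("after any stream ending in stop, nothing is active", {
  set.seed(31)
  vocab <- c("stop", "move", "go", "run",
             "forward", "backward", "left", "right")
  for (i in 1:20) {
    n <- sample(3:12, 1)
    words <- c(sample(vocab, n, replace = TRUE), "stop")
    tl <- run_voice_session(data.frame(t = seq_along(words), word = words))
    if (nrow(tl) > 0) {
      expect_true(all(is.finite(tl$t_off)))
      expect_true(all(tl$t_off <= length(words)))
    }
  }
})

test_that("sessions are deterministic and reject unordered streams", {
  tok <- data.frame(t = c(0, 1, 2, 3),
                    word = c("go", "forward", "move", "left"))
  expect_identical(run_voice_session(tok), run_voice_session(tok))
  expect_error(run_voice_session(data.frame(t = c(1, 0),
                                            word = c("move", "left"))),
               class = "hf_order_error")
})
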