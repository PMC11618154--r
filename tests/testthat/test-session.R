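# a stream fixating `pos` long enough to satisfy the collection window
collection_stream <- function(pos, n = 40, t0 = 0, valid_left = TRUE,
                              valid_right = TRUE) {
  dt <- 1000 / 60
  gaze_stream(t_ms = t0 + seq_len(n) * dt,
              left_x = pos[1], left_y = pos[2],
              left_valid = as.numeric(valid_left),
              right_x = pos[1], right_y = pos[2],
              right_valid = as.numeric(valid_right))
}

collect_all <- function(state, ids, offset = c(0.02, -0.01)) {
  tg <- current <- state$cal_targets
  for (id in ids) {
    pos <- c(tg$x[tg$id == id], tg$y[tg$id == id]) + offset
    res <- collect_point_data(state, id, collection_stream(pos))
    state <- res$state
  }
  state
}

test_that("snapshot, discard-all and reload restore the calibration exactly", {
  g <- test_geom()
  state <- new_session(g)
  state <- collect_all(state, 1:5)
  res <- dispatch(state, command("compute_calibration"))
  state <- res$state
  expect_identical(event_kinds(res$events), "calibration_computed")
  active <- state$active

  state <- dispatch(state, command("take_snapshot", label = "A"))$state
  state <- dispatch(state, command("discard_all"))$state
  expect_identical(length(state$cal_data$points), 0L)
  expect_true(all(state$cal_targets$status == "not_collected"))

  state <- dispatch(state, command("load_snapshot", label = "A"))$state
  expect_identical(state$active$mappings, active$mappings)
  expect_identical(state$active$points_used, active$points_used)
})

test_that("computing with no collected data emits calibration_failed", {
  state <- new_session(test_geom())
  res <- dispatch(state, command("compute_calibration"))
  expect_identical(event_kinds(res$events), "calibration_failed")
  expect_identical(res$state$status_text, "calibration failed")
  # the active calibration stays at the default
  expect_true(res$state$active$default)
})

test_that("validation-mode collection goes into validation data", {
  state <- new_session(test_geom())
  state <- dispatch(state, command("switch_mode", mode = "validation"))$state
  expect_identical(state$mode, "validation")
  tgt <- c(state$val_targets$x[1], state$val_targets$y[1])
  res <- collect_point_data(state, 1, collection_stream(tgt))
  expect_true("collection_succeeded" %in% event_kinds(res$events))
  expect_identical(length(res$state$cal_data$points), 0L)
  expect_identical(names(res$state$val_data), "1")
  expect_identical(res$state$val_targets$status[1], "collected")
})

test_that("per-eye validity rules: a blinking eye fails, the other succeeds", {
  state <- new_session(test_geom())
  s <- collection_stream(c(0.1, 0.1), valid_left = FALSE)
  res <- collect_point_data(state, 1, s)
  ev <- res$events[[which(event_kinds(res$events) == "collection_succeeded")]]
  expect_identical(ev$n_left, 0L)
  expect_gte(ev$n_right, 10)
  d <- res$state$cal_data$points[["1"]]
  expect_identical(nrow(d$left), 0L)
  expect_gte(nrow(d$right), 10)

  # neither eye valid: collection fails and the point resets
  res2 <- collect_point_data(state, 2, collection_stream(
    c(0.9, 0.1), valid_left = FALSE, valid_right = FALSE))
  expect_true("collection_failed" %in% event_kinds(res2$events))
  expect_identical(res2$state$cal_targets$status[2], "not_collected")
})

test_that("invalid commands are rejected with events, not errors", {
  state <- new_session(test_geom())
  expect_identical(event_kinds(dispatch(state, command("enqueue_point",
                                                       id = 99))$events),
                   "command_rejected")
  expect_identical(event_kinds(dispatch(state, command("load_snapshot",
                                                       label = "nope"))$events),
                   "command_rejected")
  res <- dispatch(state, command("start_collection", id = 1), t = 0)
  res2 <- dispatch(res$state, command("start_collection", id = 2), t = 10)
  expect_identical(event_kinds(res2$events), "command_rejected")
})

test_that("enqueued points form a FIFO queue behind the active point", {
  state <- new_session(test_geom())
  state <- dispatch(state, command("enqueue_point", id = 3))$state
  expect_identical(state$cal_targets$status[3], "showing")  # promoted
  state <- dispatch(state, command("enqueue_point", id = 1))$state
  state <- dispatch(state, command("enqueue_point", id = 2))$state
  expect_identical(state$queue, c(1L, 2L))
  expect_identical(state$cal_targets$status[1:2], rep("enqueued", 2))
  # discarding the showing point promotes the queue head
  state <- dispatch(state, command("discard_point", id = 3))$state
  expect_identical(state$cal_targets$status[1], "showing")
  expect_identical(state$queue, 2L)
})

test_that("the run loop with a null controller only accumulates gaze", {
  g <- test_geom()
  state <- new_session(g)
  out <- run_loop(state, null_controller(), fix_source(c(0.5, 0.5)), 100)
  expect_identical(nrow(out$gaze_log), 100L)
  expect_identical(out$state, state)
  expect_identical(length(out$events), 0L)
})

test_that("a scripted controller is equivalent to direct dispatch", {
  g <- test_geom()
  script <- list(
    list(t = 50, cmd = command("set_auto", on = TRUE)),
    list(t = 120, cmd = command("enqueue_point", id = 2)),
    list(t = 200, cmd = command("set_eyes", eyes = "left")),
    list(t = 300, cmd = command("switch_mode", mode = "validation")))
  out <- run_loop(new_session(g), scripted_controller(script),
                  fix_source(c(0.5, 0.5)), 30)
  direct <- new_session(g)
  for (s in script) direct <- dispatch(direct, s$cmd, s$t)$state
  for (f in c("mode", "auto", "eyes", "queue")) {
    expect_identical(out$state[[f]], direct[[f]])
  }
  expect_identical(out$state$cal_targets, direct$cal_targets)
  # auto_toggled echoed back to the controller
  expect_true("auto_toggled" %in% event_kinds(out$events))
})

test_that("a controller exception halts the loop cleanly", {
  bad <- null_controller()
  bad$tick <- function(env, view) stop("controller exploded")
  out <- run_loop(new_session(test_geom()), bad, fix_source(c(0.5, 0.5)), 50)
  expect_match(out$halted, "controller exploded")
  expect_identical(event_kinds(out$events), "controller_error")
})

test_that("target statuses follow the lifecycle ordering in a full session", {
  g <- test_geom()
  m <- participant_model(latency_median_ms = 50,
                         fixation_noise_sigma_deg = 0.2,
                         blink_rate_per_min = 2, lapse_rate_per_s = 0,
                         seed = 12)
  rank <- c(not_collected = 0, enqueued = 1, showing = 2, collecting = 3,
            collected = 4)
  ctrl <- nhp_controller()
  seen <- new.env(); seen$bad <- 0L; seen$multi <- 0L
  base_tick <- ctrl$tick
  prev <- new.env(); prev$cal <- NULL; prev$val <- NULL
  ctrl$tick <- function(env, view) {
    for (mode in c("cal", "val")) {
      tg <- if (mode == "cal") view$state$cal_targets else view$state$val_targets
      if (sum(tg$status %in% c("showing", "collecting")) > 1)
        seen$multi <- seen$multi + 1L
      if (!is.null(prev[[mode]])) {
        # transitions move forward along the lifecycle or reset to start
        step <- rank[tg$status] - rank[prev[[mode]]]
        if (any(step < 0 & rank[tg$status] != 0)) seen$bad <- seen$bad + 1L
      }
      prev[[mode]] <- tg$status
    }
    base_tick(env, view)
  }
  out <- closed_loop(m, g, controller = ctrl, skip_attention = TRUE,
                     max_duration_ms = 60000)
  expect_true(out$state$finished)
  expect_identical(seen$multi, 0L)
  expect_identical(seen$bad, 0L)
})

test_that("collection windows meet the sample-count bound at 60 Hz", {
  # 600 ms at 60 Hz yields >= 10 valid samples for a fixating participant
  state <- new_session(test_geom())
  out <- run_loop(state, scripted_controller(list(
    list(t = 20, cmd = command("start_collection", id = 3)))),
    fix_source(c(0.52, 0.48)), 60)
  ev <- out$events[event_kinds(out$events) == "collection_succeeded"]
  expect_identical(length(ev), 1L)
  expect_gte(ev[[1]]$n_left, 10)
  d <- out$state$cal_data$points[["3"]]
  expect_gte(nrow(d$left), 30)   # most of the 36-sample window
})

test_that("collection fails when the participant looks off-screen", {
  state <- new_session(test_geom())
  out <- run_loop(state, scripted_controller(list(
    list(t = 20, cmd = command("start_collection", id = 1)))),
    fix_source(c(1.5, 1.5), valid = FALSE), 60)
  expect_true("collection_failed" %in% event_kinds(out$events))
  expect_identical(out$state$cal_targets$status[1], "not_collected")
})
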