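# run the NHP controller in calibration phase (attention skipped) against a
# custom gaze source; returns the run_loop output plus the controller
run_nhp <- function(source, ticks = 400, g = test_geom(), cfg = nhp_config(),
                    scfg = session_config(), skip = TRUE) {
  ss <- nhp_session(g, cfg, scfg)
  out <- run_loop(ss$state, ss$ctrl, source, ticks,
                  operator = nhp_operator(skip_attention = skip))
  c(out, list(ctrl = ss$ctrl))
}

test_that("dwell of 500 ms at the video center triggers collection", {
  out <- run_nhp(track_source(), ticks = 120)
  dl <- out$ctrl$env$dwell_log
  expect_gte(length(dl), 1)
  elapsed <- dl[[1]]$trigger - dl[[1]]$onset
  expect_equal(elapsed, 500, tolerance = 1000 / 60 / 500)  # +- one ISI
  cmd_t <- vapply(out$commands, `[[`, numeric(1), "t")
  first_collect <- min(cmd_t[command_verbs(out$commands) == "start_collection"])
  expect_equal(first_collect, dl[[1]]$trigger)
})

test_that("the dwell criterion is one third of the vertical screen size", {
  g <- test_geom()
  # calibration point 1 sits at (0.3, 0.5); hold gaze at fixed vertical
  # offsets from the video center
  at_frac <- function(f) fix_source(c(0.3, 0.5 + f))
  out_far <- run_nhp(at_frac(0.40), ticks = 150)   # 2.5 s, no trigger
  expect_false("start_collection" %in% command_verbs(out_far$commands))
  out_near <- run_nhp(at_frac(0.30), ticks = 150)
  expect_true("start_collection" %in% command_verbs(out_near$commands))
})

test_that("the dwell timer resets on non-qualifying gaze", {
  # alternate 400 ms near the center, 400 ms far away: the filtered gaze
  # leaves the criterion region long enough that 500 ms of continuous
  # qualifying dwell is never reached
  flicker <- function(t, stim) {
    p <- if ((t %% 800) < 400) c(0.3, 0.5) else c(0.3, 0.95)
    list(left_x = p[1], left_y = p[2], left_valid = TRUE,
         right_x = p[1], right_y = p[2], right_valid = TRUE)
  }
  out <- run_nhp(flicker, ticks = 300)
  expect_false("start_collection" %in% command_verbs(out$commands))
})

test_that("a brief invalid sample is tolerated inside a dwell", {
  # one invalid sample every 20 (within the grace of 1); dwell still triggers
  blip <- function(t, stim) {
    ok <- (round(t / (1000 / 60)) %% 20) != 0
    list(left_x = 0.3, left_y = 0.5, left_valid = ok,
         right_x = 0.3, right_y = 0.5, right_valid = ok)
  }
  out <- run_nhp(blip, ticks = 200)
  expect_true("start_collection" %in% command_verbs(out$commands))
})

test_that("attention phase shrinks the video monotonically to 300 px", {
  g <- test_geom()
  cfg <- nhp_config(attention_duration_ms = 2000, shrink_duration_ms = 1500)
  out <- run_nhp(track_source(), ticks = 400, cfg = cfg, skip = FALSE)
  sizes <- t(vapply(Filter(Negate(is.null), out$draw_log),
                    function(r) c(r$w_px, r$h_px), numeric(2)))
  expect_true(all(diff(sizes[, 1]) <= 1e-9))
  expect_true(all(diff(sizes[, 2]) <= 1e-9))
  expect_gte(min(sizes[, 1]), 300)
  expect_gte(min(sizes[, 2]), 300)
  expect_equal(unname(sizes[nrow(sizes), ]), c(300, 300))
  expect_false(out$ctrl$env$phase == "attention")
})

test_that("shrinking pauses while the video is not being watched", {
  g <- test_geom()
  cfg <- nhp_config(attention_duration_ms = 1000, shrink_duration_ms = 1000)
  # watches long enough to finish attention, then looks away
  away_after <- function(cutoff) function(t, stim) {
    p <- if (t < cutoff) (if (is.null(stim)) c(0.5, 0.5) else stim$center)
         else c(1.5, 1.5)
    list(left_x = p[1], left_y = p[2], left_valid = TRUE,
         right_x = p[1], right_y = p[2], right_valid = TRUE)
  }
  out <- run_nhp(away_after(1300), ticks = 240, cfg = cfg, skip = FALSE)
  sizes <- vapply(Filter(Negate(is.null), out$draw_log), `[[`, numeric(1),
                  "w_px")
  # shrink started but froze when gaze left; never reached 300
  expect_lt(min(sizes), 1920)
  expect_gt(min(sizes), 300)
  expect_identical(out$ctrl$env$phase, "attention")
})

test_that("calibration failure discards all data and restarts at point 1", {
  ctrl <- nhp_controller()
  ctrl$env$phase <- "calibration"
  ctrl$env$cal_idx <- 2L
  ctrl$env$awaiting <- TRUE
  state <- nhp_session()$state
  view <- list(t = 1000, dt = 1000 / 60, gaze = NULL, state = state)
  ctrl$receive_update(ctrl$env, list(kind = "calibration_failed", t = 1000),
                      view)
  expect_identical(ctrl$env$cal_idx, 1L)
  cmds <- ctrl$tick(ctrl$env, c(view, list(gaze = NULL)))
  expect_identical(cmds[[1]]$verb, "discard_all")
  # after the reset, renewed dwell at point 1 triggers its collection
  state$auto <- TRUE
  view2 <- list(t = 2000, dt = 1000 / 60, gaze = c(0.3, 0.5), state = state)
  for (k in 0:40) {
    v <- view2; v$t <- 2000 + k * 1000 / 60
    cmds <- ctrl$tick(ctrl$env, v)
    if (length(cmds)) break
  }
  expect_identical(cmds[[1]]$verb, "start_collection")
  expect_identical(cmds[[1]]$id, 1L)
})

test_that("a full closed loop emits discard_all then point-1 recollection on failure", {
  g <- test_geom()
  m <- participant_model(latency_median_ms = 0,
                         fixation_noise_sigma_deg = 0.3,
                         blink_rate_per_min = 0, lapse_rate_per_s = 0,
                         seed = 5)
  # an impossible residual bound forces every calibration attempt to fail
  out <- closed_loop(m, g, controller = nhp_controller(nhp_config(max_retries = 1)),
                     config = session_config(max_residual_rms = 1e-9),
                     skip_attention = TRUE, max_duration_ms = 20000)
  verbs <- command_verbs(out$result$commands)
  times <- vapply(out$result$commands, `[[`, numeric(1), "t")
  fail_t <- vapply(Filter(function(e) e$kind == "calibration_failed",
                          out$result$events), `[[`, numeric(1), "t")[1]
  after <- which(times > fail_t)
  expect_identical(verbs[after][1], "discard_all")
  recollect <- after[verbs[after] == "start_collection"]
  expect_gte(length(recollect), 1)
  expect_identical(out$result$commands[[recollect[1]]]$cmd$id, 1L)
})

test_that("reward is active exactly when gaze is inside the video", {
  g <- test_geom()
  sink <- reward_recorder()
  rect <- stim_rect(c(0.5, 0.5), 300, 300)
  expect_true(reward_gate(c(0.5, 0.5), rect, g, sink, 1))
  expect_true(reward_gate(c(0.5 + 149 / 1920, 0.5), rect, g, sink, 2))
  expect_false(reward_gate(c(0.5, 0.8), rect, g, sink, 3))   # on-screen, off video
  expect_false(reward_gate(NULL, rect, g, sink, 4))
  expect_false(reward_gate(c(NA, NA), rect, g, sink, 5))
  expect_identical(sink$a_log, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  sink$pulse(6)
  expect_identical(sink$pulses, 6)
})

test_that("reward is never active while gaze is outside the video (full log)", {
  g <- test_geom()
  m <- participant_model(latency_median_ms = 100,
                         fixation_noise_sigma_deg = 0.4,
                         blink_rate_per_min = 10, lapse_rate_per_s = 0.1,
                         lapse_duration_ms = 500, seed = 31)
  sink <- reward_recorder()
  ctrl <- nhp_controller(sink = sink)
  out <- closed_loop(m, g, controller = ctrl, skip_attention = TRUE,
                     max_duration_ms = 40000)
  gl <- out$result$gaze_log
  active_t <- sink$t_log[sink$a_log]
  expect_gt(length(active_t), 0)
  # recompute the filtered gaze at each reward-active tick and check it
  # falls inside the rectangle drawn at that tick (skip transition ticks
  # where the stimulus just moved)
  draws <- out$result$draw_log
  dt <- 1000 / 60
  checked <- 0L
  for (t in active_t) {
    i <- as.integer(round(t / dt))
    if (i < 3 || i > length(draws)) next
    r_now <- draws[[i]]; r_prev <- draws[[i - 1]]
    if (is.null(r_now) || is.null(r_prev) ||
        any(r_now$center != r_prev$center) || r_now$w_px != r_prev$w_px) next
    w <- gl[gl$t_ms > t - 200 & gl$t_ms <= t, , drop = FALSE]
    f <- moving_average_filter(w, 200)
    expect_true(in_stim_rect(f$pos, r_now, g))
    checked <- checked + 1L
  }
  expect_gt(checked, 10)
})

test_that("validation triggers only with gaze on the video itself", {
  g <- test_geom()
  # 0.3 of screen height away qualifies in calibration but is outside the
  # 300 px video, so it must NOT trigger in validation
  ss <- nhp_session(g)
  ctrl <- ss$ctrl
  ctrl$env$phase <- "validation"
  ctrl$env$calibrated <- TRUE
  ctrl$env$video_size <- c(300, 300)
  state <- ss$state
  state$mode <- "validation"
  vt <- c(state$val_targets$x[1], state$val_targets$y[1])
  off_video <- run_loop(state, ctrl, fix_source(vt + c(0, 0.3)), 150,
                        operator = function(t, s, e)
                          if (t < 20) list(command("set_auto", on = TRUE))
                          else list())
  expect_false("start_collection" %in% command_verbs(off_video$commands))

  ss2 <- nhp_session(g)
  ctrl2 <- ss2$ctrl
  ctrl2$env$phase <- "validation"; ctrl2$env$calibrated <- TRUE
  ctrl2$env$video_size <- c(300, 300)
  st2 <- ss2$state; st2$mode <- "validation"
  on_video <- run_loop(st2, ctrl2, fix_source(vt + c(0, 100 / 1080)), 150,
                       operator = function(t, s, e)
                         if (t < 20) list(command("set_auto", on = TRUE))
                         else list())
  expect_true("start_collection" %in% command_verbs(on_video$commands))
})

test_that("arc AOIs are annular 120-degree sectors with closed boundaries", {
  g <- test_geom()
  tg <- adult_demo_targets(0.3)
  target <- c(tg$x[2], tg$y[2])   # straight above center (angle -90 deg)
  expect_true(in_arc_aoi(target, target, g))
  # radial bounds: 0.5x and 1.5x eccentricity, boundary inclusive
  c_ <- c(0.5, 0.5)
  expect_true(in_arc_aoi(c_ + (target - c_) * 0.5, target, g))
  expect_true(in_arc_aoi(c_ + (target - c_) * 1.5, target, g))
  expect_false(in_arc_aoi(c_ + (target - c_) * 0.49, target, g))
  expect_false(in_arc_aoi(c_ + (target - c_) * 1.51, target, g))
  # the wedge does not contain directions more than 60 degrees away
  other <- c(tg$x[3], tg$y[3])
  expect_false(in_arc_aoi(other, target, g))
  expect_false(in_arc_aoi(c_, target, g))
  expect_false(in_arc_aoi(NULL, target, g))
})

test_that("the adult demo computes three calibrations across its stages", {
  g <- test_geom()
  ctrl <- adult_demo_controller()
  tg <- adult_demo_targets()
  state <- new_session(g, cal_targets = tg)
  # gaze visits the center, then each remaining target of each stage
  env <- new.env(); env$ctrl <- ctrl
  source <- function(t, stim) {
    ids <- setdiff(switch(as.character(ctrl$env$stage),
                          "1" = 1L, "2" = 2:4, "3" = 5:7),
                   ctrl$env$collected)
    id <- if (length(ids)) ids[1] else 1L
    p <- c(tg$x[tg$id == id], tg$y[tg$id == id])
    list(left_x = p[1], left_y = p[2], left_valid = TRUE,
         right_x = p[1], right_y = p[2], right_valid = TRUE)
  }
  out <- run_loop(state, ctrl, source, 800,
                  operator = function(t, s, e)
                    if (t < 20) list(command("set_auto", on = TRUE))
                    else list())
  expect_true(out$state$finished)
  expect_identical(ctrl$env$n_calibrations, 3L)
  expect_identical(sum(event_kinds(out$events) == "calibration_computed"), 3L)
  expect_identical(sort(ctrl$env$collected), 1:7)
})

test_that("gaze in the gap between AOIs never triggers demo collection", {
  g <- test_geom()
  ctrl <- adult_demo_controller()
  ctrl$env$stage <- 2L
  state <- new_session(g, cal_targets = adult_demo_targets())
  # ring radius but exactly between two wedges is still inside one (closed
  # cover); use the center gap instead, inside no annulus
  out <- run_loop(state, ctrl, fix_source(c(0.5, 0.5)), 150,
                  operator = function(t, s, e)
                    if (t < 20) list(command("set_auto", on = TRUE))
                    else list())
  expect_false("start_collection" %in% command_verbs(out$commands))
})
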