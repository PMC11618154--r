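#' Stimulus rectangle helpers
#'
#' A stimulus (the calibration video) is modeled as an axis-aligned
#' rectangle: a normalized center plus a pixel size, with a media id in
#' place of actual video decoding. \code{in_stim_rect} tests whether a
#' normalized gaze position falls inside the rectangle (boundary
#' inclusive).
#'
#' @param center normalized center position.
#' @param w_px,h_px rectangle size in pixels.
#' @param media media identifier (free-form).
#' @return a list describing the rectangle.
#' @export
stim_rect <- function(center, w_px, h_px, media = "video") {
  list(center = as.numeric(center), w_px = w_px, h_px = h_px, media = media)
}

#' @rdname stim_rect
#' @param gaze normalized gaze position (or NULL).
#' @param rect a stimulus rectangle.
#' @param g a \code{\link{screen_geometry}}.
#' @export
in_stim_rect <- function(gaze, rect, g) {
  if (is.null(gaze) || any(!is.finite(gaze))) return(FALSE)
  gp <- normalized_to_px(gaze, g)
  cp <- normalized_to_px(rect$center, g)
  abs(gp[1] - cp[1]) <= rect$w_px / 2 && abs(gp[2] - cp[2]) <= rect$h_px / 2
}

dist_px <- function(a, b, g) {
  pa <- normalized_to_px(a, g); pb <- normalized_to_px(b, g)
  sqrt(sum((pa - pb)^2))
}

#' Reward sink
#'
#' Abstract interface to a reward dispenser (in the physical setup, a
#' juice pump). The recorder implementation used in tests and
#' simulations is side-effect-free: it only logs activation periods and
#' manual pulses.
#'
#' @return an environment with fields \code{active}, \code{log} (data
#'   frame of t/active transitions), \code{pulses} (manual pulse times)
#'   and functions \code{set_active(on, t)}, \code{pulse(t)}.
#' @export
reward_recorder <- function() {
  env <- new.env(parent = emptyenv())
  env$active <- FALSE
  env$t_log <- numeric(0)
  env$a_log <- logical(0)
  env$pulses <- numeric(0)
  env$set_active <- function(on, t) {
    env$t_log <- c(env$t_log, t)
    env$a_log <- c(env$a_log, isTRUE(on))
    env$active <- isTRUE(on)
  }
  env$pulse <- function(t) env$pulses <- c(env$pulses, t)
  env
}

#' Gaze-contingent reward gating
#'
#' The reward is active exactly when gaze is present and inside the
#' video rectangle: looking at on-screen locations other than the video
#' earns nothing, as does absent gaze. Manual pulses (keyboard "j") go
#' through \code{sink$pulse} unconditionally.
#'
#' @param gaze filtered normalized gaze position, or NULL when absent.
#' @param rect the current video rectangle (\code{\link{stim_rect}}).
#' @param g a \code{\link{screen_geometry}}.
#' @param sink a reward sink (\code{\link{reward_recorder}}).
#' @param t current time (ms), recorded in the sink log.
#' @return logical: whether the reward is active.
#' @export
reward_gate <- function(gaze, rect, g, sink, t = NA_real_) {
  active <- !is.null(rect) && in_stim_rect(gaze, rect, g)
  sink$set_active(active, t)
  active
}

#' Null controller
#'
#' Implements the four-method controller contract with no behavior;
#' useful as a baseline and in tests.
#' @return a controller object.
#' @export
null_controller <- function() {
  env <- new.env(parent = emptyenv())
  list(env = env,
       tick = function(env, view) list(),
       receive_update = function(env, event, view) invisible(NULL),
       get_status_text = function(env) "",
       draw = function(env, view) NULL)
}

#' Scripted controller
#'
#' Replays a fixed list of timed commands; equivalent to dispatching the
#' same list directly. Used to test the loop/dispatch equivalence and to
#' drive deterministic scenarios.
#'
#' @param script a list of \code{list(t =, cmd = command(...))} entries;
#'   each command is issued at the first tick whose time is >= t.
#' @return a controller object.
#' @export
scripted_controller <- function(script) {
  env <- new.env(parent = emptyenv())
  env$script <- script
  env$events <- list()
  list(env = env,
       tick = function(env, view) {
         due <- vapply(env$script, function(s) s$t <= view$t, logical(1))
         out <- lapply(env$script[due], `[[`, "cmd")
         env$script <- env$script[!due]
         out
       },
       receive_update = function(env, event, view) {
         env$events[[length(env$events) + 1L]] <- event
       },
       get_status_text = function(env) "",
       draw = function(env, view) NULL)
}

# ---- NHP automated procedure ----------------------------------------------

#' Configuration of the automated nonhuman-primate procedure
#'
#' Defaults follow the procedure's standard settings: roughly half a
#' minute of accumulated attention to full-screen videos, which then
#' shrink (while being watched) to the 300 x 300 px calibration video;
#' two calibration locations; data collection triggered once the
#' binocular-average gaze stays within one third of the vertical screen
#' size of the video center for at least 500 ms; validation over eight
#' points in a 2 x 4 grid, where gaze must be on the video itself.
#' Everything is overridable.
#'
#' @param ... overrides for \code{attention_duration_ms} (30000),
#'   \code{shrink_duration_ms} (10000), \code{video_cal_size_px}
#'   (c(300, 300)), \code{cal_points} (layout data frame, 2 locations),
#'   \code{dwell_distance_frac} (1/3 of screen height),
#'   \code{dwell_duration_ms} (500), \code{val_rows} (2), \code{val_cols}
#'   (4), \code{blink_grace_samples} (1), \code{max_retries} (Inf).
#' @return a named list.
#' @export
nhp_config <- function(...) {
  cfg <- list(attention_duration_ms = 30000,
              shrink_duration_ms = 10000,
              video_cal_size_px = c(300, 300),
              cal_points = data.frame(id = 1:2, x = c(0.3, 0.7), y = 0.5),
              dwell_distance_frac = 1 / 3,
              dwell_duration_ms = 500,
              val_rows = 2, val_cols = 4,
              blink_grace_samples = 1,
              max_retries = Inf)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown NHP config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$dwell_duration_ms > 0)
  cfg
}

#' Validation grid layout for the NHP procedure
#'
#' @param rows,cols grid dimensions (default 2 x 4 = eight points).
#' @return a target layout spread across the monitor.
#' @export
nhp_val_targets <- function(rows = 2, cols = 4) {
  gx <- (seq_len(cols) - 0.5) / cols
  gy <- (seq_len(rows) - 0.5) / rows
  target_layout(data.frame(
    id = seq_len(rows * cols),
    x = rep(gx, times = rows),
    y = rep(gy, each = cols)))
}

#' Automated calibration controller for nonhuman primates
#'
#' Implements the three-phase gaze-contingent procedure for participants
#' who cannot follow instructions. Phase 1 (attention): a full-screen
#' video plays; time with gaze on the screen accumulates, and once
#' enough attention has been gathered the video shrinks linearly (only
#' while being watched) down to the calibration video size, after which
#' phase 2 starts. Phase 2 (calibration): the video plays at each
#' calibration location in turn; once the binocular-average filtered
#' gaze has stayed within the criterion distance of the video center for
#' the dwell duration, data collection for that point is triggered.
#' After all points are collected a calibration is computed; on failure
#' all data is discarded and collection restarts from the first point;
#' on success the controller switches auto mode off and waits for
#' operator confirmation. Phase 3 (validation): after the operator
#' switches to validation mode and re-activates auto, the same dwell
#' logic runs over the validation grid, but gaze must be on the video
#' rectangle itself. Throughout, the reward is gated on gaze being
#' inside the video rectangle. The attention phase can be skipped with
#' the \code{skip_phase} command (keyboard "x"); \code{manual_reward}
#' ("j") pulses the sink unconditionally. The controller's methods run
#' every tick, but its procedure only acts while auto mode is on; reward
#' gating runs regardless.
#'
#' @param config an \code{\link{nhp_config}} list.
#' @param sink a reward sink (\code{\link{reward_recorder}}).
#' @return a controller object for \code{\link{run_loop}}.
#' @export
nhp_controller <- function(config = nhp_config(), sink = reward_recorder()) {
  env <- new.env(parent = emptyenv())
  env$cfg <- config
  env$sink <- sink
  env$phase <- "attention"
  env$watched_ms <- 0
  env$video_size <- NULL   # set from geometry on first tick
  env$cal_idx <- 1L
  env$val_idx <- 1L
  env$dwell_start <- NA_real_
  env$invalid_run <- 0L
  env$awaiting <- FALSE
  env$pending <- list()
  env$retries <- 0L
  env$calibrated <- FALSE
  env$status <- "NHP procedure idle"
  env$dwell_log <- list()   # per issued collection: dwell onset & trigger t

  video_rect <- function(env, view) {
    g <- view$state$geometry
    cfg <- env$cfg
    if (is.null(env$video_size)) env$video_size <- c(g$width_px, g$height_px)
    switch(env$phase,
      attention = stim_rect(c(0.5, 0.5), env$video_size[1], env$video_size[2]),
      calibration = {
        tg <- view$state$cal_targets
        i <- min(env$cal_idx, nrow(tg))
        stim_rect(c(tg$x[i], tg$y[i]), cfg$video_cal_size_px[1],
                  cfg$video_cal_size_px[2])
      },
      validation = {
        tg <- view$state$val_targets
        i <- min(env$val_idx, nrow(tg))
        stim_rect(c(tg$x[i], tg$y[i]), cfg$video_cal_size_px[1],
                  cfg$video_cal_size_px[2])
      },
      NULL)
  }

  dwell_tick <- function(env, view, qualifying, point_id) {
    # returns commands; grace of <= blink_grace_samples invalid samples
    cfg <- env$cfg
    if (is.na(qualifying)) {       # gaze absent this tick
      env$invalid_run <- env$invalid_run + 1L
      if (env$invalid_run > cfg$blink_grace_samples) env$dwell_start <- NA_real_
      return(list())
    }
    env$invalid_run <- 0L
    if (!qualifying) {
      env$dwell_start <- NA_real_
      return(list())
    }
    if (is.na(env$dwell_start)) env$dwell_start <- view$t
    if (view$t - env$dwell_start >= cfg$dwell_duration_ms) {
      env$awaiting <- TRUE
      env$dwell_log[[length(env$dwell_log) + 1L]] <-
        list(onset = env$dwell_start, trigger = view$t,
             phase = env$phase, id = point_id)
      env$dwell_start <- NA_real_
      return(list(command("start_collection", id = point_id)))
    }
    list()
  }

  tick <- function(env, view) {
    cfg <- env$cfg
    g <- view$state$geometry
    rect <- video_rect(env, view)
    reward_gate(view$gaze, rect, g, env$sink, view$t)
    cmds <- env$pending
    env$pending <- list()
    if (!view$state$auto || env$phase == "done") return(cmds)
    gaze <- view$gaze
    if (env$phase == "attention") {
      full <- c(g$width_px, g$height_px)
      watched <- !is.null(gaze) && all(on_screen(gaze))
      if (env$watched_ms < cfg$attention_duration_ms) {
        if (watched) env$watched_ms <- env$watched_ms + view$dt
        env$status <- sprintf("attention: %.0f / %.0f s watched",
                              env$watched_ms / 1000,
                              cfg$attention_duration_ms / 1000)
      } else {
        # shrink linearly over shrink_duration of watched time
        if (!is.null(gaze) && in_stim_rect(gaze, rect, g)) {
          step <- (full - cfg$video_cal_size_px) *
            (view$dt / cfg$shrink_duration_ms)
          env$video_size <- pmax(env$video_size - step, cfg$video_cal_size_px)
        }
        env$status <- sprintf("attention: shrinking video (%.0f x %.0f px)",
                              env$video_size[1], env$video_size[2])
        if (all(env$video_size <= cfg$video_cal_size_px)) {
          env$phase <- "calibration"
          env$video_size <- cfg$video_cal_size_px
        }
      }
      return(cmds)
    }
    if (env$awaiting) return(cmds)
    if (env$phase == "calibration") {
      tg <- view$state$cal_targets
      if (env$cal_idx > nrow(tg)) return(cmds)
      id <- tg$id[env$cal_idx]
      q <- if (is.null(gaze)) NA else
        dist_px(gaze, rect$center, g) < cfg$dwell_distance_frac * g$height_px
      env$status <- sprintf("calibration: point %d/%d", env$cal_idx, nrow(tg))
      return(c(cmds, dwell_tick(env, view, q, id)))
    }
    if (env$phase == "validation") {
      tg <- view$state$val_targets
      if (env$val_idx > nrow(tg)) return(cmds)
      id <- tg$id[env$val_idx]
      q <- if (is.null(gaze)) NA else in_stim_rect(gaze, rect, g)
      env$status <- sprintf("validation: point %d/%d", env$val_idx, nrow(tg))
      return(c(cmds, dwell_tick(env, view, q, id)))
    }
    cmds
  }

  receive_update <- function(env, e, view) {
    cfg <- env$cfg
    switch(e$kind,
      collection_succeeded = {
        env$awaiting <- FALSE
        env$dwell_start <- NA_real_
        if (e$mode == "calibration" && env$phase == "calibration") {
          env$cal_idx <- env$cal_idx + 1L
          if (env$cal_idx > nrow(view$state$cal_targets)) {
            env$pending <- c(env$pending, list(command("compute_calibration")))
            env$awaiting <- TRUE
          }
        } else if (e$mode == "validation" && env$phase == "validation") {
          env$val_idx <- env$val_idx + 1L
          if (env$val_idx > nrow(view$state$val_targets)) {
            env$phase <- "done"
            env$status <- "validation complete"
            env$pending <- c(env$pending,
                             list(command("set_auto", on = FALSE),
                                  command("finish")))
          }
        }
      },
      collection_failed = {
        env$awaiting <- FALSE
        env$dwell_start <- NA_real_
      },
      calibration_computed = {
        env$awaiting <- FALSE
        env$calibrated <- TRUE
        env$status <- "calibration succeeded - awaiting operator"
        env$pending <- c(env$pending, list(command("set_auto", on = FALSE)))
      },
      calibration_failed = {
        env$awaiting <- FALSE
        env$retries <- env$retries + 1L
        if (env$retries <= cfg$max_retries) {
          env$cal_idx <- 1L
          env$pending <- c(env$pending, list(command("discard_all")))
          env$status <- sprintf("calibration failed - retry %d", env$retries)
        } else {
          env$phase <- "done"
          env$pending <- c(env$pending, list(command("set_auto", on = FALSE)))
        }
      },
      mode_changed = {
        if (e$mode == "validation" && env$calibrated) {
          env$phase <- "validation"
          env$val_idx <- 1L
          env$dwell_start <- NA_real_
          env$awaiting <- FALSE
        }
      },
      phase_skipped = {
        if (env$phase == "attention") {
          env$phase <- "calibration"
          env$video_size <- cfg$video_cal_size_px
          env$status <- "attention phase skipped"
        }
      },
      reward_pulsed = env$sink$pulse(e$t),
      NULL)
    invisible(NULL)
  }

  list(env = env,
       tick = tick,
       receive_update = receive_update,
       get_status_text = function(env) env$status,
       draw = function(env, view) video_rect(env, view))
}

# ---- adult gaze-contingent demo controller ---------------------------------

#' Target layout of the adult gaze-contingent demo
#'
#' Seven points: the screen center (stage 1), then two rings of three
#' points each at the given eccentricity (stages 2 and 3).
#'
#' @param eccentricity_frac radial distance of the ring points from the
#'   screen center as a fraction of screen height.
#' @return a target layout.
#' @export
adult_demo_targets <- function(eccentricity_frac = 0.35) {
  ang2 <- c(-90, 30, 150) * pi / 180
  ang3 <- c(90, 210, 330) * pi / 180
  r <- eccentricity_frac
  target_layout(data.frame(
    id = 1:7,
    x = c(0.5, 0.5 + r * cos(c(ang2, ang3))),
    y = c(0.5, 0.5 + r * sin(c(ang2, ang3)))))
}

#' Arc (annular-sector) AOI membership
#'
#' AOIs for the ring stages of the adult demo are annular sectors
#' centered on the screen center: the sector spans the 120-degree wedge
#' containing its target, with inner and outer radii at 0.5 and 1.5
#' times the target's eccentricity. Boundaries are closed (a point on
#' the boundary is inside). Distances/angles are computed in pixels so
#' the wedges are circular on screen.
#'
#' @param gaze normalized gaze position (or NULL).
#' @param target normalized target position on the ring.
#' @param g a \code{\link{screen_geometry}}.
#' @param half_angle_deg half-width of the wedge (default 60).
#' @param inner_frac,outer_frac radial bounds as multiples of the target
#'   eccentricity.
#' @return logical.
#' @export
in_arc_aoi <- function(gaze, target, g, half_angle_deg = 60,
                       inner_frac = 0.5, outer_frac = 1.5) {
  if (is.null(gaze) || any(!is.finite(gaze))) return(FALSE)
  c_px <- normalized_to_px(c(0.5, 0.5), g)
  g_px <- normalized_to_px(gaze, g) - c_px
  t_px <- normalized_to_px(target, g) - c_px
  re <- sqrt(sum(t_px^2))
  rg <- sqrt(sum(g_px^2))
  if (rg < inner_frac * re || rg > outer_frac * re) return(FALSE)
  da <- (atan2(g_px[2], g_px[1]) - atan2(t_px[2], t_px[1])) * 180 / pi
  da <- ((da + 180) %% 360) - 180
  abs(da) <= half_angle_deg
}

#' Gaze-contingent calibration demo controller (adults)
#'
#' Three-stage gaze-contingent procedure for instructable participants.
#' Stage 1 shows a single central target; when gaze comes close enough
#' for the dwell duration, data collection is triggered and a
#' calibration is computed from this single point. Stage 2 shows three
#' targets simultaneously; arc-shaped AOIs (\code{\link{in_arc_aoi}})
#' decide which target, if any, the participant is looking at, and dwell
#' inside an AOI triggers collection for that point. After all three, a
#' new calibration is computed, and stage 3 repeats the logic with three
#' further points before the final calibration.
#'
#' @param dwell_duration_ms dwell needed inside an AOI (or near the
#'   central point) before collection is triggered.
#' @param proximity_frac stage-1 "close enough" radius as a fraction of
#'   screen height.
#' @param eccentricity_frac ring eccentricity (see
#'   \code{\link{adult_demo_targets}}).
#' @param sink optional reward sink.
#' @return a controller object for \code{\link{run_loop}}.
#' @export
adult_demo_controller <- function(dwell_duration_ms = 500,
                                  proximity_frac = 0.1,
                                  eccentricity_frac = 0.35,
                                  sink = reward_recorder()) {
  env <- new.env(parent = emptyenv())
  env$stage <- 1L
  env$dwell_ms <- dwell_duration_ms
  env$prox <- proximity_frac
  env$ecc <- eccentricity_frac
  env$sink <- sink
  env$collected <- integer(0)
  env$awaiting <- FALSE
  env$pending <- list()
  env$dwell_start <- NA_real_
  env$dwell_id <- NA_integer_
  env$n_calibrations <- 0L
  env$done <- FALSE
  env$status <- "demo idle"

  stage_ids <- function(stage) switch(stage, `1` = 1L, `2` = 2:4, `3` = 5:7)

  tick <- function(env, view) {
    cmds <- env$pending
    env$pending <- list()
    if (!view$state$auto || env$done || env$awaiting) return(cmds)
    g <- view$state$geometry
    gaze <- view$gaze
    tg <- view$state$cal_targets
    ids <- setdiff(stage_ids(as.character(env$stage)), env$collected)
    env$status <- sprintf("demo stage %d: %d point(s) left", env$stage,
                          length(ids))
    if (!length(ids)) return(cmds)
    looked <- NA_integer_
    if (!is.null(gaze)) {
      for (id in ids) {
        pos <- c(tg$x[tg$id == id], tg$y[tg$id == id])
        hit <- if (env$stage == 1L) {
          dist_px(gaze, pos, g) <= env$prox * g$height_px
        } else {
          in_arc_aoi(gaze, pos, g)
        }
        if (hit) { looked <- id; break }
      }
    }
    if (is.na(looked)) {
      env$dwell_start <- NA_real_
      env$dwell_id <- NA_integer_
      return(cmds)
    }
    if (!identical(looked, env$dwell_id)) {
      env$dwell_id <- looked
      env$dwell_start <- view$t
    }
    if (view$t - env$dwell_start >= env$dwell_ms) {
      env$awaiting <- TRUE
      env$dwell_start <- NA_real_
      env$dwell_id <- NA_integer_
      return(c(cmds, list(command("start_collection", id = looked))))
    }
    cmds
  }

  receive_update <- function(env, e, view) {
    switch(e$kind,
      collection_succeeded = {
        env$awaiting <- FALSE
        env$collected <- c(env$collected, e$id)
        if (!length(setdiff(stage_ids(as.character(env$stage)),
                            env$collected))) {
          env$pending <- c(env$pending, list(command("compute_calibration")))
          env$awaiting <- TRUE
        }
      },
      collection_failed = { env$awaiting <- FALSE },
      calibration_computed = {
        env$awaiting <- FALSE
        env$n_calibrations <- env$n_calibrations + 1L
        if (env$stage < 3L) {
          env$stage <- env$stage + 1L
        } else {
          env$done <- TRUE
          env$status <- "demo complete"
          env$pending <- c(env$pending, list(command("set_auto", on = FALSE),
                                             command("finish")))
        }
      },
      calibration_failed = {
        env$awaiting <- FALSE
        ids <- stage_ids(as.character(env$stage))
        env$collected <- setdiff(env$collected, ids)
        for (id in ids)
          env$pending <- c(env$pending, list(command("discard_point", id = id)))
      },
      reward_pulsed = env$sink$pulse(e$t),
      NULL)
    invisible(NULL)
  }

  list(env = env,
       tick = tick,
       receive_update = receive_update,
       get_status_text = function(env) env$status,
       draw = function(env, view) {
         tg <- view$state$cal_targets
         ids <- setdiff(stage_ids(as.character(env$stage)), env$collected)
         if (!length(ids)) return(NULL)
         id <- ids[1]
         stim_rect(c(tg$x[tg$id == id], tg$y[tg$id == id]), 100, 100,
                   media = "target")
       })
}
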