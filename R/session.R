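#' Default calibration and validation target layouts
#'
#' The default calibration layout has five numbered points (screen center
#' plus four corner points inset 10\% from the edges); the default
#' validation layout has four points on an inner square. Both are fully
#' configurable when constructing a session.
#'
#' @return a data frame with columns \code{id}, \code{x}, \code{y}
#'   (normalized coordinates) and \code{status}.
#' @export
default_cal_targets <- function() {
  target_layout(data.frame(
    id = 1:5,
    x = c(0.1, 0.9, 0.5, 0.1, 0.9),
    y = c(0.1, 0.1, 0.5, 0.9, 0.9)))
}

#' @rdname default_cal_targets
#' @export
default_val_targets <- function() {
  target_layout(data.frame(
    id = 1:4,
    x = c(0.3, 0.7, 0.3, 0.7),
    y = c(0.3, 0.3, 0.7, 0.7)))
}

#' Construct a target layout
#'
#' @param df data frame with columns \code{id} (unique small integers)
#'   and \code{x}, \code{y} (normalized positions).
#' @return the layout with a \code{status} column initialized to
#'   "not_collected".
#' @export
target_layout <- function(df) {
  stopifnot(all(c("id", "x", "y") %in% names(df)),
            !anyDuplicated(df$id))
  df$id <- as.integer(df$id)
  df$status <- "not_collected"
  df
}

#' Session configuration defaults
#'
#' @param ... overrides for: \code{rate_hz} (nominal sampling/tick rate,
#'   60), \code{collection_window_ms} (per-point data collection window,
#'   600), \code{min_samples_per_point} (valid samples needed for a point
#'   to count, 10), \code{filter_window_ms} (controller-side temporal
#'   averaging window, 200), \code{gaze_history_ms} (operator gaze-trail
#'   window, 500), \code{max_residual_rms} (calibration sanity bound,
#'   0.05), \code{accuracy_stat} ("mean" or "median" per-point offset,
#'   "mean"), \code{trim_fit} (FALSE).
#' @return a named list.
#' @export
session_config <- function(...) {
  cfg <- list(rate_hz = 60, collection_window_ms = 600,
              min_samples_per_point = 10, filter_window_ms = 200,
              gaze_history_ms = 500, max_residual_rms = 0.05,
              accuracy_stat = "mean", trim_fit = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown session config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Create a calibration/validation session
#'
#' The session is the state machine behind the calibration interface: it
#' owns the target lifecycles for both modes, the collected calibration
#' and validation data, the active calibration (initially the identity
#' default calibration — the uncalibrated state), the snapshot store, the
#' eye selection and the auto-mode flag. All interaction — operator
#' input and controller automation alike — flows through
#' \code{\link{dispatch}} as commands.
#'
#' @param geometry a \code{\link{screen_geometry}}.
#' @param cal_targets,val_targets target layouts
#'   (\code{\link{target_layout}}).
#' @param config a \code{\link{session_config}} list.
#' @param preload optional \code{calibration_result} to start from (a
#'   previously snapshotted calibration); it is also placed in the
#'   snapshot menu under the label "preloaded".
#' @return an object of class \code{cal_session}.
#' @export
new_session <- function(geometry, cal_targets = default_cal_targets(),
                        val_targets = default_val_targets(),
                        config = session_config(), preload = NULL) {
  stopifnot(inherits(geometry, "screen_geometry"))
  s <- list(
    geometry = geometry, config = config,
    mode = "calibration",
    cal_targets = cal_targets, val_targets = val_targets,
    cal_data = calibration_data(),
    val_data = list(),
    active = default_calibration(),
    snapshots = list(),
    queue = integer(0),
    collecting = NULL,
    auto = FALSE, eyes = "both",
    show_gaze = FALSE, show_head = FALSE,
    show_gaze_participant = FALSE, show_head_participant = FALSE,
    status_text = "not calibrated",
    finished = FALSE)
  class(s) <- "cal_session"
  if (!is.null(preload)) {
    stopifnot(inherits(preload, "calibration_result"))
    s$active <- preload
    s$snapshots[["preloaded"]] <- calibration_snapshot("preloaded", preload)
    s$status_text <- "calibration preloaded"
  }
  s
}

#' @export
print.cal_session <- function(x, ...) {
  cat(sprintf("<cal_session: mode %s, %s, auto %s, eyes %s>\n",
              x$mode, x$status_text, if (x$auto) "on" else "off", x$eyes))
  tg <- current_targets(x)
  cat("  targets:", paste(sprintf("%d:%s", tg$id, tg$status), collapse = " "),
      "\n")
  if (length(x$snapshots))
    cat("  snapshots:", paste(names(x$snapshots), collapse = ", "), "\n")
  invisible(x)
}

current_targets <- function(state) {
  if (state$mode == "calibration") state$cal_targets else state$val_targets
}

set_current_targets <- function(state, tg) {
  if (state$mode == "calibration") state$cal_targets <- tg
  else state$val_targets <- tg
  state
}

#' Construct a session command
#'
#' Commands are the single interaction path into the session: operator
#' mouse/keyboard actions and controller automation both issue them.
#' Verbs: \code{enqueue_point}, \code{start_collection},
#' \code{discard_point}, \code{discard_all}, \code{compute_calibration},
#' \code{take_snapshot}, \code{load_snapshot}, \code{switch_mode},
#' \code{set_eyes}, \code{set_auto}, \code{skip_phase},
#' \code{manual_reward}, \code{finish}.
#'
#' @param verb command verb (see above).
#' @param ... payload fields: \code{id} (point id), \code{label}
#'   (snapshot label), \code{mode}, \code{eyes}, \code{on}.
#' @return an object of class \code{session_command}.
#' @export
command <- function(verb, ...) {
  verbs <- c("enqueue_point", "start_collection", "discard_point",
             "discard_all", "compute_calibration", "take_snapshot",
             "load_snapshot", "switch_mode", "set_eyes", "set_auto",
             "skip_phase", "manual_reward", "finish")
  if (!verb %in% verbs) stop("unknown command verb: ", verb)
  structure(c(list(verb = verb), list(...)), class = "session_command")
}

make_event <- function(kind, t, ...) {
  structure(c(list(kind = kind, t = t), list(...)), class = "session_event")
}

reject <- function(state, t, why) {
  list(state = state, events = list(make_event("command_rejected", t,
                                               reason = why)))
}

# head of the enqueued FIFO becomes showing when no point is active
promote_queue <- function(state) {
  tg <- current_targets(state)
  if (is.null(state$collecting) && !any(tg$status %in% c("showing", "collecting")) &&
      length(state$queue)) {
    id <- state$queue[1]
    state$queue <- state$queue[-1]
    tg$status[tg$id == id] <- "showing"
    state <- set_current_targets(state, tg)
  }
  state
}

#' Dispatch a command against a session
#'
#' Applies a single command to the session state and returns the new
#' state together with the events it produced. Transitions are
#' deterministic; invalid commands (unknown point id, unknown snapshot
#' label, starting a collection while another is active) are rejected
#' with a \code{command_rejected} event rather than an error.
#'
#' @param state a \code{cal_session}.
#' @param cmd a \code{\link{command}}.
#' @param t stream time in milliseconds attached to emitted events.
#' @return a list with elements \code{state} and \code{events}.
#' @export
dispatch <- function(state, cmd, t = 0) {
  stopifnot(inherits(state, "cal_session"), inherits(cmd, "session_command"))
  if (!is.null(cmd$id)) cmd$id <- as.integer(cmd$id)
  ev <- list()
  tg <- current_targets(state)
  switch(cmd$verb,
    enqueue_point = {
      if (!cmd$id %in% tg$id) return(reject(state, t, "unknown point id"))
      if (tg$status[tg$id == cmd$id] %in% c("showing", "collecting"))
        return(reject(state, t, "point already active"))
      if (!cmd$id %in% state$queue) state$queue <- c(state$queue, cmd$id)
      tg$status[tg$id == cmd$id] <- "enqueued"
      state <- set_current_targets(state, tg)
    },
    start_collection = {
      if (!cmd$id %in% tg$id) return(reject(state, t, "unknown point id"))
      if (!is.null(state$collecting))
        return(reject(state, t, "another point is collecting"))
      # showing the requested point displaces any other active point
      tg$status[tg$status == "showing" & tg$id != cmd$id] <- "enqueued"
      tg$status[tg$id == cmd$id] <- "collecting"
      state$queue <- setdiff(state$queue, cmd$id)
      state <- set_current_targets(state, tg)
      state$collecting <- list(id = cmd$id, mode = state$mode, start_t = t)
      ev <- c(ev, list(make_event("collection_started", t, id = cmd$id,
                                  mode = state$mode)))
    },
    discard_point = {
      if (!cmd$id %in% tg$id) return(reject(state, t, "unknown point id"))
      if (state$mode == "calibration") {
        state$cal_data$points[[as.character(cmd$id)]] <- NULL
      } else {
        state$val_data[[as.character(cmd$id)]] <- NULL
      }
      tg$status[tg$id == cmd$id] <- "not_collected"
      state$queue <- setdiff(state$queue, cmd$id)
      state <- set_current_targets(state, tg)
      ev <- c(ev, list(make_event("point_discarded", t, id = cmd$id,
                                  mode = state$mode)))
    },
    discard_all = {
      ids <- tg$id[tg$status != "not_collected" |
                     (if (state$mode == "calibration")
                        tg$id %in% as.integer(names(state$cal_data$points))
                      else tg$id %in% as.integer(names(state$val_data)))]
      if (state$mode == "calibration") state$cal_data <- calibration_data()
      else state$val_data <- list()
      tg$status <- "not_collected"
      state$queue <- integer(0)
      state$collecting <- NULL
      state <- set_current_targets(state, tg)
      for (id in ids) ev <- c(ev, list(make_event("point_discarded", t,
                                                  id = id, mode = state$mode)))
    },
    compute_calibration = {
      res <- fit_calibration(
        state$cal_data, eyes = state$eyes, base = state$active,
        min_samples_per_point = state$config$min_samples_per_point,
        max_residual_rms = state$config$max_residual_rms,
        trim = state$config$trim_fit)
      if (identical(res$status, "success")) {
        state$active <- res
        used <- sort(unique(unlist(res$points_used)))
        state$status_text <- paste0("calibration succeeded (points ",
                                    paste(used, collapse = ","), ")")
        ev <- c(ev, list(make_event("calibration_computed", t,
                                    points_used = res$points_used)))
      } else {
        state$status_text <- "calibration failed"
        ev <- c(ev, list(make_event("calibration_failed", t,
                                    reason = res$failure_reason)))
      }
    },
    take_snapshot = {
      if (cmd$label %in% names(state$snapshots))
        return(reject(state, t, "duplicate snapshot label"))
      state$snapshots[[cmd$label]] <-
        calibration_snapshot(cmd$label, state$active,
                             if (!is.null(cmd$report)) cmd$report else NULL)
      ev <- c(ev, list(make_event("snapshot_taken", t, label = cmd$label)))
    },
    load_snapshot = {
      if (!cmd$label %in% names(state$snapshots))
        return(reject(state, t, "unknown snapshot label"))
      state$active <- state$snapshots[[cmd$label]]$result
      state$status_text <- paste0("loaded snapshot '", cmd$label, "'")
      ev <- c(ev, list(make_event("snapshot_loaded", t, label = cmd$label)))
    },
    switch_mode = {
      if (!is.null(state$collecting))
        return(reject(state, t, "cannot switch mode while collecting"))
      mode <- if (!is.null(cmd$mode)) cmd$mode else
        if (state$mode == "calibration") "validation" else "calibration"
      if (!mode %in% c("calibration", "validation"))
        return(reject(state, t, "unknown mode"))
      state$mode <- mode
      state$queue <- integer(0)
      ev <- c(ev, list(make_event("mode_changed", t, mode = mode)))
    },
    set_eyes = {
      if (!cmd$eyes %in% c("left", "right", "both"))
        return(reject(state, t, "unknown eye selection"))
      state$eyes <- cmd$eyes
    },
    set_auto = {
      on <- isTRUE(cmd$on)
      if (!identical(state$auto, on)) {
        state$auto <- on
        ev <- c(ev, list(make_event("auto_toggled", t, on = on)))
      }
    },
    skip_phase = {
      ev <- c(ev, list(make_event("phase_skipped", t)))
    },
    manual_reward = {
      ev <- c(ev, list(make_event("reward_pulsed", t, manual = TRUE)))
    },
    finish = {
      state$finished <- TRUE
      ev <- c(ev, list(make_event("session_finished", t)))
    })
  state <- promote_queue(state)
  list(state = state, events = ev)
}

# evaluate a finished collection window against the min-sample rule and
# store the data (raw for calibration, calibrated for validation)
finalize_collection <- function(state, window, t) {
  col <- state$collecting
  state$collecting <- NULL
  tg <- current_targets(state)
  target <- c(tg$x[tg$id == col$id], tg$y[tg$id == col$id])
  lv <- window$left_valid > 0
  rv <- window$right_valid > 0
  need <- state$config$min_samples_per_point
  n_ok <- switch(state$eyes,
                 left = sum(lv), right = sum(rv),
                 both = max(sum(lv), sum(rv)))
  if (n_ok >= need) {
    if (col$mode == "calibration") {
      state$cal_data <- add_calibration_samples(
        state$cal_data, col$id, target,
        cbind(window$raw_left_x[lv], window$raw_left_y[lv]),
        cbind(window$raw_right_x[rv], window$raw_right_y[rv]))
    } else {
      state$val_data[[as.character(col$id)]] <- window
    }
    tg$status[tg$id == col$id] <- "collected"
    state <- set_current_targets(state, tg)
    ev <- make_event("collection_succeeded", t, id = col$id, mode = col$mode,
                     n_left = sum(lv), n_right = sum(rv))
  } else {
    tg$status[tg$id == col$id] <- "not_collected"
    state <- set_current_targets(state, tg)
    ev <- make_event("collection_failed", t, id = col$id, mode = col$mode,
                     n_left = sum(lv), n_right = sum(rv))
  }
  state <- promote_queue(state)
  list(state = state, events = list(ev))
}

#' Collect data for one point from a prepared gaze stream
#'
#' Replay-style collection: applies the collection window and the
#' minimum-valid-sample rule to a given stream, storing raw samples for
#' calibration mode or the stream itself for validation mode, and
#' returns the success/failure events. The stream must carry raw-gaze
#' columns \code{raw_left_x/y}, \code{raw_right_x/y} (for a stream
#' recorded without calibration they equal the reported positions).
#'
#' @param state a \code{cal_session}; the point must be showable (no
#'   other point collecting).
#' @param id target point id in the current mode's layout.
#' @param stream gaze stream rows covering the collection window.
#' @return list with \code{state} and \code{events}.
#' @export
collect_point_data <- function(state, id, stream) {
  if (!all(c("raw_left_x", "raw_left_y", "raw_right_x", "raw_right_y")
           %in% names(stream))) {
    stream$raw_left_x <- stream$left_x; stream$raw_left_y <- stream$left_y
    stream$raw_right_x <- stream$right_x; stream$raw_right_y <- stream$right_y
  }
  t0 <- if (nrow(stream)) stream$t_ms[1] else 0
  res <- dispatch(state, command("start_collection", id = id), t0)
  if (is.null(res$state$collecting)) return(res)
  t1 <- if (nrow(stream)) stream$t_ms[nrow(stream)] else t0
  fin <- finalize_collection(res$state, stream, t1)
  list(state = fin$state, events = c(res$events, fin$events))
}

#' Run the session loop with a controller and a gaze source
#'
#' Drives the session tick by tick at the configured rate: each tick one
#' gaze sample is drawn from the source, calibrated with the active
#' calibration and appended to the buffer; any finished collection
#' window is evaluated; the controller's \code{tick()} is called and the
#' commands it returns are dispatched; every event is forwarded to the
#' controller's \code{receive_update()}; its status text and draw output
#' are recorded. Controller methods are called on every tick regardless
#' of whether auto mode is active — gating its procedure on the auto
#' flag is the controller's own responsibility. The loop ends on a
#' \code{finish} command, after \code{max_ticks}, or — cleanly, with a
#' logged error event — if the controller throws.
#'
#' @param state a \code{cal_session}.
#' @param controller a controller object (see \code{\link{nhp_controller}}):
#'   a list with an environment \code{env} and functions \code{tick},
#'   \code{receive_update}, \code{get_status_text}, \code{draw}.
#' @param gaze_source function \code{(t, stim)} returning one raw sample
#'   as a named list (\code{left_x}, \code{left_y}, \code{left_valid},
#'   \code{right_x}, ...), e.g. from \code{\link{make_gaze_source}}.
#' @param max_ticks maximum number of ticks to run.
#' @param operator optional function \code{(t, state, new_events)}
#'   returning a list of commands, modeling operator keyboard/mouse input
#'   injected through the same dispatch path as controller commands.
#' @param start_t stream time of the first tick (ms).
#' @return a list with the final \code{state}, the \code{gaze_log} (a
#'   gaze stream with both raw and calibrated positions), \code{events}
#'   (list of all events), \code{commands} (all dispatched commands with
#'   times), \code{draw_log} (stimulus rects per tick) and
#'   \code{status_text} history.
#' @export
run_loop <- function(state, controller, gaze_source, max_ticks,
                     operator = NULL, start_t = 0) {
  dt <- 1000 / state$config$rate_hz
  nbuf <- max_ticks
  buf <- matrix(NA_real_, nrow = nbuf, ncol = 11,
                dimnames = list(NULL, c(
                  "t_ms", "raw_left_x", "raw_left_y", "left_valid",
                  "raw_right_x", "raw_right_y", "right_valid",
                  "left_x", "left_y", "right_x", "right_y")))
  events <- vector("list", 256); n_ev <- 0L
  cmds <- vector("list", 256); n_cmd <- 0L
  draws <- vector("list", max_ticks)
  stexts <- character(max_ticks)
  stim <- NULL
  fwin <- state$config$filter_window_ms
  win_lo <- 1L
  col_start_row <- NA_integer_
  halted <- NULL

  push_ev <- function(e) {
    n_ev <<- n_ev + 1L
    if (n_ev > length(events)) length(events) <<- 2L * n_ev
    events[[n_ev]] <<- e
  }
  push_cmd <- function(cm, t) {
    n_cmd <<- n_cmd + 1L
    if (n_cmd > length(cmds)) length(cmds) <<- 2L * n_cmd
    cmds[[n_cmd]] <<- list(t = t, cmd = cm)
  }

  i <- 0L
  res <- tryCatch({
    for (i in seq_len(max_ticks)) {
      t <- start_t + i * dt
      smp <- gaze_source(t, stim)
      M <- state$active$mappings
      lp <- apply_mapping(M$left, c(smp$left_x, smp$left_y))
      rp <- apply_mapping(M$right, c(smp$right_x, smp$right_y))
      buf[i, ] <- c(t, smp$left_x, smp$left_y, as.numeric(smp$left_valid),
                    smp$right_x, smp$right_y, as.numeric(smp$right_valid),
                    lp[1], lp[2], rp[1], rp[2])
      while (buf[win_lo, 1] <= t - fwin) win_lo <- win_lo + 1L
      # filtered binocular-average gaze over the trailing window
      w <- win_lo:i
      lv <- buf[w, 4] > 0; rv <- buf[w, 7] > 0
      lmean <- if (any(lv)) c(mean(buf[w[lv], 8]), mean(buf[w[lv], 9])) else NULL
      rmean <- if (any(rv)) c(mean(buf[w[rv], 10]), mean(buf[w[rv], 11])) else NULL
      fgaze <- if (!is.null(lmean) && !is.null(rmean)) (lmean + rmean) / 2
               else if (!is.null(lmean)) lmean else rmean

      new_events <- list()
      if (!is.null(state$collecting)) {
        if (is.na(col_start_row)) col_start_row <- i
        if (t >= state$collecting$start_t + state$config$collection_window_ms) {
          rows <- col_start_row:(i - 1L)
          window <- as.data.frame(buf[rows, , drop = FALSE])
          fin <- finalize_collection(state, window, t)
          state <- fin$state
          new_events <- c(new_events, fin$events)
          col_start_row <- NA_integer_
        }
      } else col_start_row <- NA_integer_

      view <- list(t = t, dt = dt, gaze = fgaze,
                   sample = smp, state = state, stim = stim)
      for (e in new_events) {
        push_ev(e)
        controller$receive_update(controller$env, e, view)
      }
      run_cmds <- controller$tick(controller$env, view)
      if (!is.null(operator)) {
        run_cmds <- c(run_cmds, operator(t, state, new_events))
      }
      for (cm in run_cmds) {
        push_cmd(cm, t)
        dres <- dispatch(state, cm, t)
        state <- dres$state
        if (identical(cm$verb, "start_collection") &&
            !is.null(state$collecting)) col_start_row <- i + 1L
        view$state <- state
        for (e in dres$events) {
          push_ev(e)
          controller$receive_update(controller$env, e, view)
        }
      }
      stim <- controller$draw(controller$env, view)
      draws[[i]] <- stim
      stexts[i] <- controller$get_status_text(controller$env)
      if (state$finished) break
    }
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(res)) {
    halted <- res
    push_ev(make_event("controller_error", start_t + i * dt, message = res))
  }
  used <- seq_len(min(i, max_ticks))
  gl <- as.data.frame(buf[used, , drop = FALSE])
  gl <- gl[stats::complete.cases(gl[, "t_ms", drop = FALSE]), , drop = FALSE]
  list(state = state,
       gaze_log = validate_gaze_stream(gl),
       events = events[seq_len(n_ev)],
       commands = cmds[seq_len(n_cmd)],
       draw_log = draws[used],
       status_text = stexts[used],
       halted = halted)
}

#' Build a validation report from a session's collected validation data
#'
#' @param state a \code{cal_session} whose validation points have been
#'   collected.
#' @param meta metadata list passed through to the report.
#' @return a \code{\link{session_report}} over the collected points.
#' @export
session_validation_report <- function(state, meta = list()) {
  tg <- state$val_targets
  pts <- lapply(seq_len(nrow(tg)), function(i) {
    key <- as.character(tg$id[i])
    target <- c(tg$x[i], tg$y[i])
    w <- state$val_data[[key]]
    if (is.null(w) || nrow(w) == 0) {
      w <- data.frame(t_ms = numeric(0), left_x = numeric(0),
                      left_y = numeric(0), left_valid = numeric(0),
                      right_x = numeric(0), right_y = numeric(0),
                      right_valid = numeric(0))
    }
    point_quality(w, target, state$geometry,
                  duration_ms = state$config$collection_window_ms,
                  rate_hz = state$config$rate_hz)
  })
  session_report(pts, meta)
}
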