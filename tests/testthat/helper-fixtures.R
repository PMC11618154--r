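# shared geometry: 23" 1920x1080 desktop setup at 600 mm
test_geom <- function(viewing_distance_mm = 600) {
  screen_geometry(1920, 1080, 531, 299, viewing_distance_mm)
}

# ---- independent brute-force oracles (3D trig via acos, no shared code
# with the implementation's atan2-based path) --------------------------------

oracle_point_mm <- function(p, g) {
  c((p[1] - 0.5) * g$width_mm, (p[2] - 0.5) * g$height_mm, 0)
}

oracle_angle <- function(a, b, g, eye = NULL) {
  if (is.null(eye)) eye <- c(0, 0, g$viewing_distance_mm)
  u <- oracle_point_mm(a, g) - eye
  v <- oracle_point_mm(b, g) - eye
  cth <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cth))) * 180 / pi
}

oracle_accuracy <- function(pos, target, g) {
  mean(apply(pos, 1, function(p) oracle_angle(p, target, g)))
}

oracle_rms_s2s <- function(pos, valid, g) {
  d2 <- c()
  for (i in seq_len(nrow(pos) - 1)) {
    if (valid[i] && valid[i + 1]) {
      d2 <- c(d2, oracle_angle(pos[i, ], pos[i + 1, ], g)^2)
    }
  }
  if (!length(d2)) return(NA_real_)
  sqrt(mean(d2))
}

oracle_std <- function(pos, g) {
  eye <- c(0, 0, g$viewing_distance_mm)
  ang <- t(apply(pos, 1, function(p) {
    v <- oracle_point_mm(p, g) - eye
    c(atan2(v[1], -v[3]), atan2(v[2], sqrt(v[1]^2 + v[3]^2)))
  })) * 180 / pi
  n <- nrow(pos)
  sqrt(mean((ang[, 1] - mean(ang[, 1]))^2) +
       mean((ang[, 2] - mean(ang[, 2]))^2))
}

# ---- stream builders -------------------------------------------------------

# both-eyes-valid stream at fixed positions (n x 2), 60 Hz
const_stream <- function(pos, n = NULL, rate = 60) {
  pos <- if (is.null(dim(pos))) matrix(pos, ncol = 2) else pos
  if (!is.null(n)) pos <- pos[rep_len(seq_len(nrow(pos)), n), , drop = FALSE]
  dt <- 1000 / rate
  gaze_stream(t_ms = seq_len(nrow(pos)) * dt,
              left_x = pos[, 1], left_y = pos[, 2], left_valid = 1,
              right_x = pos[, 1], right_y = pos[, 2], right_valid = 1)
}

# gaze source fixating a fixed normalized position, both eyes valid
fix_source <- function(pos, valid = TRUE) {
  force(pos); force(valid)
  function(t, stim) {
    list(left_x = pos[1], left_y = pos[2], left_valid = valid,
         right_x = pos[1], right_y = pos[2], right_valid = valid)
  }
}

# gaze source tracking whatever stimulus is shown, with no noise/latency
track_source <- function(offset = c(0, 0)) {
  function(t, stim) {
    p <- if (is.null(stim)) c(0.5, 0.5) else stim$center
    list(left_x = p[1] + offset[1], left_y = p[2] + offset[2], left_valid = TRUE,
         right_x = p[1] + offset[1], right_y = p[2] + offset[2],
         right_valid = TRUE)
  }
}

# operator script: auto on at the first tick, optional attention skip,
# confirmation after calibration success (switch to validation, auto on)
nhp_operator <- function(skip_attention = TRUE) {
  started <- FALSE
  confirm_armed <- FALSE
  confirmed <- FALSE
  function(t, state, new_events) {
    out <- list()
    if (!started) {
      started <<- TRUE
      out <- c(out, list(command("set_auto", on = TRUE)))
      if (skip_attention) out <- c(out, list(command("skip_phase")))
    }
    if (!confirmed && !state$auto && state$mode == "calibration" &&
        startsWith(state$status_text, "calibration succeeded")) {
      if (confirm_armed) {
        confirmed <<- TRUE
        out <- c(out, list(command("switch_mode", mode = "validation"),
                           command("set_auto", on = TRUE)))
      } else confirm_armed <<- TRUE
    }
    out
  }
}

# a fresh NHP session (controller + matching session layouts)
nhp_session <- function(g = test_geom(), cfg = nhp_config(),
                        scfg = session_config()) {
  ctrl <- nhp_controller(cfg)
  state <- new_session(g, target_layout(cfg$cal_points),
                       nhp_val_targets(cfg$val_rows, cfg$val_cols), scfg)
  list(ctrl = ctrl, state = state)
}

event_kinds <- function(events) vapply(events, function(e) e$kind, character(1))

command_verbs <- function(cmds) vapply(cmds, function(c) c$cmd$verb, character(1))
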