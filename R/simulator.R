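#' Synthetic participant model
#'
#' Ground-truth model of a participant plus tracker used by the
#' simulator: where the participant looks (orienting latency toward new
#' stimuli, fixation noise, drift, attention lapses), when data is lost
#' (blinks), and how the tracker's raw report is distorted relative to
#' true gaze (the per-eye mapping that calibration must recover).
#'
#' @param ... overrides for:
#'   \code{sampling_rate_hz} (60);
#'   \code{latency_median_ms} (250; lognormal orienting latency) and
#'   \code{latency_sdlog} (0.4);
#'   \code{fixation_noise_sigma_deg} (0.5; per-axis, per-eye isotropic
#'   Gaussian noise in degrees);
#'   \code{drift_deg_per_s} (0);
#'   \code{blink_rate_per_min} (4) and \code{blink_duration_ms} (150;
#'   lognormal with \code{blink_sdlog} 0.3);
#'   \code{lapse_rate_per_s} (0.02; probability per second of looking
#'   away) and \code{lapse_duration_ms} (2000; exponential mean);
#'   \code{distortion} (list with per-eye 2 x 3 raw-from-true matrices;
#'   identity);
#'   \code{interocular_offset_deg} (0; horizontal split between eyes);
#'   \code{ipd_mm} (63; for simulated eye origins);
#'   \code{seed} (1).
#' @return an object of class \code{participant_model}.
#' @export
participant_model <- function(...) {
  m <- list(sampling_rate_hz = 60,
            latency_median_ms = 250, latency_sdlog = 0.4,
            fixation_noise_sigma_deg = 0.5,
            drift_deg_per_s = 0,
            blink_rate_per_min = 4, blink_duration_ms = 150,
            blink_sdlog = 0.3,
            lapse_rate_per_s = 0.02, lapse_duration_ms = 2000,
            distortion = list(left = identity_mapping(),
                              right = identity_mapping()),
            interocular_offset_deg = 0,
            ipd_mm = 63,
            seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(m))
  if (length(unknown)) stop("unknown participant model keys: ",
                            paste(unknown, collapse = ", "))
  m[names(dots)] <- dots
  stopifnot(m$fixation_noise_sigma_deg >= 0, m$sampling_rate_hz > 0)
  class(m) <- "participant_model"
  m
}

#' @export
print.participant_model <- function(x, ...) {
  cat(sprintf(paste0("<participant_model: %g Hz, noise %.2f deg, latency ",
                     "median %g ms, blinks %g/min, seed %d>\n"),
              x$sampling_rate_hz, x$fixation_noise_sigma_deg,
              x$latency_median_ms, x$blink_rate_per_min, x$seed))
  invisible(x)
}

#' An affine ground-truth distortion with a given mean offset
#'
#' Convenience constructor for simulator distortions: a small affine
#' perturbation of the identity whose average displacement over the
#' central screen region corresponds approximately to the requested
#' offset in degrees. Used to pose parameter-recovery problems with a
#' known answer.
#'
#' @param offset_deg approximate mean angular displacement.
#' @param g a \code{\link{screen_geometry}}.
#' @param scale,shear multiplicative components of the distortion.
#' @return a 2 x 3 raw-from-true mapping matrix.
#' @export
affine_distortion <- function(offset_deg, g, scale = 1.05, shear = 0.02) {
  dx <- angle_to_norm_offset(offset_deg / sqrt(2), g, "x")
  dy <- angle_to_norm_offset(offset_deg / sqrt(2), g, "y")
  S <- rbind(c(scale, shear), c(-shear, scale))
  # raw = S (p - c) + c + d, so the pure translation part is offset_deg
  tr <- c(0.5, 0.5) - S %*% c(0.5, 0.5) + c(dx, dy)
  cbind(S, tr)
}

#' Reactive gaze source for the session loop
#'
#' Returns a function \code{(t, stim)} producing one raw binocular
#' sample per call, suitable for \code{\link{run_loop}}: the participant
#' orients to the center of the currently shown stimulus after a
#' lognormal latency, fixates it with Gaussian angular noise, blinks
#' (validity drops), occasionally lapses (gaze moves off-screen), and
#' the tracker reports the per-eye distorted positions plus simulated 3D
#' eye origins. Draws come from the R session RNG in a fixed per-tick
#' order (blink, lapse, then four noise deviates; latency on stimulus
#' change), so seeding the RNG before the run makes the stream
#' reproducible.
#'
#' @param model a \code{\link{participant_model}}.
#' @param g a \code{\link{screen_geometry}}.
#' @return a function \code{(t, stim)} returning a named list (one raw
#'   gaze sample).
#' @export
make_gaze_source <- function(model, g) {
  env <- new.env(parent = emptyenv())
  env$cur <- c(0.5, 0.5)
  env$pending <- NULL
  env$switch_at <- Inf
  env$last_stim <- NULL
  env$blink_until <- -Inf
  env$away_until <- -Inf
  env$away_pos <- c(1.5, 1.5)
  env$t0 <- NA_real_
  dt <- 1000 / model$sampling_rate_hz
  sx <- angle_to_norm_offset(model$fixation_noise_sigma_deg, g, "x")
  sy <- angle_to_norm_offset(model$fixation_noise_sigma_deg, g, "y")
  iox <- angle_to_norm_offset(model$interocular_offset_deg / 2, g, "x")
  drift_x <- angle_to_norm_offset(model$drift_deg_per_s, g, "x") / 1000
  drift_y <- angle_to_norm_offset(model$drift_deg_per_s, g, "y") / 1000
  p_blink <- model$blink_rate_per_min / 60 * dt / 1000
  p_lapse <- model$lapse_rate_per_s * dt / 1000

  function(t, stim) {
    if (is.na(env$t0)) env$t0 <- t
    target <- if (!is.null(stim)) stim$center else c(0.5, 0.5)
    if (is.null(env$last_stim) || any(target != env$last_stim)) {
      env$last_stim <- target
      lat <- if (model$latency_median_ms <= 0) 0 else
        stats::rlnorm(1, log(model$latency_median_ms), model$latency_sdlog)
      env$pending <- target
      env$switch_at <- t + lat
    }
    if (t >= env$switch_at && !is.null(env$pending)) {
      env$cur <- env$pending
      env$pending <- NULL
      env$switch_at <- Inf
    }
    # stochastic processes, fixed draw order
    if (t >= env$blink_until && stats::runif(1) < p_blink) {
      env$blink_until <- t +
        stats::rlnorm(1, log(model$blink_duration_ms), model$blink_sdlog)
    }
    if (t >= env$away_until && stats::runif(1) < p_lapse) {
      env$away_until <- t + stats::rexp(1, 1 / model$lapse_duration_ms)
    }
    nz <- stats::rnorm(4)
    base <- if (t < env$away_until) env$away_pos else env$cur
    el <- t - env$t0
    true_l <- c(base[1] + nz[1] * sx - iox + drift_x * el,
                base[2] + nz[2] * sy + drift_y * el)
    true_r <- c(base[1] + nz[3] * sx + iox + drift_x * el,
                base[2] + nz[4] * sy + drift_y * el)
    raw_l <- apply_mapping(model$distortion$left, true_l)
    raw_r <- apply_mapping(model$distortion$right, true_r)
    # half-open blink interval, robust to tick-grid rounding
    valid <- t >= env$blink_until - 1e-6
    z <- g$viewing_distance_mm
    list(left_x = raw_l[1], left_y = raw_l[2], left_valid = valid,
         right_x = raw_r[1], right_y = raw_r[2], right_valid = valid,
         left_origin_x = -model$ipd_mm / 2, left_origin_y = 0,
         left_origin_z = z,
         right_origin_x = model$ipd_mm / 2, right_origin_y = 0,
         right_origin_z = z,
         true_x = base[1], true_y = base[2])
  }
}

#' Generate a gaze stream for a fixed stimulus schedule
#'
#' Runs the synthetic participant open-loop against a time-ordered
#' stimulus schedule and returns the raw (uncalibrated) binocular
#' stream. Reproducible: the model's seed is set at the start, so the
#' same model and schedule give a bitwise-identical stream.
#'
#' @param model a \code{\link{participant_model}}.
#' @param schedule data frame with columns \code{t_ms}, \code{x},
#'   \code{y} (stimulus center from that time onward) and optional
#'   \code{w_px}, \code{h_px}.
#' @param g a \code{\link{screen_geometry}}.
#' @param duration_ms stream length.
#' @return a gaze stream data frame (reported positions are the raw,
#'   uncalibrated tracker output; \code{true_x}, \code{true_y} columns
#'   carry the ground-truth gaze).
#' @export
generate_stream <- function(model, schedule, g, duration_ms) {
  stopifnot(nrow(schedule) >= 1)
  set.seed(model$seed)
  src <- make_gaze_source(model, g)
  dt <- 1000 / model$sampling_rate_hz
  n <- floor(duration_ms / dt)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t <- i * dt
    k <- findInterval(t, schedule$t_ms)
    stim <- if (k >= 1)
      stim_rect(c(schedule$x[k], schedule$y[k]),
                if ("w_px" %in% names(schedule)) schedule$w_px[k] else 300,
                if ("h_px" %in% names(schedule)) schedule$h_px[k] else 300)
      else NULL
    s <- src(t, stim)
    rows[[i]] <- c(t_ms = t, left_x = s$left_x, left_y = s$left_y,
                   left_valid = as.numeric(s$left_valid),
                   right_x = s$right_x, right_y = s$right_y,
                   right_valid = as.numeric(s$right_valid),
                   left_origin_x = s$left_origin_x,
                   left_origin_y = s$left_origin_y,
                   left_origin_z = s$left_origin_z,
                   right_origin_x = s$right_origin_x,
                   right_origin_y = s$right_origin_y,
                   right_origin_z = s$right_origin_z,
                   true_x = s$true_x, true_y = s$true_y)
  }
  df <- as.data.frame(do.call(rbind, rows))
  validate_gaze_stream(df)
}

#' Run a complete simulated calibration session (closed loop)
#'
#' Wires a synthetic participant, a session and a controller together:
#' the gaze source reacts to the stimuli the controller draws, the
#' controller reacts to the gaze, and an operator script supplies the
#' minimal human-in-the-loop actions the procedure requires (activating
#' auto mode at the start; after a successful calibration — when the
#' controller deactivates itself for inspection — confirming by
#' switching to validation mode and re-activating auto). Everything is
#' reproducible from the model seed.
#'
#' @param model a \code{\link{participant_model}}.
#' @param g a \code{\link{screen_geometry}}.
#' @param controller a controller object; default a fresh
#'   \code{\link{nhp_controller}}.
#' @param cal_targets,val_targets session target layouts; the defaults
#'   follow the controller's configuration for NHP controllers.
#' @param config a \code{\link{session_config}}; its \code{rate_hz} is
#'   forced to the model's sampling rate.
#' @param skip_attention if TRUE the operator presses the skip shortcut
#'   at the start (for participants already trained to watch the
#'   screen).
#' @param max_duration_ms wall-clock cap on the simulated session.
#' @param preload optional calibration to preload.
#' @return a list: \code{result} (the \code{\link{run_loop}} output),
#'   \code{report} (validation \code{\link{session_report}}),
#'   \code{state}, and \code{controller}.
#' @export
closed_loop <- function(model, g, controller = NULL,
                        cal_targets = NULL, val_targets = NULL,
                        config = session_config(),
                        skip_attention = FALSE,
                        max_duration_ms = 120000,
                        preload = NULL) {
  if (is.null(controller)) controller <- nhp_controller()
  is_nhp <- !is.null(controller$env$cfg$cal_points)
  if (is.null(cal_targets)) {
    cal_targets <- if (is_nhp) target_layout(controller$env$cfg$cal_points)
      else default_cal_targets()
  }
  if (is.null(val_targets)) {
    val_targets <- if (is_nhp)
      nhp_val_targets(controller$env$cfg$val_rows, controller$env$cfg$val_cols)
      else default_val_targets()
  }
  config$rate_hz <- model$sampling_rate_hz
  state <- new_session(g, cal_targets, val_targets, config, preload = preload)
  set.seed(model$seed)
  src <- make_gaze_source(model, g)

  op <- local({
    started <- FALSE
    confirmed <- FALSE
    confirm_next <- FALSE
    function(t, state, new_events) {
      out <- list()
      if (!started) {
        started <<- TRUE
        out <- c(out, list(command("set_auto", on = TRUE)))
        if (skip_attention) out <- c(out, list(command("skip_phase")))
      }
      if (!confirmed && !state$auto && state$mode == "calibration" &&
          startsWith(state$status_text, "calibration succeeded")) {
        if (confirm_next) {
          confirmed <<- TRUE
          out <- c(out, list(command("switch_mode", mode = "validation"),
                             command("set_auto", on = TRUE)))
        } else confirm_next <<- TRUE
      }
      out
    }
  })

  max_ticks <- ceiling(max_duration_ms * model$sampling_rate_hz / 1000)
  res <- run_loop(state, controller, src, max_ticks, operator = op)
  report <- session_validation_report(
    res$state, meta = list(seed = model$seed,
                           calibration = res$state$status_text))
  list(result = res, report = report, state = res$state,
       controller = controller)
}
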