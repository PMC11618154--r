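#' Gaze accuracy (offset) in degrees
#'
#' Mean angular distance between recorded gaze samples and the true
#' target location, in degrees of visual angle.
#'
#' @param pos an n x 2 matrix of valid gaze positions (normalized screen
#'   coordinates).
#' @param target the target position, normalized.
#' @param g a \code{\link{screen_geometry}}.
#' @param eye optional 3D eye position (mm); nominal distance otherwise.
#' @return mean offset in degrees, or NA if no samples.
#' @export
accuracy_deg <- function(pos, target, g, eye = NULL) {
  pos <- as_point_matrix(pos)
  pos <- pos[stats::complete.cases(pos), , drop = FALSE]
  if (nrow(pos) < 1) return(NA_real_)
  mean(angular_offset(pos, target, g, eye))
}

#' RMS sample-to-sample precision in degrees
#'
#' Root mean square of the angular distances between consecutive valid
#' samples. Pairs that bridge an invalid sample are excluded rather than
#' interpolated, so blinks do not manufacture artificial jumps.
#'
#' @param pos an n x 2 matrix of gaze positions for all samples in the
#'   window (rows for invalid samples are ignored via \code{valid}).
#' @param valid logical vector marking valid samples; defaults to rows
#'   with finite coordinates.
#' @inheritParams accuracy_deg
#' @return RMS-S2S in degrees, or NA with fewer than two valid samples
#'   forming at least one adjacent pair.
#' @export
rms_s2s_deg <- function(pos, g, valid = NULL, eye = NULL) {
  pos <- as_point_matrix(pos)
  if (is.null(valid)) valid <- stats::complete.cases(pos)
  n <- nrow(pos)
  if (n < 2) return(NA_real_)
  pair <- valid[-n] & valid[-1]
  if (!any(pair)) return(NA_real_)
  a <- pos[-n, , drop = FALSE][pair, , drop = FALSE]
  b <- pos[-1, , drop = FALSE][pair, , drop = FALSE]
  d <- angular_offset(a, b, g, eye)
  sqrt(mean(d^2))
}

#' STD precision in degrees
#'
#' Dispersion of gaze samples about their centroid: the root of the sum
#' of the per-axis variances of the samples' angular positions (RMS
#' deviation from the mean position, population variances).
#'
#' @inheritParams accuracy_deg
#' @return STD in degrees, or NA with fewer than two valid samples.
#' @export
std_deg <- function(pos, g, eye = NULL) {
  pos <- as_point_matrix(pos)
  pos <- pos[stats::complete.cases(pos), , drop = FALSE]
  n <- nrow(pos)
  if (n < 2) return(NA_real_)
  ang <- screen_to_angles(pos, g, eye)
  va <- sum((ang[, 1] - mean(ang[, 1]))^2) / n
  ve <- sum((ang[, 2] - mean(ang[, 2]))^2) / n
  sqrt(va + ve)
}

#' Data loss percentage
#'
#' Share of expected samples in a collection window that are missing or
#' flagged invalid: \code{100 * (1 - n_valid / n_expected)} with
#' \code{n_expected = round(duration_ms * rate_hz / 1000)}, clamped to
#' \code{[0, 100]}. When the nominal sampling rate is unknown the number
#' of received samples is used as the denominator and the result is
#' flagged.
#'
#' @param n_valid number of valid samples observed.
#' @param duration_ms window duration (ms).
#' @param rate_hz nominal sampling rate; NULL if unknown.
#' @param n_received samples actually received (only used when
#'   \code{rate_hz} is NULL).
#' @return a list with \code{pct} and \code{denominator}
#'   ("expected" or "received").
#' @export
data_loss_pct <- function(n_valid, duration_ms, rate_hz = NULL,
                          n_received = NULL) {
  if (!is.null(rate_hz)) {
    stopifnot(duration_ms > 0, rate_hz > 0)
    n_exp <- round(duration_ms * rate_hz / 1000)
    denom <- "expected"
  } else {
    if (is.null(n_received)) stop("need rate_hz or n_received")
    n_exp <- n_received
    denom <- "received"
  }
  pct <- if (n_exp > 0) 100 * (1 - n_valid / n_exp) else NA_real_
  list(pct = min(100, max(0, pct)), denominator = denom)
}

# metrics for one channel (a matrix of positions + validity over the window)
channel_metrics <- function(pos, valid, target, g, eye = NULL) {
  vp <- pos[valid, , drop = FALSE]
  list(accuracy_deg = accuracy_deg(vp, target, g, eye),
       rms_s2s_deg = rms_s2s_deg(pos, g, valid, eye),
       std_deg = std_deg(vp, g, eye),
       n_valid = sum(valid))
}

#' Data-quality metrics for one validation point
#'
#' Computes accuracy, RMS-S2S and STD for the left eye, the right eye and
#' the per-sample binocular-average signal, plus per-eye data loss, from
#' the gaze collected while a target was shown.
#'
#' @param stream gaze stream covering the point's collection window.
#' @param target the point's position, normalized.
#' @param g a \code{\link{screen_geometry}}.
#' @param duration_ms collection window duration; defaults to the stream's
#'   time span plus one median sample interval.
#' @param rate_hz nominal sampling rate for the data-loss denominator;
#'   NULL falls back to received samples.
#' @param eye optional 3D eye position.
#' @return an object of class \code{point_quality}: a list with per-channel
#'   metrics (\code{left}, \code{right}, \code{average}), per-eye
#'   \code{data_loss_pct}, \code{n_samples} and \code{target}.
#' @export
point_quality <- function(stream, target, g, duration_ms = NULL,
                          rate_hz = NULL, eye = NULL) {
  n <- nrow(stream)
  if (is.null(duration_ms) && n > 1) {
    duration_ms <- diff(range(stream$t_ms)) + stats::median(diff(stream$t_ms))
  } else if (is.null(duration_ms)) {
    duration_ms <- if (n == 1) 1 else 0
  }
  lv <- stream$left_valid > 0
  rv <- stream$right_valid > 0
  avg <- binocular_average(stream)
  av <- stats::complete.cases(avg)
  res <- list(
    left = channel_metrics(cbind(stream$left_x, stream$left_y), lv, target, g, eye),
    right = channel_metrics(cbind(stream$right_x, stream$right_y), rv, target, g, eye),
    average = channel_metrics(avg, av, target, g, eye),
    data_loss_pct = list(
      left = data_loss_pct(sum(lv), duration_ms, rate_hz, n)$pct,
      right = data_loss_pct(sum(rv), duration_ms, rate_hz, n)$pct),
    n_samples = n,
    target = as.numeric(target))
  class(res) <- "point_quality"
  res
}

#' @export
print.point_quality <- function(x, ...) {
  cat(sprintf("<point_quality at (%.2f, %.2f), %d samples>\n",
              x$target[1], x$target[2], x$n_samples))
  for (ch in c("left", "right", "average")) {
    m <- x[[ch]]
    cat(sprintf("  %-7s acc %.3f  RMS-S2S %.3f  STD %.3f deg (n=%d)\n",
                ch, m$accuracy_deg, m$rms_s2s_deg, m$std_deg, m$n_valid))
  }
  cat(sprintf("  data loss L %.1f%%  R %.1f%%\n",
              x$data_loss_pct$left, x$data_loss_pct$right))
  invisible(x)
}

#' Session-level validation report
#'
#' Bundles per-point quality metrics with their unweighted aggregate over
#' the points for which data is available.
#'
#' @param points a list of \code{\link{point_quality}} objects (points
#'   with no valid data may be included; they are excluded from the
#'   aggregate and flagged).
#' @param meta named list of session metadata (participant id, timestamp,
#'   calibration label, ...).
#' @return an object of class \code{session_report}.
#' @export
session_report <- function(points, meta = list()) {
  has_data <- vapply(points, function(p) {
    any(vapply(c("left", "right", "average"),
               function(ch) isTRUE(p[[ch]]$n_valid > 0), logical(1)))
  }, logical(1))
  agg <- list()
  for (ch in c("left", "right", "average")) {
    for (metric in c("accuracy_deg", "rms_s2s_deg", "std_deg")) {
      v <- vapply(points[has_data], function(p) p[[ch]][[metric]], numeric(1))
      agg[[ch]][[metric]] <- if (length(v) && any(is.finite(v)))
        mean(v[is.finite(v)]) else NA_real_
    }
  }
  for (side in c("left", "right")) {
    v <- vapply(points[has_data], function(p) p$data_loss_pct[[side]], numeric(1))
    agg$data_loss_pct[[side]] <- if (length(v) && any(is.finite(v)))
      mean(v[is.finite(v)]) else NA_real_
  }
  structure(list(points = points, aggregate = agg,
                 points_with_data = which(has_data), meta = meta),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report: %d points, %d with data>\n",
              length(x$points), length(x$points_with_data)))
  a <- x$aggregate
  cat(sprintf("  aggregate accuracy (deg): L %.3f  R %.3f  avg %.3f\n",
              a$left$accuracy_deg, a$right$accuracy_deg, a$average$accuracy_deg))
  cat(sprintf("  aggregate RMS-S2S  (deg): L %.3f  R %.3f  avg %.3f\n",
              a$left$rms_s2s_deg, a$right$rms_s2s_deg, a$average$rms_s2s_deg))
  cat(sprintf("  aggregate data loss: L %.1f%%  R %.1f%%\n",
              a$data_loss_pct$left, a$data_loss_pct$right))
  invisible(x)
}

#' Write / read a session report as JSON
#'
#' @param report a \code{\link{session_report}}.
#' @param path file path.
#' @export
write_session_report <- function(report, path) {
  x <- unclass(report)
  x$points <- lapply(x$points, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_session_report
#' @export
read_session_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$points <- lapply(x$points, function(p) {
    p$target <- as.numeric(p$target)
    class(p) <- "point_quality"
    p
  })
  x$points_with_data <- as.integer(x$points_with_data)
  class(x) <- "session_report"
  x
}

#' Summarize sessions across participants and groups
#'
#' Produces the standard multi-session summary: per participant, the
#' median over sessions of each metric together with its min-max range;
#' per group, the unweighted mean over participants of the median
#' binocular-average accuracy.
#'
#' @param sessions a data frame with one row per session and columns
#'   \code{participant}, \code{group}, \code{acc_left}, \code{acc_right},
#'   \code{acc_average}, and optionally \code{loss_left},
#'   \code{loss_right}.
#' @return a list with \code{participants} (a data frame of medians and
#'   ranges) and \code{groups} (a data frame with the group means of the
#'   median binocular-average accuracy).
#' @export
summarize_sessions <- function(sessions) {
  stopifnot(nrow(sessions) >= 1,
            all(c("participant", "group", "acc_average") %in% names(sessions)))
  metrics <- intersect(c("acc_left", "acc_right", "acc_average",
                         "loss_left", "loss_right"), names(sessions))
  parts <- unique(sessions[, c("participant", "group")])
  rows <- lapply(seq_len(nrow(parts)), function(i) {
    s <- sessions[sessions$participant == parts$participant[i], , drop = FALSE]
    out <- list(participant = parts$participant[i], group = parts$group[i],
                n_sessions = nrow(s))
    for (m in metrics) {
      v <- s[[m]][is.finite(s[[m]])]
      out[[paste0(m, "_median")]] <- if (length(v)) stats::median(v) else NA_real_
      out[[paste0(m, "_min")]] <- if (length(v)) min(v) else NA_real_
      out[[paste0(m, "_max")]] <- if (length(v)) max(v) else NA_real_
    }
    as.data.frame(out)
  })
  participants <- do.call(rbind, rows)
  grp <- unique(participants$group)
  groups <- data.frame(
    group = grp,
    n_participants = vapply(grp, function(g)
      sum(participants$group == g), numeric(1)),
    mean_median_acc_average = vapply(grp, function(g) {
      v <- participants$acc_average_median[participants$group == g]
      if (!length(v)) stop("empty group: ", g)
      mean(v)
    }, numeric(1)),
    row.names = NULL)
  list(participants = participants, groups = groups)
}

#' Write a session summary as a delimited table
#'
#' Writes the per-participant medians with min-max ranges and appends the
#' per-group mean rows, in a layout mirroring published multi-species
#' accuracy tables (per-eye accuracy median (min-max), data loss).
#'
#' @param summary result of \code{\link{summarize_sessions}}.
#' @param path output path (tab-separated text).
#' @export
write_summary_table <- function(summary, path) {
  p <- summary$participants
  fmt <- function(med, lo, hi) {
    ifelse(is.finite(med), sprintf("%.2f (%.1f-%.1f)", med, lo, hi), "")
  }
  col <- function(stub) {
    if (paste0(stub, "_median") %in% names(p))
      fmt(p[[paste0(stub, "_median")]], p[[paste0(stub, "_min")]],
          p[[paste0(stub, "_max")]])
    else rep("", nrow(p))
  }
  out <- data.frame(participant = p$participant, group = p$group,
                    acc_left = col("acc_left"), acc_right = col("acc_right"),
                    acc_average = col("acc_average"),
                    loss_left = col("loss_left"), loss_right = col("loss_right"))
  g <- summary$groups
  out <- rbind(out, data.frame(
    participant = paste0("Mean: ", sprintf("%.2f", g$mean_median_acc_average)),
    group = g$group, acc_left = "", acc_right = "",
    acc_average = sprintf("%.2f", g$mean_median_acc_average),
    loss_left = "", loss_right = ""))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
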