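#' Construct a binocular gaze stream
#'
#' The canonical in-memory representation of gaze data is a plain data
#' frame with one row per device sample and mandatory columns
#' \code{t_ms}, \code{left_x}, \code{left_y}, \code{left_valid},
#' \code{right_x}, \code{right_y}, \code{right_valid}. Positions are
#' normalized screen coordinates (top-left origin); validity flags are
#' 0/1. Optional columns carry 3D eye origins
#' (\code{left_origin_x/y/z}, \code{right_origin_x/y/z}), pupil
#' diameters (\code{left_pupil}, \code{right_pupil}, mm) and eye
#' openness fractions (\code{left_openness}, \code{right_openness}).
#' Positions of invalid samples are never interpreted.
#'
#' @param t_ms sample timestamps in milliseconds, strictly increasing.
#' @param left_x,left_y,right_x,right_y normalized gaze positions.
#' @param left_valid,right_valid validity flags (logical or 0/1).
#' @param ... further optional columns (recycled to length of t_ms).
#' @return a data frame of class \code{c("gaze_stream", "data.frame")}.
#' @export
gaze_stream <- function(t_ms, left_x, left_y, left_valid,
                        right_x, right_y, right_valid, ...) {
  df <- data.frame(t_ms = as.numeric(t_ms),
                   left_x = as.numeric(left_x), left_y = as.numeric(left_y),
                   left_valid = as.numeric(left_valid),
                   right_x = as.numeric(right_x), right_y = as.numeric(right_y),
                   right_valid = as.numeric(right_valid), ...)
  validate_gaze_stream(df)
}

#' Validate a gaze stream data frame
#'
#' @param df a data frame with the gaze stream columns.
#' @return the data frame, classed as a gaze stream.
#' @export
validate_gaze_stream <- function(df) {
  need <- c("t_ms", "left_x", "left_y", "left_valid",
            "right_x", "right_y", "right_valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gaze stream missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) > 1 && any(diff(df$t_ms) <= 0)) {
    stop("gaze stream timestamps must be strictly increasing")
  }
  for (op in c("left_openness", "right_openness")) {
    if (op %in% names(df)) {
      v <- df[[op]][is.finite(df[[op]])]
      if (length(v) && (any(v < 0) || any(v > 1))) stop(op, " must lie in [0, 1]")
    }
  }
  class(df) <- unique(c("gaze_stream", class(df)))
  df
}

#' Binocular average of gaze samples
#'
#' Averages the two eyes' positions per sample; with a single valid eye
#' that eye's position is used; with neither, the result is NA. This is
#' the "averaged over the left and right eyes" signal used by the
#' automated controllers.
#'
#' @param stream a gaze stream data frame (one or more rows).
#' @return an n x 2 matrix of positions (NA rows where no eye is valid).
#' @export
binocular_average <- function(stream) {
  lv <- stream$left_valid > 0
  rv <- stream$right_valid > 0
  n <- length(lv)
  x <- ifelse(lv & rv, (stream$left_x + stream$right_x) / 2,
              ifelse(lv, stream$left_x, ifelse(rv, stream$right_x, NA_real_)))
  y <- ifelse(lv & rv, (stream$left_y + stream$right_y) / 2,
              ifelse(lv, stream$left_y, ifelse(rv, stream$right_y, NA_real_)))
  cbind(x = as.numeric(x), y = as.numeric(y))
}

#' Temporal moving-average filter
#'
#' Averages each eye's valid samples over the trailing time window and
#' combines the per-eye means into a binocular position. Invalid samples
#' contribute nothing (their stored positions are ignored).
#'
#' @param stream a gaze stream data frame.
#' @param window_ms averaging window in milliseconds (> 0).
#' @param now reference time; defaults to the last sample's timestamp.
#'   The window is \code{(now - window_ms, now]}.
#' @return a list with \code{pos} (binocular position or NULL),
#'   \code{left}, \code{right} (per-eye means or NULL) and
#'   \code{n_valid} (samples contributing to either eye).
#' @export
moving_average_filter <- function(stream, window_ms, now = NULL) {
  stopifnot(window_ms > 0)
  if (nrow(stream) == 0) {
    return(list(pos = NULL, left = NULL, right = NULL, n_valid = 0L))
  }
  if (is.null(now)) now <- stream$t_ms[nrow(stream)]
  sel <- stream$t_ms > now - window_ms & stream$t_ms <= now
  w <- stream[sel, , drop = FALSE]
  lv <- w$left_valid > 0
  rv <- w$right_valid > 0
  left <- if (any(lv)) c(mean(w$left_x[lv]), mean(w$left_y[lv])) else NULL
  right <- if (any(rv)) c(mean(w$right_x[rv]), mean(w$right_y[rv])) else NULL
  pos <- if (!is.null(left) && !is.null(right)) (left + right) / 2
         else if (!is.null(left)) left else right
  list(pos = pos, left = left, right = right,
       n_valid = sum(lv | rv))
}

#' Trailing gaze history per eye
#'
#' Returns the valid samples of each eye within the trailing window,
#' ordered by time — the data behind the operator-screen gaze trail
#' display (shown for a configurable window, 500 ms by default).
#'
#' @inheritParams moving_average_filter
#' @return a list with elements \code{left} and \code{right}, each a data
#'   frame with columns \code{t_ms}, \code{x}, \code{y}.
#' @export
gaze_history <- function(stream, window_ms = 500, now = NULL) {
  stopifnot(window_ms > 0)
  if (nrow(stream) == 0) {
    empty <- data.frame(t_ms = numeric(0), x = numeric(0), y = numeric(0))
    return(list(left = empty, right = empty))
  }
  if (is.null(now)) now <- stream$t_ms[nrow(stream)]
  sel <- stream$t_ms > now - window_ms & stream$t_ms <= now
  w <- stream[sel, , drop = FALSE]
  one_eye <- function(prefix) {
    v <- w[[paste0(prefix, "_valid")]] > 0
    data.frame(t_ms = w$t_ms[v],
               x = w[[paste0(prefix, "_x")]][v],
               y = w[[paste0(prefix, "_y")]][v])
  }
  list(left = one_eye("left"), right = one_eye("right"))
}

#' Write a gaze stream to a delimited log file
#'
#' Plain comma-separated text with a header row; one row per binocular
#' sample. Readable back with \code{\link{read_gaze_log}}.
#'
#' @param stream a gaze stream data frame.
#' @param path output file path.
#' @export
write_gaze_log <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gaze stream from a delimited log file
#'
#' @param path file path of a log written by \code{\link{write_gaze_log}}
#'   (or any delimited file with the mandatory columns; missing optional
#'   columns are permitted).
#' @return a gaze stream data frame.
#' @export
read_gaze_log <- function(path) {
  df <- utils::read.csv(path)
  validate_gaze_stream(df)
}
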