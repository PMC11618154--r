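#' Calibration data container
#'
#' Accumulates, per calibration target, the raw (uncalibrated) gaze
#' positions each eye produced while the target was shown. Only samples
#' flagged valid should ever be added; each point id appears at most once
#' (re-adding a point replaces its data, mirroring point recollection).
#'
#' @return an empty object of class \code{calibration_data}.
#' @export
calibration_data <- function() {
  structure(list(points = list()), class = "calibration_data")
}

#' @rdname calibration_data
#' @param data a \code{calibration_data} object.
#' @param id integer point id.
#' @param target the point's position, normalized screen coordinates.
#' @param left,right n x 2 matrices of valid raw gaze positions per eye
#'   (possibly zero rows).
#' @export
add_calibration_samples <- function(data, id, target, left, right) {
  stopifnot(inherits(data, "calibration_data"))
  data$points[[as.character(id)]] <- list(
    id = as.integer(id), target = as.numeric(target),
    left = as_point_matrix(left), right = as_point_matrix(right))
  data
}

#' @export
print.calibration_data <- function(x, ...) {
  cat(sprintf("<calibration_data: %d points>\n", length(x$points)))
  for (p in x$points) {
    cat(sprintf("  point %d at (%.2f, %.2f): %d left / %d right samples\n",
                p$id, p$target[1], p$target[2], nrow(p$left), nrow(p$right)))
  }
  invisible(x)
}

# ---- mapping families ------------------------------------------------------
# a mapping is a 2 x 3 matrix M: calibrated = M %*% c(x, y, 1)

identity_mapping <- function() cbind(diag(2), c(0, 0))

apply_mapping <- function(M, pos) {
  m <- as_point_matrix(pos)
  out <- cbind(M[1, 1] * m[, 1] + M[1, 2] * m[, 2] + M[1, 3],
               M[2, 1] * m[, 1] + M[2, 2] * m[, 2] + M[2, 3])
  if (is.null(dim(pos))) drop(out) else out
}

fit_translation <- function(X, Y) {
  t <- colMeans(Y) - colMeans(X)
  cbind(diag(2), t)
}

# similarity: x' = a x - b y + tx ; y' = b x + a y + ty
fit_similarity <- function(X, Y) {
  n <- nrow(X)
  A <- rbind(cbind(X[, 1], -X[, 2], rep(1, n), rep(0, n)),
             cbind(X[, 2],  X[, 1], rep(0, n), rep(1, n)))
  b <- c(Y[, 1], Y[, 2])
  cf <- stats::lm.fit(A, b)$coefficients
  matrix(c(cf[1], -cf[2], cf[3],
           cf[2],  cf[1], cf[4]), nrow = 2, byrow = TRUE)
}

fit_affine <- function(X, Y) {
  A <- cbind(X, 1)
  cf <- stats::lm.fit(A, Y)$coefficients  # 3 x 2
  rbind(c(cf[1, 1], cf[2, 1], cf[3, 1]),
        c(cf[1, 2], cf[2, 2], cf[3, 2]))
}

# are the target centroids collinear (within tolerance)?
collinear <- function(P, tol = 1e-9) {
  if (nrow(P) < 3) return(TRUE)
  P0 <- sweep(P, 2, colMeans(P))
  s <- svd(P0)$d
  s[2] <= tol * max(s[1], 1)
}

fit_one_eye <- function(pts, min_samples, trim) {
  usable <- Filter(function(p) nrow(p$raw) >= min_samples, pts)
  if (!length(usable)) {
    return(list(ok = FALSE, reason = "no usable points"))
  }
  X <- do.call(rbind, lapply(usable, `[[`, "raw"))
  Y <- do.call(rbind, lapply(usable, function(p)
    matrix(p$target, nrow(p$raw), 2, byrow = TRUE)))
  targets <- do.call(rbind, lapply(usable, `[[`, "target"))
  dist_targets <- unique(round(targets, 9))
  notes <- character(0)
  family <- if (nrow(dist_targets) >= 3 && !collinear(dist_targets)) "affine"
            else if (nrow(dist_targets) >= 2) "similarity"
            else "translation"
  if (nrow(dist_targets) >= 3 && family != "affine") {
    notes <- c(notes, "collinear targets: fell back to similarity")
  }
  if (nrow(dist_targets) == 1 && length(usable) > 1) {
    notes <- c(notes, "coincident targets: fell back to translation")
  }
  fit_fun <- switch(family, affine = fit_affine,
                    similarity = fit_similarity, translation = fit_translation)
  M <- fit_fun(X, Y)
  if (trim && nrow(X) >= 5) {
    r <- sqrt(rowSums((apply_mapping(M, X) - Y)^2))
    keep <- r <= stats::quantile(r, 0.8)
    if (sum(keep) >= 2) M <- fit_fun(X[keep, , drop = FALSE], Y[keep, , drop = FALSE])
  }
  dimnames(M) <- NULL
  res <- apply_mapping(M, X) - Y
  list(ok = TRUE, M = M, family = family,
       points_used = unname(vapply(usable, `[[`, integer(1), "id")),
       residual_rms = sqrt(mean(rowSums(res^2))),
       notes = notes)
}

#' Fit a per-eye calibration mapping
#'
#' Stand-in for the calibration an eye tracker computes internally: a
#' least-squares mapping from raw (uncalibrated) to true screen
#' coordinates, fitted separately per eye on the data collected at the
#' calibration targets. The mapping family degrades gracefully with the
#' number of usable points: one point gives a pure translation, two
#' distinct points a similarity transform (translation, rotation, uniform
#' scale), three or more non-collinear points a full affine transform.
#' A point is usable for an eye when it holds at least
#' \code{min_samples_per_point} valid samples for that eye.
#'
#' @param data a \code{\link{calibration_data}} object.
#' @param eyes which eye(s) to calibrate: "both", "left" or "right".
#' @param base an existing \code{calibration_result} whose mappings are
#'   retained for eyes not being (re)calibrated — a monocular fit never
#'   touches the other eye. Defaults to the identity default calibration.
#' @param min_samples_per_point minimum valid samples for a point to be
#'   usable (default 10).
#' @param max_residual_rms sanity bound on the fit residual RMS in
#'   normalized screen units; a larger residual fails the calibration
#'   (the stand-in's proxy for the tracker declaring a calibration
#'   failed). The 0.05 default is a few times the residual expected from
#'   typical fixation noise, so contaminated collections are rejected
#'   and the procedure's retry path engages.
#' @param trim if TRUE, refit once after dropping the worst 20\% of
#'   residuals (simple outlier robustness; off by default).
#' @return an object of class \code{calibration_result} with
#'   \code{status} ("success"/"failure"), per-eye \code{mappings} (2 x 3
#'   matrices), \code{family}, \code{points_used}, \code{residual_rms},
#'   and \code{failure_reason} when failed. Failure is reported as a
#'   result, never as an exception.
#' @examples
#' d <- calibration_data()
#' raw <- matrix(rep(c(0.45, 0.52), 12), ncol = 2, byrow = TRUE)
#' d <- add_calibration_samples(d, 1, c(0.5, 0.5), raw, raw)
#' fit_calibration(d)
#' @export
fit_calibration <- function(data, eyes = c("both", "left", "right"),
                            base = default_calibration(),
                            min_samples_per_point = 10,
                            max_residual_rms = 0.05, trim = FALSE) {
  eyes <- match.arg(eyes)
  which_eyes <- if (eyes == "both") c("left", "right") else eyes
  out <- list(status = "failure", eyes = eyes,
              mappings = base$mappings, family = base$family,
              points_used = list(left = integer(0), right = integer(0)),
              residual_rms = list(left = NA_real_, right = NA_real_),
              default = FALSE, failure_reason = NULL, notes = character(0))
  class(out) <- "calibration_result"
  if (!inherits(data, "calibration_data") || !length(data$points)) {
    out$failure_reason <- "no calibration data"
    return(out)
  }
  ok_any <- FALSE
  for (e in which_eyes) {
    pts <- lapply(data$points, function(p)
      list(id = p$id, target = p$target, raw = p[[e]]))
    f <- fit_one_eye(pts, min_samples_per_point, trim)
    if (!f$ok) {
      out$notes <- c(out$notes, paste0(e, ": ", f$reason))
      next
    }
    if (f$residual_rms > max_residual_rms) {
      out$notes <- c(out$notes, sprintf(
        "%s: residual RMS %.4f exceeds bound %.4f", e, f$residual_rms,
        max_residual_rms))
      next
    }
    out$mappings[[e]] <- f$M
    out$family[[e]] <- f$family
    out$points_used[[e]] <- sort(f$points_used)
    out$residual_rms[[e]] <- f$residual_rms
    out$notes <- c(out$notes, f$notes)
    ok_any <- TRUE
  }
  if (ok_any) {
    out$status <- "success"
  } else {
    out$failure_reason <- paste(out$notes, collapse = "; ")
    if (!nzchar(out$failure_reason)) out$failure_reason <- "fit failed"
  }
  out
}

#' Default (identity) calibration
#'
#' The uncalibrated state: an identity mapping for both eyes, based on no
#' collected data. Always available, e.g. as the initial active
#' calibration of a session or as a snapshot-menu entry.
#'
#' @return a successful \code{calibration_result} flagged as default.
#' @export
default_calibration <- function() {
  structure(list(
    status = "success", eyes = "both",
    mappings = list(left = identity_mapping(), right = identity_mapping()),
    family = list(left = "identity", right = "identity"),
    points_used = list(left = integer(0), right = integer(0)),
    residual_rms = list(left = 0, right = 0),
    default = TRUE, failure_reason = NULL, notes = character(0)),
    class = "calibration_result")
}

#' Apply a fitted calibration to raw gaze positions
#'
#' @param raw raw position(s): \code{c(x, y)} or an n x 2 matrix.
#' @param result a successful \code{calibration_result}.
#' @param eye "left" or "right".
#' @return calibrated position(s), same shape as the input.
#' @export
apply_calibration <- function(raw, result, eye = c("left", "right")) {
  eye <- match.arg(eye)
  stopifnot(inherits(result, "calibration_result"))
  if (!identical(result$status, "success")) stop("calibration did not succeed")
  M <- result$mappings[[eye]]
  if (is.null(M)) stop("eye '", eye, "' is not calibrated")
  apply_mapping(M, raw)
}

#' @export
predict.calibration_result <- function(object, newdata,
                                       eye = c("left", "right"), ...) {
  apply_calibration(newdata, object, eye)
}

#' @export
coef.calibration_result <- function(object, ...) object$mappings

#' @export
print.calibration_result <- function(x, ...) {
  lab <- if (isTRUE(x$default)) "default calibration" else
    sprintf("calibration %s", x$status)
  cat(sprintf("<%s (%s eye%s)>\n", lab, x$eyes,
              if (x$eyes == "both") "s" else ""))
  for (e in c("left", "right")) {
    if (is.null(x$mappings[[e]])) next
    cat(sprintf("  %-5s %-11s points used: %s  residual RMS %.4g\n",
                e, x$family[[e]],
                if (length(x$points_used[[e]]))
                  paste(x$points_used[[e]], collapse = ",") else "-",
                x$residual_rms[[e]]))
  }
  if (!is.null(x$failure_reason)) cat("  reason:", x$failure_reason, "\n")
  invisible(x)
}

# ---- snapshots -------------------------------------------------------------

#' Calibration snapshots
#'
#' A snapshot stores a computed calibration under a label, optionally
#' together with the validation report collected for it, so the operator
#' can attempt further calibrations and restore an earlier one if those
#' turn out worse.
#'
#' @param label unique snapshot label.
#' @param result a \code{calibration_result}.
#' @param report optional \code{\link{session_report}} of the validation
#'   performed under this calibration.
#' @return an object of class \code{calibration_snapshot}.
#' @export
calibration_snapshot <- function(label, result, report = NULL) {
  stopifnot(is.character(label), length(label) == 1,
            inherits(result, "calibration_result"))
  structure(list(label = label, result = result, report = report),
            class = "calibration_snapshot")
}

calibration_to_list <- function(x) {
  list(status = x$status, eyes = x$eyes,
       mappings = lapply(x$mappings, function(m)
         if (is.null(m)) NULL else as.numeric(m)),
       family = x$family,
       points_used = lapply(x$points_used, as.integer),
       residual_rms = x$residual_rms,
       default = x$default, failure_reason = x$failure_reason,
       notes = as.list(x$notes))
}

calibration_from_list <- function(l) {
  structure(list(
    status = l$status, eyes = l$eyes,
    mappings = lapply(l$mappings, function(v)
      if (is.null(v)) NULL else matrix(as.numeric(v), nrow = 2)),
    family = l$family,
    points_used = lapply(l$points_used, as.integer),
    residual_rms = lapply(l$residual_rms, as.numeric),
    default = isTRUE(l$default),
    failure_reason = if (is.null(l$failure_reason)) NULL else l$failure_reason,
    notes = as.character(unlist(l$notes))),
    class = "calibration_result")
}

#' Write / read a calibration snapshot as JSON
#'
#' Snapshot files are plain structured text and reloadable across
#' sessions, so a previous calibration can be preloaded when a new
#' session starts.
#'
#' @param snapshot a \code{\link{calibration_snapshot}}.
#' @param path file path.
#' @export
write_snapshot <- function(snapshot, path) {
  jsonlite::write_json(
    list(label = snapshot$label,
         result = calibration_to_list(snapshot$result),
         report = if (is.null(snapshot$report)) NULL else {
           r <- unclass(snapshot$report)
           r$points <- lapply(r$points, unclass)
           r
         }),
    path, auto_unbox = TRUE, digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rep <- NULL
  if (!is.null(x$report)) {
    rep <- x$report
    rep$points <- lapply(rep$points, function(p) {
      p$target <- as.numeric(unlist(p$target))
      class(p) <- "point_quality"
      p
    })
    rep$points_with_data <- as.integer(unlist(rep$points_with_data))
    class(rep) <- "session_report"
  }
  calibration_snapshot(x$label, calibration_from_list(x$result), rep)
}
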