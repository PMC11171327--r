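#' Construct a tumor-volume trajectory
#'
#' A trajectory is one animal's serial caliper tumor-volume record, measured
#' from treatment start (day 0).  Volumes are in cubic millimeters; an exactly
#' zero volume records a tumor that could not be measured (disappeared).
#'
#' @param days Integer-valued measurement days, strictly increasing, first
#'   element 0 (treatment start).
#' @param volumes Tumor volumes in mm^3, non-negative, aligned to `days`.
#'   The baseline `volumes[1]` must be positive (animals are enrolled once the
#'   tumor reaches a measurable size).
#' @param animal_id,arm,model_id Identifier strings.
#' @param treatment_end_day Day on which the last scheduled dose is given.
#'   Used by the maintained-complete-response rule, which only counts
#'   unmeasurable readings recorded after treatment has been completed.
#' @return An object of class `"trajectory"`: a list with fields `model_id`,
#'   `animal_id`, `arm`, `days`, `volumes`, `treatment_end_day`.
#' @examples
#' tr <- trajectory(days = c(0, 7, 14), volumes = c(100, 300, 600))
#' event_time(tr)
#' @export
trajectory <- function(days, volumes, animal_id = "a1", arm = "arm",
                       model_id = "model", treatment_end_day = 7) {
  days <- as.numeric(days)
  volumes <- as.numeric(volumes)
  if (length(days) != length(volumes))
    stop("`days` and `volumes` must have equal length", call. = FALSE)
  if (length(days) < 1L)
    stop("a trajectory needs at least one measurement", call. = FALSE)
  if (days[1] != 0)
    stop("the first measurement must be at day 0 (treatment start)",
         call. = FALSE)
  if (any(diff(days) <= 0))
    stop("`days` must be strictly increasing", call. = FALSE)
  if (anyNA(volumes) || any(volumes < 0))
    stop("`volumes` must be non-negative and non-missing", call. = FALSE)
  if (volumes[1] <= 0)
    stop("baseline volume (day 0) must be positive", call. = FALSE)
  structure(
    list(model_id = as.character(model_id),
         animal_id = as.character(animal_id),
         arm = as.character(arm),
         days = days, volumes = volumes,
         treatment_end_day = as.numeric(treatment_end_day)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Tumor trajectory: model %s, animal %s, arm %s\n",
              x$model_id, x$animal_id, x$arm))
  cat(sprintf("  %d measurements over days %g-%g; baseline %.1f mm^3; treatment ends day %g\n",
              length(x$days), min(x$days), max(x$days), x$volumes[1],
              x$treatment_end_day))
  invisible(x)
}

#' Read tumor-volume trajectories from CSV
#'
#' Expects columns `model,animal_id,arm,day,volume_mm3` (header required,
#' `.` decimal separator).  Rows are grouped by (model, animal) and sorted by
#' day; a duplicated (animal, day) pair is an error.
#'
#' @param path Path to a CSV file.
#' @param treatment_end_day Treatment-end day attached to every trajectory
#'   (single value, or a named vector keyed by arm).
#' @return A list of [trajectory()] objects.
#' @export
read_trajectories <- function(path, treatment_end_day = 7) {
  if (!file.exists(path))
    stop(sprintf("trajectory file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("model", "animal_id", "arm", "day", "volume_mm3")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("trajectory CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!is.numeric(df$volume_mm3)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$volume_mm3))))[1]
    stop(sprintf("non-numeric volume_mm3 at data row %d", bad), call. = FALSE)
  }
  if (!is.numeric(df$day))
    stop("column `day` must be numeric", call. = FALSE)
  key <- interaction(df$model, df$animal_id, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$day), , drop = FALSE]
    if (anyDuplicated(g$day)) {
      d <- g$day[duplicated(g$day)][1]
      stop(sprintf("duplicate measurement day %g for animal %s (model %s)",
                   d, g$animal_id[1], g$model[1]), call. = FALSE)
    }
    ted <- if (length(treatment_end_day) > 1L)
      treatment_end_day[[g$arm[1]]] else treatment_end_day
    trajectory(days = g$day, volumes = g$volume_mm3,
               animal_id = g$animal_id[1], arm = g$arm[1],
               model_id = g$model[1], treatment_end_day = ted)
  })
  names(out) <- NULL
  out
}

#' Write trajectories to the CSV interchange format
#'
#' @param trajs A list of [trajectory()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    data.frame(model = tr$model_id, animal_id = tr$animal_id, arm = tr$arm,
               day = tr$days, volume_mm3 = tr$volumes,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Time to the tumor-quadrupling event
#'
#' The event is the tumor volume reaching 400% (4x) of its day-0 value.  When
#' the first measurement at or above the threshold does not hit it exactly,
#' the event time is interpolated between the measurements directly preceding
#' and following the crossing, assuming log-linear (exponential) growth over
#' the interval:
#' \deqn{t = t_{i-1} + (t_i - t_{i-1}) \frac{\log(4V_0/V_{i-1})}{\log(V_i/V_{i-1})}.}
#' Animals whose tumor never quadruples are censored at their last
#' measurement day.
#'
#' @param traj A [trajectory()].
#' @param floor_volume Volume substituted for an unmeasurable (zero) reading
#'   when it is the interpolation anchor preceding a regrowth crossing, so the
#'   logarithm stays defined.  Default 1 mm^3.
#' @return A list of class `"event_result"` with fields `time_days`, `status`
#'   (`"event"` or `"censored"`), and `threshold_volume` (4 x baseline).
#' @examples
#' event_time(trajectory(c(0, 7, 14), c(100, 300, 600)))  # ~9.90 days
#' @export
event_time <- function(traj, floor_volume = 1) {
  stopifnot(inherits(traj, "trajectory"))
  v <- traj$volumes
  t <- traj$days
  threshold <- 4 * v[1]
  idx <- which(v >= threshold)
  if (!length(idx)) {
    res <- list(time_days = t[length(t)], status = "censored",
                threshold_volume = threshold)
    return(structure(res, class = "event_result"))
  }
  i <- idx[1]
  if (i == 1L || v[i] == threshold || v[i - 1] >= threshold || v[i] == v[i - 1]) {
    time <- if (i > 1L && v[i - 1] >= threshold) t[i - 1] else t[i]
  } else {
    v_prev <- v[i - 1]
    if (v_prev <= 0) v_prev <- floor_volume   # regrowth from unmeasurable
    time <- t[i - 1] +
      (t[i] - t[i - 1]) * log(threshold / v_prev) / log(v[i] / v_prev)
  }
  structure(list(time_days = time, status = "event",
                 threshold_volume = threshold),
            class = "event_result")
}

#' @export
print.event_result <- function(x, ...) {
  cat(sprintf("%s at day %.2f (threshold %.1f mm^3)\n",
              x$status, x$time_days, x$threshold_volume))
  invisible(x)
}

#' Volumes relative to baseline
#'
#' @param traj A [trajectory()].
#' @return Numeric vector `V_t / V_0`; the first element is 1.
#' @export
relative_volumes <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$volumes / traj$volumes[1]
}

#' Compute event results for a list of trajectories
#'
#' Convenience wrapper mapping [event_time()] over a cohort and returning a
#' tidy table in the event CSV interchange layout.
#'
#' @param trajs List of [trajectory()] objects.
#' @param floor_volume Passed to [event_time()].
#' @return A data.frame with columns `model`, `animal_id`, `arm`,
#'   `time_days`, `status`.
#' @export
event_table <- function(trajs, floor_volume = 1) {
  rows <- lapply(trajs, function(tr) {
    ev <- event_time(tr, floor_volume = floor_volume)
    data.frame(model = tr$model_id, animal_id = tr$animal_id, arm = tr$arm,
               time_days = ev$time_days, status = ev$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
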