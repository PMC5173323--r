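# Per-track and per-cohort motility statistics.
#
# Definitions (units: µm, minutes):
#   instantaneous velocity - displacement between consecutive frames / dt
#   mean velocity          - path length / elapsed duration
#   arrest coefficient     - % of track time spent in steps with
#                            instantaneous velocity strictly below the
#                            threshold (default 2 µm/min); each step is
#                            weighted by its own dt, so irregular sampling
#                            is handled
#   confinement ratio      - max displacement from the first position /
#                            path length (undefined when path length is 0)
#   immotile               - mean velocity strictly below 2 µm/min

step_lengths <- function(pos) {
  d <- diff(pos)
  sqrt(rowSums(d * d))
}

#' Instantaneous velocities of a track
#'
#' One speed per inter-frame step: Euclidean displacement divided by the
#' time difference.
#'
#' @param track A [track()] with at least 2 points.
#' @param project_2d Drop the z coordinate of 3-D tracks first (default
#'   `TRUE`; displayed intravital analyses are planar).
#' @return Numeric vector of speeds in µm/min, length `n_points - 1`.
#' @export
instantaneous_velocities <- function(track, project_2d = TRUE) {
  stopifnot(inherits(track, "track"))
  if (n_points(track) < 2L)
    stop("track '", track$id,
         "': at least 2 points are needed for velocities", call. = FALSE)
  if (project_2d) track <- project_2d_track(track)
  step_lengths(track$pos) / diff(track$t)
}

#' Motility metrics for one track
#'
#' @param track A [track()] with at least 2 points.
#' @param arrest_threshold Speed (µm/min) below which a step counts as
#'   arrested (strict `<`).
#' @param immotile_threshold Mean velocity (µm/min) below which the cell is
#'   classed immotile (strict `<`).
#' @param project_2d Drop z from 3-D tracks before computing (default).
#' @return A one-row `data.frame`: `track_id`, `duration` (min), `n_frames`,
#'   `path_length` (µm), `max_displacement` (µm), `mean_velocity` (µm/min),
#'   `confinement_ratio` (`NA` for a zero-path track), `arrest_coefficient`
#'   (%), `immotile`.
#' @examples
#' tr <- track("a", t = seq(0, 2, by = 0.5),
#'             pos = cbind(x = c(0, 1, 2, 3, 4), y = 0))
#' track_metrics(tr)
#' @export
track_metrics <- function(track, arrest_threshold = 2,
                          immotile_threshold = 2, project_2d = TRUE) {
  stopifnot(inherits(track, "track"))
  if (n_points(track) < 2L)
    stop("track '", track$id, "': at least 2 points are needed",
         call. = FALSE)
  if (project_2d) track <- project_2d_track(track)
  dt <- diff(track$t)
  duration <- track$t[length(track$t)] - track$t[1L]
  if (duration <= 0)
    stop("track '", track$id, "': zero duration", call. = FALSE)
  steps <- step_lengths(track$pos)
  speeds <- steps / dt
  path_length <- sum(steps)
  disp <- sweep(track$pos, 2L, track$pos[1L, ])
  max_displacement <- max(sqrt(rowSums(disp * disp)))
  mean_velocity <- path_length / duration
  arrest <- 100 * sum(dt[speeds < arrest_threshold]) / duration
  data.frame(
    track_id = track$id,
    duration = duration,
    n_frames = n_points(track),
    path_length = path_length,
    max_displacement = max_displacement,
    mean_velocity = mean_velocity,
    confinement_ratio = if (path_length > 0)
      max_displacement / path_length else NA_real_,
    arrest_coefficient = arrest,
    immotile = mean_velocity < immotile_threshold,
    stringsAsFactors = FALSE
  )
}

#' Motility metrics for a cohort
#'
#' Computes [track_metrics()] for every track with at least `min_points`
#' points (shorter tracks are excluded with a logged count) and summarises
#' the cohort treating each cell as one observation.
#'
#' @inheritParams track_metrics
#' @param ts A `trackset`.
#' @param min_points Minimum points for a track to be retained (default 2).
#' @return A `cohort_metrics` list: `metrics` (one row per retained track),
#'   `summary` (per metric: `n`, `mean`, `sd`, `sem`; confinement-ratio
#'   rows count tracks whose ratio is defined, with `n_undefined` noting
#'   zero-path exclusions), `n_excluded`.
#' @export
cohort_metrics <- function(ts, arrest_threshold = 2, immotile_threshold = 2,
                           min_points = 2L, project_2d = TRUE) {
  stopifnot(inherits(ts, "trackset"))
  keep <- vapply(ts$tracks, function(tr) n_points(tr) >= max(2L, min_points),
                 logical(1))
  n_excluded <- sum(!keep)
  if (n_excluded > 0L)
    message("cohort_metrics: excluded ", n_excluded,
            " track(s) with fewer than ", max(2L, min_points), " points")
  retained <- ts$tracks[keep]
  if (length(retained) == 0L)
    stop("no tracks left after exclusions", call. = FALSE)
  metrics <- do.call(rbind, lapply(retained, track_metrics,
                                   arrest_threshold = arrest_threshold,
                                   immotile_threshold = immotile_threshold,
                                   project_2d = project_2d))
  rownames(metrics) <- NULL
  cols <- c("mean_velocity", "confinement_ratio", "arrest_coefficient",
            "path_length", "max_displacement")
  summary <- do.call(rbind, lapply(cols, function(k) {
    v <- metrics[[k]]
    und <- sum(is.na(v))
    v <- v[!is.na(v)]
    s <- if (length(v) > 1L) stats::sd(v) else 0
    data.frame(metric = k, n = length(v), mean = mean(v), sd = s,
               sem = s / sqrt(length(v)), n_undefined = und,
               stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics, summary = summary,
                 n_excluded = n_excluded,
                 n_immotile = sum(metrics$immotile)),
            class = "cohort_metrics")
}

#' @export
print.cohort_metrics <- function(x, ...) {
  cat(sprintf("<cohort_metrics> %d cells (%d excluded, %d immotile)\n",
              nrow(x$metrics), x$n_excluded, x$n_immotile))
  s <- x$summary
  units <- c(mean_velocity = "um/min", confinement_ratio = "",
             arrest_coefficient = "%", path_length = "um",
             max_displacement = "um")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %.2f +/- %.2f %s (n = %d cells%s)\n",
                s$metric[i], s$mean[i], s$sd[i], units[[s$metric[i]]],
                s$n[i],
                if (s$n_undefined[i] > 0)
                  sprintf(", %d undefined", s$n_undefined[i]) else ""))
  }
  invisible(x)
}
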