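# Mean-displacement-versus-sqrt(time) analysis and the random-walk
# criterion: a cell population whose mean displacement from origin grows
# linearly in sqrt(t) (OLS R-squared > 0.95) is classed as executing a
# random walk.

#' Displacement from the track origin
#'
#' Euclidean distance from each position to the track's first position.
#'
#' @param track A [track()].
#' @param project_2d Drop z from 3-D tracks first (default).
#' @return A `data.frame` with `t_elapsed` (min, starting at 0) and
#'   `displacement` (µm; first entry 0).
#' @export
displacement_from_origin <- function(track, project_2d = TRUE) {
  stopifnot(inherits(track, "track"))
  if (project_2d) track <- project_2d_track(track)
  d <- sweep(track$pos, 2L, track$pos[1L, ])
  data.frame(t_elapsed = track$t - track$t[1L],
             displacement = sqrt(rowSums(d * d)))
}

#' Cohort mean-displacement curve
#'
#' On the common time grid (multiples of the frame interval, up to the
#' longest track), averages each cell's displacement from its own first
#' position over the cells still observed at that elapsed time. Cells
#' contribute only while observed; nothing is imputed.
#'
#' @param ts A `trackset` with a uniform frame interval.
#' @param project_2d Drop z from 3-D tracks first (default).
#' @return An `md_curve` data frame: `t_min`, `sqrt_t` (min^1/2), `md_um`,
#'   `n_cells` (non-increasing in time).
#' @examples
#' ts <- simulate_trackset(sim_config("random_walk", list(step = 2),
#'                                    n_tracks = 50, n_frames = 21, seed = 3))
#' head(mean_displacement_curve(ts))
#' @export
mean_displacement_curve <- function(ts, project_2d = TRUE) {
  stopifnot(inherits(ts, "trackset"))
  if (n_tracks(ts) == 0L) stop("empty trackset", call. = FALSE)
  dt <- ts$frame_interval
  if (is.null(dt))
    stop("tracks are irregularly sampled; resample onto a uniform grid ",
         "before computing a mean-displacement curve", call. = FALSE)
  disp <- lapply(ts$tracks, displacement_from_origin,
                 project_2d = project_2d)
  max_k <- max(vapply(disp, nrow, integer(1))) - 1L
  grid <- (0:max_k) * dt
  md <- numeric(max_k + 1L)
  n_cells <- integer(max_k + 1L)
  for (k in 0:max_k) {
    vals <- unlist(lapply(disp, function(d)
      if (nrow(d) > k) d$displacement[k + 1L] else NULL))
    md[k + 1L] <- mean(vals)
    n_cells[k + 1L] <- length(vals)
  }
  structure(data.frame(t_min = grid, sqrt_t = sqrt(grid), md_um = md,
                       n_cells = n_cells),
            class = c("md_curve", "data.frame"))
}

#' Fit the mean-displacement curve against sqrt(time)
#'
#' Ordinary least squares (free intercept) of mean displacement against the
#' square root of elapsed time, over grid points with at least
#' `min_cells_per_point` contributing cells. The t = 0 point (md = 0 by
#' construction) is excluded so it cannot anchor the fit. A population is
#' classed as random-walking when R-squared strictly exceeds
#' `r2_threshold`.
#'
#' @param curve An `md_curve` from [mean_displacement_curve()].
#' @param min_cells_per_point Minimum cells a grid point needs to enter the
#'   fit (default 5); guards noisy late times where short tracks have
#'   dropped out.
#' @param r2_threshold Classification threshold on R-squared (default
#'   0.95).
#' @return An `rw_fit` list: `slope` (µm·min^-1/2), `intercept` (µm),
#'   `r_squared`, `is_random_walk`, `n_points`. A curve with zero variance
#'   in md (fully saturated) gets `r_squared = 0`.
#' @export
fit_md_sqrt_time <- function(curve, min_cells_per_point = 5L,
                             r2_threshold = 0.95) {
  stopifnot(inherits(curve, "data.frame"),
            all(c("t_min", "sqrt_t", "md_um", "n_cells") %in% names(curve)))
  use <- curve$t_min > 0 & curve$n_cells >= min_cells_per_point
  pts <- curve[use, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("fewer than 3 usable grid points (need n_cells >= ",
         min_cells_per_point, " beyond t = 0)", call. = FALSE)
  if (stats::var(pts$md_um) == 0) {
    fit <- list(slope = 0, intercept = pts$md_um[1L], r_squared = 0)
  } else {
    m <- stats::lm(md_um ~ sqrt_t, data = pts)
    r2 <- 1 - sum(stats::residuals(m)^2) /
      sum((pts$md_um - mean(pts$md_um))^2)
    fit <- list(slope = unname(stats::coef(m)[2L]),
                intercept = unname(stats::coef(m)[1L]),
                r_squared = r2)
  }
  structure(c(fit,
              list(is_random_walk = fit$r_squared > r2_threshold,
                   n_points = nrow(pts),
                   r2_threshold = r2_threshold)),
            class = "rw_fit")
}

#' @export
print.rw_fit <- function(x, ...) {
  cat(sprintf(paste0("<rw_fit> md = %.3f + %.3f * sqrt(t) um, R^2 = %.4f ",
                     "(%d points)\n  %srandom walk (criterion R^2 > %g)\n"),
              x$intercept, x$slope, x$r_squared, x$n_points,
              if (x$is_random_walk) "" else "not classed as ",
              x$r2_threshold))
  invisible(x)
}
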