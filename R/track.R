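#' Construct a single cell track
#'
#' A track is one cell's time-ordered trajectory: strictly increasing
#' timestamps in minutes and matching 2-D or 3-D positions in micrometres,
#' plus optional metadata labels (e.g. group, day, region, phenotype).
#'
#' @param id Track identifier (coerced to character).
#' @param t Numeric vector of elapsed times in minutes, strictly increasing.
#' @param pos Numeric matrix (or data.frame) of positions in µm, one row per
#'   timepoint, 2 or 3 columns.
#' @param labels Named list (or named character vector) of metadata labels.
#' @return An object of class `track`.
#' @examples
#' tr <- track("cell1", t = c(0, 0.5, 1), pos = cbind(x = 0:2, y = c(0, 0, 1)))
#' tr
#' @export
track <- function(id, t, pos, labels = list()) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  t <- as.numeric(t)
  labels <- as.list(labels)
  obj <- structure(
    list(id = as.character(id)[1], t = t, pos = pos, labels = labels),
    class = "track"
  )
  validate_track(obj)
}

validate_track <- function(x) {
  id <- x$id
  if (length(x$t) < 1L)
    stop("track '", id, "': needs at least one timepoint", call. = FALSE)
  if (nrow(x$pos) != length(x$t))
    stop("track '", id, "': positions and times differ in length", call. = FALSE)
  if (!ncol(x$pos) %in% c(2L, 3L))
    stop("track '", id, "': positions must be 2-D or 3-D", call. = FALSE)
  if (anyNA(x$t) || any(!is.finite(x$t)))
    stop("track '", id, "': non-finite time values", call. = FALSE)
  if (length(x$t) > 1L && any(diff(x$t) <= 0))
    stop("track '", id, "': times must be strictly increasing", call. = FALSE)
  if (anyNA(x$pos) || any(!is.finite(x$pos)))
    stop("track '", id, "': non-finite coordinates", call. = FALSE)
  colnames(x$pos) <- c("x", "y", "z")[seq_len(ncol(x$pos))]
  x
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track '%s'> %d points, %d-D, %.3g-%.3g min\n",
              x$id, length(x$t), ncol(x$pos), min(x$t), max(x$t)))
  if (length(x$labels))
    cat("  labels:", paste(names(x$labels), unlist(x$labels),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

n_points <- function(tr) length(tr$t)
track_dim <- function(tr) ncol(tr$pos)

#' Construct a set of tracks
#'
#' A `trackset` bundles tracks with unique identifiers, the nominal sampling
#' interval in minutes (inferred from the data when not supplied; `NULL` when
#' sampling is irregular), and a free-text provenance note.
#'
#' @param tracks List of [track()] objects.
#' @param frame_interval Nominal frame interval in minutes, or `NULL` to
#'   infer it. Consecutive time differences must equal it within `tol`.
#' @param provenance Free-text note on where the tracks came from.
#' @param tol Tolerance for the uniform-interval check, in minutes.
#'   Timestamps are written values rather than measurements, so the default
#'   is tight.
#' @return An object of class `trackset`.
#' @seealso [read_tracks()], [filter_tracks()], [simulate_trackset()]
#' @export
trackset <- function(tracks, frame_interval = NULL, provenance = "",
                     tol = 1e-6) {
  stopifnot(is.list(tracks))
  ids <- vapply(tracks, function(tr) tr$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate track ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(tracks) <- ids
  if (is.null(frame_interval)) {
    frame_interval <- infer_frame_interval(tracks, tol)
  } else {
    check_frame_interval(tracks, frame_interval, tol)
  }
  structure(
    list(tracks = tracks, frame_interval = frame_interval,
         provenance = provenance),
    class = "trackset"
  )
}

infer_frame_interval <- function(tracks, tol) {
  d <- unlist(lapply(tracks, function(tr) diff(tr$t)), use.names = FALSE)
  if (length(d) == 0L) return(NULL)
  if (max(d) - min(d) <= tol) mean(range(d)) else NULL
}

check_frame_interval <- function(tracks, dt, tol) {
  for (tr in tracks) {
    d <- diff(tr$t)
    if (length(d) && any(abs(d - dt) > tol))
      stop("track '", tr$id, "': time steps differ from frame_interval ",
           dt, " by more than ", tol, " min", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.trackset <- function(x, ...) {
  np <- vapply(x$tracks, n_points, integer(1))
  cat(sprintf("<trackset> %d tracks, %s points each",
              length(x$tracks),
              if (length(np)) paste0(min(np), "-", max(np)) else "0"))
  if (!is.null(x$frame_interval))
    cat(sprintf(", frame interval %g min", x$frame_interval))
  cat("\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.trackset <- function(x) length(x$tracks)

#' Number of tracks and track identifiers
#' @param ts A `trackset`.
#' @return `n_tracks()` the number of tracks; `track_ids()` their ids.
#' @export
n_tracks <- function(ts) length(ts$tracks)

#' @rdname n_tracks
#' @export
track_ids <- function(ts) names(ts$tracks)

#' Convert a trackset to a long-format data frame
#'
#' One row per (track, timepoint), columns `track_id`, `t_min`, `x_um`,
#' `y_um` (and `z_um` for 3-D tracks), followed by one column per label.
#'
#' @param x A `trackset`.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A `data.frame` in the canonical long layout.
#' @export
as.data.frame.trackset <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (n_tracks(x) == 0L) {
    return(data.frame(track_id = character(), t_min = numeric(),
                      x_um = numeric(), y_um = numeric()))
  }
  label_keys <- unique(unlist(lapply(x$tracks, function(tr) names(tr$labels))))
  rows <- lapply(x$tracks, function(tr) {
    df <- data.frame(track_id = tr$id, t_min = tr$t,
                     x_um = tr$pos[, 1], y_um = tr$pos[, 2],
                     stringsAsFactors = FALSE)
    if (track_dim(tr) == 3L) df$z_um <- tr$pos[, 3]
    for (k in label_keys)
      df[[k]] <- if (is.null(tr$labels[[k]])) NA_character_ else
        as.character(tr$labels[[k]])
    df
  })
  has_z <- any(vapply(x$tracks, track_dim, integer(1)) == 3L)
  cols <- c("track_id", "t_min", "x_um", "y_um", if (has_z) "z_um", label_keys)
  rows <- lapply(rows, function(df) {
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA_real_
    df[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter tracks by length and labels
#'
#' Returns the subset of tracks with at least `min_points` timepoints whose
#' labels satisfy `label_query`. The input is never modified; the number of
#' tracks removed is reported via a message and attached as attribute
#' `n_removed`.
#'
#' @param ts A `trackset`.
#' @param min_points Minimum number of timepoints a track must have (>= 1).
#' @param label_query Either `NULL` (keep all), a named list/vector of label
#'   values that must all match exactly (e.g. `list(region = "periphery")`),
#'   or a predicate `function(labels)` returning `TRUE` to keep.
#' @param quiet Suppress the removal message.
#' @return A `trackset` with attribute `n_removed`.
#' @examples
#' ts <- simulate_trackset(sim_config("random_walk", list(step = 1),
#'                                    n_tracks = 4, n_frames = 5, seed = 1))
#' filter_tracks(ts, min_points = 2)
#' @export
filter_tracks <- function(ts, min_points = 1L, label_query = NULL,
                          quiet = FALSE) {
  stopifnot(inherits(ts, "trackset"), min_points >= 1L)
  keep <- vapply(ts$tracks, function(tr) {
    if (n_points(tr) < min_points) return(FALSE)
    if (is.null(label_query)) return(TRUE)
    if (is.function(label_query)) return(isTRUE(label_query(tr$labels)))
    all(vapply(names(label_query), function(k) {
      !is.null(tr$labels[[k]]) &&
        as.character(tr$labels[[k]]) == as.character(label_query[[k]])
    }, logical(1)))
  }, logical(1))
  out <- ts
  out$tracks <- ts$tracks[keep]
  n_removed <- sum(!keep)
  if (!quiet)
    message("filter_tracks: removed ", n_removed, " of ", length(keep),
            " tracks")
  attr(out, "n_removed") <- n_removed
  out
}

#' Project 3-D tracks onto the image plane
#'
#' Drops the z coordinate from every 3-D track. Displayed motility analyses
#' of intravital z-stack data are conventionally planar, so metric functions
#' project by default; this makes the projection explicit.
#'
#' @param ts A `trackset` (or single `track`).
#' @return The same object with all positions 2-D.
#' @export
project_2d <- function(ts) {
  if (inherits(ts, "track")) return(project_2d_track(ts))
  stopifnot(inherits(ts, "trackset"))
  ts$tracks <- lapply(ts$tracks, project_2d_track)
  ts
}

project_2d_track <- function(tr) {
  if (track_dim(tr) == 3L) tr$pos <- tr$pos[, 1:2, drop = FALSE]
  tr
}
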