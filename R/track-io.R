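# Reading and writing delimited track tables.
#
# Canonical dialect: CSV, columns track_id, t_min, x_um, y_um, [z_um],
# then label columns; UTF-8, '.' decimal separator. An alternate dialect
# remaps column names only (e.g. Imaris-style statistics exports).

#' Describe the column layout of a track table
#'
#' A dialect maps the canonical roles (track id, time, x, y, optional z,
#' label columns) onto the column names found in a file. Only names are
#' remapped; units must already be µm and minutes.
#'
#' @param track_id,time,x,y,z Column names holding each role; `z = NULL`
#'   for 2-D tables.
#' @param labels Character vector of label column names, or `NULL` to treat
#'   every remaining column as a label.
#' @param sep Field separator.
#' @return A `track_dialect` object.
#' @export
track_dialect <- function(track_id = "track_id", time = "t_min",
                          x = "x_um", y = "y_um", z = "z_um",
                          labels = NULL, sep = ",") {
  structure(list(track_id = track_id, time = time, x = x, y = y, z = z,
                 labels = labels, sep = sep),
            class = "track_dialect")
}

#' @rdname track_dialect
#' @export
dialect_canonical <- function() track_dialect()

#' @rdname track_dialect
#' @details `dialect_imaris()` matches the column names of Imaris-style
#'   position exports (`TrackID`, `Time`, `Position X/Y/Z`); times must be
#'   in minutes and positions in µm, as configured in the export.
#' @export
dialect_imaris <- function() {
  track_dialect(track_id = "TrackID", time = "Time",
                x = "Position X", y = "Position Y", z = "Position Z")
}

#' Read a delimited track table
#'
#' Reads a long-format table (one row per cell per timepoint), groups rows
#' by track id, sorts each track by time, and returns a validated
#' [trackset()]. Times are minutes; coordinates are µm.
#'
#' @param path Path to a delimited text file.
#' @param dialect A [track_dialect()]; defaults to the canonical layout.
#' @param frame_interval Optional nominal frame interval (min); inferred
#'   when omitted.
#' @param project If `TRUE`, drop the z column of 3-D tables on read.
#' @return A `trackset`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_tracks(simulate_trackset(sim_config("random_walk", list(step = 2),
#'              n_tracks = 2, n_frames = 3, seed = 7)), f)
#' read_tracks(f)
#' @export
read_tracks <- function(path, dialect = dialect_canonical(),
                        frame_interval = NULL, project = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(inherits(dialect, "track_dialect"))
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  required <- c(track_id = dialect$track_id, time = dialect$time,
                x = dialect$x, y = dialect$y)
  missing <- required[!required %in% names(df)]
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  has_z <- !is.null(dialect$z) && dialect$z %in% names(df)
  z_present <- if (has_z) !is.na(df[[dialect$z]]) else
    rep(FALSE, nrow(df))
  if (has_z && any(z_present) && !all(z_present))
    stop("mixed dimensionality: column '", dialect$z,
         "' present for some rows only", call. = FALSE)
  use_z <- has_z && all(z_present) && nrow(df) > 0L
  label_cols <- dialect$labels
  if (is.null(label_cols))
    label_cols <- setdiff(names(df),
                          c(required, if (has_z) dialect$z))
  ids <- as.character(df[[dialect$track_id]])
  tracks <- lapply(split(seq_len(nrow(df)), factor(ids, unique(ids))),
                   function(idx) {
    sub <- df[idx, , drop = FALSE]
    o <- order(sub[[dialect$time]])
    sub <- sub[o, , drop = FALSE]
    tt <- as.numeric(sub[[dialect$time]])
    id <- as.character(sub[[dialect$track_id]][1])
    if (anyDuplicated(tt))
      stop("track '", id, "': duplicated timepoints", call. = FALSE)
    pos <- cbind(as.numeric(sub[[dialect$x]]), as.numeric(sub[[dialect$y]]))
    if (use_z && !project) pos <- cbind(pos, as.numeric(sub[[dialect$z]]))
    labs <- lapply(label_cols, function(k) {
      v <- unique(sub[[k]])
      if (length(v) == 1L && !is.na(v)) v else NULL
    })
    names(labs) <- label_cols
    track(id, tt, pos, labels = Filter(Negate(is.null), labs))
  })
  trackset(unname(tracks), frame_interval = frame_interval,
           provenance = paste0("read from ", basename(path)))
}

#' Write a trackset to a delimited track table
#'
#' Writes the canonical long-format CSV: header row, then one row per
#' (track, timepoint) with columns `track_id`, `t_min`, `x_um`, `y_um`
#' (plus `z_um` for 3-D tracks) and one column per label. Numeric values
#' are written with 17 significant digits, so a read/write round trip is
#' lossless.
#'
#' @param ts A `trackset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "trackset"))
  df <- as.data.frame(ts)
  num <- vapply(df, is.numeric, logical(1))
  for (k in names(df)[num]) df[[k]] <- sprintf("%.17g", df[[k]])
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write track table to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}
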