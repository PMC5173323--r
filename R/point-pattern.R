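# Labeled cell point patterns in an imaging field, and a Poisson simulator
# with tumor-disc geometry (interior / peri-tumoral ring / exterior).

#' Construct a labeled point pattern
#'
#' Cell coordinates (µm) in a rectangular imaging field with a known area
#' (mm²), optionally with a tumor-boundary geometry for radial analyses.
#'
#' @param points Two-column numeric matrix of coordinates in µm.
#' @param labels Character vector of per-point categories (recycled if
#'   length 1).
#' @param field_area Field area in mm² (> 0); see [field_areas] for the
#'   conventional field sizes.
#' @param geometry Optional tumor boundary: `list(type = "disc", center =
#'   c(x, y), radius = r)` or `list(type = "polygon", vertices = <matrix>)`
#'   (µm).
#' @param field Rectangle `c(xmin, xmax, ymin, ymax)` in µm; defaults to a
#'   square of the given area with origin 0.
#' @return A `point_pattern` object.
#' @export
point_pattern <- function(points, labels, field_area, geometry = NULL,
                          field = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) > 0L && ncol(points) != 2L)
    stop("points must have two columns (x, y) in um", call. = FALSE)
  if (!is.numeric(field_area) || field_area <= 0)
    stop("field_area must be > 0 (mm^2)", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) == 1L) labels <- rep(labels, nrow(points))
  if (length(labels) != nrow(points))
    stop("labels must match the number of points", call. = FALSE)
  if (is.null(field)) {
    side <- 1000 * sqrt(field_area)
    field <- c(0, side, 0, side)
  }
  if (!is.null(geometry)) geometry <- validate_geometry(geometry)
  structure(list(points = points, labels = labels, field_area = field_area,
                 geometry = geometry, field = field),
            class = "point_pattern")
}

validate_geometry <- function(g) {
  if (identical(g$type, "disc")) {
    stopifnot(length(g$center) == 2L, is.numeric(g$radius), g$radius > 0)
  } else if (identical(g$type, "polygon")) {
    g$vertices <- as.matrix(g$vertices)
    stopifnot(ncol(g$vertices) == 2L, nrow(g$vertices) >= 3L)
  } else {
    stop("geometry$type must be 'disc' or 'polygon'", call. = FALSE)
  }
  g
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> %d points, %g mm^2 field%s\n",
              nrow(x$points), x$field_area,
              if (is.null(x$geometry)) "" else
                paste0(", ", x$geometry$type, " tumor boundary")))
  tab <- table(x$labels)
  if (length(tab))
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Simulate a labeled Poisson point pattern with a peri-tumoral ring
#'
#' Places points of each label as independent Poisson counts per
#' compartment - tumor-disc interior, boundary annulus of width
#' `ring_width`, and the remaining field exterior - uniformly within the
#' compartment. Emulates the peri-tumoral accumulation geometry seen in
#' large-field intravital images.
#'
#' @param field_area Field area in mm² (square field).
#' @param radius Tumor disc radius in µm.
#' @param ring_width Width of the boundary annulus in µm.
#' @param intensities Named list, one entry per label, each a numeric
#'   vector `c(interior =, ring =, exterior =)` in cells/mm². A single
#'   unnamed numeric vector is taken as one label `"cell"`.
#' @param center Disc center (µm); defaults to the field center.
#' @param seed Integer seed; same seed gives the identical pattern.
#' @return A `point_pattern` with disc geometry.
#' @examples
#' pp <- simulate_point_pattern(0.40, radius = 120, ring_width = 40,
#'         intensities = list(treg = c(interior = 20, ring = 400,
#'                                     exterior = 40)), seed = 1)
#' pp
#' @export
simulate_point_pattern <- function(field_area, radius, ring_width,
                                   intensities, center = NULL, seed = 1L) {
  if (is.numeric(intensities)) intensities <- list(cell = intensities)
  stopifnot(is.list(intensities), length(intensities) >= 1L)
  for (v in intensities) {
    stopifnot(is.numeric(v), length(v) == 3L)
    if (any(v < 0)) stop("intensities must be >= 0", call. = FALSE)
  }
  side <- 1000 * sqrt(field_area)
  if (is.null(center)) center <- c(side / 2, side / 2)
  outer_r <- radius + ring_width
  if (center[1] - outer_r < 0 || center[1] + outer_r > side ||
      center[2] - outer_r < 0 || center[2] + outer_r > side)
    stop("tumor annulus extends outside the imaging field", call. = FALSE)
  areas_mm2 <- c(interior = pi * radius^2,
                 ring = pi * (outer_r^2 - radius^2),
                 exterior = side^2 - pi * outer_r^2) / 1e6
  pts <- matrix(numeric(0), ncol = 2)
  labs <- character(0)
  with_preserved_rng({
    set.seed(as.integer(seed))
    for (lab in names(intensities)) {
      inten <- intensities[[lab]]
      names(inten) <- c("interior", "ring", "exterior")
      for (comp in names(areas_mm2)) {
        n <- stats::rpois(1L, inten[[comp]] * areas_mm2[[comp]])
        if (n == 0L) next
        pts <- rbind(pts, sample_compartment(n, comp, center, radius,
                                             outer_r, side))
        labs <- c(labs, rep(lab, n))
      }
    }
  })
  point_pattern(pts, labs, field_area,
                geometry = list(type = "disc", center = center,
                                radius = radius),
                field = c(0, side, 0, side))
}

sample_compartment <- function(n, comp, center, r_in, r_out, side) {
  if (comp == "interior" || comp == "ring") {
    lim <- if (comp == "interior") c(0, r_in) else c(r_in, r_out)
    rad <- sqrt(stats::runif(n, lim[1]^2, lim[2]^2))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(center[1] + rad * cos(th), center[2] + rad * sin(th))
  } else {
    # rejection sampling: uniform in the field outside the outer circle
    out <- matrix(numeric(0), ncol = 2)
    while (nrow(out) < n) {
      m <- max(2L * (n - nrow(out)), 16L)
      cand <- cbind(stats::runif(m, 0, side), stats::runif(m, 0, side))
      keep <- (cand[, 1] - center[1])^2 + (cand[, 2] - center[2])^2 >
        r_out^2
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }
}
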