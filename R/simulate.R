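# Synthetic track simulation.
#
# Motion models operate per frame on continuous µm coordinates:
#   random_walk - independent uniform direction each frame, configurable
#                 step length (constant or drawn i.i.d. per frame)
#   confined    - mean-reverting walk tethered to the track's start
#   directed    - random walk plus a constant drift per frame
#   stop_and_go - two-state Markov chain over per-frame speeds
#
# Reproducibility: one stream per simulate call seeded from the config;
# each track uses a sub-stream derived by counter from (seed, track index),
# so results do not depend on track order and the first k tracks of a
# larger cohort equal a cohort of k tracks.

SIM_MODELS <- c("random_walk", "confined", "directed", "stop_and_go")

#' Specify a synthetic track cohort
#'
#' @param model One of `"random_walk"`, `"confined"`, `"directed"`,
#'   `"stop_and_go"`.
#' @param params Named list of model parameters:
#'   * `step`: per-frame step length in µm - a single number for a constant
#'     step, or `list(dist = "uniform", min =, max =)` for i.i.d. uniform
#'     step lengths (models `random_walk`, `confined`, `directed`; for
#'     `directed` it is the isotropic noise step and may be 0).
#'   * `tether`: mean-reversion strength in (0, 1] (model `confined`); each
#'     frame the cell moves `tether` of the way back toward its start
#'     before taking its random step. Equilibrium spread ~ step/sqrt(2*tether).
#'   * `drift`: numeric drift vector in µm per frame (model `directed`).
#'   * `speed_stop`, `speed_go`: state speeds in µm/min and
#'     `p_stop_to_go`, `p_go_to_stop`: per-frame transition probabilities
#'     (model `stop_and_go`). The chain starts in its stationary
#'     distribution.
#'   * `dim`: 2 (default) or 3; step directions are uniform on the circle
#'     or sphere.
#' @param n_tracks Number of tracks (>= 1).
#' @param n_frames Timepoints per track (>= 2).
#' @param frame_interval Sampling interval in minutes (default 0.5, the
#'   source-data time grid of the intravital recordings emulated here).
#' @param seed Integer seed; same seed gives identical output.
#' @param labels Metadata labels applied to every track.
#' @return A `sim_config` object.
#' @seealso [simulate_trackset()], [preset_regime()]
#' @export
sim_config <- function(model, params, n_tracks, n_frames,
                       frame_interval = 0.5, seed = 1L, labels = list()) {
  if (!is.character(model) || length(model) != 1L || !model %in% SIM_MODELS)
    stop("unknown motion model '", paste(model, collapse = ","),
         "'; available: ", paste(SIM_MODELS, collapse = ", "), call. = FALSE)
  stopifnot(is.list(params))
  n_tracks <- as.integer(n_tracks)
  n_frames <- as.integer(n_frames)
  if (n_tracks < 1L) stop("n_tracks must be >= 1", call. = FALSE)
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0", call. = FALSE)
  params$dim <- params$dim %||% 2L
  if (!params$dim %in% c(2L, 3L)) stop("dim must be 2 or 3", call. = FALSE)
  validate_params(model, params)
  structure(list(model = model, params = params, n_tracks = n_tracks,
                 n_frames = n_frames, frame_interval = frame_interval,
                 seed = as.integer(seed), labels = as.list(labels)),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_step_spec <- function(step) {
  if (is.numeric(step) && length(step) == 1L) {
    if (step < 0) stop("step length must be >= 0", call. = FALSE)
    return(invisible(step))
  }
  if (is.list(step) && identical(step$dist, "uniform")) {
    if (is.null(step$min) || is.null(step$max) || step$min < 0 ||
        step$max < step$min)
      stop("uniform step spec needs 0 <= min <= max", call. = FALSE)
    return(invisible(step))
  }
  stop("step must be a single non-negative number or ",
       "list(dist = 'uniform', min =, max =)", call. = FALSE)
}

validate_params <- function(model, p) {
  switch(model,
    random_walk = validate_step_spec(p$step %||%
                                       stop("random_walk needs 'step'",
                                            call. = FALSE)),
    confined = {
      validate_step_spec(p$step %||% stop("confined needs 'step'",
                                          call. = FALSE))
      if (is.null(p$tether) || p$tether <= 0 || p$tether > 1)
        stop("confined needs tether in (0, 1]", call. = FALSE)
    },
    directed = {
      validate_step_spec(p$step %||% 0)
      if (is.null(p$drift) || !is.numeric(p$drift) ||
          !length(p$drift) %in% c(2L, 3L))
        stop("directed needs a 2- or 3-vector 'drift' (um/frame)",
             call. = FALSE)
    },
    stop_and_go = {
      for (k in c("speed_stop", "speed_go"))
        if (is.null(p[[k]]) || p[[k]] < 0)
          stop("stop_and_go needs ", k, " >= 0", call. = FALSE)
      for (k in c("p_stop_to_go", "p_go_to_stop"))
        if (is.null(p[[k]]) || p[[k]] < 0 || p[[k]] > 1)
          stop("stop_and_go needs ", k, " in [0, 1]", call. = FALSE)
      if (p$p_stop_to_go + p$p_go_to_stop == 0)
        stop("stop_and_go transition probabilities cannot both be 0",
             call. = FALSE)
    })
  invisible(p)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> model %s: %d tracks x %d frames @ %g min, seed %d\n",
              x$model, x$n_tracks, x$n_frames, x$frame_interval, x$seed))
  invisible(x)
}

# Counter-derived sub-stream seed, kept inside 32-bit integer range.
# Exact in double arithmetic (< 2^53 before the modulus).
derive_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 2654435 + as.numeric(i) * 97561) %%
               2147483647)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  force(code)
}

random_directions <- function(n, dim) {
  if (dim == 2L) {
    th <- stats::runif(n, 0, 2 * pi)
    cbind(cos(th), sin(th))
  } else {
    z <- stats::runif(n, -1, 1)
    th <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(th), r * sin(th), z)
  }
}

draw_step_lengths <- function(n, step) {
  if (is.numeric(step)) rep(as.numeric(step), n)
  else stats::runif(n, step$min, step$max)
}

#' Simulate a synthetic track cohort
#'
#' Deterministic given the config seed. Track `i` of a cohort is identical
#' whatever `n_tracks` is, because each track draws from its own
#' counter-derived sub-stream.
#'
#' @param config A [sim_config()].
#' @return A `trackset` with times `0, dt, 2*dt, ...` and the config labels
#'   on every track.
#' @examples
#' cfg <- sim_config("random_walk", list(step = 2.46),
#'                   n_tracks = 5, n_frames = 21, seed = 42)
#' ts <- simulate_trackset(cfg)
#' cohort_metrics(ts)$summary
#' @export
simulate_trackset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dt <- config$frame_interval
  times <- (seq_len(config$n_frames) - 1L) * dt
  tracks <- with_preserved_rng({
    lapply(seq_len(config$n_tracks), function(i) {
      set.seed(derive_seed(config$seed, i))
      pos <- simulate_positions(config)
      track(sprintf("sim%04d", i), times, pos, labels = config$labels)
    })
  })
  trackset(tracks, frame_interval = dt,
           provenance = sprintf("simulated: %s, seed %d",
                                config$model, config$seed))
}

simulate_positions <- function(config) {
  p <- config$params
  d <- p$dim
  n_steps <- config$n_frames - 1L
  dirs <- random_directions(n_steps, d)
  steps <- switch(config$model,
    random_walk = draw_step_lengths(n_steps, p$step) * dirs,
    directed = {
      noise <- draw_step_lengths(n_steps, p$step %||% 0) * dirs
      sweep(noise, 2L, as.numeric(p$drift), "+")
    },
    confined = draw_step_lengths(n_steps, p$step) * dirs,
    stop_and_go = {
      states <- simulate_two_state_chain(n_steps, p$p_stop_to_go,
                                         p$p_go_to_stop)
      speed <- ifelse(states == 1L, p$speed_stop, p$speed_go)
      (speed * config$frame_interval) * dirs
    })
  pos <- matrix(0, nrow = config$n_frames, ncol = d)
  if (config$model == "confined") {
    for (k in seq_len(n_steps)) {
      pulled <- pos[k, ] + p$tether * (pos[1L, ] - pos[k, ])
      pos[k + 1L, ] <- pulled + steps[k, ]
    }
  } else {
    pos[-1L, ] <- apply(steps, 2L, cumsum)
  }
  pos
}

# states: 1 = stop, 2 = go; starts from the stationary distribution
simulate_two_state_chain <- function(n, p_sg, p_gs) {
  pi_stop <- p_gs / (p_sg + p_gs)
  states <- integer(n)
  u <- stats::runif(n)
  states[1L] <- if (u[1L] < pi_stop) 1L else 2L
  if (n > 1L) for (k in 2L:n) {
    states[k] <- if (states[k - 1L] == 1L) {
      if (u[k] < p_sg) 2L else 1L
    } else {
      if (u[k] < p_gs) 1L else 2L
    }
  }
  states
}
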