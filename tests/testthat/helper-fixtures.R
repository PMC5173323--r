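# Fixtures built in code: simple deterministic tracks and random tracksets.

make_track <- function(id = "t1", t = c(0, 0.5, 1),
                       pos = cbind(x = c(0, 1, 1), y = c(0, 0, 1)),
                       labels = list()) {
  track(id, t, pos, labels)
}

ballistic_track <- function(id = "b", v = 3, n = 11, dt = 0.5,
                            dir = c(1, 0)) {
  k <- 0:(n - 1)
  track(id, k * dt, cbind(dir[1] * v * k * dt, dir[2] * v * k * dt))
}

stationary_track <- function(id = "s", n = 5, dt = 0.5) {
  track(id, (0:(n - 1)) * dt, cbind(rep(1, n), rep(2, n)))
}

# random trackset with labels, optionally 3-D, uniform dt
random_trackset <- function(n = 5, n_frames = 6, dim = 2, seed = 1,
                            dt = 0.5) {
  set.seed(seed)
  tracks <- lapply(seq_len(n), function(i) {
    pos <- matrix(rnorm(n_frames * dim, sd = 3), ncol = dim)
    track(paste0("trk", i), (0:(n_frames - 1)) * dt, pos,
          labels = list(group = sample(c("pbs", "ctx_act"), 1),
                        day = sample(0:3, 1)))
  })
  trackset(tracks, frame_interval = dt, provenance = "fixture")
}

# rotate 2-D positions by angle and translate; rigid motion of a trackset
rigid_transform <- function(ts, angle = 0.7, shift = c(12, -5)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  ts$tracks <- lapply(ts$tracks, function(tr) {
    tr$pos <- sweep(tr$pos[, 1:2, drop = FALSE] %*% t(R), 2, shift, "+")
    tr
  })
  ts
}

mean_of <- function(cm, metric) {
  cm$summary$mean[cm$summary$metric == metric]
}
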