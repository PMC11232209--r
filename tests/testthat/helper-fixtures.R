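library(dplyr)

# a small hand-built stream: all landmarks at scripted positions so tests
# can reason about exact coordinates
make_tiny_stream <- function(n_frames = 2, fps = 30, jitter = 0) {
  frames <- tidyr::expand_grid(frame = seq_len(n_frames), index = 0:32) |>
    mutate(t = (frame - 1) / fps,
           x = index * 0.01 + frame * 0.001 + jitter * stats::rnorm(n()),
           y = 1 + index * 0.005,
           z = 0.1 * sin(index))
  pose_stream(frames, fps = fps, units = "m", source_id = "fixture")
}

# one standing-pose frame as a plain tibble
make_frame <- function(t = 0) {
  sch <- landmark_schema()
  tibble(frame = 1L, t = t, index = sch$index, name = sch$name,
         x = sch$index * 0.01, y = 1 + sch$index * 0.002, z = 0,
         visibility = 1)
}

# independent piecewise-linear interpolation oracle (no approx())
brute_interp <- function(tt, vv, xout) {
  vapply(xout, function(x) {
    if (x <= tt[1]) return(vv[1])
    if (x >= tt[length(tt)]) return(vv[length(vv)])
    i <- max(which(tt <= x))
    if (tt[i] == x) return(vv[i])
    vv[i] + (vv[i + 1] - vv[i]) * (x - tt[i]) / (tt[i + 1] - tt[i])
  }, numeric(1))
}

# random 3D rotation matrix from a seeded QR decomposition
random_rotation <- function(seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_stream <- function(stream, R) {
  xyz <- as.matrix(stream[, c("x", "y", "z")]) %*% t(R)
  out <- stream
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}
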