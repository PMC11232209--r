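#' Moving-average smoothing of a pose stream
#'
#' Applies a centered moving average independently to every landmark's x, y
#' and z trajectory to suppress tracking jitter before feature extraction.
#' At the stream edges the window shrinks symmetrically, so constant and
#' (away from the edges) linear trajectories pass through unchanged.
#'
#' @param stream A pose stream.
#' @param window Odd positive window length in frames (default 5).
#' @return A pose stream of identical shape with smoothed coordinates.
#' @export
smooth_stream <- function(stream, window = 5) {
  if (!is_scalar_number(window) || window < 1 || window %% 2 != 1) {
    stop_rehab("`window` must be an odd positive integer", "rehabpose_parameter_error")
  }
  validate_pose_stream(stream)
  if (nrow(stream) == 0 || window == 1) return(stream)
  half <- (window - 1) / 2
  sm <- function(v) {
    n <- length(v)
    if (n == 1) return(v)
    cs <- cumsum(c(0, v))
    i <- seq_len(n)
    h <- pmin(half, i - 1, n - i)  # symmetric shrink at edges
    (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
  }
  out <- stream |>
    arrange(.data$index, .data$frame) |>
    mutate(across(c("x", "y", "z"), sm), .by = "index") |>
    arrange(.data$frame, .data$index)
  attributes(out)[c("fps", "units", "source_id")] <- stream_meta(stream)
  class(out) <- class(stream)
  out
}

#' Centre of gravity proxy: the hip midpoint
#'
#' The whole-body weight-shift proxy used throughout: the arithmetic
#' midpoint of the left and right hip landmarks.
#'
#' @param frame One frame of a pose stream (tibble with `index`, `x`, `y`,
#'   `z`), full or reduced.
#' @return A named numeric vector `c(x, y, z)`.
#' @export
center_of_gravity <- function(frame) {
  hips <- frame |> filter(.data$index %in% c(23L, 24L))
  if (nrow(hips) != 2) {
    stop_rehab("frame is missing a hip landmark (indices 23, 24)",
               "rehabpose_schema_error")
  }
  c(x = mean(hips$x), y = mean(hips$y), z = mean(hips$z))
}

#' Reduce a 33-landmark frame to the 17-keypoint analysis skeleton
#'
#' Drops the 10 non-nose face landmarks (indices 1--10) and the 6 hand
#' landmarks (indices 17--22); the nose is retained as the head/torso
#' reference. Attaches the hip-midpoint centre of gravity as columns
#' `cog_x`, `cog_y`, `cog_z`.
#'
#' @param frame One frame (tibble rows with all 33 indices).
#' @return A tibble of exactly 17 keypoints with cog columns.
#' @export
reduce_keypoints <- function(frame) {
  if (!all(0:32 %in% frame$index)) {
    stop_rehab("frame does not carry all 33 schema indices", "rehabpose_schema_error")
  }
  cog <- center_of_gravity(frame)
  frame |>
    filter(.data$index %in% retained_landmark_indices()) |>
    mutate(cog_x = cog[["x"]], cog_y = cog[["y"]], cog_z = cog[["z"]])
}

#' Reduce every frame of a stream
#'
#' @param stream A pose stream.
#' @return A tibble of reduced frames (17 keypoints each, cog attached).
#' @export
reduce_stream <- function(stream) {
  validate_pose_stream(stream)
  stream |>
    group_by(.data$frame) |>
    group_modify(~ reduce_keypoints(.x) |> select(-any_of("frame"))) |>
    ungroup()
}

#' Interior joint angle by the cosine rule
#'
#' The angle at `vertex` subtended by `proximal` and `distal`, i.e. the
#' triangle's interior angle obtained from the two segment vectors
#' (equivalently the cosine rule on the side lengths). The cosine is clamped
#' to \[-1, 1\] before `acos` to absorb floating-point drift. All three
#' arguments may be matrices (one row per observation) for vectorized use.
#'
#' @param proximal,vertex,distal 3D points: numeric length-3 vectors or
#'   n x 3 matrices.
#' @return Angle(s) in degrees, in \[0, 180\].
#' @export
#' @examples
#' joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
joint_angle <- function(proximal, vertex, distal) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p <- as_m(proximal); v <- as_m(vertex); d <- as_m(distal)
  u1 <- p - v
  u2 <- d - v
  n1 <- sqrt(rowSums(u1^2))
  n2 <- sqrt(rowSums(u2^2))
  if (any(n1 < 1e-9 | n2 < 1e-9)) {
    stop_rehab("zero-length segment at joint vertex", "rehabpose_geometry_error")
  }
  cosang <- clamp(rowSums(u1 * u2) / (n1 * n2), -1, 1)
  acos(cosang) * 180 / pi
}

#' Default joint-angle definitions
#'
#' The joint triples (proximal, vertex, distal) measured by default on both
#' sides: elbow (shoulder--elbow--wrist), shoulder (elbow--shoulder--hip),
#' hip (shoulder--hip--knee), knee (hip--knee--ankle) and ankle
#' (knee--ankle--foot tip).
#'
#' @return Tibble with columns `joint`, `side`, `proximal`, `vertex`,
#'   `distal` (schema indices).
#' @export
default_joint_triples <- function() {
  base <- tibble(
    joint = c("elbow", "shoulder", "hip", "knee", "ankle"),
    proximal = c("shoulder", "elbow", "shoulder", "hip", "knee"),
    vertex   = c("elbow", "shoulder", "hip", "knee", "ankle"),
    distal   = c("wrist", "hip", "knee", "ankle", "foot_index")
  )
  bind_rows(
    base |> mutate(side = "left"),
    base |> mutate(side = "right")
  ) |>
    mutate(across(c("proximal", "vertex", "distal"),
                  ~ landmark_index_of(paste0(.data$side, "_", .x)))) |>
    select("joint", "side", "proximal", "vertex", "distal")
}

#' Read joint definitions from a YAML file
#'
#' Each entry is `{name, side, proximal, vertex, distal}`; points may be
#' given as landmark names or schema indices.
#'
#' @param path YAML file.
#' @return A joint-triple tibble as [default_joint_triples()].
#' @export
read_joint_triples <- function(path) {
  spec <- yaml::read_yaml(path)
  as_idx <- function(p) {
    if (is.numeric(p)) as.integer(p) else landmark_index_of(as.character(p))
  }
  map(spec, function(j) {
    tibble(joint = j$name, side = j$side %||% "center",
           proximal = as_idx(j$proximal), vertex = as_idx(j$vertex),
           distal = as_idx(j$distal))
  }) |> list_rbind()
}

validate_joint_triples <- function(joints) {
  idx <- c(joints$proximal, joints$vertex, joints$distal)
  if (any(!idx %in% 0:32)) {
    stop_rehab("joint definition references an index outside the schema",
               "rehabpose_config_error")
  }
  bad <- joints |>
    filter(.data$proximal == .data$vertex | .data$distal == .data$vertex |
             .data$proximal == .data$distal)
  if (nrow(bad) > 0) {
    stop_rehab(sprintf("joint '%s' does not use three distinct landmarks", bad$joint[1]),
               "rehabpose_config_error")
  }
  joints
}

#' Extract joint-angle time series from a pose stream
#'
#' Computes, per joint definition, the cosine-rule angle in every frame.
#' Frames where a segment degenerates (vertex coincident with an endpoint)
#' yield an `NA` angle flagged in the `degenerate` column rather than an
#' error.
#'
#' @param stream A pose stream.
#' @param joints Joint-triple tibble; defaults to [default_joint_triples()].
#' @return A tibble with columns `joint`, `side`, `frame`, `t`, `angle`
#'   (degrees), `degenerate`.
#' @export
extract_angle_series <- function(stream, joints = default_joint_triples()) {
  validate_pose_stream(stream)
  if (nrow(joints) == 0 || nrow(stream) == 0) {
    return(tibble(joint = character(), side = character(), frame = integer(),
                  t = double(), angle = double(), degenerate = logical()))
  }
  validate_joint_triples(joints)
  ord <- stream |> arrange(.data$frame, .data$index)
  nf <- length(unique(ord$frame))
  coord <- function(v) matrix(ord[[v]], nrow = nf, ncol = 33, byrow = TRUE)
  X <- coord("x"); Y <- coord("y"); Z <- coord("z")
  ts <- ord |> distinct(.data$frame, .data$t) |> arrange(.data$frame)
  at <- function(i) cbind(X[, i + 1], Y[, i + 1], Z[, i + 1])
  pmap(joints, function(joint, side, proximal, vertex, distal) {
    p <- at(proximal); v <- at(vertex); d <- at(distal)
    n1 <- sqrt(rowSums((p - v)^2)); n2 <- sqrt(rowSums((d - v)^2))
    degen <- n1 < 1e-9 | n2 < 1e-9
    ang <- rep(NA_real_, nf)
    if (any(!degen)) {
      ang[!degen] <- joint_angle(p[!degen, , drop = FALSE],
                                 v[!degen, , drop = FALSE],
                                 d[!degen, , drop = FALSE])
    }
    tibble(joint = joint, side = side, frame = ts$frame, t = ts$t,
           angle = ang, degenerate = degen)
  }) |> list_rbind()
}
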