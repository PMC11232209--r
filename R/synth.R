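#' Skeleton segment-length model
#'
#' Segment lengths (metres) of the rigid stick figure used by the motion
#' generator. Generated frames keep every bone length exactly constant, so
#' the generator doubles as a geometric oracle for the kinematics layer.
#'
#' @param trunk,upper_arm,forearm,thigh,shank,foot Segment lengths (m).
#' @param half_width Lateral half-distance of the hip and shoulder pairs
#'   (m); shoulders and hips share it so each limb chain lies in its own
#'   sagittal plane.
#' @param pelvis_height Height of the hip line above the ground (m).
#' @return A `rehab_skeleton` list.
#' @export
skeleton_model <- function(trunk = 0.5, upper_arm = 0.28, forearm = 0.25,
                           thigh = 0.45, shank = 0.42, foot = 0.2,
                           half_width = 0.15, pelvis_height = 0.95) {
  lens <- c(trunk, upper_arm, forearm, thigh, shank, foot, half_width, pelvis_height)
  if (any(lens <= 0)) stop_rehab("segment lengths must be positive", "rehabpose_parameter_error")
  structure(list(trunk = trunk, upper_arm = upper_arm, forearm = forearm,
                 thigh = thigh, shank = shank, foot = foot,
                 half_width = half_width, pelvis_height = pelvis_height),
            class = "rehab_skeleton")
}

# neutral standing pose, degrees (interior angles at the default triples)
default_pose_angles <- function() {
  c(hip = 172, knee = 172, ankle = 100, shoulder = 40, elbow = 160)
}

#' Build a motion script
#'
#' A motion script is the ground truth driving the generator: a movement
#' timeline plus, per (segment, joint, side), an angle trajectory
#' mean + amplitude * sin(2 pi freq (t - t_start) + phase) in degrees.
#' Joints without a scripted row hold the neutral standing pose. Evaluated
#' angles are clamped to \[0, 180\].
#'
#' @param timeline A [segment_timeline()].
#' @param angles Tibble with columns `segment`, `joint`, `side`, `mean`,
#'   `amp`, `freq`, `phase` (amp in degrees, freq in Hz, phase radians).
#' @param angle_noise_sd Per-frame Gaussian jitter on each joint angle,
#'   degrees (default 0).
#' @param coord_noise_sd Per-frame Gaussian jitter on each coordinate,
#'   metres (default 0).
#' @param seed Mandatory integer seed for the jitter draws.
#' @return A `rehab_motion_script` list.
#' @export
motion_script <- function(timeline, angles, angle_noise_sd = 0,
                          coord_noise_sd = 0, seed) {
  stopifnot(inherits(timeline, "rehab_timeline"))
  if (missing(seed)) stop_rehab("a seed is required", "rehabpose_parameter_error")
  angles <- as_tibble(angles)
  need <- c("segment", "joint", "side", "mean", "amp", "freq", "phase")
  stopifnot(all(need %in% names(angles)))
  if (!all(angles$segment %in% timeline$name)) {
    stop_rehab("scripted segment not present in the timeline", "rehabpose_config_error")
  }
  structure(list(timeline = timeline, angles = angles,
                 angle_noise_sd = angle_noise_sd,
                 coord_noise_sd = coord_noise_sd, seed = seed),
            class = "rehab_motion_script")
}

#' A ready-made scripted routine
#'
#' A small routine of sinusoidal joint trajectories over `n_segments`
#' consecutive movements, all ten default joints scripted, amplitudes kept
#' well inside \[0, 180\] so no clamping occurs. Used as the standard
#' fixture for round-trip and detection experiments.
#'
#' @param n_segments Number of movements (default 3).
#' @param seg_duration Seconds per movement (default 4).
#' @param seed Seed stored in the script (default 1).
#' @inheritParams motion_script
#' @return A `rehab_motion_script`.
#' @export
default_motion_script <- function(n_segments = 3, seg_duration = 4, seed = 1,
                                  angle_noise_sd = 0, coord_noise_sd = 0) {
  tl <- segment_timeline(tibble(
    name = paste0("movement_", seq_len(n_segments)),
    start = (seq_len(n_segments) - 1) * seg_duration,
    end = seq_len(n_segments) * seg_duration))
  base <- tibble(
    joint = c("hip", "knee", "ankle", "shoulder", "elbow"),
    mean = c(150, 140, 100, 60, 120),
    amp = c(12, 18, 8, 15, 20),
    freq = c(0.25, 0.25, 0.5, 0.25, 0.5))
  angles <- tidyr::expand_grid(
    segment = tl$name, side = c("left", "right"),
    base) |>
    mutate(seg_i = match(.data$segment, tl$name),
           mean = .data$mean + 5 * ((.data$seg_i - 1) %% 3),
           phase = ifelse(.data$side == "left", 0, pi / 3) + 0.2 * .data$seg_i) |>
    select("segment", "joint", "side", "mean", "amp", "freq", "phase")
  motion_script(tl, angles, angle_noise_sd = angle_noise_sd,
                coord_noise_sd = coord_noise_sd, seed = seed)
}

#' Evaluate a script's scripted angle at given times
#'
#' The noiseless ground-truth trajectory for one joint/side, used by tests
#' to compare recovered angles against the script.
#'
#' @param script A motion script.
#' @param joint,side Joint name and side.
#' @param t Times (seconds).
#' @return Angles in degrees (neutral pose where unscripted).
#' @export
script_angle_at <- function(script, joint, side, t) {
  tl <- script$timeline
  out <- rep(unname(default_pose_angles()[joint]), length(t))
  rows <- script$angles |> filter(.data$joint == !!joint, .data$side == !!side)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    seg <- tl |> filter(.data$name == r$segment)
    inside <- t >= seg$start & t <= seg$end
    out[inside] <- r$mean + r$amp * sin(2 * pi * r$freq * (t[inside] - seg$start) + r$phase)
  }
  clamp(out, 0, 180)
}

# rotate sagittal-plane components (y, z) by theta degrees
rot_yz <- function(uy, uz, theta) {
  c_ <- cospi(theta / 180); s_ <- sinpi(theta / 180)
  list(y = uy * c_ - uz * s_, z = uy * s_ + uz * c_)
}

#' Generate a pose stream by forward kinematics
#'
#' Places all 33 landmarks frame by frame from the scripted joint angles:
#' a vertical trunk over the pelvis, each limb chain rotated in its own
#' sagittal plane so that every default joint triple reproduces its
#' scripted interior angle exactly, plus rigidly attached face and hand
#' filler landmarks (present only so streams are schema-complete before
#' reduction). Seeded Gaussian jitter can be added to angles (degrees)
#' and/or coordinates (metres).
#'
#' @param script A [motion_script()].
#' @param model A [skeleton_model()].
#' @param fps Frames per second (> 0, default 20).
#' @return A [pose_stream()] covering the script's timeline.
#' @export
generate_motion <- function(script, model = skeleton_model(), fps = 20) {
  stopifnot(inherits(script, "rehab_motion_script"))
  if (!is_scalar_number(fps) || fps <= 0) {
    stop_rehab("fps must be positive", "rehabpose_parameter_error")
  }
  tl <- script$timeline
  t <- seq(min(tl$start), max(tl$end), by = 1 / fps)
  nt <- length(t)
  set.seed(script$seed)

  ang <- function(joint, side) {
    a <- script_angle_at(script, joint, side, t)
    if (script$angle_noise_sd > 0) {
      a <- clamp(a + stats::rnorm(nt, 0, script$angle_noise_sd), 0, 180)
    }
    a
  }

  X <- matrix(0, nt, 33); Y <- matrix(0, nt, 33); Z <- matrix(0, nt, 33)
  put <- function(idx, x, y, z) {
    X[, idx + 1] <<- x; Y[, idx + 1] <<- y; Z[, idx + 1] <<- z
  }
  hy <- model$pelvis_height
  sy <- hy + model$trunk
  # face block, rigid around the nose
  nose <- c(0, sy + 0.25, 0.08)
  put(0, nose[1], nose[2], nose[3])
  face_off <- list(
    `1` = c(0.02, 0.03, -0.01), `2` = c(0.035, 0.03, -0.02), `3` = c(0.05, 0.03, -0.03),
    `4` = c(-0.02, 0.03, -0.01), `5` = c(-0.035, 0.03, -0.02), `6` = c(-0.05, 0.03, -0.03),
    `7` = c(0.07, 0.01, -0.06), `8` = c(-0.07, 0.01, -0.06),
    `9` = c(0.02, -0.03, -0.01), `10` = c(-0.02, -0.03, -0.01))
  for (i in names(face_off)) {
    o <- face_off[[i]]
    put(as.integer(i), nose[1] + o[1], nose[2] + o[2], nose[3] + o[3])
  }

  for (side in c("left", "right")) {
    sx <- if (side == "left") model$half_width else -model$half_width
    i <- function(name) landmark_index_of(paste0(side, "_", name))
    put(i("hip"), sx, hy, 0)
    put(i("shoulder"), sx, sy, 0)
    # leg chain
    th <- ang("hip", side)
    d1 <- rot_yz(1, 0, th)                        # hip -> knee, from the up vector
    kx <- sx; ky <- hy + model$thigh * d1$y; kz <- model$thigh * d1$z
    put(i("knee"), kx, ky, kz)
    tk <- ang("knee", side)
    d2 <- rot_yz(-d1$y, -d1$z, tk)                # knee -> ankle, from knee -> hip
    ax <- kx; ay <- ky + model$shank * d2$y; az <- kz + model$shank * d2$z
    put(i("ankle"), ax, ay, az)
    ta <- ang("ankle", side)
    d3 <- rot_yz(-d2$y, -d2$z, ta)                # ankle -> foot tip
    put(i("foot_index"), ax, ay + model$foot * d3$y, az + model$foot * d3$z)
    put(i("heel"), ax, ay - 0.03, az - 0.06)
    # arm chain
    ts_ <- ang("shoulder", side)
    a1 <- rot_yz(-1, 0, ts_)                      # shoulder -> elbow, from shoulder -> hip
    ex <- sx; ey <- sy + model$upper_arm * a1$y; ez <- model$upper_arm * a1$z
    put(i("elbow"), ex, ey, ez)
    te <- ang("elbow", side)
    a2 <- rot_yz(-a1$y, -a1$z, te)                # elbow -> wrist
    wx <- ex; wy <- ey + model$forearm * a2$y; wz <- ez + model$forearm * a2$z
    put(i("wrist"), wx, wy, wz)
    # hand filler, rigid along the forearm direction
    put(i("pinky"), wx, wy + 0.09 * a2$y, wz + 0.09 * a2$z)
    put(i("index"), wx + 0.015 * sign(sx), wy + 0.10 * a2$y, wz + 0.10 * a2$z)
    put(i("thumb"), wx + 0.025 * sign(sx), wy + 0.05 * a2$y, wz + 0.05 * a2$z)
  }

  if (script$coord_noise_sd > 0) {
    X <- X + stats::rnorm(nt * 33, 0, script$coord_noise_sd)
    Y <- Y + stats::rnorm(nt * 33, 0, script$coord_noise_sd)
    Z <- Z + stats::rnorm(nt * 33, 0, script$coord_noise_sd)
  }
  frames <- tibble(
    frame = rep(seq_len(nt), each = 33),
    t = rep(t, each = 33),
    index = rep(0:32, nt),
    x = as.vector(t(X)), y = as.vector(t(Y)), z = as.vector(t(Z)))
  pose_stream(frames, fps = fps, units = "m", source_id = "synthetic-fk")
}

#' Inject a constant angular deviation into a script
#'
#' Adds `offset` degrees to one joint's trajectory inside one segment,
#' leaving everything else untouched -- the ground truth for
#' deviation-detection experiments.
#'
#' @param script A motion script.
#' @param joint,side Target joint.
#' @param offset Degrees to add (may be negative).
#' @param segment Segment name.
#' @return A modified `rehab_motion_script`.
#' @export
inject_deviation <- function(script, joint, side, offset, segment) {
  stopifnot(inherits(script, "rehab_motion_script"))
  if (!segment %in% script$timeline$name) {
    stop_rehab(sprintf("unknown segment '%s'", segment), "rehabpose_config_error")
  }
  if (!joint %in% names(default_pose_angles()) || !side %in% c("left", "right", "center")) {
    stop_rehab(sprintf("unknown joint '%s' (%s)", joint, side), "rehabpose_config_error")
  }
  hit <- script$angles$segment == segment & script$angles$joint == joint &
    script$angles$side == side
  if (any(hit)) {
    script$angles$mean[hit] <- script$angles$mean[hit] + offset
  } else {
    script$angles <- bind_rows(
      script$angles,
      tibble(segment = segment, joint = joint, side = side,
             mean = unname(default_pose_angles()[joint]) + offset,
             amp = 0, freq = 0, phase = 0))
  }
  script
}

#' Specify a simulated trial cohort
#'
#' Defines the generative model for three-group x m-timepoint outcome data:
#' value(i in group g, time t) = baseline + group_g + time_t +
#' interaction_gt + b_i + e_it with subject effect b_i ~ N(0, sigma_b^2)
#' and residual e_it ~ N(0, sigma_e^2), giving compound-symmetric
#' within-subject correlation rho = sigma_b^2 / (sigma_b^2 + sigma_e^2).
#'
#' @param group_sizes Integer vector of per-group sizes.
#' @param baseline Grand mean.
#' @param group_effects Length-k vector of group main effects.
#' @param time_effects Length-m vector of time main effects.
#' @param interaction k x m matrix of group x time effects (default 0).
#' @param sigma_b,sigma_e Between-subject and residual SDs (> 0).
#' @param dropout Per-subject probability of dropping out after baseline.
#' @param group_labels,time_labels Level names.
#' @param measure Measure name stamped on the rows.
#' @return A `rehab_cohort_spec` list.
#' @export
cohort_spec <- function(group_sizes = c(23, 24, 23), baseline = 0,
                        group_effects = NULL, time_effects = NULL,
                        interaction = NULL,
                        sigma_b = sqrt(0.5), sigma_e = sqrt(0.5), dropout = 0,
                        group_labels = NULL, time_labels = c("pre", "mid", "post"),
                        measure = "outcome") {
  k <- length(group_sizes)
  m <- length(time_labels)
  group_effects <- group_effects %||% rep(0, k)
  time_effects <- time_effects %||% rep(0, m)
  interaction <- interaction %||% matrix(0, k, m)
  stopifnot(length(group_effects) == k, length(time_effects) == m,
            all(dim(interaction) == c(k, m)))
  check_number(sigma_b, "sigma_b", lo = 0, strict_lo = TRUE)
  check_number(sigma_e, "sigma_e", lo = 0, strict_lo = TRUE)
  check_number(dropout, "dropout", lo = 0, hi = 1)
  structure(list(group_sizes = group_sizes, baseline = baseline,
                 group_effects = group_effects, time_effects = time_effects,
                 interaction = interaction, sigma_b = sigma_b, sigma_e = sigma_e,
                 dropout = dropout,
                 group_labels = group_labels %||% paste0("group_", seq_len(k)),
                 time_labels = time_labels, measure = measure,
                 rho = sigma_b^2 / (sigma_b^2 + sigma_e^2)),
            class = "rehab_cohort_spec")
}

#' Generate a long-format trial dataset
#'
#' Draws one cohort from a [cohort_spec()] under the stated mixed model.
#' Dropout subjects lose all rows after a uniformly chosen dropout
#' timepoint (they are then excluded listwise by [rm_anova()]).
#'
#' @param spec A [cohort_spec()].
#' @param seed Mandatory integer seed.
#' @return Long tibble: `subject`, `group`, `time` (factor), `measure`,
#'   `value`.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "rehab_cohort_spec"))
  if (missing(seed)) stop_rehab("a seed is required", "rehabpose_parameter_error")
  set.seed(seed)
  k <- length(spec$group_sizes)
  m <- length(spec$time_labels)
  N <- sum(spec$group_sizes)
  g_idx <- rep(seq_len(k), spec$group_sizes)
  b <- stats::rnorm(N, 0, spec$sigma_b)
  eps <- matrix(stats::rnorm(N * m, 0, spec$sigma_e), N, m)
  mu <- outer(spec$group_effects[g_idx], rep(1, m)) +
    outer(rep(1, N), spec$time_effects) +
    spec$interaction[g_idx, , drop = FALSE] +
    spec$baseline
  val <- mu + b + eps
  out <- tibble(
    subject = rep(sprintf("s%03d", seq_len(N)), each = m),
    group = factor(rep(spec$group_labels[g_idx], each = m),
                   levels = spec$group_labels),
    time = factor(rep(spec$time_labels, N), levels = spec$time_labels),
    measure = spec$measure,
    value = as.vector(t(val)))
  if (spec$dropout > 0) {
    drops <- stats::runif(N) < spec$dropout
    drop_from <- sample(2:m, N, replace = TRUE)
    keep_mat <- outer(seq_len(N), seq_len(m),
                      function(i, t) !drops[i] | t < drop_from[i])
    out <- out[as.vector(t(keep_mat)), ]
  }
  out
}
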