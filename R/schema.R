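#' The 33-landmark full-body pose schema
#'
#' The landmark layout produced by full-body pose trackers of the BlazePose
#' family: 33 named points indexed 0--32, with 11 face points (indices 0--10,
#' the nose first), the upper-limb chain, 6 hand points (indices 17--22), the
#' pelvis, and the lower-limb chain down to heels and foot tips.
#'
#' @return A tibble with columns `index` (0--32), `name`, `region`
#'   (one of face, hand, torso, arm, leg, foot) and `side`
#'   (left/right/center).
#' @export
#' @examples
#' landmark_schema()
landmark_schema <- function() {
  tibble(
    index = 0:32,
    name = c(
      "nose",
      "left_eye_inner", "left_eye", "left_eye_outer",
      "right_eye_inner", "right_eye", "right_eye_outer",
      "left_ear", "right_ear", "mouth_left", "mouth_right",
      "left_shoulder", "right_shoulder",
      "left_elbow", "right_elbow",
      "left_wrist", "right_wrist",
      "left_pinky", "right_pinky", "left_index", "right_index",
      "left_thumb", "right_thumb",
      "left_hip", "right_hip",
      "left_knee", "right_knee",
      "left_ankle", "right_ankle",
      "left_heel", "right_heel",
      "left_foot_index", "right_foot_index"
    ),
    region = c(
      rep("face", 11),
      "torso", "torso",
      "arm", "arm", "arm", "arm",
      rep("hand", 6),
      "torso", "torso",
      "leg", "leg", "leg", "leg",
      "foot", "foot", "foot", "foot"
    ),
    side = c(
      "center",
      "left", "left", "left", "right", "right", "right",
      "left", "right", "left", "right",
      "left", "right", "left", "right", "left", "right",
      "left", "right", "left", "right", "left", "right",
      "left", "right", "left", "right", "left", "right",
      "left", "right", "left", "right"
    )
  )
}

# indices dropped when reducing to the 17-keypoint analysis skeleton:
# the 10 non-nose face points and the 6 hand points
dropped_landmark_indices <- function() c(1:10, 17:22)

#' Indices retained in the 17-keypoint reduced skeleton
#'
#' The nose (kept as the head/torso reference), shoulders, elbows, wrists,
#' hips, knees, ankles, heels and foot tips.
#'
#' @return Integer vector of 17 schema indices.
#' @export
retained_landmark_indices <- function() {
  setdiff(0:32, dropped_landmark_indices())
}

landmark_index_of <- function(name) {
  sch <- landmark_schema()
  i <- sch$index[match(name, sch$name)]
  if (anyNA(i)) {
    stop_rehab(paste0("unknown landmark name(s): ",
                      paste(name[is.na(i)], collapse = ", ")),
               "rehabpose_config_error")
  }
  i
}
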