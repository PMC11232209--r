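#' Compare a learner stream against a template library
#'
#' Resamples the learner's joint angles onto each template's normalized-time
#' grid and scans the signed deviation curve (learner minus template). One
#' finding is emitted per maximal contiguous grid run where the absolute
#' deviation exceeds the joint's tolerance band and the run covers at least
#' `min_run` of the grid; its direction (angle too large / too small) comes
#' from the deviation sign.
#'
#' @param learner Learner pose stream spanning the library's timeline.
#' @param library A [build_template()] library.
#' @param min_run Minimum run length as a fraction of the grid (default
#'   0.1), suppressing single-point flickers.
#' @param window Smoothing window applied to the learner stream.
#' @return Tibble of findings: `segment`, `joint`, `side`, `direction`
#'   (`too_large`/`too_small`), `magnitude` (mean absolute deviation over
#'   the run, degrees), `g_start`, `g_end` (normalized-time span).
#' @export
compare_to_template <- function(learner, library, min_run = 0.1, window = 5) {
  dev <- deviation_curves(learner, library, window)
  G <- library$G
  min_len <- max(1L, ceiling(min_run * G))
  dev |>
    summarise(findings = list(runs_over_tolerance(.data$dev, .data$tolerance[1], min_len, G)),
              .by = c("segment", "joint", "side")) |>
    tidyr::unnest("findings")
}

# signed learner-minus-template deviation on the template grid
deviation_curves <- function(learner, library, window = 5) {
  tl <- library$timeline
  if (nrow(learner) == 0 ||
      min(learner$t) > min(tl$start) + 1e-9 || max(learner$t) < max(tl$end) - 1e-9) {
    stop_rehab("learner stream does not cover the template timeline",
               "rehabpose_coverage_error")
  }
  angles <- extract_angle_series(smooth_stream(learner, window), library$joints)
  G <- library$G
  lc <- pmap(tl[, c("name", "start", "end")], function(name, start, end) {
    seg <- list(start = start, end = end)
    angles |>
      summarise(learner_angle = list(resample_normalized(pick("t", "angle"), seg, G)),
                .by = c("joint", "side")) |>
      mutate(segment = name) |>
      tidyr::unnest_longer("learner_angle", indices_to = "g")
  }) |> list_rbind()
  library$curves |>
    inner_join(lc, by = c("segment", "joint", "side", "g")) |>
    mutate(dev = .data$learner_angle - .data$angle) |>
    arrange(.data$segment, .data$joint, .data$side, .data$g)
}

runs_over_tolerance <- function(dev, tol, min_len, G) {
  over <- !is.na(dev) & abs(dev) > tol
  if (!any(over)) {
    return(tibble(direction = character(), magnitude = double(),
                  g_start = double(), g_end = double()))
  }
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble(
    direction = map_chr(which(keep), ~ if (mean(dev[starts[.x]:ends[.x]]) > 0) "too_large" else "too_small"),
    magnitude = map_dbl(which(keep), ~ mean(abs(dev[starts[.x]:ends[.x]]))),
    g_start = (starts[keep] - 1) / max(G - 1, 1),
    g_end = (ends[keep] - 1) / max(G - 1, 1)
  )
}

#' Render a corrective-feedback message
#'
#' Produces the fixed prompt grammar used for on-screen guidance, e.g.
#' `"movement 3: the right knee joint is bent at too large of an angle"`.
#'
#' @param finding One finding row (fields `segment`, `joint`, `side`,
#'   `direction`), or a findings tibble (vectorized).
#' @return Character vector of messages.
#' @export
render_feedback <- function(finding) {
  dir_word <- ifelse(finding$direction == "too_large", "large", "small")
  sprintf("%s: the %s %s joint is bent at too %s of an angle",
          finding$segment, finding$side, finding$joint, dir_word)
}

#' Score a learner session against a template library
#'
#' The per-segment accuracy score is the percentage of (joint, grid-point)
#' cells whose absolute deviation from the template lies within the joint's
#' tolerance; the overall score is the duration-weighted mean across
#' segments. Findings and their rendered messages are embedded.
#'
#' @inheritParams compare_to_template
#' @return A `rehab_session_report` list: `segments` (tibble with `segment`,
#'   `score`, `duration`), `overall` (0--100), `findings`, `messages`.
#' @export
score_session <- function(learner, library, min_run = 0.1, window = 5) {
  dev <- deviation_curves(learner, library, window)
  seg_scores <- dev |>
    summarise(score = 100 * mean(!is.na(.data$dev) & abs(.data$dev) <= .data$tolerance),
              .by = "segment") |>
    left_join(library$timeline |> mutate(duration = .data$end - .data$start) |>
                select(segment = "name", "duration"),
              by = "segment")
  findings <- compare_to_template(learner, library, min_run, window)
  structure(
    list(segments = seg_scores,
         overall = stats::weighted.mean(seg_scores$score, seg_scores$duration),
         findings = findings,
         messages = if (nrow(findings)) render_feedback(findings) else character()),
    class = "rehab_session_report")
}

#' @export
print.rehab_session_report <- function(x, ...) {
  cat(sprintf("<session report: overall accuracy %.1f over %d segments, %d finding(s)>\n",
              x$overall, nrow(x$segments), nrow(x$findings)))
  if (length(x$messages)) cat(paste0("  - ", x$messages, collapse = "\n"), "\n")
  invisible(x)
}

#' Initialise state for streaming (real-time) feedback
#'
#' @param library Template library to compare against.
#' @param half_life EWMA half-life of the deviation tracker, seconds
#'   (default 0.5).
#' @param refractory Per-joint quiet period after an emission, seconds
#'   (default 3).
#' @param window Smoothing window (frames) for incoming coordinates.
#' @return A `rehab_feedback_state` environment.
#' @export
feedback_state <- function(library, half_life = 0.5, refractory = 3, window = 5) {
  st <- new.env(parent = emptyenv())
  st$library <- library
  st$half_life <- half_life
  st$refractory <- refractory
  st$ewma <- NULL     # tibble joint, side, value
  st$last_emit <- NULL
  st$last_t <- -Inf
  class(st) <- "rehab_feedback_state"
  st
}

#' Incremental feedback on arriving frames
#'
#' Streaming counterpart of [compare_to_template()]: maintains an
#' exponentially weighted signed deviation per joint (half-life
#' configurable) and emits a finding when the weighted deviation crosses the
#' joint's tolerance, with a per-joint refractory period so a sustained
#' error is reported once. On zero-noise input the emitted joints and
#' directions agree with batch comparison.
#'
#' @param frames Tibble of one or more new frames (same columns as a pose
#'   stream), timestamps strictly after all previously seen frames.
#' @param state A [feedback_state()].
#' @return Tibble of findings emitted for these frames (may be empty);
#'   `state` is updated in place.
#' @export
stream_feedback <- function(frames, state) {
  lib <- state$library
  out <- list()
  for (f in split(as_tibble(frames), frames$frame)) {
    t <- f$t[1]
    if (t <= state$last_t) {
      stop_rehab("out-of-order frame in streaming feedback", "rehabpose_ordering_error")
    }
    seg <- lib$timeline |> filter(.data$start <= t, t <= .data$end)
    if (nrow(seg) == 0) { state$last_t <- t; next }
    seg <- seg[1, ]
    u <- (t - seg$start) / (seg$end - seg$start)
    g <- 1 + round(u * (lib$G - 1))
    ref <- lib$curves |> filter(.data$segment == seg$name, .data$g == !!g)
    obs <- extract_angle_series(pose_stream(f, fps = attr(frames, "fps") %||% 30),
                                lib$joints) |>
      select("joint", "side", obs_angle = "angle")
    dev_now <- ref |>
      inner_join(obs, by = c("joint", "side")) |>
      mutate(dev = .data$obs_angle - .data$angle)
    dt <- if (is.finite(state$last_t)) t - state$last_t else 0
    lambda <- if (state$half_life > 0) 2^(-dt / state$half_life) else 0
    prev <- state$ewma %||% (dev_now |> select("joint", "side") |> mutate(value = 0))
    cur <- dev_now |>
      left_join(prev, by = c("joint", "side")) |>
      mutate(value = ifelse(is.na(.data$value), .data$dev,
                            lambda * .data$value + (1 - lambda) * .data$dev))
    emit <- cur |> filter(!is.na(.data$value), abs(.data$value) > .data$tolerance)
    if (nrow(emit) > 0) {
      last <- state$last_emit %||% tibble(joint = character(), side = character(),
                                          t_emit = double())
      emit <- emit |>
        left_join(last, by = c("joint", "side")) |>
        filter(is.na(.data$t_emit) | t - .data$t_emit >= state$refractory)
    }
    if (nrow(emit) > 0) {
      found <- emit |>
        transmute(segment = seg$name, .data$joint, .data$side,
                  direction = ifelse(.data$value > 0, "too_large", "too_small"),
                  magnitude = abs(.data$value), t = t)
      out[[length(out) + 1]] <- found
      upd <- found |> transmute(.data$joint, .data$side, t_emit = t)
      state$last_emit <- bind_rows(
        (state$last_emit %||% upd[0, ]) |> anti_join(upd, by = c("joint", "side")),
        upd)
    }
    state$ewma <- cur |> select("joint", "side", "value")
    state$last_t <- t
  }
  if (length(out)) list_rbind(out) else
    tibble(segment = character(), joint = character(), side = character(),
           direction = character(), magnitude = double(), t = double())
}
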