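#' Build and validate a movement timeline
#'
#' A routine (e.g. the 24-form Taichi sequence) is segmented into named
#' movements by fixed time settings. Segments must be non-overlapping and
#' each must have positive duration.
#'
#' @param segments Tibble or data frame with columns `name`, `start`, `end`
#'   (seconds), or a path to a YAML file containing a list of
#'   `{name, start, end}` entries.
#' @return A `rehab_timeline` tibble ordered by `start`, with an `order`
#'   column.
#' @export
segment_timeline <- function(segments) {
  if (is.character(segments) && length(segments) == 1) {
    spec <- yaml::read_yaml(segments)
    segments <- map(spec, ~ tibble(name = .x$name, start = .x$start, end = .x$end)) |>
      list_rbind()
  }
  segments <- as_tibble(segments)
  if (nrow(segments) == 0) {
    stop_rehab("timeline must contain at least one segment", "rehabpose_timeline_error")
  }
  if (!all(c("name", "start", "end") %in% names(segments))) {
    stop_rehab("timeline needs columns name, start, end", "rehabpose_timeline_error")
  }
  bad <- segments |> filter(.data$start >= .data$end)
  if (nrow(bad) > 0) {
    stop_rehab(sprintf("segment '%s' has start >= end", bad$name[1]),
               "rehabpose_timeline_error")
  }
  tl <- segments |> arrange(.data$start) |> mutate(order = row_number())
  if (nrow(tl) > 1) {
    ov <- which(tl$start[-1] < tl$end[-nrow(tl)])
    if (length(ov) > 0) {
      stop_rehab(sprintf("segments '%s' and '%s' overlap",
                         tl$name[ov[1]], tl$name[ov[1] + 1]),
                 "rehabpose_timeline_error")
    }
  }
  class(tl) <- c("rehab_timeline", class(tibble()))
  tl
}

#' Resample an angle trajectory onto a normalized-time grid
#'
#' Linearly interpolates one joint's angle samples onto `G` equally spaced
#' points of normalized time in \[0, 1\] across a segment, making streams of
#' unequal duration comparable.
#'
#' @param series Tibble with columns `t` and `angle` (one joint).
#' @param segment One timeline row (fields `start`, `end`).
#' @param G Grid size (number of points, >= 1).
#' @return Numeric vector of `G` angles.
#' @export
resample_normalized <- function(series, segment, G = 100) {
  check_number(G, "G", lo = 1)
  if (G == 1) {
    warn("grid size 1 collapses the segment to a single mean pose")
  }
  keep <- series |> filter(!is.na(.data$angle)) |> arrange(.data$t)
  if (nrow(keep) < 2 || min(keep$t) > segment$start + 1e-9 ||
      max(keep$t) < segment$end - 1e-9) {
    stop_rehab(sprintf("angle series does not cover segment [%g, %g]",
                       segment$start, segment$end),
               "rehabpose_coverage_error")
  }
  grid_t <- if (G == 1) mean(c(segment$start, segment$end)) else
    seq(segment$start, segment$end, length.out = G)
  stats::approx(keep$t, keep$angle, xout = grid_t, ties = "ordered")$y
}

#' Build an instructor template library
#'
#' Runs the full feature pipeline on an instructor stream -- smoothing,
#' keypoint reduction (implicit: angle joints only reference retained
#' landmarks), angle extraction, per-segment normalized-time resampling --
#' and stores one reference curve per (segment, joint) with a tolerance
#' band.
#'
#' @param instructor Instructor pose stream spanning the timeline.
#' @param timeline A [segment_timeline()].
#' @param joints Joint definitions (default [default_joint_triples()]).
#' @param G Normalized-time grid size per segment (default 100).
#' @param tolerance Allowed deviation in degrees, a single number or a
#'   named vector by joint name (default 10).
#' @param window Smoothing window passed to [smooth_stream()].
#' @return A `rehab_template_library` list with `curves` (tibble: segment,
#'   joint, side, grid index, angle, tolerance), `timeline`, `joints`, `G`.
#' @export
build_template <- function(instructor, timeline, joints = default_joint_triples(),
                           G = 100, tolerance = 10, window = 5) {
  stopifnot(inherits(timeline, "rehab_timeline"))
  if (nrow(instructor) == 0 ||
      min(instructor$t) > min(timeline$start) + 1e-9 ||
      max(instructor$t) < max(timeline$end) - 1e-9) {
    stop_rehab("instructor stream does not span the timeline", "rehabpose_coverage_error")
  }
  tol_of <- function(joint) {
    if (is.null(names(tolerance))) return(unname(tolerance[1]))
    v <- unname(tolerance[joint])
    if (is.na(v)) 10 else v
  }
  angles <- extract_angle_series(smooth_stream(instructor, window), joints)
  curves <- pmap(timeline[, c("name", "start", "end")], function(name, start, end) {
    seg <- list(start = start, end = end)
    angles |>
      summarise(angle = list(resample_normalized(pick("t", "angle"), seg, G)),
                .by = c("joint", "side")) |>
      mutate(segment = name) |>
      tidyr::unnest_longer("angle", indices_to = "g")
  }) |> list_rbind() |>
    mutate(tolerance = map_dbl(.data$joint, tol_of)) |>
    select("segment", "joint", "side", "g", "angle", "tolerance")
  if (any(curves$tolerance <= 0)) {
    stop_rehab("tolerances must be positive", "rehabpose_parameter_error")
  }
  structure(
    list(curves = curves, timeline = timeline, joints = joints, G = G,
         meta = list(schema_version = 1L, window = window,
                     source_id = attr(instructor, "source_id") %||% "")),
    class = "rehab_template_library")
}

#' @export
print.rehab_template_library <- function(x, ...) {
  cat(sprintf("<template library: %d segments x %d joints, grid G=%d>\n",
              nrow(x$timeline), nrow(x$joints), x$G))
  invisible(x)
}

#' Persist a template library as JSON
#'
#' @param library A [build_template()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_template_library <- function(library, path) {
  doc <- list(schema_version = library$meta$schema_version,
              G = library$G, meta = library$meta,
              timeline = as.data.frame(library$timeline),
              joints = as.data.frame(library$joints),
              curves = as.data.frame(library$curves))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 9, dataframe = "columns")
  invisible(path)
}

#' Read back a persisted template library
#'
#' @param path JSON file produced by [write_template_library()].
#' @return A `rehab_template_library`.
#' @export
read_template_library <- function(path) {
  doc <- jsonlite::fromJSON(path)
  tl <- segment_timeline(as_tibble(doc$timeline)[, c("name", "start", "end")])
  structure(
    list(curves = as_tibble(doc$curves), timeline = tl,
         joints = as_tibble(doc$joints), G = doc$G,
         meta = doc$meta),
    class = "rehab_template_library")
}
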