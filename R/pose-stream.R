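#' Construct a pose stream
#'
#' A pose stream is an ordered set of time-stamped frames, each carrying one
#' 3D keypoint per landmark of the 33-point schema. It is stored as a long
#' tibble (one row per frame x landmark) with stream-level metadata held in
#' attributes, so that the usual dplyr verbs apply directly.
#'
#' @param frames Tibble with columns `frame`, `t`, `index`, `x`, `y`, `z`
#'   and optionally `visibility` (missing visibility is taken as 1).
#' @param fps Nominal frames per second (> 0). Timestamps are authoritative;
#'   `fps` is advisory metadata that the stored timestamps must agree with
#'   to within 10%.
#' @param units Coordinate unit, declared not inferred (e.g. "m" or
#'   "normalized").
#' @param source_id Free-text provenance label.
#' @return A validated `rehab_pose_stream` tibble.
#' @export
pose_stream <- function(frames, fps = 30, units = "m", source_id = "") {
  frames <- as_tibble(frames)
  if (nrow(frames) > 0 && !"name" %in% names(frames)) {
    sch <- landmark_schema()
    frames$name <- sch$name[match(frames$index, sch$index)]
  }
  if (!"visibility" %in% names(frames)) frames$visibility <- rep(1, nrow(frames))
  frames$visibility[is.na(frames$visibility)] <- 1
  cols <- c("frame", "t", "index", "name", "x", "y", "z", "visibility")
  if (nrow(frames) == 0) {
    frames <- tibble(frame = integer(), t = double(), index = integer(),
                     name = character(), x = double(), y = double(),
                     z = double(), visibility = double())
  }
  out <- frames[, cols]
  attr(out, "fps") <- fps
  attr(out, "units") <- units
  attr(out, "source_id") <- source_id
  class(out) <- c("rehab_pose_stream", class(tibble()))
  validate_pose_stream(out)
}

#' @export
print.rehab_pose_stream <- function(x, ...) {
  nf <- length(unique(x$frame))
  cat(sprintf("<pose stream: %d frames, %.5g fps, units '%s'%s>\n",
              nf, attr(x, "fps"), attr(x, "units"),
              if (nzchar(attr(x, "source_id") %||% "")) paste0(", source ", attr(x, "source_id")) else ""))
  NextMethod()
}

#' Validate a pose stream against the schema invariants
#'
#' Checks that every frame carries exactly one keypoint per schema index,
#' coordinates are finite, visibilities lie in \[0, 1\], timestamps are
#' strictly increasing, and frame spacing agrees with the declared fps to
#' within 10%. Violations raise typed errors; nothing is silently repaired.
#'
#' @param stream A `rehab_pose_stream`.
#' @return The stream, invisibly usable in a pipe.
#' @export
validate_pose_stream <- function(stream) {
  fps <- attr(stream, "fps")
  check_number(fps, "fps", lo = 0, strict_lo = TRUE)
  if (nrow(stream) == 0) return(stream)
  if (!all(is.finite(stream$x) & is.finite(stream$y) & is.finite(stream$z))) {
    stop_rehab("non-finite coordinates in pose stream", "rehabpose_schema_error")
  }
  if (any(stream$visibility < 0 | stream$visibility > 1)) {
    stop_rehab("visibility values outside [0, 1]", "rehabpose_schema_error")
  }
  per_frame <- stream |>
    summarise(
      n = n(), t = t[1], dup = anyDuplicated(index) > 0,
      missing = paste(setdiff(0:32, index), collapse = ","),
      .by = "frame"
    )
  bad <- per_frame |> filter(.data$n != 33L | .data$dup | nzchar(.data$missing))
  if (nrow(bad) > 0) {
    stop_rehab(sprintf(
      "frame %s does not carry exactly one keypoint per schema index (missing: %s)",
      bad$frame[1], if (nzchar(bad$missing[1])) bad$missing[1] else "none; duplicated indices"),
      "rehabpose_schema_error")
  }
  if (anyNA(per_frame$t) || any(per_frame$t < 0)) {
    stop_rehab("timestamps must be non-negative", "rehabpose_schema_error")
  }
  ts <- per_frame$t[order(per_frame$frame)]
  if (any(diff(ts) <= 0)) {
    stop_rehab("timestamps not strictly increasing across frames",
               "rehabpose_ordering_error")
  }
  tvar <- stream |> summarise(nt = length(unique(t)), .by = "frame")
  if (any(tvar$nt != 1L)) {
    stop_rehab("inconsistent timestamps within a frame", "rehabpose_schema_error")
  }
  if (length(ts) > 1) {
    dt <- diff(ts)
    if (any(abs(dt - 1 / fps) > 0.1 / fps)) {
      stop_rehab("frame spacing inconsistent with declared fps (>10% off)",
                 "rehabpose_schema_error")
    }
  }
  stream
}

stream_meta <- function(stream) {
  list(fps = attr(stream, "fps"), units = attr(stream, "units"),
       source_id = attr(stream, "source_id") %||% "")
}

#' Read a pose-landmark stream from disk
#'
#' Two plain-text dialects are supported. `jsonl`: a metadata header object
#' on the first line, then one JSON object per frame
#' `{"t": .., "landmarks": [{"i","x","y","z","v"}, ...]}`. `csv`: commented
#' `# key: value` metadata lines followed by long-format columns
#' `frame,t,index,name,x,y,z,visibility`.
#'
#' @param path File to read.
#' @param dialect `"jsonl"` or `"csv"`.
#' @return A validated [pose_stream()] with frames sorted by timestamp.
#' @export
read_pose_stream <- function(path, dialect = c("jsonl", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_rehab(sprintf("no such file: %s", path), "rehabpose_io_error")
  }
  if (dialect == "jsonl") read_pose_jsonl(path) else read_pose_csv(path)
}

read_pose_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop_rehab("empty jsonl file: no metadata header", "rehabpose_parse_error")
  }
  meta <- tryCatch(jsonlite::fromJSON(lines[1]),
                   error = function(e) stop_rehab(
                     sprintf("malformed record at line 1: %s", conditionMessage(e)),
                     "rehabpose_parse_error"))
  frames <- imap(lines[-1], function(line, i) {
    rec <- tryCatch(jsonlite::fromJSON(line),
                    error = function(e) stop_rehab(
                      sprintf("malformed record at line %d: %s", i + 1, conditionMessage(e)),
                      "rehabpose_parse_error"))
    lm <- as_tibble(rec$landmarks)
    if (is.null(rec$t) || is.null(lm$i)) {
      stop_rehab(sprintf("malformed record at line %d: missing t or landmarks", i + 1),
                 "rehabpose_parse_error")
    }
    tibble(frame = i, t = rec$t, index = as.integer(lm$i),
           x = lm$x, y = lm$y, z = lm$z,
           visibility = if (is.null(lm$v)) rep(1, nrow(lm)) else lm$v)
  }) |> list_rbind()
  build_sorted_stream(frames, meta)
}

read_pose_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    stop_rehab("csv pose file has no column header", "rehabpose_parse_error")
  }
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE),
    error = function(e) stop_rehab(
      sprintf("malformed csv record: %s", conditionMessage(e)), "rehabpose_parse_error"))
  need <- c("frame", "t", "index", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_rehab(paste0("csv pose file missing columns: ",
                      paste(setdiff(need, names(df)), collapse = ", ")),
               "rehabpose_parse_error")
  }
  meta$fps <- as.numeric(meta$fps %||% 30)
  build_sorted_stream(as_tibble(df), meta)
}

build_sorted_stream <- function(frames, meta) {
  if (nrow(frames) > 0) {
    # renumber frames by timestamp order so downstream code can rely on it
    ord <- frames |> distinct(.data$frame, .data$t) |> arrange(.data$t)
    frames$frame <- match(frames$frame, ord$frame)
    frames <- frames |> arrange(.data$frame, .data$index)
  }
  pose_stream(frames,
              fps = as.numeric(meta$fps %||% 30),
              units = as.character(meta$units %||% "m"),
              source_id = as.character(meta$source_id %||% ""))
}

#' Write a pose stream to disk
#'
#' Inverse of [read_pose_stream()]; coordinates survive a round trip to at
#' least six decimal places.
#'
#' @param stream A valid pose stream.
#' @param path Output file.
#' @param dialect `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_pose_stream <- function(stream, path, dialect = c("jsonl", "csv")) {
  dialect <- match.arg(dialect)
  validate_pose_stream(stream)
  meta <- stream_meta(stream)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_rehab(
                    sprintf("cannot write %s: %s", path, conditionMessage(e)),
                    "rehabpose_io_error"))
  on.exit(close(con))
  if (dialect == "jsonl") {
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), con)
    if (nrow(stream) > 0) {
      for (f in split(stream, stream$frame)) {
        rec <- list(t = f$t[1],
                    landmarks = data.frame(i = f$index, x = f$x, y = f$y,
                                           z = f$z, v = f$visibility))
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 12,
                                    dataframe = "rows"), con)
      }
    }
  } else {
    writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
    df <- as.data.frame(stream)[, c("frame", "t", "index", "name", "x", "y", "z", "visibility")]
    for (v in c("t", "x", "y", "z", "visibility")) df[[v]] <- formatC(df[[v]], digits = 12, format = "g")
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
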