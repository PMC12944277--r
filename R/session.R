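#' Hindlimb landmarks tracked per frame
#'
#' Ordered proximal to distal along the hindlimb: iliac crest, hip, knee,
#' ankle, metatarsophalangeal (MTP) joint.
#' @export
GAIT_LANDMARKS <- c("iliac_crest", "hip", "knee", "ankle", "mtp")

#' Construct a gait session from a landmark table
#'
#' A gait session is a tibble with one row per video frame and, for each of
#' the five hindlimb landmarks (`iliac_crest`, `hip`, `knee`, `ankle`,
#' `mtp`), columns `<landmark>_x`, `<landmark>_y` and
#' `<landmark>_likelihood`, plus a 0-based `frame` column. Recording
#' metadata (frame rate, spatial units, subject, experimental group, travel
#' direction) travels as attributes so the table pipes through dplyr verbs
#' unharmed.
#'
#' @param frames data frame with a `frame` column and the 15 landmark
#'   columns described above.
#' @param fps frame rate in frames per second (default 156, the acquisition
#'   rate of the high-speed camera setup this package targets).
#' @param units `"pixel"` or `"mm"`.
#' @param mm_per_pixel scalar mm-per-pixel factor; required when
#'   `units = "mm"`.
#' @param subject free-text subject label.
#' @param group `"sham"`, `"sci"` or `"unknown"`.
#' @param direction `+1` if the animal travels toward +x in image
#'   coordinates, `-1` otherwise. Image coordinates have y growing downward.
#' @return a `gait_session` tibble.
#' @export
gait_session <- function(frames, fps = 156, units = c("pixel", "mm"),
                         mm_per_pixel = NA_real_, subject = "unknown",
                         group = c("unknown", "sham", "sci"),
                         direction = 1) {
  units <- match.arg(units)
  group <- match.arg(group)
  if (fps <= 0) abort("`fps` must be positive.", class = "gaitloop_error_value")
  if (units == "mm" && (is.na(mm_per_pixel) || mm_per_pixel <= 0)) {
    abort("`mm_per_pixel` must be a positive scalar when `units = \"mm\"`.",
          class = "gaitloop_error_value")
  }
  frames <- tibble::as_tibble(frames)
  needed <- session_columns()
  missing <- setdiff(needed, names(frames))
  if (length(missing) > 0) {
    abort(paste0("Landmark table is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "gaitloop_error_format")
  }
  frames <- frames[, needed]
  if (nrow(frames) > 0) {
    if (any(diff(frames$frame) <= 0)) {
      abort("`frame` must be strictly increasing.",
            class = "gaitloop_error_value")
    }
    lik <- as.matrix(frames[, paste0(GAIT_LANDMARKS, "_likelihood")])
    if (any(lik < 0 | lik > 1, na.rm = TRUE)) {
      abort("Likelihoods must lie in [0, 1].", class = "gaitloop_error_value")
    }
  }
  structure(frames,
            class = c("gait_session", class(frames)),
            fps = fps, units = units, mm_per_pixel = mm_per_pixel,
            subject = subject, group = group, direction = direction)
}

session_columns <- function() {
  c("frame",
    as.vector(t(outer(GAIT_LANDMARKS, c("_x", "_y", "_likelihood"),
                      paste0))))
}

#' Session metadata accessors
#'
#' @param session a `gait_session`.
#' @return `session_fps()` the frame rate; `session_units()` the coordinate
#'   units; `session_group()` the group label; `session_direction()` the
#'   travel-direction sign.
#' @export
session_fps <- function(session) attr(session, "fps")

#' @rdname session_fps
#' @export
session_units <- function(session) attr(session, "units")

#' @rdname session_fps
#' @export
session_group <- function(session) attr(session, "group")

#' @rdname session_fps
#' @export
session_direction <- function(session) attr(session, "direction")

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("<gait_session> %d frames @ %g fps (%s, group: %s)\n",
              nrow(x), attr(x, "fps"), attr(x, "units"), attr(x, "group")))
  NextMethod()
}

#' Convert pixel coordinates to millimetres
#'
#' Applies the scalar spatial calibration obtained from a checkerboard
#' calibration cube of known square size: every coordinate is multiplied by
#' `square_size_mm / square_size_px`. Likelihoods and frame indices are
#' unchanged. Joint angles are invariant under this uniform scaling.
#'
#' @param session a `gait_session` in pixel units.
#' @param square_size_mm physical size of one calibration square (mm).
#' @param square_size_px apparent size of the same square (pixels).
#' @return the calibrated `gait_session` in mm units.
#' @export
apply_calibration <- function(session, square_size_mm, square_size_px) {
  if (square_size_mm <= 0 || square_size_px <= 0) {
    abort("Calibration square sizes must be positive.",
          class = "gaitloop_error_value")
  }
  if (session_units(session) != "pixel") {
    abort("Session is already calibrated to mm.",
          class = "gaitloop_error_state")
  }
  scale <- square_size_mm / square_size_px
  coord_cols <- as.vector(t(outer(GAIT_LANDMARKS, c("_x", "_y"), paste0)))
  out <- session
  for (col in coord_cols) out[[col]] <- out[[col]] * scale
  attr(out, "units") <- "mm"
  attr(out, "mm_per_pixel") <- scale
  out
}

#' Read a pose-estimation landmark CSV
#'
#' Reads the three-header-row CSV dialect emitted by markerless
#' pose-estimation tools (row 1: scorer, row 2: bodyparts, row 3: coords),
#' expecting exactly the five hindlimb landmarks with `x`, `y` and
#' `likelihood` columns each. Extra body parts are rejected so that silent
#' landmark mix-ups cannot occur.
#'
#' @param path CSV file path.
#' @param fps frame rate of the recording (frames per second).
#' @inheritParams gait_session
#' @return a `gait_session`.
#' @export
read_pose_csv <- function(path, fps = 156, subject = "unknown",
                          group = c("unknown", "sham", "sci"),
                          direction = 1) {
  group <- match.arg(group)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "gaitloop_error_io")
  }
  lines <- readr::read_lines(path)
  if (length(lines) < 4) {
    abort("Pose CSV must have 3 header rows and at least 1 data row.",
          class = "gaitloop_error_format")
  }
  split_row <- function(l) strsplit(l, ",", fixed = TRUE)[[1]]
  bodyparts <- split_row(lines[2])[-1]
  coords <- split_row(lines[3])[-1]
  if (length(bodyparts) != length(coords)) {
    abort("Header rows disagree on column count.",
          class = "gaitloop_error_format")
  }
  extra <- setdiff(unique(bodyparts), GAIT_LANDMARKS)
  if (length(extra) > 0) {
    abort(paste0("Unknown body parts in pose CSV: ",
                 paste(extra, collapse = ", ")),
          class = "gaitloop_error_format")
  }
  key <- paste0(bodyparts, "_", coords)
  for (lm in GAIT_LANDMARKS) {
    want <- paste0(lm, "_", c("x", "y", "likelihood"))
    absent <- setdiff(want, key)
    if (length(absent) > 0) {
      abort(paste0("Pose CSV is missing column(s) for landmark \"", lm,
                   "\": ", paste(absent, collapse = ", ")),
            class = "gaitloop_error_format")
    }
  }
  data_lines <- lines[-(1:3)]
  data_lines <- data_lines[nzchar(data_lines)]
  cells <- strsplit(data_lines, ",", fixed = TRUE)
  ncol_exp <- length(key) + 1
  bad <- which(lengths(cells) != ncol_exp)
  if (length(bad) > 0) {
    abort(paste0("Row ", bad[1], " has ", lengths(cells)[bad[1]],
                 " cells, expected ", ncol_exp, "."),
          class = "gaitloop_error_format")
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(cells))),
                nrow = length(cells), byrow = TRUE)
  if (anyNA(mat)) {
    bad_row <- which(apply(mat, 1, anyNA))[1]
    abort(paste0("Non-numeric cell in data row ", bad_row, "."),
          class = "gaitloop_error_parse")
  }
  frames <- tibble::as_tibble(as.data.frame(mat[, -1, drop = FALSE]),
                              .name_repair = "minimal")
  names(frames) <- key
  frames <- frames[, setdiff(session_columns(), "frame")]
  frames <- tibble::add_column(frames, frame = as.integer(mat[, 1]),
                               .before = 1)
  gait_session(frames, fps = fps, subject = subject, group = group,
               direction = direction)
}

#' Write a gait session as a pose-estimation CSV
#'
#' Emits the same three-header-row dialect accepted by [read_pose_csv()],
#' so write/read round trips reproduce the session.
#'
#' @param session a non-empty `gait_session`.
#' @param path output file path.
#' @param scorer scorer label written in the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(session, path, scorer = "gaitloop") {
  if (nrow(session) == 0) {
    abort("Cannot write an empty session.", class = "gaitloop_error_value")
  }
  key <- setdiff(session_columns(), "frame")
  bodyparts <- sub("_(x|y|likelihood)$", "", key)
  coords <- sub("^.*_(x|y|likelihood)$", "\\1", key)
  h1 <- paste(c("scorer", rep(scorer, length(key))), collapse = ",")
  h2 <- paste(c("bodyparts", bodyparts), collapse = ",")
  h3 <- paste(c("coords", coords), collapse = ",")
  vals <- as.matrix(as.data.frame(session)[, key])
  body <- paste(session$frame,
                apply(vals, 1, function(r) {
                  paste(formatC(r, format = "f", digits = 6),
                        collapse = ",")
                }),
                sep = ",")
  con <- tryCatch(file(path, "w"),
                  error = function(e) {
                    abort(paste0("Cannot open for writing: ", path),
                          class = "gaitloop_error_io")
                  })
  on.exit(close(con))
  writeLines(c(h1, h2, h3, body), con)
  invisible(path)
}
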