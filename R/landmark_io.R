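#' I/O configuration
#'
#' Controls how pose CSV files are interpreted: how file column names map onto
#' the eight canonical landmarks, and the recording metadata that the CSV
#' dialect itself does not carry.
#'
#' @param aliases Named character vector mapping file bodypart names to
#'   canonical landmark names; merged over [default_aliases()]. Matching is
#'   case-insensitive.
#' @param image_width,image_height Frame size in pixels.
#' @param fps Frame rate, frames per second.
#'
#' @return A list of class `io_config`.
#' @export
io_config <- function(aliases = character(), image_width = 1920,
                      image_height = 1080, fps = 30) {
  full <- default_aliases()
  if (length(aliases) > 0) {
    stopifnot(!is.null(names(aliases)))
    full[tolower(names(aliases))] <- unname(aliases)
  }
  structure(
    list(aliases = full, image_width = image_width,
         image_height = image_height, fps = fps),
    class = "io_config"
  )
}

#' Default landmark-name aliases
#'
#' Pose tools name their labels freely; the reader maps common spellings onto
#' the canonical set via this table (all keys lower-case).
#'
#' @return Named character vector, file name (lower-case) -> canonical name.
#' @export
default_aliases <- function() {
  canon <- setNames(LANDMARKS, tolower(LANDMARKS))
  extra <- c(
    "left_shoulder" = "L_shoulder", "right_shoulder" = "R_shoulder",
    "lshoulder" = "L_shoulder", "rshoulder" = "R_shoulder",
    "lsho" = "L_shoulder", "rsho" = "R_shoulder",
    "left_elbow" = "L_elbow", "right_elbow" = "R_elbow",
    "lelbow" = "L_elbow", "relbow" = "R_elbow",
    "lelb" = "L_elbow", "relb" = "R_elbow",
    "left_wrist" = "L_wrist", "right_wrist" = "R_wrist",
    "lwrist" = "L_wrist", "rwrist" = "R_wrist",
    "lwra" = "L_wrist", "rwra" = "R_wrist",
    "left_hip" = "L_hip", "right_hip" = "R_hip",
    "lhip" = "L_hip", "rhip" = "R_hip",
    "lasi" = "L_hip", "rasi" = "R_hip"
  )
  c(canon, extra)
}

#' Read a landmark trace from a pose CSV
#'
#' Understands two layouts. The standard pose-tool dialect has three header
#' rows (`scorer`, `bodyparts`, `coords`) followed by one row per frame of
#' `x, y, likelihood` triples per bodypart. The flat alternative is an
#' ordinary CSV with a `frame` column and `<landmark>_x`, `<landmark>_y` and
#' optionally `<landmark>_likelihood` columns; a missing likelihood column is
#' treated as likelihood 1 for every frame (with a message).
#'
#' @param path Path to the CSV file.
#' @param config An [io_config()].
#' @param trial_id,participant_id,group Metadata for the returned trace;
#'   defaults derive the trial id from the file name.
#'
#' @return A [landmark_trace()].
#' @export
read_pose_csv <- function(path, config = io_config(),
                          trial_id = NULL, participant_id = "unknown",
                          group = "ABI") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  trial_id <- trial_id %||% sub("\\.csv$", "", basename(path))
  first <- readLines(path, n = 1L)
  raw_first <- strsplit(first, ",", fixed = TRUE)[[1]]
  frames <- if (identical(tolower(raw_first[1]), "scorer")) {
    parse_dlc_csv(path, config)
  } else {
    parse_flat_csv(path, config)
  }
  landmark_trace(frames, trial_id = trial_id,
                 participant_id = participant_id, group = group,
                 image_width = config$image_width,
                 image_height = config$image_height, fps = config$fps)
}

parse_dlc_csv <- function(path, config) {
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L) abort("malformed header: fewer than 3 header rows")
  rows <- lapply(hdr, function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  labels <- tolower(vapply(rows, `[`, "", 1L))
  if (!identical(labels, c("scorer", "bodyparts", "coords"))) {
    bad <- which(labels != c("scorer", "bodyparts", "coords"))[1]
    abort(paste0("malformed header row ", bad, ": expected '",
                 c("scorer", "bodyparts", "coords")[bad], "', got '",
                 rows[[bad]][1], "'"))
  }
  bodyparts <- rows[[2]][-1]
  coords <- tolower(rows[[3]][-1])
  if (length(bodyparts) %% 3L != 0L ||
      !all(coords == rep(c("x", "y", "likelihood"),
                         length(bodyparts) / 3L))) {
    abort("malformed header row 3: coords must repeat x,y,likelihood")
  }
  parts <- bodyparts[seq(1L, length(bodyparts), by = 3L)]
  canon <- unname(config$aliases[tolower(parts)])

  dat <- readr::read_csv(path, skip = 3L, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  if (ncol(dat) != length(bodyparts) + 1L) {
    abort("data rows do not match header width")
  }

  frames <- tibble::tibble(frame = as.integer(dat[[1]]))
  for (i in seq_along(parts)) {
    if (is.na(canon[i])) next
    base <- 1L + (i - 1L) * 3L
    frames[[paste0(canon[i], "_x")]] <- dat[[base + 1L]]
    frames[[paste0(canon[i], "_y")]] <- dat[[base + 2L]]
    frames[[paste0(canon[i], "_likelihood")]] <- dat[[base + 3L]]
  }
  unknown <- parts[is.na(canon)]
  if (length(unknown) > 0L) {
    warn(paste0("ignoring unknown bodyparts: ",
                paste(unknown, collapse = ", ")))
  }
  check_all_landmarks(frames)
  frames[, c("frame", trace_columns())]
}

parse_flat_csv <- function(path, config) {
  dat <- readr::read_csv(path, col_types = readr::cols(),
                         progress = FALSE, show_col_types = FALSE)
  if (!"frame" %in% names(dat)) {
    dat <- dplyr::mutate(dat, frame = seq_len(nrow(dat)) - 1L,
                         .before = 1L)
  }
  # canonicalize "<alias>_<coord>" column names
  out <- tibble::tibble(frame = as.integer(dat$frame))
  for (col in setdiff(names(dat), "frame")) {
    m <- regmatches(col, regexec("^(.*)_(x|y|likelihood)$", col))[[1]]
    if (length(m) == 0L) next
    canon <- config$aliases[tolower(m[2])]
    if (is.na(canon)) next
    out[[paste0(canon, "_", m[3])]] <- as.numeric(dat[[col]])
  }
  defaulted <- character()
  for (lm in LANDMARKS) {
    lik <- paste0(lm, "_likelihood")
    if (!lik %in% names(out) &&
        all(paste0(lm, c("_x", "_y")) %in% names(out))) {
      out[[lik]] <- 1.0
      defaulted <- c(defaulted, lm)
    }
  }
  if (length(defaulted) > 0L) {
    inform(paste0("no likelihood column for ",
                  paste(defaulted, collapse = ", "), "; assuming 1.0"))
  }
  check_all_landmarks(out)
  out[, c("frame", trace_columns())]
}

check_all_landmarks <- function(frames) {
  missing <- LANDMARKS[!paste0(LANDMARKS, "_x") %in% names(frames)]
  if (length(missing) > 0L) {
    abort(paste0("landmark ", missing[1], " absent from file header"))
  }
  invisible(frames)
}

#' Write a landmark trace as a pose CSV
#'
#' Emits the three-header-row pose dialect (`scorer` / `bodyparts` / `coords`)
#' so that [read_pose_csv()] round-trips the coordinates exactly at the
#' written precision (6 decimals).
#'
#' @param trace A [landmark_trace()].
#' @param path Output path.
#' @param scorer Scorer string for the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(trace, path, scorer = "gaitarm") {
  validate_trace_frames(trace)
  n_col <- length(LANDMARKS) * 3L
  hdr1 <- paste(c("scorer", rep(scorer, n_col)), collapse = ",")
  hdr2 <- paste(c("bodyparts", rep(LANDMARKS, each = 3L)), collapse = ",")
  hdr3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(LANDMARKS))),
                collapse = ",")
  mat <- as.matrix(trace[, trace_columns()])
  body <- apply(cbind(trace$frame, mat), 1L, function(r) {
    paste(c(format(r[1], scientific = FALSE, trim = TRUE),
            formatC(r[-1], digits = 6L, format = "f")), collapse = ",")
  })
  writeLines(c(hdr1, hdr2, hdr3, body), path)
  invisible(path)
}

#' Read a table of assessor ratings
#'
#' The ratings CSV carries one row per (trial, assessor) with columns
#' `trial_id`, `participant_id`, `assessor_id` and `score`, where `score` is
#' an integer ICF qualifier in 0-4 (0 = no problem, 4 = complete problem).
#'
#' @param path Path to the ratings CSV.
#' @return A validated tibble.
#' @export
read_ratings <- function(path) {
  dat <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  validate_ratings(dat)
}

#' Validate a ratings table
#'
#' @param ratings Data frame with columns `trial_id`, `participant_id`,
#'   `assessor_id`, `score`.
#' @return The ratings as a tibble, with `score` integer.
#' @export
validate_ratings <- function(ratings) {
  needed <- c("trial_id", "participant_id", "assessor_id", "score")
  missing <- setdiff(needed, names(ratings))
  if (length(missing) > 0L) {
    abort(paste0("ratings table missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  ratings <- tibble::as_tibble(ratings)
  s <- ratings$score
  bad <- which(!is.finite(s) | s != round(s) | s < 0 | s > 4)
  if (length(bad) > 0L) {
    abort(paste0("invalid score at row ", bad[1], ": ", s[bad[1]],
                 " (scores must be integers in 0-4)"))
  }
  dup <- duplicated(ratings[, c("trial_id", "assessor_id")])
  if (any(dup)) {
    abort(paste0("duplicate (trial_id, assessor_id) at row ", which(dup)[1]))
  }
  dplyr::mutate(ratings,
                dplyr::across(c("trial_id", "participant_id", "assessor_id"),
                              as.character),
                score = as.integer(.data$score))
}
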