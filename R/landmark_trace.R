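#' Construct a landmark trace
#'
#' A landmark trace is a tibble with one row per video frame and, for each of
#' the eight tracked landmarks (left/right shoulder, elbow, wrist and hip),
#' three columns `<landmark>_x`, `<landmark>_y`, `<landmark>_likelihood`.
#' Coordinates are in image pixels with the origin at the top-left and y
#' increasing downward, as emitted by marker-less pose-estimation tools.
#' Trial metadata travels in attributes so the frame table itself stays tidy.
#'
#' @param frames Data frame with a `frame` column and the 24 landmark columns.
#' @param trial_id,participant_id Identifiers for the trial and participant.
#' @param group Cohort group, `"ABI"` (acquired brain injury) or `"HC"`
#'   (healthy control).
#' @param image_width,image_height Frame size in pixels.
#' @param fps Frame rate in frames per second.
#'
#' @return A `landmark_trace` tibble.
#' @export
#' @examples
#' cfg <- synth_config(n_abi = 1, n_hc = 0)
#' tr <- simulate_trial(cfg, participant_id = "p01", trial = 1, severity = 2,
#'                      seed = 1)$trace
#' tr
landmark_trace <- function(frames, trial_id, participant_id,
                           group = c("ABI", "HC"),
                           image_width = 1920, image_height = 1080,
                           fps = 30) {
  group <- match.arg(group)
  frames <- tibble::as_tibble(frames)
  validate_trace_frames(frames)
  structure(
    frames,
    class = c("landmark_trace", "tbl_df", "tbl", "data.frame"),
    trial_id = as.character(trial_id),
    participant_id = as.character(participant_id),
    group = group,
    image_width = image_width,
    image_height = image_height,
    fps = fps
  )
}

validate_trace_frames <- function(frames) {
  if (nrow(frames) < 1L) {
    abort("a landmark trace needs at least one frame")
  }
  needed <- c("frame", trace_columns())
  missing <- setdiff(needed, names(frames))
  if (length(missing) > 0L) {
    abort(paste0("landmark trace is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  lik <- as.matrix(frames[paste0(LANDMARKS, "_likelihood")])
  bad <- is.finite(lik) & (lik < 0 | lik > 1)
  if (any(bad)) {
    abort("likelihood values must lie in [0, 1]")
  }
  invisible(frames)
}

trace_columns <- function() {
  as.vector(t(outer(LANDMARKS, c("x", "y", "likelihood"), paste, sep = "_")))
}

#' @export
print.landmark_trace <- function(x, ...) {
  cat(sprintf(
    "<landmark_trace> trial %s, participant %s (%s), %d frames @ %g fps, %dx%d px\n",
    attr(x, "trial_id"), attr(x, "participant_id"), attr(x, "group"),
    nrow(x), attr(x, "fps"),
    attr(x, "image_width"), attr(x, "image_height")
  ))
  NextMethod()
}

#' Trace metadata as a one-row tibble
#'
#' @param trace A [landmark_trace()].
#' @return One-row tibble of the trace's identifiers and recording metadata.
#' @export
trace_meta <- function(trace) {
  tibble::tibble(
    trial_id = attr(trace, "trial_id"),
    participant_id = attr(trace, "participant_id"),
    group = attr(trace, "group"),
    image_width = attr(trace, "image_width"),
    image_height = attr(trace, "image_height"),
    fps = attr(trace, "fps"),
    n_frames = nrow(trace)
  )
}

# Rebuild a landmark_trace around a modified frame table, keeping metadata.
rewrap_trace <- function(frames, template) {
  landmark_trace(
    frames,
    trial_id = attr(template, "trial_id"),
    participant_id = attr(template, "participant_id"),
    group = attr(template, "group"),
    image_width = attr(template, "image_width"),
    image_height = attr(template, "image_height"),
    fps = attr(template, "fps")
  )
}

# Logical T x 8 matrix: landmark is "lost" in a frame when its likelihood
# falls below `threshold` or a coordinate is non-finite.
lost_matrix <- function(trace, threshold) {
  vapply(LANDMARKS, function(lm) {
    x <- trace[[paste0(lm, "_x")]]
    y <- trace[[paste0(lm, "_y")]]
    lik <- trace[[paste0(lm, "_likelihood")]]
    !is.finite(x) | !is.finite(y) | !is.finite(lik) | lik < threshold
  }, logical(nrow(trace)))
}
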