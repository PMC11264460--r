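#' Trimming configuration
#'
#' Parameters for isolating the walking portion of a trial. The walk onset is
#' declared at the first frame where a monitored body width (shoulder-shoulder
#' or hip-hip pixel distance) has risen above its early-trial baseline --
#' the subject approaching the camera makes the body larger in the image.
#' The walk end is the first frame of the earliest run of more than two
#' consecutive frames in which any landmark is lost.
#'
#' @param likelihood_threshold A landmark with likelihood below this (or a
#'   non-finite coordinate) counts as lost for that frame. Default 0.6.
#' @param baseline_window Number of initial frames whose median width forms
#'   the baseline. Default 10.
#' @param rise_fraction Relative rise over baseline that signals walking
#'   onset. Default 0.05 (5%).
#' @param confirm_frames The rise must persist this many consecutive frames.
#'   Default 3.
#' @param confirm_window After a candidate onset, the median monitored width
#'   over this many following frames must also exceed the threshold; rejects
#'   jitter-induced false onsets that a short consecutive run alone lets
#'   through. Default 10.
#' @param noise_guard The rise threshold is lifted by this many robust
#'   standard deviations (MAD) of the baseline-window widths, so landmark
#'   jitter alone cannot cross it; on noiseless traces the guard is zero and
#'   the plain relative-rise rule applies. Default 3.
#' @param min_retained_frames Shortest acceptable trimmed segment. Default 20.
#' @param onset_fallback If no onset is detected, `"error"` aborts while
#'   `"start"` keeps the whole trace with a warning.
#'
#' @return A list of class `trim_config`.
#' @export
trim_config <- function(likelihood_threshold = 0.6, baseline_window = 10,
                        rise_fraction = 0.05, confirm_frames = 3,
                        confirm_window = 10, noise_guard = 3,
                        min_retained_frames = 20,
                        onset_fallback = c("error", "start")) {
  structure(
    list(likelihood_threshold = likelihood_threshold,
         baseline_window = as.integer(baseline_window),
         rise_fraction = rise_fraction,
         confirm_frames = as.integer(confirm_frames),
         confirm_window = as.integer(confirm_window),
         noise_guard = noise_guard,
         min_retained_frames = as.integer(min_retained_frames),
         onset_fallback = match.arg(onset_fallback)),
    class = "trim_config"
  )
}

monitored_widths <- function(trace) {
  dist2 <- function(a, b) {
    sqrt((trace[[paste0(a, "_x")]] - trace[[paste0(b, "_x")]])^2 +
           (trace[[paste0(a, "_y")]] - trace[[paste0(b, "_y")]])^2)
  }
  cbind(shoulder = dist2("L_shoulder", "R_shoulder"),
        hip = dist2("L_hip", "R_hip"))
}

#' Detect walking onset
#'
#' Returns the first frame index (1-based) at which any monitored
#' inter-landmark width exceeds its baseline (median over the first
#' `baseline_window` frames) by at least `rise_fraction`, sustained for
#' `confirm_frames` consecutive frames and confirmed by the median width
#' over the following `confirm_window` frames. The width series are
#' three-point median filtered before thresholding, so single-frame landmark
#' jitter cannot fake or break an onset. Returns 1 if the condition already
#' holds at the first frame.
#'
#' @param trace A [landmark_trace()].
#' @param config A [trim_config()].
#' @return Integer start index (inclusive, 1-based).
#' @export
detect_walk_start <- function(trace, config = trim_config()) {
  n <- nrow(trace)
  if (n < config$baseline_window) {
    abort("trace shorter than the baseline window")
  }
  w <- monitored_widths(trace)
  w <- apply(w, 2L, median_filter3)
  bw <- w[seq_len(config$baseline_window), , drop = FALSE]
  base <- apply(bw, 2L, median)

  # If the baseline window itself is already rising by more than the
  # threshold (a trace that starts mid-walk), the onset is the first frame.
  # A linear fit separates trend from jitter: the fitted rise across the
  # window must clear the relative threshold plus a noise guard on its own
  # standard error.
  tt <- seq_len(config$baseline_window)
  resid_mad <- numeric(ncol(bw))
  for (j in seq_len(ncol(bw))) {
    fit <- stats::lm.fit(cbind(1, tt), bw[, j])
    slope <- fit$coefficients[2]
    resid_mad[j] <- stats::mad(fit$residuals, center = 0)
    df <- length(tt) - 2L
    se_slope <- if (df > 0) {
      sqrt(sum(fit$residuals^2) / df / sum((tt - mean(tt))^2))
    } else {
      Inf
    }
    rise <- slope * (length(tt) - 1L)
    if (is.finite(rise) &&
        rise > config$rise_fraction * fit$coefficients[1] +
          config$noise_guard * se_slope * (length(tt) - 1L)) {
      return(1L)
    }
  }

  thresh <- base * (1 + config$rise_fraction) +
    config$noise_guard * resid_mad
  risen <- sweep(w, 2L, thresh, `>`)
  confirmed <- function(start) {
    idx <- seq.int(start, min(n, start + config$confirm_window - 1L))
    any(vapply(seq_len(ncol(w)), function(j) {
      median(w[idx, j]) > thresh[j]
    }, logical(1)))
  }
  any_risen <- apply(risen, 1L, any)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (any_risen[i]) run + 1L else 0L
    if (run >= config$confirm_frames) {
      cand <- i - config$confirm_frames + 1L
      if (confirmed(cand)) return(cand)
      run <- 0L
    }
  }
  if (config$onset_fallback == "start") {
    warn("no walking onset detected; keeping trace from its first frame")
    return(1L)
  }
  abort("no walking onset detected")
}

#' Detect walking end
#'
#' Returns the exclusive end index: the first frame of the earliest run of
#' strictly more than two consecutive frames in which any single landmark is
#' lost (likelihood below threshold or non-finite coordinates). If no such
#' run exists the whole trace is retained and `nrow(trace) + 1` is returned.
#'
#' @inheritParams detect_walk_start
#' @return Integer end index (exclusive, 1-based), in `[1, nrow(trace) + 1]`.
#' @export
detect_walk_end <- function(trace, config = trim_config()) {
  lost <- lost_matrix(trace, config$likelihood_threshold)
  n <- nrow(trace)
  best <- n + 1L
  for (j in seq_len(ncol(lost))) {
    r <- rle(lost[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths > 2L)
    if (length(hit) > 0L) best <- min(best, starts[hit[1]])
  }
  best
}

#' Three-point median filter
#'
#' Replaces each interior sample with the median of itself and its two
#' neighbours; endpoints are handled by edge replication so the output has
#' the same length as the input. Removes single-frame landmark spikes.
#'
#' @param x Numeric vector.
#' @return Filtered numeric vector, same length as `x`.
#' @export
#' @examples
#' median_filter3(c(0, 0, 100, 0, 0))
median_filter3 <- function(x) {
  n <- length(x)
  if (n < 1L) abort("empty series")
  if (n < 3L) return(x)
  padded <- c(x[1L], x, x[n])
  vapply(seq_len(n), function(i) median(padded[i:(i + 2L)]), numeric(1))
}

#' Trim and filter a landmark trace
#'
#' Applies [detect_walk_start()] and [detect_walk_end()], slices the trace to
#' the walking segment, then three-point median filters every landmark x and
#' y coordinate series. Likelihood series are left untouched, and joint-angle
#' series computed downstream are never filtered.
#'
#' @inheritParams detect_walk_start
#' @return A list with elements `trace` (the trimmed, filtered
#'   [landmark_trace()]) and `trim` (a one-row tibble with `start_frame`,
#'   `end_frame`, `reason_start`, `reason_end`; indices 1-based, end
#'   exclusive).
#' @export
preprocess_trace <- function(trace, config = trim_config()) {
  start <- detect_walk_start(trace, config)
  end <- detect_walk_end(trace, config)
  if (end - start < config$min_retained_frames) {
    abort(sprintf(
      "retained segment [%d, %d) has %d frames, below the minimum of %d",
      start, end, max(0L, end - start), config$min_retained_frames))
  }
  kept <- trace[seq.int(start, end - 1L), , drop = FALSE]
  frames <- tibble::as_tibble(kept)
  for (lm in LANDMARKS) {
    for (co in c("_x", "_y")) {
      col <- paste0(lm, co)
      frames[[col]] <- median_filter3(frames[[col]])
    }
  }
  trim <- tibble::tibble(
    trial_id = attr(trace, "trial_id"),
    start_frame = start,
    end_frame = end,
    reason_start = if (start == 1L) "trace_begin" else "distance_rise",
    reason_end = if (end == nrow(trace) + 1L) "trace_end" else "landmark_lost"
  )
  list(trace = rewrap_trace(frames, trace), trim = trim)
}
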