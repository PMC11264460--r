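#' Six distributional summaries of an angle series
#'
#' Maximum, minimum, mean, sample standard deviation (n - 1 denominator),
#' Fisher skewness (third standardized moment) and excess kurtosis (fourth
#' standardized moment minus 3). Moments use population (1/n) standardization
#' inside the skew/kurtosis ratios, the common default of scientific stacks.
#' A constant series returns sd = 0 and, by convention, skew = 0 and
#' kurtosis = 0 rather than 0/0.
#'
#' @param x Numeric vector, length >= 1.
#' @return Named numeric vector `max`, `min`, `mean`, `sd`, `skew`,
#'   `kurtosis`.
#' @export
#' @examples
#' summarize_trace(rep(90, 50))
summarize_trace <- function(x) {
  n <- length(x)
  if (n < 1L) abort("empty series")
  if (any(!is.finite(x))) abort("series contains non-finite values")
  m <- mean(x)
  s <- if (n > 1L) sd(x) else 0
  d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2 - 3
  }
  c(max = max(x), min = min(x), mean = m, sd = s, skew = skew,
    kurtosis = kurt)
}

#' Integer median of assessor scores
#'
#' The median keeps an odd number of integer ratings ordinal. For an even
#' number of assessors a half-integer median is rounded down (toward the less
#' impaired score) with a warning.
#'
#' @param scores Integer scores 0-4.
#' @return Integer median.
#' @export
median_score <- function(scores) {
  m <- median(scores)
  if (m != floor(m)) {
    warn("even assessor count gave a half-integer median; rounding down")
    m <- floor(m)
  }
  as.integer(m)
}

#' Build the per-trial feature table
#'
#' Reduces each trial's four angle series to the 24 summary features (see
#' [feature_names()]) and attaches the median assessor score as the ordinal
#' label. Trials without any rating are excluded with a warning.
#'
#' @param angles A tibble of per-frame angles as returned by
#'   [compute_angle_traces()] (several trials may be row-bound together).
#' @param ratings A ratings table as from [read_ratings()], or `NULL` to
#'   build an unlabelled feature table.
#' @return A tibble with `trial_id`, `participant_id`, the 24 feature
#'   columns in fixed order and, when ratings are given, `median_score`.
#' @export
build_feature_table <- function(angles, ratings = NULL) {
  feats <- angles |>
    dplyr::group_by(.data$trial_id, .data$participant_id) |>
    dplyr::group_modify(function(d, key) {
      row <- unlist(lapply(ANGLE_NAMES,
                           function(a) summarize_trace(d[[a]])))
      names(row) <- feature_names()
      tibble::as_tibble(as.list(row))
    }) |>
    dplyr::ungroup()

  if (is.null(ratings)) {
    return(feats)
  }
  ratings <- validate_ratings(ratings)
  labels <- ratings |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(median_score = median_score(.data$score),
                     .groups = "drop")
  unrated <- setdiff(feats$trial_id, labels$trial_id)
  if (length(unrated) > 0L) {
    warn(paste0("excluding ", length(unrated),
                " trial(s) without ratings: ",
                paste(head(unrated, 5L), collapse = ", "),
                if (length(unrated) > 5L) ", ..." else ""))
  }
  dplyr::inner_join(feats, labels, by = "trial_id")
}
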