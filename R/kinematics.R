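#' Angle between two vectors, in degrees
#'
#' Unsigned angle in [0, 180] via the arccosine of the normalized dot
#' product. Frontal-plane video cannot disambiguate rotation direction, so
#' all joint angles in this package are unsigned.
#'
#' @param u,v Numeric length-2 vectors.
#' @return Angle in degrees, or `NA_real_` if either vector has zero length.
#' @keywords internal
vector_angle <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (!is.finite(nu) || !is.finite(nv) || nu == 0 || nv == 0) {
    return(NA_real_)
  }
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Frontal-plane elbow angle
#'
#' The angle at the elbow between the elbow-to-wrist and elbow-to-shoulder
#' segments, in degrees. 180 means a fully extended arm (wrist, elbow and
#' shoulder collinear with the elbow between them); smaller values mean more
#' elbow flexion, matching clinical goniometry.
#'
#' @param wrist,elbow,shoulder Numeric length-2 points (x, y) in pixels.
#' @return Degrees in [0, 180], or `NA_real_` for a degenerate (zero-length)
#'   segment.
#' @export
#' @examples
#' elbow_angle(c(0, 2), c(0, 1), c(0, 0)) # extended: 180
#' elbow_angle(c(1, 1), c(0, 1), c(0, 0)) # right angle: 90
elbow_angle <- function(wrist, elbow, shoulder) {
  vector_angle(wrist - elbow, shoulder - elbow)
}

#' Trunk longitudinal axis
#'
#' Unit vector from the shoulder midpoint toward the hip midpoint -- the
#' line running approximately through the sternum and sacrum. In image
#' coordinates (y down) this points inferiorly, i.e. (0, 1) for an upright
#' subject facing the camera.
#'
#' @param hip_l,hip_r,shoulder_l,shoulder_r Numeric length-2 points.
#' @return Unit length-2 vector, or `c(NA, NA)` if the midpoints coincide.
#' @export
trunk_axis <- function(hip_l, hip_r, shoulder_l, shoulder_r) {
  hip_mid <- (hip_l + hip_r) / 2
  sho_mid <- (shoulder_l + shoulder_r) / 2
  v <- hip_mid - sho_mid
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n == 0) return(c(NA_real_, NA_real_))
  v / n
}

#' Frontal-plane shoulder angle
#'
#' Angle between the shoulder-to-elbow segment and the trunk axis, in
#' degrees. 0 means the upper arm hangs parallel to the trunk; 90 means the
#' arm is horizontal (a frontal-plane abduction proxy).
#'
#' @param elbow,shoulder Numeric length-2 points.
#' @param axis Trunk axis from [trunk_axis()].
#' @return Degrees in [0, 180], or `NA_real_` for a degenerate segment.
#' @export
shoulder_angle <- function(elbow, shoulder, axis) {
  vector_angle(elbow - shoulder, axis)
}

#' Compute the four joint-angle series of a trace
#'
#' Per frame: left and right elbow angles (vertex at the elbow) and left and
#' right shoulder angles (upper arm against a per-frame trunk axis). Frames
#' where any of the four angles is undefined (a zero-length segment or
#' coincident trunk midpoints) are dropped from all four series jointly so
#' the series stay aligned. Angle series are deliberately not filtered;
#' smoothing is applied upstream to landmark coordinates only.
#'
#' @param trace A (typically preprocessed) [landmark_trace()].
#' @param min_valid_frames Error if fewer valid frames remain. Default 20.
#' @return A tibble with columns `trial_id`, `participant_id`, `frame`,
#'   `elbow_L`, `elbow_R`, `shoulder_L`, `shoulder_R` (degrees).
#' @export
compute_angle_traces <- function(trace, min_valid_frames = 20) {
  g <- function(col) trace[[col]]
  p <- function(lm) cbind(g(paste0(lm, "_x")), g(paste0(lm, "_y")))
  pts <- lapply(setNames(LANDMARKS, LANDMARKS), p)

  n <- nrow(trace)
  ang <- matrix(NA_real_, n, 4L,
                dimnames = list(NULL, ANGLE_NAMES))
  for (i in seq_len(n)) {
    axis <- trunk_axis(pts$L_hip[i, ], pts$R_hip[i, ],
                       pts$L_shoulder[i, ], pts$R_shoulder[i, ])
    ang[i, "elbow_L"] <- elbow_angle(pts$L_wrist[i, ], pts$L_elbow[i, ],
                                     pts$L_shoulder[i, ])
    ang[i, "elbow_R"] <- elbow_angle(pts$R_wrist[i, ], pts$R_elbow[i, ],
                                     pts$R_shoulder[i, ])
    ang[i, "shoulder_L"] <- shoulder_angle(pts$L_elbow[i, ],
                                           pts$L_shoulder[i, ], axis)
    ang[i, "shoulder_R"] <- shoulder_angle(pts$R_elbow[i, ],
                                           pts$R_shoulder[i, ], axis)
  }
  ok <- stats::complete.cases(ang)
  if (sum(!ok) > 0L) {
    inform(paste0("dropped ", sum(!ok),
                  " frame(s) with undefined joint angles"))
  }
  if (sum(ok) < min_valid_frames) {
    abort(sprintf("only %d valid frames, below the minimum of %d",
                  sum(ok), min_valid_frames))
  }
  tibble::tibble(
    trial_id = attr(trace, "trial_id"),
    participant_id = attr(trace, "participant_id"),
    frame = trace$frame[ok],
    elbow_L = ang[ok, "elbow_L"],
    elbow_R = ang[ok, "elbow_R"],
    shoulder_L = ang[ok, "shoulder_L"],
    shoulder_R = ang[ok, "shoulder_R"]
  )
}
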