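#' Synthetic cohort configuration
#'
#' Parameters of the synthetic gait generator. It emulates a subject who
#' stands still, then walks toward a fixed frontal camera (so inter-landmark
#' pixel distances grow over time), swinging the arms sinusoidally in the
#' frontal-plane projection. Arm-movement abnormality is introduced on one
#' affected side as a monotone function of an ordinal severity (0-4):
#' reduced swing amplitude, a held elbow-flexion offset, and a shoulder
#' abduction offset. Landmark observations get Gaussian pixel jitter,
#' occasional isolated low-likelihood frames, and a scripted terminal
#' landmark loss when the subject comes too close to the camera. Three
#' simulated assessors rate each trial by perturbing the true severity with
#' Gaussian noise, rounding and clipping to 0-4.
#'
#' @param n_abi,n_hc Participants per group (ABI = acquired brain injury,
#'   HC = healthy control; HC severity is always 0).
#' @param trials_per_participant Walking trials per participant.
#' @param rated_hc_videos How many HC trials receive assessor ratings (all
#'   ABI trials are rated; most healthy controls are left unrated since they
#'   would trivially score 0 and skew the labelled data).
#' @param severity_probs Distribution of true severity 0-4 for ABI
#'   participants.
#' @param fps Frames per second.
#' @param n_frames Frames per trial.
#' @param stationary_prefix Frames of standing still before walking onset.
#' @param scale_growth Linear growth of the pixel scale per frame during the
#'   approach (0.01 = the subject's image grows 1% of its initial size each
#'   frame).
#' @param lost_fraction Fraction of the trial after which a wrist landmark
#'   leaves the image for good (terminal likelihood dropout).
#' @param jitter_sd Landmark jitter standard deviation in pixels.
#' @param isolated_dropout_prob Per-frame, per-landmark probability of an
#'   isolated (single-frame) low-likelihood observation.
#' @param swing_amplitude Healthy arm-swing amplitude about the trunk axis,
#'   degrees.
#' @param swing_frequency Arm-swing frequency, Hz.
#' @param base_abduction Resting shoulder abduction, degrees.
#' @param base_elbow_flexion Resting elbow flexion (180 minus the elbow
#'   angle), degrees.
#' @param elbow_swing Peak-to-trough elbow flexion excursion during swing,
#'   degrees.
#' @param swing_reduction Fractional swing-amplitude loss per severity step
#'   on the affected side (severity 4 with 0.22 keeps 12% of the swing).
#' @param flexion_offset_per_severity Added held elbow flexion per severity
#'   step, degrees.
#' @param abduction_offset_per_severity Added shoulder abduction per
#'   severity step, degrees.
#' @param rater_sd Assessor noise standard deviation (latent, score units).
#' @param n_assessors Number of simulated assessors.
#' @param image_width,image_height Frame size in pixels.
#' @param seed Master seed; every drawn quantity derives from it.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_abi = 42, n_hc = 34, trials_per_participant = 2,
                         rated_hc_videos = 5,
                         severity_probs = c(0.10, 0.20, 0.25, 0.25, 0.20),
                         fps = 30, n_frames = 240,
                         stationary_prefix = 60, scale_growth = 0.01,
                         lost_fraction = 0.92, jitter_sd = 1.5,
                         isolated_dropout_prob = 0.01,
                         swing_amplitude = 25, swing_frequency = 0.9,
                         base_abduction = 8, base_elbow_flexion = 15,
                         elbow_swing = 10,
                         swing_reduction = 0.22,
                         flexion_offset_per_severity = 12,
                         abduction_offset_per_severity = 6,
                         rater_sd = 0.6, n_assessors = 3,
                         image_width = 1920, image_height = 1080,
                         seed = 1) {
  stopifnot(length(severity_probs) == 5, all(severity_probs >= 0),
            isolated_dropout_prob >= 0, isolated_dropout_prob <= 1,
            lost_fraction > 0, lost_fraction <= 1)
  cfg <- as.list(environment())
  cfg$severity_probs <- severity_probs / sum(severity_probs)
  structure(cfg, class = "synth_config")
}

# Unscaled body geometry, pixels at unit scale. Origin at the mid-shoulder.
body_geometry <- function() {
  list(shoulder_half = 30, hip_half = 22, torso_len = 120,
       upper_arm = 70, forearm = 65, center = c(x = 960, y = 400))
}

rot2 <- function(v, theta_deg) {
  th <- theta_deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2],
    sin(th) * v[1] + cos(th) * v[2])
}

#' Simulate one walking trial
#'
#' Produces a landmark trace with (a) a stationary prefix, (b) an approach
#' phase in which the pixel scale grows linearly, (c) sinusoidal frontal-
#' plane arm swing with severity-dependent asymmetry on the affected side,
#' (d) Gaussian landmark jitter plus occasional isolated low-likelihood
#' frames, and (e) scripted terminal likelihood dropout. Deterministic given
#' `seed`.
#'
#' @param config A [synth_config()].
#' @param participant_id,trial Identifiers.
#' @param severity True severity in 0-4.
#' @param seed RNG seed for this trial.
#' @param group `"ABI"` or `"HC"`.
#' @param affected_side `"L"` or `"R"` (ignored at severity 0).
#' @return List with `trace` (a [landmark_trace()]), `truth` (one-row tibble
#'   with the scripted onset and loss frames, severity and affected side)
#'   and `angles_true` (tibble of the generator's noiseless per-frame elbow
#'   and shoulder angles).
#' @export
simulate_trial <- function(config, participant_id, trial, severity,
                           seed = 1, group = "ABI", affected_side = "R") {
  stopifnot(severity %in% 0:4)
  geom <- body_geometry()
  n <- config$n_frames
  trial_id <- sprintf("%s_t%02d", participant_id, trial)

  t_idx <- seq_len(n)
  tau <- pmax(0, t_idx - config$stationary_prefix) / config$fps
  s <- 1 + config$scale_growth * pmax(0, t_idx - config$stationary_prefix)

  side_par <- function(side) {
    aff <- severity > 0 && side == affected_side
    sev <- if (aff) severity else 0
    list(
      amp = config$swing_amplitude * max(0, 1 - config$swing_reduction * sev),
      abd = config$base_abduction + config$abduction_offset_per_severity * sev,
      flex0 = config$base_elbow_flexion +
        config$flexion_offset_per_severity * sev,
      phase = if (side == "L") 0 else pi
    )
  }

  build_side <- function(side) {
    p <- side_par(side)
    dir <- if (side == "L") -1 else 1
    swing <- sin(2 * pi * config$swing_frequency * tau + p$phase)
    swing[t_idx <= config$stationary_prefix] <- 0
    alpha <- p$abd + p$amp * swing
    flex <- p$flex0 +
      config$elbow_swing * (1 + sin(2 * pi * config$swing_frequency * tau)) / 2
    sho <- cbind(dir * geom$shoulder_half, 0)
    elb <- t(vapply(seq_len(n), function(i) {
      sho[1, ] + geom$upper_arm *
        c(sin(alpha[i] * pi / 180) * dir, cos(alpha[i] * pi / 180))
    }, numeric(2)))
    wri <- t(vapply(seq_len(n), function(i) {
      v <- (elb[i, ] - sho[1, ]) / geom$upper_arm
      elb[i, ] + geom$forearm * rot2(v, -dir * flex[i])
    }, numeric(2)))
    list(alpha = alpha, flex = flex, elbow = elb, wrist = wri,
         shoulder = matrix(sho, n, 2, byrow = TRUE))
  }

  left <- build_side("L")
  right <- build_side("R")
  hips <- list(
    L = cbind(rep(-geom$hip_half, n), rep(geom$torso_len, n)),
    R = cbind(rep(geom$hip_half, n), rep(geom$torso_len, n))
  )

  unscaled <- list(
    L_shoulder = left$shoulder, R_shoulder = right$shoulder,
    L_elbow = left$elbow, R_elbow = right$elbow,
    L_wrist = left$wrist, R_wrist = right$wrist,
    L_hip = hips$L, R_hip = hips$R
  )

  lost_from <- as.integer(floor(config$lost_fraction * n))
  frames <- with_local_seed(seed, {
    out <- tibble::tibble(frame = t_idx - 1L)
    for (lm in LANDMARKS) {
      xy <- unscaled[[lm]] * s
      xy[, 1] <- xy[, 1] + geom$center["x"] + rnorm(n, 0, config$jitter_sd)
      xy[, 2] <- xy[, 2] + geom$center["y"] + rnorm(n, 0, config$jitter_sd)
      lik <- runif(n, 0.9, 1.0)
      # isolated single-frame confidence drops, kept non-adjacent so they
      # never form a >2-frame run before the scripted terminal loss
      drops <- which(runif(n) < config$isolated_dropout_prob)
      drops <- drops[c(TRUE, diff(drops) > 2)]
      lik[drops] <- runif(length(drops), 0, 0.4)
      if (lm == "R_wrist" && lost_from <= n) {
        lik[lost_from:n] <- runif(n - lost_from + 1, 0, 0.1)
      }
      out[[paste0(lm, "_x")]] <- xy[, 1]
      out[[paste0(lm, "_y")]] <- xy[, 2]
      out[[paste0(lm, "_likelihood")]] <- lik
    }
    out
  })

  trace <- landmark_trace(frames, trial_id = trial_id,
                          participant_id = participant_id, group = group,
                          image_width = config$image_width,
                          image_height = config$image_height,
                          fps = config$fps)
  truth <- tibble::tibble(
    trial_id = trial_id, participant_id = participant_id, group = group,
    severity = as.integer(severity), affected_side = affected_side,
    onset_frame = config$stationary_prefix + 1L,
    lost_frame = lost_from, n_frames = n, seed = seed
  )
  angles_true <- tibble::tibble(
    frame = t_idx - 1L,
    elbow_L = 180 - left$flex, elbow_R = 180 - right$flex,
    shoulder_L = abs(left$alpha), shoulder_R = abs(right$alpha)
  )
  list(trace = trace, truth = truth, angles_true = angles_true)
}

#' Simulate assessor ratings for one trial
#'
#' Each assessor's score is `round(severity + N(0, rater_sd))`, clipped to
#' 0-4 -- a discretized-Gaussian rater with no systematic bias.
#'
#' @param severity True severity 0-4.
#' @param config A [synth_config()].
#' @param seed RNG seed.
#' @param trial_id,participant_id Identifiers for the returned rows.
#' @return Tibble with one row per assessor (`assessor_id`, `score`).
#' @export
simulate_ratings <- function(severity, config, seed = 1,
                             trial_id = "t", participant_id = "p") {
  scores <- with_local_seed(seed, {
    raw <- round(severity + rnorm(config$n_assessors, 0, config$rater_sd))
    pmin(4L, pmax(0L, as.integer(raw)))
  })
  tibble::tibble(
    trial_id = trial_id, participant_id = participant_id,
    assessor_id = sprintf("assessor_%d", seq_len(config$n_assessors)),
    score = scores
  )
}

#' Generate a full synthetic cohort
#'
#' Draws a cohort of ABI and healthy-control participants, simulates every
#' trial and its assessor ratings, and optionally writes the whole cohort to
#' disk as pose CSVs, a ratings CSV, a truth CSV and a JSON manifest that
#' records every per-trial seed for exact replay.
#'
#' @param config A [synth_config()].
#' @param outdir Directory to write the cohort into, or `NULL` to keep it in
#'   memory only.
#' @return List with `traces` (named list of [landmark_trace()]), `ratings`
#'   (tibble), `truth` (tibble) and `manifest` (list).
#' @export
generate_cohort <- function(config = synth_config(), outdir = NULL) {
  n_trials <- (config$n_abi + config$n_hc) * config$trials_per_participant
  draws <- with_local_seed(config$seed, {
    list(
      severities = sample(0:4, config$n_abi, replace = TRUE,
                          prob = config$severity_probs),
      sides = sample(c("L", "R"), config$n_abi + config$n_hc,
                     replace = TRUE),
      trial_seeds = sample.int(.Machine$integer.max - 1L, n_trials),
      rating_seeds = sample.int(.Machine$integer.max - 1L, n_trials)
    )
  })

  participants <- tibble::tibble(
    participant_id = c(sprintf("abi%02d", seq_len(config$n_abi)),
                       sprintf("hc%02d", seq_len(config$n_hc))),
    group = rep(c("ABI", "HC"), c(config$n_abi, config$n_hc)),
    severity = c(draws$severities, rep(0L, config$n_hc)),
    affected_side = draws$sides
  )

  traces <- list()
  truth <- list()
  ratings <- list()
  hc_rated <- 0L
  k <- 0L
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    for (tr in seq_len(config$trials_per_participant)) {
      k <- k + 1L
      sim <- simulate_trial(config, p$participant_id, tr, p$severity,
                            seed = draws$trial_seeds[k], group = p$group,
                            affected_side = p$affected_side)
      traces[[sim$truth$trial_id]] <- sim$trace
      truth[[k]] <- sim$truth
      rate_it <- p$group == "ABI" ||
        (hc_rated < config$rated_hc_videos)
      if (rate_it) {
        if (p$group == "HC") hc_rated <- hc_rated + 1L
        ratings[[length(ratings) + 1L]] <- simulate_ratings(
          p$severity, config, seed = draws$rating_seeds[k],
          trial_id = sim$truth$trial_id,
          participant_id = p$participant_id)
      }
    }
  }
  truth <- dplyr::bind_rows(truth)
  ratings <- dplyr::bind_rows(ratings)
  manifest <- list(
    generator = "gaitarm synth_gait",
    master_seed = config$seed,
    n_participants = nrow(participants),
    n_trials = n_trials,
    n_rated_trials = length(unique(ratings$trial_id)),
    config = config[setdiff(names(config), "severity_probs")],
    severity_probs = config$severity_probs,
    trial_seeds = setNames(as.list(draws$trial_seeds), truth$trial_id)
  )
  cohort <- list(traces = traces, ratings = ratings, truth = truth,
                 manifest = manifest)
  if (!is.null(outdir)) write_cohort(cohort, outdir)
  cohort
}

#' Write a cohort to disk
#'
#' @param cohort A cohort list from [generate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(file.path(outdir, "poses"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(cohort$traces)) {
    write_pose_csv(cohort$traces[[id]],
                   file.path(outdir, "poses", paste0(id, ".csv")))
  }
  readr::write_csv(cohort$ratings, file.path(outdir, "ratings.csv"))
  readr::write_csv(cohort$truth, file.path(outdir, "truth.csv"))
  jsonlite::write_json(cohort$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Run trimming, kinematics and feature extraction over a cohort
#'
#' Convenience pipeline: for every trace, [preprocess_trace()] then
#' [compute_angle_traces()], then [build_feature_table()] against the
#' ratings. Traces whose walking segment cannot be isolated are skipped with
#' a warning.
#'
#' @param traces Named list of [landmark_trace()] objects.
#' @param ratings Ratings tibble, or `NULL` for an unlabelled table.
#' @param trim A [trim_config()].
#' @return List with `features` (the feature table), `angles` (row-bound
#'   per-frame angles) and `trims` (per-trial trim records).
#' @export
extract_cohort_features <- function(traces, ratings = NULL,
                                    trim = trim_config()) {
  angles <- list()
  trims <- list()
  failed <- character()
  for (id in names(traces)) {
    res <- tryCatch({
      pp <- preprocess_trace(traces[[id]], trim)
      list(angles = compute_angle_traces(pp$trace), trim = pp$trim)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, id)
      next
    }
    angles[[id]] <- res$angles
    trims[[id]] <- res$trim
  }
  if (length(failed) > 0L) {
    warn(paste0("skipped ", length(failed), " trace(s): ",
                paste(head(failed, 5L), collapse = ", ")))
  }
  angles <- dplyr::bind_rows(angles)
  list(features = build_feature_table(angles, ratings),
       angles = angles,
       trims = dplyr::bind_rows(trims))
}
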