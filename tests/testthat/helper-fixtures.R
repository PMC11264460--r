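# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# A static trace with all landmarks fixed at the given pose, likelihood 1.
# pose "anatomical": arms hanging straight down; "tpose": arms horizontal.
static_trace <- function(n = 30, pose = c("anatomical", "tpose"),
                         scale = 1, shift = c(0, 0)) {
  pose <- match.arg(pose)
  pts <- list(
    L_shoulder = c(-30, 0), R_shoulder = c(30, 0),
    L_hip = c(-22, 120), R_hip = c(22, 120)
  )
  if (pose == "anatomical") {
    pts$L_elbow <- c(-30, 70); pts$R_elbow <- c(30, 70)
    pts$L_wrist <- c(-30, 135); pts$R_wrist <- c(30, 135)
  } else {
    pts$L_elbow <- c(-100, 0); pts$R_elbow <- c(100, 0)
    pts$L_wrist <- c(-165, 0); pts$R_wrist <- c(165, 0)
  }
  frames <- tibble::tibble(frame = seq_len(n) - 1L)
  for (lm in names(pts)) {
    p <- pts[[lm]] * scale + c(500, 300) + shift
    frames[[paste0(lm, "_x")]] <- rep(p[1], n)
    frames[[paste0(lm, "_y")]] <- rep(p[2], n)
    frames[[paste0(lm, "_likelihood")]] <- rep(1, n)
  }
  landmark_trace(frames, trial_id = "static", participant_id = "p0",
                 group = "HC")
}

# A trace whose body geometry follows a prescribed per-frame scale schedule,
# noiseless, all likelihoods 1 unless lost_frames marks losses for a landmark.
scale_schedule_trace <- function(scales, lost = list()) {
  n <- length(scales)
  pts <- list(
    L_shoulder = c(-30, 0), R_shoulder = c(30, 0),
    L_elbow = c(-30, 70), R_elbow = c(30, 70),
    L_wrist = c(-30, 135), R_wrist = c(30, 135),
    L_hip = c(-22, 120), R_hip = c(22, 120)
  )
  frames <- tibble::tibble(frame = seq_len(n) - 1L)
  for (lm in names(pts)) {
    frames[[paste0(lm, "_x")]] <- pts[[lm]][1] * scales + 500
    frames[[paste0(lm, "_y")]] <- pts[[lm]][2] * scales + 300
    lik <- rep(1, n)
    if (!is.null(lost[[lm]])) lik[lost[[lm]]] <- 0
    frames[[paste0(lm, "_likelihood")]] <- lik
  }
  landmark_trace(frames, trial_id = "sched", participant_id = "p0",
                 group = "HC")
}

# A clean noiseless simulated trial (no jitter, no random dropout).
noiseless_config <- function(...) {
  synth_config(jitter_sd = 0, isolated_dropout_prob = 0, ...)
}

# Small cohort config used by several files; modest sizes keep the suite fast.
small_cohort_config <- function(seed = 42, ...) {
  synth_config(n_abi = 10, n_hc = 6, rated_hc_videos = 6, seed = seed, ...)
}

# A compact hyperparameter grid for tests that exercise the CV machinery.
fast_model_config <- function(seed = 1, ...) {
  model_config(num_trees = 100, max_depth = c(0, 10), min_node = 1,
               seed = seed, ...)
}

# Directly constructed feature table with severity-proportional means and
# Gaussian noise; label equals the generating severity.
separable_features <- function(n = 150, noise = 0.05, seed = 1,
                               labels = NULL) {
  set.seed(seed)
  lab <- labels %||% sample(0:4, n, replace = TRUE)
  X <- matrix(rnorm(n * 24, mean = rep(lab, 24), sd = noise), nrow = n)
  colnames(X) <- feature_names()
  out <- tibble::as_tibble(X)
  out$trial_id <- sprintf("t%03d", seq_len(n))
  out$participant_id <- sprintf("p%03d", seq_len(n))
  out$median_score <- as.integer(lab)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
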