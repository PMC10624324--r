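# Synthetic BODY_25 skeleton motion for the SLST and SDT, with injectable
# execution errors and simulated expert raters. The generator emulates the
# study protocol (46-subject cohorts, ~15 s clips at 30 fps, 1280x720 image,
# three repetitions per limb, three raters) at the signal level: a
# raised-cosine squat cycle on the stance limb, a rigid trunk, and Gaussian
# keypoint jitter standing in for pose-detector noise. It makes no claim to
# biomechanical dynamics; only the kinematic signatures the feature
# catalogue monitors are modeled.

ERROR_MODES <- c("loss_of_balance", "gross_arm_deviation", "forward_lean",
                 "shallow_squat", "hip_drop", "tremor")

#' Simulation configuration
#'
#' Defaults mirror the study protocol: 46 subjects, 3 repetitions per limb,
#' 15 s clips at 30 fps, a squat to 100 degrees of knee flexion, 1 px
#' keypoint jitter, and a three-rater panel at sensitivity 0.9 / specificity
#' 0.95 per rater.
#'
#' @param n_subjects Cohort size.
#' @param reps_per_limb Squat repetitions per clip.
#' @param fps Frames per second.
#' @param duration_s Clip length in seconds.
#' @param squat_depth Target knee angle at the bottom of a correct squat
#'   (degrees; standing is ~175).
#' @param noise_sd Gaussian keypoint jitter, px.
#' @param dropout_rate Per-keypoint-frame probability of a simulated detector
#'   dropout (flagged missing; default 0).
#' @param error_prevalence Named per-mode probability that a subject commits
#'   the error (names from `loss_of_balance`, `gross_arm_deviation`,
#'   `forward_lean`, `shallow_squat`, `hip_drop`, `tremor`).
#' @param error_magnitudes Named per-mode injected effect size, in the units
#'   of the signal each mode perturbs (degrees for `forward_lean`,
#'   `shallow_squat`, `hip_drop`; px for the others).
#' @param rater_model List with one `c(sensitivity, specificity)` pair per
#'   simulated rater.
#' @param natural_variation Apply the per-subject movement-style terms of
#'   [subject_profile()] (small trunk sway, hip tilt and arm drift within
#'   the bounds of a correct execution). Default `TRUE`; with `FALSE` and
#'   `noise_sd = 0` the error-free clip is geometrically ideal (constant
#'   vertical trunk).
#' @param tests Which functional tests to generate clips for.
#' @param multi_error If `FALSE` (default) a subject commits at most one
#'   error mode, matching the one-label-per-parameter design; if `TRUE`,
#'   modes are drawn independently.
#' @param limbs Stance-limb assignment across the cohort: `"alternate"`
#'   (default, as in a study recording both sides), `"right"` or `"left"`
#'   for single-limb cohorts. The feature catalogue is side-specific, so
#'   effect sizes concentrate in single-limb cohorts.
#' @param seed Master random state; every stochastic stage derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 46, reps_per_limb = 3, fps = 30,
                              duration_s = 15, squat_depth = 100,
                              noise_sd = 1, dropout_rate = 0,
                              error_prevalence = NULL,
                              error_magnitudes = NULL,
                              rater_model = rep(list(c(0.9, 0.95)), 3),
                              natural_variation = TRUE,
                              tests = c("SLST", "SDT"),
                              multi_error = FALSE,
                              limbs = c("alternate", "right", "left"),
                              seed = 42) {
  prev <- stats::setNames(rep(0.1, 6), ERROR_MODES)
  if (!is.null(error_prevalence)) prev[names(error_prevalence)] <- error_prevalence
  mags <- c(loss_of_balance = 60, gross_arm_deviation = 120, forward_lean = 15,
            shallow_squat = 40, hip_drop = 12, tremor = 4)
  if (!is.null(error_magnitudes)) mags[names(error_magnitudes)] <- error_magnitudes
  stopifnot(all(prev >= 0 & prev <= 1), fps > 0, duration_s > 0, n_subjects >= 1)
  if (!multi_error && sum(prev) > 1)
    ms_stop("bad_argument", "single-error mode needs sum(error_prevalence) <= 1")
  structure(list(n_subjects = n_subjects, reps_per_limb = reps_per_limb,
                 fps = fps, duration_s = duration_s, squat_depth = squat_depth,
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 error_prevalence = prev, error_magnitudes = mags,
                 rater_model = rater_model, natural_variation = natural_variation,
                 tests = match.arg(tests, several.ok = TRUE),
                 multi_error = multi_error, limbs = match.arg(limbs),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Subject anthropometry and movement style for simulation
#'
#' Trunk length (neck to mid-hip, px) is drawn around 170 px with the same
#' coefficient of variation as the cohort's body height (mean 173.8 cm, SD
#' 9.9 cm); limb segments are fixed proportions of the trunk. Small
#' per-subject style terms (squat-depth offset, natural trunk sway and hip
#' tilt, arm drift) emulate the inter-subject variability of correct
#' executions.
#'
#' @param seed Per-subject random state.
#' @param trunk_length Optional fixed trunk length in px (otherwise drawn).
#' @return A `subject_profile` list, including the 25-keypoint standing
#'   template (`template`, a 25 x 2 matrix in a 1280 x 720 image).
#' @export
subject_profile <- function(seed = 1, trunk_length = NULL) {
  draws <- with_seed(derive_seed(seed, 1), list(
    trunk = stats::rnorm(1, 170, 170 * 9.9 / 173.8),
    depth_offset = stats::rnorm(1, 0, 5),
    sway_deg = stats::runif(1, 0, 2),
    hip_tilt_deg = stats::runif(1, 0, 1.5),
    arm_drift_px = stats::runif(1, 0, 6),
    phase = stats::runif(1, 0, 2 * pi)
  ))
  # clamp to ~+-2 SD so the tallest subjects still fit the 720 px frame
  L <- if (is.null(trunk_length)) min(185, max(130, draws$trunk)) else trunk_length
  hip <- c(640, 390)
  tmpl <- matrix(NA_real_, 25, 2, dimnames = list(BODY25_NAMES, c("x", "y")))
  place <- function(name, x, y) tmpl[name, ] <<- c(x, y)
  place("MidHip", hip[1], hip[2])
  place("Neck", hip[1], hip[2] - L)
  place("Nose", hip[1], hip[2] - 1.25 * L)
  place("REye", hip[1] - 0.05 * L, hip[2] - 1.28 * L)
  place("LEye", hip[1] + 0.05 * L, hip[2] - 1.28 * L)
  place("REar", hip[1] - 0.09 * L, hip[2] - 1.25 * L)
  place("LEar", hip[1] + 0.09 * L, hip[2] - 1.25 * L)
  place("RShoulder", hip[1] - 0.35 * L, hip[2] - 0.95 * L)
  place("LShoulder", hip[1] + 0.35 * L, hip[2] - 0.95 * L)
  place("RElbow", hip[1] - 0.40 * L, hip[2] - 0.40 * L)
  place("LElbow", hip[1] + 0.40 * L, hip[2] - 0.40 * L)
  place("RWrist", hip[1] - 0.42 * L, hip[2] + 0.10 * L)
  place("LWrist", hip[1] + 0.42 * L, hip[2] + 0.10 * L)
  place("RHip", hip[1] - 0.20 * L, hip[2])
  place("LHip", hip[1] + 0.20 * L, hip[2])
  place("RKnee", hip[1] - 0.20 * L, hip[2] + 0.85 * L)
  place("LKnee", hip[1] + 0.20 * L, hip[2] + 0.85 * L)
  place("RAnkle", hip[1] - 0.20 * L, hip[2] + 1.65 * L)
  place("LAnkle", hip[1] + 0.20 * L, hip[2] + 1.65 * L)
  place("RHeel", hip[1] - 0.17 * L, hip[2] + 1.70 * L)
  place("LHeel", hip[1] + 0.17 * L, hip[2] + 1.70 * L)
  place("RBigToe", hip[1] - 0.15 * L, hip[2] + 1.75 * L)
  place("LBigToe", hip[1] + 0.15 * L, hip[2] + 1.75 * L)
  place("RSmallToe", hip[1] - 0.27 * L, hip[2] + 1.75 * L)
  place("LSmallToe", hip[1] + 0.27 * L, hip[2] + 1.75 * L)
  structure(c(list(trunk_length = L, thigh = 0.85 * L, shank = 0.80 * L,
                   template = tmpl, seed = seed),
              draws[-1]),
            class = "subject_profile")
}

# Raised-cosine repetition envelope in [0, 1]: one bump per repetition.
rep_envelope <- function(t, duration, reps) {
  (1 - cos(2 * pi * reps * t / duration)) / 2
}

#' Generate an error-free functional-test clip
#'
#' The stance limb squats from ~175 degrees of knee angle down to the
#' configured depth and back, once per repetition, under a raised-cosine
#' envelope; the knee angle is imposed exactly via a symmetric two-link
#' construction (shank and thigh tilt by equal opposite half-angles, keeping
#' the hip over the ankle), so the generated knee-angle signal is ground
#' truth for the kinematics. The pelvis, trunk, head, arms and free leg ride
#' rigidly on the stance hip. The SDT variant raises the stance ankle by a
#' 20 cm step (scaled to the subject's trunk). Every keypoint receives
#' independent Gaussian jitter of `noise_sd` px.
#'
#' @param test_id `"SLST"` or `"SDT"`.
#' @param profile A [subject_profile()].
#' @param config A [simulation_config()].
#' @param limb Stance limb, `"right"` (default) or `"left"`.
#' @param subject_id Identifier stored on the sequence.
#' @return A `pose_sequence` with no missing keypoints (unless
#'   `dropout_rate > 0`).
#' @export
generate_base_motion <- function(test_id, profile, config = simulation_config(),
                                 limb = "right", subject_id = "sim") {
  test_id <- match.arg(test_id, c("SLST", "SDT"))
  limb <- match.arg(limb, c("right", "left"))
  n <- round(config$duration_s * config$fps)
  t <- (0:(n - 1)) / config$fps
  L <- profile$trunk_length
  tmpl <- profile$template
  stance <- if (limb == "right") c(hip = "RHip", knee = "RKnee", ankle = "RAnkle")
            else c(hip = "LHip", knee = "LKnee", ankle = "LAnkle")
  dir <- if (limb == "right") -1 else 1   # lateral knee-bend direction on screen
  depth <- min(170, max(60, config$squat_depth + profile$depth_offset))
  env <- rep_envelope(t, config$duration_s, config$reps_per_limb)
  theta <- 175 - (175 - depth) * env      # knee angle, degrees
  phi <- (180 - theta) * pi / 360         # half-bend, radians

  ankle0 <- tmpl[stance["ankle"], ]
  if (test_id == "SDT") ankle0[2] <- ankle0[2] - 0.42 * L  # 20 cm step
  knee_x <- ankle0[1] + dir * profile$shank * sin(phi)
  knee_y <- ankle0[2] - profile$shank * cos(phi)
  hip_x <- knee_x - dir * profile$thigh * sin(phi)
  hip_y <- knee_y - profile$thigh * cos(phi)

  # rigid pelvis offset: everything except the stance leg follows the pelvis
  pelvis_dx <- hip_x - tmpl[stance["hip"], 1]
  pelvis_dy <- hip_y - tmpl[stance["hip"], 2]

  coords <- array(NA_real_, c(n, 25, 2))
  rigid <- setdiff(BODY25_NAMES, stance[c("knee", "ankle")])
  for (k in rigid) {
    coords[, match(k, BODY25_NAMES), 1] <- tmpl[k, 1] + pelvis_dx
    coords[, match(k, BODY25_NAMES), 2] <- tmpl[k, 2] + pelvis_dy
  }
  coords[, match(stance["knee"], BODY25_NAMES), 1] <- knee_x
  coords[, match(stance["knee"], BODY25_NAMES), 2] <- knee_y
  coords[, match(stance["ankle"], BODY25_NAMES), 1] <- ankle0[1]
  coords[, match(stance["ankle"], BODY25_NAMES), 2] <- ankle0[2]
  # the stance foot is planted with its ankle (on the step for the SDT)
  step_dy <- if (test_id == "SDT") -0.42 * L else 0
  for (k in paste0(if (limb == "right") "R" else "L",
                   c("Heel", "BigToe", "SmallToe"))) {
    i <- match(k, BODY25_NAMES)
    coords[, i, 1] <- tmpl[k, 1]
    coords[, i, 2] <- tmpl[k, 2] + step_dy
  }
  free_side <- if (limb == "right") "L" else "R"
  free_foot <- paste0(free_side, c("Ankle", "Heel", "BigToe", "SmallToe"))
  free_knee <- paste0(free_side, "Knee")
  if (test_id == "SLST") {
    # free foot held off the floor, knee slightly flexed
    for (k in free_foot) {
      i <- match(k, BODY25_NAMES)
      coords[, i, 2] <- coords[, i, 2] - 0.35 * L
    }
    i <- match(free_knee, BODY25_NAMES)
    coords[, i, 2] <- coords[, i, 2] - 0.10 * L
  } else {
    # free foot reaches down from the step toward the floor
    for (k in free_foot) {
      i <- match(k, BODY25_NAMES)
      coords[, i, 2] <- coords[, i, 2] + 0.42 * L * env
    }
  }
  # the floor is rigid: the free foot never passes its template ground level
  for (k in free_foot) {
    i <- match(k, BODY25_NAMES)
    coords[, i, 2] <- pmin(coords[, i, 2], tmpl[k, 2] - 0.02 * L)
  }

  if (isTRUE(config$natural_variation)) {
    # movement style of a correct execution: small sway/tilt/drift
    sway <- profile$sway_deg * sin(2 * pi * t / config$duration_s + profile$phase)
    coords <- rotate_about(coords, kp_set = 1:9, center_kp = 9,
                           angle_deg = sway)
    tilt <- profile$hip_tilt_deg * sin(2 * pi * t / config$duration_s + profile$phase / 2)
    coords <- rotate_about(coords, kp_set = c(10, 13), center_kp = 9,
                           angle_deg = tilt)
    drift <- profile$arm_drift_px * rep_envelope(t, config$duration_s, 1)
    for (k in c("RWrist", "RElbow")) {
      i <- match(k, BODY25_NAMES)
      coords[, i, 1] <- coords[, i, 1] - drift
    }
    for (k in c("LWrist", "LElbow")) {
      i <- match(k, BODY25_NAMES)
      coords[, i, 1] <- coords[, i, 1] + drift
    }
  }

  noise_miss <- with_seed(derive_seed(profile$seed, 7), {
    nz <- if (config$noise_sd > 0)
      array(stats::rnorm(n * 25 * 2, 0, config$noise_sd), c(n, 25, 2))
    else array(0, c(n, 25, 2))
    mm <- if (config$dropout_rate > 0)
      matrix(stats::runif(n * 25) < config$dropout_rate, n, 25)
    else matrix(FALSE, n, 25)
    list(nz = nz, mm = mm)
  })
  coords <- coords + noise_miss$nz
  conf <- matrix(0.9, n, 25)
  conf[noise_miss$mm] <- 0
  pose_sequence(coords, conf, noise_miss$mm, fps = config$fps,
                subject_id = subject_id, test_id = test_id, limb = limb)
}

# Rotate keypoints `kp_set` (1-based R indices) of every frame about the
# per-frame position of `center_kp`, by per-frame `angle_deg`. Positive
# angles rotate counterclockwise on screen (image y points down).
rotate_about <- function(coords, kp_set, center_kp, angle_deg) {
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  cx <- coords[, center_kp, 1]; cy <- coords[, center_kp, 2]
  for (k in kp_set) {
    dx <- coords[, k, 1] - cx
    dy <- coords[, k, 2] - cy
    coords[, k, 1] <- cx + ca * dx + sa * dy     # y-down: screen-ccw rotation
    coords[, k, 2] <- cy - sa * dx + ca * dy
  }
  coords
}

#' Inject an execution error into a pose sequence
#'
#' Each mode perturbs the keypoints that drive the signal family an expert
#' would watch for that error:
#' \describe{
#'   \item{`forward_lean`}{rotates the upper body (keypoints 0-8) about the
#'     mid-hip by up to `magnitude` degrees over a slow envelope (targets the
#'     Spine orientation).}
#'   \item{`hip_drop`}{tilts the hip pair (9, 12) about the mid-hip by up to
#'     `magnitude` degrees (targets the Hips orientation).}
#'   \item{`tremor`}{adds band-limited 8-12 Hz oscillation of `magnitude` px
#'     to knees and ankles (targets the knee-angle signals).}
#'   \item{`gross_arm_deviation`}{drifts elbows and wrists outward by up to
#'     `magnitude` px (targets the wrist relative distances).}
#'   \item{`loss_of_balance`}{applies a transient lateral sway of up to
#'     `magnitude` px to every keypoint above the ankles, feet staying
#'     planted (targets hip/knee geometry).}
#'   \item{`shallow_squat`}{compresses the movement toward the standing
#'     frame so the squat misses its depth by about `magnitude` degrees of
#'     knee angle (targets the knee-angle ROM).}
#' }
#' `magnitude = 0` returns the input unchanged; the targeted feature
#' responds monotonically to `magnitude`.
#'
#' @param seq A `pose_sequence`.
#' @param mode One of the six error modes.
#' @param magnitude Effect size, `>= 0` (degrees or px, see above).
#' @param seed Random state for the stochastic component of `tremor`.
#' @return The perturbed `pose_sequence`.
#' @export
inject_error <- function(seq, mode, magnitude, seed = 1) {
  if (!mode %in% ERROR_MODES)
    ms_stop("configuration_error", "unknown error mode '%s'", mode)
  if (magnitude < 0) ms_stop("bad_argument", "magnitude must be >= 0")
  if (magnitude == 0) return(seq)
  n <- n_frames(seq)
  t <- timestamps(seq)
  duration <- (n - 1) / seq$fps
  env <- rep_envelope(t, max(duration, 1e-9), 1)
  co <- seq$coords
  if (mode == "forward_lean") {
    co <- rotate_about(co, kp_set = 1:9, center_kp = 9, angle_deg = magnitude * env)
  } else if (mode == "hip_drop") {
    co <- rotate_about(co, kp_set = c(10, 13), center_kp = 9,
                       angle_deg = magnitude * env)
  } else if (mode == "tremor") {
    # independent band-limited oscillation per keypoint and coordinate, so
    # the joints genuinely deform rather than translating rigidly
    ph <- with_seed(derive_seed(seed, 3),
                    array(stats::runif(4 * 2 * 3, 0, 2 * pi), c(4, 2, 3)))
    freqs <- c(8, 9.7, 11.3)
    kps <- kp_idx(c(10, 11, 13, 14))
    for (ki in seq_along(kps)) {
      for (d in 1:2) {
        # sqrt(3) scaling makes the 3-component band RMS-equivalent to a
        # single sinusoid of the declared px amplitude
        osc <- Reduce(`+`, lapply(1:3, function(h)
          sin(2 * pi * freqs[h] * t + ph[ki, d, h]))) / sqrt(3)
        amp <- magnitude * if (d == 2) 0.6 else 1
        co[, kps[ki], d] <- co[, kps[ki], d] + amp * osc
      }
    }
  } else if (mode == "gross_arm_deviation") {
    out <- magnitude * env
    for (k in kp_idx(c(3, 4))) co[, k, 1] <- co[, k, 1] - out  # right arm
    for (k in kp_idx(c(6, 7))) co[, k, 1] <- co[, k, 1] + out  # left arm
  } else if (mode == "loss_of_balance") {
    bump <- magnitude * exp(-((t - duration / 2) / (duration / 8))^2 / 2)
    planted <- kp_idx(c(11, 14, 19:24))  # ankles and feet stay on the ground
    for (k in setdiff(1:25, planted)) co[, k, 1] <- co[, k, 1] + bump
  } else if (mode == "shallow_squat") {
    ref <- which.min(co[, kp_idx(8), 2])  # most upright frame
    s <- max(0, 1 - magnitude / 75)
    refco <- co[ref, , ]
    for (k in 1:25) for (d in 1:2)
      co[, k, d] <- refco[k, d] + s * (co[, k, d] - refco[k, d])
  }
  seq$coords <- co
  seq
}

#' Simulate an expert rater panel
#'
#' Each rater independently reports a subject's true error status, flipping
#' a true positive with probability `1 - sensitivity` and a true negative
#' with probability `1 - specificity`. Perfect raters `(1, 1)` reproduce the
#' truth exactly.
#'
#' @param true_labels Binary matrix, subjects x parameters (a vector is
#'   treated as one parameter).
#' @param rater_model List of `c(sensitivity, specificity)` pairs.
#' @param seed Random state.
#' @return Array `subjects x raters x parameters` of binary ratings.
#' @export
simulate_raters <- function(true_labels, rater_model = rep(list(c(1, 1)), 3),
                            seed = 42) {
  tl <- as.matrix(true_labels)
  n <- nrow(tl); p <- ncol(tl); r <- length(rater_model)
  for (rm in rater_model)
    if (any(rm < 0 | rm > 1))
      ms_stop("bad_argument", "rater sensitivity/specificity must be in [0, 1]")
  ratings <- array(NA_real_, c(n, r, p),
                   dimnames = list(NULL, NULL, colnames(tl)))
  with_seed(derive_seed(seed, 11), {
    for (j in seq_len(r)) {
      sens <- rater_model[[j]][1]; spec <- rater_model[[j]][2]
      u <- matrix(stats::runif(n * p), n, p)
      ratings[, j, ] <- ifelse(tl == 1, as.integer(u < sens),
                               as.integer(u >= spec))
    }
  })
  ratings
}

#' Generate a full synthetic cohort
#'
#' Draws a subject profile per subject, assigns execution errors at the
#' configured per-mode prevalence (at most one mode per subject unless
#' `multi_error`), renders one clip per subject and test with the configured
#' error magnitude injected, and simulates the rater panel on the true
#' labels. Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `sequences` (named `"<subject>_<test>"`), `true_labels`
#'   (subjects x 6 modes binary matrix), `ratings` (subjects x raters x
#'   modes array), `subjects` (profile list), `config`.
#' @export
generate_dataset <- function(config = simulation_config()) {
  ns <- config$n_subjects
  modes <- ERROR_MODES
  true_labels <- matrix(0L, ns, length(modes), dimnames = list(NULL, modes))
  assign_draw <- with_seed(derive_seed(config$seed, 17), {
    if (config$multi_error) {
      matrix(stats::runif(ns * length(modes)), ns, length(modes))
    } else {
      stats::runif(ns)
    }
  })
  if (config$multi_error) {
    true_labels[] <- as.integer(assign_draw < rep(config$error_prevalence,
                                                  each = ns))
  } else {
    cuts <- cumsum(config$error_prevalence)
    for (i in seq_len(ns)) {
      m <- which(assign_draw[i] < cuts)[1]
      if (!is.na(m)) true_labels[i, m] <- 1L
    }
  }
  sequences <- list()
  subjects <- vector("list", ns)
  for (i in seq_len(ns)) {
    prof <- subject_profile(seed = derive_seed(config$seed, 1000L + i))
    subjects[[i]] <- prof
    limb <- switch(config$limbs, alternate = if (i %% 2 == 0) "left" else "right",
                   config$limbs)
    for (tt in config$tests) {
      sid <- sprintf("S%03d", i)
      seq <- generate_base_motion(tt, prof, config, limb = limb, subject_id = sid)
      for (m in modes[true_labels[i, ] == 1]) {
        seq <- inject_error(seq, m, config$error_magnitudes[[m]],
                            seed = derive_seed(config$seed, 2000L + i))
      }
      sequences[[paste0(sid, "_", tt)]] <- seq
    }
  }
  ratings <- simulate_raters(true_labels, config$rater_model,
                             seed = derive_seed(config$seed, 23))
  list(sequences = sequences, true_labels = true_labels, ratings = ratings,
       subjects = subjects, config = config)
}
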