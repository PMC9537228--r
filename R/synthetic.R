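#' Synthetic gait simulator parameters
#'
#' Controls the class-structured walking-motion generator used to test
#' the full pipeline without any external capture data.  Joints follow
#' phase-offset sinusoids (left/right limbs in antiphase) superimposed
#' on a constant forward root translation; the four diagnostic classes
#' differ through configurable kinematic effects:
#'
#' * `asymmetry_ratio` — right-side oscillation amplitudes are scaled by
#'   this ratio (1 = symmetric gait, smaller = more one-sided).
#' * `rom_scale` — range-of-motion multiplier applied to the affected
#'   joints only (default right hip and knee).
#' * `tremor_sd` — amplitude (meters) of a high-frequency (8 Hz)
#'   sinusoidal tremor with random per-joint phase.
#' * `phase_jitter_sd` — standard deviation (radians) of per-joint phase
#'   perturbations, the main source of within-class variability.
#'
#' @param n_frames_raw Frames per generated cycle (default 120, one
#'   cycle at the 100 Hz capture rate).
#' @param frame_rate Capture rate in Hz (default 100).
#' @param stride_period Gait-cycle period in seconds (default 1.2,
#'   typical of older adults walking at comfortable speed).
#' @param walking_speed Forward root speed in m/s (default 1.0).
#' @param base_amplitudes Named per-joint fore-aft oscillation
#'   amplitudes in meters; defaults model arm and leg swing.
#' @param class_effects Named list mapping each class to a list with
#'   entries `asymmetry_ratio`, `rom_scale`, `tremor_sd`,
#'   `phase_jitter_sd`.
#' @param affected_joints Joints whose amplitude `rom_scale` multiplies
#'   (default `c("r_hip", "r_knee")`).
#' @param noise_sd Sensor noise (meters) applied to all classes.
#' @param skeleton A [skeleton_def()].
#' @param seed Integer master seed.
#' @return A `gait_sim_params` object.
#' @export
gait_sim_params <- function(n_frames_raw = 120L,
                            frame_rate = 100,
                            stride_period = 1.2,
                            walking_speed = 1.0,
                            base_amplitudes = NULL,
                            class_effects = NULL,
                            affected_joints = c("r_hip", "r_knee"),
                            noise_sd = 0.002,
                            skeleton = default_skeleton(),
                            seed = 1L) {
  if (n_frames_raw < 10L) stopf("n_frames_raw must be >= 10")
  if (is.null(base_amplitudes)) {
    base_amplitudes <- c(
      pelvis = 0, spine_lower = 0.01, spine_upper = 0.01, chest = 0.015,
      neck = 0.015, head = 0.02,
      l_shoulder = 0.03, l_elbow = 0.10, l_wrist = 0.16,
      r_shoulder = 0.03, r_elbow = 0.10, r_wrist = 0.16,
      l_hip = 0.05, l_knee = 0.22, l_ankle = 0.33, l_foot = 0.38,
      r_hip = 0.05, r_knee = 0.22, r_ankle = 0.33, r_foot = 0.38)
  }
  if (is.null(class_effects)) {
    class_effects <- list(
      healthy = list(asymmetry_ratio = 1.0, rom_scale = 1.0,
                     tremor_sd = 0, phase_jitter_sd = 0.05),
      joint_problem = list(asymmetry_ratio = 1.0, rom_scale = 0.4,
                           tremor_sd = 0, phase_jitter_sd = 0.05),
      muscle_weakness = list(asymmetry_ratio = 0.55, rom_scale = 0.8,
                             tremor_sd = 0, phase_jitter_sd = 0.05),
      neurological_defect = list(asymmetry_ratio = 0.85, rom_scale = 0.9,
                                 tremor_sd = 0.012,
                                 phase_jitter_sd = 0.25))
  }
  for (cl in names(class_effects)) {
    ef <- class_effects[[cl]]
    if (ef$asymmetry_ratio <= 0 || ef$asymmetry_ratio > 1)
      stopf("asymmetry_ratio for '%s' must be in (0, 1]", cl)
    if (ef$rom_scale <= 0 || ef$rom_scale > 1)
      stopf("rom_scale for '%s' must be in (0, 1]", cl)
    if (ef$tremor_sd < 0 || ef$phase_jitter_sd < 0)
      stopf("tremor_sd and phase_jitter_sd for '%s' must be >= 0", cl)
  }
  if (any(base_amplitudes < 0)) stopf("base_amplitudes must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(n_frames_raw = as.integer(n_frames_raw),
                 frame_rate = frame_rate,
                 stride_period = stride_period,
                 walking_speed = walking_speed,
                 base_amplitudes = base_amplitudes,
                 class_effects = class_effects,
                 affected_joints = affected_joints,
                 noise_sd = noise_sd,
                 skeleton = skeleton,
                 seed = as.integer(seed)),
            class = "gait_sim_params")
}

# Standing reference pose (meters) for the default 20-joint skeleton.
base_pose <- function(joint_names) {
  pose <- rbind(
    pelvis      = c(0.00, 1.00,  0.00),
    spine_lower = c(0.00, 1.12,  0.00),
    spine_upper = c(0.00, 1.24,  0.00),
    chest       = c(0.00, 1.36,  0.00),
    neck        = c(0.00, 1.48,  0.00),
    head        = c(0.00, 1.60,  0.00),
    l_shoulder  = c(0.00, 1.45,  0.20),
    l_elbow     = c(0.00, 1.20,  0.23),
    l_wrist     = c(0.00, 0.95,  0.25),
    r_shoulder  = c(0.00, 1.45, -0.20),
    r_elbow     = c(0.00, 1.20, -0.23),
    r_wrist     = c(0.00, 0.95, -0.25),
    l_hip       = c(0.00, 0.95,  0.10),
    l_knee      = c(0.00, 0.55,  0.10),
    l_ankle     = c(0.00, 0.12,  0.10),
    l_foot      = c(0.12, 0.05,  0.10),
    r_hip       = c(0.00, 0.95, -0.10),
    r_knee      = c(0.00, 0.55, -0.10),
    r_ankle     = c(0.00, 0.12, -0.10),
    r_foot      = c(0.12, 0.05, -0.10))
  if (!all(joint_names %in% rownames(pose)))
    stopf("no reference pose for joint '%s'",
          setdiff(joint_names, rownames(pose))[1])
  pose[joint_names, , drop = FALSE]
}

# Per-joint gait phase offsets (radians).  Left leg leads at phase 0,
# right leg in antiphase; arms swing opposite their ipsilateral leg.
gait_phases <- function(joint_names) {
  ph <- c(pelvis = 0, spine_lower = 0, spine_upper = 0, chest = 0,
          neck = 0, head = 0,
          l_shoulder = pi, l_elbow = pi, l_wrist = pi,
          r_shoulder = 0, r_elbow = 0, r_wrist = 0,
          l_hip = 0, l_knee = 0, l_ankle = 0, l_foot = 0,
          r_hip = pi, r_knee = pi, r_ankle = pi, r_foot = pi)
  ph[joint_names]
}

is_right_side <- function(joint_names) startsWith(joint_names, "r_")

#' Simulate one walking cycle
#'
#' Generates one synthetic walking motion of the requested class.
#' Deterministic given `(params, class_label, seed)`.
#'
#' @param params A [gait_sim_params()].
#' @param class_label One of [gait_classes()].
#' @param seed Integer seed for this sample.
#' @param sample_id Identifier for the resulting sample.
#' @return A [motion_sample()] of shape `n_frames_raw x J x 3`.
#' @export
simulate_walk <- function(params, class_label, seed,
                          sample_id = paste0(class_label, "_", seed)) {
  classes <- gait_classes()
  if (!class_label %in% classes)
    stopf("unknown class label '%s'; valid classes: %s", class_label,
          paste(classes, collapse = ", "))
  jn <- params$skeleton$joint_names
  J <- params$skeleton$J
  Tn <- params$n_frames_raw
  ef <- params$class_effects[[class_label]]
  if (is.null(ef)) stopf("params$class_effects has no entry for '%s'",
                         class_label)

  pose <- base_pose(jn)
  phase0 <- gait_phases(jn)
  amp <- params$base_amplitudes[jn]
  amp[is.na(amp)] <- 0
  amp[is_right_side(jn)] <- amp[is_right_side(jn)] * ef$asymmetry_ratio
  aff <- intersect(params$affected_joints, jn)
  amp[aff] <- amp[aff] * ef$rom_scale

  tt <- (seq_len(Tn) - 1) / params$frame_rate
  omega <- 2 * pi / params$stride_period

  pos <- with_seed(seed, {
    jitter <- stats::rnorm(J, 0, ef$phase_jitter_sd)
    tremor_phase <- stats::runif(J * 3, 0, 2 * pi)
    p <- array(0, c(Tn, J, 3))
    # fore-aft: forward progression + limb swing
    phase_mat <- outer(omega * tt, rep(1, J)) +
      matrix(phase0 + jitter, Tn, J, byrow = TRUE)
    p[, , 1] <- params$walking_speed * tt +
      matrix(pose[, 1], Tn, J, byrow = TRUE) +
      sin(phase_mat) * matrix(amp, Tn, J, byrow = TRUE)
    # vertical: standing height + double-frequency bob scaled to swing
    p[, , 2] <- matrix(pose[, 2], Tn, J, byrow = TRUE) +
      sin(2 * phase_mat) * matrix(0.12 * amp, Tn, J, byrow = TRUE)
    # lateral: constant offset + small sway
    p[, , 3] <- matrix(pose[, 3], Tn, J, byrow = TRUE) +
      sin(phase_mat) * matrix(0.05 * amp, Tn, J, byrow = TRUE)
    if (ef$tremor_sd > 0) {
      trem_mat <- matrix(tremor_phase, Tn, J * 3, byrow = TRUE)
      p <- p + array(ef$tremor_sd * sin(2 * pi * 8 * tt + trem_mat),
                     c(Tn, J, 3))
    }
    if (params$noise_sd > 0)
      p <- p + array(stats::rnorm(Tn * J * 3, 0, params$noise_sd),
                     c(Tn, J, 3))
    p
  })
  motion_sample(pos, frame_rate = params$frame_rate, label = class_label,
                sample_id = sample_id, joint_names = jn)
}

#' Generate a class-structured cohort
#'
#' @param params A [gait_sim_params()].
#' @param counts Named integer vector mapping class to sample count,
#'   e.g. `c(healthy = 10, joint_problem = 4, muscle_weakness = 18,
#'   neurological_defect = 13)` for the benchmark cohort layout.
#' @param seed Master seed; per-sample seeds are derived from it.
#' @return List of [motion_sample()]s, grouped by class in canonical
#'   order, with `sum(counts)` elements.
#' @export
generate_cohort <- function(params, counts, seed = params$seed) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stopf("counts must be a named vector of class counts")
  bad <- setdiff(names(counts), gait_classes())
  if (length(bad)) stopf("unknown class '%s'; valid classes: %s", bad[1],
                         paste(gait_classes(), collapse = ", "))
  if (any(counts < 0)) stopf("counts must be >= 0")
  classes <- intersect(gait_classes(), names(counts))
  samples <- list()
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(counts[[cl]])) {
      k <- k + 1L
      samples[[k]] <- simulate_walk(
        params, cl, seed = derive_seed(seed, k),
        sample_id = sprintf("%s_%02d", cl, i))
    }
  }
  samples
}

cohort_labels <- function(samples)
  vapply(samples, function(s) s$label, character(1))
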