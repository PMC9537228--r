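#' Normalization configuration
#'
#' @param T_target Output frame count after temporal rescaling
#'   (default 100, one cycle at 100 Hz; must be at least 3 so the
#'   temporal convolution kernel fits).
#' @param keep_joints Ordered joint names to retain; `NULL` keeps the
#'   [default_skeleton()] set.
#' @param heading_axis Unit vector in the horizontal (x, z) plane that
#'   the walking direction is rotated onto; default +x.
#' @param root Name of the root joint used to define position and
#'   heading (default `"pelvis"`).
#' @return A `normalization_config` object.
#' @export
normalization_config <- function(T_target = 100L, keep_joints = NULL,
                                 heading_axis = c(1, 0), root = "pelvis") {
  if (T_target < 3L)
    stopf("T_target must be >= 3 (temporal kernel extent), got %d",
          T_target)
  h <- as.numeric(heading_axis)
  if (length(h) == 3) h <- h[c(1, 3)]  # accept 3-vector, use horizontal part
  nh <- sqrt(sum(h^2))
  if (nh < 1e-12) stopf("heading_axis must be a nonzero horizontal vector")
  structure(list(T_target = as.integer(T_target),
                 keep_joints = keep_joints, heading_axis = h / nh,
                 root = root),
            class = "normalization_config")
}

#' Temporal rescaling by linear interpolation
#'
#' Resamples every coordinate channel at `T_target` equally spaced
#' parameter values spanning the original first and last frames, using
#' the piecewise-linear interpolant.  First and last frames are
#' preserved exactly; trajectories affine in time are reproduced
#' exactly for any `T_target`.
#'
#' @param sample A [motion_sample()] with at least 2 frames.
#' @param T_target Output frame count (>= 3).
#' @return A [motion_sample()] with `T_target` frames.
#' @export
resample_linear <- function(sample, T_target) {
  if (T_target < 3L) stopf("T_target must be >= 3, got %d", T_target)
  pos <- sample$positions
  Tn <- dim(pos)[1]
  if (Tn == T_target) return(sample)
  x_in <- seq(0, 1, length.out = Tn)
  x_out <- seq(0, 1, length.out = T_target)
  mat <- matrix(pos, nrow = Tn)            # T x (J*3)
  out <- apply(mat, 2, function(y)
    stats::approx(x_in, y, xout = x_out)$y)
  new_pos <- array(out, c(T_target, dim(pos)[2], 3))
  motion_sample(new_pos,
                frame_rate = sample$frame_rate * (T_target - 1) / (Tn - 1),
                label = sample$label, sample_id = sample$sample_id,
                joint_names = sample$joint_names,
                synthetic = sample$synthetic)
}

#' Spatial alignment to a common start position and heading
#'
#' Applies one rigid rotation about the vertical (y) axis plus a
#' translation to every joint of every frame, so that the root joint of
#' the first frame sits at the origin and the horizontal component of
#' the root displacement from first to last frame points along the
#' configured heading axis.  All inter-joint distances are preserved.
#'
#' @param sample A [motion_sample()].
#' @param config A [normalization_config()].
#' @return The aligned [motion_sample()].
#' @export
spatial_align <- function(sample, config = normalization_config()) {
  pos <- sample$positions
  ri <- match(config$root, sample$joint_names)
  if (is.na(ri)) ri <- 1L
  Tn <- dim(pos)[1]
  disp <- pos[Tn, ri, c(1, 3)] - pos[1, ri, c(1, 3)]
  nd <- sqrt(sum(disp^2))
  if (nd < 1e-9)
    stopf("zero horizontal root displacement: heading undefined")
  u <- disp / nd
  h <- config$heading_axis
  # rotation about y mapping u onto h (2D rotation in the x-z plane)
  cosang <- sum(u * h)
  sinang <- u[1] * h[2] - u[2] * h[1]
  x <- pos[, , 1]; z <- pos[, , 3]
  new_x <- cosang * x - sinang * z
  new_z <- sinang * x + cosang * z
  out <- pos
  out[, , 1] <- new_x
  out[, , 3] <- new_z
  origin <- out[1, ri, ]
  out[, , 1] <- out[, , 1] - origin[1]
  out[, , 2] <- out[, , 2] - origin[2]
  out[, , 3] <- out[, , 3] - origin[3]
  motion_sample(out, frame_rate = sample$frame_rate, label = sample$label,
                sample_id = sample$sample_id,
                joint_names = sample$joint_names,
                synthetic = sample$synthetic)
}

#' Restrict and reorder joints
#'
#' @param sample A [motion_sample()].
#' @param keep Ordered character vector of joint names to retain.
#' @return A [motion_sample()] whose joints are exactly `keep`.
#' @export
select_joints <- function(sample, keep) {
  idx <- match(keep, sample$joint_names)
  if (anyNA(idx))
    stopf("unknown joint name '%s'", keep[is.na(idx)][1])
  motion_sample(sample$positions[, idx, , drop = FALSE],
                frame_rate = sample$frame_rate, label = sample$label,
                sample_id = sample$sample_id, joint_names = keep,
                synthetic = sample$synthetic)
}

#' Full normalization pipeline
#'
#' Joint selection, spatial alignment, then temporal rescaling.
#'
#' @param sample A [motion_sample()].
#' @param config A [normalization_config()].
#' @return The normalized [motion_sample()].
#' @export
preprocess_sample <- function(sample, config = normalization_config()) {
  if (!is.null(config$keep_joints))
    sample <- select_joints(sample, config$keep_joints)
  sample <- spatial_align(sample, config)
  resample_linear(sample, config$T_target)
}
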