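#' Canonical disorder classes
#'
#' The four diagnostic categories the classifier distinguishes: healthy
#' walkers plus three disorder groups (joint problems such as
#' osteoarthritis, muscle weakness such as muscular dystrophy, and
#' neurological defects such as Parkinson's disease).
#'
#' @return Character vector of the four class labels, in canonical order.
#' @export
gait_classes <- function() {
  c("healthy", "joint_problem", "muscle_weakness", "neurological_defect")
}

#' Skeleton definition
#'
#' An ordered list of joint names together with a parent index per joint
#' (-1 for the root), forming a kinematic tree.  The default skeleton is
#' the conventional 20-joint set solved from a Helen-Hayes-style marker
#' placement, with end effectors (toe tips, finger tips) removed.
#'
#' @param joint_names Ordered character vector of joint names.
#' @param parent_index Integer vector, 1-based index of each joint's
#'   parent; -1 marks the root.
#' @return A `skeleton_def` object with fields `joint_names`,
#'   `parent_index` and `J` (joint count).
#' @export
skeleton_def <- function(joint_names, parent_index) {
  joint_names <- as.character(joint_names)
  parent_index <- as.integer(parent_index)
  if (length(joint_names) != length(parent_index))
    stopf("joint_names (%d) and parent_index (%d) lengths differ",
          length(joint_names), length(parent_index))
  if (anyDuplicated(joint_names))
    stopf("duplicate joint name: %s",
          joint_names[duplicated(joint_names)][1])
  if (sum(parent_index == -1L) != 1L)
    stopf("exactly one root joint (parent_index -1) required")
  ok <- parent_index == -1L |
    (parent_index >= 1L & parent_index <= length(joint_names))
  if (!all(ok)) stopf("parent_index out of range for joint '%s'",
                      joint_names[!ok][1])
  # tree check: every joint must reach the root without cycles
  for (j in seq_along(joint_names)) {
    seen <- integer(0); cur <- j
    while (parent_index[cur] != -1L) {
      if (cur %in% seen) stopf("parent indices contain a cycle at '%s'",
                               joint_names[j])
      seen <- c(seen, cur)
      cur <- parent_index[cur]
    }
  }
  structure(list(joint_names = joint_names, parent_index = parent_index,
                 J = length(joint_names)),
            class = "skeleton_def")
}

#' Default 20-joint skeleton
#'
#' Six-joint spine/head chain, three joints per arm and four per leg.
#' Coordinate convention: x is the walking direction after alignment,
#' y is up, z is lateral (left positive).
#'
#' @return A [skeleton_def()] with 20 joints.
#' @export
default_skeleton <- function() {
  skeleton_def(
    joint_names = c("pelvis", "spine_lower", "spine_upper", "chest",
                    "neck", "head",
                    "l_shoulder", "l_elbow", "l_wrist",
                    "r_shoulder", "r_elbow", "r_wrist",
                    "l_hip", "l_knee", "l_ankle", "l_foot",
                    "r_hip", "r_knee", "r_ankle", "r_foot"),
    parent_index = c(-1L, 1L, 2L, 3L, 4L, 5L,
                     4L, 7L, 8L,
                     4L, 10L, 11L,
                     1L, 13L, 14L, 15L,
                     1L, 17L, 18L, 19L)
  )
}

#' Motion sample
#'
#' One subject's walking cycle: a frames x joints x 3 array of joint
#' positions in meters, plus capture metadata.
#'
#' @param positions Numeric array of dimension `frames x J x 3`.
#' @param frame_rate Capture rate in Hz.
#' @param label One of [gait_classes()] or `"unlabelled"`.
#' @param sample_id Identifier string.
#' @param joint_names Optional character vector naming the `J` joints
#'   (defaults to the [default_skeleton()] names when `J` is 20).
#' @param synthetic Logical; `TRUE` for mixup-generated samples.
#' @return A `motion_sample` object.
#' @export
motion_sample <- function(positions, frame_rate, label = "unlabelled",
                          sample_id = "sample", joint_names = NULL,
                          synthetic = FALSE) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    stopf("positions must be a frames x J x 3 array")
  if (dim(positions)[1] < 2L)
    stopf("a motion sample needs at least 2 frames, got %d",
          dim(positions)[1])
  if (!all(is.finite(positions)))
    stopf("positions contain non-finite values")
  valid <- c(gait_classes(), "unlabelled")
  if (!label %in% valid)
    stopf("unknown class label '%s'; valid labels: %s", label,
          paste(valid, collapse = ", "))
  J <- dim(positions)[2]
  if (is.null(joint_names)) {
    joint_names <- if (J == 20L) default_skeleton()$joint_names
                   else paste0("joint", seq_len(J))
  }
  if (length(joint_names) != J)
    stopf("joint_names length %d does not match J = %d",
          length(joint_names), J)
  dimnames(positions) <- list(NULL, joint_names, c("x", "y", "z"))
  structure(list(positions = positions,
                 frame_rate = as.numeric(frame_rate),
                 label = label,
                 sample_id = as.character(sample_id),
                 joint_names = joint_names,
                 synthetic = isTRUE(synthetic)),
            class = "motion_sample")
}

#' @export
print.motion_sample <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<motion_sample '%s'> %d frames x %d joints, %.0f Hz, label=%s%s\n",
              x$sample_id, d[1], d[2], x$frame_rate, x$label,
              if (x$synthetic) " (synthetic)" else ""))
  invisible(x)
}

#' @export
print.skeleton_def <- function(x, ...) {
  cat(sprintf("<skeleton_def> %d joints, root='%s'\n", x$J,
              x$joint_names[x$parent_index == -1L]))
  invisible(x)
}

n_frames <- function(sample) dim(sample$positions)[1]
n_joints <- function(sample) dim(sample$positions)[2]
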