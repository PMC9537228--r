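#' Mixup specification
#'
#' @param lam Interpolation weight in `[0, 1]`; 0.9 keeps the synthetic
#'   sample close to its label-donating anchor while injecting small
#'   inter-class similarity.
#' @param target_per_class Per-class sample count after balancing
#'   (default 45, lifting the 10/4/18/13 benchmark cohort to a
#'   balanced, four-times-larger training set).
#' @param seed Integer seed for anchor/donor selection.
#' @return A `mixup_spec` object.
#' @export
mixup_spec <- function(lam = 0.9, target_per_class = 45L, seed = 1L) {
  if (lam < 0 || lam > 1) stopf("lam must lie in [0, 1], got %g", lam)
  if (target_per_class < 1) stopf("target_per_class must be positive")
  structure(list(lam = lam, target_per_class = as.integer(target_per_class),
                 seed = as.integer(seed)),
            class = "mixup_spec")
}

#' Mixup interpolation of two tensors
#'
#' Elementwise convex combination `lam * X_a + (1 - lam) * X_b`.  In
#' the balancing protocol the synthetic sample inherits the class label
#' of `X_a`.
#'
#' @param X_a,X_b Numeric arrays of identical shape.
#' @param lam Weight in `[0, 1]` on `X_a`.
#' @return Array of the same shape.
#' @export
mixup <- function(X_a, X_b, lam) {
  if (lam < 0 || lam > 1) stopf("lam must lie in [0, 1], got %g", lam)
  if (!identical(dim(X_a) %||% length(X_a), dim(X_b) %||% length(X_b)))
    stopf("mixup inputs have mismatched shapes")
  lam * X_a + (1 - lam) * X_b
}

# Mixup of two motion samples; label and metadata follow the anchor a.
# The anchors' sample ids are recorded for provenance.
mixup_motion <- function(a, b, lam, sample_id) {
  if (!identical(dim(a$positions), dim(b$positions)))
    stopf("mixup anchors have mismatched shapes (%s vs %s): normalize first",
          paste(dim(a$positions), collapse = "x"),
          paste(dim(b$positions), collapse = "x"))
  out <- motion_sample(mixup(a$positions, b$positions, lam),
                       frame_rate = a$frame_rate, label = a$label,
                       sample_id = sample_id, joint_names = a$joint_names,
                       synthetic = TRUE)
  out$anchors <- c(a = a$sample_id, b = b$sample_id)
  out
}

#' Class balancing by mixup
#'
#' Fills every class up to `target_per_class` samples with synthetic
#' mixup samples.  For each synthetic sample of deficit class `a`, the
#' anchor `X_a` is drawn uniformly from the real samples of class `a`
#' and the donor `X_b` uniformly from a uniformly chosen *different*
#' class; the result `lam * X_a + (1-lam) * X_b` carries class `a`'s
#' label and is flagged `synthetic`.  All real samples are retained.
#' Deterministic given `spec$seed`.
#'
#' @param samples List of normalized [motion_sample()]s (equal shapes).
#' @param spec A [mixup_spec()].
#' @return List of motion samples with exactly `target_per_class`
#'   samples per class (real first, synthetic appended).
#' @export
balance_by_mixup <- function(samples, spec = mixup_spec()) {
  labels <- cohort_labels(samples)
  classes <- intersect(gait_classes(), unique(labels))
  if (length(classes) == 0) stopf("no labelled samples to balance")
  by_class <- lapply(classes, function(cl) which(labels == cl))
  names(by_class) <- classes
  counts <- lengths(by_class)
  if (any(counts == 0))
    stopf("class '%s' has no real samples: cannot synthesize from an empty class",
          classes[counts == 0][1])
  if (length(classes) < 2 && any(counts < spec$target_per_class))
    stopf("mixup needs a donor from a different class; only '%s' is present",
          classes[1])
  if (spec$target_per_class < max(counts))
    stopf("target_per_class (%d) below the largest class count (%d)",
          spec$target_per_class, max(counts))
  out <- samples[unlist(by_class)]
  with_seed(spec$seed, {
    for (cl in classes) {
      need <- spec$target_per_class - counts[[cl]]
      if (need == 0) next
      others <- setdiff(classes, cl)
      for (k in seq_len(need)) {
        ia <- by_class[[cl]][sample.int(counts[[cl]], 1)]
        clb <- others[sample.int(length(others), 1)]
        ib <- by_class[[clb]][sample.int(counts[[clb]], 1)]
        out[[length(out) + 1L]] <- mixup_motion(
          samples[[ia]], samples[[ib]], spec$lam,
          sample_id = sprintf("%s_syn_%03d", cl, k))
      }
    }
  })
  out
}
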