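#' Extract joint and joint-pair importance from attention gates
#'
#' Reads the trained sigmoid gate values of one or more
#' attention-augmented models (typically one per cross-validation
#' fold), averages them across folds, and min-max rescales each stream
#' to `[0, 1]`.  Pair importance is additionally aggregated to joints:
#' `aggregated_joint_interaction[j]` is the sum of the importance of
#' every pair containing joint `j`, so summing it over joints gives
#' exactly twice the total pair importance.
#'
#' @param models List of trained attention-augmented `fusion_net`s.
#' @return An `attention_report`: list with `joint_importance`
#'   (length `J`, named), `pair_importance` (length `D`),
#'   `pair_order`, `aggregated_joint_interaction` (length `J`, named)
#'   and `n_folds`.
#' @export
extract_importance <- function(models) {
  if (length(models) == 0) stopf("no trained folds supplied")
  if (any(vapply(models, function(m) is.null(m$attention), logical(1))))
    stopf("all models must carry an attention component")
  cfg <- models[[1]]$cfg
  J <- cfg$J; D <- J * (J - 1L)
  rescale01 <- function(x) {
    r <- range(x)
    if (diff(r) < 1e-12) rep(0.5, length(x)) else (x - r[1]) / diff(r)
  }
  gj <- gp <- NULL
  if (!is.null(models[[1]]$attention$raw_jp)) {
    gj <- rowMeans(vapply(models, function(m) sigmoid(m$attention$raw_jp),
                          numeric(J)))
    gj <- rescale01(gj)
  }
  if (!is.null(models[[1]]$attention$raw_rjdp)) {
    gp <- rowMeans(vapply(models,
                          function(m) sigmoid(m$attention$raw_rjdp),
                          numeric(D)))
    gp <- rescale01(gp)
  }
  jn <- if (J == 20L) default_skeleton()$joint_names
        else paste0("joint", seq_len(J))
  po <- pair_order(J)
  agg <- NULL
  if (!is.null(gp)) {
    agg <- vapply(seq_len(J), function(j)
      sum(gp[po$i == j | po$j == j]), numeric(1))
    names(agg) <- jn
  }
  if (!is.null(gj)) names(gj) <- jn
  structure(list(joint_importance = gj, pair_importance = gp,
                 pair_order = po, aggregated_joint_interaction = agg,
                 joint_names = jn, n_folds = length(models)),
            class = "attention_report")
}

#' Export an attention report
#'
#' Writes `joint_importance.csv` (one row per joint),
#' `pair_importance.csv` (one row per ordered pair) and a rendered
#' skeleton figure (`importance.pdf`) with marker area proportional to
#' joint importance and bones colored on a yellow-to-emerald scale by
#' aggregated joint interaction.
#'
#' @param report An `attention_report` from [extract_importance()].
#' @param out_dir Output directory (created if absent).
#' @param skeleton Skeleton used for the figure layout.
#' @return Character vector of written file paths, invisibly.
#' @export
export_importance <- function(report, out_dir,
                              skeleton = default_skeleton()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!is.null(report$joint_importance)) {
    f <- file.path(out_dir, "joint_importance.csv")
    utils::write.csv(data.frame(joint = report$joint_names,
                                importance = report$joint_importance,
                                row.names = NULL),
                     f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(report$pair_importance)) {
    f <- file.path(out_dir, "pair_importance.csv")
    po <- report$pair_order
    utils::write.csv(data.frame(
      joint_i = report$joint_names[po$i],
      joint_j = report$joint_names[po$j],
      importance = report$pair_importance, row.names = NULL),
      f, row.names = FALSE)
    files <- c(files, f)
  }
  fig <- file.path(out_dir, "importance.pdf")
  grDevices::pdf(fig, width = 5, height = 7)
  on.exit(grDevices::dev.off())
  pose <- base_pose(skeleton$joint_names)
  xy <- cbind(pose[, 3], pose[, 2])  # lateral vs height, frontal view
  graphics::plot(xy, type = "n", asp = 1, xlab = "lateral (m)",
                 ylab = "height (m)", main = "joint importance")
  pal <- grDevices::colorRampPalette(c("#f7e84b", "#1b9e77"))(100)
  agg <- report$aggregated_joint_interaction
  colv <- if (is.null(agg)) rep("grey50", skeleton$J) else {
    r <- range(agg)
    sc <- if (diff(r) < 1e-12) rep(50L, length(agg))
          else pmax(1L, round(99 * (agg - r[1]) / diff(r)) + 1L)
    pal[sc]
  }
  for (j in seq_len(skeleton$J)) {
    pj <- skeleton$parent_index[j]
    if (pj > 0)
      graphics::segments(xy[j, 1], xy[j, 2], xy[pj, 1], xy[pj, 2],
                         col = colv[j], lwd = 3)
  }
  sz <- report$joint_importance
  if (is.null(sz)) sz <- rep(0.5, skeleton$J)
  graphics::points(xy, pch = 16, cex = 0.6 + 2.4 * sz)
  files <- c(files, fig)
  invisible(files)
}
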