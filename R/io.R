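#' Write a motion sample to CSV
#'
#' Motion CSV dialect: header `frame,<joint>_x,<joint>_y,<joint>_z` for
#' every joint, one row per frame, 0-based frame indices, '.' decimal
#' separator, UTF-8.  Coordinates are written with 17 significant
#' digits, so finite doubles round-trip losslessly.
#'
#' @param sample A [motion_sample()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(sample, path) {
  if (!inherits(sample, "motion_sample")) stopf("not a motion_sample")
  pos <- sample$positions
  Tn <- dim(pos)[1]; J <- dim(pos)[2]
  cols <- as.vector(t(outer(sample$joint_names, c("x", "y", "z"),
                            paste, sep = "_")))
  mat <- matrix(aperm(pos, c(1, 3, 2)), nrow = Tn)  # frame x (J*3), xyz fastest
  df <- data.frame(frame = seq_len(Tn) - 1L,
                   formatC(mat, digits = 17, format = "g"),
                   check.names = FALSE)
  names(df) <- c("frame", cols)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a motion sample from CSV
#'
#' Columns may appear in any order; they are mapped to the skeleton's
#' joint order by header name.
#'
#' @param path CSV file following the dialect of [write_motion_csv()].
#' @param skeleton A [skeleton_def()]; defaults to [default_skeleton()].
#' @param frame_rate Capture rate to record on the sample (Hz).
#' @param label,sample_id Metadata for the resulting sample;
#'   `sample_id` defaults to the file name without extension.
#' @return A [motion_sample()].
#' @export
read_motion_csv <- function(path, skeleton = default_skeleton(),
                            frame_rate = 100, label = "unlabelled",
                            sample_id = NULL) {
  if (!file.exists(path)) stopf("motion file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"frame" %in% names(df)) stopf("%s: missing 'frame' column", path)
  need <- as.vector(t(outer(skeleton$joint_names, c("x", "y", "z"),
                            paste, sep = "_")))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("%s: missing joint column(s): %s", path,
          paste(utils::head(missing, 5), collapse = ", "))
  for (cn in c("frame", need)) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stopf("%s: non-numeric value in column '%s', row %d", path, cn,
            bad %||% 1L)
    }
    if (anyNA(v)) stopf("%s: missing value in column '%s', row %d", path,
                        cn, which(is.na(v))[1])
  }
  if (anyDuplicated(df$frame))
    stopf("%s: duplicate frame index %s", path,
          df$frame[duplicated(df$frame)][1])
  df <- df[order(df$frame), , drop = FALSE]
  Tn <- nrow(df); J <- skeleton$J
  mat <- as.matrix(df[, need, drop = FALSE])
  pos <- aperm(array(mat, c(Tn, 3, J)), c(1, 3, 2))
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  motion_sample(pos, frame_rate = frame_rate, label = label,
                sample_id = sample_id, joint_names = skeleton$joint_names)
}

#' Write a dataset manifest
#'
#' Manifest CSV dialect: header `sample_id,path,label`; fields are
#' quoted when they contain separators.
#'
#' @param manifest Data frame with columns `sample_id`, `path`, `label`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("sample_id", "path", "label")
  if (!all(need %in% names(manifest)))
    stopf("manifest needs columns: %s", paste(need, collapse = ", "))
  utils::write.csv(manifest[, need, drop = FALSE], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path Manifest CSV with header `sample_id,path,label`.
#' @return Data frame with columns `sample_id`, `path`, `label`; labels
#'   restricted to [gait_classes()] plus `"unlabelled"`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  need <- c("sample_id", "path", "label")
  missing <- setdiff(need, names(df))
  if (length(missing)) stopf("%s: missing column(s): %s", path,
                             paste(missing, collapse = ", "))
  valid <- c(gait_classes(), "unlabelled")
  bad <- setdiff(unique(df$label), valid)
  if (length(bad))
    stopf("%s: unknown label '%s'; valid labels: %s", path, bad[1],
          paste(valid, collapse = ", "))
  df[, need, drop = FALSE]
}

#' Load all samples referenced by a manifest
#'
#' Relative motion paths are resolved against the manifest's directory.
#'
#' @inheritParams read_manifest
#' @param skeleton A [skeleton_def()].
#' @param frame_rate Capture rate recorded on each sample (Hz).
#' @return List of [motion_sample()]s.
#' @export
load_manifest_samples <- function(path, skeleton = default_skeleton(),
                                  frame_rate = 100) {
  mf <- read_manifest(path)
  base <- dirname(path)
  lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$path[i]
    if (!file.exists(p)) p <- file.path(base, mf$path[i])
    read_motion_csv(p, skeleton, frame_rate = frame_rate,
                    label = mf$label[i], sample_id = mf$sample_id[i])
  })
}

#' Write a cohort as motion CSVs plus a manifest
#'
#' @param samples List of [motion_sample()]s.
#' @param out_dir Output directory (created if absent).
#' @return Path of the written manifest, invisibly.
#' @export
write_cohort <- function(samples, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    f <- paste0(s$sample_id, ".csv")
    write_motion_csv(s, file.path(out_dir, f))
    data.frame(sample_id = s$sample_id, path = f, label = s$label)
  })
  write_manifest(do.call(rbind, rows), file.path(out_dir, "manifest.csv"))
}

#' Read a TRC motion-capture file (best effort)
#'
#' Parses the tab-separated Track Row Column format exported by common
#' optical capture pipelines: marker names on the 4th header line,
#' X/Y/Z triplets from the 3rd data column on.  Units declared in the
#' header are honored (mm are converted to meters).  Markers are mapped
#' to skeleton joints by name; all skeleton joints must be present.
#'
#' @param path TRC file path.
#' @param skeleton A [skeleton_def()].
#' @param label,sample_id Metadata for the resulting sample.
#' @return A [motion_sample()].
#' @export
read_trc <- function(path, skeleton = default_skeleton(),
                     label = "unlabelled", sample_id = NULL) {
  if (!file.exists(path)) stopf("TRC file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stopf("%s: truncated TRC header", path)
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  meta <- stats::setNames(as.list(vals), keys)
  rate <- as.numeric(meta[["DataRate"]] %||% meta[["CameraRate"]] %||% 100)
  units <- tolower(meta[["Units"]] %||% "m")
  scale <- if (units %in% c("mm", "millimeters")) 1 / 1000 else 1
  hdr <- strsplit(lines[4], "\t")[[1]]
  markers <- hdr[-(1:2)]
  markers <- markers[nzchar(markers)]
  data_start <- 6L
  while (data_start <= length(lines) && !nzchar(trimws(lines[data_start])))
    data_start <- data_start + 1L
  rows <- strsplit(lines[data_start:length(lines)], "\t")
  rows <- rows[vapply(rows, function(r) any(nzchar(r)), logical(1))]
  num <- t(vapply(rows, function(r) {
    out <- suppressWarnings(as.numeric(r))
    length(out) <- 2 + 3 * length(markers)
    out
  }, numeric(2 + 3 * length(markers))))
  missing <- setdiff(skeleton$joint_names, markers)
  if (length(missing))
    stopf("%s: TRC lacks marker(s) for joint(s): %s", path,
          paste(missing, collapse = ", "))
  Tn <- nrow(num); J <- skeleton$J
  pos <- array(NA_real_, c(Tn, J, 3))
  for (j in seq_len(J)) {
    m <- match(skeleton$joint_names[j], markers)
    pos[, j, ] <- num[, (2 + 3 * (m - 1) + 1):(2 + 3 * m)] * scale
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  motion_sample(pos, frame_rate = rate, label = label,
                sample_id = sample_id, joint_names = skeleton$joint_names)
}
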