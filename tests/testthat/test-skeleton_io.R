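test_that("motion CSV round-trips losslessly and ignores column order", {
  p <- gait_sim_params()
  s <- simulate_walk(p, "healthy", 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_motion_csv(s, f)
  r <- read_motion_csv(f, frame_rate = s$frame_rate, label = s$label,
                       sample_id = s$sample_id)
  expect_equal(r$positions, s$positions, tolerance = 0)
  expect_identical(r$sample_id, s$sample_id)
  # shuffle columns: reader maps by header name
  df <- utils::read.csv(f, check.names = FALSE)
  df2 <- df[, c(1, sample(2:ncol(df)))]
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, f2, row.names = FALSE, quote = FALSE)
  r2 <- read_motion_csv(f2)
  expect_equal(r2$positions, s$positions, ignore_attr = TRUE)
})

test_that("motion CSV schema violations are reported precisely", {
  p <- gait_sim_params()
  s <- simulate_walk(p, "healthy", 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_motion_csv(s, f)
  df <- utils::read.csv(f, check.names = FALSE)
  # drop one joint's triplet -> error names the missing columns
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, !grepl("^l_knee_", names(df))], f3,
                   row.names = FALSE, quote = FALSE)
  expect_error(read_motion_csv(f3), "l_knee")
  # duplicate frame index
  df4 <- df; df4$frame[2] <- df4$frame[1]
  f4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df4, f4, row.names = FALSE, quote = FALSE)
  expect_error(read_motion_csv(f4), "duplicate frame")
  # non-numeric cell names row and column
  df5 <- df; df5$head_y <- as.character(df5$head_y); df5$head_y[3] <- "oops"
  f5 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df5, f5, row.names = FALSE, quote = FALSE)
  expect_error(read_motion_csv(f5), "head_y")
})

test_that("a minimal all-zero 2-frame file parses", {
  sk <- default_skeleton()
  z <- motion_sample(array(0, c(2, 20, 3)), 100)
  f <- withr::local_tempfile(fileext = ".csv")
  write_motion_csv(z, f)
  r <- read_motion_csv(f)
  expect_equal(dim(r$positions), c(2, 20, 3))
  expect_true(all(r$positions == 0))
})

test_that("motion samples with fewer than 2 frames are rejected", {
  expect_error(motion_sample(array(0, c(1, 20, 3)), 100), "2 frames")
})

test_that("manifest round-trips, quotes commas and validates labels", {
  mf <- data.frame(sample_id = c("a,with,commas", "b"),
                   path = c("a.csv", "b.csv"),
                   label = c("healthy", "joint_problem"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(mf, f)
  r <- read_manifest(f)
  expect_equal(r$sample_id, mf$sample_id)
  # header-only file
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,path,label", f2)
  expect_equal(nrow(read_manifest(f2)), 0)
  # unknown label
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,path,label", "x,x.csv,Parkinsons"), f3)
  expect_error(read_manifest(f3), "Parkinsons")
})

test_that("a cohort written to disk reloads with the benchmark layout", {
  p <- gait_sim_params(n_frames_raw = 12L)
  counts <- c(healthy = 10, joint_problem = 4, muscle_weakness = 18,
              neurological_defect = 13)
  co <- generate_cohort(p, counts, seed = 2)
  d <- withr::local_tempdir()
  mfp <- write_cohort(co, d)
  mf <- read_manifest(mfp)
  expect_equal(nrow(mf), 45)
  expect_equal(unname(table(factor(mf$label, gait_classes()))),
               unname(counts[gait_classes()]), ignore_attr = TRUE)
  back <- load_manifest_samples(mfp)
  expect_equal(back[[1]]$positions, co[[1]]$positions, ignore_attr = TRUE)
})

test_that("TRC reader honors header units and marker names", {
  sk <- default_skeleton()
  Tn <- 4
  set.seed(9)
  pos <- array(round(rnorm(Tn * 20 * 3), 4), c(Tn, 20, 3))
  hdr <- c("PathFileType\t4\t(X/Y/Z)\ttest.trc",
           paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units"), collapse = "\t"),
           paste(c("100", "100", Tn, "20", "mm"), collapse = "\t"),
           paste(c("Frame#", "Time",
                   as.vector(rbind(sk$joint_names, "", ""))),
                 collapse = "\t"),
           paste(c("", "", as.vector(t(outer(c("X", "Y", "Z"), 1:20,
                                             paste0)))), collapse = "\t"))
  rows <- vapply(seq_len(Tn), function(t)
    paste(c(t, (t - 1) / 100, as.vector(t(pos[t, , ]))), collapse = "\t"),
    character(1))
  f <- withr::local_tempfile(fileext = ".trc")
  writeLines(c(hdr, "", rows), f)
  r <- read_trc(f)
  expect_equal(r$frame_rate, 100)
  expect_equal(r$positions, pos / 1000, ignore_attr = TRUE)
  # missing marker is named
  bad <- sub("r_foot", "misnamed", hdr[4])
  writeLines(c(hdr[1:3], bad, hdr[5], "", rows), f)
  expect_error(read_trc(f), "r_foot")
})
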