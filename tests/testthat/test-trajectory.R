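test_that("CSV round trip preserves a synthetic trajectory exactly", {
  d <- generate_dyad(dyad_sim_params(n_frames = 120, dropout_p = 0.1, seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(d$parent, path)
  back <- load_trajectory(path, fps = 25)
  expect_equal(back$frame, d$parent$frame)
  expect_equal(back$valid, d$parent$valid)
  expect_equal(back$x, d$parent$x)
  expect_equal(back$y, d$parent$y)
  expect_equal(back$w, d$parent$w)
  expect_equal(back$h, d$parent$h)
})

test_that("malformed and degenerate trajectory files are rejected", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("frame,x,y,w,h,valid", empty)
  expect_error(load_trajectory(empty, 25), "empty")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y,w,h,valid", "0,1,1,5,5,1", "1,oops,1,5,5,1"), bad)
  expect_error(load_trajectory(bad, 25), "row 2")

  dup <- data.frame(frame = c(0, 1, 1), x = 1, y = 1, w = 5, h = 5,
                    valid = TRUE)
  expect_error(box_trajectory(dup, 25), "duplicate frame")

  short <- data.frame(frame = 0, x = 1, y = 1, w = 5, h = 5, valid = TRUE)
  expect_error(box_trajectory(short, 25), "at least 2")
})

test_that("frames missing from the file are inserted as invalid placeholders", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y,w,h,valid",
               "0,0,0,5,5,1", "1,1,0,5,5,1", "4,4,0,5,5,1"), p)
  traj <- load_trajectory(p, 25)
  expect_equal(nrow(traj), 5)
  expect_equal(traj$frame, 0:4)
  expect_equal(traj$valid, c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("tracking accuracy is the valid-frame percentage before repair", {
  all_ok <- traj_from_centers(1:10, rep(0, 10))
  expect_equal(tracking_accuracy(all_ok), 100)

  v <- rep(TRUE, 100); v[seq(5, 95, by = 10)] <- FALSE  # 10 invalid frames
  traj <- traj_from_centers(seq_len(100), rep(0, 100), valid = v)
  expect_equal(tracking_accuracy(traj), 90)

  # direct-count oracle on simulated dropout
  d <- generate_dyad(dyad_sim_params(n_frames = 1000, dropout_p = 0.2,
                                     seed = 11))
  expect_equal(tracking_accuracy(d$infant),
               100 * sum(d$infant$valid) / 1000)
})

test_that("linear interpolation fills interior gaps on the connecting segment", {
  # centers (0,0) at frame 0 and (6,0) at frame 3, frames 1-2 lost
  traj <- traj_from_centers(c(0, NA, NA, 6), c(0, NA, NA, 0),
                            valid = c(TRUE, FALSE, FALSE, TRUE))
  rep <- interpolate_gaps(traj)
  cx <- rep$x + rep$w / 2
  expect_equal(cx, c(0, 2, 4, 6))
  expect_equal(rep$y + rep$h / 2, rep(0, 4))
  expect_true(all(rep$valid))
  expect_equal(attr(rep, "n_interpolated"), 2)

  # identity on a fully valid trajectory
  ok <- traj_from_centers(1:5, 5:1)
  rep2 <- interpolate_gaps(ok)
  expect_equal(as.data.frame(rep2), as.data.frame(ok), ignore_attr = TRUE)
  expect_equal(attr(rep2, "n_interpolated"), 0)
})

test_that("interpolated centers are collinear with their bracketing frames and the repair is idempotent", {
  set.seed(21)
  for (rep_i in 1:5) {
    n <- 60
    valid <- runif(n) > 0.3
    valid[1] <- valid[n] <- TRUE
    cx <- cumsum(rnorm(n)); cy <- cumsum(rnorm(n))
    cx[!valid] <- NA; cy[!valid] <- NA
    traj <- traj_from_centers(cx, cy, valid = valid)
    fixed <- interpolate_gaps(traj)
    fcx <- fixed$x + fixed$w / 2; fcy <- fixed$y + fixed$h / 2
    known <- which(valid)
    for (i in which(!valid)) {
      lo <- max(known[known < i]); hi <- min(known[known > i])
      f <- (i - lo) / (hi - lo)
      expect_equal(fcx[i], cx[lo] + f * (cx[hi] - cx[lo]))
      expect_equal(fcy[i], cy[lo] + f * (cy[hi] - cy[lo]))
    }
    expect_equal(as.data.frame(interpolate_gaps(fixed)),
                 as.data.frame(fixed), ignore_attr = TRUE)
  }
})

test_that("boundary gaps extrapolate from the nearest valid frame with a warning", {
  traj <- traj_from_centers(c(NA, 4, 8, NA), c(NA, 1, 1, NA),
                            valid = c(FALSE, TRUE, TRUE, FALSE))
  expect_warning(rep <- interpolate_gaps(traj), "boundary")
  cx <- rep$x + rep$w / 2
  expect_equal(cx, c(4, 4, 8, 8))

  none <- traj_from_centers(c(NA, NA), c(NA, NA), valid = c(FALSE, FALSE))
  expect_error(interpolate_gaps(none), "no valid frames")
})

test_that("trim_pair cuts only the tail of the longer series", {
  a <- rand_series(1027, seed = 1)
  b <- rand_series(375, seed = 2)
  tr <- trim_pair(a, b)
  expect_equal(length(tr$a), 375)
  expect_equal(length(tr$b), 375)
  expect_equal(tr$a$codes, a$codes[1:375])

  same <- trim_pair(a, a)
  expect_equal(same$a$codes, a$codes)

  # prefix oracle
  x <- rand_series(10, seed = 3)
  y <- x; y$codes <- x$codes[1:7]
  expect_equal(trim_pair(x, y)$a$codes, y$codes)

  # property: output lengths equal min of inputs
  set.seed(4)
  for (i in 1:10) {
    la <- sample(50:200, 1); lb <- sample(50:200, 1)
    tr <- trim_pair(rand_series(la), rand_series(lb))
    expect_equal(length(tr$a), min(la, lb))
    expect_equal(length(tr$b), min(la, lb))
  }

  bad <- rand_series(10); bad$fps <- 30
  expect_error(trim_pair(a, bad), "fps")
})

test_that("repair_trajectory_file writes the repaired CSV and QC sidecar", {
  d <- generate_dyad(dyad_sim_params(n_frames = 100, dropout_p = 0.15,
                                     seed = 5))
  dir <- withr::local_tempdir()
  inp <- file.path(dir, "raw.csv"); outp <- file.path(dir, "fixed.csv")
  write_trajectory(d$parent, inp)
  suppressWarnings(repair_trajectory_file(inp, outp, fps = 25))
  fixed <- load_trajectory(outp, 25)
  expect_true(all(fixed$valid))
  qc <- jsonlite::read_json(paste0(outp, ".json"))
  expect_equal(qc$n_frames, 100)
  expect_equal(qc$accuracy_percent, tracking_accuracy(d$parent))
  expect_equal(qc$n_interpolated, sum(!d$parent$valid))
})
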