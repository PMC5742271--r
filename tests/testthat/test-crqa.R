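test_that("the cross-recurrence matrix marks every code match", {
  p <- categorical_series(c(1, 1, 2), 25, "simple")
  i <- categorical_series(c(1, 2, 2), 25, "simple")
  m <- cross_recurrence_matrix(p, i)
  expect_equal(unclass(m)[, ],
               matrix(c(1, 1, 0,
                        0, 0, 1,
                        0, 0, 1), nrow = 3, byrow = TRUE),
               ignore_attr = TRUE)

  # identical series: all-1 main diagonal
  s <- rand_series(40, seed = 1)
  ms <- cross_recurrence_matrix(s, s)
  expect_true(all(diag(ms) == 1L))

  # disjoint code sets: all-zero matrix
  a <- categorical_series(rep(1, 10), 25, "simple")
  b <- categorical_series(rep(2, 10), 25, "simple")
  expect_true(all(cross_recurrence_matrix(a, b) == 0L))

  # mismatches are rejected
  expect_error(cross_recurrence_matrix(rand_series(10), rand_series(12)),
               "trim_pair")
  expect_error(cross_recurrence_matrix(rand_series(10, "simple"),
                                       rand_series(10, "detailed")),
               "systems differ")
})

test_that("a saturated pair recurs fully at every lag", {
  a <- categorical_series(rep(1, 60), 25, "simple")
  p <- lag_profile(a, a, max_lag_s = 1)
  expect_equal(p$rr, rep(100, 51))
  expect_equal(p$n_overlap, 60 - abs(p$lag_frames))
})

test_that("a one-frame parent lead peaks at lag -1 and only there", {
  # infant echoes the parent one frame later
  set.seed(2)
  pc <- sample(0:2, 60, replace = TRUE)
  ic <- c(0L, pc[-60])
  p <- categorical_series(pc, 25, "simple")
  i <- categorical_series(ic, 25, "simple")
  prof <- lag_profile(p, i, max_lag_s = 2 / 25)  # L = 2
  expect_equal(nrow(prof), 5)
  expect_equal(prof$rr[prof$lag_frames == -1], 100)
  expect_true(all(prof$rr[prof$lag_frames != -1] < 100))
  # brute-force check of all five lags
  expect_equal(prof$rr, brute_lag_profile(pc, ic, 2))
})

test_that("the default lag window at 25 fps spans 201 bins over +-4 s", {
  a <- rand_series(375, seed = 3)
  b <- rand_series(375, seed = 4)
  p <- lag_profile(a, b, max_lag_s = 4)
  expect_equal(nrow(p), 201)
  expect_equal(range(p$lag_frames), c(-100, 100))
  expect_equal(range(p$lag_ms), c(-4000, 4000))
  # series shorter than the window are rejected
  expect_error(lag_profile(rand_series(80, seed = 5),
                           rand_series(80, seed = 6), 4), "exceed")
})

test_that("the shifted-comparison profile equals the matrix-diagonal computation", {
  set.seed(7)
  for (trial in 1:6) {
    n <- sample(40:120, 1)
    sysname <- sample(c("simple", "detailed"), 1)
    L <- sample(3:10, 1)
    a <- rand_series(n, sysname)
    b <- rand_series(n, sysname)
    prod <- lag_profile(a, b, max_lag_s = L / 25)
    expect_equal(prod$rr, brute_lag_profile(a$codes, b$codes, L))
  }
})

test_that("swapping the two series mirrors the lag profile", {
  a <- rand_series(150, "detailed", seed = 8)
  b <- rand_series(150, "detailed", seed = 9)
  ab <- lag_profile(a, b, 1)
  ba <- lag_profile(b, a, 1)
  expect_equal(ab$rr, rev(ba$rr))
})

test_that("subsampling keeps every fourth lag, endpoints included", {
  a <- rand_series(375, seed = 10); b <- rand_series(375, seed = 11)
  p <- lag_profile(a, b, 4)
  s <- subsample_profile(p, 6.25)
  expect_equal(nrow(s), 51)
  expect_equal(s$lag_frames, seq(-100, 100, by = 4))
  expect_true(0L %in% s$lag_frames)
  # identity at the native rate
  expect_equal(as.data.frame(subsample_profile(p, 25)), as.data.frame(p))
  expect_error(subsample_profile(p, 6), "integer multiple")
  # subsampled rr values are drawn from the original, not recomputed
  expect_equal(s$rr, p$rr[p$lag_frames %% 4 == 0])
})

test_that("peak_lag converts frames to ms and names the leader", {
  mk <- function(rr, lags = -10:10) {
    structure(data.frame(lag_frames = lags, lag_ms = 1000 * lags / 25,
                         rr = rr, n_overlap = 100 - abs(lags)),
              fps = 25, class = c("lag_profile", "data.frame"))
  }
  rr <- rep(10, 21); rr[-6 + 11] <- 50  # unique max at -6 frames
  pk <- peak_lag(mk(rr))
  expect_equal(pk$lag_ms, -240)
  expect_equal(pk$leader, "parent-leading")

  rr0 <- 21 - abs(-10:10)  # symmetric, unique max at 0
  pk0 <- peak_lag(mk(rr0))
  expect_equal(pk0$lag_ms, 0)
  expect_equal(pk0$leader, "synchronous")

  rrp <- rep(5, 21); rrp[3 + 11] <- 50
  expect_equal(peak_lag(mk(rrp))$leader, "infant-leading")

  # scan oracle on random profiles with a unique max
  set.seed(12)
  for (k in 1:10) {
    rr <- runif(21, 0, 99); w <- sample(21, 1); rr[w] <- 100
    expect_equal(peak_lag(mk(rr))$lag_frames, (-10:10)[w])
  }

  # ties resolve toward zero, then the negative side, with a warning
  rrt <- rep(1, 21); rrt[c(-4, 4) + 11] <- 9
  expect_warning(pkt <- peak_lag(mk(rrt)), "tie")
  expect_equal(pkt$lag_frames, -4)
  flat <- mk(rep(7, 21))
  expect_warning(pkf <- peak_lag(flat), "tie")
  expect_equal(pkf$lag_frames, 0)
})

test_that("profile averaging is the per-lag mean and SD across dyads", {
  a <- rand_series(200, seed = 13); b <- rand_series(200, seed = 14)
  p1 <- lag_profile(a, b, 1)
  one <- average_profiles(list(p1))
  expect_equal(one$rr, p1$rr)
  expect_equal(one$rr_sd, rep(0, nrow(p1)))

  p2 <- p1; p2$rr <- rep(60, nrow(p1))
  p3 <- p1; p3$rr <- rep(40, nrow(p1))
  avg <- average_profiles(list(p2, p3))
  expect_equal(avg$rr, rep(50, nrow(p1)))

  # summation oracle over 21 random profiles
  set.seed(15)
  profs <- lapply(1:21, function(k) {
    q <- p1; q$rr <- runif(nrow(p1), 0, 100); q
  })
  got <- average_profiles(profs)
  manual <- Reduce(`+`, lapply(profs, `[[`, "rr")) / 21
  expect_equal(got$rr, manual)

  bad <- lag_profile(rand_series(200, seed = 16), rand_series(200, seed = 17),
                     0.4)
  expect_error(average_profiles(list(p1, bad)), "mismatched")
})
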