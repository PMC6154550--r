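test_that("com_distance weights centroids by mass", {
  expect_equal(com_distance(c(0, 0, 0), 1, c(3, 4, 0), 1), 5)
  expect_equal(com_distance(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1),
                            c(1, 0, 0), 1), 0)
  expect_equal(com_distance(rbind(c(0, 0, 0), c(4, 0, 0)), c(1, 3),
                            c(0, 0, 0), 1), 3)
  expect_error(com_distance(matrix(numeric(0), ncol = 3), numeric(0),
                            c(0, 0, 0), 1), "empty")
  expect_error(com_distance(c(0, 0, 0), -1, c(1, 1, 1), 1), "positive")
  expect_error(com_distance(c(0, 0, 0), c(1, 2), c(1, 1, 1), 1), "match")
})

test_that("window_slope matches the closed-form least-squares slope", {
  expect_equal(window_slope(0:3, c(4, 3, 2, 1)), -1)
  expect_equal(window_slope(0:9, rep(2.5, 10)), 0)

  set.seed(21)
  for (i in 1:50) {
    t <- sort(runif(50, 0, 600)); t <- t + seq_along(t) * 1e-6
    d <- 20 - 0.01 * t + rnorm(50)
    ols <- sum((t - mean(t)) * (d - mean(d))) / sum((t - mean(t))^2)
    expect_equal(window_slope(t, d), ols, tolerance = 1e-10)
    ## literal f(x) = m x reading on shifted times
    t0 <- t - t[1]
    expect_equal(window_slope(t, d, fit_mode = "through_origin"),
                 sum(t0 * d) / sum(t0^2), tolerance = 1e-10)
  }
  expect_error(window_slope(1, 2), "at least 2")
  expect_error(window_slope(c(1, 1), c(2, 3)), "increasing")
})

test_that("supervise_window applies the tabu-like decision rule", {
  cfg <- supervision_config(window_duration = 3, arrival_threshold = 5)
  ## decreasing trend, still outside the site: accept
  expect_equal(supervise_window(make_segment(0:3, c(12, 11, 10, 9)),
                                cfg)$decision, "accept")
  ## increasing trend: reject
  expect_equal(supervise_window(make_segment(0:3, c(9, 10, 11, 12)),
                                cfg)$decision, "reject")
  ## slope exactly zero: "negative" read strictly, so reject
  expect_equal(supervise_window(make_segment(0:3, rep(8, 4)),
                                cfg)$decision, "reject")
  ## first-passage arrival beats the slope, even on an uphill window
  rec <- supervise_window(make_segment(0:3, c(4.9, 6, 7, 8)), cfg)
  expect_equal(rec$decision, "arrival")
  expect_equal(rec$min_distance, 4.9)
})

test_that("supervised runs are deterministic and time-continuous", {
  sys <- build_scenario("binder", dims = 2)
  sup <- supervision_config(window_duration = 6, max_windows = 60,
                            post_arrival_duration = 6, seed = 17)
  a <- run_sumd(sys, dyn = dynamics_config(), sup = sup)
  b <- run_sumd(sys, dyn = dynamics_config(), sup = sup)
  expect_identical(a$log, b$log)
  expect_identical(sumd_frames(a), sumd_frames(b))

  ## accepted segments concatenate without gaps or overlaps
  fr <- sumd_frames(a)
  expect_true(all(diff(fr$time) > 0))
  ends <- vapply(a$segments, function(s) s$times[length(s$times)], numeric(1))
  starts <- vapply(a$segments, function(s) s$times[1], numeric(1))
  if (length(starts) > 1)
    expect_equal(starts[-1], ends[-length(ends)], tolerance = 1e-12)

  ## rejected windows leave a log entry but no frames
  n_acc <- sum(a$log$decision %in% c("accept", "arrival"))
  expect_equal(length(a$segments), n_acc)
  expect_equal(a$total_windows_attempted, nrow(a$log))
})

test_that("rejection restores coordinates exactly and resamples velocities", {
  sys <- build_scenario("pam", dims = 2)   # plenty of rejections
  sup <- supervision_config(window_duration = 6, max_windows = 30,
                            post_arrival_duration = 0, seed = 4)
  run <- run_sumd(sys, dyn = dynamics_config(), sup = sup,
                  keep_rejected = TRUE)
  rej <- which(run$log$decision == "reject")
  rej <- rej[rej < nrow(run$log)]
  expect_gt(length(rej), 0)
  all_windows <- function(i) {
    ## window i as simulated, whether kept or rejected
    key <- as.character(i)
    if (!is.null(run$rejected_segments[[key]])) return(run$rejected_segments[[key]])
    acc <- which(run$log$decision %in% c("accept", "arrival"))
    run$segments[[match(i, acc)]]
  }
  for (i in rej) {
    w <- all_windows(i); nxt <- all_windows(i + 1)
    expect_identical(nxt$positions[1, ], w$positions[1, ])
    expect_false(isTRUE(all.equal(nxt$velocities[1, ], w$velocities[1, ])))
  }
})

test_that("supervision does not alter within-window dynamics", {
  ## the first supervised window must be the plain Langevin segment the
  ## integrator produces from the same state and RNG stream
  sys <- build_scenario("binder", dims = 2)
  st <- state(c(0, 20))
  sup <- supervision_config(window_duration = 6, max_windows = 1,
                            post_arrival_duration = 0, seed = 31)
  run <- run_sumd(sys, start = st, dyn = dynamics_config(), sup = sup,
                  keep_rejected = TRUE)
  set.seed(31)
  ref <- run_segment(sys, st, 6, dynamics_config())
  w1 <- if (length(run$segments)) run$segments[[1]] else
    run$rejected_segments[["1"]]
  expect_equal(w1$positions, ref$positions, tolerance = 1e-12)
})

test_that("arrival switches off supervision permanently", {
  sys <- build_scenario("binder", dims = 2)
  found <- FALSE
  for (sd in 1:10) {
    sup <- supervision_config(window_duration = 6, max_windows = 80,
                              post_arrival_duration = 12, seed = sd)
    run <- run_sumd(sys, dyn = dynamics_config(), sup = sup)
    if (run$productive && !is.null(run$log)) {
      found <- TRUE
      i_arr <- which(run$log$decision == "arrival")
      expect_length(i_arr, 1)
      expect_equal(i_arr, nrow(run$log))      # nothing logged afterwards
      expect_s3_class(run$classical_tail, "trajectory_segment")
      ## the tail continues the accepted trajectory in time
      last <- run$segments[[length(run$segments)]]
      expect_equal(run$classical_tail$times[1],
                   last$times[length(last$times)])
      break
    }
  }
  expect_true(found)
})

test_that("a start already inside the site goes straight to classical MD", {
  sys <- build_scenario("binder", dims = 2)
  sup <- supervision_config(window_duration = 6, max_windows = 10,
                            post_arrival_duration = 6, seed = 2)
  run <- run_sumd(sys, start = state(c(2, 0)), dyn = dynamics_config(),
                  sup = sup)
  expect_true(run$productive)
  expect_equal(run$total_windows_attempted, 0L)
  expect_null(run$log)
  expect_s3_class(run$classical_tail, "trajectory_segment")
  expect_equal(arrival_time(run), 0)
})

test_that("unbiased runs report first-passage arrival", {
  ## flat potential, zero temperature, zero velocity: never arrives
  sys <- flat_system(dims = 2)
  seg <- run_unbiased(sys, start = state(c(15, 0)), duration = 5,
                      dyn = dynamics_config(temperature = 0, friction = 0))
  expect_true(is.na(attr(seg, "arrival_time")))
  expect_error(run_unbiased(sys, start = state(c(15, 0)), duration = 0,
                            dyn = dynamics_config()), "time step")

  ## deep-well scenario at high temperature: reproducible arrival fraction
  deep <- build_scenario("diffusive", dims = 2,
                         overrides = list(orthosteric_depth = 6))
  arr <- function(offset) {
    hits <- vapply(1:20, function(i) {
      s <- run_unbiased(deep, duration = 150,
                        dyn = dynamics_config(temperature = 400,
                                              seed = offset + i))
      !is.na(attr(s, "arrival_time"))
    }, logical(1))
    mean(hits)
  }
  f1 <- arr(500); f2 <- arr(500)
  expect_gt(f1, 0)
  expect_identical(f1, f2)
})
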