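kB <- sumd_constants()$kB

test_that("bias potential sums hills term by term", {
  b0 <- empty_bias()
  expect_equal(bias_potential(b0, 1.5), 0)

  one <- bias_state(data.frame(time = 0.5, center.1 = 2, sigma.1 = 0.3,
                               height = 0.25), cv_coordinate(1),
                    sigmas = 0.3)
  expect_equal(bias_potential(one, 2), 0.25)

  ## 20 random hills vs an independent term-by-term summation
  set.seed(13)
  h <- data.frame(time = 1:20, center.1 = runif(20, -3, 3),
                  sigma.1 = 0.4, height = runif(20, 0.05, 0.3))
  b <- bias_state(h, cv_coordinate(1), sigmas = 0.4)
  for (p in runif(5, -3, 3)) {
    manual <- 0
    for (j in 1:20)
      manual <- manual + h$height[j] *
        exp(-(p - h$center.1[j])^2 / (2 * 0.4^2))
    expect_equal(bias_potential(b, p), manual, tolerance = 1e-12)
  }
  expect_error(bias_potential(b, c(1, 2)), "components")
})

test_that("angle-like CVs wrap hill distances periodically", {
  b <- bias_state(data.frame(time = 0, center.1 = pi - 0.1, sigma.1 = 0.3,
                             height = 0.3),
                  cv_angle(c(1, 2)), sigmas = 0.3)
  ## probe just across the branch cut: wrapped distance is 0.2
  expect_equal(bias_potential(b, -pi + 0.1),
               0.3 * exp(-0.2^2 / (2 * 0.09)), tolerance = 1e-12)
})

test_that("well-tempered hill heights damp with accumulated bias", {
  b0 <- empty_bias(temperature = 298, bias_factor = 6)
  expect_equal(next_hill_height(b0, 0), 0.3)

  ## V = kB (gamma-1) T at the probe: height drops to w0/e
  vtarget <- kB * 5 * 298
  hh <- data.frame(time = 0, center.1 = 0, sigma.1 = 0.5, height = vtarget)
  b1 <- bias_state(hh, cv_coordinate(1), sigmas = 0.5,
                   bias_factor = 6, temperature = 298)
  expect_equal(next_hill_height(b1, 0), 0.3 / exp(1), tolerance = 1e-12)

  ## enormous bias factor recovers standard (undamped) metadynamics
  bb <- bias_state(hh, cv_coordinate(1), sigmas = 0.5,
                   bias_factor = 1e9, temperature = 298)
  expect_equal(next_hill_height(bb, 0), 0.3, tolerance = 1e-6)
})

test_that("metadynamics deposits exactly floor(duration/stride) hills", {
  sys <- salt_bridge_system()
  cfg_short <- metad_config(cv_coordinate(1), duration = 0.3, stride = 0.5)
  r0 <- run_metadynamics(sys, state(4.5),
                         dynamics_config(temperature = 298, seed = 1),
                         cfg_short)
  expect_equal(nrow(r0$bias$hills), 0)

  cfg <- metad_config(cv_coordinate(1), duration = 20.4, stride = 0.5)
  r <- run_metadynamics(sys, state(4.5),
                        dynamics_config(temperature = 298, seed = 1), cfg)
  expect_equal(nrow(r$bias$hills), floor(20.4 / 0.5))

  ## identical hill sequence under a fixed seed
  r2 <- run_metadynamics(sys, state(4.5),
                         dynamics_config(temperature = 298, seed = 1), cfg)
  expect_identical(r$bias$hills, r2$bias$hills)
})

test_that("hill heights are non-increasing where the CV keeps revisiting", {
  ## single narrow well confines the CV, so deposits stack and damp
  sys <- toy_system(dims = 1,
                    wells = list(gaussian_well(0, depth = 8, width = 0.3)),
                    orthosteric_center = 0, ligand_mass = 50,
                    box_halflength = 3, wall_k = 20)
  cfg <- metad_config(cv_coordinate(1), duration = 300, sigmas = 0.1)
  r <- run_metadynamics(sys, state(0),
                        dynamics_config(temperature = 298, seed = 3), cfg)
  h <- r$bias$hills$height
  expect_true(all(h <= 0.3 + 1e-12))
  ## the bias only accumulates, so successive hills dropped at (nearly)
  ## the same CV position must shrink
  near0 <- h[abs(r$bias$hills$center.1) < 0.02]
  expect_gt(length(near0), 5)
  expect_true(all(diff(near0) < 0.005))
  expect_lt(near0[length(near0)], 0.5 * near0[1])
  ## and the trend shows in the run as a whole
  half <- length(h) %/% 2
  expect_lt(mean(h[(half + 1):length(h)]), mean(h[1:half]))
})

test_that("the free-energy estimator inverts and rescales the bias", {
  ## single hill: F is a scaled inverted Gaussian, prefactor gamma/(gamma-1)
  one <- bias_state(data.frame(time = 0, center.1 = 1, sigma.1 = 0.5,
                               height = 0.3),
                    cv_coordinate(1), sigmas = 0.5, bias_factor = 6)
  fes <- estimate_fes(one, grid = seq(-1, 3, by = 0.01), shift = FALSE)
  expect_equal(fes$free_energy,
               -1.2 * 0.3 * exp(-(fes$cv - 1)^2 / (2 * 0.25)),
               tolerance = 1e-12)
  expect_equal(min(estimate_fes(one)$free_energy), 0)  # shifted

  ## all-zero hill heights give a flat surface
  flat <- bias_state(data.frame(time = c(0, 1), center.1 = c(0, 1),
                                sigma.1 = 0.5, height = c(0, 0)),
                     cv_coordinate(1), sigmas = 0.5)
  expect_equal(unique(estimate_fes(flat, grid = seq(0, 1, 0.1))$free_energy),
               0)
  expect_error(estimate_fes(empty_bias()), "no hills")

  ## linearity in the accumulated bias before the min-shift
  set.seed(31)
  mk <- function(n, off) data.frame(time = seq_len(n),
                                    center.1 = runif(n, -2, 2) + off,
                                    sigma.1 = 0.4,
                                    height = runif(n, 0.1, 0.3))
  ha <- mk(8, 0); hb <- mk(6, 0.5)
  g <- seq(-3, 3, by = 0.05)
  fa <- estimate_fes(bias_state(ha, cv_coordinate(1), sigmas = 0.4),
                     grid = g, shift = FALSE)$free_energy
  fb <- estimate_fes(bias_state(hb, cv_coordinate(1), sigmas = 0.4),
                     grid = g, shift = FALSE)$free_energy
  hab <- rbind(ha, hb); hab <- hab[order(hab$time), ]
  fab <- estimate_fes(bias_state(hab, cv_coordinate(1), sigmas = 0.4),
                      grid = g, shift = FALSE)$free_energy
  expect_equal(fab, fa + fb, tolerance = 1e-10)
})

test_that("biased dynamics crosses barriers that unbiased dynamics cannot", {
  sys <- salt_bridge_system(depth = 8)
  nb <- nu <- integer(20)
  for (i in 1:20) {
    m <- run_metadynamics(sys, state(4.5),
                          dynamics_config(temperature = 298, seed = 700 + i),
                          metad_config(cv_coordinate(1), duration = 2000))
    nb[i] <- count_crossings(m$cv_series[, 1])
    u <- run_segment(sys, state(4.5), 2000,
                     dynamics_config(temperature = 298, seed = 700 + i))
    nu[i] <- count_crossings(u$positions[, 1])
  }
  expect_true(all(nb >= 5))
  expect_true(all(nu == 0))
})

test_that("closed-state fraction counts sub-threshold frames", {
  expect_equal(closed_state_fraction(c(3, 4, 4.5), 5)$fraction, 1)
  expect_equal(closed_state_fraction(c(6, 7, 9), 5)$fraction, 0)
  s <- c(runif(50, 3, 4.9), runif(50, 5.1, 9))
  expect_equal(closed_state_fraction(s, 5)$fraction, 0.5)
  expect_error(closed_state_fraction(numeric(0), 5), "empty")

  ## with a bias state the basin free-energy difference is reported
  h <- data.frame(time = 1:2, center.1 = c(4.5, 9), sigma.1 = 0.5,
                  height = c(0.3, 0.2))
  b <- bias_state(h, cv_coordinate(1), sigmas = 0.5)
  out <- closed_state_fraction(c(4, 5, 6), 6.75, bias = b)
  expect_true(is.finite(out$delta_f_open_closed))
})

test_that("hills round-trip through the PLUMED-style HILLS layout", {
  set.seed(41)
  h <- data.frame(time = seq(0.5, 5, by = 0.5),
                  center.1 = runif(10, 2, 10), sigma.1 = 0.04,
                  height = runif(10, 0.1, 0.3))
  b <- bias_state(h, cv_coordinate(1), sigmas = 0.04, bias_factor = 6)
  f <- withr::local_tempfile(fileext = ".hills")
  write_hills(b, f)
  expect_true(startsWith(readLines(f, n = 1), "#! FIELDS"))
  back <- read_hills(f, cv_coordinate(1))
  expect_equal(back$hills$center.1, h$center.1, tolerance = 1e-8)
  expect_equal(back$hills$height, h$height, tolerance = 1e-8)
  expect_equal(back$bias_factor, 6)
  g <- seq(2, 10, by = 0.5)
  expect_equal(bias_potential(back, matrix(g, ncol = 1)),
               bias_potential(b, matrix(g, ncol = 1)), tolerance = 1e-7)
})
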