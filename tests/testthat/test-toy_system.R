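test_that("potential energy sums closed-form Gaussian terms", {
  ## single well evaluated at its center gives -depth
  sys <- toy_system(dims = 3,
                    wells = list(gaussian_well(c(1, 2, 3), 10, 2)),
                    orthosteric_center = c(1, 2, 3), ligand_mass = 100)
  expect_equal(potential_energy(sys, c(1, 2, 3)), -10)

  ## flat system inside the box is exactly zero
  expect_equal(potential_energy(flat_system(), c(3, -4, 7)), 0)

  ## two wells + barrier at a probe point: term-by-term hand evaluation
  sys2 <- toy_system(
    dims = 3,
    wells = list(gaussian_well(c(0, 0, 0), 6, 3),
                 gaussian_well(c(0, 0, 0), 2, 1.5, radius = 10)),
    barriers = list(gaussian_barrier(c(5, 0, 0), 1.2, 2)),
    orthosteric_center = c(0, 0, 0), ligand_mass = 100)
  p <- c(3, 4, 0)            # |p| = 5
  expected <- -6 * exp(-25 / (2 * 9)) -
    2 * exp(-(5 - 10)^2 / (2 * 1.5^2)) +
    1.2 * exp(-sum((p - c(5, 0, 0))^2) / (2 * 4))
  expect_equal(potential_energy(sys2, p), expected, tolerance = 1e-12)

  ## confinement wall outside the box
  sysf <- flat_system(L = 10)
  expect_equal(potential_energy(sysf, c(12, 0, 0)), 10 * 2^2)
  ## interaction energy excludes the wall
  expect_equal(potential_energy(sysf, c(12, 0, 0),
                                include_confinement = FALSE), 0)
})

test_that("force is the analytic negative gradient", {
  sys <- build_scenario("pam")
  ## stationary at the center of the (isolated, point) orthosteric well
  iso <- toy_system(dims = 3, wells = list(gaussian_well(c(2, -1, 0), 5, 2)),
                    orthosteric_center = c(2, -1, 0), ligand_mass = 100)
  expect_equal(force(iso, c(2, -1, 0)), c(0, 0, 0))
  expect_equal(force(flat_system(), c(1, 1, 1)), c(0, 0, 0))

  ## matches central finite differences at 100 random probes
  set.seed(42)
  for (i in 1:100) {
    x <- runif(3, -24, 24)
    num <- vapply(1:3, function(k) {
      h <- 1e-6; e <- numeric(3); e[k] <- h
      (potential_energy(sys, x + e) - potential_energy(sys, x - e)) / (2 * h)
    }, numeric(1))
    f <- force(sys, x)
    expect_lt(max(abs(f + num)), 1e-5 * max(1, max(abs(num))))
  }
})

test_that("potential is invariant under a common translation", {
  set.seed(7)
  sys <- toy_system(
    dims = 3,
    wells = list(gaussian_well(c(0, 0, 0), 4, 2),
                 gaussian_well(c(8, 1, -2), 2, 1)),
    barriers = list(gaussian_barrier(c(4, 0, 0), 1.5, 1.5)),
    orthosteric_center = c(0, 0, 0), ligand_mass = 100)
  shift <- c(3.2, -1.7, 0.4)
  shifted <- toy_system(
    dims = 3,
    wells = lapply(sys$wells, function(w)
      gaussian_well(w$center + shift, w$depth, w$width, w$radius)),
    barriers = lapply(sys$barriers, function(b)
      gaussian_barrier(b$center + shift, b$height, b$width, b$radius)),
    orthosteric_center = shift, ligand_mass = 100,
    box_center = shift)
  for (i in 1:20) {
    x <- runif(3, -20, 20)
    expect_equal(potential_energy(sys, x),
                 potential_energy(shifted, x + shift), tolerance = 1e-12)
  }
})

test_that("binder preset has its global minimum at the orthosteric center", {
  sys <- build_scenario("binder")
  ## dense grid search oracle over the box
  ax <- seq(-24, 24, length.out = 49)
  grid <- as.matrix(expand.grid(ax, ax, ax))
  v <- potential_energy(sys, grid)
  best <- grid[which.min(v), ]
  expect_equal(unname(best), c(0, 0, 0))
  expect_lt(potential_energy(sys, c(0, 0, 0)), min(v) + 1e-9)
})

test_that("pam preset places a deeper metastable well on the 15 A shell", {
  sys <- build_scenario("pam")
  v_meta <- potential_energy(sys, c(15, 0, 0))
  v_orth <- potential_energy(sys, sys$orthosteric_center)
  expect_lt(v_meta, v_orth)
  ## the metastable feature sits at 15 A in any direction
  dirs <- rbind(c(0, 15, 0), c(0, 0, 15), 15 * c(1, 1, 1) / sqrt(3))
  for (i in 1:3)
    expect_equal(potential_energy(sys, dirs[i, ]), v_meta, tolerance = 1e-9)
  ## a repulsive barrier lies between 8 and 12 A on the approach path
  r <- seq(5.5, 14, by = 0.05)
  vr <- potential_energy(sys, cbind(r, 0, 0))
  r_top <- r[which.max(vr)]
  expect_gt(r_top, 8); expect_lt(r_top, 12)
  expect_gt(max(vr), v_orth)
})

test_that("diffusive preset with zeroed depths is flat inside the box", {
  sys <- build_scenario("diffusive",
                        overrides = list(orthosteric_depth = 0))
  set.seed(1)
  pts <- matrix(runif(30, -20, 20), ncol = 3)
  expect_equal(potential_energy(sys, pts), numeric(10))
})

test_that("presets validate their names and overrides", {
  expect_error(build_scenario("covalent"), "unknown preset")
  expect_error(build_scenario("pam", overrides = list(solvent = 1)),
               "nonexistent")
  expect_error(potential_energy(build_scenario("binder"), c(1, 2)),
               "3-D")
  expect_error(toy_system(dims = 3, wells = list(gaussian_well(c(1, 0, 0), 1, 1)),
                          orthosteric_center = c(0, 0, 0)),
               "orthosteric_center")
})

test_that("scenario files round-trip through YAML and JSON", {
  sys <- build_scenario("pam")
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_scenario(sys, f)
    back <- read_scenario(f)
    expect_equal(back$dims, sys$dims)
    expect_equal(back$ligand_mass, sys$ligand_mass)
    expect_equal(length(back$wells), length(sys$wells))
    set.seed(3)
    for (i in 1:10) {
      x <- runif(3, -20, 20)
      expect_equal(potential_energy(back, x), potential_energy(sys, x),
                   tolerance = 1e-9)
    }
  }
  expect_error(read_scenario("no/such/file.yaml"), "not found")
})
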