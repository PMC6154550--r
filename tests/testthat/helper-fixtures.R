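## Shared fixtures built in code.

## A trajectory_segment with scripted distances (positions placed on the
## first axis so com/geometry stays consistent).
make_segment <- function(times, distances, dims = 3) {
  n <- length(times)
  pos <- matrix(0, nrow = n, ncol = dims)
  pos[, 1] <- distances
  structure(list(times = as.numeric(times),
                 positions = pos,
                 velocities = matrix(0, nrow = n, ncol = dims),
                 potential_energies = numeric(n),
                 interaction_energies = numeric(n),
                 distances = as.numeric(distances)),
            class = "trajectory_segment")
}

## Flat confined box (single zero-depth well).
flat_system <- function(dims = 3, mass = 100, L = 25) {
  toy_system(dims = dims,
             wells = list(gaussian_well(numeric(dims), depth = 0, width = 1)),
             orthosteric_center = numeric(dims),
             ligand_mass = mass, box_halflength = L, wall_k = 10)
}

## Deep, wide Gaussian well: near-harmonic around its center with
## effective spring constant depth / width^2.
near_harmonic_system <- function(dims = 1, depth = 100, width = 4,
                                 mass = 100) {
  toy_system(dims = dims,
             wells = list(gaussian_well(numeric(dims), depth = depth,
                                        width = width)),
             orthosteric_center = numeric(dims),
             ligand_mass = mass, box_halflength = 20, wall_k = 20)
}

## Symmetric 1-D double well with a ~1.4 kcal/mol barrier, low enough for
## ergodic unbiased sampling at 310 K.
ergodic_double_well <- function(depth = 1.5, mass = 50) {
  toy_system(dims = 1,
             wells = list(gaussian_well(-3, depth = depth, width = 1),
                          gaussian_well(3, depth = depth, width = 1)),
             orthosteric_center = -3,
             ligand_mass = mass, box_halflength = 6, wall_k = 20)
}

## Empty 1-CV bias state.
empty_bias <- function(cv = cv_coordinate(1), ...) {
  h <- data.frame(time = numeric(0), center.1 = numeric(0),
                  sigma.1 = numeric(0), height = numeric(0))
  bias_state(h, cv, ...)
}

## Basin-transition counter with hysteresis for double-well CV series.
count_crossings <- function(s, lo = 5.5, hi = 8) {
  basin <- ifelse(s < lo, 1L, ifelse(s > hi, 2L, NA))
  b <- basin[!is.na(basin)]
  if (length(b) < 2) return(0L)
  sum(diff(b) != 0)
}

## Free energy of a 1-D system by direct Boltzmann quadrature.
quadrature_fes <- function(system, grid, temperature) {
  U <- potential_energy(system, matrix(grid, ncol = 1))
  U - min(U)
}
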