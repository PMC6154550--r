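#' Gaussian attractive well
#'
#' One term of a toy receptor-ligand energy landscape: an isotropic
#' Gaussian well contributing `-depth * exp(-|r - center|^2 / (2 width^2))`
#' to the potential. A positive `depth` is attractive (stabilising); it
#' emulates a stable or metastable ligand binding site.
#'
#' @param center Numeric vector, well center (A).
#' @param depth Well depth (kcal/mol); positive values attract. Must be finite.
#' @param width Gaussian sigma (A); must be > 0.
#' @param radius Shell radius (A, >= 0). With the default 0 the term is
#'   the point Gaussian above; with `radius = R` the energy depends on
#'   `(|r - center| - R)` instead of `|r - center|`, placing the well
#'   minimum on a spherical shell of radius R — the toy analogue of a
#'   binding region on the receptor vestibule rather than at a point.
#' @return An object of class `"gaussian_well"`.
#' @export
#' @examples
#' gaussian_well(c(0, 0, 0), depth = 6, width = 3)
gaussian_well <- function(center, depth, width, radius = 0) {
  center <- as.numeric(center)
  stopifnot(length(center) >= 1, is.finite(depth), length(depth) == 1,
            length(width) == 1, is.finite(width), width > 0,
            length(radius) == 1, is.finite(radius), radius >= 0)
  structure(list(center = center, depth = as.numeric(depth),
                 width = as.numeric(width), radius = as.numeric(radius)),
            class = "gaussian_well")
}

#' Gaussian repulsive barrier
#'
#' An isotropic Gaussian bump contributing
#' `+height * exp(-|r - center|^2 / (2 width^2))` to the potential. It
#' emulates a locally unfavourable region along a binding pathway (for a
#' GPCR vestibule, e.g. electrostatic repulsion by an acidic loop residue).
#'
#' @param center Numeric vector, barrier center (A).
#' @param height Barrier height (kcal/mol); must be > 0.
#' @param width Gaussian sigma (A); must be > 0.
#' @param radius Shell radius (A, >= 0); 0 (default) gives the point
#'   Gaussian, a positive value a spherical-shell barrier (see
#'   [gaussian_well()]).
#' @return An object of class `"gaussian_barrier"`.
#' @export
gaussian_barrier <- function(center, height, width, radius = 0) {
  center <- as.numeric(center)
  stopifnot(length(center) >= 1, length(height) == 1, is.finite(height),
            height > 0, length(width) == 1, is.finite(width), width > 0,
            length(radius) == 1, is.finite(radius), radius >= 0)
  structure(list(center = center, height = as.numeric(height),
                 width = as.numeric(width), radius = as.numeric(radius)),
            class = "gaussian_barrier")
}

#' Construct a toy receptor-ligand system
#'
#' A toy system is an analytic potential landscape for a single point
#' ligand: a sum of Gaussian wells (binding sites), Gaussian barriers
#' (unfavourable transition regions) and a harmonic confinement wall
#' outside a cubic box, standing in for a bounded simulation box. One well
#' must be centred on `orthosteric_center`; that well is the designated
#' orthosteric site whose center of mass the supervision engine monitors.
#'
#' @param dims Spatial dimensionality, 1, 2 or 3 (default 3).
#' @param wells List of [gaussian_well()] terms. Exactly one must be
#'   centred at `orthosteric_center`.
#' @param barriers List of [gaussian_barrier()] terms (may be empty).
#' @param orthosteric_center Numeric vector of length `dims` (A).
#' @param ligand_mass Ligand mass (amu), > 0. Default 200, a typical
#'   fragment-sized ligand.
#' @param box_halflength Half-length L of the confinement box (A);
#'   the walls are flat inside `|x_i| <= L` about `box_center`.
#' @param wall_k Harmonic wall spring constant (kcal/mol/A^2).
#' @param box_center Center of the confinement box (default origin).
#' @return An object of class `"toy_system"`.
#' @seealso [build_scenario()] for preset landscapes,
#'   [potential_energy()], [force()].
#' @export
toy_system <- function(dims = 3, wells = list(), barriers = list(),
                       orthosteric_center = numeric(dims),
                       ligand_mass = 200,
                       box_halflength = 25, wall_k = 10,
                       box_center = numeric(dims)) {
  stopifnot(dims %in% c(1L, 2L, 3L))
  dims <- as.integer(dims)
  orthosteric_center <- as.numeric(orthosteric_center)
  box_center <- as.numeric(box_center)
  stopifnot(length(orthosteric_center) == dims, length(box_center) == dims,
            is.finite(ligand_mass), ligand_mass > 0,
            box_halflength > 0, wall_k >= 0)
  if (!is.list(wells) || inherits(wells, "gaussian_well")) wells <- list(wells)
  if (!is.list(barriers) || inherits(barriers, "gaussian_barrier"))
    barriers <- list(barriers)
  for (w in wells) {
    if (!inherits(w, "gaussian_well"))
      stop("all elements of 'wells' must be gaussian_well objects")
    if (length(w$center) != dims)
      stop("well center dimensionality does not match dims = ", dims)
  }
  for (b in barriers) {
    if (!inherits(b, "gaussian_barrier"))
      stop("all elements of 'barriers' must be gaussian_barrier objects")
    if (length(b$center) != dims)
      stop("barrier center dimensionality does not match dims = ", dims)
  }
  if (length(wells) == 0)
    stop("a toy_system needs at least one well (the orthosteric site)")
  hit <- vapply(wells, function(w)
    max(abs(w$center - orthosteric_center)) < 1e-9 && w$radius == 0,
    logical(1))
  if (sum(hit) != 1L)
    stop("exactly one point well must be centred on orthosteric_center ",
         "(found ", sum(hit), ")")
  structure(list(
    dims = dims,
    wells = wells,
    barriers = barriers,
    orthosteric_center = orthosteric_center,
    orthosteric_well = which(hit),
    ligand_mass = as.numeric(ligand_mass),
    confinement = list(box_halflength = as.numeric(box_halflength),
                       wall_k = as.numeric(wall_k),
                       center = box_center)
  ), class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat("Toy receptor-ligand system (", x$dims, "-D)\n", sep = "")
  cat("  wells:    ", length(x$wells),
      " (orthosteric = #", x$orthosteric_well, ")\n", sep = "")
  cat("  barriers: ", length(x$barriers), "\n", sep = "")
  cat("  ligand mass: ", x$ligand_mass, " amu\n", sep = "")
  cat("  box half-length: ", x$confinement$box_halflength,
      " A (wall k = ", x$confinement$wall_k, " kcal/mol/A^2)\n", sep = "")
  invisible(x)
}

## Flatten a toy_system into the plain matrices the C++ core consumes.
sys_to_cpp <- function(system) {
  d <- system$dims
  nw <- length(system$wells)
  nb <- length(system$barriers)
  wc <- matrix(0, nrow = max(nw, 1), ncol = d)
  wd <- numeric(max(nw, 1)); ww <- rep(1, max(nw, 1))
  wr <- numeric(max(nw, 1))
  for (i in seq_len(nw)) {
    wc[i, ] <- system$wells[[i]]$center
    wd[i] <- system$wells[[i]]$depth
    ww[i] <- system$wells[[i]]$width
    wr[i] <- system$wells[[i]]$radius %||% 0
  }
  bc <- matrix(0, nrow = max(nb, 1), ncol = d)
  bh <- numeric(max(nb, 1)); bw <- rep(1, max(nb, 1))
  br <- numeric(max(nb, 1))
  for (i in seq_len(nb)) {
    bc[i, ] <- system$barriers[[i]]$center
    bh[i] <- system$barriers[[i]]$height
    bw[i] <- system$barriers[[i]]$width
    br[i] <- system$barriers[[i]]$radius %||% 0
  }
  list(dims = d, n_wells = nw, n_barriers = nb,
       well_centers = wc, well_depths = wd, well_widths = ww,
       well_radii = wr,
       barrier_centers = bc, barrier_heights = bh, barrier_widths = bw,
       barrier_radii = br,
       box_halflength = system$confinement$box_halflength,
       wall_k = system$confinement$wall_k,
       box_center = system$confinement$center,
       site_center = system$orthosteric_center,
       mass = system$ligand_mass)
}

as_position_matrix <- function(system, position) {
  if (is.matrix(position)) {
    if (ncol(position) != system$dims)
      stop("position has ", ncol(position), " columns; system is ",
           system$dims, "-D")
    position
  } else {
    position <- as.numeric(position)
    if (length(position) != system$dims)
      stop("position has ", length(position), " components; system is ",
           system$dims, "-D")
    matrix(position, nrow = 1)
  }
}

#' Potential energy of the toy landscape
#'
#' Evaluates the total potential (wells + barriers + confinement wall), or
#' with `include_confinement = FALSE` the receptor-ligand interaction part
#' only (the landscape analyses use the latter as the toy analogue of a
#' force-field interaction energy).
#'
#' @param system A [toy_system()].
#' @param position Numeric vector of length `dims`, or a matrix with one
#'   position per row for vectorised evaluation.
#' @param include_confinement Include the harmonic wall term? Default TRUE.
#' @return Energy in kcal/mol (scalar, or vector for matrix input).
#' @export
#' @examples
#' sys <- build_scenario("binder")
#' potential_energy(sys, sys$orthosteric_center)
potential_energy <- function(system, position, include_confinement = TRUE) {
  stopifnot(inherits(system, "toy_system"))
  x <- as_position_matrix(system, position)
  n <- nrow(x)
  e <- numeric(n)
  for (w in system$wells) {
    dx <- sweep(x, 2, w$center)
    dev <- sqrt(rowSums(dx * dx)) - w$radius
    e <- e - w$depth * exp(-dev^2 / (2 * w$width^2))
  }
  for (b in system$barriers) {
    dx <- sweep(x, 2, b$center)
    dev <- sqrt(rowSums(dx * dx)) - b$radius
    e <- e + b$height * exp(-dev^2 / (2 * b$width^2))
  }
  if (include_confinement) {
    conf <- system$confinement
    dx <- abs(sweep(x, 2, conf$center)) - conf$box_halflength
    dx[dx < 0] <- 0
    e <- e + conf$wall_k * rowSums(dx * dx)
  }
  if (!is.matrix(position)) e[[1]] else e
}

#' Force on the ligand
#'
#' Analytic negative gradient of [potential_energy()] at one position.
#'
#' @inheritParams potential_energy
#' @return Numeric vector of length `dims`, kcal/mol/A.
#' @export
force <- function(system, position, include_confinement = TRUE) {
  stopifnot(inherits(system, "toy_system"))
  x <- as_position_matrix(system, position)
  if (nrow(x) != 1) stop("force() takes a single position")
  x <- drop(x)
  f <- numeric(system$dims)
  ## U = -D exp(-(rho - R)^2 / 2 sigma^2), rho = |x - c|
  ## F = -dU/dx = -D g (rho - R)/sigma^2 * (x - c)/rho  (point case R = 0
  ## reduces to -D g (x - c)/sigma^2)
  shell_force <- function(dx, amp, width, radius) {
    rho <- sqrt(sum(dx * dx))
    dev <- rho - radius
    g <- exp(-dev^2 / (2 * width^2))
    unit <- if (rho > 1e-10) dx / rho else numeric(length(dx))
    -amp * g * dev / width^2 * unit
  }
  for (w in system$wells)
    f <- f + shell_force(x - w$center, w$depth, w$width, w$radius)
  for (b in system$barriers)
    f <- f - shell_force(x - b$center, b$height, b$width, b$radius)
  if (include_confinement) {
    conf <- system$confinement
    dx <- x - conf$center
    over <- abs(dx) - conf$box_halflength
    over[over < 0] <- 0
    f <- f - 2 * conf$wall_k * over * sign(dx)
  }
  f
}

## ---- presets ---------------------------------------------------------------

preset_parameters <- function(name) {
  switch(name,
    ## A well-behaved orthosteric binder (caffeine-like): the orthosteric
    ## well is the global minimum; a metastable shell well and a mild
    ## barrier sit along the entry pathway.
    binder = list(
      orthosteric_depth = 6, orthosteric_width = 3,
      metastable_distance = 15, metastable_depth = 1.5, metastable_width = 2,
      barrier_distance = 10, barrier_height = 1, barrier_width = 2,
      ligand_mass = 200, box_halflength = 25, wall_k = 10),
    ## A PAM-like fragment: the extracellular metastable well (15 A out)
    ## is deeper than the orthosteric well, with a repulsive barrier in
    ## between, so trajectories stall on the metastable shell.
    pam = list(
      orthosteric_depth = 3, orthosteric_width = 3,
      metastable_distance = 15, metastable_depth = 7, metastable_width = 2.5,
      barrier_distance = 10, barrier_height = 3, barrier_width = 2,
      ligand_mass = 200, box_halflength = 25, wall_k = 10),
    ## Nearly free diffusion: one shallow orthosteric well, no other
    ## features; zeroing the depth gives a flat confined box.
    diffusive = list(
      orthosteric_depth = 1, orthosteric_width = 3,
      metastable_distance = 15, metastable_depth = 0, metastable_width = 2.5,
      barrier_distance = 10, barrier_height = 0, barrier_width = 2,
      ligand_mass = 200, box_halflength = 25, wall_k = 10),
    stop("unknown preset '", name,
         "'; available presets: binder, pam, diffusive")
  )
}

#' Build a preset toy scenario
#'
#' Resolves a named scenario preset into a full [toy_system()]. The
#' presets encode the qualitative binding phenomenology the toolkit is
#' designed to reproduce:
#' \describe{
#'   \item{binder}{the orthosteric well is the global minimum of the
#'     landscape; ligands that reach it stay bound (caffeine-like
#'     orthosteric binder).}
#'   \item{pam}{a metastable well on a shell 15 A from the orthosteric
#'     center is deeper than the orthosteric well and a repulsive barrier
#'     sits at 10 A, so trajectories stall in the extracellular
#'     vestibule-like shell (fragment PAM-like behaviour).}
#'   \item{diffusive}{a single shallow well; binding is nearly diffusive.}
#' }
#'
#' @param preset Preset name: `"binder"`, `"pam"` or `"diffusive"`.
#' @param overrides Named list overriding preset parameters. Valid names
#'   are the preset parameter fields: `orthosteric_depth`,
#'   `orthosteric_width`, `metastable_distance`, `metastable_depth`,
#'   `metastable_width`, `barrier_distance`, `barrier_height`,
#'   `barrier_width`, `ligand_mass`, `box_halflength`, `wall_k`.
#'   Unknown names are an error.
#' @param dims Dimensionality of the resulting system (default 3).
#' @return A [toy_system()]. Metastable well and barrier are placed on the
#'   first coordinate axis; zero depths/heights drop the term.
#' @export
#' @examples
#' pam <- build_scenario("pam")
#' flat <- build_scenario("diffusive",
#'                        overrides = list(orthosteric_depth = 0))
build_scenario <- function(preset = c("binder", "pam", "diffusive"),
                           overrides = list(), dims = 3) {
  if (length(preset) != 1 || !is.character(preset))
    preset <- match.arg(preset)
  p <- preset_parameters(preset)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad))
      stop("override of nonexistent preset field(s): ",
           paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  ## The metastable well and the barrier are spherical shells about the
  ## orthosteric center: the toy analogue of the extracellular vestibule
  ## ring every approach path must cross.
  wells <- list(gaussian_well(numeric(dims), depth = p$orthosteric_depth,
                              width = p$orthosteric_width))
  if (p$metastable_depth != 0)
    wells <- c(wells, list(gaussian_well(numeric(dims),
                                         depth = p$metastable_depth,
                                         width = p$metastable_width,
                                         radius = p$metastable_distance)))
  barriers <- list()
  if (p$barrier_height != 0)
    barriers <- list(gaussian_barrier(numeric(dims),
                                      height = p$barrier_height,
                                      width = p$barrier_width,
                                      radius = p$barrier_distance))
  toy_system(dims = dims, wells = wells, barriers = barriers,
             orthosteric_center = numeric(dims),
             ligand_mass = p$ligand_mass,
             box_halflength = p$box_halflength, wall_k = p$wall_k)
}
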