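#' Collective variables on the toy system
#'
#' Collective variables (CVs) map a ligand state to a scalar along which
#' metadynamics bias is deposited.
#'
#' * `cv_coordinate(axis)` — one Cartesian coordinate of the ligand (A);
#'   the toy stand-in for an atom-pair distance CV on a 1-D landscape.
#' * `cv_distance(center)` — Euclidean distance from a fixed point (A).
#' * `cv_angle(axes, center)` — the polar angle `atan2` in a coordinate
#'   plane (rad), periodic on `[-pi, pi)`; the toy stand-in for a
#'   dihedral-like CV.
#'
#' @param axis,axes Coordinate axis (1-based), or two axes for the angle.
#' @param center Reference point (defaults to the origin for `cv_angle`).
#' @param label Optional CV label used in HILLS headers.
#' @return An object of class `"collective_variable"`.
#' @export
cv_coordinate <- function(axis = 1, label = paste0("coord", axis)) {
  stopifnot(axis >= 1)
  structure(list(kind = "coordinate", axis = as.integer(axis),
                 center = NULL, periodic = FALSE, label = label),
            class = "collective_variable")
}

#' @rdname cv_coordinate
#' @export
cv_distance <- function(center, label = "dist") {
  structure(list(kind = "distance", axis = NULL,
                 center = as.numeric(center), periodic = FALSE,
                 label = label),
            class = "collective_variable")
}

#' @rdname cv_coordinate
#' @export
cv_angle <- function(axes = c(1, 2), center = NULL, label = "angle") {
  stopifnot(length(axes) == 2, all(axes >= 1), axes[1] != axes[2])
  structure(list(kind = "angle", axis = as.integer(axes),
                 center = center, periodic = TRUE, label = label),
            class = "collective_variable")
}

#' Evaluate a collective variable
#'
#' @param cv A `collective_variable`.
#' @param position Numeric position vector, or a matrix (frames x dims).
#' @return CV value(s).
#' @export
cv_value <- function(cv, position) {
  stopifnot(inherits(cv, "collective_variable"))
  x <- if (is.matrix(position)) position else matrix(position, nrow = 1)
  v <- switch(cv$kind,
    coordinate = x[, cv$axis[1]],
    distance = {
      dx <- sweep(x, 2, cv$center)
      sqrt(rowSums(dx * dx))
    },
    angle = {
      ctr <- cv$center %||% numeric(ncol(x))
      atan2(x[, cv$axis[2]] - ctr[cv$axis[2]],
            x[, cv$axis[1]] - ctr[cv$axis[1]])
    })
  if (is.matrix(position)) v else v[[1]]
}

cv_to_cpp <- function(cv, dims) {
  kind <- match(cv$kind, c("coordinate", "distance", "angle")) - 1L
  center <- cv$center %||% numeric(dims)
  if (length(center) != dims) stop("CV center dimensionality mismatch")
  list(kind = kind,
       axis_a = as.integer((cv$axis[1] %||% 1L) - 1L),
       axis_b = as.integer((if (length(cv$axis) > 1) cv$axis[2] else 1L) - 1L),
       center = center,
       periodic = isTRUE(cv$periodic))
}

#' Well-tempered metadynamics configuration
#'
#' Defaults follow a standard well-tempered salt-bridge protocol: initial
#' hill height 0.3 kcal/mol, hill widths 0.04 A for length-like CVs and
#' 0.3 rad for angle-like CVs, deposition every 0.5 ps, bias factor 6,
#' 298 K, 10 ns of production (scale `duration` down for toy runs).
#'
#' @param cvs A `collective_variable` or list of one or two.
#' @param w0 Initial Gaussian hill height (kcal/mol), > 0.
#' @param sigmas Hill widths, one per CV. Defaults to 0.04 (A) per
#'   length-like CV and 0.3 (rad) per angle-like CV.
#' @param stride Hill deposition period (ps). Default 0.5.
#' @param bias_factor Well-tempered bias factor (gamma), > 1. Default 6.
#' @param temperature Temperature (K). Default 298.
#' @param duration Production length (ps). Default 10000 (10 ns).
#' @param grid_min,grid_max Optional per-CV grid bounds for the internal
#'   gridded bias (defaults: the confinement box for length-like CVs,
#'   `[-pi, pi]` for angles).
#' @param grid_bin Grid spacing per CV (defaults to `sigmas / 5`).
#' @return An object of class `"metad_config"`.
#' @export
metad_config <- function(cvs, w0 = 0.3, sigmas = NULL, stride = 0.5,
                         bias_factor = 6, temperature = 298,
                         duration = 10000,
                         grid_min = NULL, grid_max = NULL, grid_bin = NULL) {
  if (inherits(cvs, "collective_variable")) cvs <- list(cvs)
  stopifnot(length(cvs) >= 1, length(cvs) <= 2)
  for (cv in cvs)
    if (!inherits(cv, "collective_variable"))
      stop("cvs must be collective_variable objects")
  if (is.null(sigmas))
    sigmas <- vapply(cvs, function(cv) if (cv$periodic) 0.3 else 0.04,
                     numeric(1))
  stopifnot(length(sigmas) == length(cvs), all(sigmas > 0),
            w0 > 0, stride > 0, temperature > 0, duration >= 0)
  if (bias_factor <= 1) stop("bias_factor (gamma) must be > 1")
  structure(list(cvs = cvs, w0 = w0, sigmas = as.numeric(sigmas),
                 stride = stride, bias_factor = bias_factor,
                 temperature = temperature, duration = duration,
                 grid_min = grid_min, grid_max = grid_max,
                 grid_bin = grid_bin),
            class = "metad_config")
}

new_bias_state <- function(hills, cvs, w0, sigmas, bias_factor, temperature) {
  structure(list(hills = hills, cvs = cvs, w0 = w0, sigmas = sigmas,
                 bias_factor = bias_factor, temperature = temperature),
            class = "bias_state")
}

#' Create a bias state from explicit hills
#'
#' Mainly for testing, HILLS-file import and composing bias states. The
#' hills data.frame needs columns `time`, one `center.<k>` per CV,
#' `sigma.<k>` per CV, and `height`.
#'
#' @param hills Data.frame of deposited hills (may have zero rows).
#' @param cvs CV list (as in [metad_config()]).
#' @param w0,sigmas,bias_factor,temperature Scheme parameters recorded
#'   with the state.
#' @return An object of class `"bias_state"`.
#' @export
bias_state <- function(hills, cvs, w0 = 0.3, sigmas = NULL,
                       bias_factor = 6, temperature = 298) {
  if (inherits(cvs, "collective_variable")) cvs <- list(cvs)
  ncv <- length(cvs)
  if (is.null(sigmas)) {
    sc <- grep("^sigma\\.", names(hills), value = TRUE)
    sigmas <- if (length(sc) && nrow(hills)) as.numeric(hills[1, sc])
              else rep(0.04, ncv)
  }
  need <- c("time", paste0("center.", seq_len(ncv)),
            paste0("sigma.", seq_len(ncv)), "height")
  miss <- setdiff(need, names(hills))
  if (length(miss) && nrow(hills))
    stop("hills is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(hills) > 1 && is.unsorted(hills$time))
    stop("hills must be ordered by deposit time")
  new_bias_state(hills, cvs, w0, sigmas, bias_factor, temperature)
}

#' @export
print.bias_state <- function(x, ...) {
  cat("Well-tempered metadynamics bias: ", nrow(x$hills), " hills, ",
      length(x$cvs), " CV(s), gamma = ", x$bias_factor,
      ", T = ", x$temperature, " K\n", sep = "")
  invisible(x)
}

hill_centers <- function(bias) {
  ncv <- length(bias$cvs)
  as.matrix(bias$hills[, paste0("center.", seq_len(ncv)), drop = FALSE])
}

#' Accumulated bias potential
#'
#' Sums the deposited Gaussian hills at one or more CV-space points:
#' `V(s) = sum_j h_j prod_k exp(-(s_k - c_jk)^2 / (2 sigma_k^2))`, with
#' minimum-image wrapping of angle-like CV differences.
#'
#' @param bias A `bias_state`.
#' @param cv_point Numeric vector (one point, length = number of CVs) or
#'   matrix of points (rows).
#' @return Bias energy (kcal/mol), scalar or vector.
#' @export
bias_potential <- function(bias, cv_point) {
  stopifnot(inherits(bias, "bias_state"))
  ncv <- length(bias$cvs)
  pts <- if (is.matrix(cv_point)) cv_point else matrix(cv_point, nrow = 1)
  if (ncol(pts) != ncv)
    stop("cv_point has ", ncol(pts), " components; bias has ", ncv, " CV(s)")
  nh <- nrow(bias$hills)
  v <- numeric(nrow(pts))
  if (nh > 0) {
    ctr <- hill_centers(bias)
    sig <- bias$sigmas
    gmat <- matrix(1, nrow = nrow(pts), ncol = nh)  # points x hills
    for (k in seq_len(ncv)) {
      dlt <- outer(pts[, k], ctr[, k], "-")
      if (bias$cvs[[k]]$periodic)
        dlt <- (dlt + pi) %% (2 * pi) - pi
      gmat <- gmat * exp(-dlt^2 / (2 * sig[k]^2))
    }
    v <- as.numeric(gmat %*% bias$hills$height)
  }
  if (is.matrix(cv_point)) v else v[[1]]
}

#' Height of the next well-tempered hill
#'
#' The well-tempered damping rule
#' `w = w0 * exp(-V(s) / (kB (gamma - 1) T))`: hills shrink geometrically
#' where bias has already accumulated.
#'
#' @param bias A `bias_state`.
#' @param cv_point CV-space point (numeric vector).
#' @return Hill height (kcal/mol).
#' @export
#' @examples
#' b <- bias_state(data.frame(time = numeric(0), center.1 = numeric(0),
#'                            sigma.1 = numeric(0), height = numeric(0)),
#'                 cv_coordinate(1))
#' next_hill_height(b, 0)  # w0 = 0.3 at zero accumulated bias
next_hill_height <- function(bias, cv_point) {
  stopifnot(inherits(bias, "bias_state"))
  if (bias$bias_factor <= 1) stop("bias_factor (gamma) must be > 1")
  v <- bias_potential(bias, cv_point)
  bias$w0 * exp(-v / (.kB * (bias$bias_factor - 1) * bias$temperature))
}

default_grid <- function(system, cv, gmin, gmax, gbin, sigma) {
  if (cv$periodic) {
    lo <- gmin %||% -pi; hi <- gmax %||% pi
  } else {
    L <- system$confinement$box_halflength
    ctr <- system$confinement$center
    lo <- gmin %||% (min(ctr) - L - 5)
    hi <- gmax %||% (max(ctr) + L + 5)
    if (cv$kind == "distance") lo <- max(gmin %||% 0, 0)
  }
  bin <- gbin %||% (sigma / 5)
  n <- max(2L, as.integer(ceiling((hi - lo) / bin)) + 1L)
  list(lo = lo, hi = hi, n = n)
}

#' Run well-tempered metadynamics
#'
#' Langevin dynamics under the total force (toy landscape force plus the
#' analytic gradient of the accumulated bias, evaluated from a fine
#' internal CV grid), with a Gaussian hill deposited every
#' `config$stride` ps at the current CV value, its height set by the
#' well-tempered damping rule.
#'
#' @param system A [toy_system()].
#' @param start An [state()].
#' @param dyn A [dynamics_config()] (use `temperature` consistent with
#'   `config$temperature`).
#' @param config A [metad_config()].
#' @return An object of class `"metad_run"`: list with `bias` (a
#'   `bias_state` holding the deposited hills), `segment` (a
#'   `trajectory_segment`), and `cv_series` (matrix frames x CVs).
#' @export
run_metadynamics <- function(system, start, dyn = dynamics_config(temperature = 298),
                             config) {
  stopifnot(inherits(system, "toy_system"), inherits(start, "md_state"),
            inherits(dyn, "dynamics_config"), inherits(config, "metad_config"))
  if (!is.null(dyn$seed)) set.seed(dyn$seed)
  ncv <- length(config$cvs)
  cvl <- lapply(config$cvs, cv_to_cpp, dims = system$dims)
  glo <- numeric(ncv); ghi <- numeric(ncv); gn <- integer(ncv)
  for (k in seq_len(ncv)) {
    g <- default_grid(system, config$cvs[[k]],
                      config$grid_min[k], config$grid_max[k],
                      config$grid_bin[k], config$sigmas[k])
    glo[k] <- g$lo; ghi[k] <- g$hi; gn[k] <- g$n
  }
  nsteps <- max(1L, as.integer(round(config$duration / dyn$dt)))
  dep_steps <- as.integer(round(config$stride / dyn$dt))
  raw <- cpp_run_metad(sys_to_cpp(system), start$position, start$velocity,
                       start$time, nsteps, dyn$dt, config$temperature,
                       dyn$friction, dyn$sample_stride,
                       cvl, config$sigmas, config$w0, config$bias_factor,
                       dep_steps, glo, ghi, gn)
  nh <- raw$n_hills
  ctr <- raw$hill_centers[seq_len(nh), , drop = FALSE]
  hills <- data.frame(time = raw$hill_times[seq_len(nh)])
  for (k in seq_len(ncv)) hills[[paste0("center.", k)]] <- ctr[, k]
  for (k in seq_len(ncv)) hills[[paste0("sigma.", k)]] <- rep(config$sigmas[k], nh)
  hills$height <- raw$hill_heights[seq_len(nh)]
  bias <- new_bias_state(hills, config$cvs, config$w0, config$sigmas,
                         config$bias_factor, config$temperature)
  seg <- new_segment(raw)
  structure(list(bias = bias, segment = seg,
                 cv_series = raw$cv_series, config = config),
            class = "metad_run")
}

#' @export
print.metad_run <- function(x, ...) {
  print(x$bias)
  print(x$segment)
  invisible(x)
}

#' Free-energy estimate from a well-tempered bias
#'
#' The standard well-tempered estimator
#' `F(s) = -(gamma / (gamma - 1)) V(s)`, evaluated on a regular CV grid
#' and (by default) shifted so that `min F = 0`.
#'
#' @param bias A `bias_state` with at least one hill.
#' @param grid Optional numeric vector of 1-D grid points (or list of two
#'   vectors for 2 CVs); by default 512 points spanning the hill centers
#'   padded by 5 sigma.
#' @param n Number of default grid points per CV.
#' @param shift Shift the minimum to zero? Default TRUE. With
#'   `shift = FALSE` the estimator is linear in the accumulated bias.
#' @param tail_average Fraction of the deposition history (from the end)
#'   over which to time-average the free-energy estimate (1-CV only).
#'   `0` (default) uses the final bias alone; a value like `0.5` averages
#'   the estimator over checkpoints spanning the last half of the hills,
#'   which damps the deposition ripple of converged runs.
#' @return For one CV, a data.frame of class `"metad_fes"` with columns
#'   `cv` and `free_energy` (kcal/mol); for two CVs, a list with `grid1`,
#'   `grid2` and matrix `free_energy`.
#' @export
estimate_fes <- function(bias, grid = NULL, n = 512, shift = TRUE,
                         tail_average = 0) {
  stopifnot(inherits(bias, "bias_state"))
  if (nrow(bias$hills) == 0) stop("bias has no hills; nothing to estimate")
  ncv <- length(bias$cvs)
  pref <- bias$bias_factor / (bias$bias_factor - 1)
  ctr <- hill_centers(bias)
  make_grid <- function(k) {
    if (bias$cvs[[k]]$periodic) seq(-pi, pi, length.out = n) else
      seq(min(ctr[, k]) - 5 * bias$sigmas[k],
          max(ctr[, k]) + 5 * bias$sigmas[k], length.out = n)
  }
  if (ncv == 1) {
    g <- grid %||% make_grid(1)
    if (tail_average > 0 && nrow(bias$hills) > 1) {
      stopifnot(tail_average <= 1)
      nh <- nrow(bias$hills)
      dlt <- outer(g, ctr[, 1], "-")
      if (bias$cvs[[1]]$periodic) dlt <- (dlt + pi) %% (2 * pi) - pi
      gmat <- exp(-dlt^2 / (2 * bias$sigmas[1]^2))
      from <- max(1L, as.integer(ceiling((1 - tail_average) * nh)))
      checkpoints <- unique(as.integer(round(seq(from, nh, length.out =
                                                 min(25, nh - from + 1)))))
      ## incremental partial sums: one pass over the hills in total
      acc <- numeric(length(g))
      vk <- as.numeric(gmat[, seq_len(checkpoints[1]), drop = FALSE] %*%
                         bias$hills$height[seq_len(checkpoints[1])])
      fk <- -pref * vk
      acc <- acc + (fk - min(fk))
      for (i in seq_along(checkpoints)[-1]) {
        idx <- (checkpoints[i - 1] + 1):checkpoints[i]
        vk <- vk + as.numeric(gmat[, idx, drop = FALSE] %*%
                                bias$hills$height[idx])
        fk <- -pref * vk
        acc <- acc + (fk - min(fk))
      }
      f <- acc / length(checkpoints)
    } else {
      f <- -pref * bias_potential(bias, matrix(g, ncol = 1))
    }
    if (shift) f <- f - min(f)
    out <- data.frame(cv = g, free_energy = f)
    class(out) <- c("metad_fes", "data.frame")
    out
  } else {
    g1 <- if (is.list(grid)) grid[[1]] else make_grid(1)
    g2 <- if (is.list(grid)) grid[[2]] else make_grid(2)
    pts <- as.matrix(expand.grid(g1, g2))
    f <- matrix(-pref * bias_potential(bias, pts), nrow = length(g1))
    if (shift) f <- f - min(f)
    list(grid1 = g1, grid2 = g2, free_energy = f)
  }
}

#' @export
plot.metad_fes <- function(x, ...) {
  plot(x$cv, x$free_energy, type = "l", xlab = "collective variable",
       ylab = "free energy (kcal/mol)", ...)
  invisible(x)
}

#' Fraction of frames in the closed state
#'
#' Fraction of CV frames below `closed_threshold` (e.g. a salt-bridge
#' distance under which the bridge counts as formed/closed). When a
#' `bias_state` is supplied, the basin free-energy difference
#' `F(open) - F(closed)` is also reported, each basin free energy being
#' the Boltzmann integral of the FES over its side of the threshold.
#'
#' @param cv_series Numeric CV series (A), non-empty.
#' @param closed_threshold Threshold (A), > 0.
#' @param bias Optional `bias_state` for the free-energy difference.
#' @return A list of class `"closed_state"` with `fraction` and (if
#'   `bias` given) `delta_f_open_closed` (kcal/mol; positive when the
#'   closed state is more stable).
#' @export
closed_state_fraction <- function(cv_series, closed_threshold, bias = NULL) {
  cv_series <- as.numeric(cv_series)
  if (length(cv_series) == 0) stop("empty CV series")
  stopifnot(closed_threshold > 0)
  out <- list(fraction = mean(cv_series < closed_threshold),
              closed_threshold = closed_threshold)
  if (!is.null(bias)) {
    out$delta_f_open_closed <-
      -delta_f_closed_open(bias, closed_threshold)
  }
  class(out) <- "closed_state"
  out
}

#' @export
print.closed_state <- function(x, ...) {
  cat("closed-state fraction (CV < ", x$closed_threshold, " A): ",
      format(round(x$fraction, 4)), "\n", sep = "")
  if (!is.null(x$delta_f_open_closed))
    cat("F(open) - F(closed) = ",
        format(round(x$delta_f_open_closed, 3)), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Basin free-energy difference closed minus open
#'
#' Splits the 1-D FES at `threshold` and Boltzmann-integrates each basin:
#' `F_basin = -kB T log( sum exp(-F(s)/kB T) ds )`. Returns
#' `F(closed) - F(open)` (negative when the closed basin is more stable).
#'
#' @param bias A 1-CV `bias_state`.
#' @param threshold CV value separating closed (below) from open (above).
#' @param n Grid resolution for the integration.
#' @param tail_average Passed to [estimate_fes()]; defaults to averaging
#'   over the last half of the deposition history.
#' @return Free-energy difference (kcal/mol).
#' @export
delta_f_closed_open <- function(bias, threshold, n = 1024,
                                tail_average = 0.5) {
  stopifnot(inherits(bias, "bias_state"), length(bias$cvs) == 1)
  fes <- estimate_fes(bias, n = n, shift = TRUE, tail_average = tail_average)
  kT <- .kB * bias$temperature
  ds <- diff(fes$cv[1:2])
  wclosed <- fes$cv < threshold
  if (!any(wclosed) || all(wclosed))
    stop("threshold ", threshold, " does not split the sampled CV range")
  fb <- function(sel)
    -kT * log(sum(exp(-fes$free_energy[sel] / kT)) * ds)
  fb(wclosed) - fb(!wclosed)
}

#' Toy salt-bridge double-well system
#'
#' A 1-D double-well landscape for a salt-bridge-like distance coordinate:
#' a "closed" well (bridge formed, around 4.5 A) and an "open" well
#' (bridge broken, around 9 A) separated by a barrier of a few kcal/mol.
#' `delta_closed` deepens the closed well, emulating the extra
#' stabilisation of the closed conformation produced by a bound positive
#' allosteric modulator; metadynamics on this system should recover that
#' shift in the closed-open free-energy difference.
#'
#' @param delta_closed Extra depth of the closed well (kcal/mol, >= 0).
#' @param closed_center,open_center Well positions (A).
#' @param depth Base depth of both wells (kcal/mol).
#' @param width Well sigma (A).
#' @param mass Effective mass of the coordinate (amu).
#' @return A 1-D [toy_system()] whose orthosteric (monitored) center is
#'   the closed-well position.
#' @export
salt_bridge_system <- function(delta_closed = 0, closed_center = 4.5,
                               open_center = 9, depth = 6, width = 0.8,
                               mass = 50) {
  stopifnot(delta_closed >= 0, open_center > closed_center)
  mid <- (closed_center + open_center) / 2
  half <- (open_center - closed_center) / 2 + 2
  toy_system(
    dims = 1,
    wells = list(
      gaussian_well(closed_center, depth = depth + delta_closed, width = width),
      gaussian_well(open_center, depth = depth, width = width)),
    barriers = list(),
    orthosteric_center = closed_center,
    ligand_mass = mass,
    box_halflength = half, wall_k = 20, box_center = mid)
}
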