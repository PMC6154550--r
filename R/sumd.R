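#' Supervision configuration
#'
#' Settings of the slope-supervised (tabu-like) adaptive sampling loop:
#' short unbiased windows are accepted when the ligand-site distance trend
#' over the window is decreasing, rejected (coordinates restored,
#' velocities resampled) otherwise, and supervision switches off
#' permanently once the distance first drops below the arrival threshold.
#'
#' @param window_duration Length of one supervised window (ps). Default
#'   600, the production window length; tests and toy runs scale it down.
#' @param arrival_threshold Ligand-site distance (A) below which the
#'   ligand counts as arrived and supervision is disabled. Default 5.
#' @param slope_threshold Accept a window iff its fitted slope is strictly
#'   below this value (A/ps). Default 0: only decreasing-distance windows
#'   are kept, and a slope of exactly zero is rejected.
#' @param fit_mode `"affine"` (ordinary least-squares line, default) or
#'   `"through_origin"` (a literal f(x) = m x fit on times shifted to
#'   start at zero).
#' @param max_windows Give up after this many attempted windows if the
#'   ligand never arrives. Default 2000.
#' @param post_arrival_duration Length (ps) of the classical
#'   (unsupervised) tail run after arrival. Default 10x window_duration.
#' @param seed Optional integer seed for the whole supervised run.
#' @return An object of class `"supervision_config"`.
#' @export
supervision_config <- function(window_duration = 600, arrival_threshold = 5.0,
                               slope_threshold = 0,
                               fit_mode = c("affine", "through_origin"),
                               max_windows = 2000,
                               post_arrival_duration = 10 * window_duration,
                               seed = NULL) {
  fit_mode <- match.arg(fit_mode)
  stopifnot(window_duration > 0, arrival_threshold > 0, max_windows >= 1,
            post_arrival_duration >= 0)
  structure(list(window_duration = window_duration,
                 arrival_threshold = arrival_threshold,
                 slope_threshold = slope_threshold,
                 fit_mode = fit_mode,
                 max_windows = as.integer(max_windows),
                 post_arrival_duration = post_arrival_duration,
                 seed = seed),
            class = "supervision_config")
}

#' Center-of-mass distance between two atom groups
#'
#' Euclidean distance between the mass-weighted centroids of two atom
#' sets. This is the quantity the supervision monitors (for the toy
#' point ligand it reduces to the particle-site distance).
#'
#' @param coords_a,coords_b Numeric matrices (atoms x dims) or vectors for
#'   a single atom.
#' @param masses_a,masses_b Positive masses (amu), one per atom.
#' @return Distance (A).
#' @export
#' @examples
#' com_distance(c(0, 0, 0), 1, c(3, 4, 0), 1)  # 5
com_distance <- function(coords_a, masses_a, coords_b, masses_b) {
  com <- function(xyz, m, lab) {
    if (!is.matrix(xyz)) xyz <- matrix(as.numeric(xyz), nrow = 1)
    m <- as.numeric(m)
    if (nrow(xyz) == 0 || length(m) == 0)
      stop("empty atom set for ", lab)
    if (length(m) != nrow(xyz))
      stop("number of masses does not match number of atoms for ", lab)
    if (any(!is.finite(m)) || any(m <= 0))
      stop("masses must be positive and finite for ", lab)
    colSums(xyz * m) / sum(m)
  }
  a <- com(coords_a, masses_a, "group A")
  b <- com(coords_b, masses_b, "group B")
  if (length(a) != length(b)) stop("coordinate dimensionality mismatch")
  sqrt(sum((a - b)^2))
}

#' Fitted distance-trend slope of a supervision window
#'
#' Fits the recorded distance points of a window against time with a
#' linear function and returns its slope m (A/ps). The affine mode is the
#' ordinary least-squares slope; the through-origin mode fits a literal
#' f(x) = m x after shifting times to start at zero.
#'
#' @param times Strictly increasing times (ps), length >= 2.
#' @param distances Distances (A), same length.
#' @param fit_mode `"affine"` or `"through_origin"`.
#' @return Slope m (A/ps).
#' @export
#' @examples
#' window_slope(0:3, c(4, 3, 2, 1))  # -1
window_slope <- function(times, distances,
                         fit_mode = c("affine", "through_origin")) {
  fit_mode <- match.arg(fit_mode)
  times <- as.numeric(times); distances <- as.numeric(distances)
  if (length(times) < 2 || length(distances) != length(times))
    stop("need at least 2 aligned (time, distance) points")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  t0 <- times - times[1]
  if (fit_mode == "affine") {
    tc <- t0 - mean(t0)
    sum(tc * (distances - mean(distances))) / sum(tc * tc)
  } else {
    if (sum(t0 * t0) == 0) stop("degenerate times for through-origin fit")
    sum(t0 * distances) / sum(t0 * t0)
  }
}

#' Classify one supervision window
#'
#' Applies the tabu-like decision rule to a simulated window: `"arrival"`
#' if the minimum recorded distance dropped below the arrival threshold
#' (a first-passage reading of the arrival condition), otherwise
#' `"accept"` iff the fitted slope is strictly below `slope_threshold`,
#' else `"reject"`.
#'
#' @param segment A `trajectory_segment` with populated distances.
#' @param config A [supervision_config()].
#' @return A one-row data.frame (a window record) with columns
#'   `slope_m`, `decision`, `end_distance`, `min_distance`, `start_time`.
#' @export
supervise_window <- function(segment, config = supervision_config()) {
  stopifnot(inherits(segment, "trajectory_segment"),
            inherits(config, "supervision_config"))
  if (length(segment$distances) == 0) stop("empty segment")
  m <- window_slope(segment$times, segment$distances, config$fit_mode)
  mind <- min(segment$distances)
  decision <- if (mind < config$arrival_threshold) "arrival"
              else if (m < config$slope_threshold) "accept"
              else "reject"
  data.frame(slope_m = m, decision = decision,
             end_distance = segment$distances[length(segment$distances)],
             min_distance = mind,
             start_time = segment$times[1])
}

#' Run a supervised (SuMD) adaptive sampling simulation
#'
#' The supervision loop: simulate one unbiased window from the current
#' state; if the fitted distance slope is negative (below
#' `slope_threshold`) keep it and continue from its final coordinates and
#' velocities; otherwise restore the window's initial coordinates and
#' reassign random Maxwell-Boltzmann velocities; once the distance first
#' drops below the arrival threshold, disable supervision permanently and
#' run a classical (plain Langevin) tail. The run aborts unproductively
#' after `max_windows` attempts.
#'
#' @param system A [toy_system()].
#' @param start An [state()]; if `NULL`, a [random_start()] on a
#'   `start_distance` shell is drawn.
#' @param dyn A [dynamics_config()].
#' @param sup A [supervision_config()].
#' @param start_distance Shell radius for the default random start (A).
#' @param keep_rejected Keep the trajectory segments of rejected windows
#'   (in `$rejected_segments`, named by window index)? Default FALSE.
#' @return An object of class `"sumd_run"`: list with `segments` (accepted
#'   windows, in order), `log` (one row per attempted window:
#'   `window_index`, `slope_m`, `decision`, `end_distance`, `min_distance`,
#'   `start_time`), `productive` (logical), `total_windows_attempted`,
#'   `classical_tail` (a `trajectory_segment`, or `NULL`), `system`,
#'   and configs.
#' @seealso [run_unbiased()] for the unsupervised control,
#'   [sumd_frames()], [arrival_time()].
#' @export
#' @examples
#' sys <- build_scenario("binder", dims = 2)
#' run <- run_sumd(sys, dyn = dynamics_config(seed = 7),
#'                 sup = supervision_config(window_duration = 6,
#'                                          max_windows = 40,
#'                                          post_arrival_duration = 6))
#' run$productive
run_sumd <- function(system, start = NULL, dyn = dynamics_config(),
                     sup = supervision_config(), start_distance = 20,
                     keep_rejected = FALSE) {
  stopifnot(inherits(system, "toy_system"),
            inherits(dyn, "dynamics_config"),
            inherits(sup, "supervision_config"))
  if (sup$max_windows < 1) stop("max_windows must be >= 1")
  seed <- sup$seed %||% dyn$seed
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start))
    start <- random_start(system, start_distance, dyn$temperature)
  stopifnot(inherits(start, "md_state"))
  ## avoid re-seeding inside run_segment
  dyn_inner <- dyn; dyn_inner$seed <- NULL

  segments <- list()
  rejected <- list()
  log <- NULL
  current <- start
  productive <- FALSE
  attempted <- 0L
  traj_time <- start$time   # continuous time of the accepted trajectory

  start_dist <- sqrt(sum((start$position - system$orthosteric_center)^2))
  if (start_dist < sup$arrival_threshold) {
    productive <- TRUE
  } else {
    while (attempted < sup$max_windows) {
      attempted <- attempted + 1L
      current$time <- traj_time
      seg <- run_segment(system, current, sup$window_duration, dyn_inner)
      rec <- supervise_window(seg, sup)
      rec <- cbind(window_index = attempted, rec)
      log <- rbind(log, rec)
      if (rec$decision == "arrival") {
        segments[[length(segments) + 1L]] <- seg
        current <- segment_end_state(seg)
        traj_time <- current$time
        productive <- TRUE
        break
      } else if (rec$decision == "accept") {
        segments[[length(segments) + 1L]] <- seg
        current <- segment_end_state(seg)
        traj_time <- current$time
      } else {
        if (keep_rejected) rejected[[as.character(attempted)]] <- seg
        ## tabu-like restore: same coordinates, fresh random velocities
        current <- state(current$position,
                         sample_velocities(system, dyn$temperature),
                         traj_time)
      }
    }
  }

  tail_seg <- NULL
  if (productive && sup$post_arrival_duration >= dyn$dt) {
    current$time <- traj_time
    tail_seg <- run_segment(system, current, sup$post_arrival_duration,
                            dyn_inner)
  }

  structure(list(segments = segments, log = log, productive = productive,
                 total_windows_attempted = attempted,
                 classical_tail = tail_seg,
                 rejected_segments = if (keep_rejected) rejected,
                 system = system, dynamics = dyn, supervision = sup,
                 start = start),
            class = "sumd_run")
}

#' Run a long unsupervised simulation
#'
#' The unsupervised control for a supervised run: one long classical
#' Langevin segment with no windowing, restarts, or velocity reassignment.
#' The first recorded frame whose site distance is below
#' `arrival_threshold` defines the arrival time.
#'
#' @inheritParams run_sumd
#' @param duration Total simulated time (ps), > 0.
#' @param arrival_threshold Arrival distance (A) used only for the
#'   reported arrival time.
#' @return A `trajectory_segment` with attribute `"arrival_time"` (ps
#'   since the start, or `NA` if the ligand never arrived).
#' @export
run_unbiased <- function(system, start = NULL, duration,
                         dyn = dynamics_config(), arrival_threshold = 5.0,
                         start_distance = 20) {
  stopifnot(inherits(system, "toy_system"), inherits(dyn, "dynamics_config"))
  if (duration < dyn$dt) stop("duration must be at least one time step")
  if (!is.null(dyn$seed)) set.seed(dyn$seed)
  if (is.null(start))
    start <- random_start(system, start_distance, dyn$temperature)
  dyn_inner <- dyn; dyn_inner$seed <- NULL
  seg <- run_segment(system, start, duration, dyn_inner)
  hit <- which(seg$distances < arrival_threshold)
  attr(seg, "arrival_time") <-
    if (length(hit)) seg$times[hit[1]] - seg$times[1] else NA_real_
  seg
}

#' Concatenated accepted frames of a supervised run
#'
#' @param run A `sumd_run`.
#' @param include_tail Include the classical tail frames? Default TRUE.
#' @return A data.frame of frames (time, coordinates, distance, energies),
#'   with duplicated junction frames between consecutive segments removed.
#' @export
sumd_frames <- function(run, include_tail = TRUE) {
  stopifnot(inherits(run, "sumd_run"))
  segs <- run$segments
  if (include_tail && !is.null(run$classical_tail))
    segs <- c(segs, list(run$classical_tail))
  if (length(segs) == 0) return(NULL)
  out <- NULL
  for (s in segs) {
    df <- as.data.frame(s)
    if (!is.null(out)) df <- df[-1, , drop = FALSE]  # drop junction frame
    out <- rbind(out, df)
  }
  rownames(out) <- NULL
  out
}

#' Simulated time to first arrival of a supervised run
#'
#' Total simulated time invested before the ligand first came within the
#' arrival threshold, counting every attempted window (accepted and
#' rejected) in full and, for the arrival window, the time up to the
#' first sub-threshold frame.
#'
#' @param run A `sumd_run`.
#' @return Time (ps), or `NA` if the run was not productive.
#' @export
arrival_time <- function(run) {
  stopifnot(inherits(run, "sumd_run"))
  if (!run$productive) return(NA_real_)
  if (is.null(run$log)) return(0)   # started already inside the threshold
  i_arr <- which(run$log$decision == "arrival")
  full_before <- (run$log$window_index[i_arr] - 1) * run$supervision$window_duration
  seg <- run$segments[[length(run$segments)]]
  hit <- which(seg$distances < run$supervision$arrival_threshold)[1]
  full_before + (seg$times[hit] - seg$times[1])
}

#' @export
print.sumd_run <- function(x, ...) {
  cat("Supervised MD run:",
      if (x$productive) "productive (arrived)" else "not productive", "\n")
  cat("  windows attempted: ", x$total_windows_attempted,
      " (accepted ", length(x$segments), ")\n", sep = "")
  if (!is.null(x$log)) {
    tab <- table(x$log$decision)
    cat("  decisions: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  if (x$productive)
    cat("  simulated time to arrival: ", format(round(arrival_time(x), 2)),
        " ps\n", sep = "")
  invisible(x)
}

#' @export
summary.sumd_run <- function(object, ...) {
  fr <- sumd_frames(object)
  out <- list(productive = object$productive,
              windows_attempted = object$total_windows_attempted,
              windows_accepted = length(object$segments),
              arrival_time = arrival_time(object),
              final_distance = if (!is.null(fr)) fr$distance[nrow(fr)] else NA,
              min_distance = if (!is.null(fr)) min(fr$distance) else NA)
  class(out) <- "summary.sumd_run"
  out
}

#' @export
print.summary.sumd_run <- function(x, ...) {
  cat("Supervised MD run summary\n")
  cat("  productive:        ", x$productive, "\n")
  cat("  windows attempted: ", x$windows_attempted, "\n")
  cat("  windows accepted:  ", x$windows_accepted, "\n")
  cat("  arrival time (ps): ", format(x$arrival_time), "\n")
  cat("  final distance (A):", format(round(x$final_distance, 3)), "\n")
  cat("  min distance (A):  ", format(round(x$min_distance, 3)), "\n")
  invisible(x)
}

#' @export
plot.sumd_run <- function(x, ...) {
  fr <- sumd_frames(x)
  if (is.null(fr)) stop("run has no accepted frames to plot")
  plot(fr$time, fr$distance, type = "l", xlab = "time (ps)",
       ylab = "ligand-site distance (A)", ...)
  abline(h = x$supervision$arrival_threshold, lty = 2)
  invisible(x)
}
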