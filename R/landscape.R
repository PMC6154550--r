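#' Recognition-event energy landscape
#'
#' A 2-D histogram of trajectory frames over (ligand-site distance,
#' interaction energy), the summary used to judge whether a ligand reaches
#' deep, strongly stabilised positions near the orthosteric site or stalls
#' in more stable metastable states along the way.
#'
#' @param distances Frame distances (A).
#' @param energies Frame interaction energies (kcal/mol), same length.
#'   Stabilisation is negative by the package's sign convention.
#' @param n_distance_bins,n_energy_bins Number of bins (default 24).
#' @param distance_range,energy_range Optional c(lo, hi) ranges; default
#'   spans the data (degenerate ranges are widened by 0.5 either side).
#' @return An object of class `"landscape_grid"`: list with
#'   `distance_bin_edges`, `energy_bin_edges` and the `counts` matrix
#'   (distance bins x energy bins). `sum(counts)` equals the number of
#'   input frames.
#' @export
recognition_landscape <- function(distances, energies,
                                  n_distance_bins = 24, n_energy_bins = 24,
                                  distance_range = NULL, energy_range = NULL) {
  distances <- as.numeric(distances); energies <- as.numeric(energies)
  if (length(distances) == 0) stop("empty input series")
  if (length(energies) != length(distances))
    stop("distances and energies must have the same length")
  stopifnot(n_distance_bins >= 1, n_energy_bins >= 1)
  widen <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  dr <- widen(distance_range %||% range(distances))
  er <- widen(energy_range %||% range(energies))
  de <- seq(dr[1], dr[2], length.out = n_distance_bins + 1)
  ee <- seq(er[1], er[2], length.out = n_energy_bins + 1)
  bin_of <- function(x, edges) {
    i <- findInterval(x, edges, rightmost.closed = TRUE)
    pmin(pmax(i, 1L), length(edges) - 1L)   # clamp out-of-range values
  }
  di <- bin_of(distances, de)
  ei <- bin_of(energies, ee)
  counts <- matrix(0L, nrow = n_distance_bins, ncol = n_energy_bins)
  tab <- table(factor(di, levels = seq_len(n_distance_bins)),
               factor(ei, levels = seq_len(n_energy_bins)))
  counts[] <- as.integer(tab)
  structure(list(distance_bin_edges = de, energy_bin_edges = ee,
                 counts = counts),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat("Recognition energy landscape: ",
      nrow(x$counts), " x ", ncol(x$counts), " bins, ",
      sum(x$counts), " frames\n", sep = "")
  cat("  distance range: ", format(round(range(x$distance_bin_edges), 2))[1],
      " .. ", format(round(range(x$distance_bin_edges), 2))[2], " A\n",
      sep = "")
  cat("  energy range:   ", format(round(range(x$energy_bin_edges), 2))[1],
      " .. ", format(round(range(x$energy_bin_edges), 2))[2], " kcal/mol\n",
      sep = "")
  invisible(x)
}

#' @export
plot.landscape_grid <- function(x, ...) {
  dmid <- (head(x$distance_bin_edges, -1) + tail(x$distance_bin_edges, -1)) / 2
  emid <- (head(x$energy_bin_edges, -1) + tail(x$energy_bin_edges, -1)) / 2
  image(dmid, emid, x$counts, xlab = "ligand-site distance (A)",
        ylab = "interaction energy (kcal/mol)", ...)
  invisible(x)
}

#' Detect metastable states as distance plateaus
#'
#' Scans the trajectory for maximal time-contiguous runs during which the
#' ligand-site distance stays within `distance_tolerance` of the run's
#' running mean; runs lasting at least `min_dwell` are reported as
#' metastable states, ordered by start time.
#'
#' @param distances Frame distances (A).
#' @param energies Frame interaction energies (kcal/mol).
#' @param times Frame times (ps), strictly increasing; all three series
#'   must be aligned.
#' @param min_dwell Minimum dwell time for a state (ps), > 0.
#' @param distance_tolerance Allowed deviation from the running mean (A).
#' @return A data.frame of class `"metastable_states"` with one row per
#'   state: `mean_distance`, `distance_span`, `dwell_time`, `mean_energy`,
#'   `start_frame`, `end_frame`, `start_time`.
#' @export
find_metastable_states <- function(distances, energies, times,
                                   min_dwell, distance_tolerance = 1.0) {
  distances <- as.numeric(distances); energies <- as.numeric(energies)
  times <- as.numeric(times)
  n <- length(distances)
  if (n == 0) stop("empty input series")
  if (length(energies) != n || length(times) != n)
    stop("distances, energies and times must be aligned")
  stopifnot(min_dwell > 0, distance_tolerance > 0)
  if (n > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")

  states <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    run_sum <- distances[i]
    while (j < n) {
      mu <- run_sum / (j - i + 1)
      if (abs(distances[j + 1] - mu) > distance_tolerance) break
      j <- j + 1L
      run_sum <- run_sum + distances[j]
    }
    dwell <- times[j] - times[i]
    if (dwell >= min_dwell) {
      idx <- i:j
      states[[length(states) + 1L]] <- data.frame(
        mean_distance = mean(distances[idx]),
        distance_span = diff(range(distances[idx])),
        dwell_time = dwell,
        mean_energy = mean(energies[idx]),
        start_frame = i, end_frame = j,
        start_time = times[i])
    }
    i <- j + 1L
  }
  out <- if (length(states)) do.call(rbind, states) else
    data.frame(mean_distance = numeric(0), distance_span = numeric(0),
               dwell_time = numeric(0), mean_energy = numeric(0),
               start_frame = integer(0), end_frame = integer(0),
               start_time = numeric(0))
  class(out) <- c("metastable_states", "data.frame")
  out
}

#' Poorly populated distance intervals
#'
#' Finds contiguous distance bins whose occupancy fraction is below
#' `occupancy_threshold` and that lie strictly between two populated
#' regions — the signature of energetically unfavourable transition
#' configurations between a metastable shell and the orthosteric site.
#'
#' @param distances Frame distances (A), non-empty.
#' @param bin_width Histogram bin width (A), > 0.
#' @param occupancy_threshold Fraction in `[0, 1)`; bins strictly below it
#'   count as poorly populated. Default 0.005 (0.5% occupancy).
#' @return A data.frame with columns `low` and `high` (A), one row per
#'   merged gap interval (possibly zero rows).
#' @export
occupancy_gaps <- function(distances, bin_width, occupancy_threshold = 0.005) {
  distances <- as.numeric(distances)
  if (length(distances) == 0) stop("empty input series")
  stopifnot(bin_width > 0)
  if (!is.finite(occupancy_threshold) || occupancy_threshold < 0 ||
      occupancy_threshold >= 1)
    stop("occupancy_threshold must be in [0, 1)")
  lo <- floor(min(distances) / bin_width) * bin_width
  edges <- seq(lo, max(distances) + bin_width, by = bin_width)
  idx <- findInterval(distances, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  frac <- counts / length(distances)
  populated <- frac >= occupancy_threshold
  nb <- length(frac)
  gaps <- NULL
  in_gap <- FALSE
  gstart <- 0L
  for (b in seq_len(nb)) {
    if (!populated[b] && any(populated[seq_len(b - 1)])) {
      if (!in_gap) { in_gap <- TRUE; gstart <- b }
    } else {
      if (in_gap && populated[b]) {
        gaps <- rbind(gaps, data.frame(low = edges[gstart], high = edges[b]))
      }
      in_gap <- FALSE
    }
  }
  ## a trailing low-occupancy stretch has no populated region after it: drop
  gaps %||% data.frame(low = numeric(0), high = numeric(0))
}

#' Residence-weighted binding-path summary
#'
#' Coarse-grains a trajectory into cubic cells and summarises each visited
#' cell as a path node at its time-weighted mean position with the total
#' residence time spent in the cell. Nodes are ordered by first visit, so
#' the sequence approximates the binding pathway and node sizes encode
#' where the ligand spent its simulation time (the toy analogue of
#' pathway plots in which sphere diameters scale with time spent).
#'
#' Per-frame weights use the trapezoidal (midpoint) rule on the frame
#' times, so node residence times sum exactly to the trajectory duration.
#'
#' @param positions Matrix of frame positions (frames x dims).
#' @param times Frame times (ps), strictly increasing, aligned.
#' @param cell_size Cubic cell edge (A), > 0.
#' @param replica_id Integer tag copied to every node (default 1).
#' @return A data.frame of class `"path_nodes"`: `node`, position columns
#'   `x1..xd`, `residence_time`, `first_visit_time`, `replica_id`.
#' @export
path_summary <- function(positions, times, cell_size, replica_id = 1L) {
  if (!is.matrix(positions)) positions <- matrix(as.numeric(positions), ncol = 1)
  times <- as.numeric(times)
  n <- nrow(positions)
  if (n == 0) stop("empty trajectory")
  if (length(times) != n) stop("positions and times must be aligned")
  if (n > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  stopifnot(cell_size > 0)

  ## midpoint-rule frame weights: sum(w) == total duration
  w <- if (n == 1) 0 else {
    dtf <- diff(times)
    c(dtf[1] / 2, (head(dtf, -1) + tail(dtf, -1)) / 2, dtf[n - 1] / 2)
  }
  if (n == 1) w <- 1   # single frame: unit weight, zero duration handled below

  cells <- apply(floor(positions / cell_size), 1, paste, collapse = ",")
  first_visit <- !duplicated(cells)
  order_keys <- cells[first_visit]
  cell_f <- factor(cells, levels = order_keys)

  res <- tapply(w, cell_f, sum)
  fvt <- tapply(times, cell_f, function(t) t[1])
  d <- ncol(positions)
  mean_pos <- matrix(0, nrow = length(order_keys), ncol = d)
  for (k in seq_len(d)) {
    num <- tapply(w * positions[, k], cell_f, sum)
    den <- res
    mean_pos[, k] <- ifelse(den > 0, num / den,
                            tapply(positions[, k], cell_f, mean))
  }
  if (n == 1) res[] <- 0   # zero-duration trajectory

  out <- data.frame(node = seq_along(order_keys), mean_pos,
                    residence_time = as.numeric(res),
                    first_visit_time = as.numeric(fvt),
                    replica_id = as.integer(replica_id))
  names(out)[1 + seq_len(d)] <- paste0("x", seq_len(d))
  ## drop zero-residence nodes (e.g. an isolated final frame)
  out <- out[out$residence_time > 0 | n == 1, , drop = FALSE]
  out$node <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("path_nodes", "data.frame")
  out
}

#' Write landscape or analysis tables to CSV
#'
#' Locale-independent fixed-precision CSV writers for the analysis
#' outputs.
#'
#' @param grid A `landscape_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(grid, path) {
  stopifnot(inherits(grid, "landscape_grid"))
  dmid <- (head(grid$distance_bin_edges, -1) +
           tail(grid$distance_bin_edges, -1)) / 2
  emid <- (head(grid$energy_bin_edges, -1) +
           tail(grid$energy_bin_edges, -1)) / 2
  df <- expand.grid(distance = dmid, energy = emid)
  df$count <- as.vector(grid$counts)
  write_fixed_csv(df, path)
}
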