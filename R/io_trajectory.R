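#' Write a trajectory segment as XYZ
#'
#' Standard XYZ dialect: per frame an atom-count line (always 1, the point
#' ligand), a comment line carrying the frame time (`t= <ps> ps`), then
#' one `LIG x y z` line. Coordinates are printed to 6 decimals; systems
#' with fewer than 3 dimensions are zero-padded.
#'
#' @param segment A `trajectory_segment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(segment, path) {
  stopifnot(inherits(segment, "trajectory_segment"))
  pos <- segment$positions
  if (ncol(pos) < 3)
    pos <- cbind(pos, matrix(0, nrow = nrow(pos), ncol = 3 - ncol(pos)))
  con <- file(path, "wb")   # binary mode: LF endings on every platform
  on.exit(close(con))
  lines <- character(3 * nrow(pos))
  for (i in seq_len(nrow(pos))) {
    lines[3 * i - 2] <- "1"
    lines[3 * i - 1] <- sprintf("t= %.6f ps", segment$times[i])
    lines[3 * i] <- sprintf("LIG %.6f %.6f %.6f",
                            pos[i, 1], pos[i, 2], pos[i, 3])
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' Parses the single-pseudo-atom XYZ dialect written by [write_xyz()]
#' (and any single-atom-per-frame XYZ file). Frame times are recovered
#' from comment lines of the form `t= <time> ps` when present.
#'
#' @param path XYZ file path.
#' @return List with `positions` (frames x 3 matrix), `times` (or `NULL`
#'   if the comments carry no times) and `n_frames`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0) stop("malformed XYZ: file is empty")
  i <- 1L
  pos <- list(); times <- numeric(0)
  while (i <= length(lines)) {
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms) || natoms < 1)
      stop("malformed XYZ header at line ", i, ": '", lines[i], "'")
    if (i + 1 + natoms > length(lines))
      stop("truncated XYZ frame starting at line ", i)
    cm <- lines[i + 1]
    tm <- regmatches(cm, regexec("t=\\s*([-0-9.eE+]+)", cm))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    frame <- matrix(NA_real_, nrow = natoms, ncol = 3)
    for (a in seq_len(natoms)) {
      tok <- strsplit(trimws(lines[i + 1 + a]), "\\s+")[[1]]
      if (length(tok) < 4)
        stop("malformed XYZ atom record at line ", i + 1 + a)
      frame[a, ] <- as.numeric(tok[2:4])
    }
    if (anyNA(frame)) stop("non-numeric coordinates in frame at line ", i)
    pos[[length(pos) + 1L]] <- frame
    i <- i + 2L + natoms
  }
  natoms <- nrow(pos[[1]])
  if (any(vapply(pos, nrow, integer(1)) != natoms))
    stop("inconsistent atom counts across XYZ frames")
  positions <- do.call(rbind, lapply(pos, function(p) p[1, , drop = FALSE]))
  list(positions = positions,
       times = if (all(is.na(times))) NULL else times,
       n_frames = length(pos))
}

#' Write the per-frame series of a segment as CSV
#'
#' Columns: time, coordinates, distance, potential and interaction
#' energy, in locale-independent fixed precision.
#'
#' @param segment A `trajectory_segment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_csv <- function(segment, path) {
  stopifnot(inherits(segment, "trajectory_segment"))
  write_fixed_csv(as.data.frame(segment), path)
}

#' Read a per-frame series CSV
#'
#' Reads a CSV with at least `time`, `distance` and (optionally) energy
#' columns, as written by [write_segment_csv()] or produced externally,
#' for use with the landscape analyses.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_segment_csv <- function(path) {
  if (!file.exists(path)) stop("CSV file not found: ", path)
  df <- read.csv(path)
  if (!"time" %in% names(df)) stop("series CSV needs a 'time' column")
  df
}

## Fixed-precision, locale-independent CSV writer used for all outputs.
write_fixed_csv <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) {
    if (is.integer(df[[j]])) next
    out[[j]] <- sprintf(paste0("%.", digits, "g"), df[[j]])
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

## ---- PDB -------------------------------------------------------------------

.element_masses <- c(
  "H" = 1.008, "C" = 12.011, "N" = 14.007, "O" = 15.999, "S" = 32.06,
  "P" = 30.974, "F" = 18.998, "CL" = 35.45, "BR" = 79.904, "I" = 126.904,
  "NA" = 22.990, "MG" = 24.305, "K" = 39.098, "CA" = 40.078, "ZN" = 65.38,
  "FE" = 55.845)

#' Read coordinates and masses from a PDB file
#'
#' Extracts ATOM/HETATM coordinates matching simple chain / residue /
#' atom-name filters, with element-inferred atomic masses, e.g. to
#' compute the center of mass of a binding-site residue selection on a
#' real structure. Parsing and selection are delegated to
#' \pkg{bio3d}; the element symbol falls back to the first letter of the
#' atom name when the element column is absent.
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier(s).
#' @param resno Optional residue number(s).
#' @param resid Optional residue name(s) (e.g. `"ASN"`).
#' @param elety Optional atom name(s) (e.g. `"CA"`).
#' @return List with `coords` (atoms x 3 matrix, A), `masses` (amu) and
#'   `atoms` (the selected rows of the bio3d atom table).
#' @export
read_pdb_coords <- function(path, chain = NULL, resno = NULL, resid = NULL,
                            elety = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  args <- list(pdb)
  if (!is.null(chain)) args$chain <- chain
  if (!is.null(resno)) args$resno <- resno
  if (!is.null(resid)) args$resid <- resid
  if (!is.null(elety)) args$elety <- elety
  sel <- do.call(bio3d::atom.select, c(args, verbose = FALSE))
  if (length(sel$atom) == 0)
    stop("selection matched no atoms in ", path)
  atoms <- pdb$atom[sel$atom, , drop = FALSE]
  elem <- toupper(trimws(atoms$elesy))
  fallback <- toupper(substr(trimws(atoms$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <- fallback[is.na(elem) | elem == ""]
  masses <- .element_masses[elem]
  if (anyNA(masses))
    stop("unknown element(s): ",
         paste(unique(elem[is.na(masses)]), collapse = ", "))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(coords) <- NULL
  list(coords = coords, masses = unname(masses), atoms = atoms)
}

#' Export path nodes as PDB pseudo-atoms
#'
#' Writes one HETATM pseudo-atom per path node with the B-factor column
#' proportional to the node residence time (rescaled to a maximum of
#' 99.99), so molecular viewers can render the binding pathway as spheres
#' sized by time spent.
#'
#' @param nodes A `path_nodes` data.frame from [path_summary()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_path_pdb <- function(nodes, path) {
  stopifnot(inherits(nodes, "data.frame"), nrow(nodes) >= 1)
  xc <- grep("^x[0-9]+$", names(nodes), value = TRUE)
  pos <- as.matrix(nodes[, xc, drop = FALSE])
  if (ncol(pos) < 3)
    pos <- cbind(pos, matrix(0, nrow = nrow(pos), ncol = 3 - ncol(pos)))
  bmax <- max(nodes$residence_time)
  b <- if (bmax > 0) 99.99 * nodes$residence_time / bmax else
    rep(0, nrow(nodes))
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- sprintf(
    "HETATM%5d  C   PTH %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    nodes$node, "A", nodes$node, pos[, 1], pos[, 2], pos[, 3], 1.00, b)
  writeLines(c(lines, "END"), con)
  invisible(path)
}

## ---- PLUMED-style HILLS ----------------------------------------------------

#' Write or read hills in a PLUMED-style HILLS text layout
#'
#' Whitespace-delimited text with a `#! FIELDS` header: time, one center
#' and sigma per CV, the hill height and the bias factor. The layout is
#' interoperable with common metadynamics post-processing tools.
#'
#' @param bias A `bias_state`.
#' @param path File path.
#' @return `write_hills()` returns `path` invisibly; `read_hills()`
#'   returns a `bias_state`.
#' @export
write_hills <- function(bias, path) {
  stopifnot(inherits(bias, "bias_state"))
  ncv <- length(bias$cvs)
  labs <- vapply(seq_len(ncv), function(k)
    bias$cvs[[k]]$label %||% paste0("cv", k), character(1))
  header <- paste("#! FIELDS time", paste(labs, collapse = " "),
                  paste(paste0("sigma_", labs), collapse = " "),
                  "height biasf")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  h <- bias$hills
  if (nrow(h)) {
    ctr <- hill_centers(bias)
    body <- sprintf("%.6f", h$time)
    for (k in seq_len(ncv)) body <- paste(body, sprintf("%.9f", ctr[, k]))
    for (k in seq_len(ncv))
      body <- paste(body, sprintf("%.9f", rep(bias$sigmas[k], nrow(h))))
    body <- paste(body, sprintf("%.9f", h$height),
                  sprintf("%.3f", rep(bias$bias_factor, nrow(h))))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_hills
#' @param cvs CV definitions matching the file (labels are not enough to
#'   reconstruct a CV's geometry).
#' @param temperature Temperature (K) to record on the imported state.
#' @export
read_hills <- function(path, cvs, temperature = 298) {
  if (!file.exists(path)) stop("HILLS file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#! FIELDS"))
    stop("malformed HILLS file: missing '#! FIELDS' header")
  if (inherits(cvs, "collective_variable")) cvs <- list(cvs)
  ncv <- length(cvs)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    hills <- data.frame(time = numeric(0))
    for (k in seq_len(ncv)) hills[[paste0("center.", k)]] <- numeric(0)
    for (k in seq_len(ncv)) hills[[paste0("sigma.", k)]] <- numeric(0)
    hills$height <- numeric(0)
    return(bias_state(hills, cvs, temperature = temperature))
  }
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (ncol(mat) < 2 * ncv + 3)
    stop("HILLS file has too few columns for ", ncv, " CV(s)")
  hills <- data.frame(time = mat[, 1])
  for (k in seq_len(ncv)) hills[[paste0("center.", k)]] <- mat[, 1 + k]
  for (k in seq_len(ncv)) hills[[paste0("sigma.", k)]] <- mat[, 1 + ncv + k]
  hills$height <- mat[, 2 * ncv + 2]
  biasf <- mat[1, 2 * ncv + 3]
  bias_state(hills, cvs, sigmas = as.numeric(mat[1, (2 + ncv):(1 + 2 * ncv)]),
             bias_factor = biasf, temperature = temperature)
}

#' Write a 1-D free-energy surface as CSV
#'
#' @param fes A `metad_fes` data.frame from [estimate_fes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fes_csv <- function(fes, path) {
  write_fixed_csv(as.data.frame(fes), path)
}
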