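#' Read or write a scenario file
#'
#' Scenario files describe a [toy_system()] as YAML or JSON with keys
#' `dims`, `wells` (list of `center`/`depth`/`width`), `barriers` (list of
#' `center`/`height`/`width`), `orthosteric_center`, `ligand_mass` and
#' `confinement` (`box_halflength`, `wall_k`, optional `center`). The
#' format is chosen from the file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path File path.
#' @return `read_scenario()` returns a validated [toy_system()];
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  scenario_from_list(raw)
}

#' @rdname read_scenario
#' @param system A [toy_system()].
#' @export
write_scenario <- function(system, path) {
  stopifnot(inherits(system, "toy_system"))
  lst <- list(
    dims = system$dims,
    ligand_mass = system$ligand_mass,
    orthosteric_center = system$orthosteric_center,
    confinement = list(box_halflength = system$confinement$box_halflength,
                       wall_k = system$confinement$wall_k,
                       center = system$confinement$center),
    wells = lapply(system$wells, function(w)
      list(center = w$center, depth = w$depth, width = w$width,
           radius = w$radius)),
    barriers = lapply(system$barriers, function(b)
      list(center = b$center, height = b$height, width = b$width,
           radius = b$radius))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

scenario_from_list <- function(raw) {
  need <- c("dims", "wells", "orthosteric_center")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("scenario is missing required key(s): ", paste(miss, collapse = ", "))
  wells <- lapply(raw$wells, function(w) {
    if (is.null(w$center) || is.null(w$depth) || is.null(w$width))
      stop("each well needs center, depth and width")
    gaussian_well(unlist(w$center), w$depth, w$width, w$radius %||% 0)
  })
  barriers <- lapply(raw$barriers %||% list(), function(b) {
    if (is.null(b$center) || is.null(b$height) || is.null(b$width))
      stop("each barrier needs center, height and width")
    gaussian_barrier(unlist(b$center), b$height, b$width, b$radius %||% 0)
  })
  conf <- raw$confinement %||% list()
  toy_system(
    dims = raw$dims,
    wells = wells,
    barriers = barriers,
    orthosteric_center = unlist(raw$orthosteric_center),
    ligand_mass = raw$ligand_mass %||% 200,
    box_halflength = conf$box_halflength %||% 25,
    wall_k = conf$wall_k %||% 10,
    box_center = unlist(conf$center %||% numeric(raw$dims))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
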