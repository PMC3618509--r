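# The four-stage pipeline tying the framework together:
# 1) build or load the surface, 2) ray-cast it on the grid, 3) detect and
# optionally fill cavities, 4) triangulate consistently with the filled
# grid; plus run statistics and file outputs.

#' Default run configuration
#'
#' @return Named list of pipeline defaults (see [run_pipeline()]).
#' @export
default_config <- function() {
  list(surface = "ses", input = NULL, format = "xyzr",
       scale = 2, perfil = 90, probe_radius = 1.4, shrink = 0.45,
       blobbyness = -2.5, cutoff = 6,
       cavity_policy = "keep", min_volume = 11.49,
       mc = "analytic", smooth_iterations = 0L, smooth_lambda = 0.5,
       volume_rays = 2L, retry = 5L, seed = 1L,
       out_mesh = NULL, mesh_format = "off", out_stats = NULL,
       out_colormap = NULL, out_cavities = NULL)
}

#' Read a run configuration from a flat key=value file
#'
#' Lines of the form `key = value`; `#` comments and blank lines are
#' ignored; unknown keys are rejected.
#'
#' @param path Configuration file.
#' @return A configuration list merged over [default_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    old <- cfg[[key]]
    cfg[[key]] <- if (is.numeric(old) || is.null(old) &&
                        grepl("^[-+0-9.eE]+$", val)) {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) num else val
    } else val
  }
  cfg
}

#' Run the full surfacing pipeline
#'
#' Executes build -> ray-cast -> cavity handling -> triangulation and
#' returns the run statistics (area, volume per axis, cavities, parity
#' report, mesh counts).  Artifacts (mesh, color map, cavity report,
#' stats JSON) are written when the corresponding `out_*` entries are
#' set.
#'
#' @param config A configuration list (see [default_config()]); entries
#'   given in `...` override it.
#' @param atoms Optionally, an [atom_set()] (or a fixture's atoms) used
#'   directly instead of reading `config$input`.
#' @param mesh Optionally, a `mesh_surface` for `surface = "mesh"`.
#' @param ... Configuration overrides.
#' @return List with `stats`, `surface`, `status`, `cavities`, `mesh`.
#' @export
run_pipeline <- function(config = default_config(), atoms = NULL,
                         mesh = NULL, ...) {
  cfg <- utils::modifyList(config, list(...))
  seed <- as.integer(cfg$seed)

  # stage 1: build or load the surface
  if (cfg$surface != "mesh" && is.null(atoms)) {
    if (is.null(cfg$input)) stop("no input atoms given")
    atoms <- read_atoms(cfg$input, cfg$format)
  }
  surface <- switch(cfg$surface,
    ses = build_ses(atoms, probe_radius = cfg$probe_radius, seed = seed),
    vdw = build_vdw(atoms, seed = seed),
    sas = build_sas(atoms, probe_radius = cfg$probe_radius, seed = seed),
    skin = build_skin(atoms, shrink = cfg$shrink, seed = seed),
    gaussian = NULL,                       # needs the grid first
    mesh = {
      if (is.null(mesh)) mesh <- load_mesh_surface(cfg$input)
      mesh
    },
    stop("unknown surface definition: ", cfg$surface))
  inflate <- switch(cfg$surface, ses = , sas = cfg$probe_radius,
                    gaussian = 1, 0)
  grid <- if (cfg$surface == "mesh") {
    V <- surface$vertices
    make_grid(rbind(apply(V, 2L, min), apply(V, 2L, max)),
              scale = cfg$scale, perfil = cfg$perfil)
  } else {
    make_grid(atoms, scale = cfg$scale, perfil = cfg$perfil,
              inflate = inflate)
  }
  if (cfg$surface == "gaussian")
    surface <- build_gaussian(atoms, grid, blobbyness = cfg$blobbyness,
                              cutoff = cfg$cutoff)

  # stage 2: ray casting
  status <- cast_surface(surface, grid, retry = cfg$retry, seed = seed,
                         edge_rays = identical(cfg$mc, "analytic"))
  vol <- estimate_volume(surface, grid, rays_per_cell = cfg$volume_rays,
                         seed = seed, retry = cfg$retry)

  # stage 3: cavities
  cav <- detect_cavities(status)
  filled <- switch(cfg$cavity_policy,
                   keep = status,
                   fill_below = fill_cavities(status, cav,
                                              min_volume = cfg$min_volume),
                   fill_all = fill_cavities(status, cav, fill_all = TRUE),
                   stop("unknown cavity policy: ", cfg$cavity_policy))

  # stage 4: triangulation
  tri <- if (identical(cfg$mc, "analytic")) mc_analytic(filled) else
    mc_bisecting(filled)
  if (cfg$smooth_iterations > 0L)
    tri <- laplacian_smooth(tri, cfg$smooth_iterations, cfg$smooth_lambda)
  area <- mesh_area(tri)
  topo <- mesh_topology(tri)

  stats <- list(
    surface = cfg$surface,
    n_atoms = if (!is.null(atoms)) nrow(atoms) else NA_integer_,
    scale = cfg$scale, perfil = cfg$perfil, h = grid$h,
    grid_vertices = grid$nv[1L],
    area = area$total,
    volume_per_axis = as.list(vol$per_axis),
    volume = vol$averaged,
    cavity_count = length(cav$cavities),
    cavity_volumes = cav$table$volume_A3,
    cavities_filled = attr(filled, "fill_log") %||% integer(0),
    parity = status$report,
    vertices = nrow(tri$vertices),
    triangles = nrow(tri$triangles),
    euler = topo$euler, genus = topo$genus, closed = topo$closed,
    seed = seed)

  if (!is.null(cfg$out_mesh))
    export_mesh(tri, cfg$out_mesh, cfg$mesh_format)
  if (!is.null(cfg$out_cavities))
    write_cavity_report(cav, cfg$out_cavities)
  if (!is.null(cfg$out_colormap))
    write_colormap(color_grid(filled), cfg$out_colormap)
  if (!is.null(cfg$out_stats))
    jsonlite::write_json(stats, cfg$out_stats, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

  invisible(list(stats = stats, surface = surface, status = filled,
                 cavities = cav, mesh = tri, grid = grid))
}
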