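#' Phantom phases and background media
#'
#' A phantom is a stack of cylindrical phases inside a background medium.
#' Each phase carries a contrast element and a concentration; phases may
#' overlap, in which case their solute contributions add on top of the
#' single medium (Beer-Lambert additivity, supporting multi-stained
#' voxels).
#'
#' @param cx,cy Cylinder centre in mm, in-plane (x, y); the grid is centred
#'   on (0, 0).
#' @param radius Cylinder radius in mm (> 0).
#' @param z_range Axial extent in mm, `c(zmin, zmax)`; defaults to the full
#'   grid depth.
#' @param element Element symbol (must be present in the element table), or
#'   `NA` for an unstained phase.
#' @param concentration Solute concentration in mg/ml (>= 0).
#' @param medium Optional [medium_model()] added over the phase's own
#'   footprint (e.g. the agarose filling of a sample tube standing in air);
#'   `NULL` adds no background of its own.
#' @return An object of class `phantom_phase`.
#' @export
phantom_phase <- function(cx, cy, radius, element, concentration,
                          z_range = NULL, medium = NULL) {
  stopifnot(radius > 0, concentration >= 0)
  structure(list(cx = cx, cy = cy, radius = radius, z_range = z_range,
                 element = element, concentration = concentration,
                 medium = medium),
            class = "phantom_phase")
}

#' @rdname phantom_phase
#' @param mu_ref Medium linear attenuation in mm^-1 at `e_ref` keV.
#' @param e_ref Reference energy for the power-law medium, keV.
#' @param type `"power"` for an E^-3 power law, `"flat"` for an
#'   energy-independent medium.
#' @export
medium_model <- function(mu_ref = 0.027, e_ref = 35, type = c("power", "flat")) {
  type <- match.arg(type)
  structure(list(type = type, mu_ref = mu_ref, e_ref = e_ref),
            class = "medium_model")
}

medium_mu <- function(medium, energy_kev) {
  switch(medium$type,
    flat = rep(medium$mu_ref, length(energy_kev)),
    power = medium$mu_ref * (energy_kev / medium$e_ref)^-3
  )
}

#' Phantom grid geometry
#'
#' @param nx,ny,nz Grid dimensions in voxels.
#' @param voxel_size_um Isotropic voxel size in micrometres.
#' @return An object of class `phantom_grid`.
#' @export
phantom_grid <- function(nx = 64, ny = 64, nz = 8, voxel_size_um = 200) {
  stopifnot(nx >= 2, ny >= 2, nz >= 1, voxel_size_um > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), voxel_size_um = voxel_size_um),
            class = "phantom_grid")
}

# in-plane voxel-centre coordinates in mm, grid centred on (0,0)
grid_coords_mm <- function(grid) {
  vs <- grid$voxel_size_um / 1000
  list(
    x = (seq_len(grid$nx) - (grid$nx + 1) / 2) * vs,
    y = (seq_len(grid$ny) - (grid$ny + 1) / 2) * vs,
    z = (seq_len(grid$nz) - 0.5) * vs
  )
}

#' Build a synthetic hyperspectral phantom volume with ground truth
#'
#' Rasterises cylindrical phases onto a voxel grid (a voxel belongs to a
#' cylinder if its centre is inside; optional supersampling emulates
#' partial-volume averaging at phase boundaries) and fills each voxel's
#' spectrum with the medium attenuation plus the summed solute
#' contributions of all covering phases. Ground-truth per-element
#' concentration maps aligned with the volume are returned alongside.
#'
#' @param phases List of [phantom_phase()] objects. Phases falling outside
#'   the grid are clipped with a warning.
#' @param grid A [phantom_grid()].
#' @param axis An [energy_axis()].
#' @param medium A [medium_model()].
#' @param table An [element_table()].
#' @param supersample Integer >= 1; subdivides each voxel in-plane into
#'   `supersample^2` sample points and uses the covered fraction, so
#'   boundary voxels get fractional concentrations (partial-volume effect).
#' @return A list with `volume` (a [hyperspectral_volume()]),
#'   `concentration` (named list of 3D mg/ml arrays, one per element
#'   present), and `labels` (3D integer array; bit i set if phase i covers
#'   the voxel, stored as a plain sum of powers of two).
#' @export
build_phantom_volume <- function(phases, grid, axis,
                                 medium = medium_model(),
                                 table = element_table(),
                                 supersample = 1L) {
  stopifnot(inherits(grid, "phantom_grid"), inherits(axis, "energy_axis"))
  supersample <- as.integer(supersample)
  stopifnot(supersample >= 1L)
  co <- grid_coords_mm(grid)
  energies <- axis_energies(axis)
  nz <- grid$nz; ny <- grid$ny; nx <- grid$nx; nch <- axis$n_channels
  vs <- grid$voxel_size_um / 1000

  mu_med <- medium_mu(medium, energies)
  vol <- array(rep(mu_med, each = nz * ny * nx), dim = c(nz, ny, nx, nch))

  conc <- list()
  labels <- array(0, dim = c(nz, ny, nx))

  half_extent_x <- (nx / 2) * vs
  half_extent_y <- (ny / 2) * vs

  for (i in seq_along(phases)) {
    ph <- phases[[i]]
    if (abs(ph$cx) - ph$radius > half_extent_x ||
        abs(ph$cy) - ph$radius > half_extent_y) {
      warning(sprintf("phase %d lies entirely outside the grid; clipped", i))
      next
    }
    # in-plane coverage fraction per (y, x) voxel
    if (supersample == 1L) {
      frac <- outer(co$y, co$x,
                    function(y, x) as.numeric((x - ph$cx)^2 + (y - ph$cy)^2
                                              <= ph$radius^2))
    } else {
      off <- (seq_len(supersample) - (supersample + 1) / 2) / supersample * vs
      frac <- matrix(0, ny, nx)
      for (oy in off) for (ox in off) {
        frac <- frac + outer(co$y + oy, co$x + ox,
                             function(y, x) as.numeric((x - ph$cx)^2 +
                                                       (y - ph$cy)^2
                                                       <= ph$radius^2))
      }
      frac <- frac / supersample^2
    }
    if (all(frac == 0)) {
      warning(sprintf("phase %d covers no voxel centres; clipped", i))
      next
    }
    zmask <- if (is.null(ph$z_range)) rep(TRUE, nz) else
      (co$z >= ph$z_range[1] & co$z <= ph$z_range[2])
    if (!any(zmask)) {
      warning(sprintf("phase %d z-range outside the grid; clipped", i))
      next
    }
    cov3 <- outer(as.numeric(zmask), frac)   # (z, y, x) coverage fraction
    labels <- labels + (cov3 > 0) * 2^(i - 1)

    if (!is.null(ph$medium)) {
      vol <- vol + outer(cov3, medium_mu(ph$medium, energies))
    }
    if (!is.na(ph$element) && ph$concentration > 0) {
      elem <- element_record(ph$element, table)
      if (is.null(conc[[ph$element]])) {
        conc[[ph$element]] <- array(0, dim = c(nz, ny, nx))
      }
      conc[[ph$element]] <- conc[[ph$element]] + cov3 * ph$concentration
      mu_sol <- elemental_mu(elem, energies, 1)  # per unit concentration
      vol <- vol + outer(cov3 * ph$concentration, mu_sol)
    }
  }

  list(
    volume = hyperspectral_volume(vol, axis, grid$voxel_size_um),
    concentration = conc,
    labels = labels
  )
}

#' Built-in calibration phantom layouts
#'
#' Builds the cylinder-in-tube calibration phantom layouts for the three
#' contrast agents: aqueous I2KI at 25.3/50.6/76.0/101.2 mg/ml of iodine
#' (four containers), BaSO4 in agarose at 100/200/400 mg/ml (three
#' containers), and aqueous phosphotungstic acid (PTA) at 50/100/200 mg/ml
#' (three containers). Containers are placed symmetrically inside an
#' agarose-filled tube.
#'
#' @param agent One of `"I2KI"`, `"BaSO4"`, `"PTA"`.
#' @param grid A [phantom_grid()].
#' @param concentrations Optional override of the phase concentrations
#'   (mg/ml), one per container.
#' @param tube_medium [medium_model()] filling the tube (agarose-like by
#'   default). Build the returned phases over an air background
#'   (`medium_model(0, type = "flat")`) so the tube stands in air as in a
#'   real scan.
#' @return A list with `phases` (the tube phase followed by one
#'   [phantom_phase()] per concentration), `element` (the stain's heavy
#'   element symbol), `concentrations`, and the container geometry
#'   (`container_radius_mm`, `centres_mm`, one row per container).
#' @export
calibration_phantom <- function(agent = c("I2KI", "BaSO4", "PTA"),
                                grid = phantom_grid(),
                                concentrations = NULL,
                                tube_medium = medium_model()) {
  agent <- match.arg(agent)
  defaults <- switch(agent,
    I2KI  = list(element = "I",  conc = c(25.3, 50.6, 76.0, 101.2)),
    BaSO4 = list(element = "Ba", conc = c(100, 200, 400)),
    PTA   = list(element = "W",  conc = c(50, 100, 200))
  )
  conc <- if (is.null(concentrations)) defaults$conc else concentrations
  n <- length(conc)
  vs <- grid$voxel_size_um / 1000
  tube_r <- 0.45 * min(grid$nx, grid$ny) * vs   # tube radius, mm
  ring_r <- 0.52 * tube_r                       # container centre offset
  cont_r <- 0.30 * tube_r                       # container radius
  ang <- (seq_len(n) - 1) / n * 2 * pi + pi / 2
  tube <- phantom_phase(0, 0, tube_r, NA, 0, medium = tube_medium)
  containers <- lapply(seq_len(n), function(i) {
    phantom_phase(cx = ring_r * cos(ang[i]), cy = ring_r * sin(ang[i]),
                  radius = cont_r, element = defaults$element,
                  concentration = conc[i])
  })
  list(phases = c(list(tube), containers), element = defaults$element,
       concentrations = conc, container_radius_mm = cont_r,
       tube_radius_mm = tube_r,
       centres_mm = cbind(cx = ring_r * cos(ang), cy = ring_r * sin(ang)))
}
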