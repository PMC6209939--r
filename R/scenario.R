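#' Cylindrical target
#'
#' @param center Numeric length-2, target axis position (x, y) in meters,
#'   tank-centered coordinates.
#' @param diameter Target diameter in meters (> 0).
#' @param medium A [debye_medium()] or the string `"PEC"` for a perfect
#'   electric conductor.
#' @return An object of class `cylinder_target`.
#' @export
cylinder_target <- function(center, diameter, medium) {
  if (length(center) != 2 || any(!is.finite(center)))
    mwt_stop("center must be (x, y) in meters")
  if (diameter <= 0) mwt_stop("diameter must be > 0")
  if (!is_pec(medium) && !inherits(medium, "debye_medium"))
    mwt_stop("medium must be a debye_medium or \"PEC\"")
  structure(list(center = as.numeric(center), diameter = diameter,
                 medium = medium), class = "cylinder_target")
}

#' Imaging scenario: tanks, antenna ring, background and targets
#'
#' Geometry of the imaging tank: two concentric cylindrical tanks (inner
#' 100 mm / outer 200 mm by default), an antenna ring (130 mm, 8 antennas
#' by default), a lossy immersion background, optional cylindrical targets,
#' and the reconstruction ring (120 mm by default, i.e. 10 mm inside the
#' array to keep antenna artifacts out of the image). All lengths in meters.
#' Antenna 1 sits on the +x axis; numbering proceeds counter-clockwise.
#'
#' @param background Immersion medium, a [debye_medium()].
#' @param targets List of [cylinder_target()]s (may be empty).
#' @param tank_inner_diam,tank_outer_diam,array_diam,recon_ring_diam Meters.
#' @param n_antennas Number of ring antennas (>= 2).
#' @param antenna_start_angle Angle of antenna 1 in radians (default 0).
#' @return An object of class `mwt_scenario`.
#' @examples
#' scn <- scenario(background = get_material("glycerine90"))
#' antenna_positions(scn)
#' @export
scenario <- function(background,
                     targets = list(),
                     tank_inner_diam = 0.100,
                     tank_outer_diam = 0.200,
                     array_diam = 0.130,
                     n_antennas = 8,
                     recon_ring_diam = 0.120,
                     antenna_start_angle = 0) {
  stopifnot(inherits(background, "debye_medium"))
  if (inherits(targets, "cylinder_target")) targets <- list(targets)
  if (!all(vapply(targets, inherits, TRUE, "cylinder_target")))
    mwt_stop("targets must be a list of cylinder_target objects")
  if (!(array_diam < tank_outer_diam))
    mwt_stop("array must fit inside the outer tank")
  if (!(recon_ring_diam < array_diam))
    mwt_stop("reconstruction ring must be inside the antenna ring")
  if (n_antennas < 2) mwt_stop("need at least 2 antennas")
  for (tg in targets) {
    if (sqrt(sum(tg$center^2)) + tg$diameter / 2 > recon_ring_diam / 2)
      mwt_stop("every target must lie entirely within the reconstruction ring")
  }
  structure(list(tank_inner_diam = tank_inner_diam,
                 tank_outer_diam = tank_outer_diam,
                 array_diam = array_diam,
                 n_antennas = as.integer(n_antennas),
                 antenna_start_angle = antenna_start_angle,
                 background = background,
                 targets = targets,
                 recon_ring_diam = recon_ring_diam),
            class = "mwt_scenario")
}

#' @export
print.mwt_scenario <- function(x, ...) {
  cat(sprintf("<mwt_scenario> tanks %.0f/%.0f mm, %d antennas on %.0f mm ring, recon ring %.0f mm, %d target(s)\n",
              x$tank_inner_diam * 1e3, x$tank_outer_diam * 1e3, x$n_antennas,
              x$array_diam * 1e3, x$recon_ring_diam * 1e3, length(x$targets)))
  invisible(x)
}

#' Antenna positions on the ring
#'
#' @param scn A [scenario()].
#' @return A matrix with columns `x`, `y` (meters); row i is antenna i.
#'   Antenna 1 is at `antenna_start_angle` (default +x axis), numbering
#'   counter-clockwise.
#' @export
antenna_positions <- function(scn) {
  stopifnot(inherits(scn, "mwt_scenario"))
  ang <- scn$antenna_start_angle + 2 * pi * (seq_len(scn$n_antennas) - 1) / scn$n_antennas
  r <- scn$array_diam / 2
  cbind(x = r * cos(ang), y = r * sin(ang))
}

#' Theoretical antenna count for an imaging domain
#'
#' The degrees-of-freedom argument for ring arrays suggests the antenna
#' count should equal \eqn{2\beta\alpha}, with \eqn{\beta} the background
#' wave number and \eqn{\alpha} the imaging-domain radius. The real part of
#' the background permittivity sets the wave number.
#'
#' @param background A [debye_medium()].
#' @param freq Frequency in Hz (> 0).
#' @param imaging_radius Radius of the imaging domain in meters (>= 0).
#' @return Integer count, `max(1, ceiling(2 * beta * alpha))`.
#' @export
suggest_num_antennas <- function(background, freq, imaging_radius) {
  if (freq <= 0) mwt_stop("freq must be > 0")
  if (imaging_radius < 0) mwt_stop("imaging_radius must be >= 0")
  eps1 <- Re(eval_debye(background, freq))
  beta <- 2 * pi * freq * sqrt(eps1) / C0
  max(1L, as.integer(ceiling(2 * beta * imaging_radius)))
}

#' Uniform 2-D grid
#'
#' @param nx,ny Cell counts (>= 8).
#' @param dx Square cell size in meters.
#' @param origin (x, y) of the center of cell (1, 1), meters.
#' @return An object of class `grid2d`.
#' @export
grid2d <- function(nx, ny, dx, origin) {
  if (nx < 8 || ny < 8) mwt_stop("grid must be at least 8x8")
  if (dx <= 0) mwt_stop("dx must be > 0")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, origin = as.numeric(origin)),
            class = "grid2d")
}

#' Cell-center coordinates of a grid
#' @param grid A [grid2d()].
#' @return List with vectors `x` (length nx) and `y` (length ny).
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx,
       y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dx)
}

#' Build a grid covering the tank
#'
#' Centers a square grid on the tank covering the outer tank diameter plus
#' a margin (meant to absorb the PML cells of the forward solver).
#'
#' @param scn A [scenario()].
#' @param dx Cell size in meters.
#' @param margin_cells Extra cells on each side beyond the outer tank.
#' @return A [grid2d()] centered on the tank.
#' @export
scenario_grid <- function(scn, dx, margin_cells = 14) {
  half <- scn$tank_outer_diam / 2
  n_half <- ceiling(half / dx) + margin_cells
  n <- 2L * n_half + 1L
  grid2d(n, n, dx, origin = c(-n_half * dx, -n_half * dx))
}

#' Rasterize a scenario onto a grid
#'
#' Center-in/center-out staircase rasterization: a cell takes a target's
#' medium when its center lies inside the target disk, the background
#' otherwise. No sub-cell averaging, matching the blocky voxels the
#' inversion reconstructs.
#'
#' @param scn A [scenario()].
#' @param grid A [grid2d()] covering the tank interior.
#' @return An object of class `property_map`: per-cell rasters `eps_inf`,
#'   `delta_eps`, `tau`, `sigma_s` (nx x ny matrices) and logical `pec`.
#' @export
rasterize <- function(scn, grid) {
  stopifnot(inherits(scn, "mwt_scenario"), inherits(grid, "grid2d"))
  ax <- grid_axes(grid)
  if (max(ax$x) < scn$tank_outer_diam / 2 || min(ax$x) > -scn$tank_outer_diam / 2 ||
      max(ax$y) < scn$tank_outer_diam / 2 || min(ax$y) > -scn$tank_outer_diam / 2)
    mwt_stop("grid does not cover the tank interior")
  bg <- scn$background
  dims <- c(grid$nx, grid$ny)
  pm <- list(grid = grid,
             eps_inf  = matrix(bg$eps_inf, dims[1], dims[2]),
             delta_eps = matrix(bg$delta_eps, dims[1], dims[2]),
             tau      = matrix(bg$tau, dims[1], dims[2]),
             sigma_s  = matrix(bg$sigma_s, dims[1], dims[2]),
             pec      = matrix(FALSE, dims[1], dims[2]))
  X <- outer(ax$x, rep(1, grid$ny))
  Y <- outer(rep(1, grid$nx), ax$y)
  for (tg in scn$targets) {
    inside <- (X - tg$center[1])^2 + (Y - tg$center[2])^2 <= (tg$diameter / 2)^2
    if (is_pec(tg$medium)) {
      pm$pec[inside] <- TRUE
    } else {
      m <- tg$medium
      pm$eps_inf[inside] <- m$eps_inf
      pm$delta_eps[inside] <- m$delta_eps
      pm$tau[inside] <- m$tau
      pm$sigma_s[inside] <- m$sigma_s
    }
  }
  class(pm) <- "property_map"
  pm
}

#' Indices of inversion voxels (cells inside the reconstruction ring)
#'
#' @param scn A [scenario()].
#' @param grid A [grid2d()].
#' @return Integer matrix with columns `i`, `j` (1-based cell indices) for
#'   cells whose centers lie inside the reconstruction ring.
#' @export
recon_voxels <- function(scn, grid) {
  ax <- grid_axes(grid)
  X <- outer(ax$x, rep(1, grid$ny))
  Y <- outer(rep(1, grid$nx), ax$y)
  idx <- which(X^2 + Y^2 < (scn$recon_ring_diam / 2)^2, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

medium_to_json <- function(m) {
  if (is_pec(m)) return(list(pec = TRUE))
  list(eps_inf = m$eps_inf, delta_eps = m$delta_eps,
       tau_ps = m$tau * 1e12, sigma_s = m$sigma_s, name = m$name)
}

medium_from_json <- function(e) {
  if (isTRUE(e$pec)) return("PEC")
  if (!is.null(e$material)) return(get_material(e$material))
  debye_medium(e$eps_inf, e$delta_eps, e$tau_ps * 1e-12, e$sigma_s,
               name = e$name)
}

#' Read / write a scenario as JSON
#'
#' User-facing lengths are millimeters in the JSON document; media are given
#' inline as Debye parameters or by library name (`"material": "water"`).
#' @param scn A [scenario()].
#' @param path File path.
#' @return `read_scenario_json` returns a [scenario()].
#' @export
write_scenario_json <- function(scn, path) {
  doc <- list(
    schema = "mwtomo/scenario/v1",
    tank_inner_diam_mm = scn$tank_inner_diam * 1e3,
    tank_outer_diam_mm = scn$tank_outer_diam * 1e3,
    array_diam_mm = scn$array_diam * 1e3,
    n_antennas = scn$n_antennas,
    antenna_start_angle_rad = scn$antenna_start_angle,
    recon_ring_diam_mm = scn$recon_ring_diam * 1e3,
    background = medium_to_json(scn$background),
    targets = lapply(scn$targets, function(tg)
      list(center_mm = tg$center * 1e3, diameter_mm = tg$diameter * 1e3,
           medium = medium_to_json(tg$medium))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  doc <- jsonlite::read_json(path)
  targets <- lapply(doc$targets, function(tg)
    cylinder_target(unlist(tg$center_mm) * 1e-3, tg$diameter_mm * 1e-3,
                    medium_from_json(tg$medium)))
  scenario(background = medium_from_json(doc$background),
           targets = targets,
           tank_inner_diam = doc$tank_inner_diam_mm * 1e-3,
           tank_outer_diam = doc$tank_outer_diam_mm * 1e-3,
           array_diam = doc$array_diam_mm * 1e-3,
           n_antennas = doc$n_antennas,
           recon_ring_diam = doc$recon_ring_diam_mm * 1e-3,
           antenna_start_angle = doc$antenna_start_angle_rad %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default single- and two-target demonstration scenarios
#'
#' The single-target layout places a 16 mm cylinder 30 mm from the tank
#' center along the first-quadrant diagonal; the two-target layout adds an
#' identical cylinder point-symmetrically in the third quadrant.
#'
#' @param target_medium Medium for the target(s); default library water.
#' @param background Immersion medium; default library 90% glycerine-water.
#' @param two_targets Add the symmetric second target.
#' @param recon_ring_diam Reconstruction ring diameter (m).
#' @return A [scenario()].
#' @export
demo_scenario <- function(target_medium = get_material("water"),
                          background = get_material("glycerine90"),
                          two_targets = FALSE,
                          recon_ring_diam = 0.120) {
  c1 <- 0.030 / sqrt(2) * c(1, 1)
  targets <- list(cylinder_target(c1, 0.016, target_medium))
  if (two_targets)
    targets <- c(targets, list(cylinder_target(-c1, 0.016, target_medium)))
  scenario(background = background, targets = targets,
           recon_ring_diam = recon_ring_diam)
}
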