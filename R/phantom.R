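#' Ellipse phantom specification
#'
#' Parameterizes the water-equivalent elliptical phantom with a C-shaped
#' target surrounding a central circular OAR. The elliptical outline makes
#' the water-equivalent path length to the target direction-dependent,
#' mimicking a patient body contour. Lengths are in cm except `voxel_size`
#' (mm).
#'
#' @param semi_major,semi_minor ellipse semi-axes (cm); the major axis lies
#'   along x (lateral), the minor axis along y (anterior-posterior).
#' @param target_outer_radius outer radius of the C-shaped target annulus (cm).
#' @param oar_radius radius of the central OAR disk (cm).
#' @param gap radial separation between OAR and target inner edge (cm).
#' @param target_rsp,oar_rsp relative stopping power inside target / OAR.
#'   For these near-water media the quoted mass densities are used directly
#'   as RSP.
#' @param c_opening_angle full angular width of the C opening wedge
#'   (degrees); 0 gives a closed annulus.
#' @param c_opening_direction azimuth the opening faces, degrees
#'   counter-clockwise from +x in the axial plane.
#' @param voxel_size isotropic voxel size (mm).
#' @param slab_thickness extent of the phantom along the superior-inferior
#'   (z) axis (cm); the 2-D section is extruded over this thickness.
#' @param air_padding air margin added around the body on every side (cm).
#' @param body_rsp,air_rsp RSP of the body interior and of surrounding air.
#'   Air is slightly above zero so log/ratio operations stay safe.
#' @return object of class `ellipse_phantom_spec`.
#' @export
ellipse_phantom_spec <- function(semi_major = 15, semi_minor = 10,
                                 target_outer_radius = 3, oar_radius = 1,
                                 gap = 0.5, target_rsp = 1.01, oar_rsp = 0.99,
                                 c_opening_angle = 90,
                                 c_opening_direction = 0,
                                 voxel_size = 2, slab_thickness = 2,
                                 air_padding = 1,
                                 body_rsp = 1.0, air_rsp = 0.001) {
  spec <- list(semi_major = semi_major, semi_minor = semi_minor,
               target_outer_radius = target_outer_radius,
               oar_radius = oar_radius, gap = gap,
               target_rsp = target_rsp, oar_rsp = oar_rsp,
               c_opening_angle = c_opening_angle,
               c_opening_direction = c_opening_direction,
               voxel_size = voxel_size, slab_thickness = slab_thickness,
               air_padding = air_padding,
               body_rsp = body_rsp, air_rsp = air_rsp)
  lengths <- c(semi_major, semi_minor, target_outer_radius, oar_radius, gap,
               voxel_size, slab_thickness)
  if (any(!is.finite(unlist(spec))) || any(lengths <= 0))
    stop("ellipse_phantom_spec: all lengths must be finite and > 0")
  if (oar_radius + gap >= target_outer_radius)
    stop("ellipse_phantom_spec: need oar_radius + gap < target_outer_radius")
  if (target_outer_radius >= min(semi_major, semi_minor))
    stop("ellipse_phantom_spec: target must fit inside the body ellipse")
  # geometry must be resolvable on the grid
  if (voxel_size / 10 > min(gap, oar_radius,
                            target_outer_radius - oar_radius - gap))
    stop("ellipse_phantom_spec: voxel_size ", voxel_size,
         " mm cannot resolve the smallest geometric feature (",
         10 * min(gap, oar_radius, target_outer_radius - oar_radius - gap),
         " mm)")
  structure(spec, class = "ellipse_phantom_spec")
}

#' Build the ellipse phantom image and structure set
#'
#' Produces the voxelized RSP image (body = 1.0, target/OAR at their
#' specified RSP, air outside the body) and the masks: `body` (ellipse
#' interior over the slab), `oar` (central disk), `ptv` (annulus between
#' `oar_radius + gap` and `target_outer_radius` minus the C-opening wedge).
#' (alpha/beta)_x is 10 Gy for the target and 3 Gy for OAR and body.
#' A voxel belongs to a region when its centre does.
#'
#' @param spec an [ellipse_phantom_spec()].
#' @return list with elements `image` (`image3`) and `structures`
#'   (`structure_set`).
#' @export
build_ellipse_phantom <- function(spec = ellipse_phantom_spec()) {
  stopifnot(inherits(spec, "ellipse_phantom_spec"))
  dx <- spec$voxel_size            # mm
  pad <- spec$air_padding * 10     # mm
  half_x <- spec$semi_major * 10 + pad
  half_y <- spec$semi_minor * 10 + pad
  half_z <- spec$slab_thickness * 10 / 2 + pad
  nx <- ceiling(2 * half_x / dx); ny <- ceiling(2 * half_y / dx)
  nz <- ceiling(2 * half_z / dx)
  # grid centred on the phantom centre (= isocentre at the origin)
  origin <- -c(nx - 1, ny - 1, nz - 1) / 2 * dx
  xs <- origin[1] + (seq_len(nx) - 1) * dx
  ys <- origin[2] + (seq_len(ny) - 1) * dx
  zs <- origin[3] + (seq_len(nz) - 1) * dx

  # 2-D section in cm
  xc <- xs / 10; yc <- ys / 10
  X <- matrix(xc, nx, ny); Y <- matrix(yc, nx, ny, byrow = TRUE)
  in_ellipse <- (X / spec$semi_major)^2 + (Y / spec$semi_minor)^2 <= 1
  r2 <- X^2 + Y^2
  in_oar <- r2 <= spec$oar_radius^2
  inner <- spec$oar_radius + spec$gap
  in_annulus <- r2 >= inner^2 & r2 <= spec$target_outer_radius^2
  if (spec$c_opening_angle > 0) {
    ang <- atan2(Y, X) * 180 / pi - spec$c_opening_direction
    ang <- ((ang + 180) %% 360) - 180          # wrap to (-180, 180]
    in_wedge <- abs(ang) <= spec$c_opening_angle / 2
    in_target2d <- in_annulus & !in_wedge
  } else {
    in_target2d <- in_annulus
  }

  in_slab <- abs(zs) <= spec$slab_thickness * 10 / 2
  extrude <- function(m2d) {
    a <- array(FALSE, dim = c(nx, ny, nz))
    for (k in which(in_slab)) a[, , k] <- m2d
    a
  }
  body <- extrude(in_ellipse)
  oar <- extrude(in_oar)
  ptv <- extrude(in_target2d)

  vals <- array(spec$air_rsp, dim = c(nx, ny, nz))
  vals[body] <- spec$body_rsp
  vals[ptv] <- spec$target_rsp
  vals[oar] <- spec$oar_rsp

  img <- image3(vals, spacing = rep(dx, 3), origin = origin)
  strs <- structure_set(
    masks = list(body = body, ptv = ptv, oar = oar),
    alpha_beta = c(ptv = 10, oar = 3, body = 3),
    target = "ptv"
  )
  list(image = img, structures = strs, spec = spec)
}

#' Uniform box phantom (test fixture generator)
#'
#' A rectangular water-equivalent box with a centred rectangular target,
#' useful for analytic checks (flat WEPL, known chord lengths).
#'
#' @param size_cm length-3 box size (cm).
#' @param target_size_cm length-3 target size (cm), centred.
#' @param voxel_size mm.
#' @param rsp,target_rsp,air_rsp RSP assignments.
#' @param air_padding cm of air around the box.
#' @return list(image, structures) as for [build_ellipse_phantom()].
#' @export
build_box_phantom <- function(size_cm = c(10, 10, 4),
                              target_size_cm = c(3, 3, 2),
                              voxel_size = 2, rsp = 1.0, target_rsp = 1.0,
                              air_rsp = 0.001, air_padding = 0.5) {
  dx <- voxel_size
  # integer voxel counts so box faces land on voxel boundaries and the
  # water-equivalent thickness equals the nominal size exactly
  nb <- round(size_cm * 10 / dx)
  npad <- pmax(1, ceiling(air_padding * 10 / dx))
  n <- nb + 2 * npad
  origin <- -(n - 1) / 2 * dx
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(n[a]) - 1) * dx)
  inside <- function(hs) {
    keep <- lapply(1:3, function(a) abs(ax[[a]]) <= hs[a] * 10 - dx / 4)
    outer(outer(keep[[1]], keep[[2]], "&"), keep[[3]], "&")
  }
  body <- inside(size_cm / 2)
  tgt <- inside(target_size_cm / 2)
  vals <- array(air_rsp, dim = n)
  vals[body] <- rsp
  vals[tgt] <- target_rsp
  img <- image3(vals, spacing = rep(dx, 3), origin = origin)
  strs <- structure_set(masks = list(body = body, ptv = tgt),
                        alpha_beta = c(ptv = 10, body = 3), target = "ptv")
  list(image = img, structures = strs)
}
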