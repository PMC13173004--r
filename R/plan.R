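# Plan container and the three strategy builders (mid-range arc, full-range
# arc, static-field IMPT). A plan couples beam geometry with per-control-
# point spot lists (BEV coordinates, energy, nonnegative weight) and the
# prescription; spot weights start at 1 and are replaced by the optimizer.

new_pat_plan <- function(cps, spots, prescription, fractions, strategy,
                         geometry = NULL, empty_cps = integer(0)) {
  stopifnot(all(spots$cp %in% seq_along(cps)), all(spots$weight >= 0))
  structure(list(cps = cps, spots = spots, prescription = prescription,
                 fractions = fractions, strategy = strategy,
                 geometry = geometry, empty_cps = empty_cps),
            class = "pat_plan")
}

#' @exportS3Method base::print
print.pat_plan <- function(x, ...) {
  cat(sprintf("<pat_plan> %s: %d control points, %d spots, %d energy layers\n",
              x$strategy, length(x$cps), nrow(x$spots),
              sum(!duplicated(x$spots[c("cp", "energy")]))),
      sprintf("  prescription %g Gy in %d fractions\n",
              x$prescription, x$fractions))
  invisible(x)
}

# place spots and gather per-position traces/intervals for every control
# point; shared by the strategy builders
.survey_cps <- function(image, structures, cps, spacing, margin) {
  tmask <- structures$masks[[structures$target]]
  lapply(cps, function(cp)
    place_spots_bev(image, tmask, cp, spacing = spacing, margin = margin))
}

#' Build a mid-range arc plan
#'
#' One energy layer per control point, at the aggregated mid-range of the
#' target-intersecting spot rays. Control points whose rays all miss the
#' target are flagged empty and carry no spots.
#'
#' @param image an `image3`.
#' @param structures a `structure_set`.
#' @param geometry an [arc_geometry()].
#' @param machine a `machine_model`.
#' @param config an [mrel_config()].
#' @param spot_spacing BEV lattice pitch in mm.
#' @param margin lateral margin in mm (0: mid-range spots stay within the
#'   target projection).
#' @param prescription total prescription dose in Gy.
#' @param fractions number of fractions.
#' @return a `pat_plan` (strategy `"mrpat"`).
#' @export
plan_mrpat <- function(image, structures, geometry = arc_geometry(),
                       machine = machine_model(), config = mrel_config(),
                       spot_spacing = 3, margin = 0,
                       prescription = 20, fractions = 10) {
  cps <- make_arc(geometry)
  sv <- .survey_cps(image, structures, cps, spot_spacing, margin)
  rows <- list(); empty <- integer(0)
  for (ic in seq_along(cps)) {
    pos <- sv[[ic]]
    ivs <- attr(pos, "intervals")
    E <- select_mrel(ivs, machine, config)
    if (is.na(E) || nrow(pos) == 0) { empty <- c(empty, ic); next }
    rows[[length(rows) + 1]] <- data.frame(
      cp = ic, a = pos$a, b = pos$b, energy = E,
      range = range_from_energy(E, machine), weight = 1)
  }
  if (length(rows) == 0) stop("plan_mrpat: no control point sees the target")
  new_pat_plan(cps, do.call(rbind, rows), prescription, fractions,
               "mrpat", geometry, empty)
}

# spot rows for one control point under full-range enumeration: a layer
# gets a spot at a lattice position only where the layer's range lies
# inside target tissue along that ray (union of target WEPL segments);
# positions whose segments catch no layer fall back to their nearest layer
# so no intersecting ray is left uncovered
.fullrange_rows <- function(ic, pos, layers, machine) {
  if (length(layers) == 0 || nrow(pos) == 0) return(NULL)
  ivs <- attr(pos, "intervals")
  lr <- range_from_energy(layers, machine)
  out <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    iv <- ivs[[i]]
    if (is.null(iv)) next
    seg <- iv$segments
    inside <- rep(FALSE, length(lr))
    for (s in seq_len(nrow(seg)))
      inside <- inside | (lr >= seg[s, 1] & lr <= seg[s, 2])
    if (!any(inside))
      inside[which.min(abs(lr - mid_range(iv, 0.5)))] <- TRUE
    es <- layers[inside]
    out[[i]] <- data.frame(cp = ic, a = pos$a[i], b = pos$b[i], energy = es,
                           range = lr[inside], weight = 1)
  }
  do.call(rbind, out)
}

#' Build a full-range arc plan ("full-arc" comparator)
#'
#' Every deliverable energy in each control point's target envelope, with
#' spots wherever the layer's range lies inside target tissue along the
#' spot ray.
#'
#' @inheritParams plan_mrpat
#' @return a `pat_plan` (strategy `"fullarc"`).
#' @export
plan_fullarc <- function(image, structures, geometry = arc_geometry(),
                         machine = machine_model(), spot_spacing = 3,
                         margin = 0, prescription = 20, fractions = 10) {
  cps <- make_arc(geometry)
  sv <- .survey_cps(image, structures, cps, spot_spacing, margin)
  rows <- list(); empty <- integer(0)
  for (ic in seq_along(cps)) {
    layers <- enumerate_full_arc_layers(attr(sv[[ic]], "intervals"), machine)
    r <- .fullrange_rows(ic, sv[[ic]], layers, machine)
    if (is.null(r)) { empty <- c(empty, ic); next }
    rows[[length(rows) + 1]] <- r
  }
  if (length(rows) == 0) stop("plan_fullarc: no control point sees the target")
  new_pat_plan(cps, do.call(rbind, rows), prescription, fractions,
               "fullarc", geometry, empty)
}

#' Build a static-beam IMPT plan
#'
#' Full-range layer stacks on a small number of static beams (default: two
#' lateral-opposed fields).
#'
#' @inheritParams plan_mrpat
#' @param angles gantry angles of the static beams (degrees).
#' @return a `pat_plan` (strategy `"impt"`).
#' @export
plan_impt <- function(image, structures, angles = c(90, 270),
                      machine = machine_model(), spot_spacing = 3,
                      margin = 0, prescription = 20, fractions = 10,
                      isocenter = c(0, 0, 0)) {
  cps <- make_static_beams(angles, isocenter)
  sv <- .survey_cps(image, structures, cps, spot_spacing, margin)
  per_beam <- select_impt_layers(lapply(sv, attr, "intervals"), machine)
  rows <- list()
  for (ic in seq_along(cps)) {
    r <- .fullrange_rows(ic, sv[[ic]], per_beam[[ic]], machine)
    if (is.null(r)) stop("plan_impt: beam ", ic, " has no usable spots")
    rows[[length(rows) + 1]] <- r
  }
  new_pat_plan(cps, do.call(rbind, rows), prescription, fractions,
               "impt", NULL)
}

#' Serialize a plan to JSON
#'
#' Geometry (angles in degrees, vectors in the image mm frame), spots
#' (cp, a, b, energy, weight) and prescription round-trip losslessly.
#'
#' @param plan a `pat_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  obj <- list(
    strategy = plan$strategy,
    prescription = plan$prescription,
    fractions = plan$fractions,
    control_points = lapply(plan$cps, function(cp)
      list(index = cp$index, gantry_angle = cp$gantry_angle,
           direction = cp$direction, u = cp$u, v = cp$v,
           isocenter = cp$isocenter)),
    geometry = if (!is.null(plan$geometry)) unclass(plan$geometry),
    empty_cps = plan$empty_cps,
    spots = as.list(plan$spots)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plan written by [write_plan_json()]
#'
#' @param path JSON path.
#' @return a `pat_plan`.
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cps <- lapply(seq_len(nrow(obj$control_points)), function(i) {
    row <- obj$control_points[i, ]
    structure(list(index = row$index, gantry_angle = row$gantry_angle,
                   direction = unlist(row$direction), u = unlist(row$u),
                   v = unlist(row$v), isocenter = unlist(row$isocenter)),
              class = "control_point")
  })
  geometry <- if (!is.null(obj$geometry))
    structure(obj$geometry, class = "arc_geometry")
  new_pat_plan(cps, as.data.frame(obj$spots), obj$prescription,
               obj$fractions, obj$strategy, geometry,
               as.integer(obj$empty_cps))
}
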