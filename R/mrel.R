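# Energy-layer selection strategies.
#
# The mid-range strategy assigns each control point a single energy layer
# whose in-water range equals an aggregate (default: median) of the per-spot
# mid-range points R_p + alpha * (R_d - R_p); with alpha = 1/2 the Bragg
# peaks sit at the water-equivalent centre of the target along each ray,
# leaving proximal and distal buffers against range error. alpha = 1
# reproduces distal-edge tracking. The full-range comparator enumerates
# every deliverable energy whose range falls in the control point's
# [min R_p, max R_d] envelope.

#' Mid-range selection configuration
#'
#' @param alpha range scaling factor in (0, 1]; 1/2 places peaks at the
#'   target mid-point, 1 tracks the distal edge.
#' @param aggregation statistic over per-spot mid ranges: `"median"`
#'   (even counts break to the lower central value, biasing peaks slightly
#'   proximal) or `"mean"`.
#' @return object of class `mrel_config`.
#' @export
mrel_config <- function(alpha = 0.5, aggregation = c("median", "mean")) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("mrel_config: alpha must lie in (0, 1]")
  structure(list(alpha = alpha, aggregation = match.arg(aggregation)),
            class = "mrel_config")
}

#' Mid-range point of a target range interval
#'
#' @param interval a `range_interval`.
#' @param alpha range scaling factor in (0, 1].
#' @return `R_p + alpha * (R_d - R_p)` in cm water.
#' @export
mid_range <- function(interval, alpha = 0.5) {
  stopifnot(inherits(interval, "range_interval"))
  interval$R_p + alpha * interval$dR
}

# lower-of-two median: for even counts return the lower central value
.low_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' Select the single mid-range energy layer for a control point
#'
#' Computes the mid-range point of every target-intersecting spot ray,
#' aggregates them (median by default), converts the aggregate range to
#' energy, and snaps to the deliverable list. All spots of the control
#' point carry this single energy.
#'
#' @param intervals list of `range_interval` objects (NULL entries = rays
#'   that miss the target are ignored).
#' @param machine a `machine_model`.
#' @param config an [mrel_config()].
#' @return deliverable energy in MeV, or `NA_real_` when no ray intersects
#'   the target (the control point is flagged empty and excluded from
#'   delivery sequencing by the plan builders).
#' @export
select_mrel <- function(intervals, machine, config = mrel_config()) {
  ivs <- Filter(Negate(is.null), intervals)
  if (length(ivs) == 0) return(NA_real_)
  mids <- vapply(ivs, mid_range, numeric(1), alpha = config$alpha)
  m <- switch(config$aggregation,
              median = .low_median(mids),
              mean = mean(mids))
  # clamp to the machine's achievable range interval (a target shallower
  # than the minimum energy's range snaps to the lowest deliverable layer)
  lim <- range_from_energy(range(machine$energy_list), machine)
  m <- min(max(m, lim[1]), lim[2])
  nearest_deliverable_energy(energy_from_range(m, machine), machine)
}

#' Enumerate all deliverable energy layers for a control point
#'
#' Full-range ("full-arc") enumeration: every machine energy whose in-water
#' range lies within the control point's target envelope
#' `[min R_p, max R_d]` over its spot rays. At least one layer is always
#' returned (the nearest deliverable to the envelope midpoint when the
#' envelope is narrower than the local energy granularity).
#'
#' @param intervals list of `range_interval` objects (NULLs ignored).
#' @param machine a `machine_model`.
#' @return ascending numeric vector of energies (MeV), or `numeric(0)` when
#'   no ray intersects the target.
#' @export
enumerate_full_arc_layers <- function(intervals, machine) {
  ivs <- Filter(Negate(is.null), intervals)
  if (length(ivs) == 0) return(numeric(0))
  rp <- min(vapply(ivs, `[[`, numeric(1), "R_p"))
  rd <- max(vapply(ivs, `[[`, numeric(1), "R_d"))
  rng <- range_from_energy(machine$energy_list, machine)
  sel <- machine$energy_list[rng >= rp & rng <= rd]
  if (length(sel) == 0)
    sel <- nearest_deliverable_energy(
      energy_from_range((rp + rd) / 2, machine), machine)
  sort(sel)
}

#' Per-beam full-range energy lists for the IMPT comparator
#'
#' @param intervals_per_beam list (one element per static beam) of lists of
#'   `range_interval` objects.
#' @param machine a `machine_model`.
#' @return list of ascending energy vectors, one per beam.
#' @export
select_impt_layers <- function(intervals_per_beam, machine) {
  if (length(intervals_per_beam) < 1)
    stop("select_impt_layers: need at least one beam")
  out <- lapply(seq_along(intervals_per_beam), function(i) {
    e <- enumerate_full_arc_layers(intervals_per_beam[[i]], machine)
    if (length(e) == 0)
      stop("select_impt_layers: beam ", i, " does not intersect the target")
    e
  })
  out
}
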