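# Scenario-based robustness evaluation: the eight standard uncertainty
# scenarios (range: uniform +-3% scaling of all stopping-power ratios;
# setup: +-3 mm rigid shifts along each anatomical axis), recomputed with
# the frozen nominal spot weights and normalization.

#' A perturbation scenario
#'
#' Exactly one of `rsp_scale != 1` (range scenario) or `shift != 0` (setup
#' scenario) for non-nominal scenarios; the nominal scenario is
#' `(1, c(0,0,0))`.
#'
#' @param label scenario label.
#' @param rsp_scale uniform multiplicative factor on all RSP values.
#' @param shift rigid patient shift in mm (x, y, z).
#' @return object of class `scenario`.
#' @export
scenario <- function(label, rsp_scale = 1, shift = c(0, 0, 0)) {
  structure(list(label = label, rsp_scale = rsp_scale,
                 shift = as.numeric(shift)),
            class = "scenario")
}

#' Generate the uncertainty scenario set
#'
#' Two range scenarios (RSP scaled by 1 +- range_pct/100, shifting every
#' Bragg peak by -+ that fraction of its depth) plus six setup scenarios
#' (+-shift_mm along each of the three axes) = eight scenarios; the nominal
#' scenario is carried separately by [nominal_scenario()].
#'
#' @param range_pct range uncertainty in percent.
#' @param shift_mm setup shift magnitude in mm.
#' @return list of 8 `scenario` objects.
#' @export
make_scenarios <- function(range_pct = 3, shift_mm = 3) {
  stopifnot(range_pct >= 0, shift_mm >= 0)
  sc <- list(
    scenario("range+", rsp_scale = 1 + range_pct / 100),
    scenario("range-", rsp_scale = 1 - range_pct / 100)
  )
  axes <- c("x", "y", "z")
  for (a in 1:3) for (s in c(1, -1)) {
    sh <- c(0, 0, 0); sh[a] <- s * shift_mm
    sc[[length(sc) + 1]] <- scenario(
      paste0("shift", c("+", "-")[(3 - s) / 2], axes[a]), shift = sh)
  }
  sc
}

#' @rdname make_scenarios
#' @export
nominal_scenario <- function() scenario("nominal")

#' Recompute dose/LET under a perturbation scenario
#'
#' Range scenarios multiply every RSP value before WEPL/dose/LET
#' computation (+3% SPR means shorter geometric ranges); setup scenarios
#' rigidly translate image and structures relative to the fixed beam
#' geometry. Spot weights, energies, and the nominal normalization are
#' frozen — nothing is re-optimized or re-normalized.
#'
#' @param plan optimized, normalized `pat_plan`.
#' @param image nominal `image3`.
#' @param structures `structure_set` (rides with the image under shifts).
#' @param sc a `scenario`.
#' @param machine a `machine_model`.
#' @param ... passed to [accumulate()].
#' @return a `dose_let` on the (possibly shifted) image grid.
#' @export
apply_scenario <- function(plan, image, structures, sc,
                           machine = machine_model(), ...) {
  stopifnot(inherits(sc, "scenario"))
  img <- image
  if (sc$rsp_scale != 1) img$values <- img$values * sc$rsp_scale
  if (any(sc$shift != 0)) {
    img$origin <- img$origin + sc$shift
    # the target must stay inside the dose grid relative to the beams
    tidx <- which(structures$masks[[structures$target]])
    i3 <- arrayInd(tidx, image$dims)
    box <- rbind(apply(i3, 2, min), apply(i3, 2, max))
    b <- image_bounds(image)
    pts <- sweep(sweep(box - 1, 2, img$spacing, "*"), 2, img$origin, "+")
    if (any(sweep(pts, 2, b[1, ], "<")) || any(sweep(pts, 2, b[2, ], ">")))
      stop("apply_scenario: shift ", paste(sc$shift, collapse = "/"),
           " mm pushes the target outside the dose grid [",
           paste(round(b[1, ]), collapse = ", "), "] - [",
           paste(round(b[2, ]), collapse = ", "), "] mm")
  }
  accumulate(plan, img, machine, ...)
}

#' DVH band envelope and worst-case summary over scenarios
#'
#' Per dose bin, the min and max cumulative volume over the scenario DVHs
#' (the shaded robustness band); worst case is taken per metric, not per
#' scenario: coverage metrics worst = min over scenarios, hotspot metrics
#' worst = max.
#'
#' @param dvhs list of `dvh` objects (one per scenario) for one structure.
#' @return list with `edges`, `lo`, `hi` (band), and `n_scenarios`.
#' @export
summarize_band <- function(dvhs) {
  stopifnot(length(dvhs) >= 1)
  bin <- dvhs[[1]]$edges[2] - dvhs[[1]]$edges[1]
  emax <- max(vapply(dvhs, function(d) max(d$edges), numeric(1)))
  edges <- seq(0, emax, by = bin)
  curves <- vapply(dvhs, function(d) {
    stats::approx(d$edges, d$cumfrac, xout = edges, yleft = 1, yright = 0)$y
  }, numeric(length(edges)))
  list(edges = edges,
       lo = apply(curves, 1, min), hi = apply(curves, 1, max),
       n_scenarios = length(dvhs))
}

#' Worst-case and spread of a metric across scenarios
#'
#' @param values numeric metric values, one per scenario.
#' @param direction `"coverage"` (worst = min, e.g. target D95) or
#'   `"hotspot"` (worst = max, e.g. OAR D2).
#' @return list with `worst`, `median`, `p5`, `p95`.
#' @export
worst_case_metric <- function(values, direction = c("coverage", "hotspot")) {
  direction <- match.arg(direction)
  qs <- stats::quantile(values, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  list(worst = if (direction == "coverage") min(values) else max(values),
       median = qs[2], p5 = qs[1], p95 = qs[3])
}

#' Fraction of delivered Bragg peaks confined within the target
#'
#' For every positive-weight spot, checks whether the spot's in-water range
#' stays confined to the target along its ray under a uniform RSP scaling.
#' Two containment criteria are offered:
#' \describe{
#'   \item{`"envelope"` (default)}{the range lies within the ray's target
#'     envelope `[R_p, R_d]` recomputed on the scaled image — the
#'     proximal/distal-buffer reading of confinement: the peak sits between
#'     the target's entry and exit along the beam, never beyond either
#'     edge. This is the mechanism that keeps range errors from pushing
#'     end-of-range LET past the target.}
#'   \item{`"tissue"`}{the geometric peak position falls inside target
#'     tissue. Stricter: for a C-shaped target it excludes peaks in the
#'     enclosed cavity even though they are buffered on both sides.}
#' }
#' The fraction is MU-weighted by default: it measures the share of
#' delivered monitor units whose peak is contained — the delivery-relevant
#' statistic (the placement stage also creates spots the optimizer switches
#' off; counting those would grade spots that deliver no protons).
#'
#' @param plan optimized `pat_plan`.
#' @param image nominal `image3`.
#' @param structures a `structure_set`.
#' @param rsp_scale uniform RSP scale factor (1 = nominal).
#' @param weighted MU-weighted (default) or unweighted spot counting.
#' @param criterion `"envelope"` or `"tissue"`.
#' @return fraction in [0, 1].
#' @export
bragg_containment <- function(plan, image, structures, rsp_scale = 1,
                              weighted = TRUE,
                              criterion = c("envelope", "tissue")) {
  criterion <- match.arg(criterion)
  img <- image
  if (rsp_scale != 1) img$values <- img$values * rsp_scale
  tmask <- structures$masks[[structures$target]]
  sp <- plan$spots
  keep <- sp$weight > 0
  sp <- sp[keep, , drop = FALSE]
  if (nrow(sp) == 0) stop("bragg_containment: no positive-weight spots")
  key <- paste(sp$cp, sp$a, sp$b, sep = "|")
  tr_cache <- new.env(parent = emptyenv())
  iv_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(sp))) {
    k <- key[i]
    if (!is.null(tr_cache[[k]])) next
    cp <- plan$cps[[sp$cp[i]]]
    p0 <- cp$isocenter + sp$a[i] * cp$u + sp$b[i] * cp$v
    tr <- trace_wepl(img, ray(p0, cp$direction))
    if (is.null(tr)) next
    tr_cache[[k]] <- tr
    iv <- target_range_interval(img, tmask, NULL, trace = tr)
    if (!is.null(iv)) iv_cache[[k]] <- iv
  }
  inside <- logical(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    if (criterion == "envelope") {
      iv <- iv_cache[[key[i]]]
      if (is.null(iv)) next
      inside[i] <- sp$range[i] >= iv$R_p && sp$range[i] <= iv$R_d
    } else {
      tr <- tr_cache[[key[i]]]
      if (is.null(tr)) next
      tpk <- t_at_wepl(tr, sp$range[i])
      if (is.na(tpk)) next
      p <- tr$entry + tpk * tr$direction
      ivx <- world_to_index(img, p)
      if (is.na(ivx[1])) next
      inside[i] <- tmask[ivx[1], ivx[2], ivx[3]]
    }
  }
  if (weighted) sum(sp$weight[inside]) / sum(sp$weight)
  else mean(inside)
}
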