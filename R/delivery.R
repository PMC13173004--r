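# Delivery-efficiency accounting: MU / energy-layer / spot counts and the
# additive time model TBD = SST + SSWT + ELST + GRT. Energy switches
# BETWEEN control points cost nothing (they happen during gantry rotation);
# only within-control-point layer switches accrue ELST, which is the
# defining delivery advantage of the single-layer-per-angle strategy.

#' Plan delivery counts
#'
#' Per-fraction monitor units, energy-layer count (distinct energies summed
#' over control points), and positive-weight spot count. Zero-weight spots
#' are excluded from all counts.
#'
#' @param plan a `pat_plan` with finalized weights.
#' @param machine a `machine_model`.
#' @return list with `total_mu` (per fraction), `el_count`, `spot_count`,
#'   and `layers_per_cp` (named integer vector).
#' @export
count_stats <- function(plan, machine = machine_model()) {
  sp <- plan$spots[plan$spots$weight > 0, , drop = FALSE]
  if (nrow(sp) == 0)
    return(list(total_mu = 0, el_count = 0L, spot_count = 0L,
                layers_per_cp = integer(0)))
  layers_per_cp <- vapply(split(sp$energy, sp$cp),
                          function(e) length(unique(e)), integer(1))
  list(total_mu = machine$mu_per_weight * sum(sp$weight) / plan$fractions,
       el_count = sum(layers_per_cp),
       spot_count = nrow(sp),
       layers_per_cp = layers_per_cp)
}

#' Estimate the delivery-time breakdown
#'
#' `SST = MU / mu_rate`; `SSWT = t_spot_switch x (spot_count - el_count)`
#' (intra-layer transitions); `ELST = sum over control points of
#' (layers - 1) x t_el_switch_down` (layers are delivered in descending
#' energy order within a control point; between-control-point switches are
#' free); `GRT = arc_span / gantry_speed` for arcs, and the per-field setup
#' constant times the field count for static plans. `TBD` is the exact sum.
#'
#' @param plan a `pat_plan`.
#' @param machine a `machine_model`.
#' @return list of class `delivery_time_breakdown` with `SST`, `SSWT`,
#'   `ELST`, `GRT`, `TBD` (seconds) and the counts of [count_stats()].
#' @export
estimate_times <- function(plan, machine = machine_model()) {
  if (machine$mu_rate <= 0 || machine$gantry_speed <= 0)
    stop("estimate_times: mu_rate and gantry_speed must be > 0")
  cs <- count_stats(plan, machine)
  sst <- cs$total_mu / machine$mu_rate
  sswt <- machine$t_spot_switch * max(cs$spot_count - cs$el_count, 0)
  elst <- machine$t_el_switch_down *
    sum(pmax(cs$layers_per_cp - 1L, 0L))
  grt <- if (!is.null(plan$geometry) && plan$geometry$type == "arc")
    plan$geometry$arc_span / machine$gantry_speed
  else machine$field_setup_time * length(plan$cps)
  structure(list(SST = sst, SSWT = sswt, ELST = elst, GRT = grt,
                 TBD = sst + sswt + elst + grt,
                 total_mu = cs$total_mu, el_count = cs$el_count,
                 spot_count = cs$spot_count),
            class = "delivery_time_breakdown")
}

#' @exportS3Method base::print
print.delivery_time_breakdown <- function(x, ...) {
  cat(sprintf(paste0("MU %.2f | ELs %d | spots %d\n",
                     "SST %.2f s + SSWT %.2f s + ELST %.2f s + GRT %.2f s",
                     " = TBD %.2f s\n"),
              x$total_mu, x$el_count, x$spot_count,
              x$SST, x$SSWT, x$ELST, x$GRT, x$TBD))
  invisible(x)
}

#' Compare delivery efficiency across strategies
#'
#' @param plans named list of >= 2 `pat_plan` objects on the same case.
#' @param machine a `machine_model`.
#' @return list with `table` (one row per plan: counts and time
#'   components) and `ratios` (pairwise EL-count and TBD ratios).
#' @export
compare_strategies <- function(plans, machine = machine_model()) {
  stopifnot(length(plans) >= 2)
  if (is.null(names(plans)))
    names(plans) <- vapply(plans, `[[`, character(1), "strategy")
  rows <- lapply(names(plans), function(nm) {
    tb <- estimate_times(plans[[nm]], machine)
    data.frame(plan = nm, total_mu = tb$total_mu, el_count = tb$el_count,
               spot_count = tb$spot_count, SST = tb$SST, SSWT = tb$SSWT,
               ELST = tb$ELST, GRT = tb$GRT, TBD = tb$TBD)
  })
  tab <- do.call(rbind, rows)
  pairs <- expand.grid(a = names(plans), b = names(plans),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  ratios <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ta <- tab[tab$plan == pairs$a[i], ]; tb <- tab[tab$plan == pairs$b[i], ]
    data.frame(a = pairs$a[i], b = pairs$b[i],
               el_ratio = ta$el_count / tb$el_count,
               tbd_ratio = ta$TBD / tb$TBD)
  }))
  list(table = tab, ratios = ratios)
}
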