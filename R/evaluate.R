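#' Cumulative dose-volume histogram
#'
#' `curve(d)` = fraction of the structure's voxels receiving at least `d`;
#' monotone nonincreasing with value 1 at 0 Gy. Voxel-count weighted
#' (uniform voxels, no partial-volume handling).
#'
#' @param grid numeric array (Gy, or any grid units).
#' @param mask non-empty logical mask on the same grid.
#' @param bin_width histogram bin width in grid units.
#' @param name structure name carried in the result.
#' @return object of class `dvh`: list with `edges`, `cumfrac`, `name`.
#' @export
compute_dvh <- function(grid, mask, bin_width = 0.01, name = "structure") {
  if (!any(mask)) stop("compute_dvh: empty mask for ", name)
  v <- grid[mask]
  v <- v[is.finite(v)]
  edges <- seq(0, max(v, 0) + bin_width, by = bin_width)
  fi <- findInterval(v, edges)
  cnt <- tabulate(fi, nbins = length(edges))
  less <- c(0, cumsum(cnt))[seq_along(edges)]   # voxels with value < edge
  structure(list(edges = edges, cumfrac = 1 - less / length(v), name = name),
            class = "dvh")
}

#' @exportS3Method base::plot
plot.dvh <- function(x, ..., xlab = "Dose (Gy)",
                     ylab = "Volume fraction") {
  graphics::plot(x$edges, x$cumfrac, type = "s", xlab = xlab, ylab = ylab,
                 main = x$name, ylim = c(0, 1), ...)
  invisible(x)
}

#' D_x% metric from a DVH
#'
#' The dose that x% of the structure volume at least receives: the level at
#' which the cumulative curve crosses x/100, linearly interpolated (plateaus
#' resolve to their midpoint).
#'
#' @param dvh a `dvh`.
#' @param x percent of volume, 0 < x < 100.
#' @return dose in grid units.
#' @export
d_metric <- function(dvh, x) {
  stopifnot(x > 0, x < 100)
  q <- x / 100
  cf <- dvh$cumfrac; e <- dvh$edges
  i <- max(which(cf >= q - 1e-12))   # cf[1] = 1, so i always exists
  if (i == length(e)) return(e[i])
  if (abs(cf[i] - q) <= 1e-12) {
    # the curve sits exactly at q over a plateau: take its midpoint
    j <- min(which(abs(cf - q) <= 1e-12))
    return((e[j] + e[i]) / 2)
  }
  # interpolate across the drop below q
  e[i] + (e[i + 1] - e[i]) * (cf[i] - q) / (cf[i] - cf[i + 1])
}

#' Upper q-percentile hotspot metric
#'
#' The value exceeded by q% of the structure's voxels (equals D_q% for dose
#' grids). For LET grids pass the validity mask through `valid`; a
#' structure lying entirely below the dose threshold reports `NA`
#' ("undefined"), never zero.
#'
#' @param grid numeric array.
#' @param mask non-empty logical mask.
#' @param q upper percentile (default 2).
#' @param valid optional logical validity mask intersected with `mask`.
#' @return value in grid units, or `NA_real_` when undefined.
#' @export
hotspot_percentile <- function(grid, mask, q = 2, valid = NULL) {
  if (!any(mask)) stop("hotspot_percentile: empty mask")
  m <- if (is.null(valid)) mask else (mask & valid)
  v <- grid[m]
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  as.numeric(stats::quantile(v, probs = 1 - q / 100, type = 7, names = FALSE))
}

#' Plan metric table (DVH and hotspot metrics per structure)
#'
#' Emits, per structure: D98/D50/D2 of physical dose, the 2-percentile
#' LET_d (over the validity mask), and the 2-percentile RBE-weighted dose.
#'
#' @param dose_let a `dose_let`.
#' @param drbe RBE-weighted dose array (from [rbe_weighted_dose()]), or
#'   NULL to skip.
#' @param structures a `structure_set`.
#' @param bin_width DVH bin width (Gy).
#' @return data.frame, one row per structure.
#' @export
metrics_table <- function(dose_let, drbe, structures, bin_width = 0.01) {
  rows <- lapply(names(structures$masks), function(nm) {
    m <- structures$masks[[nm]]
    dv <- compute_dvh(dose_let$dose, m, bin_width, nm)
    data.frame(
      structure = nm,
      D98 = d_metric(dv, 98), D50 = d_metric(dv, 50), D2 = d_metric(dv, 2),
      LETd_2pc = hotspot_percentile(dose_let$letd, m, 2,
                                    valid = dose_let$valid),
      DRBE_2pc = if (is.null(drbe)) NA_real_
                 else hotspot_percentile(drbe, m, 2)
    )
  })
  do.call(rbind, rows)
}

#' Write DVH curves for several structures to CSV
#'
#' @param dvhs list of `dvh` objects.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvhs, path) {
  df <- do.call(rbind, lapply(dvhs, function(d)
    data.frame(structure = d$name, dose = d$edges, volume = d$cumfrac)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
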