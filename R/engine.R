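# R-side driver of the compiled pencil-beam deposition kernel: gathers
# per-position central-axis WEPL traces, per-energy depth tables, and spot
# geometry, and dispatches to cpp_deposit() for accumulation (dose and
# dose-weighted LET numerator) and/or sparse influence triplets.

# central-axis trace per unique spot position; returns engine-ready pieces
.plan_traces <- function(plan, image) {
  sp <- plan$spots
  key <- paste(sp$cp, sp$a, sp$b, sep = "|")
  upos <- !duplicated(key)
  uid <- match(key, key[upos])
  ucp <- sp$cp[upos]; ua <- sp$a[upos]; ub <- sp$b[upos]
  traces <- vector("list", sum(upos))
  geo <- matrix(0, nrow(sp), 5)   # ex, ey, zb, dx, dy
  trace_of_spot <- integer(nrow(sp))
  for (i in seq_along(traces)) {
    cp <- plan$cps[[ucp[i]]]
    p0 <- cp$isocenter + ua[i] * cp$u + ub[i] * cp$v
    tr <- trace_wepl(image, ray(p0, cp$direction))
    if (is.null(tr)) next
    traces[[i]] <- list(t = tr$t, wepl = tr$wepl, entry = tr$entry,
                        dir = tr$direction)
  }
  ok <- !vapply(traces, is.null, logical(1))
  remap <- cumsum(ok)
  for (s in seq_len(nrow(sp))) {
    i <- uid[s]
    if (!ok[i]) next
    tr <- traces[[i]]
    geo[s, ] <- c(tr$entry[1], tr$entry[2], tr$entry[3],
                  tr$dir[1], tr$dir[2])
    trace_of_spot[s] <- remap[i]
  }
  list(traces = traces[ok], geo = geo, trace_of_spot = trace_of_spot)
}

.engine_tables <- function(energies, machine) {
  tt <- .depth_model_table(energies, machine)
  list(tabs = lapply(tt$models, function(m)
    list(dz = m$dz, dose = m$dose, let = m$let, sigma = m$sigma,
         peak_amp = m$peak_amp)),
    id_of = tt$id_of)
}

#' Physical dose, dose-averaged LET, and RBE-weighted dose container
#'
#' Produced by [accumulate()]: paired scalar grids on the image geometry —
#' physical dose (Gy), dose-averaged LET (keV/um), and the validity mask of
#' voxels whose dose exceeds the LET reporting threshold.
#'
#' @name dose_let
NULL

#' Accumulate a plan's dose and dose-averaged LET
#'
#' Sums per-spot pencil-beam contributions `w_i d_i` and forms the
#' dose-averaged LET `sum(w_i d_i L_i) / sum(w_i d_i)` per voxel. LET is
#' reported only where the accumulated dose exceeds
#' `dose_threshold_rel * prescription` (dose-averaging is unstable at
#' near-zero dose).
#'
#' @param plan a `pat_plan` with finalized weights.
#' @param image an `image3`.
#' @param machine a `machine_model`.
#' @param weights spot weights (defaults to `plan$spots$weight`).
#' @param cutoff relative per-spot kernel cutoff (fraction of the spot's
#'   on-axis maximum).
#' @param dose_threshold_rel LET validity threshold as a fraction of the
#'   prescription dose.
#' @param traces optional precomputed result of the internal trace step
#'   (reused across scenarios for speed).
#' @return object of class `dose_let`: list with `dose` (Gy array), `letd`
#'   (keV/um array, NA outside `valid`), `valid` (logical array),
#'   `prescription`.
#' @export
accumulate <- function(plan, image, machine = machine_model(),
                       weights = plan$spots$weight, cutoff = 1e-4,
                       dose_threshold_rel = 0.01, traces = NULL) {
  if (all(weights == 0)) stop("accumulate: all spot weights are zero")
  if (is.null(traces)) traces <- .plan_traces(plan, image)
  et <- .engine_tables(plan$spots$energy, machine)
  res <- cpp_deposit(image$dims, image$origin, image$spacing,
                     traces$geo, traces$trace_of_spot, et$id_of,
                     as.numeric(weights),
                     traces$traces, et$tabs,
                     integer(0), TRUE, cutoff)
  dose <- array(res$dose, dim = image$dims)
  valid <- dose >= dose_threshold_rel * plan$prescription
  letd <- array(NA_real_, dim = image$dims)
  letd[valid] <- res$letnum[valid] / dose[valid]
  structure(list(dose = dose, letd = letd, valid = valid,
                 prescription = plan$prescription),
            class = "dose_let")
}

#' Dose and track-LET contribution of a single spot
#'
#' @param image an `image3`.
#' @param cp the spot's `control_point`.
#' @param a,b BEV lateral coordinates (mm).
#' @param energy spot energy (MeV).
#' @param machine a `machine_model`.
#' @param cutoff relative kernel cutoff.
#' @return list with `idx` (linear voxel indices), `dose` (Gy per unit
#'   weight) and `let` (keV/um track LET) of all voxels above the cutoff;
#'   empty vectors when the spot ray misses the body.
#' @export
compute_spot_dose <- function(image, cp, a, b, energy,
                              machine = machine_model(), cutoff = 1e-4) {
  plan <- new_pat_plan(list(cp),
                       data.frame(cp = 1, a = a, b = b, energy = energy,
                                  range = range_from_energy(energy, machine),
                                  weight = 1),
                       prescription = 1, fractions = 1, strategy = "spot")
  tr <- .plan_traces(plan, image)
  if (tr$trace_of_spot[1] == 0)
    return(list(idx = integer(0), dose = numeric(0), let = numeric(0)))
  et <- .engine_tables(energy, machine)
  res <- cpp_deposit(image$dims, image$origin, image$spacing,
                     tr$geo, tr$trace_of_spot, et$id_of, 1,
                     tr$traces, et$tabs, integer(0), TRUE, cutoff)
  idx <- which(res$dose > 0)
  list(idx = idx, dose = res$dose[idx], let = res$letnum[idx] / res$dose[idx])
}

#' Build the sparse dose-influence matrix
#'
#' Rows are the selected optimization voxels, columns the plan's spots;
#' entries are dose per unit spot weight, consistent with
#' [compute_spot_dose()] by construction (same kernel).
#'
#' @param plan a `pat_plan`.
#' @param image an `image3`.
#' @param machine a `machine_model`.
#' @param voxels integer linear voxel indices to include as rows. Default:
#'   the union of all non-body structure masks.
#' @param structures used for the default voxel selection.
#' @param stride keep every `stride`-th voxel of the selection (dose-grid
#'   downsampling for large plans).
#' @param cutoff relative kernel cutoff.
#' @return list with `A` (dgCMatrix, voxels x spots), `voxels` (row voxel
#'   indices), `traces` (reusable trace bundle).
#' @export
build_influence <- function(plan, image, machine = machine_model(),
                            structures = NULL, voxels = NULL, stride = 1,
                            cutoff = 1e-4) {
  if (is.null(voxels)) {
    if (is.null(structures))
      stop("build_influence: give either voxels or structures")
    sel <- Reduce(`|`, structures$masks[setdiff(names(structures$masks),
                                                "body")])
    voxels <- which(sel)
  }
  if (stride > 1) voxels <- voxels[seq(1, length(voxels), by = stride)]
  nvox <- prod(image$dims)
  # triplets are ~16 bytes each; assume ~15% fill as a coarse guard
  if (0.15 * length(voxels) * nrow(plan$spots) * 16 > 6e9)
    stop("build_influence: estimated influence matrix exceeds memory; ",
         "use a larger stride or a coarser dose grid")
  rowmap <- integer(nvox)
  rowmap[voxels] <- seq_along(voxels)
  traces <- .plan_traces(plan, image)
  et <- .engine_tables(plan$spots$energy, machine)
  nspot <- nrow(plan$spots)
  # build in spot chunks so triplet buffers never dominate memory
  chunk <- 25000L
  starts <- seq(1L, nspot, by = chunk)
  blocks <- lapply(starts, function(s0) {
    sel <- s0:min(s0 + chunk - 1L, nspot)
    res <- cpp_deposit(image$dims, image$origin, image$spacing,
                       traces$geo[sel, , drop = FALSE],
                       traces$trace_of_spot[sel], et$id_of[sel],
                       rep(1, length(sel)),
                       traces$traces, et$tabs,
                       rowmap, FALSE, cutoff)
    Matrix::sparseMatrix(i = res$i, j = res$j, x = res$x,
                         dims = c(length(voxels), length(sel)))
  })
  A <- do.call(cbind, blocks)
  list(A = A, voxels = voxels, traces = traces)
}

# box (Chebyshev) dilation of a logical mask by r voxels per axis
dilate_mask <- function(mask, r_vox) {
  out <- mask
  d <- dim(mask)
  for (axis in 1:3) {
    acc <- out
    for (s in seq_len(r_vox)) {
      shifted_fwd <- array(FALSE, d)
      shifted_bwd <- array(FALSE, d)
      idx <- seq_len(d[axis] - s)
      if (axis == 1) {
        shifted_fwd[idx + s, , ] <- out[idx, , ]
        shifted_bwd[idx, , ] <- out[idx + s, , ]
      } else if (axis == 2) {
        shifted_fwd[, idx + s, ] <- out[, idx, ]
        shifted_bwd[, idx, ] <- out[, idx + s, ]
      } else {
        shifted_fwd[, , idx + s] <- out[, , idx]
        shifted_bwd[, , idx] <- out[, , idx + s]
      }
      acc <- acc | shifted_fwd | shifted_bwd
    }
    out <- acc
  }
  out
}
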