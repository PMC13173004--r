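#' Voxelized relative-stopping-power image
#'
#' An `image3` is an axis-aligned voxel grid of relative stopping power (RSP,
#' dimensionless relative to water) with origin/spacing metadata. It is the
#' patient/phantom model used by all ray tracing and dose computation.
#' Spatial coordinates are in millimetres; the origin is the centre of the
#' first voxel (NRRD convention). Water-equivalent quantities derived from it
#' (ranges, WEPL) are reported in centimetres.
#'
#' @param values numeric 3D array of RSP values; finite and >= 0.
#' @param spacing numeric length-3, voxel spacing in mm (> 0).
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @return An object of class `image3`.
#' @export
image3 <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image3: spacing components must be finite and > 0")
  if (any(!is.finite(values)))
    stop("image3: RSP values must be finite")
  if (any(values < 0))
    stop("image3: RSP values must be >= 0")
  structure(
    list(values = values, spacing = spacing, origin = origin,
         dims = dim(values)),
    class = "image3"
  )
}

#' @exportS3Method base::print
print.image3 <- function(x, ...) {
  cat("<image3> ", paste(x$dims, collapse = " x "),
      " voxels, spacing [", paste(format(x$spacing), collapse = ", "),
      "] mm\n  origin [", paste(format(x$origin), collapse = ", "),
      "] mm, RSP range [", format(min(x$values)), ", ",
      format(max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' Voxel-centre coordinates along each axis
#'
#' @param image an `image3`.
#' @return list of three numeric vectors (mm), one per axis.
#' @export
voxel_centers <- function(image) {
  lapply(1:3, function(a)
    image$origin[a] + (seq_len(image$dims[a]) - 1) * image$spacing[a])
}

#' World-space bounding box of the voxel grid
#'
#' Outer faces of the boundary voxels, i.e. the region a ray can traverse.
#' @param image an `image3`.
#' @return 2 x 3 matrix: rows = lower/upper corner (mm).
#' @export
image_bounds <- function(image) {
  lo <- image$origin - 0.5 * image$spacing
  hi <- image$origin + (image$dims - 0.5) * image$spacing
  rbind(lo = lo, hi = hi)
}

#' Convert world coordinates (mm) to 1-based voxel indices
#'
#' @param image an `image3`.
#' @param p numeric length-3 point or n x 3 matrix of points (mm).
#' @return integer matrix n x 3 of voxel indices; NA where outside the grid.
#' @export
world_to_index <- function(image, p) {
  p <- matrix(p, ncol = 3)
  idx <- sweep(sweep(p, 2, image$origin), 2, image$spacing, "/")
  idx <- round(idx) + 1
  for (a in 1:3) idx[idx[, a] < 1 | idx[, a] > image$dims[a], a] <- NA
  bad <- rowSums(is.na(idx)) > 0
  idx[bad, ] <- NA
  storage.mode(idx) <- "integer"
  idx
}

#' Named structure masks sharing an image grid
#'
#' A `structure_set` couples named boolean voxel masks (body, PTV, OARs) with
#' the photon linear-quadratic alpha/beta ratio assigned to each structure
#' (Gy). All masks must share the grid of the image they annotate; the PTV
#' must be non-empty. A `"body"` entry acts as the fallback for voxels not
#' covered by any other structure.
#'
#' @param masks named list of logical 3D arrays with identical dims.
#' @param alpha_beta named numeric vector, (alpha/beta)_x in Gy per
#'   structure; every mask name must be resolvable (directly or via the
#'   `"body"` default).
#' @param target name of the target structure (used for priority when
#'   assigning per-voxel alpha/beta); default `"ptv"`.
#' @return object of class `structure_set`.
#' @export
structure_set <- function(masks, alpha_beta, target = "ptv") {
  stopifnot(is.list(masks), length(masks) > 0, !is.null(names(masks)))
  dims <- dim(masks[[1]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), dims))
      stop("structure_set: mask '", nm, "' must be a logical array on the shared grid")
  }
  if (!target %in% names(masks))
    stop("structure_set: target mask '", target, "' missing")
  if (!any(masks[[target]]))
    stop("structure_set: target mask '", target, "' is empty")
  alpha_beta <- unlist(alpha_beta)
  if (!"body" %in% names(alpha_beta) && !all(names(masks) %in% names(alpha_beta)))
    stop("structure_set: alpha_beta must cover every structure or provide a 'body' default")
  structure(list(masks = masks, alpha_beta = alpha_beta, target = target,
                 dims = dims),
            class = "structure_set")
}

#' @exportS3Method base::print
print.structure_set <- function(x, ...) {
  cat("<structure_set> on ", paste(x$dims, collapse = " x "), " grid\n", sep = "")
  for (nm in names(x$masks)) {
    ab <- if (nm %in% names(x$alpha_beta)) x$alpha_beta[[nm]] else x$alpha_beta[["body"]]
    cat(sprintf("  %-10s %8d voxels  (alpha/beta)_x = %.1f Gy%s\n", nm,
                sum(x$masks[[nm]]), ab,
                if (nm == x$target) "  [target]" else ""))
  }
  invisible(x)
}

#' Per-voxel (alpha/beta)_x grid with structure priority
#'
#' Overlapping structures are resolved target-first, then OARs (all
#' non-body structures in their listed order), then body; uncovered voxels
#' fall back to the body value. The count of uncovered voxels is attached as
#' attribute `n_unassigned`.
#'
#' @param structures a `structure_set`.
#' @return numeric array of (alpha/beta)_x (Gy) with attribute `n_unassigned`.
#' @export
alpha_beta_grid <- function(structures) {
  ab_of <- function(nm) {
    if (nm %in% names(structures$alpha_beta)) structures$alpha_beta[[nm]]
    else structures$alpha_beta[["body"]]
  }
  body_ab <- ab_of("body")
  grid <- array(body_ab, dim = structures$dims)
  covered <- array(FALSE, dim = structures$dims)
  # lowest priority first so later (higher-priority) writes win
  order_names <- c(
    setdiff(names(structures$masks), c(structures$target, "body")),
    structures$target
  )
  if ("body" %in% names(structures$masks)) {
    grid[structures$masks[["body"]]] <- body_ab
    covered <- covered | structures$masks[["body"]]
  }
  for (nm in order_names) {
    m <- structures$masks[[nm]]
    grid[m] <- ab_of(nm)
    covered <- covered | m
  }
  attr(grid, "n_unassigned") <- sum(!covered)
  grid
}
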