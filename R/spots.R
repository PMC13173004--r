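#' Place scanning spots on the BEV lateral grid of a control point
#'
#' Spots sit on a uniform square lattice (pitch = `spacing`) in the
#' beam's-eye-view (u, v) frame, anchored at the centroid of the target's
#' BEV projection, covering the projection dilated by `margin`. A lattice
#' position is kept when its central ray intersects the target, or (for
#' `margin > 0`) lies within `margin` of the projected target point cloud.
#'
#' @param image an `image3`.
#' @param target_mask logical target mask on the image grid.
#' @param cp a `control_point`.
#' @param spacing lattice pitch in mm.
#' @param margin lateral margin in mm around the projection.
#' @return data.frame with columns `a`, `b` (BEV coordinates, mm) of kept
#'   positions; attributes `traces` and `intervals` hold the per-position
#'   `wepl_trace` and `range_interval` (NULL where the ray misses the
#'   target). Empty data.frame when the projection is empty.
#' @export
place_spots_bev <- function(image, target_mask, cp, spacing = 3, margin = 0) {
  stopifnot(spacing > 0)
  vox <- which(target_mask)
  if (length(vox) == 0)
    return(structure(data.frame(a = numeric(0), b = numeric(0)),
                     traces = list(), intervals = list()))
  dims <- image$dims
  i3 <- arrayInd(vox, dims)
  pts <- sweep(sweep(i3 - 1, 2, image$spacing, "*"), 2, image$origin, "+")
  rel <- sweep(pts, 2, cp$isocenter)
  pa <- as.numeric(rel %*% cp$u)
  pb <- as.numeric(rel %*% cp$v)
  ca <- mean(pa); cb <- mean(pb)
  ka <- seq(floor((min(pa) - margin - ca) / spacing),
            ceiling((max(pa) + margin - ca) / spacing))
  kb <- seq(floor((min(pb) - margin - cb) / spacing),
            ceiling((max(pb) + margin - cb) / spacing))
  cand <- expand.grid(a = ca + ka * spacing, b = cb + kb * spacing)
  keep <- logical(nrow(cand))
  traces <- vector("list", nrow(cand))
  intervals <- vector("list", nrow(cand))
  half_diag <- sqrt(sum((image$spacing / 2)^2))
  for (i in seq_len(nrow(cand))) {
    p0 <- cp$isocenter + cand$a[i] * cp$u + cand$b[i] * cp$v
    rr <- ray(p0, cp$direction)
    tr <- trace_wepl(image, rr)
    if (is.null(tr)) next
    iv <- target_range_interval(image, target_mask, rr, trace = tr)
    hit <- !is.null(iv)
    near <- FALSE
    if (!hit && margin > 0) {
      d2 <- (pa - cand$a[i])^2 + (pb - cand$b[i])^2
      near <- min(d2) <= (margin + half_diag)^2
    }
    if (hit || near) {
      keep[i] <- TRUE
      traces[[i]] <- tr
      intervals[[i]] <- iv
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "traces") <- traces[keep]
  attr(out, "intervals") <- intervals[keep]
  out
}
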