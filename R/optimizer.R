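# Nonnegative spot-weight optimization with quadratic physical-dose
# objectives: a two-sided target-uniformity term, one-sided overdose
# penalties for OARs (and optional ring/conformity structures), and a
# one-sided hotspot cap on the target. Solved by projected gradient with
# Armijo backtracking from a cold start at w = 0 — deterministic, no
# randomness, objective nonincreasing by construction.

#' Quadratic objective specification
#'
#' @param terms data.frame with columns `structure`, `kind`
#'   (`"target_uniform"`, `"max_dose"`, `"mean_dose"`), `ref` (reference
#'   dose, Gy) and `weight` (>= 0). Exactly one `target_uniform` term is
#'   required.
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(terms) {
  stopifnot(is.data.frame(terms),
            all(c("structure", "kind", "ref", "weight") %in% names(terms)))
  if (sum(terms$kind == "target_uniform") != 1)
    stop("objective_spec: exactly one target_uniform term required")
  if (any(terms$weight < 0)) stop("objective_spec: weights must be >= 0")
  structure(list(terms = terms), class = "objective_spec")
}

#' Default phantom objectives
#'
#' Target uniformity at the prescription, one-sided OAR overdose penalty
#' toward zero, a conformity ring penalty at half the prescription, and a
#' target hotspot cap at `cap_frac` of the prescription. The weights are
#' tuning parameters of this package.
#'
#' @param prescription Gy.
#' @param target,oars,ring structure names (set `ring = NULL` to omit).
#' @param cap_frac hotspot cap as a fraction of prescription.
#' @return an [objective_spec()].
#' @export
default_objectives <- function(prescription, target = "ptv", oars = "oar",
                               ring = "ring", cap_frac = 1.07) {
  terms <- data.frame(structure = target, kind = "target_uniform",
                      ref = prescription, weight = 100)
  for (o in oars)
    terms <- rbind(terms, data.frame(structure = o, kind = "max_dose",
                                     ref = 0, weight = 10))
  if (!is.null(ring))
    terms <- rbind(terms, data.frame(structure = ring, kind = "max_dose",
                                     ref = 0.5 * prescription, weight = 2))
  terms <- rbind(terms, data.frame(structure = target, kind = "max_dose",
                                   ref = cap_frac * prescription, weight = 50))
  objective_spec(terms)
}

#' Add a conformity ring structure
#'
#' Adds a `"ring"` mask: body voxels within a Chebyshev radius
#' `width_cm` of the target, excluding the target itself. Standard practice
#' for controlling dose just outside the target when only the target and
#' distant OARs carry objectives.
#'
#' @param structures a `structure_set`.
#' @param image the `image3` (for voxel size).
#' @param width_cm ring width in cm.
#' @return the extended `structure_set`.
#' @export
add_ring_structure <- function(structures, image, width_cm = 1) {
  tmask <- structures$masks[[structures$target]]
  r <- max(1L, round(width_cm * 10 / min(image$spacing)))
  ring <- dilate_mask(tmask, r) & !tmask
  if ("body" %in% names(structures$masks))
    ring <- ring & structures$masks[["body"]]
  masks <- c(structures$masks, list(ring = ring))
  structure_set(masks, structures$alpha_beta, structures$target)
}

# objective value and gradient in dose space
.obj_terms <- function(d, objectives, rows_of) {
  f <- 0
  g <- numeric(length(d))
  for (k in seq_len(nrow(objectives$terms))) {
    tm <- objectives$terms[k, ]
    rows <- rows_of[[tm$structure]]
    if (length(rows) == 0 || tm$weight == 0) next
    n <- length(rows)
    if (tm$kind == "target_uniform") {
      r <- d[rows] - tm$ref
      f <- f + tm$weight * sum(r^2) / n
      g[rows] <- g[rows] + 2 * tm$weight * r / n
    } else if (tm$kind == "max_dose") {
      r <- pmax(d[rows] - tm$ref, 0)
      f <- f + tm$weight * sum(r^2) / n
      g[rows] <- g[rows] + 2 * tm$weight * r / n
    } else if (tm$kind == "mean_dose") {
      r <- max(mean(d[rows]) - tm$ref, 0)
      f <- f + tm$weight * r^2
      g[rows] <- g[rows] + 2 * tm$weight * r / n
    } else stop("unknown objective kind: ", tm$kind)
  }
  list(f = f, g = g)
}

#' Optimize nonnegative spot weights
#'
#' Projected-gradient descent with Armijo backtracking on the quadratic
#' objective, cold-started at zero weights; converges when the relative
#' objective decrease drops below `tol` or after `max_iter` iterations.
#' Deterministic: identical spots receive identical weights (the symmetric
#' split of degenerate optima).
#'
#' @param influence result of [build_influence()] (or a bare dgCMatrix).
#' @param objectives an [objective_spec()].
#' @param rows_of named list: structure name -> row indices of the
#'   influence matrix (see [influence_rows()]).
#' @param max_iter iteration cap.
#' @param tol relative objective-decrease convergence threshold.
#' @return list with `weights`, `objective` (per-iteration values),
#'   `converged`, and `uncovered` (count of target rows receiving no
#'   influence from any spot — reported with a warning, optimization still
#'   proceeds).
#' @export
optimize_weights <- function(influence, objectives, rows_of,
                             max_iter = 400, tol = 1e-6) {
  A <- if (is.list(influence)) influence$A else influence
  tgt <- objectives$terms$structure[objectives$terms$kind == "target_uniform"]
  trows <- rows_of[[tgt]]
  cov <- Matrix::rowSums(A[trows, , drop = FALSE] != 0)
  uncovered <- sum(cov == 0)
  if (uncovered > 0)
    warning("optimize_weights: ", uncovered,
            " target voxels receive no influence from any spot")
  nspot <- ncol(A)
  w <- numeric(nspot)
  d <- numeric(nrow(A))
  ob <- .obj_terms(d, objectives, rows_of)
  f <- ob$f
  fs <- f
  # initial step from a gradient-based curvature probe
  gw <- as.numeric(Matrix::crossprod(A, ob$g))
  gnorm <- sqrt(sum(gw^2))
  if (gnorm == 0) return(list(weights = w, objective = fs, converged = TRUE,
                              uncovered = uncovered))
  probe <- as.numeric(A %*% gw)
  curv <- sum(probe^2) / sum(gw^2)
  step <- if (curv > 0) 1 / (2 * curv) else 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gw <- as.numeric(Matrix::crossprod(A, ob$g))
    repeat {
      w_new <- pmax(w - step * gw, 0)
      d_new <- as.numeric(A %*% w_new)
      ob_new <- .obj_terms(d_new, objectives, rows_of)
      if (ob_new$f <= f + 1e-12 || step < 1e-18) break
      step <- step / 2
    }
    rel <- (f - ob_new$f) / max(f, 1e-300)
    w <- w_new; d <- d_new; ob <- ob_new; f <- ob$f
    fs <- c(fs, f)
    step <- step * 1.3
    if (rel >= 0 && rel < tol) { converged <- TRUE; break }
  }
  list(weights = w, objective = fs, converged = converged,
       uncovered = uncovered)
}

#' Row indices of each structure within an influence matrix
#'
#' @param influence result of [build_influence()].
#' @param structures a `structure_set`.
#' @return named list: structure name -> integer row indices.
#' @export
influence_rows <- function(influence, structures) {
  lapply(structures$masks, function(m) which(m[influence$voxels]))
}

#' Scale a plan to meet a coverage prescription
#'
#' Returns the factor s such that the dose received by at least
#' `coverage`% of the target volume equals the prescription; applied
#' multiplicatively to weights and dose (D95 normalization with the
#' defaults).
#'
#' @param dose numeric dose array (Gy).
#' @param target_mask logical mask.
#' @param prescription Gy.
#' @param coverage percent of the target volume.
#' @return scale factor s.
#' @export
normalize_to_coverage <- function(dose, target_mask, prescription,
                                  coverage = 95) {
  v <- dose[target_mask]
  if (length(v) == 0 || max(v) <= 0)
    stop("normalize_to_coverage: target receives no dose")
  dcov <- as.numeric(stats::quantile(v, probs = 1 - coverage / 100,
                                     type = 7, names = FALSE))
  if (dcov <= 0)
    stop("normalize_to_coverage: coverage dose is zero; cannot normalize")
  prescription / dcov
}
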