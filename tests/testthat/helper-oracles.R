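# Independent test oracles, deliberately naive implementations.

# brute-force WEPL by fixed-step marching along the ray (0.1 mm steps),
# measured from the body surface (first sample with RSP > threshold)
wepl_march <- function(image, r, step_mm = 0.1, air_threshold = 0.05) {
  b <- image_bounds(image)
  p <- r$point; d <- r$direction
  tmin <- -Inf; tmax <- Inf
  for (a in 1:3) {
    if (abs(d[a]) < 1e-12) {
      if (p[a] < b[1, a] || p[a] > b[2, a]) return(NULL)
    } else {
      t1 <- (b[1, a] - p[a]) / d[a]; t2 <- (b[2, a] - p[a]) / d[a]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmax <= tmin) return(NULL)
  ts <- seq(tmin + step_mm / 2, tmax, by = step_mm)
  pts <- cbind(p[1] + ts * d[1], p[2] + ts * d[2], p[3] + ts * d[3])
  iv <- world_to_index(image, pts)
  rsp <- rep(0, length(ts))
  ok <- !is.na(iv[, 1])
  lin <- iv[ok, 1] + (iv[ok, 2] - 1) * image$dims[1] +
    (iv[ok, 3] - 1) * image$dims[1] * image$dims[2]
  rsp[ok] <- image$values[lin]
  surf <- which(rsp > air_threshold)[1]
  if (is.na(surf)) return(list(total = 0))
  list(total = sum(rsp[surf:length(rsp)]) * step_mm / 10,
       t = ts - tmin, wepl = pmax(0, cumsum(rsp) - sum(rsp[1:surf])) *
         step_mm / 10)
}

# brute-force nonnegative least squares for the target-uniform objective by
# enumerating active sets (exact for small spot counts)
nnls_enumerate <- function(A, p, lambda = 1) {
  n <- ncol(A)
  nv <- nrow(A)
  best <- list(f = Inf, w = numeric(n))
  for (mask in 0:(2^n - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    w <- numeric(n)
    if (length(free) > 0) {
      Af <- A[, free, drop = FALSE]
      sol <- tryCatch(qr.solve(crossprod(Af), crossprod(Af, p)),
                      error = function(e) NULL)
      if (is.null(sol) || any(sol < 0)) next
      w[free] <- sol
    }
    f <- lambda * sum((A %*% w - p)^2) / nv
    if (f < best$f) best <- list(f = f, w = w)
  }
  best
}

# McNamara RBE evaluated in an independently arranged form
rbe_oracle <- function(dp, letd, ab, p0 = 0.99, p1 = 0.36, p2 = 1.101,
                       p3 = -0.0039) {
  alpha_ratio <- p0 + p1 * letd / ab
  beta_ratio <- (p2 + p3 * sqrt(ab) * letd)^2
  # roots of the LQ-equivalence quadratic: RBE solves
  # ab * (RBE*dp) + (RBE*dp)^2/1 ... arranged as quadratic in x = RBE*dp:
  # x^2 * (1/ab) + x - (alpha_ratio * dp + beta_ratio * dp^2 / ab) = 0
  cterm <- alpha_ratio * dp + beta_ratio * dp^2 / ab
  x <- (-1 + sqrt(1 + 4 * cterm / ab)) / (2 / ab)
  x / dp
}
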