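test_that("scenario generator produces the canonical eight", {
  sc <- make_scenarios()
  expect_length(sc, 8)
  scales <- vapply(sc, `[[`, numeric(1), "rsp_scale")
  shifts <- t(vapply(sc, `[[`, numeric(3), "shift"))
  expect_equal(sort(scales[scales != 1]), c(0.97, 1.03))
  expect_equal(sum(scales != 1), 2)
  expect_equal(sum(rowSums(abs(shifts)) > 0), 6)
  # exactly one perturbation per scenario
  for (s in sc)
    expect_true(xor(s$rsp_scale != 1, any(s$shift != 0)))
  # closed under sign flip
  for (s in sc[3:8])
    expect_true(any(vapply(sc[3:8], function(o)
      all(o$shift == -s$shift), logical(1))))
  expect_equal(sort(unique(abs(shifts[shifts != 0]))), 3)
  # degenerate magnitudes collapse to nominal
  sc0 <- make_scenarios(0, 0)
  expect_length(sc0, 8)
  for (s in sc0) {
    expect_equal(s$rsp_scale, 1)
    expect_equal(s$shift, c(0, 0, 0))
  }
})

test_that("nominal scenario recomputation is bitwise identical", {
  bp <- build_box_phantom(size_cm = c(8, 10, 4), target_size_cm = c(3, 3, 2),
                          voxel_size = 2)
  m <- machine_model()
  plan <- plan_mrpat(bp$image, bp$structures,
                     arc_geometry(cp_spacing = 45), m,
                     prescription = 2, fractions = 1)
  dl <- accumulate(plan, bp$image, m)
  dl2 <- apply_scenario(plan, bp$image, bp$structures, nominal_scenario(), m)
  expect_identical(dl$dose, dl2$dose)
  expect_identical(dl$letd, dl2$letd)
})

test_that("+3% stopping power pulls a single-spot peak proximally to R0/1.03", {
  bp <- build_box_phantom(size_cm = c(8, 14, 4), target_size_cm = c(2, 2, 1),
                          voxel_size = 1)
  img <- bp$image
  m <- machine_model()
  cp <- make_static_beams(0)[[1]]
  E <- nearest_deliverable_energy(energy_from_range(10, m), m)
  R0 <- range_from_energy(E, m)
  plan <- mrpat:::new_pat_plan(
    list(cp), data.frame(cp = 1, a = 0, b = 0, energy = E, range = R0,
                         weight = 1),
    prescription = 0.1, fractions = 1, strategy = "test")
  peak_depth <- function(scale) {
    dl <- apply_scenario(plan, img, bp$structures,
                         scenario("s", rsp_scale = scale), m)
    pk <- arrayInd(which.max(dl$dose), img$dims)
    (70 - voxel_centers(img)[[2]][pk[2]]) / 10    # cm below surface
  }
  d_nom <- peak_depth(1)
  d_scaled <- peak_depth(1.03)
  # 1-D oracle: peak of the tabulated curve mapped through the scaled WEPL
  dd <- build_depth_dose(R0, m)
  zpk <- dd$z[which.max(dd$dose)]
  expect_lt(abs(d_nom - zpk), 0.11)
  expect_lt(abs(d_scaled - zpk / 1.03), 0.11)
  expect_lt(abs(d_scaled - d_nom / 1.03), 0.15)
})

test_that("lateral setup shift translates the dose pattern accordingly", {
  bp <- build_box_phantom(size_cm = c(10, 12, 4), target_size_cm = c(3, 3, 2),
                          voxel_size = 1)
  img <- bp$image
  m <- machine_model()
  cp <- make_static_beams(0)[[1]]   # beam along -y; x is lateral
  E <- nearest_deliverable_energy(energy_from_range(8, m), m)
  plan <- mrpat:::new_pat_plan(
    list(cp), data.frame(cp = 1, a = 0, b = 0, energy = E,
                         range = range_from_energy(E, m), weight = 1),
    prescription = 0.1, fractions = 1, strategy = "test")
  dl0 <- accumulate(plan, img, m)
  dls <- apply_scenario(plan, img, bp$structures,
                        scenario("sx", shift = c(3, 0, 0)), m)
  # cross-correlation oracle: the lateral profile at the peak depth moves
  # by the shift (in the image frame the beam axis moves by -shift)
  pk <- arrayInd(which.max(dl0$dose), img$dims)
  prof0 <- dl0$dose[, pk[2], pk[3]]
  profs <- dls$dose[, pk[2], pk[3]]
  lags <- -6:6
  cc <- vapply(lags, function(L) {
    i <- seq_along(prof0)
    j <- i + L
    ok <- j >= 1 & j <= length(prof0)
    sum(prof0[i[ok]] * profs[j[ok]])
  }, numeric(1))
  best <- lags[which.max(cc)]
  expect_lte(abs(abs(best) - 3), 1)   # 3 mm at 1 mm voxels, +-1 voxel
})

test_that("shift beyond the padding is rejected with the grid bounds", {
  bp <- build_box_phantom(size_cm = c(6, 6, 3), target_size_cm = c(4, 4, 2),
                          voxel_size = 2, air_padding = 0.2)
  m <- machine_model()
  cp <- make_static_beams(0)[[1]]
  plan <- mrpat:::new_pat_plan(
    list(cp), data.frame(cp = 1, a = 0, b = 0, energy = 100,
                         range = range_from_energy(100, m), weight = 1),
    prescription = 1, fractions = 1, strategy = "test")
  expect_error(apply_scenario(plan, bp$image, bp$structures,
                              scenario("far", shift = c(50, 0, 0)), m),
               "outside the dose grid")
})

test_that("DVH band envelopes behave as set operations", {
  g1 <- array(rep(c(10, 20), each = 50), dim = c(100, 1, 1))
  g2 <- g1 * 1.1
  m <- array(TRUE, dim = dim(g1))
  d1 <- compute_dvh(g1, m); d2 <- compute_dvh(g2, m)
  # single scenario: band collapses to its DVH
  b1 <- summarize_band(list(d1))
  expect_equal(b1$lo, b1$hi)
  # identical scenarios: zero-width band
  b8 <- summarize_band(rep(list(d1), 8))
  expect_equal(b8$lo, b8$hi)
  # nominal lies within the band when included
  b <- summarize_band(list(d1, d2))
  nom <- stats::approx(d1$edges, d1$cumfrac, xout = b$edges,
                       yleft = 1, yright = 0)$y
  expect_true(all(nom >= b$lo - 1e-12 & nom <= b$hi + 1e-12))
  # worst-case directionality
  wc <- worst_case_metric(c(19, 20, 18.5), "coverage")
  expect_equal(wc$worst, 18.5)
  wh <- worst_case_metric(c(5, 7, 6), "hotspot")
  expect_equal(wh$worst, 7)
})
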