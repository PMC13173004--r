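# construct bare plans with prescribed layer structure for time-model tests
mk_plan <- function(layers_per_cp, spots_per_layer = 10, weight = 1,
                    arc = TRUE, fractions = 1) {
  cps <- if (arc) make_arc(arc_geometry(arc_span = 360,
                                        cp_spacing = 360 / length(layers_per_cp)))
         else make_static_beams(rep(90, length(layers_per_cp)))
  rows <- list()
  for (ic in seq_along(layers_per_cp)) {
    nl <- layers_per_cp[ic]
    if (nl == 0) next
    for (l in seq_len(nl))
      rows[[length(rows) + 1]] <- data.frame(
        cp = ic, a = seq_len(spots_per_layer) * 3, b = 0,
        energy = 100 + l, range = 0.0022 * (100 + l)^1.77, weight = weight)
  }
  mrpat:::new_pat_plan(cps, do.call(rbind, rows), prescription = 20,
                       fractions = fractions, strategy = "test",
                       geometry = if (arc) arc_geometry(
                         arc_span = 360,
                         cp_spacing = 360 / length(layers_per_cp)))
}

test_that("counts follow the positive-weight spots", {
  m <- machine_model()
  plan <- mk_plan(c(1, 1, 2), spots_per_layer = 5, fractions = 2)
  cs <- count_stats(plan, m)
  expect_equal(cs$el_count, 4L)
  expect_equal(cs$spot_count, 20L)
  expect_equal(cs$total_mu, 20 * 1 / 2)   # per fraction
  # zero-weight plan: all counts zero
  plan0 <- plan; plan0$spots$weight <- 0
  cs0 <- count_stats(plan0, m)
  expect_equal(c(cs0$total_mu, cs0$el_count, cs0$spot_count), c(0, 0, 0))
  # merging two plans adds counts
  plan2 <- mk_plan(c(2, 1), spots_per_layer = 5)
  merged <- plan
  merged$cps <- c(plan$cps, plan2$cps)
  sp2 <- plan2$spots; sp2$cp <- sp2$cp + length(plan$cps)
  merged$spots <- rbind(plan$spots, sp2)
  merged$fractions <- 1
  plan1 <- plan; plan1$fractions <- 1
  expect_equal(count_stats(merged, m)$el_count,
               count_stats(plan1, m)$el_count + count_stats(plan2, m)$el_count)
  expect_equal(count_stats(merged, m)$spot_count,
               count_stats(plan1, m)$spot_count +
                 count_stats(plan2, m)$spot_count)
})

test_that("single-layer-per-control-point plans have zero ELST", {
  m <- machine_model()
  plan <- mk_plan(rep(1, 71))
  tb <- estimate_times(plan, m)
  expect_identical(tb$ELST, 0)
  # the identity TBD = SST + SSWT + ELST + GRT holds exactly
  expect_identical(tb$TBD, tb$SST + tb$SSWT + tb$ELST + tb$GRT)
  # ELST = 0 iff every control point delivers <= 1 layer
  plan2 <- mk_plan(c(1, 1, 3, 1))
  expect_gt(estimate_times(plan2, m)$ELST, 0)
})

test_that("ELST arithmetic matches the layer-switch model", {
  m <- machine_model()
  # 1 control point, 3 layers, 0.6 s per switch: (3 - 1) x 0.6 = 1.2 s
  expect_equal(estimate_times(mk_plan(3), m)$ELST, 1.2)
  # two-beam IMPT, 23 + 23 layers: (22 + 22) x 0.6 = 26.4 s
  impt <- mk_plan(c(23, 23), arc = FALSE)
  expect_equal(estimate_times(impt, m)$ELST, 26.4)
  # static plans accrue no rotation time under the default setup constant
  expect_equal(estimate_times(impt, m)$GRT, 0)
})

test_that("time components scale with their machine constants", {
  plan <- mk_plan(c(2, 2), spots_per_layer = 8, weight = 2)
  m1 <- machine_model()
  tb <- estimate_times(plan, m1)
  expect_equal(tb$SST, count_stats(plan, m1)$total_mu / 40)
  expect_equal(tb$SSWT, 0.002 * (tb$spot_count - tb$el_count))
  expect_equal(tb$GRT, 360 / (360 / 390.5))
  m2 <- machine_model(mu_rate = 80)
  expect_equal(estimate_times(plan, m2)$SST, tb$SST / 2)
})

test_that("strategy comparison reports counts, times and ratios", {
  m <- machine_model()
  a <- mk_plan(rep(1, 10)); b <- mk_plan(rep(4, 10))
  cmpr <- compare_strategies(list(mrpat = a, fullarc = b), m)
  expect_equal(nrow(cmpr$table), 2)
  r <- cmpr$ratios
  expect_equal(r$el_ratio[r$a == "mrpat" & r$b == "fullarc"], 10 / 40)
  # a plan compared with itself: all ratios 1
  same <- compare_strategies(list(x = a, y = a), m)
  expect_true(all(abs(same$ratios$el_ratio - 1) < 1e-12))
  expect_true(all(abs(same$ratios$tbd_ratio - 1) < 1e-12))
  # EL and spot counts invariant to MU calibration
  m3 <- machine_model(mu_per_weight = 7)
  cmpr3 <- compare_strategies(list(mrpat = a, fullarc = b), m3)
  expect_equal(cmpr3$ratios$el_ratio, r$el_ratio)
})
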