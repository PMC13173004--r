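# Lazily built, cached study cases shared across test files. Everything is
# deterministic, so caching only saves time, never changes results.

.case_cache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (is.null(.case_cache[[key]])) .case_cache[[key]] <- builder()
  .case_cache[[key]]
}

default_case <- function() .cached("base", function() {
  ph <- build_ellipse_phantom()
  st <- add_ring_structure(ph$structures, ph$image, 1)
  list(image = ph$image, structures = st, machine = machine_model(),
       geometry = arc_geometry())
})

# mid-range plan, selection stage only (weights all 1)
case_mrpat_plan <- function() .cached("mrpat_plan", function() {
  cs <- default_case()
  plan_mrpat(cs$image, cs$structures, cs$geometry, cs$machine)
})

# full optimization + D95 normalization + dose/LET grids
.optimized <- function(plan, stride = 1, max_iter = 400) {
  cs <- default_case()
  infl <- build_influence(plan, cs$image, cs$machine,
                          structures = cs$structures, stride = stride)
  opt <- optimize_weights(infl, default_objectives(plan$prescription),
                          influence_rows(infl, cs$structures),
                          max_iter = max_iter)
  plan$spots$weight <- opt$weights
  dl <- accumulate(plan, cs$image, cs$machine, traces = infl$traces)
  s <- normalize_to_coverage(dl$dose,
                             cs$structures$masks[[cs$structures$target]],
                             plan$prescription)
  plan$spots$weight <- plan$spots$weight * s
  dl <- accumulate(plan, cs$image, cs$machine, traces = infl$traces)
  list(plan = plan, dose_let = dl, scale = s)
}

case_mrpat_opt <- function() .cached("mrpat_opt", function()
  .optimized(case_mrpat_plan()))

case_fullarc_plan <- function() .cached("fullarc_plan", function() {
  cs <- default_case()
  plan_fullarc(cs$image, cs$structures, cs$geometry, cs$machine)
})

case_fullarc_opt <- function() .cached("fullarc_opt", function()
  .optimized(case_fullarc_plan(), stride = 4, max_iter = 300))

# mid-range plan optimized under the same conditions (stride, iterations)
# as the full-range comparator, for difference-map comparisons
case_mrpat_opt4 <- function() .cached("mrpat_opt4", function()
  .optimized(case_mrpat_plan(), stride = 4, max_iter = 300))

# distal-edge-tracking comparator (alpha = 1)
case_alpha1_opt <- function() .cached("alpha1_opt", function() {
  cs <- default_case()
  plan <- plan_mrpat(cs$image, cs$structures, cs$geometry, cs$machine,
                     config = mrel_config(alpha = 1))
  .optimized(plan)
})
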