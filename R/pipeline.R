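# End-to-end orchestration: phantom/load -> geometry -> spots -> energy
# layers -> influence -> optimize -> normalize -> dose/LET -> RBE ->
# metrics -> (optional) robustness -> timing. Deterministic: the same
# config reproduces outputs bit-identically; the config hash is recorded in
# the run report.

#' Assemble a run configuration
#'
#' @param case either `list(type = "ellipse", ...)` with
#'   [ellipse_phantom_spec()] arguments, or `list(type = "files",
#'   image = <nrrd path>, structures = <labelmap path>)`.
#' @param strategy `"mrpat"`, `"fullarc"`, or `"impt"`.
#' @param machine a `machine_model`, or a path readable by
#'   [read_machine_model()].
#' @param arc list of [arc_geometry()] arguments (arc strategies).
#' @param impt_angles static beam angles (impt strategy).
#' @param alpha mid-range scaling factor.
#' @param spot_spacing BEV lattice pitch (mm).
#' @param prescription,fractions prescription (Gy) and fraction count.
#' @param objectives an [objective_spec()], or `"default"`.
#' @param ring_width_cm conformity-ring width (0 disables the ring).
#' @param optimizer list: `max_iter`, `tol`, `stride` (optimization voxel
#'   subsampling).
#' @param robustness list: `enabled`, `range_pct`, `shift_mm`.
#' @param coverage D_x% coverage level used for normalization (95 = D95).
#' @param seed reserved; the pipeline is deterministic.
#' @return object of class `run_config`.
#' @export
run_config <- function(case = list(type = "ellipse"),
                       strategy = c("mrpat", "fullarc", "impt"),
                       machine = machine_model(),
                       arc = list(), impt_angles = c(90, 270),
                       alpha = 0.5, spot_spacing = 3,
                       prescription = 20, fractions = 10,
                       objectives = "default", ring_width_cm = 1,
                       optimizer = list(max_iter = 400, tol = 1e-6,
                                        stride = 1),
                       robustness = list(enabled = FALSE, range_pct = 3,
                                         shift_mm = 3),
                       coverage = 95, seed = 1L) {
  strategy <- match.arg(strategy)
  if (is.character(machine)) machine <- read_machine_model(machine)
  structure(list(case = case, strategy = strategy, machine = machine,
                 arc = arc, impt_angles = impt_angles, alpha = alpha,
                 spot_spacing = spot_spacing, prescription = prescription,
                 fractions = fractions, objectives = objectives,
                 ring_width_cm = ring_width_cm,
                 optimizer = utils::modifyList(
                   list(max_iter = 400, tol = 1e-6, stride = 1), optimizer),
                 robustness = utils::modifyList(
                   list(enabled = FALSE, range_pct = 3, shift_mm = 3),
                   robustness),
                 coverage = coverage, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.load_case <- function(case) {
  type <- case$type %||% "ellipse"
  if (type == "ellipse") {
    args <- case[intersect(names(case), names(formals(ellipse_phantom_spec)))]
    build_ellipse_phantom(do.call(ellipse_phantom_spec, args))
  } else if (type == "files") {
    list(image = read_nrrd(case$image),
         structures = read_structures(case$structures))
  } else stop("run_pipeline: unknown case type '", type, "'")
}

#' Run the full planning pipeline
#'
#' Builds (or loads) the case, constructs the plan for the configured
#' strategy, optimizes and normalizes spot weights, computes dose /
#' dose-averaged LET / RBE-weighted dose, evaluates DVH and hotspot
#' metrics, optionally evaluates the eight uncertainty scenarios, and
#' estimates the delivery-time breakdown. When `out_dir` is given, writes
#' NRRD grids (dose, LET_d, D_RBE), the plan JSON, metric and DVH CSVs,
#' and a JSON run report with the config hash.
#'
#' @param config a `run_config`.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param verbose print stage progress.
#' @return list with `plan`, `dose_let`, `drbe`, `metrics`, `timing`,
#'   `normalization`, `scenarios` (or NULL), `image`, `structures`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[mrpat] ", ...)
  t0 <- Sys.time()
  say("case")
  case <- .load_case(config$case)
  image <- case$image; structures <- case$structures
  machine <- config$machine

  say("plan: ", config$strategy)
  plan <- switch(
    config$strategy,
    mrpat = plan_mrpat(image, structures, do.call(arc_geometry, config$arc),
                       machine, mrel_config(alpha = config$alpha),
                       spot_spacing = config$spot_spacing,
                       prescription = config$prescription,
                       fractions = config$fractions),
    fullarc = plan_fullarc(image, structures,
                           do.call(arc_geometry, config$arc), machine,
                           spot_spacing = config$spot_spacing,
                           prescription = config$prescription,
                           fractions = config$fractions),
    impt = plan_impt(image, structures, config$impt_angles, machine,
                     spot_spacing = config$spot_spacing,
                     prescription = config$prescription,
                     fractions = config$fractions)
  )

  say("objectives")
  if (config$ring_width_cm > 0 && !"ring" %in% names(structures$masks))
    structures <- add_ring_structure(structures, image,
                                     config$ring_width_cm)
  objectives <- config$objectives
  if (identical(objectives, "default"))
    objectives <- default_objectives(
      config$prescription, target = structures$target,
      oars = setdiff(names(structures$masks),
                     c(structures$target, "body", "ring")),
      ring = if (config$ring_width_cm > 0) "ring" else NULL)

  say("influence (", nrow(plan$spots), " spots)")
  infl <- build_influence(plan, image, machine, structures = structures,
                          stride = config$optimizer$stride)
  say("optimize")
  opt <- optimize_weights(infl, objectives,
                          influence_rows(infl, structures),
                          max_iter = config$optimizer$max_iter,
                          tol = config$optimizer$tol)
  plan$spots$weight <- opt$weights

  say("dose / LET accumulation")
  dl <- accumulate(plan, image, machine, traces = infl$traces)
  tmask <- structures$masks[[structures$target]]
  s <- normalize_to_coverage(dl$dose, tmask, config$prescription,
                             config$coverage)
  plan$spots$weight <- plan$spots$weight * s
  dl <- accumulate(plan, image, machine, traces = infl$traces)

  say("RBE-weighted dose")
  drbe <- rbe_weighted_dose(dl, config$fractions, structures)

  say("metrics")
  metrics <- metrics_table(dl, drbe, structures)
  timing <- estimate_times(plan, machine)

  scen <- NULL
  if (isTRUE(config$robustness$enabled)) {
    say("robustness scenarios")
    scen <- lapply(make_scenarios(config$robustness$range_pct,
                                  config$robustness$shift_mm),
                   function(sc) {
                     dls <- apply_scenario(plan, image, structures, sc,
                                           machine)
                     list(scenario = sc$label, dose_let = dls,
                          metrics = metrics_table(
                            dls, rbe_weighted_dose(dls, config$fractions,
                                                   structures),
                            structures))
                   })
  }

  hash <- .config_hash(config)
  out <- list(plan = plan, dose_let = dl, drbe = drbe, metrics = metrics,
              timing = timing, normalization = s, optimizer = opt,
              scenarios = scen, image = image, structures = structures,
              config_hash = hash)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_nrrd(image3(dl$dose, image$spacing, image$origin),
               file.path(out_dir, "dose.nrrd"), content = "dose [Gy]")
    letd <- dl$letd; letd[!is.finite(letd)] <- 0
    write_nrrd(image3(letd, image$spacing, image$origin),
               file.path(out_dir, "letd.nrrd"), content = "LET_d [keV/um]")
    write_nrrd(image3(array(drbe, dim = image$dims), image$spacing,
                      image$origin),
               file.path(out_dir, "drbe.nrrd"), content = "D_RBE [Gy(RBE)]")
    write_plan_json(plan, file.path(out_dir, "plan.json"))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    dvhs <- lapply(names(structures$masks), function(nm)
      compute_dvh(dl$dose, structures$masks[[nm]], name = nm))
    write_dvh_csv(dvhs, file.path(out_dir, "dvh.csv"))
    utils::write.csv(
      data.frame(component = c("SST", "SSWT", "ELST", "GRT", "TBD"),
                 seconds = c(timing$SST, timing$SSWT, timing$ELST,
                             timing$GRT, timing$TBD)),
      file.path(out_dir, "timing.csv"), row.names = FALSE)
    if (!is.null(scen)) {
      sm <- do.call(rbind, lapply(scen, function(s2)
        cbind(scenario = s2$scenario, s2$metrics)))
      utils::write.csv(sm, file.path(out_dir, "scenario_metrics.csv"),
                       row.names = FALSE)
      # DVH band envelopes per structure and box summaries across scenarios
      bands <- list()
      for (nm in names(structures$masks)) {
        dvhs_sc <- lapply(scen, function(s2)
          compute_dvh(s2$dose_let$dose, structures$masks[[nm]], name = nm))
        band <- summarize_band(dvhs_sc)
        bands[[nm]] <- data.frame(structure = nm, dose = band$edges,
                                  lo = band$lo, hi = band$hi)
      }
      utils::write.csv(do.call(rbind, bands),
                       file.path(out_dir, "scenario_bands.csv"),
                       row.names = FALSE)
      tgt <- structures$target
      box <- list(
        target_D95 = worst_case_metric(vapply(scen, function(s2)
          d_metric(compute_dvh(s2$dose_let$dose, structures$masks[[tgt]]),
                   95), numeric(1)), "coverage"),
        oar_D2 = lapply(
          stats::setNames(nm = setdiff(names(structures$masks),
                                       c(tgt, "body", "ring"))),
          function(nm) worst_case_metric(vapply(scen, function(s2)
            d_metric(compute_dvh(s2$dose_let$dose, structures$masks[[nm]]),
                     2), numeric(1)), "hotspot")))
      jsonlite::write_json(box, file.path(out_dir, "scenario_box.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    utils::write.csv(
      data.frame(iteration = seq_along(opt$objective) - 1,
                 objective = opt$objective),
      file.path(out_dir, "optimizer_log.csv"), row.names = FALSE)
    report <- list(
      config_hash = hash,
      strategy = config$strategy,
      n_spots = nrow(plan$spots),
      n_energy_layers = count_stats(plan, machine)$el_count,
      empty_control_points = plan$empty_cps,
      normalization = s,
      optimizer_converged = opt$converged,
      uncovered_target_voxels = opt$uncovered,
      alpha_beta_unassigned = attr(drbe, "n_unassigned"),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
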