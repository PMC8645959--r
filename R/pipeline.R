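# Three-stage coupling pipeline.
#
# Stage A: simplified loading — a 7.5 N.m pure moment on T10, FE solve,
#          per-joint ranges of motion.
# Stage B: the stage-A rotations are imposed on the calibrated rigid-chain
#          MSK model; inverse statics gives the net joint moments; muscle
#          redundancy is resolved by static optimization.
# Stage C: realistic loading — the recruited muscle forces are applied to
#          the FE model as concentrated loads, the T10 translation is
#          prescribed to the MSK prediction, the pure moment is removed.
#
# The validation mirrors the coupling logic: stage-C ROMs must track the
# stage-A ROMs imposed on stage B, and the T10 reaction moment must agree
# between the MSK and FE solutions.

#' Full pipeline configuration
#'
#' Bundles the per-module configurations plus the reporting bounds: the
#' ROM-consistency limits (0.7 deg intact, 0.3 deg instrumented) and the
#' T10 reaction-moment relative-difference limit (3.5 %).
#'
#' @param anatomy,muscle,joints,fixation,solver,recruit module configs.
#' @param rom_bound_intact_deg,rom_bound_instrumented_deg,t10_moment_bound_pct
#'   consistency bounds used by [validate_and_report()].
#' @param pure_moment applied simplified moment, N.mm.
#' @param seed random seed recorded for perturbation studies.
#' @return list with class `pipeline_config`.
#' @export
pipeline_config <- function(anatomy = anatomy_config(),
                            muscle = muscle_config(),
                            joints = joint_config(),
                            fixation = fixation_config(),
                            solver = solver_config(),
                            recruit = recruit_config(),
                            rom_bound_intact_deg = 0.7,
                            rom_bound_instrumented_deg = 0.3,
                            t10_moment_bound_pct = 3.5,
                            pure_moment = 7500,
                            seed = 1L) {
  structure(list(anatomy = anatomy, muscle = muscle, joints = joints,
                 fixation = fixation, solver = solver, recruit = recruit,
                 rom_bound_intact_deg = rom_bound_intact_deg,
                 rom_bound_instrumented_deg = rom_bound_instrumented_deg,
                 t10_moment_bound_pct = t10_moment_bound_pct,
                 pure_moment = pure_moment, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Every file entry overrides the corresponding default; sections are
#' `anatomy`, `muscle`, `joints`, `fixation`, `solver`, `recruit`,
#' `bounds`, `loading`.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  to_num <- function(x) {
    if (is.list(x)) unlist(x) else x
  }
  sec <- function(name, ctor) {
    ov <- y[[name]]
    if (is.null(ov)) return(ctor())
    ov <- lapply(ov, to_num)
    do.call(ctor, ov)
  }
  cfg <- pipeline_config(
    anatomy = sec("anatomy", anatomy_config),
    muscle = sec("muscle", muscle_config),
    joints = sec("joints", joint_config),
    fixation = sec("fixation", fixation_config),
    solver = sec("solver", solver_config),
    recruit = sec("recruit", recruit_config)
  )
  if (!is.null(y$bounds$rom_intact_deg)) {
    cfg$rom_bound_intact_deg <- y$bounds$rom_intact_deg
  }
  if (!is.null(y$bounds$rom_instrumented_deg)) {
    cfg$rom_bound_instrumented_deg <- y$bounds$rom_instrumented_deg
  }
  if (!is.null(y$bounds$t10_moment_pct)) {
    cfg$t10_moment_bound_pct <- y$bounds$t10_moment_pct
  }
  if (!is.null(y$loading$pure_moment)) {
    cfg$pure_moment <- y$loading$pure_moment
  }
  if (!is.null(y$seed)) cfg$seed <- y$seed
  cfg
}

# Build (and cache inside the returned list) everything a variant needs.
#' @keywords internal
build_variant <- function(config, variant = c("intact", "instrumented")) {
  variant <- match.arg(variant)
  geom <- build_default_spine(config$anatomy)
  joints <- build_bushings(geom, config$joints)
  ligaments <- build_ligaments(geom, config$joints)
  construct <- NULL
  fused <- NULL
  if (variant == "instrumented") {
    construct <- build_fixation(geom, config$fixation)
    fused <- fuse_msk(config$fixation$levels)
  }
  muscles <- build_muscle_set(geom, config$muscle)
  list(variant = variant, geom = geom, joints = joints,
       ligaments = ligaments, construct = construct, fused = fused,
       muscles = muscles, config = config)
}

#' Stage A: simplified (pure moment) FE solve
#'
#' @param vb a variant bundle from the pipeline (or a `pipeline_config`,
#'   in which case the bundle is built for `variant`).
#' @param motion motion label; axial rotation is allowed here (it is used
#'   for torsional calibration) but excluded from stages B and C.
#' @param variant model variant when `vb` is a config.
#' @return an `fe_result`.
#' @export
stage_a_simplified <- function(vb, motion, variant = "intact") {
  if (inherits(vb, "pipeline_config")) vb <- build_variant(vb, variant)
  lc <- loadcase_pure_moment(motion, vb$config$pure_moment)
  model <- assemble(vb$geom, vb$joints, vb$ligaments, vb$construct, lc,
                    vb$config$solver)
  solve_static(model)
}

#' Stage B: inverse statics and muscle recruitment
#'
#' @param vb a variant bundle.
#' @param motion one of flexion, extension, lateral_left, lateral_right.
#' @param stage_a named list of stage-A results covering the calibration
#'   motions (and `motion` itself).
#' @return a `muscle_solution` with the T10 translation prediction filled.
#' @export
stage_b_msk <- function(vb, motion, stage_a) {
  if (!(motion %in% all_motions())) {
    stop("stage B error: motion must be one of ",
         paste(all_motions(), collapse = ", "))
  }
  stiffness <- calibrate_stiffness(stage_a, vb$config$recruit,
                                   vb$config$pure_moment)
  imposed <- imposed_motion_from_fe(stage_a[[motion]], vb$fused)
  grav <- gravity_loads(vb$geom, vb$config$recruit)
  moments <- inverse_statics(vb$geom, imposed, stiffness, grav)
  sol <- recruit_muscles(moments, vb$muscles, vb$geom, vb$config$recruit,
                         motion, grav)
  sol$t10_translation <- predict_t10_translation(vb, sol)
  sol$imposed <- imposed
  sol
}

#' Stage C: realistic (muscle force) FE solve
#'
#' @param vb a variant bundle.
#' @param solution the stage-B `muscle_solution` for the same variant and
#'   motion.
#' @return an `fe_result`.
#' @export
stage_c_realistic <- function(vb, solution) {
  lc <- loadcase_muscle(solution, vb$muscles, vb$geom)
  model <- assemble(vb$geom, vb$joints, vb$ligaments, vb$construct, lc,
                    vb$config$solver)
  solve_static(model)
}

# T10 reaction moment on the FE side: load transmitted across T10/T11,
# reported about the T10 upper endplate (same convention as the MSK side).
#' @keywords internal
fe_t10_transmitted <- function(result) {
  transmitted_load(result, "T10/T11",
                   result$model$geom$bodies$T10$upper_endplate)
}

#' Run the full coupling for one variant and one motion
#'
#' @param config a `pipeline_config`.
#' @param variant `"intact"` or `"instrumented"`.
#' @param motion one of flexion, extension, lateral_left, lateral_right.
#' @param vb optional prebuilt variant bundle (reused across motions).
#' @param stage_a optional precomputed stage-A result list.
#' @return list with `rom_simplified`, `rom_realistic` (named, degrees),
#'   `solution`, `result_a`, `result_c`, `t10_fe`, `t10_msk`.
#' @export
run_coupling <- function(config, variant, motion, vb = NULL, stage_a = NULL) {
  if (is.null(vb)) vb <- build_variant(config, variant)
  if (is.null(stage_a)) {
    stage_a <- lapply(calibration_motions(), function(m)
      stage_a_simplified(vb, m))
    names(stage_a) <- calibration_motions()
  }
  sol <- stage_b_msk(vb, motion, stage_a)
  res_c <- stage_c_realistic(vb, sol)
  list(variant = variant, motion = motion,
       rom_simplified = compute_rom(stage_a[[motion]], motion),
       rom_realistic = compute_rom(res_c, motion),
       solution = sol, result_a = stage_a[[motion]], result_c = res_c,
       t10_fe = fe_t10_transmitted(res_c),
       t10_msk = sol$t10_transmitted)
}

#' Run the coupling validation suite and build the comparison report
#'
#' Runs stages A to C for the requested motions, assembles the
#' simplified-vs-realistic comparison (ROMs, T10 reaction moments, implant
#' stresses) and checks the configured consistency bounds.
#'
#' @param config a `pipeline_config`.
#' @param variant `"intact"` or `"instrumented"`.
#' @param motions motion labels (default: all four).
#' @param out_dir optional directory for the CSV reports.
#' @return object of class `coupling_report`.
#' @export
validate_and_report <- function(config, variant = "intact",
                                motions = all_motions(), out_dir = NULL) {
  vb <- build_variant(config, variant)
  stage_a <- lapply(calibration_motions(), function(m) stage_a_simplified(vb, m))
  names(stage_a) <- calibration_motions()

  runs <- lapply(motions, function(m)
    run_coupling(config, variant, m, vb = vb, stage_a = stage_a))
  names(runs) <- motions

  per_motion <- lapply(runs, function(r) {
    diff <- abs(r$rom_realistic - r$rom_simplified)
    axis <- motion_axis(r$motion)
    m_fe <- sum(r$t10_fe$moment * axis)
    m_msk <- sum(r$t10_msk$moment * axis)
    rel <- abs(m_fe - m_msk) / abs(m_msk)
    rel_norm <- abs(sqrt(sum(r$t10_fe$moment^2)) -
                    sqrt(sum(r$t10_msk$moment^2))) /
      sqrt(sum(r$t10_msk$moment^2))
    list(motion = r$motion,
         rom_simplified = r$rom_simplified,
         rom_realistic = r$rom_realistic,
         rom_max_abs_diff = max(diff),
         t10_moment_fe = m_fe, t10_moment_msk = m_msk,
         t10_moment_rel_diff = rel,
         t10_moment_rel_diff_norm = rel_norm,
         stresses_simplified = r$result_a$von_mises,
         stresses_realistic = r$result_c$von_mises)
  })

  rom_bound <- if (variant == "intact") config$rom_bound_intact_deg else
    config$rom_bound_instrumented_deg
  rom_max <- max(vapply(per_motion, `[[`, numeric(1), "rom_max_abs_diff"))
  t10_max_pct <- 100 * max(vapply(per_motion, `[[`, numeric(1),
                                  "t10_moment_rel_diff"))
  bounds_ok <- rom_max <= rom_bound &&
    t10_max_pct <= config$t10_moment_bound_pct

  stress_delta <- NULL
  if (variant == "instrumented") {
    stress_delta <- do.call(rbind, lapply(per_motion, function(pm) {
      s <- merge(pm$stresses_simplified, pm$stresses_realistic,
                 by = "component", suffixes = c("_simplified", "_realistic"))
      s$delta_MPa <- s$max_von_mises_MPa_realistic -
        s$max_von_mises_MPa_simplified
      ys <- config$fixation$yield_stress
      s$delta_pct_yield <- if (!is.null(ys)) 100 * s$delta_MPa / ys else NA_real_
      s$motion <- pm$motion
      s
    }))
    rownames(stress_delta) <- NULL
  }

  report <- structure(list(
    variant = variant, motions = motions, per_motion = per_motion,
    rom_max_abs_diff = rom_max, rom_bound_deg = rom_bound,
    t10_moment_max_rel_diff_pct = t10_max_pct,
    t10_moment_bound_pct = config$t10_moment_bound_pct,
    bounds_ok = bounds_ok, stress_delta = stress_delta,
    runs = runs
  ), class = "coupling_report")

  if (!is.null(out_dir)) write_report_csvs(report, out_dir)
  report
}

#' @keywords internal
write_report_csvs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rom <- do.call(rbind, lapply(report$per_motion, function(pm) {
    data.frame(motion = pm$motion, joint = names(pm$rom_simplified),
               rom_simplified_deg = as.numeric(pm$rom_simplified),
               rom_realistic_deg = as.numeric(pm$rom_realistic),
               abs_diff_deg = abs(as.numeric(pm$rom_realistic) -
                                  as.numeric(pm$rom_simplified)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rom, file.path(out_dir, "rom_comparison.csv"),
                   row.names = FALSE)
  t10 <- do.call(rbind, lapply(report$per_motion, function(pm) {
    data.frame(motion = pm$motion,
               t10_moment_fe_Nm = pm$t10_moment_fe / 1000,
               t10_moment_msk_Nm = pm$t10_moment_msk / 1000,
               rel_diff_pct = 100 * pm$t10_moment_rel_diff,
               rel_diff_norm_pct = 100 * pm$t10_moment_rel_diff_norm,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(t10, file.path(out_dir, "t10_moment_comparison.csv"),
                   row.names = FALSE)
  if (!is.null(report$stress_delta)) {
    utils::write.csv(report$stress_delta,
                     file.path(out_dir, "stress_comparison.csv"),
                     row.names = FALSE)
  }
  forces <- do.call(rbind, lapply(report$runs, function(r) {
    data.frame(motion = r$motion, fascicle = names(r$solution$fascicle_forces),
               force_N = as.numeric(r$solution$fascicle_forces),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(forces, file.path(out_dir, "muscle_forces.csv"),
                   row.names = FALSE)
  meta <- c(
    paste0("package: spinecouple ",
           as.character(utils::packageVersion("spinecouple"))),
    paste0("variant: ", report$variant),
    paste0("motions: ", paste(report$motions, collapse = ", ")),
    paste0("rom_max_abs_diff_deg: ", format(report$rom_max_abs_diff)),
    paste0("t10_moment_max_rel_diff_pct: ",
           format(report$t10_moment_max_rel_diff_pct)),
    paste0("bounds_ok: ", report$bounds_ok)
  )
  writeLines(meta, file.path(out_dir, "run_metadata.txt"))
  invisible(out_dir)
}

#' @export
print.coupling_report <- function(x, ...) {
  cat("Coupling report (", x$variant, "): motions ",
      paste(x$motions, collapse = ", "), "\n", sep = "")
  cat("  max |ROM realistic - simplified| = ",
      format(x$rom_max_abs_diff, digits = 3), " deg (bound ",
      x$rom_bound_deg, " deg)\n", sep = "")
  cat("  max T10 reaction-moment relative difference = ",
      format(x$t10_moment_max_rel_diff_pct, digits = 3), " % (bound ",
      x$t10_moment_bound_pct, " %)\n", sep = "")
  if (!is.null(x$stress_delta)) {
    cat("  max implant stress increase (realistic - simplified) = ",
        format(max(x$stress_delta$delta_MPa), digits = 3), " MPa\n", sep = "")
  }
  cat("  consistency bounds ", if (x$bounds_ok) "hold" else "VIOLATED", "\n",
      sep = "")
  invisible(x)
}
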