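stage_a_all <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      vb <- spinecouple:::build_variant(pipeline_config(), "intact")
      res <- lapply(calibration_motions(), function(m) stage_a_simplified(vb, m))
      names(res) <- calibration_motions()
      cache <<- list(vb = vb, stage_a = res)
    }
    cache
  }
})

test_that("secant stiffness is moment over rotation (5 deg at 7.5 N.m)", {
  # hand-computed oracle: 7500 / (5 * pi / 180) N.mm/rad
  th <- 5 * pi / 180
  expect_equal(7500 / th, 85943.6692696, tolerance = 1e-10)
  # and the calibration reproduces it on a joint arranged to rotate 5 deg
  k_true <- 7500 / th
  joints <- build_bushings(default_geom, linear_joint_config)
  for (jl in setdiff(names(joints), c("SIJ-left", "SIJ-right"))) {
    joints[[jl]]$K_rot <- diag(rep(k_true, 3))
  }
  vb <- list(geom = default_geom, joints = joints, ligaments = list(),
             construct = NULL, config = pipeline_config())
  sa <- lapply(calibration_motions(), function(m) {
    solve_static(assemble(default_geom, joints, list(), NULL,
                          loadcase_pure_moment(m, 7500)))
  })
  names(sa) <- calibration_motions()
  st <- calibrate_stiffness(sa)
  expect_equal(unname(st[["L2/L3"]]["y", "pos"]), k_true, tolerance = 1e-6)
  expect_equal(unname(st[["L2/L3"]]["y", "neg"]), k_true, tolerance = 1e-6)
})

test_that("calibration round-trips exactly on an all-linear model", {
  # with linear bushings the MSK required moment about the motion axis
  # equals the applied pure moment at every cut
  joints <- build_bushings(default_geom, linear_joint_config)
  sa <- lapply(calibration_motions(), function(m) {
    solve_static(assemble(default_geom, joints, list(), NULL,
                          loadcase_pure_moment(m, 7500)))
  })
  names(sa) <- calibration_motions()
  st <- calibrate_stiffness(sa)
  for (motion in all_motions()) {
    imp <- imposed_motion_from_fe(sa[[motion]])
    mom <- inverse_statics(default_geom, imp, st)
    axis <- motion_axis(motion)
    for (cutl in names(mom)) {
      expect_equal(sum(mom[[cutl]] * axis), 7500, tolerance = 1e-6)
    }
  }
})

test_that("calibration round-trip stays within 5% with tension-only ligaments", {
  sa <- stage_a_all()$stage_a
  st <- calibrate_stiffness(sa)
  for (motion in all_motions()) {
    imp <- imposed_motion_from_fe(sa[[motion]])
    mom <- inverse_statics(default_geom, imp, st)
    axis <- motion_axis(motion)
    for (cutl in names(mom)) {
      expect_equal(sum(mom[[cutl]] * axis) / 7500, 1, tolerance = 0.05)
    }
  }
})

test_that("inverse statics obeys the null case, the spring law and mirroring", {
  sa <- stage_a_all()$stage_a
  st <- calibrate_stiffness(sa)
  # null case: zero imposed motion -> zero required moments
  imp0 <- imposed_motion_from_fe(sa$flexion)
  for (cl in names(imp0)) imp0[[cl]] <- c(0, 0, 0)
  mom0 <- inverse_statics(default_geom, imp0, st)
  expect_lt(max(vapply(mom0, function(m) max(abs(m)), numeric(1))), 1e-12)
  # single joint spring law: moment = k * theta componentwise
  imp1 <- imp0
  th <- c(0, 0.02, 0)
  imp1[["L1/L2"]] <- th
  mom1 <- inverse_statics(default_geom, imp1, st)
  Rj <- spinecouple:::cut_frame(default_geom, "L1/L2")
  expect_equal(mom1[["L1/L2"]],
               as.numeric(Rj %*% (st[["L1/L2"]][, "pos"] * th)),
               tolerance = 1e-12)
  # mirrored motion gives mirrored moments
  ml <- inverse_statics(default_geom, imposed_motion_from_fe(sa$lateral_left), st)
  mr <- inverse_statics(default_geom, imposed_motion_from_fe(sa$lateral_right), st)
  for (cl in names(ml)) {
    expect_equal(ml[[cl]] * c(-1, 1, -1), mr[[cl]], tolerance = 1e-6)
  }
  # out-of-range rotations are rejected
  imp_big <- imp0
  imp_big[["L1/L2"]] <- c(0, 1, 0)   # 57 deg
  expect_error(inverse_statics(default_geom, imp_big, st), "small-angle")
})

test_that("a single fascicle at 50 mm carries exactly 150 N for 7.5 N.m", {
  A <- matrix(50, 1, 1, dimnames = list(NULL, "toy"))
  r <- recruit_forces(A, 7500, f_max = 1000)
  expect_equal(unname(r$f), 150, tolerance = 1e-7)
})

test_that("two identical fascicles split the force exactly in half", {
  A <- matrix(c(50, 50), 1, 2, dimnames = list(NULL, c("a", "b")))
  r <- recruit_forces(A, 7500, f_max = c(1000, 1000))
  expect_equal(unname(r$f[["a"]]), 75, tolerance = 1e-6)
  expect_equal(unname(r$f[["a"]]), unname(r$f[["b"]]), tolerance = 1e-9)
})

test_that("zero required moments produce zero forces and zero objective", {
  A <- matrix(rnorm(12), 3, 4)
  r <- recruit_forces(A, c(0, 0, 0), f_max = rep(100, 4))
  expect_identical(max(r$f), 0)
  expect_identical(r$objective, 0)
})

test_that("recruitment satisfies the independent equilibrium certificate on random problems", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 12; m <- 4
    A <- matrix(rnorm(m * n, sd = 40), m, n,
                dimnames = list(NULL, paste0("f", 1:n)))
    f_true <- runif(n, 1, 50)
    b <- as.numeric(A %*% f_true)        # feasible by construction
    f_max <- rep(500, n)
    r <- recruit_forces(A, b, f_max)
    # brute-force verification, independent of the optimizer internals
    resid <- sqrt(sum((as.numeric(A %*% r$f) - b)^2)) / sqrt(sum(b^2))
    expect_lt(resid, 1e-6)
    expect_true(all(r$f >= -1e-12))
  }
})

test_that("objective scales with the required moments and is monotone", {
  A <- matrix(c(50, 30, 10, 45), 2, 2, dimnames = list(NULL, c("a", "b")))
  b0 <- c(4000, 3000)
  f_max <- c(400, 400)
  r1 <- recruit_forces(A, b0, f_max)
  alphas <- c(0.25, 0.5, 0.75, 1)
  objs <- vapply(alphas, function(al)
    recruit_forces(A, al * b0, f_max)$objective, numeric(1))
  expect_true(all(diff(objs) > 0))       # non-decreasing in the load scale
  # square system: unique solution scales linearly, objective cubically
  r_half <- recruit_forces(A, 0.5 * b0, f_max)
  expect_equal(unname(r_half$f), unname(0.5 * r1$f), tolerance = 1e-6)
})

test_that("full recruitment passes the certificate and activates antagonistic patterns", {
  st <- calibrate_stiffness(stage_a_all()$stage_a)
  vb <- stage_a_all()$vb
  sa <- stage_a_all()$stage_a
  sols <- lapply(c("flexion", "extension"), function(m) {
    imp <- imposed_motion_from_fe(sa[[m]])
    mom <- inverse_statics(vb$geom, imp, st)
    recruit_muscles(mom, vb$muscles, vb$geom, motion = m)
  })
  names(sols) <- c("flexion", "extension")
  for (s in sols) expect_lt(s$equilibrium_residual_rel, 1e-6)
  # flexors dominate flexion, extensors extension: compare group shares
  share <- function(sol, groups) {
    g <- vapply(vb$muscles, `[[`, character(1), "group")
    sum(sol$fascicle_forces[g %in% groups]) / sum(sol$fascicle_forces)
  }
  extensors <- c("erector_spinae", "multifidus", "spinalis", "semispinalis")
  flexors <- c("psoas_major", "obliquus_externus", "obliquus_internus",
               "transversus")
  expect_gt(share(sols$extension, extensors), share(sols$flexion, extensors))
  expect_gt(share(sols$flexion, flexors), share(sols$extension, flexors))
})

test_that("fused joints are forced to zero rotation and dropped from recruitment", {
  cfg <- pipeline_config()
  vb <- spinecouple:::build_variant(cfg, "instrumented")
  sa <- lapply(calibration_motions(), function(m) stage_a_simplified(vb, m))
  names(sa) <- calibration_motions()
  imp <- imposed_motion_from_fe(sa$flexion, vb$fused)
  for (jl in vb$fused) expect_identical(imp[[jl]], c(0, 0, 0))
  # fused cuts carry no recruitment constraint: moments pass through whole
  st <- calibrate_stiffness(sa)
  mom <- inverse_statics(vb$geom, imp, st)
  expect_false(any(vb$fused %in% names(mom)))
  expect_true(all(c("T10/T11", "T12/L1", "L5/S1") %in% names(mom)))
})

test_that("a rigid joint is calibrated to the configured ceiling with a warning", {
  joints <- build_bushings(default_geom, linear_joint_config)
  joints[["L2/L3"]]$K_rot <- diag(rep(1e11, 3))
  sa <- lapply(calibration_motions(), function(m) {
    solve_static(assemble(default_geom, joints, list(), NULL,
                          loadcase_pure_moment(m, 7500)))
  })
  names(sa) <- calibration_motions()
  st <- NULL
  w <- capture_warnings(st <- calibrate_stiffness(sa))
  expect_true(all(grepl("rigid ceiling", w)))
  expect_length(w, 5)    # one per calibrated axis/direction of L2/L3
  ceiling_rad <- recruit_config()$rigid_ceiling * 180 / pi
  expect_true(all(st[["L2/L3"]] == ceiling_rad))
  expect_false(any(st[["L3/L4"]] == ceiling_rad))
})

test_that("the muscle force solution round-trips through its CSV hand-off", {
  st <- calibrate_stiffness(stage_a_all()$stage_a)
  vb <- stage_a_all()$vb
  imp <- imposed_motion_from_fe(stage_a_all()$stage_a$extension)
  mom <- inverse_statics(vb$geom, imp, st)
  sol <- recruit_muscles(mom, vb$muscles, vb$geom, motion = "extension")
  sol$t10_translation <- c(1.23456789, -0.000123456789, 9.87654321)
  path <- withr::local_tempfile(fileext = ".csv")
  write_solution_csv(sol, path)
  sol2 <- read_solution_csv(path)
  # bit-exact at the printed precision (9 significant digits)
  expect_equal(sol2$fascicle_forces, sol$fascicle_forces, tolerance = 1e-8)
  expect_equal(sol2$t10_transmitted$moment, sol$t10_transmitted$moment,
               tolerance = 1e-8 * max(abs(sol$t10_transmitted$moment)))
  expect_equal(sol2$t10_translation, sol$t10_translation, tolerance = 1e-8)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_solution_csv(sol2, path2)
  expect_identical(readLines(path), readLines(path2))
})
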