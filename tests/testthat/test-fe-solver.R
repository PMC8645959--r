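test_that("zero load produces zero displacements, stresses and reactions", {
  lc <- loadcase_pure_moment("flexion", 7500)
  lc$pure_moment <- c(0, 0, 0)       # null case
  m <- assemble(default_geom, default_joints, default_ligaments, NULL, lc)
  r <- solve_static(m)
  expect_lt(max(abs(r$body_disp)), 1e-12)
  expect_lt(max(abs(r$reactions)), 1e-9)
  expect_equal(unname(compute_rom(r, "flexion")),
               rep(0, length(r$joint_rot)))
})

test_that("a single linear bushing reproduces the closed form in all six DOF", {
  # chain rigid everywhere except T10/T11: the T10 response to loads at
  # the joint centre is the hand-computed bushing flexibility
  k_rot <- 1e5; k_trans <- 2000
  joints <- single_joint_bushings(default_geom, "T10/T11", k_rot, k_trans)
  jc <- default_geom$joints[["T10/T11"]]$center
  Rj <- default_geom$joints[["T10/T11"]]$R
  for (dof in 1:6) {
    lc <- loadcase_pure_moment("flexion", 1)
    lc$pure_moment <- c(0, 0, 0)
    load6 <- numeric(6); load6[dof] <- 1000
    lc$point_loads <- list(list(body = "T10", point = jc,
                                force = load6[1:3], moment = load6[4:6]))
    r <- solve_static(assemble(default_geom, joints, list(), NULL, lc))
    th <- r$joint_rot[["T10/T11"]]          # local frame
    # closed form: theta = Kr^-1 R' M, u(at jc) = Kt^-1 R' F
    th_exp <- as.numeric(t(Rj) %*% load6[4:6]) / k_rot
    expect_equal(th, th_exp, tolerance = 1e-5)
    # relative displacement at the joint centre (T10 relative to T11)
    da <- r$body_disp["T10", ]; db <- r$body_disp["T11", ]
    u_rel <- (da[1:3] + spinecouple:::cross3(
      da[4:6], jc - default_geom$bodies$T10$center)) -
      (db[1:3] + spinecouple:::cross3(
        db[4:6], jc - default_geom$bodies$T11$center))
    u_exp <- as.numeric(Rj %*% (t(Rj) %*% load6[1:3]) / k_trans)
    expect_equal(unname(u_rel), u_exp, tolerance = 1e-5)
  }
})

test_that("single linear joint under 7.5 N.m rotates by M/k", {
  # k = 1 N.m/deg about the motion axis -> 7.5 deg under 7.5 N.m
  k <- 1000 * 180 / pi                     # 1 N.m/deg in N.mm/rad
  joints <- single_joint_bushings(default_geom, "L3/L4", k_rot = k,
                                  k_trans = 5e4)
  r <- solve_static(assemble(default_geom, joints, list(), NULL,
                             loadcase_pure_moment("extension", 7500)))
  rom <- compute_rom(r, "extension")
  expect_equal(unname(rom[["L3/L4"]]), 7.5, tolerance = 1e-5)
})

test_that("the response is linear in the load when ligaments are disabled", {
  joints <- build_bushings(default_geom, linear_joint_config)
  r1 <- solve_static(assemble(default_geom, joints, list(), NULL,
                              loadcase_pure_moment("flexion", 7500)))
  r2 <- solve_static(assemble(default_geom, joints, list(), NULL,
                              loadcase_pure_moment("flexion", 15000)))
  expect_equal(2 * r1$body_disp, r2$body_disp, tolerance = 1e-10)
})

test_that("a pure moment is transmitted unchanged across every intact joint", {
  for (motion in c("flexion", "lateral_left", "axial_rotation")) {
    r <- solve_static(assemble(default_geom, default_joints,
                               default_ligaments, NULL,
                               loadcase_pure_moment(motion, 7500)))
    m_applied <- 7500 * motion_axis(motion)
    for (cutl in spinecouple:::cut_labels()) {
      tl <- transmitted_load(r, cutl)
      expect_equal(tl$moment, m_applied, tolerance = 1e-8 * 7500)
      expect_lt(max(abs(tl$force)), 1e-8 * 7500)
    }
  }
})

test_that("flexion and extension moments are exact negatives", {
  lf <- loadcase_pure_moment("flexion", 7500)
  le <- loadcase_pure_moment("extension", 7500)
  expect_identical(lf$pure_moment, -le$pure_moment)
  expect_error(loadcase_pure_moment("sidebend", 7500), "unknown motion")
  expect_error(loadcase_pure_moment("flexion", -5), "positive")
})

test_that("lateral bending left and right mirror each other on the symmetric model", {
  rl <- solve_static(assemble(default_geom, default_joints,
                              default_ligaments, NULL,
                              loadcase_pure_moment("lateral_left", 7500)))
  rr <- solve_static(assemble(default_geom, default_joints,
                              default_ligaments, NULL,
                              loadcase_pure_moment("lateral_right", 7500)))
  expect_equal(compute_rom(rl, "lateral_left"),
               compute_rom(rr, "lateral_right"), tolerance = 1e-9)
})

test_that("ROM is invariant to a rigid translation of the configuration", {
  r <- solve_static(assemble(default_geom, default_joints,
                             default_ligaments, NULL,
                             loadcase_pure_moment("flexion", 7500)))
  rom0 <- compute_rom(r, "flexion")
  shifted <- r
  shifted$body_disp[, 1:3] <- shifted$body_disp[, 1:3] +
    matrix(c(3, -2, 5), nrow(shifted$body_disp), 3, byrow = TRUE)
  shifted$joint_rot <- lapply(names(shifted$joint_rot), function(jl) {
    b <- shifted$model$joints[[jl]]
    as.numeric(t(b$R) %*% (shifted$body_disp[b$a, 4:6] -
                             shifted$body_disp[b$b, 4:6]))
  })
  names(shifted$joint_rot) <- names(r$joint_rot)
  expect_equal(compute_rom(shifted, "flexion"), rom0, tolerance = 1e-12)
})

test_that("beam von Mises stress matches the closed-form section oracles", {
  sec <- circular_section(5.5)
  # oracles computed independently from 32 M / (pi d^3) and 4 N / (pi d^2)
  expect_equal(beam_von_mises(list(My = 7500), sec), 459.169783225,
               tolerance = 1e-10)
  expect_equal(beam_von_mises(list(N = 1000), sec), 42.0905634623,
               tolerance = 1e-10)
  expect_identical(beam_von_mises(list(), sec), 0)
  # pure torsion: sqrt(3) * 16 T / (pi d^3)
  Tq <- 5000
  expect_equal(beam_von_mises(list(T = Tq), sec),
               sqrt(3) * 16 * Tq / (pi * 5.5^3), tolerance = 1e-10)
  expect_error(circular_section(-1), "diameter")
})

test_that("muscle point loads are equal and opposite along the line of action", {
  ms <- toy_muscle_set(default_geom, n_fascicles = 1)
  # add a via point on L3 to exercise the redirection forces
  via_ms <- ms
  via_ms[[1]]$via_points <- list(list(
    point = default_geom$bodies$L3$center + c(-60, 0, 0), body = "L3"))
  sol <- structure(list(fascicle_forces = c(toy_1 = 120),
                        t10_reaction = NULL, t10_translation = NULL,
                        motion = "flexion"), class = "muscle_solution")
  lc <- loadcase_muscle(sol, via_ms, default_geom)
  Ftot <- Reduce(`+`, lapply(lc$point_loads, `[[`, "force"))
  Mtot <- Reduce(`+`, lapply(lc$point_loads, function(pl)
    pl$moment + spinecouple:::cross3(pl$point, pl$force)))
  expect_lt(max(abs(Ftot)), 1e-9)
  expect_lt(max(abs(Mtot)), 1e-6)
})

test_that("zero muscle forces reproduce the zero-load state", {
  sol <- structure(list(fascicle_forces = setNames(
    rep(0, length(default_muscles)), names(default_muscles)),
    t10_reaction = NULL, t10_translation = NULL, motion = "flexion"),
    class = "muscle_solution")
  lc <- loadcase_muscle(sol, default_muscles, default_geom)
  r <- solve_static(assemble(default_geom, default_joints,
                             default_ligaments, NULL, lc))
  expect_lt(max(abs(r$body_disp)), 1e-12)
})

test_that("an unsupported chain is reported as a mechanism", {
  joints <- default_joints
  joints[["L3/L4"]] <- NULL    # break the chain: T10..L3 float free
  expect_error(
    solve_static(assemble(default_geom, joints, list(), NULL,
                          loadcase_pure_moment("flexion", 7500))),
    "singular|unconstrained")
})
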