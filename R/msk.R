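# Inverse-static musculoskeletal stage.  The joint rotational stiffness of
# the rigid-chain MSK model is calibrated to the secant moment-rotation
# behaviour of the FE model under 7.5 N.m pure moments (per axis and per
# signed direction, since tension-only ligaments make the response
# direction-dependent; coupling terms are discarded).  Intervertebral
# rotations from the FE stage are then imposed, the net joint moments the
# muscles must supply are computed, and muscle redundancy is resolved by a
# convex polynomial criterion min sum (f_i/f_max_i)^p subject to moment
# equilibrium about every free joint cut and f >= 0.

#' Recruitment configuration
#'
#' @param ... named overrides merged over the defaults: `exponent` (the
#'   polynomial criterion power, > 1), `gravity` (include gravitational
#'   segment loads in the realistic stage; on by default, since the
#'   compressive body weight carried by the muscles is what distinguishes
#'   realistic from pure-moment loading), `segment_masses` (kg per
#'   vertebral level), `above_t10_mass` (kg of head, arms and thorax above
#'   the T10 boundary, applied as the T10 reaction load),
#'   `rigid_ceiling` (N.mm/deg stiffness assigned to joints the FE reports
#'   as rigid), `eq_tol_rel` (relative equilibrium certificate tolerance).
#' @return list with class `recruit_config`.
#' @export
recruit_config <- function(...) {
  cfg <- list(exponent = 3, gravity = TRUE, g = 9.81,
              segment_masses = c(T10 = 1.6, T11 = 1.6, T12 = 1.6,
                                 L1 = 2, L2 = 2, L3 = 2, L4 = 2, L5 = 2),
              segment_com_offset = c(10, 0, 0),     # body frame, mm
              above_t10_mass = 21,
              # global offset of the upper-body COM from the T10 centre:
              # the head/arm/thorax mass sits slightly anterior of the
              # thoracolumbar junction in balanced standing
              above_t10_com_offset = c(5, 0, 150),
              rigid_ceiling = 1e6,
              eq_tol_rel = 1e-6, ip_tol = 1e-10, ip_max_iter = 200)
  override_config(cfg, list(...), "recruit_config")
}

#' Gravitational segment loads
#'
#' Point weights of the modelled trunk slices (T10..L5, at a configurable
#' anterior centre-of-mass offset) plus the lumped weight of the body
#' above the T10 boundary.  Used by both the inverse statics (moment
#' balance) and the realistic FE load case, so the two stages see the
#' identical load set.
#'
#' @param geom a `spine_geometry`.
#' @param config a [recruit_config()].
#' @return list of loads (`body`, `point`, `force`); the above-T10 entry
#'   is flagged with `boundary = TRUE`.
#' @export
gravity_loads <- function(geom, config = recruit_config()) {
  if (!isTRUE(config$gravity)) return(list())
  out <- list()
  for (lv in names(config$segment_masses)) {
    b <- geom$bodies[[lv]]
    com <- as.numeric(b$center + b$R %*% config$segment_com_offset)
    out[[length(out) + 1]] <- list(
      body = lv, point = com,
      force = c(0, 0, -config$g * config$segment_masses[[lv]]),
      boundary = FALSE)
  }
  bT10 <- geom$bodies$T10
  com <- as.numeric(bT10$center + config$above_t10_com_offset)
  out[[length(out) + 1]] <- list(
    body = "T10", point = com,
    force = c(0, 0, -config$g * config$above_t10_mass),
    boundary = TRUE)
  out
}

#' Calibrate MSK joint stiffness from FE pure-moment solves
#'
#' For every joint cut and every rotational axis, the secant stiffness
#' k = (transmitted local moment component) / (local rotation component)
#' at 7.5 N.m, taken from the FE solve whose dominant local component is
#' that axis and direction (flexion and extension give the two signed
#' secants of the sagittal axis, the lateral solves those of the frontal
#' axis, axial rotation the torsional one).  Joints the FE reports as rigid
#' (fused levels) get the configured rigid ceiling with a warning.
#'
#' @param stage_a named list of `fe_result`s keyed by calibration motion
#'   (must contain flexion, extension, lateral_left, lateral_right,
#'   axial_rotation).
#' @param config a [recruit_config()].
#' @param moment applied pure-moment magnitude used in the solves, N.mm.
#' @return object of class `joint_stiffness`: per cut, a 3 x 2 matrix of
#'   secants (rows = local x/y/z axis, columns = negative/positive rotation
#'   direction), N.mm/rad.
#' @export
calibrate_stiffness <- function(stage_a, config = recruit_config(),
                                moment = 7500) {
  needed <- calibration_motions()
  if (!all(needed %in% names(stage_a))) {
    stop("calibration error: stage-A results required for ",
         paste(setdiff(needed, names(stage_a)), collapse = ", "))
  }
  ceiling_rad <- config$rigid_ceiling * 180 / pi   # N.mm/deg -> N.mm/rad
  cuts <- cut_labels()
  # which solve calibrates which (axis, sign): dominant local component
  sources <- list(
    list(motion = "lateral_right", axis = 1, sign = 2),
    list(motion = "lateral_left", axis = 1, sign = 1),
    list(motion = "flexion", axis = 2, sign = 2),
    list(motion = "extension", axis = 2, sign = 1),
    list(motion = "axial_rotation", axis = 3, sign = 2)
  )
  out <- list()
  for (cutl in cuts) {
    K <- matrix(NA_real_, 3, 2, dimnames = list(c("x", "y", "z"),
                                                c("neg", "pos")))
    for (s in sources) {
      res <- stage_a[[s$motion]]
      theta <- cut_rotation(res, cutl)
      tl <- transmitted_load(res, cutl)
      Rj <- cut_frame(res$model$geom, cutl)
      m_local <- as.numeric(t(Rj) %*% tl$moment)
      th <- theta[s$axis]
      if (abs(th) < deg2rad(1e-4)) {
        warning("calibration: joint ", cutl, " is rigid about axis ",
                c("x", "y", "z")[s$axis], "; using the rigid ceiling")
        K[s$axis, s$sign] <- ceiling_rad
      } else {
        K[s$axis, s$sign] <- m_local[s$axis] / th
      }
    }
    # axial torsion: symmetric, one calibration direction serves both signs
    K[3, 1] <- K[3, 2]
    if (any(!is.finite(K)) || any(K <= 0)) {
      stop("calibration error: non-positive secant stiffness at ", cutl)
    }
    out[[cutl]] <- K
  }
  structure(out, class = "joint_stiffness", moment = moment)
}

# local rotation vector of a cut (cranial part relative to caudal, cut frame)
#' @keywords internal
cut_rotation <- function(result, cut) {
  if (cut == "S/P") {
    # sacrum relative to pelvis; both SIJ bushings share this rotation
    ta <- result$body_disp["Sacrum", 4:6]
    tb <- result$body_disp["Pelvis", 4:6]
    as.numeric(ta - tb)
  } else {
    result$joint_rot[[cut]]
  }
}

#' Imposed motion from a stage-A FE result
#'
#' Extracts the per-cut relative rotation vectors (cut frame, radians) of a
#' simplified-loading FE solve; joints fused by the instrumented variant
#' are forced to exactly zero.
#'
#' @param result a stage-A `fe_result`.
#' @param fused optional `msk_fusion` (fused joint labels).
#' @return object of class `imposed_motion`: named list of length-3
#'   rotation vectors per cut, with attributes `motion` and `fused`.
#' @export
imposed_motion_from_fe <- function(result, fused = NULL) {
  motion <- result$loadcase$motion
  rots <- lapply(cut_labels(), function(cl) cut_rotation(result, cl))
  names(rots) <- cut_labels()
  if (!is.null(fused)) {
    for (jl in fused) rots[[jl]] <- c(0, 0, 0)
  }
  structure(rots, class = "imposed_motion", motion = motion, fused = fused)
}

#' Net joint moments required from the muscles
#'
#' For each non-fused cut, the muscles must supply the passive joint moment
#' k * rotation (per local axis, signed secants), expressed in the global
#' frame about the cut centre.  Fused cuts transmit force and moment
#' rigidly and require no muscle balance.  Gravity segment loads are off by
#' default, matching the pure-moment-driven kinematics.
#'
#' The sacrum-pelvis cut carries no recruitment constraint: as in the
#' rigid-chain trunk models this stage emulates, the sacrum belongs to the
#' grounded pelvis segment, so the sacroiliac reaction is free and the
#' muscle set (which has no SIJ-only actuators) is not asked to balance
#' it.  The elastic sacroiliac response still appears in the FE stages.
#'
#' @param geom a `spine_geometry`.
#' @param motion an `imposed_motion`.
#' @param stiffness a `joint_stiffness` from [calibrate_stiffness()].
#' @param gravity list of gravitational loads from [gravity_loads()]
#'   (empty when gravity is disabled): the muscles must additionally
#'   balance the weight of everything above each cut.
#' @return named list of global moment 3-vectors (N.mm) per free cut.
#' @export
inverse_statics <- function(geom, motion, stiffness, gravity = list()) {
  stopifnot(inherits(motion, "imposed_motion"),
            inherits(stiffness, "joint_stiffness"))
  fused <- attr(motion, "fused")
  out <- list()
  for (cutl in IV_JOINTS) {
    if (!is.null(fused) && cutl %in% fused) next
    theta <- motion[[cutl]]
    if (max(abs(theta)) > deg2rad(30)) {
      stop("inverse statics error: rotation at ", cutl,
           " outside the small-angle regime (+/-30 deg)")
    }
    K <- stiffness[[cutl]]
    if (is.null(K)) stop("inverse statics error: missing stiffness for ", cutl)
    m_local <- vapply(1:3, function(a) {
      k <- if (theta[a] >= 0) K[a, "pos"] else K[a, "neg"]
      k * theta[a]
    }, numeric(1))
    Rj <- cut_frame(geom, cutl)
    req <- as.numeric(Rj %*% m_local)
    # moment of the weights above the cut, about the cut centre
    req <- req - gravity_moment_above(geom, cutl, gravity)
    out[[cutl]] <- req
  }
  out
}

#' @keywords internal
gravity_moment_above <- function(geom, cutl, gravity) {
  if (!length(gravity)) return(c(0, 0, 0))
  k <- cut_level(cutl)
  cc <- cut_center(geom, cutl)
  m <- c(0, 0, 0)
  for (gl in gravity) {
    if (body_index(gl$body) <= k) {
      m <- m + cross3(gl$point - cc, gl$force)
    }
  }
  m
}

#' Solve the polynomial recruitment problem
#'
#' Minimises `sum_i (f_i / f_max_i)^p` subject to `A f = b`, `f >= 0`,
#' with p > 1 (strictly convex on the feasible set, hence a unique
#' solution).  Solved by a primal-dual interior-point Newton method on the
#' perturbed KKT conditions.
#'
#' @param A m x n constraint matrix (moment arms, N.mm per N).
#' @param b length-m required moment vector (N.mm).
#' @param f_max length-n vector of maximum forces (N).
#' @param p criterion exponent (> 1).
#' @param config a [recruit_config()].
#' @return list with `f` (forces, N), `objective`, `iterations`,
#'   `primal_residual`.
#' @export
recruit_forces <- function(A, b, f_max, p = 3, config = recruit_config()) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(f_max) == n, all(f_max > 0), p > 1)
  bscale <- max(sqrt(sum(b^2)), 1)
  if (sqrt(sum(b^2)) < 1e-12) {
    return(list(f = setNames(numeric(n), colnames(A)), objective = 0,
                iterations = 0L, primal_residual = 0))
  }
  # normalise: x = f / f_max in [0, ~1], constraint rows scaled to O(1)
  As <- (A %*% diag(f_max, n)) / bscale
  bs <- b / bscale
  grad <- function(x) p * x^(p - 1)
  hess <- function(x) p * (p - 1) * x^(p - 2)

  x <- rep(0.1, n)
  s <- rep(1, n)
  lam <- rep(0, m)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    rd <- grad(x) - as.numeric(t(As) %*% lam) - s
    rp <- as.numeric(As %*% x) - bs
    mu <- sum(x * s) / n
    if (max(sqrt(sum(rp^2)), max(abs(rd)), mu) < config$ip_tol) break
    if (iter > config$ip_max_iter) {
      viol <- abs(rp) * bscale
      worst <- order(viol, decreasing = TRUE)[seq_len(min(3, m))]
      stop("recruitment error: interior-point solver did not converge; ",
           "largest constraint residuals at rows ",
           paste(worst, collapse = ", "), " (",
           paste(format(viol[worst], digits = 3), collapse = ", "), " N.mm)")
    }
    # adaptive centering: stay well-centred while infeasible, then reduce mu
    sigma <- if (sqrt(sum(rp^2)) > 1e-8) 0.5 else 0.2
    # reduced KKT: (H + S/X) dx - A' dlam = -rd + sigma*mu/x - s
    Hd <- hess(x) + s / x
    rhs1 <- -rd + sigma * mu / x - s
    AHinv <- As / matrix(Hd, m, n, byrow = TRUE)   # As %*% diag(1/Hd)
    S_lam <- AHinv %*% t(As)
    rhs_lam <- -rp - as.numeric(As %*% (rhs1 / Hd))
    dlam <- tryCatch(solve(S_lam, rhs_lam), error = function(e) NULL)
    if (is.null(dlam)) {
      stop("recruitment error: singular constraint system ",
           "(joint left without independent actuators)")
    }
    dx <- (rhs1 + as.numeric(t(As) %*% dlam)) / Hd
    ds <- sigma * mu / x - s - (s / x) * dx
    # fraction-to-boundary step
    amax <- 0.995 * min(c(1 / 0.995, ifelse(dx < 0, -x / dx, Inf),
                          ifelse(ds < 0, -s / ds, Inf)))
    alpha <- min(1, amax)
    x <- x + alpha * dx
    s <- s + alpha * ds
    lam <- lam + alpha * dlam
  }
  f_out <- pmax(x, 0) * f_max
  names(f_out) <- colnames(A)
  list(f = f_out, objective = sum((f_out / f_max)^p), iterations = iter,
       primal_residual = sqrt(sum((as.numeric(A %*% f_out) - b)^2)))
}

#' Assemble and solve muscle recruitment for an imposed motion
#'
#' Builds the moment-arm matrix over the free cuts, solves the polynomial
#' recruitment problem and verifies the solution with an independent
#' brute-force moment summation (the equilibrium certificate).  Also
#' computes the T10 boundary quantities: the reaction load transmitted
#' across the most cranial joint (reported about the T10 upper endplate)
#' and the predicted T10 translation.
#'
#' @param joint_moments named list of required global moments per free cut
#'   (from [inverse_statics()]).
#' @param muscles a `muscle_set`.
#' @param geom a `spine_geometry`.
#' @param config a [recruit_config()].
#' @param motion motion label carried into the solution.
#' @return object of class `muscle_solution`: `fascicle_forces` (named, N),
#'   `objective_value`, `t10_reaction` (`force`, `moment` about the T10
#'   upper endplate), `t10_translation` (filled by the pipeline),
#'   `equilibrium_residual_rel`.
#' @export
recruit_muscles <- function(joint_moments, muscles, geom,
                            config = recruit_config(),
                            motion = NA_character_, gravity = list()) {
  cuts <- names(joint_moments)
  n <- length(muscles)
  A <- matrix(0, 3 * length(cuts), n,
              dimnames = list(NULL, names(muscles)))
  b <- numeric(3 * length(cuts))
  for (i in seq_along(cuts)) {
    rows <- (i - 1) * 3 + 1:3
    b[rows] <- joint_moments[[cuts[i]]]
    for (j in seq_len(n)) {
      A[rows, j] <- fascicle_moment_arm(muscles[[j]], geom, cuts[i])
    }
  }
  f_max <- vapply(muscles, `[[`, numeric(1), "f_max")
  sol <- recruit_forces(A, b, f_max, p = config$exponent, config = config)

  # independent certificate: brute-force moment summation, not the
  # optimizer's own constraint values
  resid <- equilibrium_certificate(sol$f, muscles, geom, joint_moments)
  if (resid > config$eq_tol_rel) {
    stop("recruitment error: equilibrium certificate failed (relative ",
         "residual ", format(resid, digits = 3), ")")
  }

  t10 <- t10_reaction_from_forces(sol$f, muscles, geom, gravity)
  # boundary load at the T10 upper endplate: the weight of the body above
  # the modelled chain, handed to the realistic FE stage as applied loads
  t10_ep <- geom$bodies$T10$upper_endplate
  boundary <- Filter(function(g) isTRUE(g$boundary), gravity)
  t10_reaction <- NULL
  if (length(boundary)) {
    Fb <- Reduce(`+`, lapply(boundary, `[[`, "force"))
    Mb <- Reduce(`+`, lapply(boundary, function(g)
      cross3(g$point - t10_ep, g$force)))
    t10_reaction <- list(force = Fb, moment = Mb)
  }
  structure(list(
    fascicle_forces = sol$f,
    objective_value = sol$objective,
    t10_reaction = t10_reaction,
    t10_transmitted = t10,   # load transmitted across T10/T11 (MSK side)
    t10_translation = NULL,  # filled by the pipeline stage
    gravity_loads = Filter(function(g) !isTRUE(g$boundary), gravity),
    equilibrium_residual_rel = resid,
    motion = motion
  ), class = "muscle_solution")
}

#' Independent equilibrium certificate
#'
#' Recomputes the muscle moment about each free cut by direct summation of
#' fascicle line-of-action moments and returns the largest relative
#' mismatch with the required moments.
#'
#' @param forces named fascicle forces (N).
#' @param muscles,geom the muscle set and geometry.
#' @param joint_moments required moments per free cut.
#' @return maximal relative residual (scalar).
#' @export
equilibrium_certificate <- function(forces, muscles, geom, joint_moments) {
  scale <- max(vapply(joint_moments, function(m) sqrt(sum(m^2)), numeric(1)), 1)
  worst <- 0
  for (cutl in names(joint_moments)) {
    m <- c(0, 0, 0)
    for (nm in names(forces)) {
      if (forces[[nm]] == 0) next
      fas <- muscles[[nm]]
      if (!(cutl %in% fas$spanned)) next
      k <- cut_level(cutl)
      pts <- fascicle_polyline(fas)
      bod <- fascicle_point_bodies(fas)
      i <- max(which(body_index_vec(bod) <= k))
      u <- unit3(pts[i + 1, ] - pts[i, ])
      m <- m + forces[[nm]] * cross3(pts[i, ] - cut_center(geom, cutl), u)
    }
    worst <- max(worst, sqrt(sum((m - joint_moments[[cutl]])^2)) / scale)
  }
  worst
}

# Load transmitted across the T10/T11 cut on the MSK side (the "reaction
# at the T10 upper endplate"): by equilibrium of the part above the cut,
# the load it carries downward equals the external load applied to it --
# the crossing muscle forces plus any weights acting at or above T10.
#' @keywords internal
t10_reaction_from_forces <- function(forces, muscles, geom,
                                     gravity = list()) {
  cutl <- "T10/T11"
  k <- cut_level(cutl)
  p_ref <- geom$bodies$T10$upper_endplate
  Fm <- c(0, 0, 0); Mm <- c(0, 0, 0)
  for (nm in names(forces)) {
    f <- forces[[nm]]
    if (f == 0) next
    fas <- muscles[[nm]]
    if (!(cutl %in% fas$spanned)) next
    pts <- fascicle_polyline(fas)
    bod <- fascicle_point_bodies(fas)
    i <- max(which(body_index_vec(bod) <= k))
    u <- unit3(pts[i + 1, ] - pts[i, ])
    Fm <- Fm + f * u
    Mm <- Mm + f * cross3(pts[i, ] - p_ref, u)
  }
  for (gl in gravity) {
    if (body_index(gl$body) <= k) {
      Fm <- Fm + gl$force
      Mm <- Mm + cross3(gl$point - p_ref, gl$force)
    }
  }
  list(force = Fm, moment = Mm)
}

#' Predict the T10 translation for the realistic load case
#'
#' A rigid-chain model cannot predict the boundary translation of an
#' elastic spine, so the coupling obtains it from the calibrated elastic
#' chain itself: a load-controlled FE solve under the recruited muscle
#' loads (free T10 boundary) yields the T10 translation that the
#' displacement-controlled realistic solve then prescribes.  Prescribing a
#' consistent translation keeps the boundary constraint force near zero,
#' which is what makes the T10 reaction-moment comparison meaningful; the
#' residual constraint force is reported by the solver.
#'
#' @param vb a pipeline variant bundle (geometry, joints, ligaments,
#'   construct, muscle set, solver config).
#' @param solution the stage-B `muscle_solution` (its forces are applied;
#'   any existing translation prediction is ignored).
#' @return length-3 translation of the T10 body, mm.
#' @export
predict_t10_translation <- function(vb, solution) {
  free_sol <- solution
  free_sol$t10_translation <- NULL
  lc <- loadcase_muscle(free_sol, vb$muscles, vb$geom)
  res <- solve_static(assemble(vb$geom, vb$joints, vb$ligaments,
                               vb$construct, lc, vb$config$solver))
  as.numeric(res$body_disp["T10", 1:3])
}

#' Write a muscle force solution to CSV
#'
#' Fascicle forces plus a one-row T10 boundary record, printed at 9
#' significant digits so the stage B to stage C hand-off round-trips
#' bit-exactly at the printed precision.
#'
#' @param solution a `muscle_solution`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path) {
  fmt <- function(x) formatC(x, digits = 9, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("record,name,v1,v2,v3", con)
  for (nm in names(solution$fascicle_forces)) {
    writeLines(paste("force", nm, fmt(solution$fascicle_forces[[nm]]), "", "",
                     sep = ","), con)
  }
  tr <- solution$t10_transmitted
  writeLines(paste("t10_force", "", paste(fmt(tr$force), collapse = ","),
                   sep = ","), con)
  writeLines(paste("t10_moment", "", paste(fmt(tr$moment), collapse = ","),
                   sep = ","), con)
  if (!is.null(solution$t10_translation)) {
    writeLines(paste("t10_translation", "",
                     paste(fmt(solution$t10_translation), collapse = ","),
                     sep = ","), con)
  }
  invisible(path)
}

#' Read a muscle force solution from CSV
#' @param path CSV path written by [write_solution_csv()].
#' @return a `muscle_solution` (forces and T10 records only).
#' @export
read_solution_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ff <- df[df$record == "force", ]
  forces <- setNames(as.numeric(ff$v1), ff$name)
  getv <- function(rec) {
    r <- df[df$record == rec, ]
    if (!nrow(r)) return(NULL)
    as.numeric(r[1, c("v1", "v2", "v3")])
  }
  structure(list(
    fascicle_forces = forces,
    objective_value = NA_real_,
    t10_reaction = NULL,
    t10_transmitted = list(force = getv("t10_force"),
                           moment = getv("t10_moment")),
    t10_translation = getv("t10_translation"),
    equilibrium_residual_rel = NA_real_,
    motion = NA_character_
  ), class = "muscle_solution")
}

#' @export
print.muscle_solution <- function(x, ...) {
  act <- sum(x$fascicle_forces > 1e-6)
  cat("Muscle solution: ", act, "/", length(x$fascicle_forces),
      " active fascicles, objective ", format(x$objective_value, digits = 4),
      "\n", sep = "")
  invisible(x)
}
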