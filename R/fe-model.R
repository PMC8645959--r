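# Static finite element model of the spine: rigid vertebral nodes (6 DOF),
# bushing joints, tension-only ligaments and beam-element instrumentation.
# Small-rotation kinematics; the only nonlinearity is the ligament tension
# state, resolved by Newton iteration.  Dense base-R linear algebra (the
# assembled systems stay around two hundred DOF).

#' Solver configuration
#'
#' @param ... named overrides merged over the defaults (`tol_rel`,
#'   `tol_abs` in N, `max_iter`, `fused_rom_tol_deg`).
#' @return list with class `solver_config`.
#' @export
solver_config <- function(...) {
  cfg <- list(tol_rel = 1e-8, tol_abs = 1e-6, max_iter = 50,
              fused_rom_tol_deg = 0.1)
  override_config(cfg, list(...), "solver_config")
}

#' Simplified (pure moment) load case
#'
#' A pure moment about the motion axis, transferred to the T10 body through
#' the rigid endplate interface (kinematically equivalent to a generalized
#' moment on the T10 node).
#'
#' @param motion motion label (all five directions allowed here).
#' @param magnitude moment magnitude in N.mm (default 7500 = 7.5 N.m).
#' @return a `load_case` list.
#' @export
loadcase_pure_moment <- function(motion, magnitude = 7500) {
  if (magnitude <= 0) stop("load case error: pure moment must be positive")
  axis <- motion_axis(motion)   # errors on unknown labels
  structure(list(mode = "simplified", motion = motion,
                 pure_moment = magnitude * axis,
                 point_loads = list(), t10_reaction = NULL,
                 t10_translation = NULL),
            class = "load_case")
}

#' Realistic (muscle force) load case
#'
#' Converts a muscle force solution into equal-and-opposite concentrated
#' loads along each fascicle's line of action (with redirection forces at
#' via points), adds the boundary reaction loads at the T10 upper endplate,
#' and prescribes the T10 translation predicted by the musculoskeletal
#' stage.  The pure moment is removed.
#'
#' @param solution a `muscle_solution` (see [recruit_muscles()]).
#' @param muscles the `muscle_set` the solution refers to.
#' @param geom the `spine_geometry`.
#' @return a `load_case` list.
#' @export
loadcase_muscle <- function(solution, muscles, geom) {
  forces <- solution$fascicle_forces
  if (any(forces < -1e-9)) stop("load case error: negative fascicle force")
  loads <- list()
  for (nm in names(forces)) {
    f <- forces[[nm]]
    fas <- muscles[[nm]]
    if (is.null(fas)) stop("load case error: unknown fascicle ", nm)
    pts <- fascicle_polyline(fas)
    bod <- fascicle_point_bodies(fas)
    for (b in bod) {
      if (!(b %in% BODY_LABELS)) {
        stop("muscle load mapping error: attachment on unknown body ", b)
      }
    }
    np <- nrow(pts)
    for (i in seq_len(np)) {
      u_next <- if (i < np) unit3(pts[i + 1, ] - pts[i, ]) else c(0, 0, 0)
      u_prev <- if (i > 1) unit3(pts[i, ] - pts[i - 1, ]) else c(0, 0, 0)
      Fv <- f * (u_next - u_prev)
      loads[[length(loads) + 1]] <- list(body = bod[i], point = pts[i, ],
                                         force = Fv, moment = c(0, 0, 0))
    }
  }
  t10_ep <- geom$bodies$T10$upper_endplate
  if (!is.null(solution$t10_reaction)) {
    loads[[length(loads) + 1]] <- list(body = "T10", point = t10_ep,
                                       force = solution$t10_reaction$force,
                                       moment = solution$t10_reaction$moment)
  }
  # gravitational segment weights of the modelled chain, if the MSK stage
  # included them (the above-T10 weight is already in t10_reaction)
  for (gl in solution$gravity_loads) {
    loads[[length(loads) + 1]] <- list(body = gl$body, point = gl$point,
                                       force = gl$force,
                                       moment = c(0, 0, 0))
  }
  structure(list(mode = "realistic", motion = solution$motion,
                 pure_moment = c(0, 0, 0), point_loads = loads,
                 t10_reaction = solution$t10_reaction,
                 t10_translation = solution$t10_translation),
            class = "load_case")
}

#' Assemble the static model
#'
#' Builds the nodal system: one 6-DOF node per body, beam nodes for the
#' optional fixation construct (screw tips rigidly tied to their vertebrae),
#' bushings, ligaments, the pelvis support and the load case.
#'
#' @param geom a `spine_geometry`.
#' @param joints bushing list from [build_bushings()].
#' @param ligaments ligament list from [build_ligaments()] (may be empty).
#' @param instrumentation optional `fixation_construct` from
#'   [build_fixation()].
#' @param loadcase a `load_case`.
#' @param solver a [solver_config()].
#' @return an object of class `fe_model`.
#' @export
assemble <- function(geom, joints, ligaments = list(), instrumentation = NULL,
                     loadcase, solver = solver_config()) {
  stopifnot(inherits(geom, "spine_geometry"), inherits(loadcase, "load_case"))
  nodes <- data.frame(label = BODY_LABELS, kind = "body",
                      stringsAsFactors = FALSE)
  pos <- t(vapply(BODY_LABELS, function(b) geom$bodies[[b]]$center,
                  numeric(3)))
  slaves <- list()
  beams <- list()

  if (!is.null(instrumentation)) {
    stopifnot(inherits(instrumentation, "fixation_construct"))
    for (lv in names(instrumentation$extra_nodes)) {
      nd <- instrumentation$extra_nodes[[lv]]
      nodes <- rbind(nodes, data.frame(label = lv, kind = "beam",
                                       stringsAsFactors = FALSE))
      pos <- rbind(pos, nd$point)
      if (!is.null(nd$tied_to)) {
        if (!(nd$tied_to %in% BODY_LABELS)) {
          stop("assembly error: tie references unknown body ", nd$tied_to)
        }
        slaves[[lv]] <- nd$tied_to
      }
    }
    node_id <- function(lbl) match(lbl, nodes$label)
    for (be in instrumentation$beam_elements) {
      n1 <- node_id(be$n1); n2 <- node_id(be$n2)
      if (is.na(n1) || is.na(n2)) {
        stop("assembly error: beam references unknown node")
      }
      beams[[length(beams) + 1]] <-
        make_beam(n1, n2, pos[n1, ], pos[n2, ], be$section, be$E, be$poisson,
                  be$component)
    }
  }
  rownames(pos) <- nodes$label
  nnode <- nrow(nodes)
  ndof <- 6 * nnode

  # master-slave transformation full DOFs <- master DOFs
  is_slave <- nodes$label %in% names(slaves)
  master_nodes <- which(!is_slave)
  Tm <- matrix(0, ndof, 6 * length(master_nodes))
  mcol <- function(node) {
    j <- match(node, master_nodes)
    (j - 1) * 6 + 1:6
  }
  for (n in seq_len(nnode)) {
    rows <- (n - 1) * 6 + 1:6
    if (!is_slave[n]) {
      Tm[rows, mcol(n)] <- diag(6)
    } else {
      m <- match(slaves[[nodes$label[n]]], nodes$label)
      G <- point_map(pos[n, ], pos[m, ])
      Tm[rows, mcol(m)] <- G
    }
  }

  bush_idx <- lapply(joints, function(b) {
    c(match(b$a, nodes$label), match(b$b, nodes$label))
  })
  lig_idx <- lapply(ligaments, function(l) {
    c(match(l$a, nodes$label), match(l$b, nodes$label))
  })
  if (length(bush_idx) && any(is.na(unlist(bush_idx)))) {
    stop("assembly error: bushing references unknown body")
  }
  if (length(lig_idx) && any(is.na(unlist(lig_idx)))) {
    stop("assembly error: ligament references unknown body")
  }

  # linear stiffness (bushings + beams) in full nodal space
  Kfull <- matrix(0, ndof, ndof)
  for (i in seq_along(joints)) {
    b <- joints[[i]]
    ab <- bush_idx[[i]]
    bm <- bushing_matrices(b, pos[ab[1], ], pos[ab[2], ])
    idx <- c((ab[1] - 1) * 6 + 1:6, (ab[2] - 1) * 6 + 1:6)
    Kfull[idx, idx] <- Kfull[idx, idx] + bm$K
  }
  for (be in beams) {
    idx <- c((be$n1 - 1) * 6 + 1:6, (be$n2 - 1) * 6 + 1:6)
    Kfull[idx, idx] <- Kfull[idx, idx] + beam_global_stiffness(be)
  }

  # supports: the pelvis (acetabula) is completely fixed; duplicate support
  # specifications on the same DOF are a union, hence idempotent.
  pelvis_m <- mcol(match("Pelvis", nodes$label))
  fixed <- pelvis_m
  fixed_values <- rep(0, length(fixed))
  if (!is.null(loadcase$t10_translation)) {
    t10_m <- mcol(match("T10", nodes$label))[1:3]
    fixed <- c(fixed, t10_m)
    fixed_values <- c(fixed_values, loadcase$t10_translation)
  }
  keep <- !duplicated(fixed)
  fixed <- fixed[keep]; fixed_values <- fixed_values[keep]

  # external load vector in full space, then reduced
  f_full <- numeric(ndof)
  add_load <- function(body, point, force, moment) {
    n <- match(body, nodes$label)
    if (is.na(n)) stop("load mapping error: unknown body ", body)
    rows <- (n - 1) * 6 + 1:6
    f_full[rows[1:3]] <<- f_full[rows[1:3]] + force
    f_full[rows[4:6]] <<- f_full[rows[4:6]] + moment +
      cross3(point - pos[n, ], force)
  }
  if (any(loadcase$pure_moment != 0)) {
    add_load("T10", geom$bodies$T10$upper_endplate, c(0, 0, 0),
             loadcase$pure_moment)
  }
  for (pl in loadcase$point_loads) {
    add_load(pl$body, pl$point, pl$force, pl$moment)
  }

  structure(list(
    geom = geom, nodes = nodes, pos = pos, Tm = Tm,
    master_nodes = master_nodes, joints = joints, ligaments = ligaments,
    beams = beams, instrumentation = instrumentation,
    bush_idx = bush_idx, lig_idx = lig_idx,
    Kfull = Kfull, f_full = f_full, fixed = fixed,
    fixed_values = fixed_values, loadcase = loadcase, solver = solver
  ), class = "fe_model")
}

# internal force and tangent of the ligaments in full nodal space
#' @keywords internal
ligament_state <- function(model, qfull) {
  n <- length(qfull)
  f <- numeric(n)
  Kt <- matrix(0, n, n)
  forces <- numeric(length(model$ligaments))
  for (i in seq_along(model$ligaments)) {
    lg <- model$ligaments[[i]]
    ab <- model$lig_idx[[i]]
    idx <- c((ab[1] - 1) * 6 + 1:6, (ab[2] - 1) * 6 + 1:6)
    g <- ligament_row(lg, model$pos[ab[1], ], model$pos[ab[2], ])
    e <- sum(g * qfull[idx])
    fk <- curve_force(lg$curve, e)
    forces[i] <- fk[["force"]]
    f[idx] <- f[idx] + g * fk[["force"]]
    if (fk[["k"]] > 0) Kt[idx, idx] <- Kt[idx, idx] + fk[["k"]] * (g %o% g)
  }
  list(f = f, Kt = Kt, forces = forces)
}

#' Solve the assembled static model
#'
#' Newton iteration over the ligament tension state; everything else is
#' linear.  Converges when the free-DOF residual norm is below
#' `tol_abs + tol_rel * ||external load||`; aborts early on three
#' consecutive residual increases.
#'
#' @param model an `fe_model` from [assemble()].
#' @return an object of class `fe_result`.
#' @export
solve_static <- function(model) {
  stopifnot(inherits(model, "fe_model"))
  Tm <- model$Tm
  Kred <- t(Tm) %*% model$Kfull %*% Tm
  fred <- as.numeric(t(Tm) %*% model$f_full)
  nred <- length(fred)
  free <- setdiff(seq_len(nred), model$fixed)
  q <- numeric(nred)
  q[model$fixed] <- model$fixed_values

  load_scale <- sqrt(sum(fred^2)) +
    sqrt(sum((Kred[, model$fixed, drop = FALSE] %*% model$fixed_values)^2))
  tol <- model$solver$tol_abs + model$solver$tol_rel * load_scale

  residual <- function(q) {
    qfull <- as.numeric(Tm %*% q)
    ls <- ligament_state(model, qfull)
    r <- as.numeric(Kred %*% q) + as.numeric(t(Tm) %*% ls$f) - fred
    list(r = r, lig = ls)
  }

  rs <- residual(q)
  rnorm <- sqrt(sum(rs$r[free]^2))
  grow <- 0L
  iter <- 0L
  while (rnorm > tol) {
    iter <- iter + 1L
    if (iter > model$solver$max_iter) {
      stop("solver error: no convergence in ", model$solver$max_iter,
           " iterations (last residual ", format(rnorm), " N)")
    }
    Ktan <- Kred + t(Tm) %*% rs$lig$Kt %*% Tm
    Kff <- Ktan[free, free, drop = FALSE]
    dq <- tryCatch(solve(Kff, -rs$r[free]),
                   error = function(e) NULL)
    if (is.null(dq)) {
      ev <- eigen(Kff, symmetric = TRUE)
      nmodes <- sum(ev$values < 1e-8 * max(ev$values))
      stop("assembly error: singular constrained stiffness (",
           nmodes, " unconstrained mode(s))")
    }
    q[free] <- q[free] + dq
    rs <- residual(q)
    rnew <- sqrt(sum(rs$r[free]^2))
    if (rnew > rnorm) {
      grow <- grow + 1L
      if (grow >= 3L) {
        stop("solver error: diverging residual (", format(rnew), " N)")
      }
    } else grow <- 0L
    rnorm <- rnew
  }

  qfull <- as.numeric(Tm %*% q)
  # reactions at fixed DOFs (support + prescribed translation constraints)
  r_all <- as.numeric(Kred %*% q) + as.numeric(t(Tm) %*% rs$lig$f) - fred
  reactions <- r_all[model$fixed]

  body_disp <- matrix(qfull[as.vector(vapply(
    match(BODY_LABELS, model$nodes$label),
    function(n) (n - 1) * 6 + 1:6, numeric(6)))],
    nrow = length(BODY_LABELS), ncol = 6, byrow = TRUE,
    dimnames = list(BODY_LABELS, c("ux", "uy", "uz", "rx", "ry", "rz")))

  # relative joint rotations, cranial body relative to caudal, joint frame
  joint_rot <- lapply(model$joints, function(b) {
    ta <- body_disp[b$a, 4:6]
    tb <- body_disp[b$b, 4:6]
    as.numeric(t(b$R) %*% (ta - tb))
  })
  names(joint_rot) <- names(model$joints)

  beam_forces <- lapply(model$beams, function(be) {
    idx <- c((be$n1 - 1) * 6 + 1:6, (be$n2 - 1) * 6 + 1:6)
    bf <- beam_end_forces(be, qfull[idx])
    list(component = be$component, section = be$section,
         end1 = bf$end1, end2 = bf$end2)
  })

  vm <- beam_stress_table(beam_forces)

  structure(list(
    model = model, q = q, qfull = qfull, body_disp = body_disp,
    joint_rot = joint_rot, ligament_forces = rs$lig$forces,
    beam_forces = beam_forces, von_mises = vm,
    reactions = reactions, residual_norm = rnorm,
    loadcase = model$loadcase, iterations = iter
  ), class = "fe_result")
}

#' @keywords internal
beam_stress_table <- function(beam_forces) {
  if (!length(beam_forces)) {
    return(data.frame(component = character(0), max_von_mises_MPa = numeric(0),
                      stringsAsFactors = FALSE))
  }
  comp <- vapply(beam_forces, `[[`, character(1), "component")
  vm_el <- vapply(beam_forces, function(bf) {
    max(beam_von_mises(as.list(bf$end1), bf$section),
        beam_von_mises(as.list(bf$end2), bf$section))
  }, numeric(1))
  agg <- tapply(vm_el, comp, max)
  data.frame(component = names(agg), max_von_mises_MPa = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-joint range of motion about a motion axis
#'
#' Projects the relative rotation of each joint (cranial body relative to
#' caudal, a relative quantity invariant to rigid translations) onto the
#' motion axis expressed in the joint frame; positive values follow the
#' motion direction.
#'
#' @param result an `fe_result`.
#' @param motion motion label.
#' @return named numeric vector, degrees, over all joints.
#' @export
compute_rom <- function(result, motion) {
  stopifnot(inherits(result, "fe_result"))
  a <- motion_axis(motion)
  vapply(names(result$joint_rot), function(jl) {
    b <- result$model$joints[[jl]]
    al <- as.numeric(t(b$R) %*% a)
    rad2deg(sum(result$joint_rot[[jl]] * al))
  }, numeric(1))
}

#' Load transmitted across a joint cut
#'
#' Sum of the loads that the structure below the cut applies to the
#' structure above it, through every bushing and ligament crossing the cut,
#' expressed as a force and a moment about `ref_point`.  Sign convention:
#' the returned load is the one carried downward (above-on-below), so under
#' an intact pure moment it equals the applied moment at every cut.
#'
#' @param result an `fe_result`.
#' @param cut a cut label (intervertebral joint or `"S/P"`).
#' @param ref_point reference point for the moment (default: cut centre).
#' @return list with `force`, `moment` (global frame).
#' @export
transmitted_load <- function(result, cut, ref_point = NULL) {
  model <- result$model
  geom <- model$geom
  k <- cut_level(cut)
  if (is.null(ref_point)) ref_point <- cut_center(geom, cut)
  Ftot <- c(0, 0, 0); Mtot <- c(0, 0, 0)
  qfull <- result$qfull
  for (i in seq_along(model$joints)) {
    b <- model$joints[[i]]
    ia <- body_index(b$a); ib <- body_index(b$b)
    if (!(ia <= k && ib > k)) next
    ab <- model$bush_idx[[i]]
    idx <- c((ab[1] - 1) * 6 + 1:6, (ab[2] - 1) * 6 + 1:6)
    bm <- bushing_matrices(b, model$pos[ab[1], ], model$pos[ab[2], ])
    delta <- as.numeric(bm$D %*% qfull[idx])        # a relative to b, local
    load_local <- as.numeric(bm$Kl %*% delta)       # above-on-below
    Fj <- as.numeric(b$R %*% load_local[1:3])
    Mj <- as.numeric(b$R %*% load_local[4:6])
    Ftot <- Ftot + Fj
    Mtot <- Mtot + Mj + cross3(b$center - ref_point, Fj)
  }
  for (i in seq_along(model$ligaments)) {
    lg <- model$ligaments[[i]]
    ia <- body_index(lg$a); ib <- body_index(lg$b)
    if (!(ia <= k && ib > k)) next
    fmag <- result$ligament_forces[i]
    if (fmag == 0) next
    u0 <- unit3(lg$pb - lg$pa)
    # tension pulls the caudal attachment toward the cranial one; the load
    # carried downward by the ligament onto the part below is +f*u0 at pb
    Fl <- fmag * u0
    Fx <- -Fl   # force applied to the part below by the part above at pb
    # equivalently the ligament applies -f*u0 to the below part at pb:
    Ftot <- Ftot + Fx
    Mtot <- Mtot + cross3(lg$pb - ref_point, Fx)
  }
  list(force = Ftot, moment = Mtot)
}

#' @export
print.fe_result <- function(x, ...) {
  cat("FE result: residual ", format(x$residual_norm, digits = 3), " N in ",
      x$iterations, " Newton step(s)\n", sep = "")
  if (nrow(x$von_mises)) {
    cat("max implant von Mises: ",
        format(max(x$von_mises$max_von_mises_MPa), digits = 4), " MPa\n",
        sep = "")
  }
  invisible(x)
}

#' Export joint ROMs and implant stresses to CSV
#'
#' One row per joint (`label`, `rom_deg`) followed by one row per implant
#' component (`component_id`, `max_von_mises_MPa`).
#'
#' @param result an `fe_result`.
#' @param motion motion label used for the ROM projection.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fe_result_csv <- function(result, motion, path) {
  rom <- compute_rom(result, motion)
  df1 <- data.frame(row_type = "joint", id = names(rom), value = as.numeric(rom),
                    unit = "deg", stringsAsFactors = FALSE)
  df2 <- if (nrow(result$von_mises)) {
    data.frame(row_type = "implant", id = result$von_mises$component,
               value = result$von_mises$max_von_mises_MPa, unit = "MPa",
               stringsAsFactors = FALSE)
  } else NULL
  utils::write.csv(rbind(df1, df2), path, row.names = FALSE)
  invisible(path)
}
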