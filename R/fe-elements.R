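# Element library for the static spine model: generalized bushing joints
# (6x6 spring between two rigid bodies), tension-only piecewise-linear
# ligament springs, and 2-node 3D Euler-Bernoulli beams for the
# instrumentation.  All element routines work on the full nodal DOF vector
# (6 DOF per node: ux, uy, uz, rx, ry, rz) under small-rotation kinematics.

#' Default joint (bushing) configuration
#'
#' Rotational stiffnesses in N.mm/rad per local axis (x lateral bending,
#' y flexion-extension, z axial torsion in the joint frame), translational
#' stiffnesses in N/mm (x, y shear, z axial).  The values produce segmental
#' ranges of motion of a few degrees under a 7.5 N.m pure moment, in the
#' range reported for thoracolumbar functional spinal units.
#'
#' @param ... named overrides merged over the defaults.
#' @return a list with class `joint_config`.
#' @export
joint_config <- function(...) {
  kr <- rbind(
    "T10/T11" = c(1.8e5, 1.6e5, 1.5e5),
    "T11/T12" = c(1.8e5, 1.6e5, 1.5e5),
    "T12/L1"  = c(1.6e5, 1.4e5, 1.8e5),
    "L1/L2"   = c(1.2e5, 1.0e5, 2.5e5),
    "L2/L3"   = c(1.2e5, 1.0e5, 2.5e5),
    "L3/L4"   = c(1.2e5, 1.0e5, 2.5e5),
    "L4/L5"   = c(1.2e5, 1.0e5, 2.5e5),
    "L5/S1"   = c(1.4e5, 1.2e5, 3.0e5)
  )
  colnames(kr) <- c("x", "y", "z")
  cfg <- list(
    k_rot = kr,                         # N.mm/rad, per joint local axis
    k_trans = c(x = 800, y = 800, z = 3000),  # N/mm, joint local axes
    sij_k_rot = c(x = 5e6, y = 5e6, z = 5e6),
    sij_k_trans = c(x = 5000, y = 5000, z = 5000),
    ligaments_enabled = TRUE,
    ligament_stiffness = 10,            # N/mm beyond the slack region
    ligament_slack = 1                  # mm
  )
  override_config(cfg, list(...), "joint_config")
}

#' Build the default bushing joints
#'
#' One generalized bushing per intervertebral joint plus one per sacroiliac
#' joint, with diagonal stiffness in the joint frame.
#'
#' @param geom a `spine_geometry`.
#' @param config a [joint_config()].
#' @return list of bushing elements (`label`, `a`, `b`, `center`, `R`,
#'   `K_rot`, `K_trans`).
#' @export
build_bushings <- function(geom, config = joint_config()) {
  stopifnot(inherits(config, "joint_config"))
  out <- lapply(geom$joints, function(j) {
    if (j$label %in% SIJ_JOINTS) {
      Kr <- diag(config$sij_k_rot)
      Kt <- diag(config$sij_k_trans)
    } else {
      Kr <- diag(config$k_rot[j$label, ])
      Kt <- diag(config$k_trans)
    }
    list(label = j$label, a = j$a, b = j$b, center = j$center, R = j$R,
         K_rot = Kr, K_trans = Kt)
  })
  names(out) <- names(geom$joints)
  out
}

#' Build the default ligament set
#'
#' One tension-only posterior ligament per intervertebral level, spanning
#' the spinous tips of the adjacent vertebrae (the lumbosacral level spans
#' L5 spinous to the posterior sacrum).  The force-elongation curve is zero
#' up to the slack length and linear beyond it.
#'
#' @param geom a `spine_geometry`.
#' @param config a [joint_config()].
#' @return list of ligament elements (possibly empty).
#' @export
build_ligaments <- function(geom, config = joint_config()) {
  stopifnot(inherits(config, "joint_config"))
  if (!isTRUE(config$ligaments_enabled)) return(list())
  k <- config$ligament_stiffness
  s <- config$ligament_slack
  curve <- ligament_curve(k, s)
  out <- lapply(IV_JOINTS, function(jl) {
    jt <- geom$joints[[jl]]
    pa <- if (jt$a == "Sacrum") geom$bodies$Sacrum$posterior else
      geom$bodies[[jt$a]]$spinous_tip
    pb <- if (jt$b == "Sacrum") geom$bodies$Sacrum$posterior else
      geom$bodies[[jt$b]]$spinous_tip
    list(label = paste0("lig_", jl), a = jt$a, b = jt$b,
         pa = pa, pb = pb, curve = curve, joint = jl)
  })
  names(out) <- paste0("lig_", IV_JOINTS)
  out
}

#' Piecewise-linear tension-only ligament curve
#'
#' Returns a curve object: a monotone non-decreasing force-elongation table
#' with zero force for elongation below the slack length.
#'
#' @param stiffness N/mm slope beyond the slack region.
#' @param slack mm of free elongation before tension builds.
#' @return list with `elong`, `force` breakpoints and evaluation helpers.
#' @export
ligament_curve <- function(stiffness, slack) {
  stopifnot(stiffness >= 0, slack >= 0)
  list(elong = c(0, slack, slack + 1), force = c(0, 0, stiffness))
}

# Force and tangent stiffness of a curve at elongation e (e <= 0 is slack).
#' @keywords internal
curve_force <- function(curve, e) {
  el <- curve$elong; fo <- curve$force
  if (e <= el[1]) return(c(force = 0, k = 0))
  n <- length(el)
  if (e >= el[n]) {
    k <- (fo[n] - fo[n - 1]) / (el[n] - el[n - 1])
    return(c(force = fo[n] + k * (e - el[n]), k = k))
  }
  i <- findInterval(e, el)
  k <- (fo[i + 1] - fo[i]) / (el[i + 1] - el[i])
  c(force = fo[i] + k * (e - el[i]), k = k)
}

# --- element kinematic maps -------------------------------------------------

# 6x6 map from the 6 DOF of a rigid node at x to the (displacement, rotation)
# of a material point at p on that node.
#' @keywords internal
point_map <- function(p, x) {
  G <- diag(6)
  G[1:3, 4:6] <- -skew3(p - x)
  G
}

# Bushing element: 12x12 stiffness over the stacked DOFs (node a, node b),
# a = cranial, b = caudal.  Relative motion is "a relative to b" evaluated at
# the joint centre in the joint frame.
#' @keywords internal
bushing_matrices <- function(bush, xa, xb) {
  Rhat <- matrix(0, 6, 6)
  Rhat[1:3, 1:3] <- t(bush$R)
  Rhat[4:6, 4:6] <- t(bush$R)
  D <- cbind(Rhat %*% point_map(bush$center, xa),
             -Rhat %*% point_map(bush$center, xb))
  Kl <- matrix(0, 6, 6)
  Kl[1:3, 1:3] <- bush$K_trans
  Kl[4:6, 4:6] <- bush$K_rot
  list(D = D, Kl = Kl, K = t(D) %*% Kl %*% D)
}

# Ligament elongation row vector over (node a dofs, node b dofs); tension
# builds when the attachment points separate along the undeformed direction.
#' @keywords internal
ligament_row <- function(lig, xa, xb) {
  u0 <- unit3(lig$pb - lig$pa)
  ra <- lig$pa - xa
  rb <- lig$pb - xb
  # e = u0 . (u_b(pb) - u_a(pa))
  c(-u0, -cross3(ra, u0), u0, cross3(rb, u0))
}

# --- beams ------------------------------------------------------------------

#' Circular beam section properties
#' @param diameter section diameter, mm.
#' @return list with `A`, `I`, `J` (mm^2, mm^4).
#' @export
circular_section <- function(diameter) {
  if (diameter <= 0) stop("beam section error: diameter must be positive")
  list(d = diameter,
       A = pi * diameter^2 / 4,
       I = pi * diameter^4 / 64,
       J = pi * diameter^4 / 32)
}

# Local 12x12 Euler-Bernoulli stiffness for a circular-section beam.
#' @keywords internal
beam_local_stiffness <- function(E, G, A, I, J, L) {
  K <- matrix(0, 12, 12)
  a <- E * A / L
  t <- G * J / L
  K[1, 1] <- a; K[1, 7] <- -a; K[7, 1] <- -a; K[7, 7] <- a
  K[4, 4] <- t; K[4, 10] <- -t; K[10, 4] <- -t; K[10, 10] <- t
  c1 <- 12 * E * I / L^3; c2 <- 6 * E * I / L^2
  c3 <- 4 * E * I / L; c4 <- 2 * E * I / L
  # bending in the local x-y plane (uy, rz)
  iy <- c(2, 6, 8, 12)
  K[iy, iy] <- matrix(c(c1, c2, -c1, c2,
                        c2, c3, -c2, c4,
                        -c1, -c2, c1, -c2,
                        c2, c4, -c2, c3), 4, 4, byrow = TRUE)
  # bending in the local x-z plane (uz, ry): coupling signs flipped
  iz <- c(3, 5, 9, 11)
  K[iz, iz] <- matrix(c(c1, -c2, -c1, -c2,
                        -c2, c3, c2, c4,
                        -c1, c2, c1, c2,
                        -c2, c4, c2, c3), 4, 4, byrow = TRUE)
  K
}

# Local axes for a beam from p1 to p2: rows of the returned matrix are the
# local x (axial), y, z directions in global coordinates.
#' @keywords internal
beam_local_axes <- function(p1, p2) {
  ex <- unit3(p2 - p1)
  ref <- if (abs(ex[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  ey <- unit3(cross3(ref, ex))
  ez <- cross3(ex, ey)
  rbind(ex, ey, ez)
}

#' @keywords internal
make_beam <- function(n1, n2, p1, p2, section, E, poisson, component) {
  if (poisson < 0 || poisson >= 0.5) stop("beam error: poisson out of range")
  if (E <= 0) stop("beam error: elastic modulus must be positive")
  L <- sqrt(sum((p2 - p1)^2))
  Rl <- beam_local_axes(p1, p2)
  G <- E / (2 * (1 + poisson))
  list(n1 = n1, n2 = n2, p1 = p1, p2 = p2, L = L, R = Rl,
       E = E, G = G, section = section, component = component,
       K_local = beam_local_stiffness(E, G, section$A, section$I, section$J, L))
}

#' @keywords internal
beam_transform <- function(beam) {
  T12 <- matrix(0, 12, 12)
  for (k in 0:3) T12[k * 3 + 1:3, k * 3 + 1:3] <- beam$R
  T12
}

#' @keywords internal
beam_global_stiffness <- function(beam) {
  T12 <- beam_transform(beam)
  t(T12) %*% beam$K_local %*% T12
}

#' Beam end section forces from nodal displacements
#'
#' @param beam a beam element.
#' @param q12 the 12 global DOFs of its two nodes.
#' @return list with `end1`, `end2`, each `c(N, Vy, Vz, T, My, Mz)` (local
#'   axial force, shears, torsion, bending moments).
#' @keywords internal
beam_end_forces <- function(beam, q12) {
  f <- as.numeric(beam$K_local %*% (beam_transform(beam) %*% q12))
  list(end1 = c(N = f[1], Vy = f[2], Vz = f[3], T = f[4], My = f[5], Mz = f[6]),
       end2 = c(N = f[7], Vy = f[8], Vz = f[9], T = f[10], My = f[11], Mz = f[12]))
}

#' von Mises stress of a circular beam section
#'
#' Outer-fiber normal stress `|N|/A + sqrt(My^2 + Mz^2) (d/2)/I` combined
#' with the torsional shear `|T| (d/2)/J` as `sqrt(sigma^2 + 3 tau^2)`.
#' Transverse shear is neglected (slender-member stress recovery).
#'
#' @param section_forces named vector or list with `N`, `T`, `My`, `Mz`
#'   (N and N.mm); missing components are treated as zero.
#' @param section a [circular_section()].
#' @return von Mises stress, MPa.
#' @export
beam_von_mises <- function(section_forces, section) {
  if (is.null(section$d) || section$d <= 0) {
    stop("beam section error: diameter must be positive")
  }
  g <- function(nm) {
    v <- section_forces[[nm]]
    if (is.null(v) || is.na(v)) 0 else as.numeric(v)
  }
  r <- section$d / 2
  sigma <- abs(g("N")) / section$A +
    sqrt(g("My")^2 + g("Mz")^2) * r / section$I
  tau <- abs(g("T")) * r / section$J
  sqrt(sigma^2 + 3 * tau^2)
}
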