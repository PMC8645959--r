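# Parametric synthetic thoracolumbar anatomy: vertebral frames T10..L5,
# sacrum and pelvis, intervertebral joint centres and the two sacroiliac
# joints.  The geometry stands in for a subject-derived surface model: all
# dimensions are plain config values so that every default can be overridden.

VERTEBRA_LABELS <- c("T10", "T11", "T12", "L1", "L2", "L3", "L4", "L5")
IV_JOINTS <- c("T10/T11", "T11/T12", "T12/L1", "L1/L2", "L2/L3",
               "L3/L4", "L4/L5", "L5/S1")
SIJ_JOINTS <- c("SIJ-left", "SIJ-right")
BODY_LABELS <- c(VERTEBRA_LABELS, "Sacrum", "Pelvis")

#' Default anatomy configuration
#'
#' Returns the configuration of the synthetic spine: vertebral body heights,
#' disc heights, per-level sagittal tilt angles (a mild standing lordosis
#' below a beginning thoracic kyphosis), pedicle/landmark offsets in the
#' body-fixed frame and the pelvis landmark set.  All lengths in mm, angles
#' in degrees.
#'
#' @param ... named overrides merged over the defaults (top-level fields).
#' @return a list with class `anatomy_config`.
#' @export
anatomy_config <- function(...) {
  cfg <- list(
    vertebral_heights = c(T10 = 20, T11 = 21, T12 = 22, L1 = 25,
                          L2 = 26, L3 = 27, L4 = 27, L5 = 26),
    # disc between the named pair; L5/S1 is the lumbosacral disc
    disc_heights = c("T10/T11" = 5, "T11/T12" = 5, "T12/L1" = 6,
                     "L1/L2" = 8, "L2/L3" = 9, "L3/L4" = 10,
                     "L4/L5" = 11, "L5/S1" = 10),
    # sagittal tilt of each body frame about +Y (positive pitches the
    # anterior direction caudally); decreasing values up the lumbar spine
    # produce the lordosis, slightly negative thoracic values the kyphosis
    tilt_deg = c(Sacrum = 32, L5 = 20, L4 = 12, L3 = 5, L2 = 0,
                 L1 = -3, T12 = -6, T11 = -9, T10 = -12),
    sacrum_height = 30,
    sacrum_center = c(-10, 0, 75),
    sij_center_local = c(-20, 35, -20),   # relative to sacrum frame, left side
    pelvis_center = c(0, 0, 0),
    # body-fixed landmark offsets (x anterior, y left, z cranial)
    pedicle_entry_local = c(-35, 16, 0),  # left side; right is mirrored
    spinous_tip_local = c(-55, 0, 0),
    transverse_process_local = c(0, 35, 0),
    sagittal_symmetry = TRUE
  )
  override_config(cfg, list(...), "anatomy_config")
}

# Shallow merge of named overrides over a default config list.
#' @keywords internal
override_config <- function(cfg, overrides, class_name) {
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      stop(class_name, ": overrides must be named")
    }
    unknown <- setdiff(nm, names(cfg))
    if (length(unknown)) {
      stop(class_name, ": unknown field(s): ", paste(unknown, collapse = ", "))
    }
    for (n in nm) cfg[[n]] <- overrides[[n]]
  }
  structure(cfg, class = class_name)
}

#' Build the default synthetic spine geometry
#'
#' Stacks the vertebral bodies T10..L5 on top of the sacrum along the
#' sagittal curve defined by the per-level tilt angles, placing one
#' intervertebral joint centre at mid-disc between consecutive bodies and
#' the two sacroiliac joints between sacrum and pelvis.  The builder is
#' deterministic: the same configuration always yields the identical
#' geometry.
#'
#' @param config an [anatomy_config()].
#' @return an object of class `spine_geometry` with elements
#'   `bodies` (named list of frames: `center`, `R`, landmark points),
#'   `joints` (named list: `a`, `b` body labels, `center`, `R`),
#'   `sp_cut_center` (midpoint of the two SIJ centres, the sacrum-pelvis
#'   cut reference), `config`.
#' @export
build_default_spine <- function(config = anatomy_config()) {
  stopifnot(inherits(config, "anatomy_config"))
  hv <- config$vertebral_heights
  hd <- config$disc_heights
  if (any(hv <= 0)) {
    stop("anatomy config error: non-positive vertebral_heights for ",
         paste(names(hv)[hv <= 0], collapse = ", "))
  }
  if (any(hd <= 0)) {
    stop("anatomy config error: non-positive disc_heights for ",
         paste(names(hd)[hd <= 0], collapse = ", "))
  }
  missing_h <- setdiff(VERTEBRA_LABELS, names(hv))
  if (length(missing_h)) {
    stop("anatomy config error: vertebral_heights missing ",
         paste(missing_h, collapse = ", "))
  }
  missing_d <- setdiff(IV_JOINTS, names(hd))
  if (length(missing_d)) {
    stop("anatomy config error: disc_heights missing ",
         paste(missing_d, collapse = ", "))
  }
  missing_t <- setdiff(c("Sacrum", VERTEBRA_LABELS), names(config$tilt_deg))
  if (length(missing_t)) {
    stop("anatomy config error: tilt_deg missing ",
         paste(missing_t, collapse = ", "))
  }
  if (any(abs(config$tilt_deg) >= 60)) {
    stop("anatomy config error: tilt_deg must stay below 60 degrees ",
         "(non-monotonic stacking)")
  }

  bodies <- list()
  joints <- list()

  # Pelvis: fixed reference body at the configured centre.
  bodies$Pelvis <- list(label = "Pelvis", center = config$pelvis_center,
                        R = diag(3))

  # Sacrum.
  R_s <- rot_y(deg2rad(config$tilt_deg[["Sacrum"]]))
  c_s <- config$sacrum_center
  bodies$Sacrum <- list(
    label = "Sacrum", center = c_s, R = R_s,
    upper_endplate = c_s + R_s %*% c(0, 0, config$sacrum_height / 2),
    lower_endplate = c_s - R_s %*% c(0, 0, config$sacrum_height / 2),
    posterior = c_s + R_s %*% c(-40, 0, 0)
  )
  bodies$Sacrum$upper_endplate <- as.numeric(bodies$Sacrum$upper_endplate)
  bodies$Sacrum$lower_endplate <- as.numeric(bodies$Sacrum$lower_endplate)
  bodies$Sacrum$posterior <- as.numeric(bodies$Sacrum$posterior)

  # Sacroiliac joints, in the sacrum frame, mirrored across the sagittal plane.
  sij_l <- as.numeric(c_s + R_s %*% config$sij_center_local)
  sij_r <- as.numeric(c_s + R_s %*% mirror_point(config$sij_center_local))
  joints[["SIJ-left"]] <- list(label = "SIJ-left", a = "Sacrum", b = "Pelvis",
                               center = sij_l, R = diag(3))
  joints[["SIJ-right"]] <- list(label = "SIJ-right", a = "Sacrum", b = "Pelvis",
                                center = sij_r, R = diag(3))

  # Stack vertebrae caudal -> cranial, starting from the sacral endplate.
  stack_order <- rev(VERTEBRA_LABELS)          # L5 first
  top_point <- bodies$Sacrum$upper_endplate
  phi_prev <- deg2rad(config$tilt_deg[["Sacrum"]])
  joint_below <- "L5/S1"
  for (lab in stack_order) {
    phi <- deg2rad(config$tilt_deg[[lab]])
    R_v <- rot_y(phi)
    R_mid <- rot_y((phi + phi_prev) / 2)
    d <- hd[[joint_below]]
    dir_mid <- as.numeric(R_mid %*% c(0, 0, 1))
    lower_ep <- top_point + d * dir_mid
    center <- as.numeric(lower_ep + R_v %*% c(0, 0, hv[[lab]] / 2))
    upper_ep <- as.numeric(center + R_v %*% c(0, 0, hv[[lab]] / 2))
    ped_l <- as.numeric(center + R_v %*% config$pedicle_entry_local)
    ped_r <- as.numeric(center + R_v %*% mirror_point(config$pedicle_entry_local))
    if (isTRUE(config$sagittal_symmetry)) {
      # exact mirror by construction; keep bitwise identity
      ped_r <- c(ped_l[1], -ped_l[2], ped_l[3])
    }
    bodies[[lab]] <- list(
      label = lab, center = center, R = R_v,
      upper_endplate = upper_ep, lower_endplate = lower_ep,
      pedicle_entry_left = ped_l, pedicle_entry_right = ped_r,
      spinous_tip = as.numeric(center + R_v %*% config$spinous_tip_local),
      transverse_process_left =
        as.numeric(center + R_v %*% config$transverse_process_local),
      transverse_process_right =
        as.numeric(center + R_v %*% mirror_point(config$transverse_process_local))
    )
    jc <- top_point + (d / 2) * dir_mid
    caudal_label <- if (joint_below == "L5/S1") "Sacrum" else
      sub(".*/", "", joint_below)
    joints[[joint_below]] <- list(label = joint_below, a = lab,
                                  b = caudal_label,
                                  center = as.numeric(jc), R = R_mid)
    # next joint up connects this vertebra to the one above it
    idx <- match(lab, VERTEBRA_LABELS)
    if (idx > 1) joint_below <- paste0(VERTEBRA_LABELS[idx - 1], "/", lab)
    top_point <- upper_ep
    phi_prev <- phi
  }

  # order bodies and joints canonically (cranial -> caudal)
  bodies <- bodies[BODY_LABELS]
  joints <- joints[c(IV_JOINTS, SIJ_JOINTS)]

  geom <- structure(list(
    bodies = bodies,
    joints = joints,
    sp_cut_center = (sij_l + sij_r) / 2,
    sagittal_symmetry = isTRUE(config$sagittal_symmetry),
    config = config
  ), class = "spine_geometry")
  validate_spine_geometry(geom)
  geom
}

#' @keywords internal
validate_spine_geometry <- function(geom) {
  z <- vapply(geom$bodies[c(VERTEBRA_LABELS, "Sacrum")],
              function(b) b$center[3], numeric(1))
  if (any(diff(z) >= 0)) {
    stop("spine geometry invalid: body centres not strictly decreasing ",
         "cranio-caudally")
  }
  for (b in geom$bodies) {
    R <- b$R
    if (max(abs(t(R) %*% R - diag(3))) > 1e-10 || abs(det(R) - 1) > 1e-10) {
      stop("spine geometry invalid: non-orthonormal frame for ", b$label)
    }
  }
  # joint centres between adjacent body centres along z
  for (j in geom$joints[IV_JOINTS]) {
    za <- geom$bodies[[j$a]]$center[3]
    zb <- geom$bodies[[j$b]]$center[3]
    if (!(j$center[3] < za && j$center[3] > zb)) {
      stop("spine geometry invalid: joint centre of ", j$label,
           " not between its adjacent bodies")
    }
  }
  if (geom$sagittal_symmetry) {
    for (lab in VERTEBRA_LABELS) {
      b <- geom$bodies[[lab]]
      if (!identical(b$pedicle_entry_right,
                     c(b$pedicle_entry_left[1], -b$pedicle_entry_left[2],
                       b$pedicle_entry_left[3]))) {
        stop("spine geometry invalid: pedicle entries not mirrored at ", lab)
      }
    }
  }
  invisible(geom)
}

#' Body index in the cranial-to-caudal ordering
#'
#' T10 = 1 ... L5 = 8, Sacrum = 9, Pelvis = 10.  Used to decide which
#' fascicles cross which joint cut.
#' @param label body label.
#' @return integer index.
#' @keywords internal
body_index <- function(label) {
  i <- match(label, BODY_LABELS)
  if (is.na(i)) stop("unknown body label: ", label)
  i
}

#' Recruitment cut labels
#'
#' The eight intervertebral joints plus the single sacrum-pelvis cut `"S/P"`
#' that lumps the two parallel sacroiliac joints for inverse statics.
#' @param geom spine geometry (unused, kept for symmetry of the interface).
#' @return character vector of cut labels.
#' @keywords internal
cut_labels <- function(geom = NULL) c(IV_JOINTS, "S/P")

# Cut k separates bodies with index <= k (above) from index > k (below);
# the S/P cut separates pelvis (10) from everything else.
#' @keywords internal
cut_level <- function(cut) {
  if (cut == "S/P") return(9L)
  i <- match(cut, IV_JOINTS)
  if (is.na(i)) stop("unknown cut label: ", cut)
  i
}

#' @keywords internal
cut_center <- function(geom, cut) {
  if (cut == "S/P") geom$sp_cut_center else geom$joints[[cut]]$center
}

#' @keywords internal
cut_frame <- function(geom, cut) {
  if (cut == "S/P") diag(3) else geom$joints[[cut]]$R
}

#' Mirror a spine geometry across the sagittal plane
#'
#' Used by the symmetry property tests: on a sagittally symmetric
#' configuration this is an exact involution.
#'
#' @param geom a `spine_geometry`.
#' @return the mirrored `spine_geometry`.
#' @export
mirror_spine <- function(geom) {
  swap_lr <- function(nm) {
    nm2 <- gsub("left", "@@", nm)
    nm2 <- gsub("right", "left", nm2)
    gsub("@@", "right", nm2)
  }
  m <- geom
  for (lab in names(m$bodies)) {
    b <- m$bodies[[lab]]
    for (f in names(b)) {
      if (is.numeric(b[[f]]) && length(b[[f]]) == 3) b[[f]] <- mirror_point(b[[f]])
    }
    b$R <- mirror_rotation(geom$bodies[[lab]]$R)
    names(b) <- swap_lr(names(b))
    m$bodies[[lab]] <- b[names(geom$bodies[[lab]])]
  }
  for (lab in names(m$joints)) {
    j <- m$joints[[lab]]
    j$center <- mirror_point(j$center)
    j$R <- mirror_rotation(j$R)
    m$joints[[lab]] <- j
  }
  # swap the SIJ labels so "SIJ-left" stays on the +y side
  tmp <- m$joints[["SIJ-left"]]
  m$joints[["SIJ-left"]] <- m$joints[["SIJ-right"]]
  m$joints[["SIJ-right"]] <- tmp
  m$joints[["SIJ-left"]]$label <- "SIJ-left"
  m$joints[["SIJ-right"]]$label <- "SIJ-right"
  m$sp_cut_center <- mirror_point(geom$sp_cut_center)
  m
}

#' @export
print.spine_geometry <- function(x, ...) {
  cat("Synthetic spine geometry: ", length(x$bodies), " bodies (",
      paste(names(x$bodies)[c(1, length(x$bodies))], collapse = " .. "),
      "), ", length(x$joints), " joints (",
      sum(names(x$joints) %in% IV_JOINTS), " intervertebral + ",
      sum(names(x$joints) %in% SIJ_JOINTS), " SIJ)\n", sep = "")
  invisible(x)
}
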