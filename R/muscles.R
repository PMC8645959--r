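# Synthetic muscle fascicle architecture.  Nine trunk muscle groups
# (transversus, spinalis, semispinalis, erector spinae, obliquus internus,
# obliquus externus, psoas major, multifidi, quadratus lumborum) are
# represented bilaterally by straight-line fascicles between body-fixed
# attachment points.  Slip counts and attachments are a minimal defensible
# architecture, not a subject-specific one; everything is driven by the
# configuration so that attachment rules and strengths can be overridden.

MUSCLE_GROUPS <- c("transversus", "spinalis", "semispinalis", "erector_spinae",
                   "obliquus_internus", "obliquus_externus", "psoas_major",
                   "multifidus", "quadratus_lumborum")

#' Default muscle configuration
#'
#' Physiological cross-sectional areas are per fascicle slip (cm^2); the
#' maximum isometric force of a slip is `f_max = PCSA x specific_tension`.
#'
#' @param ... named overrides merged over the defaults.
#' @return a list with class `muscle_config`.
#' @export
muscle_config <- function(...) {
  cfg <- list(
    specific_tension = 90,   # N/cm^2
    pcsa = c(transversus = 2, spinalis = 1.5, semispinalis = 1.5,
             erector_spinae = 4, obliquus_internus = 4,
             obliquus_externus = 4, psoas_major = 3, multifidus = 2,
             quadratus_lumborum = 2),
    # body-local attachment offsets (left side; right mirrored)
    offsets = list(
      spinous = c(-50, 6, 0),
      mamillary = c(-22, 20, 0),
      transverse = c(0, 32, 0),
      body_anterolateral = c(12, 18, 0),
      body_lateral = c(8, 55, 0),
      sacrum_posterior = c(-35, 14, 0),
      sacrum_posterior_low = c(-30, 10, -12),
      # pelvis landmarks (global, pelvis frame = identity at origin)
      iliac_crest_posterior = c(-60, 38, 38),
      iliac_crest_lateral = c(-12, 58, 38),
      lesser_trochanter = c(10, 45, -60),
      pelvis_anterior = c(48, 20, -8),
      pelvis_anterolateral = c(30, 42, 5)
    ),
    check_coverage = TRUE
  )
  override_config(cfg, list(...), "muscle_config")
}

#' @keywords internal
attachment_point <- function(geom, body, local, side) {
  b <- geom$bodies[[body]]
  loc <- if (side == "right") mirror_point(local) else local
  if (body == "Pelvis") {
    as.numeric(b$center + loc)
  } else {
    as.numeric(b$center + b$R %*% loc)
  }
}

#' @keywords internal
make_fascicle <- function(geom, name, group, side, origin_body, origin_local,
                          insertion_body, insertion_local, pcsa,
                          specific_tension) {
  o <- attachment_point(geom, origin_body, origin_local, side)
  i <- attachment_point(geom, insertion_body, insertion_local, side)
  bo <- body_index(origin_body)
  bi <- body_index(insertion_body)
  # store cranial attachment first
  if (bo > bi) {
    tmp <- o; o <- i; i <- tmp
    tmpb <- origin_body; origin_body <- insertion_body; insertion_body <- tmpb
  }
  if (sqrt(sum((o - i)^2)) < 1e-9) stop("fascicle ", name, ": origin == insertion")
  f_max <- pcsa * specific_tension
  if (f_max <= 0) stop("fascicle ", name, ": f_max must be positive")
  lo <- body_index(origin_body); hi <- body_index(insertion_body)
  spanned <- cut_labels()[vapply(cut_labels(), function(cl) {
    k <- cut_level(cl); lo <= k && hi > k
  }, logical(1))]
  list(name = name, group = group, side = side,
       points = rbind(o, i), bodies = c(origin_body, insertion_body),
       via_points = list(), f_max = f_max, spanned = spanned)
}

#' Build the bilateral muscle fascicle set
#'
#' Generates straight-line fascicles for the nine trunk muscle groups on
#' both sides of the synthetic spine and verifies the joint-coverage
#' invariant: every intervertebral cut must be crossed by fascicles with
#' both positive and negative moment-arm components about the
#' flexion-extension and lateral-bending axes, otherwise recruitment for
#' that motion would be infeasible.
#'
#' @param geom a `spine_geometry`.
#' @param config a [muscle_config()].
#' @return an object of class `muscle_set`: a list of fascicles, each with
#'   `name`, `group`, `side`, `points` (2 x 3, cranial attachment first),
#'   `bodies`, `f_max` (N) and `spanned` cut labels.
#' @export
build_muscle_set <- function(geom, config = muscle_config()) {
  stopifnot(inherits(geom, "spine_geometry"), inherits(config, "muscle_config"))
  os <- config$offsets
  st <- config$specific_tension
  pc <- config$pcsa
  missing_g <- setdiff(MUSCLE_GROUPS, names(pc))
  if (length(missing_g)) {
    stop("muscle config error: pcsa missing for ",
         paste(missing_g, collapse = ", "))
  }
  fas <- list()
  add <- function(group, slip, side, ob, ol, ib, il, pcsa_scale = 1) {
    nm <- paste(group, side, slip, sep = "_")
    fas[[nm]] <<- make_fascicle(geom, nm, group, side, ob, ol, ib, il,
                                pc[[group]] * pcsa_scale, st)
  }
  for (side in c("left", "right")) {
    # multifidus: spinous process to 2 levels caudal (or sacrum)
    mf_pairs <- list(c("L1", "L3"), c("L2", "L4"), c("L3", "L5"),
                     c("L4", "Sacrum"), c("L5", "Sacrum"))
    for (k in seq_along(mf_pairs)) {
      p <- mf_pairs[[k]]
      il <- if (p[2] == "Sacrum") {
        if (p[1] == "L5") os$sacrum_posterior_low else os$sacrum_posterior
      } else os$mamillary
      add("multifidus", k, side, p[1], os$spinous, p[2], il)
    }
    # erector spinae: posterior iliac crest up to T10..L3; the superficial
    # thoracic parts bypass the lumbar vertebrae and carry most of the
    # extensor capacity, the lumbar slips are smaller
    es_targets <- c("T10", "T11", "T12", "L1", "L2", "L3")
    es_scale <- c(1.2, 1.2, 1.2, 0.5, 0.5, 0.5)
    for (k in seq_along(es_targets)) {
      add("erector_spinae", k, side, es_targets[k], c(-28, 30, 0),
          "Pelvis", os$iliac_crest_posterior, pcsa_scale = es_scale[k])
    }
    # spinalis: upper-lumbar spinous to low-thoracic spinous
    add("spinalis", 1, side, "L1", os$spinous, "T10", os$spinous)
    add("spinalis", 2, side, "L2", os$spinous, "T11", os$spinous)
    # semispinalis: lumbar transverse process to thoracic spinous
    add("semispinalis", 1, side, "L1", os$transverse, "T10", os$spinous)
    add("semispinalis", 2, side, "L2", os$transverse, "T11", os$spinous)
    # quadratus lumborum: lateral iliac crest to T12 and L1..L4 transverse
    ql_targets <- c("T12", "L1", "L2", "L3", "L4")
    for (k in seq_along(ql_targets)) {
      add("quadratus_lumborum", k, side, ql_targets[k], os$transverse,
          "Pelvis", os$iliac_crest_lateral)
    }
    # psoas major: anterolateral lumbar bodies to the lesser trochanter
    ps_targets <- c("L1", "L2", "L3", "L4", "L5")
    for (k in seq_along(ps_targets)) {
      add("psoas_major", k, side, ps_targets[k], os$body_anterolateral,
          "Pelvis", os$lesser_trochanter)
    }
    # obliquus externus: low-ribcage surrogate to the anterior pelvis,
    # running caudal-medial along the abdominal wall (well anterior of the
    # spine, as the wall itself is)
    oe_targets <- c("T10", "T11", "T12")
    oe_org <- list(c(30, 70, 0), c(32, 66, 0), c(34, 62, 0))
    oe_ins <- list(c(70, 22, -10), c(64, 32, -5), c(58, 42, 0))
    for (k in seq_along(oe_targets)) {
      add("obliquus_externus", k, side, oe_targets[k], oe_org[[k]],
          "Pelvis", oe_ins[[k]])
    }
    # obliquus internus: lateral iliac crest, cranial-medial run along the wall
    oi_ins <- list(c(55, 40, 0), c(52, 44, 0), c(48, 48, 0))
    for (k in seq_along(oe_targets)) {
      add("obliquus_internus", k, side, oe_targets[k], oi_ins[[k]],
          "Pelvis", c(15, 62, 32))
    }
    # transversus: near-horizontal anterolateral wrap surrogate
    add("transversus", 1, side, "L2", c(20, 72, 0), "Pelvis", c(72, 12, 5))
    add("transversus", 2, side, "L3", c(22, 70, 0), "Pelvis", c(72, 12, -8))
  }
  ms <- structure(fas, class = "muscle_set")
  if (isTRUE(config$check_coverage)) check_joint_coverage(ms, geom)
  ms
}

#' Moment arm of a fascicle about a joint cut
#'
#' For a fascicle crossing the cut, the moment (per unit tension, N.mm/N)
#' that the force it applies to the chain above the cut exerts about the
#' cut reference point, in the global frame.  Zero vector if the fascicle
#' does not cross the cut.
#'
#' @param fas a fascicle from a `muscle_set`.
#' @param geom a `spine_geometry`.
#' @param cut a cut label (`"T10/T11"` .. `"L5/S1"` or `"S/P"`).
#' @return length-3 numeric vector.
#' @export
fascicle_moment_arm <- function(fas, geom, cut) {
  if (!(cut %in% fas$spanned)) return(c(0, 0, 0))
  k <- cut_level(cut)
  pts <- fascicle_polyline(fas)
  bod <- fascicle_point_bodies(fas)
  idx <- which(body_index_vec(bod) <= k)
  i <- max(idx)   # lowest point above the cut
  u <- unit3(pts[i + 1, ] - pts[i, ])
  cross3(pts[i, ] - cut_center(geom, cut), u)
}

#' @keywords internal
body_index_vec <- function(labels) vapply(labels, body_index, integer(1))

#' @keywords internal
fascicle_polyline <- function(fas) {
  if (length(fas$via_points)) {
    rbind(fas$points[1, , drop = FALSE],
          do.call(rbind, lapply(fas$via_points, `[[`, "point")),
          fas$points[2, , drop = FALSE])
  } else fas$points
}

#' @keywords internal
fascicle_point_bodies <- function(fas) {
  if (length(fas$via_points)) {
    c(fas$bodies[1], vapply(fas$via_points, `[[`, character(1), "body"),
      fas$bodies[2])
  } else fas$bodies
}

#' @keywords internal
check_joint_coverage <- function(ms, geom) {
  for (cut in IV_JOINTS) {
    Rj <- cut_frame(geom, cut)
    for (axis_name in c("flexion-extension", "lateral-bending")) {
      a <- if (axis_name == "flexion-extension") Rj[, 2] else Rj[, 1]
      comp <- vapply(ms, function(f) sum(fascicle_moment_arm(f, geom, cut) * a),
                     numeric(1))
      if (!(any(comp > 1) && any(comp < -1))) {
        stop("muscle coverage error: joint ", cut, " lacks an ",
             "agonist/antagonist pair about the ", axis_name, " axis")
      }
    }
  }
  invisible(ms)
}

#' Mirror a muscle set across the sagittal plane
#' @param ms a `muscle_set`.
#' @return the mirrored `muscle_set` (sides swapped, names updated).
#' @export
mirror_muscle_set <- function(ms) {
  out <- lapply(ms, function(f) {
    f$points <- t(apply(f$points, 1, mirror_point))
    if (length(f$via_points)) {
      f$via_points <- lapply(f$via_points, function(v) {
        v$point <- mirror_point(v$point); v
      })
    }
    f$side <- if (f$side == "left") "right" else "left"
    f$name <- sub("_(left|right)_", paste0("_", f$side, "_"), f$name)
    f
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  structure(out[order(names(out))], class = "muscle_set")
}

#' Export a muscle set to CSV
#'
#' Columns: name, side, group, origin/insertion coordinates, via points
#' (semicolon-separated x|y|z triplets), f_max_N, spanned_joints
#' (semicolon-separated labels).
#'
#' @param ms a `muscle_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_muscle_csv <- function(ms, path) {
  df <- data.frame(
    name = vapply(ms, `[[`, character(1), "name"),
    side = vapply(ms, `[[`, character(1), "side"),
    group = vapply(ms, `[[`, character(1), "group"),
    origin_x = vapply(ms, function(f) f$points[1, 1], numeric(1)),
    origin_y = vapply(ms, function(f) f$points[1, 2], numeric(1)),
    origin_z = vapply(ms, function(f) f$points[1, 3], numeric(1)),
    insertion_x = vapply(ms, function(f) f$points[2, 1], numeric(1)),
    insertion_y = vapply(ms, function(f) f$points[2, 2], numeric(1)),
    insertion_z = vapply(ms, function(f) f$points[2, 3], numeric(1)),
    via_points = vapply(ms, function(f) {
      if (!length(f$via_points)) return("")
      paste(vapply(f$via_points, function(v)
        paste(v$point, collapse = "|"), character(1)), collapse = ";")
    }, character(1)),
    f_max_N = vapply(ms, `[[`, numeric(1), "f_max"),
    spanned_joints = vapply(ms, function(f) paste(f$spanned, collapse = ";"),
                            character(1)),
    origin_body = vapply(ms, function(f) f$bodies[1], character(1)),
    insertion_body = vapply(ms, function(f) f$bodies[2], character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a muscle set from CSV
#'
#' Inverse of [write_muscle_csv()]; validates the fascicle invariants
#' (positive `f_max`, distinct attachments, contiguous spanned joints).
#'
#' @param path CSV path.
#' @return a `muscle_set`.
#' @export
read_muscle_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fas <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    pts <- rbind(c(r$origin_x, r$origin_y, r$origin_z),
                 c(r$insertion_x, r$insertion_y, r$insertion_z))
    if (r$f_max_N <= 0) stop("invalid fascicle ", r$name, ": f_max <= 0")
    if (sqrt(sum((pts[1, ] - pts[2, ])^2)) < 1e-9) {
      stop("invalid fascicle ", r$name, ": origin == insertion")
    }
    spanned <- strsplit(r$spanned_joints, ";")[[1]]
    lev <- sort(vapply(spanned, cut_level, integer(1)))
    if (length(lev) && any(diff(lev) != 1)) {
      stop("invalid fascicle ", r$name, ": spanned joints not contiguous")
    }
    list(name = r$name, group = r$group, side = r$side, points = pts,
         bodies = c(r$origin_body, r$insertion_body), via_points = list(),
         f_max = r$f_max_N, spanned = spanned)
  })
  names(fas) <- df$name
  structure(fas, class = "muscle_set")
}

#' @export
print.muscle_set <- function(x, ...) {
  cat("Muscle set: ", length(x), " fascicles, ",
      length(unique(vapply(x, `[[`, character(1), "group"))), " groups\n",
      sep = "")
  invisible(x)
}
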