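# L1-L5 posterior fixation: pedicle screws and rods as titanium beam
# elements for the FE model, and rigid fusion constraints for the MSK model.
# Screw trajectory: from the pedicle entry point toward the anterior body
# centre with a configurable medial angulation; each screw is one beam from
# its head (shared with the rod polyline) to its tip (rigidly tied to the
# vertebral body).  Rods run caudally through the ipsilateral screw heads as
# straight segments, discretized with >= 2 elements per inter-screw span.

#' Fixation construct configuration
#'
#' Defaults: 5.5 mm rods, 6 x 45 mm pedicle screws, titanium
#' (E = 110 GPa, nu = 0.3), L1-L5.
#'
#' @param ... named overrides merged over the defaults.
#' @return list with class `fixation_config`.
#' @export
fixation_config <- function(...) {
  cfg <- list(
    levels = c("L1", "L2", "L3", "L4", "L5"),
    rod_diameter = 5.5,          # mm
    screw_diameter = 6,          # mm
    screw_length = 45,           # mm
    head_offset = 12,            # mm the head sticks out behind the entry
    medial_angle_deg = 15,       # axial-plane convergence of the screw axis
    elastic_modulus = 110000,    # MPa (titanium)
    poisson = 0.3,
    elements_per_span = 2,       # rod beam elements per inter-screw span
    yield_stress = NULL          # MPa; enables percent-of-yield reporting
  )
  cfg <- override_config(cfg, list(...), "fixation_config")
  if (length(cfg$levels) < 2) {
    stop("fixation config error: a rod needs at least 2 instrumented levels")
  }
  for (f in c("rod_diameter", "screw_diameter", "screw_length",
              "elastic_modulus")) {
    if (cfg[[f]] <= 0) stop("fixation config error: ", f, " must be positive")
  }
  if (cfg$elements_per_span < 2) {
    stop("fixation config error: elements_per_span must be >= 2")
  }
  cfg
}

#' Build the pedicle screw and rod construct
#'
#' Creates 2 screws per instrumented vertebra and 2 rod polylines passing
#' through the ipsilateral screw heads in cranio-caudal order.  Screw tips
#' are rigidly tied to their vertebral bodies (bonded screw-bone
#' interface); screw heads are shared nodes with the rods.
#'
#' @param geom a `spine_geometry`.
#' @param config a [fixation_config()].
#' @return an object of class `fixation_construct` with `extra_nodes`
#'   (named list: `point`, optional `tied_to`), `beam_elements`, `screws`
#'   and `rods` summaries, and the `config`.
#' @export
build_fixation <- function(geom, config = fixation_config()) {
  stopifnot(inherits(geom, "spine_geometry"),
            inherits(config, "fixation_config"))
  missing_lv <- setdiff(config$levels, VERTEBRA_LABELS)
  if (length(missing_lv)) {
    stop("fixation error: unknown level(s) ", paste(missing_lv, collapse = ", "))
  }
  levels <- VERTEBRA_LABELS[VERTEBRA_LABELS %in% config$levels]  # cranio-caudal
  rod_sec <- circular_section(config$rod_diameter)
  screw_sec <- circular_section(config$screw_diameter)
  E <- config$elastic_modulus; nu <- config$poisson

  extra_nodes <- list()
  beam_elements <- list()
  screws <- list()
  rods <- list()

  for (side in c("left", "right")) {
    sgn <- if (side == "left") 1 else -1
    head_labels <- character(0)
    for (lv in levels) {
      b <- geom$bodies[[lv]]
      entry <- if (side == "left") b$pedicle_entry_left else
        b$pedicle_entry_right
      # screw axis: posterior entry toward the anterior body centre,
      # convergent (medial) in the axial plane of the vertebra
      am <- deg2rad(config$medial_angle_deg)
      axis_local <- c(cos(am), -sgn * sin(am), 0)
      axis <- as.numeric(b$R %*% axis_local)
      head <- entry - config$head_offset * axis
      tip <- entry + (config$screw_length - config$head_offset) * axis
      hl <- paste0("screw_head_", lv, "_", side)
      el <- paste0("screw_entry_", lv, "_", side)
      tl <- paste0("screw_tip_", lv, "_", side)
      # the shank is bonded to the vertebra (entry and tip nodes tied);
      # only the exposed head segment is compliant
      extra_nodes[[hl]] <- list(point = head, tied_to = NULL)
      extra_nodes[[el]] <- list(point = entry, tied_to = lv)
      extra_nodes[[tl]] <- list(point = tip, tied_to = lv)
      comp <- paste0("screw_", lv, "_", side)
      beam_elements[[length(beam_elements) + 1]] <-
        list(n1 = hl, n2 = el, section = screw_sec, E = E, poisson = nu,
             component = comp)
      beam_elements[[length(beam_elements) + 1]] <-
        list(n1 = el, n2 = tl, section = screw_sec, E = E, poisson = nu,
             component = comp)
      screws[[comp]] <- list(level = lv, side = side, head = head, tip = tip,
                             entry = entry,
                             length = config$screw_length,
                             diameter = config$screw_diameter)
      head_labels <- c(head_labels, hl)
    }
    # rod polyline through the screw heads, >= 2 elements per span
    rod_comp <- paste0("rod_", side)
    for (i in seq_len(length(levels) - 1)) {
      h1 <- head_labels[i]; h2 <- head_labels[i + 1]
      p1 <- extra_nodes[[h1]]$point; p2 <- extra_nodes[[h2]]$point
      nseg <- config$elements_per_span
      prev <- h1
      for (s in seq_len(nseg)) {
        if (s < nseg) {
          ml <- paste0("rod_", side, "_", levels[i], "_", levels[i + 1], "_", s)
          pm <- p1 + (s / nseg) * (p2 - p1)
          extra_nodes[[ml]] <- list(point = pm, tied_to = NULL)
          nxt <- ml
        } else nxt <- h2
        beam_elements[[length(beam_elements) + 1]] <-
          list(n1 = prev, n2 = nxt, section = rod_sec, E = E, poisson = nu,
               component = rod_comp)
        prev <- nxt
      }
    }
    rods[[rod_comp]] <- list(side = side, levels = levels,
                             diameter = config$rod_diameter,
                             heads = head_labels)
  }

  structure(list(extra_nodes = extra_nodes, beam_elements = beam_elements,
                 screws = screws, rods = rods, levels = levels,
                 config = config),
            class = "fixation_construct")
}

#' Rigid fusion constraints for the MSK model
#'
#' For a contiguous set of instrumented levels, returns the labels of the
#' joints interior to the fused block.  These joints are constrained to
#' zero relative rotation in the imposed motion and dropped from the
#' recruitment moment-equilibrium constraints: the rigid connection
#' transmits force and moment in full, so no muscle moment balance is
#' required there.
#'
#' @param levels ordered vertebra labels (default L1..L5).
#' @return character vector of fused joint labels, class `msk_fusion`.
#' @export
fuse_msk <- function(levels = c("L1", "L2", "L3", "L4", "L5")) {
  idx <- match(levels, VERTEBRA_LABELS)
  if (any(is.na(idx))) stop("fusion error: unknown level(s)")
  idx <- sort(idx)
  if (length(idx) < 2 || any(diff(idx) != 1)) {
    stop("fusion error: levels must be a contiguous set of >= 2 vertebrae")
  }
  fused <- vapply(seq_len(length(idx) - 1), function(i) {
    paste0(VERTEBRA_LABELS[idx[i]], "/", VERTEBRA_LABELS[idx[i + 1]])
  }, character(1))
  structure(fused, class = "msk_fusion")
}

#' Construct summary as a data frame
#'
#' One row per component: `component_id`, `type`, `level`, `side`,
#' `length_mm`, `diameter_mm`.
#'
#' @param construct a `fixation_construct`.
#' @return data.frame.
#' @export
fixation_summary <- function(construct) {
  sc <- construct$screws
  df1 <- data.frame(
    component_id = names(sc),
    type = "screw",
    level = vapply(sc, `[[`, character(1), "level"),
    side = vapply(sc, `[[`, character(1), "side"),
    length_mm = vapply(sc, `[[`, numeric(1), "length"),
    diameter_mm = vapply(sc, `[[`, numeric(1), "diameter"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  rd <- construct$rods
  rod_len <- vapply(rd, function(r) {
    hs <- r$heads
    sum(vapply(seq_len(length(hs) - 1), function(i) {
      sqrt(sum((construct$extra_nodes[[hs[i + 1]]]$point -
                construct$extra_nodes[[hs[i]]]$point)^2))
    }, numeric(1)))
  }, numeric(1))
  df2 <- data.frame(
    component_id = names(rd),
    type = "rod",
    level = paste(construct$levels[1], construct$levels[length(construct$levels)],
                  sep = "-"),
    side = vapply(rd, `[[`, character(1), "side"),
    length_mm = as.numeric(rod_len),
    diameter_mm = vapply(rd, `[[`, numeric(1), "diameter"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  rbind(df1, df2)
}

#' @export
print.fixation_construct <- function(x, ...) {
  cat("Fixation construct: ", length(x$screws), " screws, ",
      length(x$rods), " rods spanning ", x$levels[1], "-",
      x$levels[length(x$levels)], "\n", sep = "")
  invisible(x)
}
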