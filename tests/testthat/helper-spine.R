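# Shared fixtures, built in code.  Everything here is cheap (< 1 s) and
# deterministic, so the objects are constructed once per test run.

default_geom <- build_default_spine()
default_joints <- build_bushings(default_geom)
default_ligaments <- build_ligaments(default_geom)
default_muscles <- build_muscle_set(default_geom)

# Joint set with ligaments disabled (fully linear model).
linear_joint_config <- joint_config(ligaments_enabled = FALSE)

# A chain in which every joint except `flex_joint` is made effectively
# rigid, so the response is that of a single bushing: used for the
# closed-form single-joint oracles.
single_joint_bushings <- function(geom, flex_joint = "T10/T11",
                                  k_rot = 1e5, k_trans = 2000,
                                  rigid = 1e9) {
  joints <- build_bushings(geom, linear_joint_config)
  for (jl in names(joints)) {
    if (jl == flex_joint) {
      joints[[jl]]$K_rot <- diag(rep(k_rot, 3))
      joints[[jl]]$K_trans <- diag(rep(k_trans, 3))
    } else {
      joints[[jl]]$K_rot <- diag(rep(rigid, 3))
      joints[[jl]]$K_trans <- diag(rep(rigid / 100, 3))
    }
  }
  joints
}

# A hand-built two-fascicle muscle set acting about a single joint, for
# the recruitment closed forms.
toy_muscle_set <- function(geom, arm_mm = 50, n_fascicles = 1,
                           f_max = 1000) {
  jc <- geom$joints[["T10/T11"]]$center
  fas <- lapply(seq_len(n_fascicles), function(i) {
    # vertical line of action offset posteriorly by arm_mm: moment about
    # the joint's y axis = -arm for a downward pull, +arm upward
    p_top <- jc + c(-arm_mm, 0, 80)
    p_bot <- jc + c(-arm_mm, 0, -80)
    list(name = paste0("toy_", i), group = "toy", side = "left",
         points = rbind(p_top, p_bot), bodies = c("T10", "Pelvis"),
         via_points = list(), f_max = f_max,
         spanned = spinecouple:::cut_labels())
  })
  names(fas) <- vapply(fas, `[[`, character(1), "name")
  structure(fas, class = "muscle_set")
}

run_intact_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- validate_and_report(pipeline_config(),
                                                      "intact")
    cache
  }
})

run_instrumented_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- validate_and_report(pipeline_config(),
                                                      "instrumented")
    cache
  }
})
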