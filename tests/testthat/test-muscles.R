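test_that("all nine trunk muscle groups are present bilaterally", {
  ms <- default_muscles
  groups <- vapply(ms, `[[`, character(1), "group")
  sides <- vapply(ms, `[[`, character(1), "side")
  expected <- c("transversus", "spinalis", "semispinalis", "erector_spinae",
                "obliquus_internus", "obliquus_externus", "psoas_major",
                "multifidus", "quadratus_lumborum")
  for (g in expected) {
    expect_true(any(groups == g & sides == "left"), label = paste(g, "left"))
    expect_true(any(groups == g & sides == "right"), label = paste(g, "right"))
  }
})

test_that("maximum force is PCSA times specific tension", {
  cfg <- muscle_config(pcsa = c(transversus = 5, spinalis = 1.5,
                                semispinalis = 1.5, erector_spinae = 4,
                                obliquus_internus = 4, obliquus_externus = 4,
                                psoas_major = 3, multifidus = 2,
                                quadratus_lumborum = 2),
                       specific_tension = 90)
  ms <- build_muscle_set(default_geom, cfg)
  tv <- ms[[which(vapply(ms, `[[`, character(1), "group") == "transversus")[1]]]
  expect_equal(tv$f_max, 450)   # 5 cm^2 x 90 N/cm^2
})

test_that("left and right fascicle sets are mirror images", {
  ms <- default_muscles
  for (f in ms) {
    if (f$side != "left") next
    twin_name <- sub("_left_", "_right_", f$name)
    twin <- ms[[twin_name]]
    expect_false(is.null(twin))
    expect_equal(twin$points,
                 t(apply(f$points, 1, function(p) c(p[1], -p[2], p[3]))),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(twin$f_max, f$f_max)
    expect_identical(twin$spanned, f$spanned)
  }
})

test_that("every intervertebral joint has opposing moment arms about both bending axes", {
  geom <- default_geom
  ms <- default_muscles
  for (cutl in setdiff(spinecouple:::cut_labels(), "S/P")) {
    Rj <- spinecouple:::cut_frame(geom, cutl)
    for (col in 1:2) {   # x lateral bending, y flexion-extension
      a <- Rj[, col]
      comp <- vapply(ms, function(f)
        sum(fascicle_moment_arm(f, geom, cutl) * a), numeric(1))
      expect_gt(max(comp), 1)
      expect_lt(min(comp), -1)
    }
  }
})

test_that("an uncovered joint raises a coverage error naming it", {
  # with only posterior (extensor) groups left, the coverage check must
  # fail about the flexion-extension axis
  ms <- default_muscles
  keep <- vapply(ms, function(f)
    f$group %in% c("multifidus", "erector_spinae", "spinalis",
                   "semispinalis"), logical(1))
  ms2 <- structure(unclass(ms)[keep], class = "muscle_set")
  expect_error(spinecouple:::check_joint_coverage(ms2, default_geom),
               "coverage error.*flexion-extension")
})

test_that("the fascicle table round-trips through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_muscle_csv(default_muscles, path)
  ms2 <- read_muscle_csv(path)
  expect_identical(names(ms2), names(default_muscles))
  for (nm in names(default_muscles)) {
    expect_equal(ms2[[nm]]$points, default_muscles[[nm]]$points,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(ms2[[nm]]$f_max, default_muscles[[nm]]$f_max)
    expect_identical(ms2[[nm]]$spanned, default_muscles[[nm]]$spanned)
  }
})

test_that("invalid fascicle tables are rejected on load", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_muscle_csv(default_muscles, path)
  df <- utils::read.csv(path)
  df$f_max_N[1] <- -10
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_muscle_csv(path), "f_max")
})
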