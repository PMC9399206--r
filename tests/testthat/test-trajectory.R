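test_that("session bundles round-trip losslessly through CSV", {
  set.seed(4)
  n <- 60
  pos <- matrix(rnorm(n * 3, sd = 20), n, 3)
  att <- matrix(runif(n * 3, -3, 3), n, 3)
  tr1 <- make_track(pos, fs = 120, instrument = "grasper",
                    attitude = lapgoals:::wrap_angle(att),
                    gripper = runif(n, 0, 0.8),
                    in_view = c(rep(FALSE, 5), rep(TRUE, n - 5)))
  tr2 <- make_track(pos + 10, fs = 120, instrument = "scissors",
                    port = c(60, -70, 90))
  geom <- cbind(seq(-50, 50, 10), 0, 0)
  rec <- session_record("sessA", "task1", list(grasper = tr1, scissors = tr2),
                        target_geometry = geom,
                        participant_meta = list(skill = 0.4))
  dir <- withr::local_tempdir()
  write_session(rec, file.path(dir, "sessA"))
  back <- read_session(file.path(dir, "sessA"))

  expect_s3_class(back, "session_record")
  expect_length(back$tracks, 2)
  expect_equal(back$session_id, "sessA")
  for (id in names(rec$tracks)) {
    expect_equal(back$tracks[[id]]$tip_position, rec$tracks[[id]]$tip_position,
                 tolerance = 1e-9)
    expect_equal(back$tracks[[id]]$attitude, rec$tracks[[id]]$attitude,
                 tolerance = 1e-9)
    expect_equal(back$tracks[[id]]$gripper_angle, rec$tracks[[id]]$gripper_angle,
                 tolerance = 1e-9)
    expect_identical(back$tracks[[id]]$in_view, rec$tracks[[id]]$in_view)
    expect_equal(back$tracks[[id]]$port_position, rec$tracks[[id]]$port_position)
  }
  expect_equal(unname(back$target_geometry), unname(geom), tolerance = 1e-9)

  # absent geometry writes no geometry file
  rec2 <- session_record("sessB", "task1", list(grasper = tr1))
  write_session(rec2, file.path(dir, "sessB"))
  expect_false(file.exists(file.path(dir, "sessB", "target_geometry.csv")))
  expect_null(read_session(file.path(dir, "sessB"))$target_geometry)
})

test_that("declared cm/degree units are converted to mm/rad on read", {
  dir <- withr::local_tempdir()
  tr <- line_track(c(0, 0, 0), c(30, 40, 0), speed = 50)
  rec <- session_record("sessU", "task1", list(grasper = tr))
  write_session(rec, file.path(dir, "sessU"))
  # rewrite metadata declaring cm/deg, rescaling the stored numbers
  meta <- jsonlite::read_json(file.path(dir, "sessU", "session.json"),
                              simplifyVector = TRUE)
  meta$position_unit <- "cm"; meta$angle_unit <- "deg"
  meta$instruments$grasper$port_position <- meta$instruments$grasper$port_position / 10
  jsonlite::write_json(meta, file.path(dir, "sessU", "session.json"),
                       auto_unbox = TRUE, digits = NA)
  d <- read.csv(file.path(dir, "sessU", "grasper.csv"))
  d[c("x", "y", "z")] <- d[c("x", "y", "z")] / 10
  d[c("roll", "pitch", "yaw", "gripper")] <- d[c("roll", "pitch", "yaw", "gripper")] * 180 / pi
  write.csv(d, file.path(dir, "sessU", "grasper.csv"), row.names = FALSE)
  back <- read_session(file.path(dir, "sessU"))
  expect_equal(back$tracks$grasper$tip_position, tr$tip_position, tolerance = 1e-6)
  expect_equal(back$tracks$grasper$port_position, tr$port_position, tolerance = 1e-6)
})

test_that("malformed bundles are rejected with a format error", {
  dir <- withr::local_tempdir()
  tr <- line_track(c(0, 0, 0), c(10, 0, 0), speed = 10)
  rec <- session_record("sessE", "task1", list(grasper = tr))
  write_session(rec, file.path(dir, "sessE"))

  # decreasing timestamps
  d <- read.csv(file.path(dir, "sessE", "grasper.csv"))
  d$t[3] <- d$t[2] - 0.5
  write.csv(d, file.path(dir, "sessE", "grasper.csv"), row.names = FALSE)
  expect_error(read_session(file.path(dir, "sessE")), "format error.*increasing")

  # missing column
  write_session(rec, file.path(dir, "sessE"))
  d <- read.csv(file.path(dir, "sessE", "grasper.csv"))
  d$yaw <- NULL
  write.csv(d, file.path(dir, "sessE", "grasper.csv"), row.names = FALSE)
  expect_error(read_session(file.path(dir, "sessE")), "format error.*yaw")

  # unknown instrument label
  expect_error(make_track(matrix(0, 5, 3), instrument = "forceps_x"),
               "unknown instrument")

  # task3 instrument contract
  expect_error(
    session_record("sessT", "task3", list(grasper = tr)),
    "right and left needle holders"
  )
})

test_that("track invariants catch non-uniform sampling and bad channels", {
  pos <- matrix(0, 10, 3)
  expect_error(instrument_track("grasper", 100, c(0:8, 9.5) / 100, pos,
                                matrix(0, 10, 3), rep(0, 10), rep(TRUE, 10),
                                c(0, 0, 0)),
               "non-uniform")
  expect_error(make_track(pos, gripper = c(rep(0.1, 9), -0.2)), "gripper")
  bad_pos <- pos; bad_pos[4, 2] <- NaN
  expect_error(make_track(bad_pos), "non-finite tip")
  # non-finite coordinates are fine while out of view
  iv <- rep(TRUE, 10); iv[4] <- FALSE
  expect_s3_class(make_track(bad_pos, in_view = iv), "instrument_track")
})

test_that("GOALS scores validate, sum exactly, and round-trip CSV", {
  s <- goals_score("s1", "r1", "task1", named_items(c(3, 4, 3, 4, 4)))
  expect_equal(s$total, 18)
  expect_equal(s$total, sum(s$items))

  expect_error(goals_score("s1", "r1", "task1", named_items(c(3, 4, 3, 4, 6))),
               "\\[1, 5\\]")
  expect_error(goals_score("s1", "r1", "task1", named_items(c(3, 4.5, 3, 4, 4))),
               "multiples")
  s_half <- goals_score("s1", "mean", "task1", named_items(c(3, 4.5, 3, 4, 4)),
                        allow_half = TRUE)
  expect_equal(s_half$total, 18.5)

  # task3 omits tissue handling; totals live in [4, 20]
  s3 <- goals_score("s2", "r1", "task3", named_items(c(5, 5, 5, 5), "task3"))
  expect_equal(s3$total, 20)
  expect_false("tissue_handling" %in% names(s3$items))

  f <- withr::local_tempfile(fileext = ".csv")
  two <- c(toy_goals(named_items(c(3, 4, 3, 4, 4)), named_items(c(2, 4, 3, 5, 4))),
           list(goals_score("s2", "rater1", "task3", named_items(c(1, 2, 3, 4), "task3"))))
  write_goals(two, f)
  back <- read_goals(f)
  expect_length(back, 3)
  expect_equal(back[[1]]$items, two[[1]]$items)
  expect_equal(back[[3]]$total, 10)
  expect_equal(vapply(back, function(s) s$rater_id, character(1)),
               c("rater1", "rater2", "rater1"))
})

test_that("pipeline config validates thresholds and reads partial files", {
  expect_error(pipeline_config(sg_window = 20), "odd")
  expect_error(pipeline_config(velocity_thresholds = c(5, 5, 75, 150)), "ascending")
  expect_error(pipeline_config(gripper_open = 0.1, gripper_close = 0.2), "hysteresis")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("sg_window: 15", "repetitions: 3"), f)
  cfg <- read_pipeline_config(f)
  expect_equal(cfg$sg_window, 15L)
  expect_equal(cfg$repetitions, 3L)
  expect_equal(cfg$k_outer, 10L)  # untouched default
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_field: 1", f2)
  expect_error(read_pipeline_config(f2), "unknown config field")
})
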