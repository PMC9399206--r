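test_that("path length matches closed-form arc lengths", {
  # 3-4-5 right triangle line: exactly 50 mm whatever the sampling
  for (n in c(2, 7, 101)) {
    tau <- seq(0, 1, length.out = n)
    pos <- cbind(30 * tau, 40 * tau, 0)
    expect_equal(path_length(manual_series(pos)), 50)
  }
  # single sample has zero length
  expect_equal(path_length(manual_series(matrix(c(1, 2, 3), 1, 3))), 0)
  # helix r = 10 mm, pitch 5 mm, 2 turns, 1 kHz sampling
  r <- 10; pitch <- 5; fs <- 1000
  t <- seq(0, 2, by = 1 / fs)  # one turn per second
  pos <- cbind(r * cos(2 * pi * t), r * sin(2 * pi * t), pitch * t)
  analytic <- 2 * sqrt((2 * pi * r)^2 + pitch^2)
  expect_equal(path_length(manual_series(pos, fs = fs)), analytic,
               tolerance = 1e-3)
})

test_that("speed metrics recover analytic circular motion through the filter", {
  fs <- 200; r <- 20; om <- 2 * pi * 0.5
  t <- seq(0, 4, by = 1 / fs)
  pos <- cbind(r * cos(om * t), r * sin(om * t), 0)
  ks <- savgol_smooth(make_track(pos, fs = fs), 21, 3)
  sm <- speed_metrics(ks)
  expect_equal(sm$V, r * om, tolerance = 0.005)
  expect_equal(sm$A, r * om^2, tolerance = 0.005)
  # uniform straight motion: V exact, A and J vanish
  tr <- line_track(c(0, 0, 0), c(100, 0, 0), speed = 10, fs = 100)
  sl <- speed_metrics(savgol_smooth(tr, 21, 3))
  expect_equal(sl$V, 10, tolerance = 1e-6)
  expect_lt(sl$A, 1e-6)
  expect_lt(sl$J, 1e-4)
  expect_lt(sl$VR, 1e-6)
  # all-masked series yields missing values
  ks0 <- manual_series(matrix(0, 30, 3), valid = rep(FALSE, 30))
  expect_true(all(is.na(unlist(speed_metrics(ks0)))))
})

test_that("velocity bands count samples exactly and sum to one", {
  n <- 100
  sp <- c(rep(10, n / 2), rep(100, n / 2))
  ks <- manual_series(matrix(0, n, 3), d1 = cbind(sp, 0, 0))
  vd <- velocity_distribution(ks, c(5, 25, 75, 150))
  expect_equal(unname(vd[c("Low", "High")]), c(0.5, 0.5))
  expect_equal(sum(vd), 1)
  # stationary track is all idle
  vd0 <- velocity_distribution(manual_series(matrix(0, 20, 3)))
  expect_equal(unname(vd0["Idle"]), 1)
  # random speeds: counting oracle + normalisation
  set.seed(2)
  spr <- runif(500, 0, 300)
  ksr <- manual_series(matrix(0, 500, 3), d1 = cbind(spr, 0, 0))
  vdr <- velocity_distribution(ksr, c(5, 25, 75, 150))
  expect_equal(sum(vdr), 1, tolerance = 1e-9)
  expect_equal(unname(vdr["Middle"]), mean(spr >= 25 & spr < 75))
  expect_error(velocity_distribution(ksr, c(5, 5, 75, 150)), "ascending")
})

test_that("depth metrics project motion onto the port-to-tip axis", {
  port <- c(0, 0, 0)
  # purely axial motion: 30 mm along z over 1 s
  fs <- 100; n <- 101
  z <- seq(50, 80, length.out = n)
  ks <- manual_series(cbind(0, 0, z), fs = fs,
                      d1 = cbind(0, 0, rep(30, n)), port = port)
  dm <- depth_metrics(ks)
  expect_equal(dm$DPL, 30, tolerance = 1e-9)
  expect_equal(dm$DV, 30, tolerance = 1e-9)
  # orthogonal (circular at constant radius): DPL negligible vs PL
  th <- seq(0, pi, length.out = 500)
  pos <- cbind(40 * cos(th), 40 * sin(th), 0)
  ksc <- manual_series(pos, port = port)
  expect_lt(depth_metrics(ksc)$DPL, 0.01 * path_length(ksc))
  # random walks never exceed the full path length
  set.seed(5)
  for (i in 1:200) {
    steps <- matrix(rnorm(60), 20, 3)
    pos <- apply(steps, 2, cumsum) + 50
    ksw <- manual_series(pos, port = c(0, -10, 0))
    expect_lte(depth_metrics(ksw)$DPL, path_length(ksw) + 1e-9)
  }
})

test_that("gripper cycle counting agrees with a brute-force hysteresis automaton", {
  fs <- 50
  k <- 4
  sq <- rep(c(rep(0.6, 10), rep(0.05, 10)), k)
  tr <- make_track(matrix(0, length(sq), 3), fs = fs, gripper = sq)
  expect_equal(opening_closing_count(tr, 0.35, 0.15), k)
  expect_equal(opening_closing_count(make_track(matrix(0, 50, 3)), 0.35, 0.15), 0)
  # jitter below the hysteresis band cannot create or destroy cycles
  set.seed(8)
  for (i in 1:25) {
    base <- rep(c(rep(0.6, 12), rep(0.05, 12)), 5)
    noisy <- pmax(base + rnorm(length(base), 0, 0.04), 0)
    trj <- make_track(matrix(0, length(noisy), 3), fs = fs, gripper = noisy)
    expect_equal(opening_closing_count(trj, 0.35, 0.15),
                 brute_noc(noisy, 0.35, 0.15))
    expect_equal(opening_closing_count(trj, 0.35, 0.15), 5)
  }
  expect_error(opening_closing_count(tr, 0.15, 0.35), "hysteresis|exceed")
})

test_that("gripper rotation average is the in-view time average", {
  tr <- make_track(matrix(0, 40, 3), gripper = rep(0.3, 40))
  expect_equal(gripper_rotation_average(tr), 0.3)
  # triangular wave between 0 and 0.4 averages to 0.2 (direct-mean oracle)
  up <- seq(0, 0.4, length.out = 41)
  tri <- rep(c(up[-41], rev(up)[-41]), 10)
  trt <- make_track(matrix(0, length(tri), 3), gripper = tri)
  expect_equal(gripper_rotation_average(trt), mean(tri), tolerance = 1e-12)
  expect_equal(gripper_rotation_average(trt), 0.2, tolerance = 1e-3)
  # never in view: missing
  trn <- make_track(matrix(0, 10, 3), in_view = rep(FALSE, 10))
  expect_true(is.na(gripper_rotation_average(trn)))
})

test_that("angular lengths use shortest-arc wrapping", {
  n <- 90
  att <- cbind(seq(0, pi / 2, length.out = n), rep(0.3, n), rep(-0.2, n))
  tr <- make_track(matrix(0, n, 3), attitude = att)
  am <- attitude_metrics(tr)
  expect_equal(am$AL_Roll, pi / 2, tolerance = 1e-9)
  expect_equal(am$AL_PitchYaw, 0, tolerance = 1e-12)
  expect_equal(am$Pitch, 0.3, tolerance = 1e-9)
  # constant attitude: zero angular length
  am0 <- attitude_metrics(make_track(matrix(0, 20, 3)))
  expect_equal(am0$AL_Roll, 0)
  expect_equal(am0$AL_PitchYaw, 0)
  # a sweep crossing the +/- pi seam equals the unwrap-then-sum oracle
  sweep_raw <- seq(2.8, 2 * pi + 0.6, length.out = 120)  # passes through pi
  roll <- lapgoals:::wrap_angle(sweep_raw)
  att2 <- cbind(roll, 0, 0)
  am2 <- attitude_metrics(make_track(matrix(0, 120, 3), attitude = att2))
  oracle <- sum(abs(diff(brute_unwrap(roll))))
  expect_equal(am2$AL_Roll, oracle, tolerance = 1e-9)
  expect_equal(am2$AL_Roll, diff(range(sweep_raw)), tolerance = 1e-9)
})

test_that("working area equals hull volumes from an independent implementation", {
  # degenerate clouds
  expect_equal(working_area(manual_series(matrix(c(1, 2, 3), 1, 3))), 0)
  expect_equal(working_area(manual_series(cbind(runif(30), runif(30), 0))), 0)
  # 10 mm cube corners
  cube <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  expect_equal(working_area(manual_series(cube)), 1000, tolerance = 1e-6)
  # random clouds vs scipy/qhull
  set.seed(13)
  for (n in c(20, 400)) {
    P <- matrix(rnorm(n * 3, sd = 15), n, 3)
    mine <- convex_hull_volume(P)
    ref <- scipy_hull_volume(P)
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("distance zones follow the point-to-polyline distance oracle", {
  G <- cbind(seq(-50, 50, length.out = 11), 0, 0)
  # all samples 10 mm above the line
  pos <- cbind(seq(-40, 40, length.out = 50), 0, 10)
  zd <- zone_distribution(manual_series(pos), G)
  expect_equal(unname(zd["Close"]), 1)
  # half at 10 mm, half at 30 mm
  pos2 <- rbind(cbind(0, 0, rep(10, 25)), cbind(0, 0, rep(30, 25)))
  zd2 <- zone_distribution(manual_series(pos2), G)
  expect_equal(unname(zd2[c("Close", "Near")]), c(0.5, 0.5))
  # random points: bands equal brute-force distance classification
  set.seed(21)
  P <- cbind(runif(120, -80, 80), runif(120, -40, 40), runif(120, 0, 90))
  zd3 <- zone_distribution(manual_series(P), G, c(20, 50))
  d <- apply(P, 1, brute_polyline_dist, G = G)
  expect_equal(unname(zd3), unname(c(mean(d < 20), mean(d >= 20 & d < 50),
                                     mean(d >= 50))), tolerance = 1e-12)
  expect_equal(sum(zd3), 1)
  # no geometry: flagged missing, no error
  expect_true(all(is.na(zone_distribution(manual_series(P), NULL))))
})

test_that("average inserting time is the mean insertion-to-movement delay", {
  fs <- 100
  episode <- function(gap_s, dwell_s, move_s) {
    n_gap <- gap_s * fs; n_dwell <- dwell_s * fs; n_move <- move_s * fs
    list(iv = c(rep(FALSE, n_gap), rep(TRUE, n_dwell + n_move)),
         sp = c(rep(0, n_gap + n_dwell), rep(30, n_move)))
  }
  build <- function(dwells) {
    parts <- lapply(dwells, function(d) episode(1, d, 2))
    iv <- unlist(lapply(parts, `[[`, "iv"))
    sp <- unlist(lapply(parts, `[[`, "sp"))
    manual_series(matrix(0, length(iv), 3), fs = fs,
                  d1 = cbind(sp, 0, 0), valid = iv, in_view = iv)
  }
  expect_equal(inserting_time(build(5), idle_threshold = 5), 5, tolerance = 1.5 / fs)
  expect_equal(inserting_time(build(c(2, 4, 6)), idle_threshold = 5), 4,
               tolerance = 1.5 / fs)
  # a track that is always in view was never inserted: missing
  always <- manual_series(matrix(0, 50, 3))
  expect_true(is.na(inserting_time(always)))
})

test_that("bimanual metrics match their direct-definition oracle", {
  fs <- 100; n <- 400
  set.seed(31)
  base <- apply(matrix(rnorm(n * 3), n, 3), 2, cumsum)
  a <- manual_series(base, fs = fs, d1 = matrix(rnorm(n * 3, 0, 20), n, 3),
                     gripper = pmax(0, 0.3 + cumsum(rnorm(n, 0, 0.05))))
  b <- manual_series(base + matrix(rep(c(40, 0, 0), each = n), n, 3), fs = fs,
                     d1 = matrix(rnorm(n * 3, 0, 20), n, 3),
                     gripper = pmax(0, 0.3 + cumsum(rnorm(n, 0, 0.05))))
  bm <- bimanual_metrics(a, b, 0.35, 0.15, idle_threshold = 5, event_window = 0.25)
  # identical paths offset by a constant 40 mm
  expect_equal(bm$ADB, 40, tolerance = 1e-9)
  expect_equal(bm$RPLB, 1, tolerance = 1e-9)
  # direct-summation oracles
  d_ab <- sqrt(rowSums((a$position - b$position)^2))
  expect_equal(bm$ADB, mean(d_ab), tolerance = 1e-9)
  sp_a <- sqrt(rowSums(a$deriv1^2)); sp_b <- sqrt(rowSums(b$deriv1^2))
  expect_equal(bm$BD, mean(sp_a > 5 & sp_b > 5), tolerance = 1e-9)
  noc_a <- brute_noc(a$gripper_angle, 0.35, 0.15)
  noc_b <- brute_noc(b$gripper_angle, 0.35, 0.15)
  rob_oracle <- if (noc_a == 0 && noc_b == 0) 1 else
    min(noc_a, noc_b) / max(noc_a, noc_b)
  expect_equal(bm$ROB, rob_oracle)
  # ADBO oracle: samples within the window of any gripper event
  ev <- function(s) lapgoals:::gripper_events(s$gripper_angle, s$in_view, 0.35, 0.15)$events
  evs <- c(ev(a), ev(b))
  near <- rep(FALSE, n)
  for (e in evs) near <- near | abs(a$timestamps - a$timestamps[e]) <= 0.25
  if (any(near)) expect_equal(bm$ADBO, mean(d_ab[near]), tolerance = 1e-9)
  # one instrument stationary: BD = 0
  still <- manual_series(base, fs = fs)  # zero derivatives
  expect_equal(bimanual_metrics(a, still)$BD, 0)
  # no overlap: all missing
  a2 <- manual_series(base, valid = c(rep(TRUE, 200), rep(FALSE, 200)))
  b2 <- manual_series(base, valid = c(rep(FALSE, 200), rep(TRUE, 200)))
  expect_true(all(is.na(unlist(bimanual_metrics(a2, b2)))))
})

test_that("feature extraction follows the naming registry and is deterministic", {
  st <- generate_study(sim_config(n_sessions = 1, seed = 301))
  s <- st$sessions[[1]]
  v1 <- extract_features(s)
  v2 <- extract_features(s)
  expect_identical(v1, v2)
  expect_true(all(c("G-PL", "S-V", "C-AIT", "Time", "BD", "G-Close") %in% names(v1)))
  man <- metric_manifest("task1", has_geometry = TRUE)
  expect_identical(names(v1), man$name)
  # task3 manifest: two needle holders, no clip metrics
  man3 <- metric_manifest("task3", has_geometry = TRUE)
  expect_true(all(grepl("^(R|L)-", setdiff(man3$name, lapgoals:::GENERAL_METRICS))))
  st3 <- generate_study(sim_config(n_sessions = 1, task = "task3", seed = 302))
  v3 <- extract_features(st3$sessions[[1]])
  expect_identical(names(v3), man3$name)
})

test_that("metrics are invariant to rigid motions of the whole session", {
  st <- generate_study(sim_config(n_sessions = 1, seed = 77))
  s <- st$sessions[[1]]
  th <- 0.7; shift <- c(35, -20, 12)
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s2 <- s
  for (id in names(s2$tracks)) {
    s2$tracks[[id]]$tip_position <- s$tracks[[id]]$tip_position %*% t(R) +
      matrix(rep(shift, each = nrow(s$tracks[[id]]$tip_position)), ncol = 3)
    s2$tracks[[id]]$port_position <- as.vector(R %*% s$tracks[[id]]$port_position) + shift
  }
  s2$target_geometry <- s$target_geometry %*% t(R) +
    matrix(rep(shift, each = nrow(s$target_geometry)), ncol = 3)
  v1 <- extract_features(s)
  v2 <- extract_features(s2)
  invariant <- grep("-(PL|V|A|J|NOC|WA|AL-Roll|AL-PitchYaw)$|^(Time|ADB|ROB|RPLB|BD)$",
                    names(v1), value = TRUE)
  for (m in invariant) {
    expect_equal(v2[[m]], v1[[m]], tolerance = 1e-6, label = m)
  }
})

test_that("playing a trajectory at double speed rescales the metrics lawfully", {
  st <- generate_study(sim_config(n_sessions = 1, seed = 55))
  tr <- st$sessions[[1]]$tracks$grasper
  fast <- tr
  fast$sample_rate <- tr$sample_rate * 2
  fast$timestamps <- tr$timestamps / 2
  k1 <- savgol_smooth(tr, 21, 3)
  k2 <- savgol_smooth(fast, 21, 3)
  s1 <- speed_metrics(k1); s2 <- speed_metrics(k2)
  expect_equal(s2$V / s1$V, 2, tolerance = 0.01)
  expect_equal(s2$A / s1$A, 4, tolerance = 0.01)
  expect_equal(s2$J / s1$J, 8, tolerance = 0.01)
  expect_equal(path_length(k2) / path_length(k1), 1, tolerance = 0.01)
  t1 <- diff(range(k1$timestamps[k1$valid_mask]))
  t2 <- diff(range(k2$timestamps[k2$valid_mask]))
  expect_equal(t2 / t1, 0.5, tolerance = 0.01)
})
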