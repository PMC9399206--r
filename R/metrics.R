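# ---------------------------------------------------------------------------
# Kinematic metric catalogue.
#
# Per-instrument metrics are computed from the Savitzky-Golay smoothed
# series; metric names follow the instrument-prefix scheme G/S/C/R/L
# ("G-PL", "R-DV", ...). General metrics (Time, BD, ROB, RPLB, ADB,
# ADBO) have no prefix. All operational definitions are centralised here
# and flagged `reconstructed` in the manifest where the published source
# gives only the abbreviation expansion.
# ---------------------------------------------------------------------------

adjacent_valid_pairs <- function(mask) {
  n <- length(mask)
  if (n < 2L) return(integer(0))
  which(mask[-n] & mask[-1L])
}

speed_norm <- function(series) sqrt(rowSums(series$deriv1^2))

#' Path length of the smoothed tip trajectory (PL)
#'
#' Sum of Euclidean distances between consecutive valid smoothed
#' positions (index-adjacent pairs, so untracked gaps contribute
#' nothing).
#'
#' @param series A [savgol_smooth()] result.
#' @return Path length in mm (0 with fewer than 2 valid samples).
#' @export
path_length <- function(series) {
  i <- adjacent_valid_pairs(series$valid_mask)
  if (length(i) == 0L) return(0)
  steps <- series$position[i + 1L, , drop = FALSE] - series$position[i, , drop = FALSE]
  sum(sqrt(rowSums(steps^2)))
}

#' Average velocity, acceleration, jerk and velocity range (V, A, J, VR)
#'
#' Time-averages of the Euclidean norms of the 1st-3rd smoothed
#' derivatives over valid samples; `VR` is max - min speed.
#'
#' @param series A [savgol_smooth()] result.
#' @return List `V` (mm/s), `A` (mm/s^2), `J` (mm/s^3), `VR` (mm/s); all
#'   `NA` when fewer than 2 valid samples.
#' @export
speed_metrics <- function(series) {
  v <- series$valid_mask
  if (sum(v) < 2L) return(list(V = NA_real_, A = NA_real_, J = NA_real_, VR = NA_real_))
  sp <- speed_norm(series)[v]
  list(
    V = mean(sp),
    A = mean(sqrt(rowSums(series$deriv2[v, , drop = FALSE]^2))),
    J = mean(sqrt(rowSums(series$deriv3[v, , drop = FALSE]^2))),
    VR = max(sp) - min(sp)
  )
}

#' Distribution of tip speed over velocity bands
#'
#' Fraction of valid samples whose speed falls in each half-open band
#' `[0,t1), [t1,t2), [t2,t3), [t3,t4), [t4,Inf)`; sums to 1.
#'
#' @param series A [savgol_smooth()] result.
#' @param thresholds Four strictly ascending speeds (mm/s).
#' @return Named numeric: `Idle`, `Low`, `Middle`, `High`, `Very_high`.
#' @export
velocity_distribution <- function(series, thresholds = c(5, 25, 75, 150)) {
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0)) {
    stop("configuration error: thresholds must be 4 strictly ascending speeds",
         call. = FALSE)
  }
  v <- series$valid_mask
  out <- c(Idle = NA_real_, Low = NA_real_, Middle = NA_real_,
           High = NA_real_, Very_high = NA_real_)
  if (!any(v)) return(out)
  sp <- speed_norm(series)[v]
  band <- findInterval(sp, thresholds) + 1L  # 1..5
  out[] <- tabulate(band, 5L) / length(sp)
  out
}

#' Depth path length and depth velocity (DPL, DV)
#'
#' Motion projected onto the instantaneous port-to-tip axis (the
#' physical sheath axis imposed by the trocar). DPL sums the absolute
#' projected displacement over adjacent valid pairs; DV is the
#' time-average absolute projected velocity. Samples coincident with the
#' port are excluded.
#'
#' @param series A [savgol_smooth()] result.
#' @param port_position Port location (mm); defaults to the track's.
#' @return List `DPL` (mm), `DV` (mm/s); `NA` with no usable samples.
#' @export
depth_metrics <- function(series, port_position = series$port_position) {
  v <- series$valid_mask
  rel <- sweep(series$position, 2, port_position)
  r <- sqrt(rowSums(rel^2))
  ok <- v & r > 1e-9
  if (sum(ok) < 2L) return(list(DPL = NA_real_, DV = NA_real_))
  axis <- rel / pmax(r, 1e-12)
  i <- which(ok[-length(ok)] & ok[-1L])
  dpl <- if (length(i) == 0L) 0 else {
    steps <- series$position[i + 1L, , drop = FALSE] - series$position[i, , drop = FALSE]
    sum(abs(rowSums(steps * axis[i, , drop = FALSE])))
  }
  dv <- mean(abs(rowSums(series$deriv1[ok, , drop = FALSE] * axis[ok, , drop = FALSE])))
  list(DPL = dpl, DV = dv)
}

# hysteresis automaton over the gripper angle; returns completed
# open->close cycle count and the sample indices of open/close events
gripper_events <- function(gripper_angle, in_view, open_thresh, close_thresh) {
  if (open_thresh <= close_thresh) {
    stop("configuration error: open threshold must exceed close threshold",
         call. = FALSE)
  }
  idx <- which(in_view)
  state_open <- FALSE
  count <- 0L
  events <- integer(0)
  for (i in idx) {
    a <- gripper_angle[i]
    if (!state_open && a >= open_thresh) {
      state_open <- TRUE
      events <- c(events, i)
    } else if (state_open && a <= close_thresh) {
      state_open <- FALSE
      count <- count + 1L
      events <- c(events, i)
    }
  }
  list(count = count, events = events)
}

#' Number of gripper opening/closing operations (NOC)
#'
#' Counts complete open-to-close cycles of the gripper angle under a
#' two-threshold hysteresis (noise smaller than the hysteresis band
#' cannot create spurious cycles).
#'
#' @param track An [instrument_track()] (or kinematic series).
#' @param open_thresh,close_thresh Hysteresis thresholds (rad),
#'   `open_thresh > close_thresh`.
#' @return Integer count >= 0.
#' @export
opening_closing_count <- function(track, open_thresh = 0.35, close_thresh = 0.15) {
  gripper_events(track$gripper_angle, track$in_view, open_thresh, close_thresh)$count
}

#' Average gripper rotation angle (AGRA)
#'
#' Time-average of the gripper opening angle over in-view samples.
#'
#' @param track An [instrument_track()] (or kinematic series).
#' @return Mean angle in rad; `NA` if never in view.
#' @export
gripper_rotation_average <- function(track) {
  v <- track$in_view
  if (!any(v)) return(NA_real_)
  mean(track$gripper_angle[v])
}

#' Attitude means and angular lengths (Roll, Pitch, Yaw, AL-Roll, AL-PitchYaw)
#'
#' Circular means of each attitude angle, plus angular path lengths:
#' `AL_Roll` sums absolute shortest-arc roll increments; `AL_PitchYaw`
#' sums `sqrt(dpitch^2 + dyaw^2)` with the same wrapping.
#'
#' @param track An [instrument_track()] (or kinematic series).
#' @return List `Roll`, `Pitch`, `Yaw`, `AL_Roll`, `AL_PitchYaw` (rad).
#' @export
attitude_metrics <- function(track) {
  v <- track$in_view
  if (!any(v)) {
    return(list(Roll = NA_real_, Pitch = NA_real_, Yaw = NA_real_,
                AL_Roll = NA_real_, AL_PitchYaw = NA_real_))
  }
  att <- track$attitude
  cmean <- function(a) atan2(mean(sin(a)), mean(cos(a)))
  i <- adjacent_valid_pairs(v)
  d <- if (length(i) == 0L) matrix(0, 0, 3) else
    wrap_angle(att[i + 1L, , drop = FALSE] - att[i, , drop = FALSE])
  list(
    Roll = cmean(att[v, 1]),
    Pitch = cmean(att[v, 2]),
    Yaw = cmean(att[v, 3]),
    AL_Roll = sum(abs(d[, 1])),
    AL_PitchYaw = sum(sqrt(d[, 2]^2 + d[, 3]^2))
  )
}

#' Working area (WA): convex-hull volume of tip positions
#'
#' Spatial extent of the task, measured as the volume of the convex hull
#' of all valid smoothed tip positions. Degenerate clouds (fewer than 4
#' non-coplanar points) have volume 0.
#'
#' @param series A [savgol_smooth()] result.
#' @return Volume in mm^3.
#' @export
working_area <- function(series) {
  convex_hull_volume(series$position[series$valid_mask, , drop = FALSE])
}

# minimum distance from each point (rows of P) to a polyline/point set
point_geometry_distance <- function(P, geometry) {
  G <- as.matrix(geometry)
  n <- nrow(P)
  best <- rep(Inf, n)
  if (nrow(G) == 1L) {
    return(sqrt(rowSums(sweep(P, 2, G[1, ])^2)))
  }
  for (s in seq_len(nrow(G) - 1L)) {
    a <- G[s, ]; b <- G[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel <- sweep(P, 2, a)
    t <- if (len2 == 0) rep(0, n) else pmin(pmax(rel %*% ab / len2, 0), 1)
    proj <- rel - outer(as.vector(t), ab)
    best <- pmin(best, sqrt(rowSums(proj^2)))
  }
  best
}

#' Distribution of tip distance to the target structure (Close, Near, Far)
#'
#' Fraction of valid samples by minimum distance to the target polyline:
#' `Close < b1 <= Near < b2 <= Far` (defaults 20 mm and 50 mm).
#'
#' @param series A [savgol_smooth()] result.
#' @param target_geometry `m x 3` matrix of polyline vertices (mm), or
#'   `NULL` (all three fractions are then flagged missing).
#' @param boundaries Two ascending distances (mm).
#' @return Named numeric: `Close`, `Near`, `Far`; sums to 1.
#' @export
zone_distribution <- function(series, target_geometry, boundaries = c(20, 50)) {
  out <- c(Close = NA_real_, Near = NA_real_, Far = NA_real_)
  if (is.null(target_geometry)) return(out)
  if (length(boundaries) != 2L || diff(boundaries) <= 0) {
    stop("configuration error: boundaries must be 2 ascending distances",
         call. = FALSE)
  }
  v <- series$valid_mask
  if (!any(v)) return(out)
  d <- point_geometry_distance(series$position[v, , drop = FALSE], target_geometry)
  band <- findInterval(d, boundaries) + 1L
  out[] <- tabulate(band, 3L) / length(d)
  out
}

#' Average inserting time (AIT)
#'
#' Mean duration of insertion episodes: from each out-of-view to in-view
#' rising edge until the first valid sample whose speed exceeds the idle
#' threshold (capped at the end of the in-view run). Sessions without a
#' rising edge have no episode and the metric is missing.
#'
#' @param series A [savgol_smooth()] result.
#' @param idle_threshold Speed (mm/s) that ends the insertion phase.
#' @return Mean episode duration (s), or `NA` with zero episodes.
#' @export
inserting_time <- function(series, idle_threshold = 5) {
  iv <- series$in_view
  n <- length(iv)
  rising <- which(iv & !c(FALSE, iv[-n]))
  rising <- rising[rising > 1L]  # a track that starts in view was never inserted
  if (length(rising) == 0L) return(NA_real_)
  sp <- speed_norm(series)
  durations <- vapply(rising, function(r0) {
    run_end <- r0
    while (run_end < n && iv[run_end + 1L]) run_end <- run_end + 1L
    seg <- r0:run_end
    moving <- seg[series$valid_mask[seg] & sp[seg] > idle_threshold]
    stop_at <- if (length(moving) > 0) moving[1] else run_end
    series$timestamps[stop_at] - series$timestamps[r0]
  }, numeric(1))
  mean(durations)
}

#' Bimanual coordination metrics (BD, ROB, RPLB, ADB, ADBO)
#'
#' Over the samples where both instruments are valid: `ADB` is the mean
#' tip-to-tip distance; `ADBO` the same restricted to samples within
#' `event_window` s of either instrument's gripper opening/closing
#' events; `ROB` and `RPLB` are order-invariant min/max ratios of the
#' two NOC counts (1 if both 0) and path lengths; `BD` is the fraction
#' of overlapping time during which both tips move faster than the idle
#' threshold.
#'
#' @param series_a,series_b [savgol_smooth()] results with overlapping
#'   valid samples on a common clock.
#' @param open_thresh,close_thresh Gripper hysteresis thresholds (rad).
#' @param idle_threshold Idle speed (mm/s) for BD.
#' @param event_window Half-width (s) of the ADBO event window.
#' @return List `BD`, `ROB`, `RPLB`, `ADB`, `ADBO`; all `NA` without
#'   temporal overlap, `ADBO` `NA` without gripper events.
#' @export
bimanual_metrics <- function(series_a, series_b,
                             open_thresh = 0.35, close_thresh = 0.15,
                             idle_threshold = 5, event_window = 0.25) {
  n <- min(length(series_a$valid_mask), length(series_b$valid_mask))
  both <- series_a$valid_mask[seq_len(n)] & series_b$valid_mask[seq_len(n)]
  if (!any(both)) {
    return(list(BD = NA_real_, ROB = NA_real_, RPLB = NA_real_,
                ADB = NA_real_, ADBO = NA_real_))
  }
  dist_ab <- sqrt(rowSums((series_a$position[seq_len(n), , drop = FALSE] -
                           series_b$position[seq_len(n), , drop = FALSE])^2))
  adb <- mean(dist_ab[both])

  ev_a <- gripper_events(series_a$gripper_angle, series_a$in_view, open_thresh, close_thresh)
  ev_b <- gripper_events(series_b$gripper_angle, series_b$in_view, open_thresh, close_thresh)
  ev_idx <- c(ev_a$events, ev_b$events)
  ev_idx <- ev_idx[ev_idx <= n]
  adbo <- if (length(ev_idx) == 0L) NA_real_ else {
    t_all <- series_a$timestamps[seq_len(n)]
    near_event <- rep(FALSE, n)
    for (e in ev_idx) {
      near_event <- near_event | abs(t_all - t_all[e]) <= event_window
    }
    sel <- both & near_event
    if (any(sel)) mean(dist_ab[sel]) else NA_real_
  }

  ratio <- function(a, b) {
    if (a == 0 && b == 0) return(1)
    min(a, b) / max(a, b)
  }
  pl_a <- path_length(series_a)
  pl_b <- path_length(series_b)
  sp_a <- speed_norm(series_a)[seq_len(n)]
  sp_b <- speed_norm(series_b)[seq_len(n)]
  list(
    BD = mean(sp_a[both] > idle_threshold & sp_b[both] > idle_threshold),
    ROB = ratio(ev_a$count, ev_b$count),
    RPLB = if (max(pl_a, pl_b) == 0) 1 else min(pl_a, pl_b) / max(pl_a, pl_b),
    ADB = adb,
    ADBO = adbo
  )
}

# per-instrument metric suffixes, in manifest order
INSTRUMENT_SUFFIXES <- c("PL", "V", "A", "J", "VR",
                         "Idle", "Low", "Middle", "High", "Very_high",
                         "DPL", "DV", "NOC", "AGRA",
                         "Roll", "Pitch", "Yaw", "AL-Roll", "AL-PitchYaw",
                         "WA", "AIT")
ZONE_SUFFIXES <- c("Close", "Near", "Far")
GENERAL_METRICS <- c("Time", "BD", "ROB", "RPLB", "ADB", "ADBO")

bimanual_pair <- function(task) {
  if (task == "task3") c("right_needle_holder", "left_needle_holder")
  else c("grasper", "scissors")
}

#' Metric manifest for a task
#'
#' Enumerates every metric name the feature extractor produces for a
#' task, with instrument, units and a `reconstructed` flag marking
#' definitions rebuilt from abbreviation expansions rather than a
#' published formula.
#'
#' @param task `"task1"` or `"task3"`.
#' @param instruments Instrument ids present; defaults to the task's
#'   standard set.
#' @param has_geometry Include the Close/Near/Far zone metrics.
#' @return data.frame with columns `name`, `instrument`, `suffix`,
#'   `units`, `reconstructed`.
#' @export
metric_manifest <- function(task,
                            instruments = NULL,
                            has_geometry = TRUE) {
  task <- match.arg(task, c("task1", "task3"))
  if (is.null(instruments)) {
    instruments <- if (task == "task3") {
      c("right_needle_holder", "left_needle_holder")
    } else {
      c("grasper", "scissors", "clip_applier")
    }
  }
  units <- c(PL = "mm", V = "mm/s", A = "mm/s^2", J = "mm/s^3", VR = "mm/s",
             Idle = "fraction", Low = "fraction", Middle = "fraction",
             High = "fraction", Very_high = "fraction",
             DPL = "mm", DV = "mm/s", NOC = "count", AGRA = "rad",
             Roll = "rad", Pitch = "rad", Yaw = "rad",
             `AL-Roll` = "rad", `AL-PitchYaw` = "rad",
             WA = "mm^3", AIT = "s",
             Close = "fraction", Near = "fraction", Far = "fraction",
             Time = "s", BD = "fraction", ROB = "ratio", RPLB = "ratio",
             ADB = "mm", ADBO = "mm")
  exact <- c("PL", "V", "A", "J", "VR", "NOC", "AGRA", "Time")  # direct expansions
  suffixes <- c(INSTRUMENT_SUFFIXES, if (has_geometry) ZONE_SUFFIXES)
  rows <- do.call(rbind, lapply(instruments, function(id) {
    data.frame(
      name = paste0(INSTRUMENT_PREFIX[[id]], "-", suffixes),
      instrument = id, suffix = suffixes,
      units = unname(units[suffixes]),
      reconstructed = !(suffixes %in% exact),
      stringsAsFactors = FALSE
    )
  }))
  general <- data.frame(
    name = GENERAL_METRICS, instrument = "general", suffix = GENERAL_METRICS,
    units = unname(units[GENERAL_METRICS]),
    reconstructed = !(GENERAL_METRICS %in% exact),
    stringsAsFactors = FALSE
  )
  out <- rbind(general, rows)
  rownames(out) <- NULL
  out
}

#' Extract the full metric vector for one session
#'
#' Runs [savgol_smooth()] on every track, then every applicable metric:
#' per-instrument metrics under their prefix, the task duration `Time`
#' (first to last valid sample across instruments) and the bimanual
#' metrics for the task's instrument pair. Missing optional inputs
#' (geometry, insertions, overlap) yield `NA` values, never errors.
#' Deterministic.
#'
#' @param session A [session_record()].
#' @param config A [pipeline_config()].
#' @return Named numeric vector of metrics with attributes `session_id`
#'   and `task`.
#' @export
extract_features <- function(session, config = pipeline_config()) {
  validate_session_record(session)
  series <- lapply(session$tracks, function(tr) {
    if (length(tr$timestamps) < config$sg_window) {
      # too short to support the filter: every sample masked, metrics
      # degrade to missing/zero instead of failing the whole session
      n <- length(tr$timestamps)
      return(structure(list(
        instrument_id = tr$instrument_id, sample_rate = tr$sample_rate,
        timestamps = tr$timestamps,
        position = matrix(NA_real_, n, 3),
        deriv1 = matrix(NA_real_, n, 3), deriv2 = matrix(NA_real_, n, 3),
        deriv3 = matrix(NA_real_, n, 3),
        valid_mask = rep(FALSE, n), port_position = tr$port_position,
        attitude = tr$attitude, gripper_angle = tr$gripper_angle,
        in_view = tr$in_view
      ), class = "kinematic_series"))
    }
    savgol_smooth(tr, config$sg_window, config$sg_polyorder)
  })
  has_geom <- !is.null(session$target_geometry)
  vals <- c()
  for (id in names(series)) {
    s <- series[[id]]
    pre <- INSTRUMENT_PREFIX[[id]]
    sm <- speed_metrics(s)
    vd <- velocity_distribution(s, config$velocity_thresholds)
    dm <- depth_metrics(s)
    am <- attitude_metrics(s)
    zd <- zone_distribution(s, session$target_geometry, config$zone_boundaries)
    v <- c(
      PL = path_length(s), V = sm$V, A = sm$A, J = sm$J, VR = sm$VR,
      vd,
      DPL = dm$DPL, DV = dm$DV,
      NOC = opening_closing_count(s, config$gripper_open, config$gripper_close),
      AGRA = gripper_rotation_average(s),
      Roll = am$Roll, Pitch = am$Pitch, Yaw = am$Yaw,
      `AL-Roll` = am$AL_Roll, `AL-PitchYaw` = am$AL_PitchYaw,
      WA = working_area(s),
      AIT = inserting_time(s, config$idle_threshold),
      if (has_geom) zd
    )
    names(v) <- paste0(pre, "-", names(v))
    vals <- c(vals, v)
  }
  t_valid <- unlist(lapply(series, function(s) s$timestamps[s$valid_mask]))
  time_metric <- if (length(t_valid) == 0L) NA_real_ else max(t_valid) - min(t_valid)
  pair <- bimanual_pair(session$task)
  bm <- if (all(pair %in% names(series))) {
    bimanual_metrics(series[[pair[1]]], series[[pair[2]]],
                     open_thresh = config$gripper_open,
                     close_thresh = config$gripper_close,
                     idle_threshold = config$idle_threshold,
                     event_window = config$adbo_window)
  } else {
    list(BD = NA_real_, ROB = NA_real_, RPLB = NA_real_, ADB = NA_real_, ADBO = NA_real_)
  }
  general <- c(Time = time_metric, BD = bm$BD, ROB = bm$ROB,
               RPLB = bm$RPLB, ADB = bm$ADB, ADBO = bm$ADBO)
  out <- c(general, vals)
  manifest <- metric_manifest(session$task, instruments = names(session$tracks),
                              has_geometry = has_geom)
  out <- out[manifest$name]
  names(out) <- manifest$name
  attr(out, "session_id") <- session$session_id
  attr(out, "task") <- session$task
  out
}

#' Assemble a feature table from many sessions
#'
#' @param sessions List of [session_record()]s (same task).
#' @param config A [pipeline_config()].
#' @return data.frame: `session_id`, `task`, one column per metric
#'   (missing values as `NA`).
#' @export
extract_feature_table <- function(sessions, config = pipeline_config()) {
  rows <- lapply(sessions, function(s) {
    v <- extract_features(s, config)
    cbind(data.frame(session_id = attr(v, "session_id"), task = attr(v, "task"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(nm, names(r))) r[[m]] <- NA_real_
    r[nm]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table and its metric manifest
#'
#' @param features Output of [extract_feature_table()].
#' @param path Output CSV path; the manifest is written alongside as
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  task <- features$task[1]
  manifest <- metric_manifest(task,
                              has_geometry = any(grepl("-Close$", names(features))))
  manifest <- manifest[manifest$name %in% names(features), ]
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame with metric columns.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
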