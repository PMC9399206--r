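# Recognised instrument labels and their single-letter metric prefixes
# (grasping forceps, scissors, clip applier, right/left needle holder).
INSTRUMENT_PREFIX <- c(
  grasper = "G",
  scissors = "S",
  clip_applier = "C",
  right_needle_holder = "R",
  left_needle_holder = "L"
)

GOALS_ITEMS <- c("depth_perception", "bimanual_dexterity", "efficiency",
                 "tissue_handling", "autonomy")

task_items <- function(task) {
  if (task == "task3") setdiff(GOALS_ITEMS, "tissue_handling") else GOALS_ITEMS
}

task_total_range <- function(task) {
  if (task == "task3") c(4, 20) else c(5, 25)
}

wrap_angle <- function(a) {
  # map to (-pi, pi]
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Construct an instrument-tip track
#'
#' One uniformly sampled time series for a single instrument in a single
#' training session: 3-D tip position, attitude angles, gripper opening
#' angle and an in-view flag, plus the trocar (port) position through
#' which the instrument enters the body wall.
#'
#' @param instrument_id One of `grasper`, `scissors`, `clip_applier`,
#'   `right_needle_holder`, `left_needle_holder`.
#' @param sample_rate Sampling rate in Hz.
#' @param timestamps Strictly increasing times (s) with constant step
#'   `1/sample_rate` (tolerance 1e-6 s).
#' @param tip_position Numeric matrix `n x 3`, millimetres.
#' @param attitude Numeric matrix `n x 3` of (roll, pitch, yaw), radians
#'   in `(-pi, pi]`.
#' @param gripper_angle Non-negative opening angle (rad), length `n`.
#' @param in_view Logical length `n`; `TRUE` where the instrument is
#'   inserted and tracked. Coordinates may be arbitrary where `FALSE`.
#' @param port_position Numeric length-3 port location, millimetres.
#' @return An object of class `instrument_track`.
#' @export
instrument_track <- function(instrument_id, sample_rate, timestamps,
                             tip_position, attitude, gripper_angle,
                             in_view, port_position) {
  tr <- structure(list(
    instrument_id = as.character(instrument_id),
    sample_rate = as.numeric(sample_rate),
    timestamps = as.numeric(timestamps),
    tip_position = as.matrix(tip_position),
    attitude = as.matrix(attitude),
    gripper_angle = as.numeric(gripper_angle),
    in_view = as.logical(in_view),
    port_position = as.numeric(port_position)
  ), class = "instrument_track")
  validate_instrument_track(tr)
}

#' Validate an instrument track against its invariants
#'
#' @param tr An `instrument_track`.
#' @param where Label used in error messages (e.g. a file name).
#' @return `tr`, invisibly usable; errors on violation.
#' @export
validate_instrument_track <- function(tr, where = tr$instrument_id) {
  if (!tr$instrument_id %in% names(INSTRUMENT_PREFIX)) {
    stop("format error [", where, "]: unknown instrument label '",
         tr$instrument_id, "'", call. = FALSE)
  }
  n <- length(tr$timestamps)
  if (n < 1L) stop("format error [", where, "]: empty track", call. = FALSE)
  lens_ok <- nrow(tr$tip_position) == n && nrow(tr$attitude) == n &&
    length(tr$gripper_angle) == n && length(tr$in_view) == n
  if (!lens_ok || ncol(tr$tip_position) != 3L || ncol(tr$attitude) != 3L) {
    stop("format error [", where, "]: channel lengths disagree", call. = FALSE)
  }
  if (n > 1L) {
    dt <- diff(tr$timestamps)
    if (any(dt <= 0)) {
      stop("format error [", where, "]: timestamps not strictly increasing (row ",
           which(dt <= 0)[1] + 1L, ")", call. = FALSE)
    }
    if (any(abs(dt - 1 / tr$sample_rate) > 1e-6)) {
      stop("format error [", where, "]: non-uniform timestamps (row ",
           which(abs(dt - 1 / tr$sample_rate) > 1e-6)[1] + 1L,
           "), expected step ", 1 / tr$sample_rate, " s", call. = FALSE)
    }
  }
  iv <- tr$in_view
  if (any(iv & !is.finite(rowSums(tr$tip_position)))) {
    stop("format error [", where, "]: non-finite tip position while in view",
         call. = FALSE)
  }
  if (any(iv & !is.finite(rowSums(tr$attitude)))) {
    stop("format error [", where, "]: non-finite attitude while in view",
         call. = FALSE)
  }
  att <- tr$attitude[iv, , drop = FALSE]
  if (nrow(att) > 0 && (max(att) > pi + 1e-9 || min(att) <= -pi - 1e-9)) {
    stop("format error [", where, "]: attitude angles outside (-pi, pi]",
         call. = FALSE)
  }
  if (any(iv & (tr$gripper_angle < 0 | !is.finite(tr$gripper_angle)))) {
    stop("format error [", where, "]: gripper_angle must be finite and >= 0",
         call. = FALSE)
  }
  if (length(tr$port_position) != 3L || any(!is.finite(tr$port_position))) {
    stop("format error [", where, "]: port_position must be a finite 3-vector",
         call. = FALSE)
  }
  tr
}

#' Construct a training-session record
#'
#' @param session_id Session identifier.
#' @param task `"task1"` (tissue dissection around the aorta: grasping
#'   forceps, scissors, clip applier) or `"task3"` (parenchymal suturing:
#'   right and left needle holders).
#' @param tracks Named list of [instrument_track()]s (names = instrument ids).
#' @param target_geometry Optional `m x 3` matrix (mm): point set or
#'   polyline vertices of the target structure (aorta / kidney surface).
#' @param participant_meta Free-form named list.
#' @return An object of class `session_record`.
#' @export
session_record <- function(session_id, task, tracks,
                           target_geometry = NULL,
                           participant_meta = list()) {
  if (!is.null(target_geometry)) target_geometry <- as.matrix(target_geometry)
  rec <- structure(list(
    session_id = as.character(session_id),
    task = match.arg(task, c("task1", "task3")),
    tracks = tracks,
    target_geometry = target_geometry,
    participant_meta = participant_meta
  ), class = "session_record")
  validate_session_record(rec)
}

#' Validate a session record
#' @param rec A `session_record`.
#' @return `rec` on success.
#' @export
validate_session_record <- function(rec) {
  if (length(rec$tracks) < 1L) {
    stop("format error [", rec$session_id, "]: session has no tracks", call. = FALSE)
  }
  ids <- vapply(rec$tracks, function(t) t$instrument_id, character(1))
  if (is.null(names(rec$tracks))) names(rec$tracks) <- ids
  if (!identical(unname(names(rec$tracks)), unname(ids))) {
    stop("format error [", rec$session_id, "]: track names must match instrument ids",
         call. = FALSE)
  }
  rates <- vapply(rec$tracks, function(t) t$sample_rate, numeric(1))
  if (max(rates) - min(rates) > 1e-9) {
    stop("format error [", rec$session_id, "]: tracks do not share a sample rate",
         call. = FALSE)
  }
  for (tr in rec$tracks) validate_instrument_track(tr, paste0(rec$session_id, "/", tr$instrument_id))
  if (rec$task == "task3" &&
      !setequal(ids, c("right_needle_holder", "left_needle_holder"))) {
    stop("format error [", rec$session_id,
         "]: task3 requires exactly right and left needle holders", call. = FALSE)
  }
  if (!is.null(rec$target_geometry)) {
    g <- rec$target_geometry
    if (ncol(g) != 3L || any(!is.finite(g))) {
      stop("format error [", rec$session_id,
           "]: target_geometry must be a finite m x 3 matrix", call. = FALSE)
    }
  }
  rec
}

#' Construct a GOALS rating record
#'
#' GOALS rates five items (depth perception, bimanual dexterity,
#' efficiency, tissue handling, autonomy) on a 1-5 Likert scale. The
#' suturing task (`task3`) omits tissue handling, so its total ranges
#' 4-20 instead of 5-25.
#'
#' @param session_id,rater_id Identifiers.
#' @param task `"task1"` or `"task3"`.
#' @param items Named numeric vector/list of item scores in `[1, 5]`;
#'   names from `depth_perception`, `bimanual_dexterity`, `efficiency`,
#'   `tissue_handling`, `autonomy`. Single-rater scores must be integers;
#'   two-rater means may end in .5.
#' @param allow_half `TRUE` for mean-of-raters scores.
#' @return An object of class `goals_score` with a `total` field equal to
#'   the exact sum of the present items.
#' @export
goals_score <- function(session_id, rater_id, task, items, allow_half = FALSE) {
  task <- match.arg(task, c("task1", "task3"))
  items <- unlist(items)
  expected <- task_items(task)
  missing_items <- setdiff(expected, names(items))
  if (length(missing_items) > 0) {
    stop("validation error [", session_id, "/", rater_id, "]: missing item(s) ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  items <- items[expected]
  if (any(!is.finite(items)) || any(items < 1) || any(items > 5)) {
    stop("validation error [", session_id, "/", rater_id,
         "]: item scores must lie in [1, 5]", call. = FALSE)
  }
  grain <- if (allow_half) 0.5 else 1
  if (any(abs(items / grain - round(items / grain)) > 1e-9)) {
    stop("validation error [", session_id, "/", rater_id,
         "]: scores must be multiples of ", grain, call. = FALSE)
  }
  structure(list(
    session_id = as.character(session_id),
    rater_id = as.character(rater_id),
    task = task,
    items = items,
    total = sum(items)
  ), class = "goals_score")
}

# ---------------------------------------------------------------------------
# Session CSV bundle I/O.
#
# A session is a directory:
#   session.json         metadata: session_id, task, sample_rate, units,
#                        per-instrument port positions, participant_meta
#   <instrument>.csv     t,x,y,z,roll,pitch,yaw,gripper,in_view
#   target_geometry.csv  x,y,z (optional)
# CSV dialect: comma-separated, '.' decimal, UTF-8, one header line.
# Declared units (position_unit mm|cm, angle_unit rad|deg) are converted
# to the internal mm/rad on read.
# ---------------------------------------------------------------------------

TRACK_COLUMNS <- c("t", "x", "y", "z", "roll", "pitch", "yaw", "gripper", "in_view")

#' Read a session CSV bundle
#'
#' @param path Session directory written by [write_session()] (or by any
#'   producer of the documented dialect).
#' @param config Unused placeholder for forward compatibility.
#' @return A validated [session_record()], with declared units converted
#'   to millimetres/radians.
#' @export
read_session <- function(path, config = NULL) {
  meta_path <- file.path(path, "session.json")
  if (!file.exists(meta_path)) {
    stop("format error: no session.json in ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pos_scale <- switch(meta$position_unit %||% "mm",
                      mm = 1, cm = 10,
                      stop("format error [", meta_path, "]: unknown position_unit",
                           call. = FALSE))
  ang_scale <- switch(meta$angle_unit %||% "rad",
                      rad = 1, deg = pi / 180,
                      stop("format error [", meta_path, "]: unknown angle_unit",
                           call. = FALSE))
  inst_names <- names(meta$instruments)
  tracks <- lapply(inst_names, function(id) {
    f <- file.path(path, paste0(id, ".csv"))
    if (!file.exists(f)) stop("format error: missing track file ", f, call. = FALSE)
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    missing_cols <- setdiff(TRACK_COLUMNS, names(d))
    if (length(missing_cols) > 0) {
      stop("format error [", f, "]: missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    port <- as.numeric(meta$instruments[[id]]$port_position) * pos_scale
    instrument_track(
      instrument_id = id,
      sample_rate = meta$sample_rate,
      timestamps = d$t,
      tip_position = cbind(d$x, d$y, d$z) * pos_scale,
      attitude = wrap_angle(cbind(d$roll, d$pitch, d$yaw) * ang_scale),
      gripper_angle = d$gripper * ang_scale,
      in_view = as.logical(d$in_view),
      port_position = port
    )
  })
  names(tracks) <- inst_names
  geom <- NULL
  gf <- file.path(path, "target_geometry.csv")
  if (file.exists(gf)) {
    g <- utils::read.csv(gf, stringsAsFactors = FALSE)
    geom <- as.matrix(g[, c("x", "y", "z")]) * pos_scale
  }
  session_record(meta$session_id, meta$task, tracks,
                 target_geometry = geom,
                 participant_meta = as.list(meta$participant_meta))
}

#' Write a session CSV bundle
#'
#' Inverse of [read_session()]: lossless for finite values (full double
#' precision), always in internal units (mm, rad). An absent target
#' geometry writes no geometry file.
#'
#' @param record A [session_record()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  validate_session_record(record)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory ", path, call. = FALSE)
  meta <- list(
    session_id = record$session_id,
    task = record$task,
    sample_rate = record$tracks[[1]]$sample_rate,
    position_unit = "mm",
    angle_unit = "rad",
    instruments = lapply(record$tracks, function(tr) {
      list(port_position = tr$port_position)
    }),
    participant_meta = record$participant_meta
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (tr in record$tracks) {
    d <- data.frame(
      t = tr$timestamps,
      x = tr$tip_position[, 1], y = tr$tip_position[, 2], z = tr$tip_position[, 3],
      roll = tr$attitude[, 1], pitch = tr$attitude[, 2], yaw = tr$attitude[, 3],
      gripper = tr$gripper_angle,
      in_view = tr$in_view
    )
    utils::write.csv(format(d, digits = 17, trim = TRUE, scientific = FALSE),
                     file.path(path, paste0(tr$instrument_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(record$target_geometry)) {
    g <- data.frame(x = record$target_geometry[, 1],
                    y = record$target_geometry[, 2],
                    z = record$target_geometry[, 3])
    utils::write.csv(format(g, digits = 17, trim = TRUE, scientific = FALSE),
                     file.path(path, "target_geometry.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read GOALS ratings from CSV
#'
#' Expects columns `session_id`, `rater_id`, `task`, and one column per
#' GOALS item. `task3` rows leave `tissue_handling` empty.
#'
#' @param path CSV file.
#' @param allow_half Accept .5 scores (mean-of-raters files).
#' @return List of [goals_score()] records, one per row.
#' @export
read_goals <- function(path, allow_half = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("session_id", "rater_id", "task")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0) {
    stop("format error [", path, "]: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(d)), function(i) {
    task <- d$task[i]
    its <- task_items(task)
    vals <- as.numeric(d[i, its])
    names(vals) <- its
    goals_score(d$session_id[i], d$rater_id[i], task, vals, allow_half = allow_half)
  })
}

#' Write GOALS ratings to CSV
#' @param scores List of [goals_score()] records.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_goals <- function(scores, path) {
  rows <- lapply(scores, function(s) {
    row <- as.list(rep(NA_real_, length(GOALS_ITEMS)))
    names(row) <- GOALS_ITEMS
    row[names(s$items)] <- s$items
    c(list(session_id = s$session_id, rater_id = s$rater_id, task = s$task), row)
  })
  d <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Tabulate GOALS records
#'
#' @param scores List of [goals_score()] records.
#' @return A data.frame with one row per record: `session_id`, `rater_id`,
#'   `task`, one column per item (NA where absent) and `total`.
#' @export
goals_table <- function(scores) {
  d <- do.call(rbind, lapply(scores, function(s) {
    row <- rep(NA_real_, length(GOALS_ITEMS))
    names(row) <- GOALS_ITEMS
    row[names(s$items)] <- s$items
    data.frame(session_id = s$session_id, rater_id = s$rater_id, task = s$task,
               as.list(row), total = s$total, check.names = FALSE)
  }))
  rownames(d) <- NULL
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
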