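# ---------------------------------------------------------------------------
# Skill-parameterised synthetic study generator.
#
# The generator encodes, as construction assumptions, the empirical
# direction of skill effects in laparoscopic motion analysis: skilled
# operators move faster and more dynamically, along shorter paths, with
# fewer gripper cycles, fewer pauses, less tremor and quicker engagement
# after insertion. It is a test harness for the pipeline, not a model of
# surgeons. Trajectories are waypoint paths interpolated with
# minimum-jerk segments (so the jerk metric is finite and
# skill-sensitive), resampled at the camera rate.
# ---------------------------------------------------------------------------

#' Synthetic-study configuration
#'
#' @param n_sessions Number of training sessions. Default 90,
#'   mirroring a realistic wet-lab cohort.
#' @param task `"task1"` (dissection: grasper, scissors, clip applier)
#'   or `"task3"` (suturing: right/left needle holders).
#' @param sample_rate Camera rate, Hz (default 120).
#' @param base_speed,speed_gain Cruise speed = base + gain * skill (mm/s).
#' @param tremor_amp Tremor amplitude at skill 0 (mm); decays linearly
#'   to 0 at skill 1.
#' @param detour_gain Expected detour waypoints at skill 0.
#' @param pause_base,pause_gain Expected total pause time (s) =
#'   base + gain * (1 - skill).
#' @param cycle_base,cycle_gain Expected gripper cycles =
#'   base + gain * (1 - skill).
#' @param ait_base,ait_gain Post-insertion dwell (s) =
#'   base + gain * (1 - skill).
#' @param n_waypoints Work waypoints along the target per instrument.
#' @param item_jitter_sd SD of the latent per-item skill jitter.
#' @param rater_sigma SD of each rater's scoring noise (Likert points).
#' @param rater_bias Length-2 per-rater additive bias.
#' @param missing_rate Fraction of sessions dropped (recording failure
#'   emulation).
#' @param seed Master seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_sessions = 90L,
                       task = "task1",
                       sample_rate = 120,
                       base_speed = 25,
                       speed_gain = 45,
                       tremor_amp = 0.05,
                       detour_gain = 6,
                       pause_base = 1,
                       pause_gain = 12,
                       cycle_base = 6,
                       cycle_gain = 10,
                       ait_base = 0.4,
                       ait_gain = 2.5,
                       n_waypoints = 12L,
                       item_jitter_sd = 0.06,
                       rater_sigma = 1.0,
                       rater_bias = c(-0.25, 0.25),
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  cfg$task <- match.arg(task, c("task1", "task3"))
  stopifnot(cfg$n_sessions >= 1, cfg$sample_rate > 0, cfg$rater_sigma >= 0,
            all(is.finite(unlist(cfg[sapply(cfg, is.numeric)]))))
  cfg
}

sim_target_geometry <- function(task) {
  s <- seq(-50, 50, length.out = 21)
  if (task == "task3") {
    cbind(x = s, y = 10 * cos(s / 35), z = 2 * sin(s / 20))
  } else {
    cbind(x = s, y = 8 * sin(s / 30), z = rep(0, length(s)))
  }
}

sim_ports <- function(task) {
  if (task == "task3") {
    list(right_needle_holder = c(55, -70, 95), left_needle_holder = c(-55, -70, 95))
  } else {
    list(grasper = c(-60, -70, 90), scissors = c(60, -70, 90),
         clip_applier = c(0, -90, 100))
  }
}

# minimum-jerk position profile: s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5
min_jerk_s <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# build one instrument trajectory; returns an instrument_track
sim_instrument <- function(instrument_id, skill, task, cfg, geometry, port) {
  fs <- cfg$sample_rate
  dt <- 1 / fs

  # -- waypoints: along the target, plus skill-dependent detours --
  n_work <- cfg$n_waypoints
  along <- sort(stats::runif(n_work))
  seg_pos <- along * (nrow(geometry) - 1) + 1
  base_pts <- geometry[pmin(nrow(geometry), round(seg_pos)), , drop = FALSE]
  offsets <- cbind(stats::rnorm(n_work, 0, 4), stats::rnorm(n_work, 0, 4),
                   stats::runif(n_work, 5, 22))
  wp <- base_pts + offsets
  n_det <- stats::rpois(1, cfg$detour_gain * (1 - skill))
  if (n_det > 0) {
    at <- sample(seq_len(nrow(wp) - 1), min(n_det, nrow(wp) - 1))
    for (i in sort(at, decreasing = TRUE)) {
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      det <- (wp[i, ] + wp[i + 1, ]) / 2 + dir * stats::runif(1, 30, 60) +
        c(0, 0, 25)
      wp <- rbind(wp[seq_len(i), , drop = FALSE], det,
                  wp[(i + 1):nrow(wp), , drop = FALSE])
    }
  }

  # -- piecewise schedule: min-jerk moves with skill-dependent pauses --
  cruise <- cfg$base_speed + cfg$speed_gain * skill
  n_seg <- nrow(wp) - 1
  seg_len <- sqrt(rowSums((wp[-1, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2))
  seg_v <- cruise * stats::runif(n_seg, 0.8, 1.2)
  seg_T <- pmax(seg_len / seg_v, 4 * dt)
  # total pause budget is tightly skill-determined; it is then split over
  # randomly chosen waypoints so pause placement varies but the idle
  # fraction tracks skill
  p_pause <- 0.1 + 0.4 * (1 - skill)
  pause_total <- (cfg$pause_base + cfg$pause_gain * (1 - skill)) *
    stats::runif(1, 0.8, 1.2)
  at_pause <- stats::runif(n_seg) < p_pause
  if (!any(at_pause)) at_pause[sample(n_seg, 1)] <- TRUE
  pause_T <- numeric(n_seg)
  shares <- stats::rgamma(sum(at_pause), shape = 2)
  pause_T[at_pause] <- pause_total * shares / sum(shares)

  # initial insertion: out-of-view approach then an in-view dwell whose
  # length shrinks with skill (drives the AIT metric)
  t_out <- stats::runif(1, 0.5, 2.0)
  dwell <- cfg$ait_base + cfg$ait_gain * (1 - skill) + abs(stats::rnorm(1, 0, 0.15))

  starts <- numeric(0); ends <- numeric(0); p0 <- list(); p1 <- list()
  tcur <- 0
  add_seg <- function(a, b, T_) {
    starts <<- c(starts, tcur); ends <<- c(ends, tcur + T_)
    p0[[length(p0) + 1]] <<- a; p1[[length(p1) + 1]] <<- b
    tcur <<- tcur + T_
  }
  add_seg(wp[1, ], wp[1, ], dwell)
  for (s in seq_len(n_seg)) {
    add_seg(wp[s, ], wp[s + 1, ], seg_T[s])
    if (pause_T[s] > 0) add_seg(wp[s + 1, ], wp[s + 1, ], pause_T[s])
  }

  n_pre <- max(2L, round(t_out * fs))
  n_move <- max(2L, ceiling(tcur * fs))
  n <- n_pre + n_move
  tt <- (seq_len(n) - 1) * dt
  t_rel <- tt[(n_pre + 1):n] - tt[n_pre + 1]

  seg_idx <- pmin(findInterval(t_rel, starts), length(starts))
  tau <- (t_rel - starts[seg_idx]) / (ends[seg_idx] - starts[seg_idx])
  tau <- pmin(pmax(tau, 0), 1)
  P0 <- do.call(rbind, p0)[seg_idx, , drop = FALSE]
  P1 <- do.call(rbind, p1)[seg_idx, , drop = FALSE]
  pos_in <- P0 + (P1 - P0) * min_jerk_s(tau)

  # band-limited tremor, amplitude decaying with skill
  amp <- cfg$tremor_amp * (1 - skill)
  if (amp > 0) {
    noise <- matrix(stats::rnorm(length(t_rel) * 3, 0, amp), ncol = 3)
    w <- max(3L, round(fs / 8))
    noise <- apply(noise, 2, function(x) {
      y <- stats::filter(x, rep(1 / w, w), sides = 2)
      y[is.na(y)] <- 0
      as.numeric(y) * sqrt(w)  # restore amplitude lost to averaging
    })
    pos_in <- pos_in + noise
  }

  pos <- rbind(matrix(rep(port, n_pre), ncol = 3, byrow = TRUE), pos_in)
  in_view <- c(rep(FALSE, n_pre), rep(TRUE, length(t_rel)))

  # attitude: roll sweeps with the work rhythm; pitch/yaw follow the
  # approach direction with smooth oscillation
  phase <- stats::runif(3, 0, 2 * pi)
  k <- n_seg / tcur  # waypoints per second sets the angular rhythm
  roll <- 0.9 * sin(2 * pi * 0.25 * k * tt + phase[1])
  pitch <- -0.9 + 0.35 * sin(2 * pi * 0.18 * k * tt + phase[2])
  yaw <- 0.4 * cos(2 * pi * 0.15 * k * tt + phase[3])
  att <- wrap_angle(cbind(roll, pitch, yaw))
  att[!in_view, ] <- 0

  # gripper: open/close cycles, more numerous at low skill
  n_cyc <- max(0L, round(cfg$cycle_base + cfg$cycle_gain * (1 - skill) +
                           stats::rnorm(1, 0, 1)))
  grip <- rep(0.08, n)
  if (n_cyc > 0) {
    usable <- which(in_view)
    span <- range(usable)
    centers <- sort(sample(seq(span[1] + fs %/% 2, span[2] - fs %/% 2,
                               length.out = max(n_cyc, 2))[seq_len(n_cyc)]))
    half <- max(3L, round(0.22 * fs))
    prof <- 0.08 + 0.62 * sin(seq(0, pi, length.out = 2 * half + 1))^2
    for (cidx in centers) {
      lo <- max(1, round(cidx) - half); hi <- min(n, round(cidx) + half)
      grip[lo:hi] <- pmax(grip[lo:hi], prof[seq_len(hi - lo + 1)])
    }
  }
  grip[!in_view] <- 0

  instrument_track(instrument_id, fs, tt, pos, att, grip, in_view, port)
}

#' Simulate one training session
#'
#' Deterministic in `(skill, task, seed, sim_config)`.
#'
#' @param skill Latent skill in `[0, 1]`.
#' @param task `"task1"` or `"task3"`.
#' @param seed Integer seed.
#' @param cfg A [sim_config()].
#' @param session_id Identifier (defaults to a seed-derived label).
#' @return A validated [session_record()] including target geometry and
#'   port positions.
#' @export
simulate_session <- function(skill, task = cfg$task, seed = 1L,
                             cfg = sim_config(),
                             session_id = sprintf("sim%06d", seed)) {
  if (!is.finite(skill) || skill < 0 || skill > 1) {
    stop("domain error: skill must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  geometry <- sim_target_geometry(task)
  ports <- sim_ports(task)
  tracks <- lapply(names(ports), function(id) {
    sim_instrument(id, skill, task, cfg, geometry, ports[[id]])
  })
  names(tracks) <- names(ports)
  session_record(session_id, task, tracks, target_geometry = geometry,
                 participant_meta = list(skill = skill, seed = seed))
}

#' Simulate two raters' GOALS scores for one session
#'
#' Latent item score `1 + 4 * clamp(skill + jitter, 0, 1)`; each rater
#' reports `round(latent + bias + noise)` clamped to `[1, 5]`. The
#' suturing task omits tissue handling.
#'
#' @param skill Latent skill in `[0, 1]`.
#' @param task `"task1"` or `"task3"`.
#' @param seed Integer seed.
#' @param cfg A [sim_config()] (uses `item_jitter_sd`, `rater_sigma`,
#'   `rater_bias`).
#' @param session_id Session identifier for the records.
#' @return List of two [goals_score()] records (`rater1`, `rater2`).
#' @export
simulate_goals <- function(skill, task = cfg$task, seed = 1L,
                           cfg = sim_config(),
                           session_id = sprintf("sim%06d", seed)) {
  if (!is.finite(skill) || skill < 0 || skill > 1) {
    stop("domain error: skill must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed + 499979L)
  items <- task_items(task)
  jitter <- stats::rnorm(length(items), 0, cfg$item_jitter_sd)
  latent <- 1 + 4 * pmin(pmax(skill + jitter, 0), 1)
  lapply(1:2, function(r) {
    reported <- round(latent + cfg$rater_bias[r] +
                        stats::rnorm(length(items), 0, cfg$rater_sigma))
    reported <- pmin(pmax(reported, 1), 5)
    names(reported) <- items
    goals_score(session_id, paste0("rater", r), task, reported)
  })
}

#' Generate a full synthetic study
#'
#' Draws a skill per session, simulates motion and two-rater GOALS
#' scores, and records every seed in a manifest so the study is exactly
#' regenerable.
#'
#' @param cfg A [sim_config()].
#' @return List: `sessions` (list of [session_record()]),
#'   `goals` (flat list of [goals_score()], two per session),
#'   `skill` (named vector), `manifest` (config echo + per-session seeds).
#' @export
generate_study <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_sessions
  skills <- stats::runif(n)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  keep <- stats::runif(n) >= cfg$missing_rate
  ids <- sprintf("S%03d", seq_len(n))
  sessions <- list(); goals <- list(); skill_out <- numeric(0)
  for (i in which(keep)) {
    sessions[[ids[i]]] <- simulate_session(skills[i], cfg$task, seeds[i], cfg,
                                           session_id = ids[i])
    goals <- c(goals, simulate_goals(skills[i], cfg$task, seeds[i], cfg,
                                     session_id = ids[i]))
    skill_out[ids[i]] <- skills[i]
  }
  manifest <- list(config = unclass(cfg), session_ids = ids[keep],
                   skills = skills[keep], session_seeds = seeds[keep])
  list(sessions = sessions, goals = goals, skill = skill_out,
       manifest = manifest)
}
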