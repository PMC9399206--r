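# Shared fixtures and independent oracles used across the suite.

# --- track/series construction ---------------------------------------------

# build a validated track from a position matrix at a given rate
make_track <- function(pos, fs = 100, instrument = "grasper",
                       attitude = NULL, gripper = NULL, in_view = NULL,
                       port = c(0, -50, 80)) {
  n <- nrow(pos)
  instrument_track(
    instrument_id = instrument,
    sample_rate = fs,
    timestamps = (seq_len(n) - 1) / fs,
    tip_position = pos,
    attitude = attitude %||% matrix(0, n, 3),
    gripper_angle = gripper %||% rep(0.1, n),
    in_view = in_view %||% rep(TRUE, n),
    port_position = port
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# straight-line track traversed at constant speed (mm/s)
line_track <- function(from, to, speed, fs = 100, ...) {
  d <- sqrt(sum((to - from)^2))
  n <- max(2L, round(d / speed * fs) + 1L)
  tau <- seq(0, 1, length.out = n)
  pos <- outer(rep(1, n), from) + outer(tau, to - from)
  make_track(pos, fs = fs, ...)
}

# smooth a track with a small window so short fixtures keep interior samples
smooth_small <- function(track, window = 11L, polyorder = 3L) {
  savgol_smooth(track, window_length = window, polyorder = polyorder)
}

# wrap an arbitrary position matrix as a pseudo kinematic series with
# exact derivative channels (for metric-level oracles that do not test
# the filter itself)
manual_series <- function(pos, fs = 100, d1 = NULL, d2 = NULL, d3 = NULL,
                          valid = NULL, port = c(0, -50, 80),
                          gripper = NULL, attitude = NULL, in_view = NULL) {
  n <- nrow(pos)
  structure(list(
    instrument_id = "grasper",
    sample_rate = fs,
    timestamps = (seq_len(n) - 1) / fs,
    position = pos,
    deriv1 = d1 %||% matrix(0, n, 3),
    deriv2 = d2 %||% matrix(0, n, 3),
    deriv3 = d3 %||% matrix(0, n, 3),
    valid_mask = valid %||% rep(TRUE, n),
    port_position = port,
    attitude = attitude %||% matrix(0, n, 3),
    gripper_angle = gripper %||% rep(0.1, n),
    in_view = in_view %||% rep(TRUE, n)
  ), class = "kinematic_series")
}

# --- independent oracles ----------------------------------------------------

# convex hull volume via scipy (qhull), the independent reference
scipy_hull_volume <- function(P) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(as.data.frame(P), f, row.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy, scipy.spatial; ",
    "P = numpy.loadtxt('", f, "', delimiter=',', skiprows=1); ",
    "print(repr(scipy.spatial.ConvexHull(P).volume))"
  ))), stdout = TRUE, stderr = TRUE)
  as.numeric(out[length(out)])
}

# brute-force Spearman: mid-ranks then explicit Pearson formula
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# exhaustive two-sided Mann-Whitney p-value (no ties)
enumerate_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  u_low <- min(u_obs, n1 * n2 - u_obs)
  min(1, 2 * mean(u_all <= u_low))
}

# naive two-state hysteresis automaton for gripper cycle counting
brute_noc <- function(angle, open_t, close_t) {
  open_state <- FALSE
  k <- 0L
  for (a in angle) {
    if (!open_state && a >= open_t) open_state <- TRUE
    if (open_state && a <= close_t) { open_state <- FALSE; k <- k + 1L }
  }
  k
}

# phase unwrap by brute enumeration: pick the 2*pi shift minimising each jump
brute_unwrap <- function(a) {
  out <- a
  for (i in 2:length(a)) {
    cand <- a[i] + 2 * pi * (-3:3)
    out[i] <- cand[which.min(abs(cand - out[i - 1]))]
  }
  out
}

# brute-force point-to-polyline minimum distance (per point loop)
brute_polyline_dist <- function(p, G) {
  best <- Inf
  for (s in seq_len(nrow(G) - 1)) {
    a <- G[s, ]; b <- G[s + 1, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    best <- min(best, sqrt(sum((p - a - t * ab)^2)))
  }
  best
}

# small two-rater GOALS fixture
toy_goals <- function(items1, items2, task = "task1", id = "s1") {
  list(
    goals_score(id, "rater1", task, items1),
    goals_score(id, "rater2", task, items2)
  )
}

named_items <- function(v, task = "task1") {
  its <- if (task == "task3") {
    c("depth_perception", "bimanual_dexterity", "efficiency", "autonomy")
  } else {
    c("depth_perception", "bimanual_dexterity", "efficiency",
      "tissue_handling", "autonomy")
  }
  stats::setNames(v, its)
}

# feature table + goals with a known linear structure, for validation tests
linear_fixture <- function(n = 40, p = 5, noise = 0, seed = 1, task = "task1") {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("G-M", seq_len(p))
  w <- seq_len(p) / p
  lin <- as.vector(X %*% w)
  total_rng <- if (task == "task3") c(4, 20) else c(5, 25)
  total <- total_rng[1] + (total_rng[2] - total_rng[1]) *
    (lin - min(lin)) / (max(lin) - min(lin))
  total <- total + rnorm(n, 0, noise)
  total <- pmin(pmax(total, total_rng[1]), total_rng[2])
  ids <- sprintf("F%03d", seq_len(n))
  features <- data.frame(session_id = ids, task = task, X, check.names = FALSE)
  goals <- data.frame(session_id = ids, task = task, total = total,
                      stringsAsFactors = FALSE)
  sel <- list(total = colnames(X))
  attr(sel, "task") <- task
  class(sel) <- "selection_map"
  list(features = features, goals = goals, selection = sel)
}
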