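# Closed-loop saccadic flight: 50 ms intersaccadic translations with jittered
# motion direction gather integrated squared flow; the control law converts
# it into a saccade amplitude; a Gaussian yaw-velocity profile executes the
# turn while translation continues. Sensors run on every 1 ms tick.

#' Closed-loop simulation configuration
#'
#' @param flow_source \code{"geometric"} (ground-truth flow benchmark) or
#'   \code{"emd"} (correlator front end).
#' @param gain,threshold sigmoid parameters of the avoidance weighting.
#' @param goal goal position c(x, y) (m) or \code{NULL}; without a goal the
#'   goal-direction term is 0 ("keep straight").
#' @param goal_sd_deg SD of the Gaussian goal-direction noise (deg).
#' @param dt_ms simulation step (ms).
#' @param intersaccade_ms intersaccade duration; one motion-direction segment
#'   per tick.
#' @param segment_sd_deg SD of the per-segment motion direction around the
#'   heading (deg).
#' @param speed translation speed (m/s), held constant in both phases.
#' @param collision_radius crash when the distance to any surface falls below
#'   this (m).
#' @param goal_radius goal reached within this horizontal distance (m).
#' @param max_time_s simulated time budget (s).
#' @param n_subrays renderer sub-rays per receptor (EMD mode).
#' @param emd_window_ms accumulation window at the end of each intersaccade
#'   (EMD mode); geometric flow integrates over the whole intersaccade.
#' @param emd_calibration EMD-to-geometric nearness unit scale; \code{NULL}
#'   uses the package constant (see \code{\link{emd_calibration}}).
#' @param flight_height flight plane (m); \code{NULL} = arena mid-height.
#' @param seed master seed for all randomness of the run.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(flow_source = c("geometric", "emd"), gain = 2,
                       threshold = 4, goal = NULL, goal_sd_deg = 0,
                       dt_ms = 1, intersaccade_ms = 50, segment_sd_deg = 18,
                       speed = 0.1, collision_radius = 0.01,
                       goal_radius = 0.05, max_time_s = 10, n_subrays = 13,
                       emd_window_ms = 5, emd_calibration = NULL,
                       flight_height = NULL, seed = 1L) {
  flow_source <- match.arg(flow_source)
  stopifnot(dt_ms > 0, intersaccade_ms %% dt_ms == 0, segment_sd_deg >= 0,
            speed > 0, max_time_s > 0, emd_window_ms >= dt_ms)
  structure(list(flow_source = flow_source, gain = gain,
                 threshold = threshold, goal = goal,
                 goal_sd_deg = goal_sd_deg, dt_ms = dt_ms,
                 intersaccade_ms = intersaccade_ms,
                 segment_sd_deg = segment_sd_deg, speed = speed,
                 collision_radius = collision_radius,
                 goal_radius = goal_radius, max_time_s = max_time_s,
                 n_subrays = n_subrays, emd_window_ms = emd_window_ms,
                 emd_calibration = emd_calibration,
                 flight_height = flight_height, seed = as.integer(seed)),
            class = "sim_config")
}

#' Initialize a simulation state
#'
#' @param env environment or compiled scene.
#' @param config a \code{sim_config}.
#' @param start start position c(x, y) (m).
#' @param heading_deg initial heading (deg).
#' @return A \code{sim_state}: position, heading, elapsed time and (for the
#'   EMD source) the filter states of the motion-detection cascade.
#' @export
sim_state_init <- function(env, config, start, heading_deg = 0) {
  sc <- as_scene(env)
  z <- config$flight_height %||% flight_height(sc$env)
  pos <- c(start[1], start[2], z)
  if (cpp_scene_distance(sc$ptr, pos) < config$collision_radius)
    stop("start position is in collision")
  ep <- emd_params(dt_ms = config$dt_ms)
  st <- emd_state_init(ep)
  if (config$flow_source == "emd") {
    # adapted initialization: the agent has been at rest in the scene, so
    # the photoreceptor and DC-tracking states start at their fixed point
    # for the initial view (no turn-on transient in the first decision)
    img <- render_view(sc, make_pose(pos, heading_deg), config$n_subrays)
    st$pr <- img
    st$hp_lp <- img
  }
  list(position = pos, heading_deg = heading_deg, t_ms = 0,
       emd_state = st, emd_params = ep, scene = sc)
}

# advance one phase; shared by intersaccade (dir jitter, no yaw) and saccade
# (yaw profile). Returns accumulated squared flow when `accumulate` has any
# TRUE tick. Geometric mode uses the nearness map cached at phase entry (the
# displacement within a phase, ~5 mm, is negligible at arena scale).
run_phase <- function(state, config, dir_off_deg, yaw_dps, accumulate) {
  sc <- state$scene
  n <- length(dir_off_deg)
  dt_s <- config$dt_ms / 1000
  if (config$flow_source == "emd") {
    st <- render_stencil(config$n_subrays)
    p <- state$emd_params
    out <- cpp_emd_phase(sc$ptr,
                         c(state$position, state$heading_deg * pi / 180),
                         config$speed, config$dt_ms, dir_off_deg, yaw_dps,
                         accumulate, state$emd_state, st$dirs, st$weights,
                         list(nrow = p$nrow, ncol = p$ncol,
                              tau_pr = p$tau_pr, tau_hp = p$tau_hp,
                              tau_lp = p$tau_lp),
                         config$collision_radius)
    crash <- out$crash_tick
    nt <- if (crash > 0) crash else n
    path <- out$path[seq_len(nt), , drop = FALSE]
    state$position <- c(out$pose[1], out$pose[2], out$pose[3])
    state$heading_deg <- out$pose[4] * 180 / pi
    state$emd_state <- out$state
    isf <- if (out$n_accumulated > 0)
      structure(list(h = out$hsq, v = out$vsq, n = out$n_accumulated,
                     source = "emd"), class = "integrated_squared_flow")
  } else {
    mu <- nearness_truth(sc, state$position, state$heading_deg)
    g <- retina_geometry()
    hs <- matrix(0, g$nrow, g$ncol); vs <- hs
    nacc <- 0L
    pos <- state$position; heading <- state$heading_deg
    path <- matrix(NA_real_, n, 3)
    crash <- -1L
    for (t in seq_len(n)) {
      mdir <- (heading + dir_off_deg[t]) * pi / 180
      pos[1] <- pos[1] + config$speed * dt_s * cos(mdir)
      pos[2] <- pos[2] + config$speed * dt_s * sin(mdir)
      heading <- heading + yaw_dps[t] * dt_s
      path[t, ] <- c(pos[1], pos[2], heading)
      if (cpp_scene_distance(sc$ptr, pos) < config$collision_radius) {
        crash <- t
        break
      }
      if (accumulate[t]) {
        d <- dir_off_deg[t] * pi / 180
        vmu <- config$speed * mu
        ofh <- vmu * sin(g$phi - d)
        ofv <- vmu * sin(g$eps) * cos(g$phi - d)
        hs <- hs + ofh^2
        vs <- vs + ofv^2
        nacc <- nacc + 1L
      }
    }
    nt <- if (crash > 0) crash else n
    path <- path[seq_len(nt), , drop = FALSE]
    state$position <- pos
    state$heading_deg <- heading
    isf <- if (nacc > 0)
      structure(list(h = hs / nacc, v = vs / nacc, n = nacc,
                     source = "geometric"), class = "integrated_squared_flow")
  }
  state$t_ms <- state$t_ms + nt * config$dt_ms
  list(state = state, isf = isf, path = path,
       crash = if (crash > 0) crash else NULL)
}

#' Run one intersaccadic translation
#'
#' Translates for the configured 50 ms in per-tick motion directions drawn
#' from N(0, 18 deg) around the (unchanged) heading, while the sensors run
#' and squared flow is accumulated: over the whole phase for the geometric
#' source, over the last \code{emd_window_ms} for the correlator source.
#'
#' @param state a \code{sim_state}.
#' @param config a \code{sim_config}.
#' @return List with the updated \code{state}, the
#'   \code{integrated_squared_flow} \code{isf}, the per-tick \code{path}
#'   (x, y, heading) and \code{crash} (tick index or NULL).
#' @export
run_intersaccade <- function(state, config) {
  n <- as.integer(config$intersaccade_ms / config$dt_ms)
  dir_off <- if (config$segment_sd_deg > 0)
    stats::rnorm(n, 0, config$segment_sd_deg) else numeric(n)
  acc <- if (config$flow_source == "emd") {
    k <- as.integer(config$emd_window_ms / config$dt_ms)
    c(rep(FALSE, n - k), rep(TRUE, k))
  } else rep(TRUE, n)
  run_phase(state, config, dir_off, numeric(n), acc)
}

#' Gaussian saccade yaw-velocity profile
#'
#' Duration follows the template D = max(10, 30 + 20 |gamma| / 90) ms
#' (spanning the insect range for amplitudes up to 180 deg); a zero amplitude
#' yields the minimal 10 ms zero-velocity profile. Per-tick yaw velocities
#' follow a Gaussian bell (sigma = D/6) renormalized so the integrated turn
#' equals gamma exactly.
#'
#' @param gamma saccade amplitude (deg), |gamma| <= 180.
#' @param dt_ms tick length (ms).
#' @return A \code{saccade_profile}: \code{gamma}, \code{duration_ms} and the
#'   per-tick \code{yaw_dps} samples.
#' @export
saccade_profile <- function(gamma, dt_ms = 1) {
  stopifnot(abs(gamma) <= 180)
  if (gamma == 0) {
    n <- as.integer(round(10 / dt_ms))
    return(structure(list(gamma = 0, duration_ms = n * dt_ms,
                          yaw_dps = numeric(n)), class = "saccade_profile"))
  }
  dur <- max(10, 30 + 20 * abs(gamma) / 90)
  n <- as.integer(round(dur / dt_ms))
  tt <- seq_len(n)
  ctr <- (n + 1) / 2
  w <- exp(-((tt - ctr)^2) / (2 * (n / 6)^2))
  yaw <- gamma * w / (sum(w) * dt_ms / 1000)
  structure(list(gamma = gamma, duration_ms = n * dt_ms, yaw_dps = yaw),
            class = "saccade_profile")
}

#' Execute a saccade
#'
#' Integrates the yaw profile while translation continues at the configured
#' speed along the instantaneous heading. Sensor filters keep running, so the
#' rotational flow of the saccade contaminates the next intersaccade's early
#' correlator responses, as intended.
#'
#' @param state a \code{sim_state}.
#' @param profile a \code{saccade_profile}.
#' @param config a \code{sim_config}.
#' @return As \code{\link{run_intersaccade}} (without accumulated flow).
#' @export
run_saccade <- function(state, profile, config) {
  n <- length(profile$yaw_dps)
  run_phase(state, config, numeric(n), profile$yaw_dps, rep(FALSE, n))
}

#' Crash test against the arena surfaces
#'
#' @param env environment or compiled scene.
#' @param position 3-vector (m).
#' @param radius collision radius (m).
#' @return TRUE iff the distance to any surface is strictly below
#'   \code{radius}.
#' @export
detect_collision <- function(env, position, radius = 0.01) {
  surface_distance(env, position) < radius
}

#' Closed-loop flight simulation
#'
#' Alternates intersaccades and saccades until a crash, the goal, or the time
#' budget. After each intersaccade the integrated squared flow is turned into
#' a relative nearness map, its elevation average into the COMANV, and the
#' saccade amplitude into \code{W * CAD + (1 - W) * alpha} where alpha is the
#' bearing to the goal (0 without a goal).
#'
#' @param env environment or compiled scene (the scene is compiled once).
#' @param config a \code{sim_config}.
#' @param start start position c(x, y) (m).
#' @param heading_deg initial heading (deg).
#' @return A \code{ca_trajectory}: per-tick \code{data} (t_ms, x_m, y_m,
#'   heading_deg, phase), per-saccade \code{events} (t_ms, gamma, cad, can,
#'   weight, alpha), the terminal \code{result} ("timeout", "crash" or
#'   "goal"), and the seed/config provenance.
#' @export
simulate_agent <- function(env, config, start, heading_deg = 0) {
  sc <- as_scene(env)
  with_seed(config$seed, {
    state <- sim_state_init(sc, config, start, heading_deg)
    max_ticks <- round(config$max_time_s * 1000 / config$dt_ms)
    paths <- list(); phases <- list()
    events <- list()
    result <- "timeout"
    goal <- config$goal %||% sc$env$goal
    repeat {
      ph <- run_intersaccade(state, config)
      state <- ph$state
      paths[[length(paths) + 1]] <- ph$path
      phases[[length(phases) + 1]] <-
        rep("intersaccade", nrow(ph$path))
      st <- check_terminal(ph, goal, config)
      if (!is.null(st)) { result <- st$result
        if (!is.null(st$trim)) paths <- trim_last(paths, st$trim)
        break }
      if (state$t_ms >= max_ticks * config$dt_ms) break
      alpha <- if (is.null(goal)) 0 else
        wrap_angle(atan2(goal[2] - state$position[2],
                         goal[1] - state$position[1]) * 180 / pi -
                   state$heading_deg)
      ctl <- control_step(ph$isf, config$gain, config$threshold, alpha,
                          config$goal_sd_deg, config$emd_calibration)
      events[[length(events) + 1]] <-
        data.frame(t_ms = state$t_ms, gamma = ctl$gamma, cad = ctl$cad,
                   can = ctl$can, weight = ctl$weight, alpha = alpha)
      prof <- saccade_profile(ctl$gamma, config$dt_ms)
      ph <- run_saccade(state, prof, config)
      state <- ph$state
      paths[[length(paths) + 1]] <- ph$path
      phases[[length(phases) + 1]] <- rep("saccade", nrow(ph$path))
      st <- check_terminal(ph, goal, config)
      if (!is.null(st)) { result <- st$result
        if (!is.null(st$trim)) paths <- trim_last(paths, st$trim)
        break }
      if (state$t_ms >= max_ticks * config$dt_ms) break
    }
    path <- do.call(rbind, paths)
    nt <- nrow(path)
    data <- data.frame(t_ms = seq_len(nt) * config$dt_ms,
                       x_m = path[, 1], y_m = path[, 2],
                       heading_deg = path[, 3],
                       phase = unlist(phases)[seq_len(nt)])
    structure(list(data = data, result = result,
                   events = if (length(events)) do.call(rbind, events)
                            else data.frame(),
                   config = config, env_kind = sc$env$kind,
                   start = start, heading_deg = heading_deg,
                   seed = config$seed),
              class = "ca_trajectory")
  })
}

# terminal condition of a finished phase: crash, or first tick within the
# goal radius (the path is trimmed to that tick)
check_terminal <- function(ph, goal, config) {
  if (!is.null(ph$crash)) return(list(result = "crash"))
  if (!is.null(goal)) {
    d <- sqrt((ph$path[, 1] - goal[1])^2 + (ph$path[, 2] - goal[2])^2)
    hit <- which(d < config$goal_radius)
    if (length(hit))
      return(list(result = "goal", trim = hit[1]))
  }
  NULL
}

trim_last <- function(paths, k) {
  n <- length(paths)
  paths[[n]] <- paths[[n]][seq_len(k), , drop = FALSE]
  paths
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ca_trajectory %s: %.2f s, %d saccades, result: %s>\n",
    x$config$flow_source, nrow(x$data) * x$config$dt_ms / 1000,
    nrow(x$events), x$result))
  invisible(x)
}

#' @export
plot.ca_trajectory <- function(x, ..., add = FALSE, col_is = "steelblue",
                               col_sac = "firebrick") {
  if (!add)
    plot(x$data$x_m, x$data$y_m, type = "n", asp = 1,
         xlab = "x (m)", ylab = "y (m)", ...)
  is_sac <- x$data$phase == "saccade"
  graphics::lines(x$data$x_m, x$data$y_m, col = col_is)
  graphics::points(x$data$x_m[is_sac], x$data$y_m[is_sac], col = col_sac,
                   pch = ".", cex = 2)
  invisible(x)
}

#' Canonical start-position sets
#'
#' Evenly spaced lattices over the arena interior (or a strip at the low-x
#' end for goal-crossing experiments), filtered to keep a safe clearance to
#' all surfaces.
#'
#' @param env environment or compiled scene.
#' @param n number of starts (4, 40, 51 and 201 mirror the reference
#'   experiment sizes; any n >= 1 works).
#' @param region \code{"full"} or \code{"end"} (strip at the low-x end).
#' @param clearance minimum distance to any surface (m).
#' @return n x 2 matrix of start positions.
#' @export
start_grid <- function(env, n, region = c("full", "end"), clearance = 0.05) {
  region <- match.arg(region)
  sc <- as_scene(env)
  e <- sc$env
  z <- flight_height(e)
  d <- e$hi - e$lo
  if (region == "end") {
    # a column (or narrow band) at the low-x end, spread across y
    x0 <- e$lo[1] + 0.14 * d[1]
    yr <- c(e$lo[2] + 0.18 * d[2], e$hi[2] - 0.18 * d[2])
    ny <- n
    repeat {
      ys <- seq(yr[1], yr[2], length.out = ny)
      pts <- cbind(x0, ys)
      ok <- vapply(seq_len(nrow(pts)), function(i)
        cpp_scene_distance(sc$ptr, c(pts[i, ], z)) >= clearance, logical(1))
      pts <- pts[ok, , drop = FALSE]
      if (nrow(pts) >= n) break
      ny <- ny + 2
      if (ny > 20 * n) stop("could not place ", n, " clear start positions")
    }
    idx <- round(seq(1, nrow(pts), length.out = n))
    return(pts[idx, , drop = FALSE])
  }
  xr <- c(e$lo[1] + 0.2 * d[1], e$hi[1] - 0.2 * d[1])
  yr <- c(e$lo[2] + 0.2 * d[2], e$hi[2] - 0.2 * d[2])
  k <- ceiling(sqrt(n))
  repeat {
    nx <- max(2, ceiling(k * (xr[2] - xr[1]) /
                           max(xr[2] - xr[1], yr[2] - yr[1])))
    ny <- max(2, ceiling(k * (yr[2] - yr[1]) /
                           max(xr[2] - xr[1], yr[2] - yr[1])))
    pts <- as.matrix(expand.grid(x = seq(xr[1], xr[2], length.out = nx),
                                 y = seq(yr[1], yr[2], length.out = ny)))
    ok <- vapply(seq_len(nrow(pts)), function(i)
      cpp_scene_distance(sc$ptr, c(pts[i, ], z)) >= clearance, logical(1))
    pts <- pts[ok, , drop = FALSE]
    if (nrow(pts) >= n) break
    k <- k + 1
    if (k > 40) stop("could not place ", n, " clear start positions")
  }
  idx <- round(seq(1, nrow(pts), length.out = n))
  pts[idx, , drop = FALSE]
}
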