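# Reproducible experiment orchestration: seed substreams, the EMD unit
# calibration, figure-style presets, and output writers.

#' Derive a named sub-seed from a master seed
#'
#' Deterministic, documented substreams (e.g. "texture", "placement",
#' "sim1") so that changing one stream leaves the others untouched.
#'
#' @param master integer master seed.
#' @param role character stream name (or an integer index).
#' @return Integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, role) {
  m <- 2147483647
  h <- if (is.character(role)) {
    acc <- 0
    for (cp in utf8ToInt(role)) acc <- (acc * 131 + cp) %% m
    acc
  } else as.numeric(role) %% m
  s <- ((as.numeric(master) %% m) * 48271 + h * 7919 + 12345) %% m
  as.integer(s + (s == 0))
}

#' Calibrate EMD nearness units against the geometric benchmark
#'
#' The correlator output scale is arbitrary (it depends on texture contrast,
#' optics and filter gains), while the control thresholds are stated on the
#' geometric relative-nearness scale (1/s). Because correlators respond most
#' strongly to the contrast contours of nearby objects, the calibration is
#' anchored to the camouflaged-object paradigm: a single 3 cm vertical bar,
#' covered with the same 1 mm checks as the walls of a large (0.8 m) box so
#' that the distant walls contribute symmetrically, viewed from 0.1 m
#' clearance while translating parallel to it. The routine measures the
#' ratio of geometric to EMD collision-avoidance necessity there (after the
#' filters settle) and returns the scale that makes the two agree. The
#' package default (\code{EMD_CALIBRATION_DEFAULT}) was obtained with this
#' routine (seed 1, 13 sub-rays) and is applied to all EMD-derived nearness
#' maps unless overridden.
#'
#' @param env reference environment; default 0.8 m box, 1 mm checks, one
#'   camouflaged 3 cm bar at the centre.
#' @param position,heading_deg reference pose; default 0.1 m clearance from
#'   the object face, heading parallel to it.
#' @param n_settle settling intersaccades before the measured one.
#' @param seed RNG seed for the segment jitter.
#' @param n_subrays renderer sub-rays.
#' @return The calibration scale (geometric CAN / uncalibrated EMD CAN).
#' @export
emd_calibration <- function(env = NULL, position = c(-0.115, 0),
                            heading_deg = 90, n_settle = 5, seed = 1L,
                            n_subrays = 13) {
  env <- env %||% env_object_box(
    1, texture = list(kind = "checkerboard", texel_size_mm = 1),
    edge = 0.8, seed = 1L)
  sc <- as_scene(env)
  can_of <- function(source) {
    cfg <- sim_config(source, seed = seed, n_subrays = n_subrays,
                      max_time_s = 1)
    with_seed(seed, {
      st <- sim_state_init(sc, cfg, position, heading_deg)
      isf <- NULL
      for (k in seq_len(n_settle + 1)) {
        ph <- run_intersaccade(st, cfg)
        # return to the reference pose so every pass measures the same place
        ph$state$position <- st$position
        ph$state$heading_deg <- st$heading_deg
        st <- ph$state
        isf <- ph$isf
      }
      cc <- cad_can(comanv(vertical_average(
        nearness_from_integrated(isf, calibration = 1))))
      cc$can
    })
  }
  can_of("geometric") / can_of("emd")
}

#' Experiment specification
#'
#' A serializable bundle: environment recipe, simulation configuration,
#' start set and analysis switches, with one master seed feeding documented
#' substreams (textures/placement vs per-start simulations).
#'
#' @param environment a \code{ca_environment} (with a recipe) or a recipe
#'   list as stored by \code{\link{write_environment}}.
#' @param config a \code{sim_config}.
#' @param starts matrix of start positions, or a list
#'   \code{list(n =, region =)} for \code{\link{start_grid}}.
#' @param routes cluster trajectories into routes (needs >= 3 obstacles).
#' @param efficiency compute reliability/efficiency metrics (needs a goal).
#' @param outdir output directory or NULL (results only returned).
#' @param seed master seed.
#' @return An \code{experiment_spec}.
#' @export
experiment_spec <- function(environment, config, starts = list(n = 4),
                            routes = FALSE, efficiency = FALSE,
                            outdir = NULL, seed = 1L) {
  structure(list(environment = environment, config = config, starts = starts,
                 routes = routes, efficiency = efficiency, outdir = outdir,
                 seed = as.integer(seed)), class = "experiment_spec")
}

# stable content hash (polynomial, base 131) over the serialized spec
spec_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run an experiment
#'
#' Generates the environment, simulates every start, and (optionally)
#' clusters routes and computes efficiency metrics. When \code{outdir} is
#' set, writes trajectory and event CSVs, a routes CSV and a JSON summary,
#' each stamped with the spec hash and seed.
#'
#' @param spec an \code{experiment_spec}.
#' @return List with \code{trajectories}, optional \code{routes} /
#'   \code{metrics}, and a \code{summary} list (crash/goal/route counts,
#'   spec hash).
#' @export
run_experiment <- function(spec) {
  env <- if (inherits(spec$environment, "ca_environment")) spec$environment
         else read_environment_config(spec$environment)
  sc <- compile_scene(env)
  starts <- if (is.matrix(spec$starts)) spec$starts
            else start_grid(sc, spec$starts$n,
                            spec$starts$region %||% "full")
  goal <- spec$config$goal %||% env$goal
  trajs <- lapply(seq_len(nrow(starts)), function(i) {
    cfg <- spec$config
    cfg$seed <- derive_seed(spec$seed, paste0("sim", i))
    h0 <- if (!is.null(goal))
      atan2(goal[2] - starts[i, 2], goal[1] - starts[i, 1]) * 180 / pi else 0
    simulate_agent(sc, cfg, starts[i, ], h0)
  })
  results <- vapply(trajs, `[[`, character(1), "result")
  out <- list(trajectories = trajs)
  hash <- spec_hash(list(env$config %||% env$kind, spec$config, spec$starts,
                         spec$seed))
  summary <- list(spec_hash = hash, seed = spec$seed,
                  n_starts = nrow(starts),
                  n_crash = sum(results == "crash"),
                  n_goal = sum(results == "goal"),
                  n_timeout = sum(results == "timeout"))
  if (isTRUE(spec$routes) && length(env$obstacles) >= 3) {
    mesh <- delaunay_mesh(t(vapply(env$obstacles, `[[`, numeric(2),
                                   "center")))
    seqs <- lapply(trajs, function(tr)
      simplify_sequence(cell_sequence(tr, mesh)))
    rs <- cluster_routes(seqs)
    out$mesh <- mesh
    out$routes <- rs
    summary$n_routes <- length(rs$routes)
  }
  if (isTRUE(spec$efficiency) && !is.null(goal)) {
    met <- efficiency_metrics(trajs, env, goal,
                              inflate = spec$config$collision_radius)
    out$metrics <- met
    summary <- c(summary, attr(met, "summary"))
  }
  out$summary <- summary
  if (!is.null(spec$outdir)) write_experiment_outputs(out, env, spec)
  out
}

read_environment_config <- function(cfg) {
  path <- tempfile(fileext = ".yml")
  on.exit(unlink(path))
  yaml::write_yaml(cfg, path)
  read_environment(path)
}

write_experiment_outputs <- function(out, env, spec) {
  dir.create(spec$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- out$summary$spec_hash
  for (i in seq_along(out$trajectories)) {
    tr <- out$trajectories[[i]]
    write_trajectory(tr, file.path(spec$outdir,
                                   sprintf("trajectory_%03d.csv", i)),
                     provenance = hash)
  }
  if (!is.null(out$routes)) {
    rows <- data.frame(
      trajectory = seq_along(out$routes$assignment),
      route = out$routes$assignment,
      sequence = vapply(out$routes$assignment, function(r)
        paste(out$routes$routes[[r]]$sequence, collapse = " "),
        character(1)))
    utils::write.csv(rows, file.path(spec$outdir, "routes.csv"),
                     row.names = FALSE)
  }
  if (!is.null(out$metrics))
    utils::write.csv(out$metrics, file.path(spec$outdir, "metrics.csv"),
                     row.names = FALSE)
  jsonlite::write_json(out$summary, file.path(spec$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(spec$outdir)
}

#' Write / read a trajectory as CSV
#'
#' Stable column layout \code{t_ms, x_m, y_m, heading_deg, phase}; the
#' events (saccade decisions) go to a sibling \code{*_events.csv}. A
#' provenance comment line records seed and spec hash.
#'
#' @param trajectory a \code{ca_trajectory}.
#' @param path CSV file path.
#' @param provenance optional hash string for the header comment.
#' @return \code{path} invisibly; \code{read_trajectory} returns a
#'   \code{ca_trajectory} (data and events only).
#' @export
write_trajectory <- function(trajectory, path, provenance = NULL) {
  con <- file(path, "w")
  writeLines(sprintf("# comanv trajectory seed=%s result=%s spec=%s",
                     trajectory$seed, trajectory$result,
                     provenance %||% "-"), con)
  utils::write.csv(trajectory$data, con, row.names = FALSE)
  close(con)
  if (nrow(trajectory$events))
    utils::write.csv(trajectory$events,
                     sub("\\.csv$", "_events.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  data <- utils::read.csv(path, comment.char = "#")
  epath <- sub("\\.csv$", "_events.csv", path)
  events <- if (file.exists(epath)) utils::read.csv(epath) else data.frame()
  structure(list(data = data, events = events,
                 result = sub(".*result=(\\S+).*", "\\1",
                              readLines(path, 1)),
                 config = NULL, seed = NA_integer_),
            class = "ca_trajectory")
}

#' Figure-style experiment presets
#'
#' \describe{
#'   \item{box-geometric}{0.4 m cubic box, geometric flow, thresholds as in
#'     the weighting-function exploration (gain 2, threshold 3.2).}
#'   \item{box-textures}{0.4 m cubic box, EMD agent, gain 2 / threshold 4,
#'     4 starts; \code{texture} picks the wall pattern (1, 4, 8 or 35 mm
#'     checks, or 1/f).}
#'   \item{clutter-goal}{cluttered corridor with a goal at the far end,
#'     gain 2 / threshold 4, route clustering and efficiency metrics.}
#' }
#'
#' @param name preset name.
#' @param seed master seed.
#' @param texture wall texture spec for \code{box-textures}.
#' @param flow_source override of the flow source.
#' @param n_starts number of start positions.
#' @param max_time_s simulated time budget per start.
#' @return An \code{experiment_spec}.
#' @export
experiment_preset <- function(name = c("box-geometric", "box-textures",
                                       "clutter-goal"),
                              seed = 1L,
                              texture = list(kind = "checkerboard",
                                             texel_size_mm = 1),
                              flow_source = NULL, n_starts = NULL,
                              max_time_s = NULL) {
  name <- match.arg(name)
  if (name == "box-geometric") {
    env <- env_cubic_box(seed = derive_seed(seed, "texture"))
    cfg <- sim_config("geometric", gain = 2, threshold = 3.2,
                      max_time_s = max_time_s %||% 10)
    experiment_spec(env, cfg, starts = list(n = n_starts %||% 4), seed = seed)
  } else if (name == "box-textures") {
    env <- env_cubic_box(wall_texture = texture,
                         seed = derive_seed(seed, "texture"))
    cfg <- sim_config(flow_source %||% "emd", gain = 2, threshold = 4,
                      max_time_s = max_time_s %||% 10)
    experiment_spec(env, cfg, starts = list(n = n_starts %||% 4), seed = seed)
  } else {
    env <- env_cluttered(derive_seed(seed, "texture"),
                         goal = c(0.85, 0))
    cfg <- sim_config(flow_source %||% "emd", gain = 2, threshold = 4,
                      goal = c(0.85, 0), max_time_s = max_time_s %||% 60)
    experiment_spec(env, cfg, starts = list(n = n_starts %||% 5,
                                            region = "end"),
                    routes = TRUE, efficiency = TRUE, seed = seed)
  }
}
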