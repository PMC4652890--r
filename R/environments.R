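# Virtual flight arenas: axis-aligned textured boxes, optionally containing
# vertical square-base obstacles. Coordinates are in metres; the floor is at
# z = 0 and the (x, y) origin is at the arena centre.

new_environment <- function(kind, lo, hi, has_walls, wall_textures,
                            obstacles = list(), goal = NULL,
                            background = 0.5, config = NULL) {
  for (ob in obstacles) {
    stopifnot(ob$base_edge > 0, ob$height > 0)
    if (has_walls) {
      e <- ob$base_edge / 2
      inside <- ob$center[1] - e > lo[1] && ob$center[1] + e < hi[1] &&
        ob$center[2] - e > lo[2] && ob$center[2] + e < hi[2]
      if (!inside) stop("obstacle extends outside the arena walls")
    }
  }
  structure(list(kind = kind, lo = lo, hi = hi, has_walls = has_walls,
                 wall_textures = wall_textures, obstacles = obstacles,
                 goal = goal, background = background, config = config),
            class = "ca_environment")
}

# resolve a texture spec against a face size; spec is a ca_texture (reused,
# tiled), or a list(kind, texel_size_mm, levels) generated with `seed`
resolve_texture <- function(spec, extent_mm, seed) {
  if (inherits(spec, "ca_texture")) return(spec)
  if (is.character(spec)) spec <- list(kind = spec)
  kind <- spec$kind %||% "checkerboard"
  texel <- spec$texel_size_mm %||% 1
  if (kind == "checkerboard") {
    texture_checkerboard(texel, extent_mm, seed, spec$levels %||% c(0, 1))
  } else if (kind == "one_over_f") {
    texture_one_over_f(extent_mm, seed, texel)
  } else stop("unknown texture kind: ", kind)
}

# face order used throughout: x-, x+, y-, y+, floor (z-), ceiling (z+);
# face-local (u, v) axes are ((a+1) %% 3, (a+2) %% 3) for fixed axis a
face_extents_mm <- function(lo, hi) {
  d <- (hi - lo) * 1000
  list(c(d[2], d[3]), c(d[2], d[3]),   # x walls: u = y, v = z
       c(d[3], d[1]), c(d[3], d[1]),   # y walls: u = z, v = x
       c(d[1], d[2]), c(d[1], d[2]))   # floor / ceiling: u = x, v = y
}

#' Cubic flight arena
#'
#' A closed textured box modelled on classic fly flight arenas: 40 cm cube,
#' patterned side walls, dark-grey floor and light-grey ceiling checks.
#'
#' @param edge inner edge length (m). The 3.9 m tall variant used for
#'   apparent-size controls can be obtained with \code{height}.
#' @param wall_texture texture for the four side walls: a \code{ca_texture}
#'   (tiled over each wall) or a spec list such as
#'   \code{list(kind = "checkerboard", texel_size_mm = 1)}.
#' @param floor_texture,ceiling_texture as \code{wall_texture}; defaults are
#'   8 mm random checks with brightness \{0, 0.5\} and \{1, 0.5\}.
#' @param height wall height (m), defaults to \code{edge}.
#' @param seed master seed for texture generation (one substream per face).
#' @param goal optional goal position c(x, y) (m).
#' @return A \code{ca_environment} with six textured faces and no obstacles.
#' @export
env_cubic_box <- function(edge = 0.4,
                          wall_texture = list(kind = "checkerboard",
                                              texel_size_mm = 8),
                          floor_texture = NULL, ceiling_texture = NULL,
                          height = edge, seed = 1L, goal = NULL) {
  stopifnot(edge > 0, height > 0)
  lo <- c(-edge / 2, -edge / 2, 0)
  hi <- c(edge / 2, edge / 2, height)
  fe <- face_extents_mm(lo, hi)
  floor_texture <- floor_texture %||%
    list(kind = "checkerboard", texel_size_mm = 8, levels = c(0, 0.5))
  ceiling_texture <- ceiling_texture %||%
    list(kind = "checkerboard", texel_size_mm = 8, levels = c(1, 0.5))
  wt <- vector("list", 6)
  for (f in 1:4)
    wt[[f]] <- resolve_texture(wall_texture, fe[[f]],
                               derive_seed(seed, paste0("wall", f)))
  wt[[5]] <- resolve_texture(floor_texture, fe[[5]], derive_seed(seed, "floor"))
  wt[[6]] <- resolve_texture(ceiling_texture, fe[[6]],
                             derive_seed(seed, "ceiling"))
  new_environment("cubic_box", lo, hi, TRUE, wt, goal = goal,
                  config = list(kind = "cubic_box", edge = edge,
                                height = height, seed = seed,
                                wall_texture = texture_recipe(wall_texture),
                                floor_texture = texture_recipe(floor_texture),
                                ceiling_texture = texture_recipe(ceiling_texture),
                                goal = goal))
}

#' Cubic arena with camouflaged vertical obstacles
#'
#' Inserts 0, 1, 2 or 4 vertical bars (3 cm square base, full arena height)
#' covered with the same pattern as the walls: one at the centre, two on one
#' diagonal, or four on both diagonals at 25\% of the edge from the centre.
#'
#' @inheritParams env_cubic_box
#' @param n_objects number of obstacles: 0, 1, 2 or 4.
#' @param texture texture spec used for walls and obstacles alike.
#' @return A \code{ca_environment}.
#' @export
env_object_box <- function(n_objects,
                           texture = list(kind = "checkerboard",
                                          texel_size_mm = 1),
                           edge = 0.4, seed = 1L, goal = NULL) {
  stopifnot(n_objects %in% c(0L, 1L, 2L, 4L))
  env <- env_cubic_box(edge, wall_texture = texture, seed = seed, goal = goal)
  off <- 0.25 * edge
  pos <- switch(as.character(n_objects),
                "0" = matrix(numeric(0), 0, 2),
                "1" = rbind(c(0, 0)),
                "2" = rbind(c(-off, -off), c(off, off)),
                "4" = rbind(c(-off, -off), c(off, off),
                            c(-off, off), c(off, -off)))
  obstacles <- lapply(seq_len(nrow(pos)), function(i) {
    tex <- resolve_texture(texture, c(30, edge * 1000),
                           derive_seed(seed, paste0("obj", i)))
    list(center = pos[i, ], base_edge = 0.03, height = edge, texture = tex)
  })
  env$obstacles <- obstacles
  env$kind <- "object_box"
  env$config <- list(kind = "object_box", n_objects = n_objects, edge = edge,
                     seed = seed, texture = texture_recipe(texture),
                     goal = goal)
  env
}

# object-size rosters of the cluttered corridors (base edges, mm)
clutter_roster <- function(variant = c("first", "second")) {
  variant <- match.arg(variant)
  if (variant == "first")
    rep(c(80, 72, 64, 56, 48, 40), c(5, 5, 10, 5, 5, 5))
  else
    rep(c(80, 72, 64, 56, 48, 40), c(5, 10, 5, 5, 5, 5))
}

#' Cluttered corridor with 35 randomly placed obstacles
#'
#' A 2000 x 1000 x 400 mm box containing 35 vertical obstacles with square
#' bases (height five times the base edge), placed uniformly at random in the
#' inner part of the box (shrunk by 10\% per side) under a minimum clearance
#' of 60 mm between obstacle footprints. All surfaces carry random
#' checkerboards of the same texel size.
#'
#' @param seed integer seed driving placement and textures.
#' @param texel_size_mm checkerboard texel size (1 or 4 mm in the reference
#'   experiments; any positive value is accepted).
#' @param walls if \code{FALSE}, the outer walls, floor and ceiling are
#'   removed (open variant); rays that escape see a uniform background.
#' @param roster \code{"first"} (5/5/10/5/5/5 objects of 80/72/64/56/48/40 mm)
#'   or \code{"second"} (ten 72 mm and five 64 mm objects instead).
#' @param goal optional goal position c(x, y) (m).
#' @param max_tries placement attempts per obstacle before giving up.
#' @return A \code{ca_environment} with 35 obstacles.
#' @export
env_cluttered <- function(seed, texel_size_mm = 1, walls = TRUE,
                          roster = c("first", "second"), goal = NULL,
                          max_tries = 5000L) {
  roster <- match.arg(roster)
  edges_m <- sort(clutter_roster(roster), decreasing = TRUE) / 1000
  lo <- c(-1, -0.5, 0); hi <- c(1, 0.5, 0.4)
  inner <- c(0.1 * (hi[1] - lo[1]), 0.1 * (hi[2] - lo[2]))  # 10% per side
  centers <- matrix(NA_real_, length(edges_m), 2)
  with_seed(derive_seed(seed, "placement"), {
    for (i in seq_along(edges_m)) {
      e <- edges_m[i]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        x <- stats::runif(1, lo[1] + inner[1] + e / 2, hi[1] - inner[1] - e / 2)
        y <- stats::runif(1, lo[2] + inner[2] + e / 2, hi[2] - inner[2] - e / 2)
        ok <- TRUE
        if (i > 1) {
          dx <- abs(centers[seq_len(i - 1), 1] - x)
          dy <- abs(centers[seq_len(i - 1), 2] - y)
          gap <- pmax(dx, dy) - (edges_m[seq_len(i - 1)] + e) / 2
          ok <- all(gap >= 0.060)
        }
        if (ok) { centers[i, ] <- c(x, y); placed <- TRUE; break }
      }
      if (!placed)
        stop("obstacle placement failed after ", max_tries,
             " tries (obstacle ", i, ")")
    }
  })
  fe <- face_extents_mm(lo, hi)
  spec <- list(kind = "checkerboard", texel_size_mm = texel_size_mm)
  wt <- vector("list", 6)
  for (f in 1:6)
    wt[[f]] <- resolve_texture(spec, fe[[f]],
                               derive_seed(seed, paste0("face", f)))
  obstacles <- lapply(seq_along(edges_m), function(i) {
    e <- edges_m[i]
    tex <- resolve_texture(spec, c(e * 1000, 5 * e * 1000),
                           derive_seed(seed, paste0("obj", i)))
    list(center = centers[i, ], base_edge = e, height = 5 * e, texture = tex)
  })
  new_environment("cluttered", lo, hi, walls, wt, obstacles, goal = goal,
                  config = list(kind = "cluttered", seed = seed,
                                texel_size_mm = texel_size_mm, walls = walls,
                                roster = roster, goal = goal))
}

texture_recipe <- function(spec) {
  if (inherits(spec, "ca_texture"))
    list(kind = spec$kind, texel_size_mm = spec$texel_size_mm,
         seed = spec$seed, levels = spec$levels)
  else spec
}

#' @export
print.ca_environment <- function(x, ...) {
  dims <- paste(sprintf("%.2f", x$hi - x$lo), collapse = " x ")
  cat(sprintf("<ca_environment %s: %s m, %s, %d obstacle(s)%s>\n",
              x$kind, dims, if (x$has_walls) "walled" else "open",
              length(x$obstacles),
              if (is.null(x$goal)) ""
              else sprintf(", goal (%.2f, %.2f)", x$goal[1], x$goal[2])))
  invisible(x)
}

#' Mid-height of an arena, the default flight plane
#' @param env a \code{ca_environment}.
#' @return Height in metres.
#' @export
flight_height <- function(env) (env$lo[3] + env$hi[3]) / 2

#' Compile an environment into a ray-castable scene
#'
#' Builds the native scene (textures, summed-area tables, obstacle grid)
#' once; every function taking an environment also accepts the compiled
#' scene, which avoids recompilation in tight loops.
#'
#' @param env a \code{ca_environment}.
#' @param footprint_deg half-angle (deg) of the per-sub-ray texture filter:
#'   each surface lookup averages the texture over a box of half-width
#'   distance * tan(footprint), so sub-resolution texture washes out with
#'   distance as it does optically. 0 switches to raw nearest-texel lookup.
#' @return A \code{ca_scene} wrapping the native scene and the environment.
#' @export
compile_scene <- function(env, footprint_deg = 1.5) {
  stopifnot(inherits(env, "ca_environment"))
  textures <- list()
  add_tex <- function(tex) {
    textures[[length(textures) + 1]] <<-
      list(grid = tex$grid, texel = tex$texel_size_mm / 1000)
    length(textures) - 1L               # 0-based index for the native side
  }
  wall_tex <- vapply(env$wall_textures, add_tex, integer(1))
  boxes <- lapply(env$obstacles, function(ob) {
    e <- ob$base_edge / 2
    list(lo = c(ob$center[1] - e, ob$center[2] - e, env$lo[3]),
         hi = c(ob$center[1] + e, ob$center[2] + e, env$lo[3] + ob$height),
         tex = add_tex(ob$texture))
  })
  ptr <- cpp_scene_build(list(
    textures = textures, has_walls = env$has_walls,
    lo = env$lo, hi = env$hi, wall_tex = as.integer(wall_tex),
    boxes = boxes, background = env$background,
    footprint = footprint_deg))
  structure(list(ptr = ptr, env = env), class = "ca_scene")
}

as_scene <- function(x) {
  if (inherits(x, "ca_scene")) x else compile_scene(x)
}

#' Distance from a point to the nearest surface
#' @param env environment or compiled scene.
#' @param position 3-vector (m).
#' @return Distance in metres (Inf in an empty open scene).
#' @export
surface_distance <- function(env, position) {
  sc <- as_scene(env)
  cpp_scene_distance(sc$ptr, as.numeric(position))
}

#' Write / read an environment recipe as a YAML config
#'
#' Environments are serialized as their generating recipe (kind, sizes,
#' texture specs, seeds), not as raw grids, so configs are small and
#' reproduce the identical arena on read.
#'
#' @param env a \code{ca_environment} built by one of the constructors.
#' @param path file path.
#' @return \code{write_environment} returns \code{path} invisibly;
#'   \code{read_environment} returns the regenerated \code{ca_environment}.
#' @export
write_environment <- function(env, path) {
  if (is.null(env$config)) stop("environment carries no serializable recipe")
  yaml::write_yaml(env$config, path)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  cfg <- yaml::read_yaml(path)
  goal <- if (!is.null(cfg$goal)) as.numeric(unlist(cfg$goal))
  switch(cfg$kind,
    cubic_box = env_cubic_box(cfg$edge, cfg$wall_texture, cfg$floor_texture,
                              cfg$ceiling_texture, height = cfg$height,
                              seed = cfg$seed, goal = goal),
    object_box = env_object_box(cfg$n_objects, cfg$texture, cfg$edge,
                                cfg$seed, goal = goal),
    cluttered = env_cluttered(cfg$seed, cfg$texel_size_mm, cfg$walls,
                              cfg$roster, goal = goal),
    stop("unknown environment kind: ", cfg$kind))
}
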