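# Reliability and path-length efficiency of goal-directed trajectories.
# The benchmark path is the shortest collision-free path on a visibility
# graph over obstacle corners inflated by the collision radius; a
# maximal-clearance (Voronoi-skeleton style) baseline path is computed on an
# occupancy grid.

# inflated obstacle rectangles: list of (xlo, xhi, ylo, yhi)
inflated_rects <- function(env, inflate) {
  lapply(env$obstacles, function(ob) {
    e <- ob$base_edge / 2 + inflate
    c(ob$center[1] - e, ob$center[1] + e, ob$center[2] - e, ob$center[2] + e)
  })
}

# does segment p-q intersect the open rectangle r = (xlo, xhi, ylo, yhi)?
seg_hits_rect <- function(p, q, r, eps = 1e-12) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (ax in 1:2) {
    lo <- r[2 * ax - 1]; hi <- r[2 * ax]
    if (abs(d[ax]) < eps) {
      if (p[ax] <= lo + eps || p[ax] >= hi - eps) return(FALSE)
    } else {
      ta <- (lo - p[ax]) / d[ax]; tb <- (hi - p[ax]) / d[ax]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 >= t1 - eps) return(FALSE)
    }
  }
  TRUE
}

segment_free <- function(p, q, rects) {
  for (r in rects) if (seg_hits_rect(p, q, r)) return(FALSE)
  TRUE
}

#' Shortest collision-free path via a visibility graph
#'
#' Nodes are the start, the goal and the corners of all obstacles inflated by
#' the collision radius (clipped to the walkable interior); edges connect
#' mutually visible nodes, weighted by Euclidean length.
#'
#' @param env a \code{ca_environment}.
#' @param from,to 2-vectors (m).
#' @param inflate obstacle inflation radius (m), normally the collision
#'   radius.
#' @return List with \code{length} (m), the \code{path} matrix of waypoints,
#'   and \code{reachable}.
#' @export
shortest_path_visibility <- function(env, from, to, inflate = 0.01) {
  rects <- inflated_rects(env, inflate)
  margin <- inflate
  xr <- c(env$lo[1] + margin, env$hi[1] - margin)
  yr <- c(env$lo[2] + margin, env$hi[2] - margin)
  corners <- do.call(rbind, lapply(rects, function(r) {
    g <- 1e-9
    rbind(c(r[1] - g, r[3] - g), c(r[2] + g, r[3] - g),
          c(r[1] - g, r[4] + g), c(r[2] + g, r[4] + g))
  }))
  nodes <- rbind(from, to, corners)
  if (env$has_walls) {
    ok <- nodes[, 1] >= xr[1] & nodes[, 1] <= xr[2] &
      nodes[, 2] >= yr[1] & nodes[, 2] <= yr[2]
    ok[1:2] <- TRUE
    nodes <- nodes[ok, , drop = FALSE]
  }
  # drop nodes inside another inflated obstacle
  free <- vapply(seq_len(nrow(nodes)), function(i) {
    p <- nodes[i, ]
    !any(vapply(rects, function(r)
      p[1] > r[1] & p[1] < r[2] & p[2] > r[3] & p[2] < r[4], logical(1)))
  }, logical(1))
  free[1:2] <- TRUE
  nodes <- nodes[free, , drop = FALSE]
  n <- nrow(nodes)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (segment_free(nodes[i, ], nodes[j, ], rects)) {
        ii <- c(ii, i); jj <- c(jj, j)
        ww <- c(ww, sqrt(sum((nodes[i, ] - nodes[j, ])^2)))
      }
  if (!length(ii)) return(list(length = Inf, path = NULL, reachable = FALSE))
  gr <- igraph::graph_from_edgelist(cbind(ii, jj), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
  sp <- suppressWarnings(
    igraph::shortest_paths(gr, 1, 2, weights = ww, output = "vpath"))
  vp <- sp$vpath[[1]]
  if (length(vp) < 2 && !isTRUE(all.equal(as.numeric(from), as.numeric(to))))
    return(list(length = Inf, path = NULL, reachable = FALSE))
  path <- nodes[as.integer(vp), , drop = FALSE]
  len <- sum(sqrt(rowSums(diff(path)^2)))
  list(length = len, path = path, reachable = TRUE)
}

#' Maximal-clearance baseline path (Voronoi-skeleton style)
#'
#' On a regular occupancy grid, finds the largest clearance c* such that a
#' path from start to goal exists through cells with clearance >= c*, then
#' returns the shortest such path. This follows the ridge of the clearance
#' field, the discrete analogue of a Voronoi-skeleton path.
#'
#' @param env a \code{ca_environment}.
#' @param from,to 2-vectors (m).
#' @param resolution grid cell size (m).
#' @return List with \code{length} (m), \code{clearance} (c*, m) and the
#'   \code{path} matrix of grid waypoints.
#' @export
max_clearance_path <- function(env, from, to, resolution = 0.02) {
  xs <- seq(env$lo[1] + resolution / 2, env$hi[1] - resolution / 2,
            by = resolution)
  ys <- seq(env$lo[2] + resolution / 2, env$hi[2] - resolution / 2,
            by = resolution)
  nx <- length(xs); ny <- length(ys)
  cl <- matrix(Inf, nx, ny)
  if (env$has_walls) {
    wx <- pmin(xs - env$lo[1], env$hi[1] - xs)
    wy <- pmin(ys - env$lo[2], env$hi[2] - ys)
    cl <- pmin(matrix(wx, nx, ny), matrix(wy, nx, ny, byrow = TRUE))
  }
  for (ob in env$obstacles) {
    e <- ob$base_edge / 2
    dx <- pmax(abs(xs - ob$center[1]) - e, 0)
    dy <- pmax(abs(ys - ob$center[2]) - e, 0)
    d <- sqrt(outer(dx^2, dy^2, `+`))
    cl <- pmin(cl, d)
  }
  idx <- function(p) c(which.min(abs(xs - p[1])), which.min(abs(ys - p[2])))
  a <- idx(from); b <- idx(to)
  id <- function(i, j) (j - 1L) * nx + i
  # 4-connected adjacency, built once; bottleneck clearance of an edge is the
  # smaller endpoint clearance
  i1 <- rep(seq_len(nx - 1), ny);      j1 <- rep(seq_len(ny), each = nx - 1)
  i2 <- rep(seq_len(nx), ny - 1);      j2 <- rep(seq_len(ny - 1), each = nx)
  efrom <- c(id(i1, j1), id(i2, j2))
  eto <- c(id(i1 + 1L, j1), id(i2, j2 + 1L))
  ecl <- pmin(cl[cbind(c(i1, i2), c(j1, j2))],
              cl[cbind(c(i1 + 1L, i2), c(j1, j2 + 1L))])
  reach <- function(cmin) {
    keep <- ecl >= cmin
    gr <- igraph::make_empty_graph(nx * ny, directed = FALSE)
    gr <- igraph::add_edges(gr, rbind(efrom[keep], eto[keep]))
    cmp <- igraph::components(gr)$membership
    cmp[id(a[1], a[2])] == cmp[id(b[1], b[2])]
  }
  lo <- 0; hi <- max(ecl[is.finite(ecl)])
  if (!reach(0)) return(list(length = Inf, clearance = 0, path = NULL))
  for (k in 1:12) {
    mid <- (lo + hi) / 2
    if (reach(mid)) lo <- mid else hi <- mid
  }
  cstar <- lo
  # shortest 8-connected path through cells with clearance >= c*
  open <- cl >= cstar
  id <- function(i, j) (j - 1L) * nx + i
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  steps <- list(c(1, 0, 1), c(0, 1, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  for (s in steps) {
    i0 <- seq_len(nx - abs(s[1])); j0 <- seq_len(ny - abs(s[2]))
    if (s[2] < 0) j0 <- j0 + abs(s[2])
    for (j in j0) {
      src <- which(open[i0, j])
      if (!length(src)) next
      i <- i0[src]
      k <- j + s[2]
      tgt <- open[i + s[1], k]
      i <- i[tgt]
      if (!length(i)) next
      ii <- c(ii, id(i, j)); jj <- c(jj, id(i + s[1], k))
      ww <- c(ww, rep(s[3] * resolution, length(i)))
    }
  }
  gr <- igraph::make_empty_graph(nx * ny, directed = FALSE)
  gr <- igraph::add_edges(gr, rbind(ii, jj))
  sp <- suppressWarnings(igraph::shortest_paths(
    gr, id(a[1], a[2]), id(b[1], b[2]), weights = ww, output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) < 2)
    return(list(length = Inf, clearance = cstar, path = NULL))
  path <- cbind(xs[(vp - 1L) %% nx + 1L], ys[(vp - 1L) %/% nx + 1L])
  list(length = sum(sqrt(rowSums(diff(path)^2))), clearance = cstar,
       path = path)
}

#' Reliability and efficiency of goal-directed trajectories
#'
#' Classifies each trajectory as goal-reached, crash, or dead-end (timeout);
#' reliability is the percentage of crashes; each goal-reaching trajectory
#' gets an efficiency = shortest collision-free path length / realized path
#' length (in [0, 1], 1 = straight to the goal).
#'
#' @param trajectories list of \code{ca_trajectory}.
#' @param env the \code{ca_environment} they were simulated in.
#' @param goal goal position c(x, y); defaults to the environment goal.
#' @param inflate obstacle inflation for the benchmark paths (m).
#' @param clearance_baseline also compute the maximal-clearance baseline
#'   (slower).
#' @return A data.frame (one row per trajectory: result, realized length,
#'   shortest length, efficiency) with the summary (reliability_pct,
#'   n_goal, n_crash, n_deadend, and optionally baseline lengths) attached
#'   as attribute \code{summary}.
#' @export
efficiency_metrics <- function(trajectories, env, goal = NULL,
                               inflate = 0.01, clearance_baseline = FALSE) {
  goal <- goal %||% env$goal
  stopifnot(!is.null(goal))
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    xy <- cbind(tr$data$x_m, tr$data$y_m)
    lreal <- sum(sqrt(rowSums(diff(xy)^2)))
    if (tr$result == "goal") {
      sp <- shortest_path_visibility(env, xy[1, ], goal, inflate)
      if (!sp$reachable)
        return(data.frame(trajectory = i, result = "unreachable",
                          length_m = lreal, shortest_m = NA_real_,
                          efficiency = NA_real_))
      data.frame(trajectory = i, result = "goal", length_m = lreal,
                 shortest_m = sp$length, efficiency = sp$length / lreal)
    } else {
      data.frame(trajectory = i, result = tr$result, length_m = lreal,
                 shortest_m = NA_real_, efficiency = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  summ <- list(
    n = nrow(out),
    n_goal = sum(out$result == "goal"),
    n_crash = sum(out$result == "crash"),
    n_deadend = sum(out$result == "timeout"),
    reliability_pct = 100 * sum(out$result == "crash") / nrow(out),
    min_efficiency = if (any(out$result == "goal"))
      min(out$efficiency, na.rm = TRUE) else NA_real_)
  if (clearance_baseline && any(out$result == "goal")) {
    i0 <- which(out$result == "goal")[1]
    xy0 <- c(trajectories[[i0]]$data$x_m[1], trajectories[[i0]]$data$y_m[1])
    summ$clearance_baseline_m <- max_clearance_path(env, xy0, goal)$length
  }
  attr(out, "summary") <- summ
  out
}
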