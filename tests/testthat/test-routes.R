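test_that("delaunay meshing handles canonical and degenerate inputs", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  m <- delaunay_mesh(sq)
  expect_equal(nrow(m$triangles), 2)
  m3 <- delaunay_mesh(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_equal(nrow(m3$triangles), 1)
  expect_error(delaunay_mesh(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
  expect_error(delaunay_mesh(rbind(c(0, 0), c(1, 1))))
})

test_that("delaunay triangulations satisfy the empty-circumcircle property", {
  withr::with_seed(8, {
    for (rep in 1:5) {
      pts <- cbind(runif(20), runif(20))
      m <- delaunay_mesh(pts)
      # brute force: no node strictly inside any triangle's circumcircle
      for (k in seq_len(nrow(m$triangles))) {
        t <- m$triangles[k, ]
        p <- pts[t, ]
        d <- 2 * (p[1, 1] * (p[2, 2] - p[3, 2]) +
                    p[2, 1] * (p[3, 2] - p[1, 2]) +
                    p[3, 1] * (p[1, 2] - p[2, 2]))
        sq <- rowSums(p^2)
        ux <- (sq[1] * (p[2, 2] - p[3, 2]) + sq[2] * (p[3, 2] - p[1, 2]) +
                 sq[3] * (p[1, 2] - p[2, 2])) / d
        uy <- (sq[1] * (p[3, 1] - p[2, 1]) + sq[2] * (p[1, 1] - p[3, 1]) +
                 sq[3] * (p[2, 1] - p[1, 1])) / d
        r2 <- (ux - p[1, 1])^2 + (uy - p[1, 2])^2
        inside <- (pts[, 1] - ux)^2 + (pts[, 2] - uy)^2 < r2 - 1e-9
        inside[t] <- FALSE
        expect_false(any(inside))
      }
      # coverage: the triangles tile the convex hull (areas add up)
      tri_area <- sum(vapply(seq_len(nrow(m$triangles)), function(k) {
        p <- pts[m$triangles[k, ], ]
        abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
              (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
      }, numeric(1)))
      hull <- grDevices::chull(pts)
      hp <- pts[hull, ]
      hull_area <- abs(sum(hp[, 1] * hp[c(2:nrow(hp), 1), 2] -
                             hp[c(2:nrow(hp), 1), 1] * hp[, 2])) / 2
      expect_equal(tri_area, hull_area, tolerance = 1e-6)
    }
  })
})

test_that("cell sequences track the crossed triangles", {
  m <- delaunay_mesh(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  inside_one <- cbind(seq(0.2, 0.4, 0.01), 0.1)
  expect_length(cell_sequence(inside_one, m), 1)
  crossing <- cbind(0.5, seq(0.2, 1.8, 0.02))
  expect_equal(length(cell_sequence(crossing, m)), 2)
  # oscillation A,B,A kept in the raw sequence
  osc <- rbind(c(0.5, 0.2), c(0.5, 1.8), c(0.5, 0.2))
  s <- cell_sequence(osc, m)
  expect_length(s, 3)
  expect_equal(s[1], s[3])
  # outside the hull: reserved token 0
  out <- cell_sequence(rbind(c(-1, -1), c(0.5, 0.2)), m)
  expect_equal(out[1], 0)
})

test_that("sequence simplification removes loops and is idempotent", {
  expect_equal(simplify_sequence(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(simplify_sequence(c(1, 2, 1, 3)), c(1, 3))
  expect_equal(simplify_sequence(c(1, 2, 3, 2, 4, 2, 5)), c(1, 2, 5))
  withr::with_seed(2, {
    for (k in 1:20) {
      s <- sample(1:6, 15, replace = TRUE)
      s1 <- simplify_sequence(s)
      expect_false(any(duplicated(s1)))
      expect_identical(simplify_sequence(s1), s1)
      expect_equal(s1[1], s[1])
      expect_equal(s1[length(s1)], s[length(s)])
    }
  })
})

test_that("routes are exact-sequence clusters, largest first", {
  rs <- cluster_routes(list(c(1, 2), c(1, 3), c(1, 2)))
  expect_length(rs$routes, 2)
  expect_equal(rs$routes[[1]]$count, 2)
  expect_equal(rs$routes[[1]]$sequence, c(1, 2))
  expect_equal(rs$assignment, c(1, 2, 1))
  all_diff <- cluster_routes(list(1, 2, 3))
  expect_length(all_diff$routes, 3)
  empty <- cluster_routes(list())
  expect_length(empty$routes, 0)
})

test_that("route distance is the symmetric difference and a pseudo-metric", {
  expect_equal(route_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(route_distance(c(1, 2, 3), c(1, 4, 3)), 2)
  expect_equal(route_distance(c(1, 2), c(3, 4)), 4)
  withr::with_seed(3, {
    seqs <- lapply(1:8, function(i) sample(1:5, sample(1:6, 1),
                                           replace = TRUE))
    for (i in 1:8) for (j in 1:8) {
      dij <- route_distance(seqs[[i]], seqs[[j]])
      expect_equal(dij, route_distance(seqs[[j]], seqs[[i]]))
      if (setequal(seqs[[i]], seqs[[j]])) expect_equal(dij, 0)
      for (k in 1:8)
        expect_lte(dij, route_distance(seqs[[i]], seqs[[k]]) +
                     route_distance(seqs[[k]], seqs[[j]]))
    }
  })
})

test_that("route dendrograms merge identical routes first", {
  tree <- route_dendrogram(list(c(1, 2, 3), c(1, 2, 3), c(7, 8, 9, 10)))
  expect_s3_class(tree, "hclust")
  expect_equal(length(tree$order), 3)
  expect_equal(tree$height[1], 0)
  expect_gt(tree$height[2], 0)
})

test_that("path efficiency compares realized to shortest free paths", {
  env <- env_cubic_box(edge = 1.4, seed = 1, goal = c(0.3, 0))
  # straight synthetic trajectory start -> goal
  straight <- structure(list(
    data = data.frame(t_ms = 1:601, x_m = seq(-0.3, 0.3, 0.001), y_m = 0,
                      heading_deg = 0, phase = "intersaccade"),
    result = "goal"), class = "ca_trajectory")
  # a triangular detour of exactly twice the length (two 0.6 m legs)
  h <- sqrt(0.6^2 - 0.3^2)
  leg1 <- cbind(seq(-0.3, 0, length.out = 300), seq(0, h, length.out = 300))
  leg2 <- cbind(seq(0, 0.3, length.out = 300), seq(h, 0, length.out = 300))
  detour <- structure(list(
    data = data.frame(t_ms = 1:600, x_m = c(leg1[, 1], leg2[, 1]),
                      y_m = c(leg1[, 2], leg2[, 2]), heading_deg = 0,
                      phase = "intersaccade"),
    result = "goal"), class = "ca_trajectory")
  crashed <- structure(list(
    data = data.frame(t_ms = 1:10, x_m = seq(-0.3, -0.29, length.out = 10),
                      y_m = 0, heading_deg = 0, phase = "intersaccade"),
    result = "crash"), class = "ca_trajectory")
  met <- efficiency_metrics(list(straight, detour, crashed), env, c(0.3, 0))
  expect_equal(met$efficiency[1], 1, tolerance = 0.01)
  expect_equal(met$efficiency[2], 0.5, tolerance = 0.01)
  expect_true(is.na(met$efficiency[3]))
  expect_equal(attr(met, "summary")$reliability_pct, 100 / 3)
})

test_that("the visibility graph routes around inflated obstacles", {
  env <- env_object_box(1, edge = 1, seed = 1)   # 3 cm bar at the centre
  sp <- shortest_path_visibility(env, c(-0.3, 0), c(0.3, 0), inflate = 0.01)
  expect_true(sp$reachable)
  expect_gt(sp$length, 0.6)          # must deviate around the bar
  expect_lt(sp$length, 0.66)
  # spot check against a dense-grid search: the visibility path is shorter
  # or equal
  grid <- max_clearance_path(env, c(-0.3, 0), c(0.3, 0), resolution = 0.02)
  expect_lte(sp$length, grid$length + 1e-9)
})
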