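# Route analysis: trajectories through a cluttered arena are encoded as the
# sequence of Delaunay cells (triangles of neighbouring obstacle centres)
# they cross; trajectories sharing the simplified sequence form a route.
# Route similarity is the number of cells not shared (a Hamming-like set
# distance), and performance is quantified by reliability (crash rate) and
# path-length efficiency against a visibility-graph shortest path.

#' Delaunay triangulation of obstacle centres
#'
#' Direct construction by the defining property: a triple of nodes forms a
#' cell exactly when no other node lies strictly inside its circumcircle
#' (tested with the signed in-circle determinant). Co-circular quadruples
#' admit two tilings; candidates are accepted in lexicographic order,
#' rejecting overlaps, so ties resolve deterministically. Quadratic in cell
#' candidates, which is perfectly adequate for obstacle layouts (tens of
#' nodes).
#'
#' @param centers n x 2 matrix of node coordinates (n >= 3, not all
#'   collinear).
#' @return A \code{ca_mesh}: \code{nodes} and \code{triangles} (m x 3 node
#'   indices, each row sorted, rows ordered lexicographically; the row index
#'   is the cell id).
#' @export
delaunay_mesh <- function(centers) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2)
  n <- nrow(centers)
  if (n < 3) stop("need at least 3 points")
  x <- centers[, 1]; y <- centers[, 2]
  scale <- max(abs(centers)) + 1
  a2 <- cbind(x - x[1], y - y[1])
  cross <- a2[2, 1] * a2[, 2] - a2[2, 2] * a2[, 1]
  if (all(abs(cross) < 1e-12 * scale^2)) stop("points are collinear")
  orient <- function(i, j, k)
    (x[j] - x[i]) * (y[k] - y[i]) - (y[j] - y[i]) * (x[k] - x[i])
  sq <- x^2 + y^2
  # signed in-circle determinant of every node against triangle (i, j, k),
  # normalized to the triangle's orientation; > 0 means strictly inside
  incircle_all <- function(i, j, k, o) {
    ax <- x[i] - x; ay <- y[i] - y; as <- sq[i] - sq - 2 * (ax * x + ay * y)
    bx <- x[j] - x; by <- y[j] - y; bs <- sq[j] - sq - 2 * (bx * x + by * y)
    cx <- x[k] - x; cy <- y[k] - y; cs <- sq[k] - sq - 2 * (cx * x + cy * y)
    det <- ax * (by * cs - cy * bs) - ay * (bx * cs - cx * bs) +
      as * (bx * cy - cx * by)
    det * sign(o)
  }
  tol <- 1e-9 * scale^4
  cand <- list()
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    o <- orient(i, j, k)
    if (abs(o) < 1e-12 * scale^2) next
    det <- incircle_all(i, j, k, o)
    det[c(i, j, k)] <- 0
    if (all(det <= tol)) cand[[length(cand) + 1]] <- c(i, j, k)
  }
  if (!length(cand)) stop("points are collinear")
  # greedy lexicographic acceptance; overlapping candidates (co-circular
  # tilings) are dropped
  seg_cross <- function(p1, p2, q1, q2) {
    o1 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
    o2 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
    o3 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
    o4 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
    e <- 1e-14 * scale^2
    (o1 > e) != (o2 > e) && (o1 < -e) != (o2 < -e) &&
      (o3 > e) != (o4 > e) && (o3 < -e) != (o4 < -e)
  }
  inside_tri <- function(tr, qx, qy) {
    s1 <- (x[tr[2]] - x[tr[1]]) * (qy - y[tr[1]]) -
      (y[tr[2]] - y[tr[1]]) * (qx - x[tr[1]])
    s2 <- (x[tr[3]] - x[tr[2]]) * (qy - y[tr[2]]) -
      (y[tr[3]] - y[tr[2]]) * (qx - x[tr[2]])
    s3 <- (x[tr[1]] - x[tr[3]]) * (qy - y[tr[3]]) -
      (y[tr[1]] - y[tr[3]]) * (qx - x[tr[3]])
    e <- 1e-12 * scale^2
    (s1 > e & s2 > e & s3 > e) | (s1 < -e & s2 < -e & s3 < -e)
  }
  overlaps <- function(t1, t2) {
    # shared-edge neighbours never overlap; proper edge crossings or strict
    # containment of a centroid do
    for (e1 in list(c(1, 2), c(2, 3), c(1, 3)))
      for (e2 in list(c(1, 2), c(2, 3), c(1, 3))) {
        a <- t1[e1]; b <- t2[e2]
        if (length(intersect(a, b))) next
        if (seg_cross(centers[a[1], ], centers[a[2], ],
                      centers[b[1], ], centers[b[2], ])) return(TRUE)
      }
    c1 <- colMeans(centers[t1, ]); c2 <- colMeans(centers[t2, ])
    inside_tri(t1, c2[1], c2[2]) || inside_tri(t2, c1[1], c1[2])
  }
  keep <- list()
  for (tr in cand) {
    ok <- TRUE
    for (kp in keep) if (overlaps(kp, tr)) { ok <- FALSE; break }
    if (ok) keep[[length(keep) + 1]] <- tr
  }
  tris <- do.call(rbind, keep)
  tris <- tris[order(tris[, 1], tris[, 2], tris[, 3]), , drop = FALSE]
  structure(list(nodes = centers, triangles = tris), class = "ca_mesh")
}

#' @export
print.ca_mesh <- function(x, ...) {
  cat(sprintf("<ca_mesh: %d nodes, %d triangular cells>\n",
              nrow(x$nodes), nrow(x$triangles)))
  invisible(x)
}

#' Cell sequence of a trajectory
#'
#' Looks up, per sample, the mesh cell containing the (x, y) position;
#' positions outside the convex hull emit the reserved token 0, so detours
#' around the obstacle field still differentiate routes. Consecutive
#' duplicates are collapsed.
#'
#' @param trajectory a \code{ca_trajectory}, or a matrix/data.frame whose
#'   first two columns are x and y (m).
#' @param mesh a \code{ca_mesh}.
#' @return Integer vector of cell ids (row indices of \code{mesh$triangles};
#'   0 = outside), consecutive duplicates removed.
#' @export
cell_sequence <- function(trajectory, mesh) {
  xy <- if (inherits(trajectory, "ca_trajectory"))
    cbind(trajectory$data$x_m, trajectory$data$y_m)
  else as.matrix(trajectory)[, 1:2, drop = FALSE]
  cell <- integer(nrow(xy))
  px <- xy[, 1]; py <- xy[, 2]
  for (k in seq_len(nrow(mesh$triangles))) {
    t <- mesh$triangles[k, ]
    ax <- mesh$nodes[t[1], 1]; ay <- mesh$nodes[t[1], 2]
    bx <- mesh$nodes[t[2], 1]; by <- mesh$nodes[t[2], 2]
    cx <- mesh$nodes[t[3], 1]; cy <- mesh$nodes[t[3], 2]
    d1 <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    d2 <- (cx - bx) * (py - by) - (cy - by) * (px - bx)
    d3 <- (ax - cx) * (py - cy) - (ay - cy) * (px - cx)
    inside <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
    cell[inside & cell == 0L] <- k
  }
  r <- rle(cell)$values
  r
}

#' Remove multiple visits from a cell sequence
#'
#' Scanning from the front, everything between the first and last occurrence
#' of a recurring element is suppressed (one copy kept); applied to
#' convergence so no id appears twice. Idempotent.
#'
#' @param seq vector of cell ids.
#' @return Simplified sequence.
#' @export
simplify_sequence <- function(seq) {
  i <- 1L
  while (i <= length(seq)) {
    last <- max(which(seq == seq[i]))
    if (last > i)
      seq <- c(seq[seq_len(i)],
               if (last < length(seq)) seq[(last + 1L):length(seq)])
    i <- i + 1L
  }
  rle(seq)$values
}

#' Cluster trajectories into routes
#'
#' Trajectories sharing exactly the same simplified cell sequence form one
#' route.
#'
#' @param sequences list of (simplified) cell-id vectors.
#' @return A \code{ca_routes}: \code{routes} (list with \code{sequence},
#'   \code{members}, \code{count}, ordered by descending membership then
#'   lexicographic sequence) and \code{assignment} (route id per input).
#' @export
cluster_routes <- function(sequences) {
  if (!length(sequences))
    return(structure(list(routes = list(), assignment = integer(0)),
                     class = "ca_routes"))
  keys <- vapply(sequences, paste, character(1), collapse = ",")
  uk <- unique(keys)
  counts <- vapply(uk, function(k) sum(keys == k), integer(1))
  ord <- order(-counts, uk)
  uk <- uk[ord]
  routes <- lapply(seq_along(uk), function(i) {
    members <- which(keys == uk[i])
    list(sequence = sequences[[members[1]]], members = members,
         count = length(members))
  })
  assignment <- match(keys, uk)
  structure(list(routes = routes, assignment = assignment),
            class = "ca_routes")
}

#' @export
print.ca_routes <- function(x, ...) {
  cat(sprintf("<ca_routes: %d trajectories in %d route(s)>\n",
              length(x$assignment), length(x$routes)))
  for (i in seq_along(x$routes))
    cat(sprintf("  route %d (%d): %s\n", i, x$routes[[i]]$count,
                paste(x$routes[[i]]$sequence, collapse = " ")))
  invisible(x)
}

#' Route distance: cells not shared by two routes
#'
#' Size of the symmetric difference of the two sequences' cell sets.
#'
#' @param a,b cell-id vectors.
#' @return Non-negative integer.
#' @export
route_distance <- function(a, b) {
  length(setdiff(unique(a), unique(b))) +
    length(setdiff(unique(b), unique(a)))
}

#' Dendrogram of route similarity
#'
#' Agglomerative clustering (average linkage) on the pairwise route-distance
#' matrix. Routes from different runs (e.g. different textures over the same
#' obstacle layout) can be pooled by concatenating their sequences lists.
#'
#' @param x a \code{ca_routes} or a list of cell sequences.
#' @param labels optional leaf labels.
#' @return An \code{\link[stats]{hclust}} tree.
#' @export
route_dendrogram <- function(x, labels = NULL) {
  seqs <- if (inherits(x, "ca_routes"))
    lapply(x$routes, `[[`, "sequence") else x
  n <- length(seqs)
  if (n < 2) stop("need at least two routes")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- route_distance(seqs[[i]], seqs[[j]])
  dimnames(d) <- list(labels %||% paste0("route", seq_len(n)),
                      labels %||% paste0("route", seq_len(n)))
  stats::hclust(stats::as.dist(d), method = "average")
}
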