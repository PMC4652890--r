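# Panoramic sampling of the environment onto the spherical eye, ground-truth
# nearness, and the geometric optic-flow benchmark.

#' Cast rays from a point
#'
#' @param env environment or compiled scene.
#' @param origin 3-vector (m), inside the environment.
#' @param directions n x 3 matrix of unit direction vectors (world frame).
#' @return A data.frame with \code{distance} (m; Inf when a ray escapes an
#'   open scene) and \code{brightness} (texel value of the hit surface, or
#'   the background brightness for escaped rays).
#' @export
cast_ray <- function(env, origin, directions) {
  sc <- as_scene(env)
  if (is.null(dim(directions))) directions <- matrix(directions, 1)
  r <- cpp_cast_rays(sc$ptr, as.numeric(origin), directions)
  data.frame(distance = r$distance, brightness = r$brightness)
}

#' Render the panoramic brightness image seen from a pose
#'
#' Each receptor value is the Gaussian-weighted (sigma = 2 deg, truncated at
#' 2 sigma) average of \code{n_subrays} ray casts around the receptor
#' direction, using a fixed deterministic sub-ray stencil.
#'
#' @param env environment or compiled scene.
#' @param pose a \code{ca_pose} (position and heading are used).
#' @param n_subrays sub-rays per receptor (1 disables the optical blur).
#' @return 91 x 181 matrix of brightness values in [0, 1], rows spanning
#'   elevation -90..90 deg, columns azimuth -180..180 deg relative to the
#'   heading.
#' @export
render_view <- function(env, pose, n_subrays = 13) {
  sc <- as_scene(env)
  g <- retina_geometry()
  st <- render_stencil(n_subrays)
  cpp_render(sc$ptr, pose$position, pose$heading_deg * pi / 180,
             st$dirs, st$weights, g$nrow, g$ncol)
}

#' Ground-truth nearness map
#'
#' Inverse distance along the central ray of every viewing direction (no
#' blur). Directions that escape an open environment get nearness 0.
#'
#' @param env environment or compiled scene.
#' @param position 3-vector (m).
#' @param heading_deg heading defining the body frame of the grid.
#' @return 91 x 181 matrix of nearness (1/m).
#' @export
nearness_truth <- function(env, position, heading_deg = 0) {
  sc <- as_scene(env)
  g <- retina_geometry()
  d <- cpp_distances(sc$ptr, as.numeric(position), heading_deg * pi / 180,
                     g$dir, g$nrow, g$ncol)
  mu <- 1 / d
  mu[!is.finite(mu)] <- 0
  mu
}

#' Geometric (ground-truth) optic flow
#'
#' Apparent angular velocity induced by the pose's self-motion given a
#' nearness map, projected on the local (azimuth, elevation) basis. For a
#' pure translation at speed v in body direction delta the components reduce
#' to \code{OF_phi = v * mu * sin(phi - delta)} and
#' \code{OF_eps = v * mu * sin(eps) * cos(phi - delta)}; a yaw rotation adds
#' \code{-omega * cos(eps)} to the azimuthal component.
#'
#' @param nearness 91 x 181 nearness map (1/m) in the body frame of the pose.
#' @param pose a \code{ca_pose}; \code{speed}, \code{motion_dir_deg} and
#'   \code{yaw_rate_dps} define the self-motion.
#' @return List with 91 x 181 matrices \code{h} (azimuthal component) and
#'   \code{v} (elevational component), rad/s.
#' @export
geometric_flow <- function(nearness, pose) {
  g <- retina_geometry()
  stopifnot(all(dim(nearness) == c(g$nrow, g$ncol)))
  delta <- pose$motion_dir_deg * pi / 180
  omega <- pose$yaw_rate_dps * pi / 180
  vmu <- pose$speed * nearness
  list(h = vmu * sin(g$phi - delta) - omega * cos(g$eps),
       v = vmu * sin(g$eps) * cos(g$phi - delta))
}

#' Export a retina-grid matrix as CSV or scaled grayscale PNG
#'
#' @param x 91 x 181 matrix (brightness or nearness).
#' @param path output file; format chosen by extension (.csv or .png).
#' @return \code{path}, invisibly. PNG output is min-max scaled.
#' @export
write_retina_matrix <- function(x, path) {
  if (grepl("\\.png$", path)) {
    rng <- range(x, finite = TRUE)
    scaled <- (x - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    png::writePNG(pmin(pmax(scaled, 0), 1), path)
  } else {
    utils::write.table(x, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
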