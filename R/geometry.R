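# Spherical retina geometry: a cylindrical-projection grid of viewing
# directions, 2 deg spacing, 91 elevation rows (-90..+90, equator at 0) and
# 181 azimuth columns (-180..+180, the two end columns are the same physical
# direction). Azimuth 0 is the agent's heading; positive azimuth is
# counter-clockwise seen from above.

#' Retina sampling geometry
#'
#' Builds the fixed grid of viewing directions of the spherical eye together
#' with the local flow basis. All grids in the package are 91 x 181 matrices
#' whose element \code{[i, j]} belongs to elevation \code{eps_deg[i]} and
#' azimuth \code{phi_deg[j]}.
#'
#' @return An object of class \code{ca_retina} with elements
#'   \item{eps_deg, phi_deg}{row / column angles in degrees.}
#'   \item{dir}{n x 3 matrix of body-frame unit viewing directions, receptors
#'     in column-major grid order.}
#'   \item{e_phi, e_eps}{n x 3 matrices with the local unit basis along
#'     increasing azimuth and elevation.}
#'   \item{mask}{logical 91 x 181 matrix, TRUE for rows excluded from nearness
#'     estimation (the poles).}
#' @export
retina_geometry <- function() {
  if (!is.null(.comanv_cache$retina)) return(.comanv_cache$retina)
  eps_deg <- seq(-90, 90, by = 2)
  phi_deg <- seq(-180, 180, by = 2)
  nr <- length(eps_deg); nc <- length(phi_deg)
  eps <- matrix(eps_deg * pi / 180, nr, nc)
  phi <- matrix(phi_deg * pi / 180, nr, nc, byrow = TRUE)
  dir <- cbind(c(cos(eps) * cos(phi)), c(cos(eps) * sin(phi)), c(sin(eps)))
  e_phi <- cbind(c(-sin(phi)), c(cos(phi)), rep(0, nr * nc))
  e_eps <- cbind(c(-sin(eps) * cos(phi)), c(-sin(eps) * sin(phi)), c(cos(eps)))
  mask <- matrix(FALSE, nr, nc)
  mask[c(1, nr), ] <- TRUE          # pole rows: degenerate azimuth
  rotz <- function(m, heading_deg) {
    ch <- cos(heading_deg * pi / 180); sh <- sin(heading_deg * pi / 180)
    cbind(ch * m[, 1] - sh * m[, 2], sh * m[, 1] + ch * m[, 2], m[, 3])
  }
  g <- structure(list(
    eps_deg = eps_deg, phi_deg = phi_deg, nrow = nr, ncol = nc,
    eps = eps, phi = phi, dir = dir, e_phi = e_phi, e_eps = e_eps,
    mask = mask,
    dir_world = function(heading_deg) rotz(dir, heading_deg),
    e_phi_world = function(heading_deg) rotz(e_phi, heading_deg),
    e_eps_world = function(heading_deg) rotz(e_eps, heading_deg)),
    class = "ca_retina")
  .comanv_cache$retina <- g
  g
}

# Gaussian sub-ray stencil used by the renderer: body-frame unit vectors for
# every receptor and sub-ray (receptor-major), plus normalized weights. The
# blur emulates the optics: sigma = 2 deg, truncated at 2 sigma. Sub-rays sit
# on rings at 1 and 2 sigma around the receptor axis.
render_stencil <- function(n_subrays = 13, sigma_deg = 2) {
  key <- paste0("stencil", n_subrays, "_", sigma_deg)
  if (!is.null(.comanv_cache[[key]])) return(.comanv_cache[[key]])
  stopifnot(n_subrays >= 1)
  g <- retina_geometry()
  if (n_subrays == 1) {
    off <- cbind(0, 0)
  } else if (n_subrays < 10) {
    k <- n_subrays - 1
    off <- rbind(c(0, 0), cbind(1, seq(0, 360 - 360 / k, by = 360 / k)))
  } else {
    k1 <- floor((n_subrays - 1) / 2); k2 <- n_subrays - 1 - k1
    off <- rbind(
      c(0, 0),
      cbind(1, seq(0, 360 - 360 / k1, by = 360 / k1)),
      cbind(2, seq(0, 360 - 360 / k2, by = 360 / k2) + 180 / k2))
  }
  r <- off[, 1] * sigma_deg * pi / 180
  th <- off[, 2] * pi / 180
  w <- exp(-(off[, 1] * sigma_deg)^2 / (2 * sigma_deg^2))
  w <- w / sum(w)
  ns <- length(r)
  n <- nrow(g$dir)
  dirs <- matrix(0, n * ns, 3)
  for (s in seq_len(ns)) {
    d <- cos(r[s]) * g$dir +
      sin(r[s]) * (cos(th[s]) * g$e_phi + sin(th[s]) * g$e_eps)
    dirs[seq(s, by = ns, length.out = n), ] <- d
  }
  # transposed so the native side reads contiguous (x, y, z) triplets
  st <- list(dirs = t(dirs), weights = w, n_subrays = ns)
  .comanv_cache[[key]] <- st
  st
}

#' Agent pose
#'
#' @param position numeric 2- or 3-vector (m); a 2-vector is completed with
#'   the flight height given in \code{height}.
#' @param heading_deg yaw of the body axis, degrees, counter-clockwise from
#'   the world x axis.
#' @param speed translation speed (m/s).
#' @param motion_dir_deg direction of the translation relative to the heading
#'   (degrees); 0 is straight ahead.
#' @param yaw_rate_dps yaw velocity (deg/s).
#' @param height flight height (m) used when \code{position} has length 2.
#' @return A \code{ca_pose} list.
#' @export
make_pose <- function(position, heading_deg = 0, speed = 0.1,
                      motion_dir_deg = 0, yaw_rate_dps = 0, height = 0.2) {
  if (length(position) == 2) position <- c(position, height)
  stopifnot(length(position) == 3)
  structure(list(position = as.numeric(position),
                 heading_deg = heading_deg, speed = speed,
                 motion_dir_deg = motion_dir_deg,
                 yaw_rate_dps = yaw_rate_dps), class = "ca_pose")
}
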