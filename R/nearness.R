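# From integrated squared optic flow to steering: relative nearness map,
# azimuthal profile, COMANV, collision avoidance direction (CAD) and
# necessity (CAN), sigmoid weighting, and the saccade command.

# default mapping from (squared) EMD units to geometric-equivalent 1/s units;
# obtained once by matching EMD-derived CAN to geometric CAN in the reference
# condition (camouflaged 3 cm object at 0.1 m clearance, 1 mm checks,
# standard intersaccade) -- see emd_calibration().
EMD_CALIBRATION_DEFAULT <- 9532

#' Accumulate squared optic flow over a time window
#'
#' Squares each flow (or correlator response) field and averages over the
#' ticks of the window. Correlator fields (91 x 180 horizontal, 90 x 181
#' vertical) are first re-gridded to receptor positions by averaging the two
#' flanking detectors (azimuth wraps; the top/bottom rows use their single
#' flanking vertical detector).
#'
#' @param fields list of per-tick fields, each a list with \code{h} and
#'   \code{v} matrices: either 91 x 181 flow components (rad/s, source
#'   "geometric") or correlator responses (source "emd").
#' @param source \code{"geometric"} or \code{"emd"}.
#' @return An \code{integrated_squared_flow} list with 91 x 181 matrices
#'   \code{h}, \code{v} (time-averaged squared components), the tick count
#'   \code{n} and the \code{source} tag.
#' @export
accumulate_squared_flow <- function(fields, source = c("geometric", "emd")) {
  source <- match.arg(source)
  stopifnot(length(fields) >= 1)
  g <- retina_geometry()
  hs <- matrix(0, g$nrow, g$ncol); vs <- hs
  for (f in fields) {
    if (source == "emd") f <- regrid_emd(f, g)
    hs <- hs + f$h^2
    vs <- vs + f$v^2
  }
  structure(list(h = hs / length(fields), v = vs / length(fields),
                 n = length(fields), source = source),
            class = "integrated_squared_flow")
}

# signed mean of the two flanking detectors at each receptor
regrid_emd <- function(f, g = retina_geometry()) {
  nr <- g$nrow; nc <- g$ncol
  stopifnot(all(dim(f$h) == c(nr, nc - 1)), all(dim(f$v) == c(nr - 1, nc)))
  h <- 0.5 * (f$h[, c(nc - 1, seq_len(nc - 1))] +
              f$h[, c(seq_len(nc - 1), 1)])
  v <- rbind(f$v[1, ],
             0.5 * (f$v[-(nr - 1), ] + f$v[-1, ]),
             f$v[nr - 1, ])
  list(h = h, v = v)
}

#' Relative nearness map from integrated squared flow
#'
#' Applies the retinotopically modified norm: the relative nearness
#' (speed times inverse distance) obeys
#' \code{(v mu)^2 = OF_phi^2 + OF_eps^2 / sin(eps)^2} for planar motion on a
#' spherical eye, independent of the viewing angle, so no correction for the
#' motion direction is needed and mixing motion directions within the window
#' removes the FOE/FOC singularities. The equator row (where the identity is
#' singular) is interpolated from the two neighbouring rows, or excluded when
#' \code{equator = "exclude"}; the pole rows are always masked.
#'
#' @param isf an \code{integrated_squared_flow}.
#' @param calibration scale factor applied to the square root; defaults to 1
#'   for geometric sources and to the package EMD calibration constant (see
#'   \code{\link{emd_calibration}}) for EMD sources.
#' @param equator \code{"interpolate"} (default) or \code{"exclude"}.
#' @param correction_floor_deg the 1/sin(eps)^2 correction of the vertical
#'   component is clamped at this elevation: below it, correlator noise and
#'   the aperture leakage of horizontal contrast edges would be amplified by
#'   up to three orders of magnitude. Defaults to 0 (exact identity) for
#'   geometric sources and 20 degrees for EMD sources.
#' @return A \code{relative_nearness} list: \code{map} (91 x 181, units 1/s
#'   for geometric sources), logical \code{mask} of excluded rows, and the
#'   source tag.
#' @export
nearness_from_integrated <- function(isf, calibration = NULL,
                                     equator = c("interpolate", "exclude"),
                                     correction_floor_deg = NULL) {
  equator <- match.arg(equator)
  g <- retina_geometry()
  calibration <- calibration %||%
    if (isf$source == "emd") EMD_CALIBRATION_DEFAULT else 1
  correction_floor_deg <- correction_floor_deg %||%
    if (isf$source == "emd") 20 else 0
  s2 <- pmax(sin(g$eps)^2, sin(correction_floor_deg * pi / 180)^2)
  eq <- which(g$eps_deg == 0)
  s2[eq, ] <- pmax(s2[eq, ], 1)                     # placeholder, row replaced
  vmu <- calibration * sqrt(isf$h + isf$v / s2)
  mask <- g$mask
  if (equator == "interpolate") {
    vmu[eq, ] <- (vmu[eq - 1, ] + vmu[eq + 1, ]) / 2
  } else {
    mask[eq, ] <- TRUE
  }
  vmu[mask] <- NA_real_
  structure(list(map = vmu, mask = mask, source = isf$source,
                 calibration = calibration), class = "relative_nearness")
}

#' Average a nearness map along the elevation
#'
#' For geometric maps this is the plain mean over unmasked rows. For
#' EMD-derived maps the rows are combined by inverse-variance weights
#' proportional to sin(eps)^2: the retinotopic correction divides the
#' vertical flow component by sin(eps)^2, so correlator noise in
#' near-equator rows is amplified by up to three orders of magnitude, and an
#' unweighted mean would be dominated by it.
#'
#' @param nearness a \code{relative_nearness} (or a plain 91 x 181 matrix,
#'   in which case only the pole rows are excluded).
#' @param weighting \code{"uniform"}, \code{"sin"} or \code{"sin2"}; the
#'   default picks \code{"sin2"} for EMD sources, \code{"uniform"}
#'   otherwise.
#' @return An \code{azimuthal_profile}: numeric vector of 180 bins (2 deg
#'   each, duplicate +180 column dropped) with attribute \code{phi_deg}.
#' @export
vertical_average <- function(nearness, weighting = NULL) {
  g <- retina_geometry()
  if (inherits(nearness, "relative_nearness")) {
    m <- nearness$map; mask <- nearness$mask
    weighting <- weighting %||%
      if (identical(nearness$source, "emd")) "sin2" else "uniform"
  } else {
    m <- nearness; mask <- g$mask
    weighting <- weighting %||% "uniform"
  }
  if (any(colSums(!mask) == 0)) stop("a fully masked azimuth column")
  w <- if (weighting %in% c("sin", "sin2")) {
    s2 <- if (weighting == "sin2") sin(g$eps)^2 else abs(sin(g$eps))
    # the (interpolated) equator row inherits the weight of its neighbours
    s2[g$eps_deg == 0, ] <- s2[g$eps_deg == 2, ]
    s2
  } else matrix(1, g$nrow, g$ncol)
  w[mask] <- 0
  m[mask] <- 0
  p <- (colSums(m * w) / colSums(w))[seq_len(g$ncol - 1)]
  structure(p, phi_deg = g$phi_deg[seq_len(g$ncol - 1)],
            class = "azimuthal_profile")
}

#' Center-of-mass average nearness vector (COMANV)
#'
#' Vector sum over azimuth of the elevation-averaged relative nearness,
#' each bin contributing its value along its viewing direction. The COMANV
#' points toward the average direction of close surfaces; its norm grows
#' with their nearness and apparent size.
#'
#' @param profile an \code{azimuthal_profile} (180 bins).
#' @return Numeric 2-vector (x = ahead, y = left), same units as the profile.
#' @export
comanv <- function(profile) {
  phi <- attr(profile, "phi_deg") * pi / 180
  stopifnot(length(profile) == 180)
  c(sum(profile * cos(phi)), sum(profile * sin(phi)))
}

#' Collision avoidance direction and necessity
#'
#' @param comanv_vec 2-vector from \code{\link{comanv}}.
#' @return List with \code{cad} (degrees relative to heading, wrapped to
#'   (-180, 180]; the direction opposite the COMANV) and \code{can} (the
#'   COMANV norm). A zero vector yields cad = 0 with can = 0 (the weight is
#'   then 0, so the value is never acted upon).
#' @export
cad_can <- function(comanv_vec) {
  can <- sqrt(sum(comanv_vec^2))
  cad <- if (can == 0) 0 else
    wrap_angle(atan2(comanv_vec[2], comanv_vec[1]) * 180 / pi + 180)
  list(cad = cad, can = can)
}

#' Sigmoid weighting of the collision avoidance necessity
#'
#' \code{W = 1 / (1 + (CAN / n0)^(-g))}: 0 at CAN = 0, 1/2 at the threshold
#' n0, approaching 1 for large CAN. \code{n0 = 0} forces W = 1 for any
#' positive CAN (avoidance always fully engaged).
#'
#' @param can collision avoidance necessity (norm of the COMANV).
#' @param gain sigmoid gain g (> 0).
#' @param threshold sigmoid threshold n0 (>= 0).
#' @return Weight(s) in [0, 1].
#' @export
avoidance_weight <- function(can, gain, threshold) {
  stopifnot(gain > 0, threshold >= 0)
  if (threshold == 0) return(as.numeric(can > 0))
  w <- 1 / (1 + (can / threshold)^(-gain))
  w[can == 0] <- 0
  w
}

#' Saccade amplitude from avoidance and goal terms
#'
#' \code{gamma = W * CAD + (1 - W) * wrap(alpha + sigma)}: a compromise,
#' gated by the weight, between turning away from obstacles and turning
#' toward the goal direction alpha (alpha = 0 keeps the previous course).
#'
#' @param cad collision avoidance direction (deg, relative to heading).
#' @param weight weight in [0, 1] from \code{\link{avoidance_weight}}.
#' @param alpha goal direction (deg, relative to heading).
#' @param sigma_sd standard deviation of the optional zero-mean Gaussian
#'   goal-direction noise (deg); 0 disables it.
#' @return Saccade amplitude gamma in degrees (positive = counter-clockwise).
#' @export
saccade_command <- function(cad, weight, alpha = 0, sigma_sd = 0) {
  sigma <- if (sigma_sd > 0) stats::rnorm(1, 0, sigma_sd) else 0
  weight * cad + (1 - weight) * wrap_angle(alpha + sigma)
}

#' Control output from an integrated squared flow field
#'
#' Convenience chain: nearness map, elevation average, COMANV, CAD/CAN,
#' weight and saccade amplitude.
#'
#' @param isf an \code{integrated_squared_flow}.
#' @param gain,threshold sigmoid parameters of the weighting.
#' @param alpha goal direction (deg, relative to heading).
#' @param sigma_sd goal-direction noise SD (deg).
#' @param calibration optional override of the nearness calibration.
#' @return List with \code{comanv}, \code{cad}, \code{can}, \code{weight},
#'   \code{gamma}, \code{alpha} and the intermediate \code{profile}.
#' @export
control_step <- function(isf, gain = 2, threshold = 4, alpha = 0,
                         sigma_sd = 0, calibration = NULL) {
  nm <- nearness_from_integrated(isf, calibration)
  prof <- vertical_average(nm)
  cv <- comanv(prof)
  cc <- cad_can(cv)
  w <- avoidance_weight(cc$can, gain, threshold)
  gamma <- saccade_command(cc$cad, w, alpha, sigma_sd)
  list(comanv = cv, cad = cc$cad, can = cc$can, weight = w, gamma = gamma,
       alpha = alpha, profile = prof)
}
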