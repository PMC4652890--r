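# Correlation-type elementary motion detector (Reichardt-Hassenstein) front
# end: photoreceptor temporal filtering, DC-removing high-pass, and
# mirror-symmetric correlators between azimuth- and elevation-adjacent
# receptors. All temporal filters use exact exponential (zero-order-hold)
# updates, so the configured time constants hold irrespective of dt.

#' EMD front-end parameters
#'
#' @param tau_pr photoreceptor low-pass time constant (ms). The reference
#'   photoreceptor kernel is a measured band-pass with a DC component; here a
#'   first-order low-pass with unity DC gain stands in (the following 20 ms
#'   high-pass removes the DC exactly as required), and the time constant is
#'   pluggable.
#' @param tau_hp high-pass time constant (ms).
#' @param tau_lp correlator delay-branch low-pass time constant (ms).
#' @param dt_ms simulation step (ms).
#' @return An \code{emd_params} list (also carries the grid size).
#' @export
emd_params <- function(tau_pr = 8, tau_hp = 20, tau_lp = 35, dt_ms = 1) {
  stopifnot(tau_pr > 0, tau_hp > 0, tau_lp > 0, dt_ms > 0)
  g <- retina_geometry()
  structure(list(tau_pr = tau_pr, tau_hp = tau_hp, tau_lp = tau_lp,
                 dt_ms = dt_ms, nrow = g$nrow, ncol = g$ncol),
            class = "emd_params")
}

#' Initialize (or reset) the filter states of the EMD cascade
#'
#' @param params an \code{emd_params}.
#' @return List of zero state matrices: \code{pr} (photoreceptor low-pass),
#'   \code{hp_lp} (low-pass tracked by the high-pass stage), \code{lp}
#'   (correlator delay branch).
#' @export
emd_state_init <- function(params = emd_params()) {
  z <- matrix(0, params$nrow, params$ncol)
  list(pr = z, hp_lp = z, lp = z)
}

#' Photoreceptor stage: temporal low-pass with unity DC gain
#'
#' @param image 91 x 181 brightness matrix.
#' @param state state list from \code{\link{emd_state_init}}.
#' @param params an \code{emd_params}.
#' @return List with the filtered \code{image} and the updated \code{state}.
#' @export
photoreceptor_stage <- function(image, state, params = emd_params()) {
  stopifnot(all(dim(image) == c(params$nrow, params$ncol)))
  a <- exp(-params$dt_ms / params$tau_pr)
  state$pr <- a * state$pr + (1 - a) * image
  list(image = state$pr, state = state)
}

#' High-pass stage: removes the DC component (time constant 20 ms)
#'
#' Implemented as the input minus its tracked low-pass, the exact discrete
#' first-order high-pass: constant inputs decay to zero.
#'
#' @inheritParams photoreceptor_stage
#' @return List with the detrended \code{image} and the updated \code{state}.
#' @export
highpass_stage <- function(image, state, params = emd_params()) {
  a <- exp(-params$dt_ms / params$tau_hp)
  state$hp_lp <- a * state$hp_lp + (1 - a) * image
  list(image = image - state$hp_lp, state = state)
}

#' Correlator step
#'
#' For each pair of adjacent receptors (A, B) the response is
#' \code{LP(A) * HP(B) - LP(B) * HP(A)}, where HP is the high-passed signal
#' and LP its 35 ms low-pass (the delay branch); the two mirror-symmetric
#' subunits are the two products. Horizontal detectors pair azimuth
#' neighbours (positive = motion toward increasing azimuth, i.e.
#' front-to-back on the left eye); vertical detectors pair elevation
#' neighbours (positive = upward).
#'
#' @param detrended 91 x 181 high-passed image (output of
#'   \code{\link{highpass_stage}}).
#' @param state state list (the \code{lp} entry is advanced).
#' @param params an \code{emd_params}.
#' @return List with \code{h} (91 x 180 horizontal responses), \code{v}
#'   (90 x 181 vertical responses) and the updated \code{state}.
#' @export
emd_step <- function(detrended, state, params = emd_params()) {
  a <- exp(-params$dt_ms / params$tau_lp)
  state$lp <- a * state$lp + (1 - a) * detrended
  D <- state$lp; H <- detrended
  nc <- params$ncol; nr <- params$nrow
  h <- D[, -nc] * H[, -1] - D[, -1] * H[, -nc]
  v <- D[-nr, ] * H[-1, ] - D[-1, ] * H[-nr, ]
  list(h = h, v = v, state = state)
}

#' Run the full EMD cascade over an image stream
#'
#' Convenience wrapper: feeds one image per tick through photoreceptor,
#' high-pass and correlator stages.
#'
#' @param images list of 91 x 181 brightness matrices (one per tick).
#' @param params an \code{emd_params}.
#' @param state optional initial state (defaults to all-zero).
#' @return List with \code{responses} (list of per-tick \code{h}/\code{v}
#'   response fields) and the final \code{state}.
#' @export
emd_run <- function(images, params = emd_params(), state = NULL) {
  state <- state %||% emd_state_init(params)
  responses <- vector("list", length(images))
  for (t in seq_along(images)) {
    s1 <- photoreceptor_stage(images[[t]], state, params)
    s2 <- highpass_stage(s1$image, s1$state, params)
    s3 <- emd_step(s2$image, s2$state, params)
    state <- s3$state
    responses[[t]] <- list(h = s3$h, v = s3$v)
  }
  list(responses = responses, state = state)
}
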