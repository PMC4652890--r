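# shared fixtures: tiny environments built in code

uniform_texture <- function(value = 0.7, n = 8, texel_mm = 50) {
  comanv:::new_texture(matrix(value, n, n), texel_mm, "checkerboard", 1L)
}

uniform_box <- function(value = 0.7, edge = 0.4) {
  tex <- uniform_texture(value)
  env_cubic_box(edge, wall_texture = tex, floor_texture = tex,
                ceiling_texture = tex, seed = 1L)
}

check_box <- function(texel_mm = 8, seed = 1L, edge = 0.4) {
  env_cubic_box(edge, wall_texture = list(kind = "checkerboard",
                                          texel_size_mm = texel_mm),
                seed = seed)
}

# standard 50-segment mixed-direction accumulation of analytic flow over a
# constant-nearness sphere (radius r, speed v)
sphere_isf <- function(r = 0.2, v = 0.1, n_seg = 50, sd_deg = 18, seed = 1) {
  g <- retina_geometry()
  mu <- matrix(1 / r, g$nrow, g$ncol)
  withr::with_seed(seed, {
    deltas <- rnorm(n_seg, 0, sd_deg)
    fields <- lapply(deltas, function(d)
      geometric_flow(mu, make_pose(c(0, 0), 0, speed = v,
                                   motion_dir_deg = d)))
    accumulate_squared_flow(fields, "geometric")
  })
}

# drifting-grating probes of the correlator front end
grating_mean_response <- function(tf_hz, lambda_deg = 20, contrast = 1,
                                  params = emd_params()) {
  g <- retina_geometry()
  k <- 2 * pi / (lambda_deg * pi / 180)
  img <- function(t_ms)
    0.5 + contrast * 0.5 * sin(2 * pi * tf_hz * t_ms / 1000 - k * g$phi)
  period <- round(1000 / abs(tf_hz))
  n_settle <- 400
  st <- emd_state_init(params)
  r <- emd_run(lapply(seq_len(n_settle), img), params, st)
  st <- r$state
  acc <- 0
  for (t in n_settle + seq_len(period)) {
    r1 <- photoreceptor_stage(img(t), st, params)
    r2 <- highpass_stage(r1$image, r1$state, params)
    r3 <- emd_step(r2$image, r2$state, params)
    st <- r3$state
    acc <- acc + mean(r3$h[46, ])
  }
  acc / period
}

closed_form_mean_response <- function(tf_hz, lambda_deg = 20, contrast = 1,
                                      params = emd_params()) {
  w <- 2 * pi * tf_hz
  P <- 1 / (1 + 1i * w * params$tau_pr / 1000)
  HP <- 1i * w * params$tau_hp / 1000 / (1 + 1i * w * params$tau_hp / 1000)
  wt <- w * params$tau_lp / 1000
  kDelta <- 2 * pi * 2 / lambda_deg
  (contrast * 0.5)^2 * Mod(P)^2 * Mod(HP)^2 * wt / (1 + wt^2) * sin(kDelta)
}

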