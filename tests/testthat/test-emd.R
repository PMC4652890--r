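const_img <- function(v) matrix(v, 91, 181)

test_that("photoreceptor stage has unity DC gain and first-order step response", {
  p <- emd_params()
  st <- emd_state_init(p)
  # step response: 1 - exp(-t / tau) at t = k * dt, exactly, for the
  # zero-order-hold discretization
  out <- numeric(40)
  for (k in 1:40) {
    r <- photoreceptor_stage(const_img(1), st, p)
    st <- r$state
    out[k] <- r$image[1, 1]
  }
  expect_equal(out, 1 - exp(-(1:40) / p$tau_pr), tolerance = 1e-12)
  expect_equal(out[p$tau_pr], 1 - exp(-1), tolerance = 1e-12)
  # impulse response sums to the DC gain (= 1)
  st <- emd_state_init(p)
  tot <- 0
  r <- photoreceptor_stage(const_img(1), st, p)
  tot <- r$image[1, 1]
  st <- r$state
  for (k in 1:400) {
    r <- photoreceptor_stage(const_img(0), st, p)
    st <- r$state
    tot <- tot + r$image[1, 1]
  }
  expect_equal(tot, 1, tolerance = 1e-8)
})

test_that("high-pass stage removes DC with the configured time constant", {
  p <- emd_params()
  st <- emd_state_init(p)
  out <- numeric(200)
  for (k in 1:200) {
    r <- highpass_stage(const_img(0.6), st, p)
    st <- r$state
    out[k] <- r$image[1, 1]
  }
  # exact first-order high-pass: h * exp(-t / tau)
  expect_equal(out, 0.6 * exp(-(1:200) / p$tau_hp), tolerance = 1e-12)
  expect_lt(abs(out[200]), 1e-4)
  r0 <- highpass_stage(const_img(0), emd_state_init(p), p)
  expect_true(all(r0$image == 0))
})

test_that("correlators are silent on static scenes and mirror-antisymmetric", {
  p <- emd_params()
  withr::with_seed(1, img <- matrix(runif(91 * 181), 91, 181))
  res <- emd_run(rep(list(img), 400), p)
  last <- res$responses[[400]]
  expect_lt(max(abs(last$h)), 1e-9)
  expect_lt(max(abs(last$v)), 1e-9)
  # mirroring the stimulus in azimuth mirrors horizontal responses with
  # flipped sign
  withr::with_seed(2, imgs <- lapply(1:30, function(i)
    matrix(runif(91 * 181), 91, 181)))
  mirr <- lapply(imgs, function(m) m[, 181:1])
  r1 <- emd_run(imgs, p)$responses[[30]]
  r2 <- emd_run(mirr, p)$responses[[30]]
  expect_equal(r2$h, -r1$h[, 180:1], tolerance = 1e-12)
})

test_that("response scales with the square of contrast", {
  p <- emd_params()
  g <- retina_geometry()
  grating <- function(contrast, t)
    0.5 + contrast * 0.5 * sin(2 * pi * 4 * t / 1000 - 2 * pi * g$phi /
                                 (20 * pi / 180))
  adapted <- function() {
    st <- emd_state_init(p)
    st$pr[] <- 0.5
    st$hp_lp[] <- 0.5
    st
  }
  r1 <- emd_run(lapply(1:300, function(t) grating(1, t)), p,
                adapted())$responses[[300]]
  r2 <- emd_run(lapply(1:300, function(t) grating(0.5, t)), p,
                adapted())$responses[[300]]
  expect_equal(r2$h, r1$h / 4, tolerance = 1e-9)
})

test_that("grating responses follow correlator temporal-frequency tuning", {
  tf <- c(1, 2, 4, 8, 16)
  sim <- vapply(tf, grating_mean_response, numeric(1))
  ref <- vapply(tf, closed_form_mean_response, numeric(1))
  # normalized tuning curves agree within 5% of the peak
  expect_lt(max(abs(sim / max(sim) - ref / max(ref))), 0.05)
  # single interior maximum (band-pass in temporal frequency)
  pk <- which.max(sim)
  expect_true(pk %in% 2:(length(tf) - 1))
  expect_true(all(diff(sim[1:pk]) > 0) && all(diff(sim[pk:length(tf)]) < 0))
  # direction reversal flips the sign of the mean response
  rev <- grating_mean_response(-4)
  fwd <- grating_mean_response(4)
  expect_equal(rev, -fwd, tolerance = 1e-6)
  # temporal-frequency (not velocity) tuning: doubling the wavelength at
  # fixed temporal frequency leaves the temporal tuning factor unchanged up
  # to the spatial-phase factor sin(k Delta)
  r40 <- grating_mean_response(4, lambda_deg = 40)
  expect_equal(r40 / sin(2 * pi * 2 / 40), fwd / sin(2 * pi * 2 / 20),
               tolerance = 0.02)
})

test_that("the R stage cascade and the native phase engine agree", {
  env <- check_box(8)
  sc <- compile_scene(env)
  cfg <- sim_config("emd", seed = 3, emd_window_ms = 5)
  st <- sim_state_init(sc, cfg, c(0.05, 0.02), 20)
  withr::with_seed(3, dirs <- rnorm(50, 0, 18))
  # native engine
  stn <- comanv:::render_stencil(13)
  p <- st$emd_params
  out <- comanv:::cpp_emd_phase(
    sc$ptr, c(st$position, st$heading_deg * pi / 180), 0.1, 1, dirs,
    numeric(50), c(rep(FALSE, 45), rep(TRUE, 5)), st$emd_state, stn$dirs,
    stn$weights, list(nrow = p$nrow, ncol = p$ncol, tau_pr = p$tau_pr,
                      tau_hp = p$tau_hp, tau_lp = p$tau_lp), 0.01)
  # same pipeline through the R stages (starting from the same adapted state)
  pos <- st$position; heading <- st$heading_deg
  state <- st$emd_state
  fields <- list()
  for (t in 1:50) {
    wdir <- (heading + dirs[t]) * pi / 180
    pos <- pos + 0.1 * 0.001 * c(cos(wdir), sin(wdir), 0)
    img <- render_view(sc, make_pose(pos, heading), 13)
    r1 <- photoreceptor_stage(img, state, p)
    r2 <- highpass_stage(r1$image, r1$state, p)
    r3 <- emd_step(r2$image, r2$state, p)
    state <- r3$state
    if (t > 45) fields[[length(fields) + 1]] <- list(h = r3$h, v = r3$v)
  }
  isf <- accumulate_squared_flow(fields, "emd")
  expect_equal(out$hsq, isf$h, tolerance = 1e-10)
  expect_equal(out$vsq, isf$v, tolerance = 1e-10)
  expect_equal(out$state$pr, state$pr, tolerance = 1e-12)
})
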