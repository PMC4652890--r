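test_that("squared-flow accumulation averages squares and ignores sign", {
  g <- retina_geometry()
  f <- list(h = matrix(0.3, 91, 181), v = matrix(0.4, 91, 181))
  isf <- accumulate_squared_flow(list(f), "geometric")
  expect_equal(isf$h[1, 1], 0.09)
  expect_equal(isf$v[1, 1], 0.16)
  isf2 <- accumulate_squared_flow(rep(list(f), 7), "geometric")
  expect_equal(isf2$h, isf$h)
  neg <- list(h = -f$h, v = -f$v)
  isf3 <- accumulate_squared_flow(list(f, neg, f, neg), "geometric")
  expect_equal(isf3$h, isf$h)
  expect_error(accumulate_squared_flow(list(), "geometric"))
})

test_that("the retinotopically modified norm recovers relative nearness", {
  g <- retina_geometry()
  # direct arithmetic at eps = 30: sqrt(0.09 + 0.04 / 0.25) = 0.5
  h <- matrix(0, 91, 181); v <- matrix(0, 91, 181)
  r30 <- which(g$eps_deg == 30)
  h[r30, ] <- 0.3^2; v[r30, ] <- 0.2^2
  isf <- structure(list(h = h, v = v, n = 1, source = "geometric"),
                   class = "integrated_squared_flow")
  nm <- nearness_from_integrated(isf)
  expect_equal(nm$map[r30, 1], 0.5, tolerance = 1e-12)
  # pole rows masked, equator interpolated from its neighbours
  expect_true(all(is.na(nm$map[c(1, 91), ])))
  expect_equal(nm$map[46, 5], (nm$map[45, 5] + nm$map[47, 5]) / 2)
  nm2 <- nearness_from_integrated(isf, equator = "exclude")
  expect_true(all(is.na(nm2$map[46, ])))
})

test_that("mixed-direction integration recovers v/R on a sphere without FOE holes", {
  isf <- sphere_isf(r = 0.2, v = 0.1)
  nm <- nearness_from_integrated(isf)
  vals <- nm$map[!nm$mask]
  expect_lt(max(abs(vals - 0.5)) / 0.5, 0.01)
  # single-direction translation: the flow, and hence the numerator of the
  # modified norm, vanishes exactly at the FOE grid point (equator, azimuth
  # 0), independent of the nearness there
  g <- retina_geometry()
  mu <- matrix(5, 91, 181)
  single <- accumulate_squared_flow(list(
    geometric_flow(mu, make_pose(c(0, 0), 0, speed = 0.1))), "geometric")
  foe <- c(which(g$eps_deg == 0), which(g$phi_deg == 0))
  expect_identical(single$h[foe[1], foe[2]], 0)
  expect_identical(single$v[foe[1], foe[2]], 0)
})

test_that("vertical averaging respects the mask", {
  g <- retina_geometry()
  m <- matrix(2.5, 91, 181)
  p <- vertical_average(m)
  expect_length(p, 180)
  expect_true(all(abs(p - 2.5) < 1e-12))
  # single nonzero column
  m2 <- matrix(0, 91, 181); m2[, 10] <- 1
  p2 <- vertical_average(m2)
  expect_true(p2[10] > 0 && all(p2[-10] == 0))
  # changing a masked (pole) cell changes nothing
  m3 <- m2; m3[1, 20] <- 99
  expect_equal(vertical_average(m3), p2)
})

test_that("the COMANV points toward close surfaces", {
  g <- retina_geometry()
  prof <- function(vals) structure(vals, phi_deg = g$phi_deg[1:180],
                                   class = "azimuthal_profile")
  expect_lt(sqrt(sum(comanv(prof(rep(1, 180)))^2)), 1e-12)
  one <- rep(0, 180); one[g$phi_deg[1:180] == 90] <- 1
  cv <- comanv(prof(one))
  expect_equal(atan2(cv[2], cv[1]) * 180 / pi, 90)
  two <- rep(0, 180)
  two[g$phi_deg[1:180] == 60] <- 1; two[g$phi_deg[1:180] == -60] <- 1
  cv2 <- comanv(prof(two))
  expect_equal(atan2(cv2[2], cv2[1]) * 180 / pi, 0, tolerance = 1e-12)
})

test_that("CAD opposes the COMANV and CAN is its norm", {
  cc <- cad_can(c(0, 1))
  expect_equal(cc$cad, -90)
  expect_equal(cad_can(c(0.3, 0.4))$can, 0.5)
  z <- cad_can(c(0, 0))
  expect_equal(z$cad, 0)
  expect_equal(z$can, 0)
})

test_that("the sigmoid weight has threshold 1/2, zero floor and the printed value", {
  expect_equal(avoidance_weight(4, 2, 4), 0.5)
  expect_equal(avoidance_weight(0, 2, 4), 0)
  expect_equal(avoidance_weight(8, 2, 4), 0.8)  # 1 / (1 + 2^-2)
  expect_true(all(diff(avoidance_weight(seq(0, 50, 0.5), 2, 4)) >= 0))
})

test_that("saccade command blends avoidance and goal directions", {
  expect_equal(saccade_command(45, 1, alpha = -30), 45)
  expect_equal(saccade_command(45, 0, alpha = -30), -30)
  expect_equal(saccade_command(90, 0.8, alpha = -30), 0.8 * 90 + 0.2 * -30)
  # goal-direction noise is seedable and zero-mean-shaped
  withr::with_seed(1, a <- saccade_command(0, 0, alpha = 10, sigma_sd = 5))
  withr::with_seed(1, b <- saccade_command(0, 0, alpha = 10, sigma_sd = 5))
  expect_equal(a, b)
  expect_false(a == 10)
})

test_that("nearness error grows with out-of-plane motion", {
  # planar-motion assumption: adding a vertical velocity w while still
  # assuming planar motion biases the recovered nearness, monotonically in w
  g <- retina_geometry()
  mu <- matrix(1 / 0.2, 91, 181)
  v <- 0.1
  err <- vapply(c(0, 0.01, 0.02, 0.04), function(w) {
    # flow of translation (v, 0, w): project velocity on the local basis
    t3 <- c(v, 0, w)
    ofh <- -mu * matrix(g$e_phi %*% t3, 91, 181)
    ofv <- -mu * matrix(g$e_eps %*% t3, 91, 181)
    isf <- accumulate_squared_flow(list(list(h = ofh, v = ofv)), "geometric")
    nm <- nearness_from_integrated(isf)
    mean(abs(nm$map[!nm$mask] - v * mu[1, 1]))
  }, numeric(1))
  expect_true(all(diff(err) > 0))
})
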