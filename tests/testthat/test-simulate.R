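test_that("intersaccades are pure translations with jittered segment directions", {
  env <- uniform_box()
  sc <- compile_scene(env)
  cfg <- sim_config("geometric", segment_sd_deg = 0, seed = 1)
  st <- sim_state_init(sc, cfg, c(0, 0), 30)
  ph <- run_intersaccade(st, cfg)
  # SD = 0: straight 5 mm displacement along the heading, heading unchanged
  disp <- ph$state$position - st$position
  expect_equal(sqrt(sum(disp^2)), 0.005, tolerance = 1e-12)
  expect_equal(atan2(disp[2], disp[1]) * 180 / pi, 30, tolerance = 1e-9)
  expect_equal(ph$state$heading_deg, 30)
  # jittered: 50 draws at SD 18 deg, sample mean within 3 * 18/sqrt(50)
  cfg2 <- sim_config("geometric", seed = 1)
  withr::with_seed(5, {
    st2 <- sim_state_init(sc, cfg2, c(0, 0), 0)
    d <- rnorm(50, 0, 18)
  })
  expect_lt(abs(mean(d)), 3 * 18 / sqrt(50))
  withr::with_seed(5, ph2 <- run_intersaccade(st2, cfg2))
  expect_equal(ph2$state$heading_deg, 0)
  expect_equal(nrow(ph2$path), 50)
})

test_that("saccade profiles integrate exactly to their amplitude", {
  p0 <- saccade_profile(0)
  expect_equal(p0$duration_ms, 10)
  expect_true(all(p0$yaw_dps == 0))
  for (g in c(-170, -45, 10, 66, 180)) {
    p <- saccade_profile(g)
    expect_equal(sum(p$yaw_dps) * 0.001, g, tolerance = 1e-10)
    expect_equal(p$duration_ms, round(max(10, 30 + 20 * abs(g) / 90)))
    # symmetric bell with a single interior maximum
    expect_equal(p$yaw_dps, rev(p$yaw_dps), tolerance = 1e-12)
    pk <- which.max(abs(p$yaw_dps))
    expect_true(all(diff(abs(p$yaw_dps[1:pk])) >= 0))
  }
  expect_error(saccade_profile(200))
})

test_that("saccades turn exactly and keep translating and sensing", {
  env <- check_box(8)
  sc <- compile_scene(env)
  cfg <- sim_config("emd", seed = 2)
  st <- sim_state_init(sc, cfg, c(0, 0), 0)
  ph0 <- run_intersaccade(st, cfg)     # charge the filters
  st <- ph0$state
  pr_before <- st$emd_state$pr
  ph <- run_saccade(st, saccade_profile(90), cfg)
  expect_equal(ph$state$heading_deg, 90, tolerance = 1e-9)
  expect_gt(sqrt(sum((ph$state$position - st$position)^2)), 0.003)
  # filter states keep evolving during the turn (contamination is real)
  expect_gt(max(abs(ph$state$emd_state$pr - pr_before)), 1e-6)
  # zero amplitude: straight advance
  ph0 <- run_saccade(st, saccade_profile(0), cfg)
  expect_equal(ph0$state$heading_deg, st$heading_deg)
})

test_that("collision detection uses a strict distance threshold", {
  env <- uniform_box()
  expect_false(detect_collision(env, c(0, 0, 0.2), 0.01))
  expect_true(detect_collision(env, c(0.195, 0, 0.2), 0.01))
  expect_false(detect_collision(env, c(0.19, 0, 0.2), 0.01))  # exactly r
})

test_that("closed-loop runs are deterministic and account for every tick", {
  env <- check_box(8)
  sc <- compile_scene(env)
  cfg <- sim_config("geometric", gain = 2, threshold = 3.2, max_time_s = 2,
                    seed = 11)
  tr1 <- simulate_agent(sc, cfg, c(0.1, 0.05), 0)
  tr2 <- simulate_agent(sc, cfg, c(0.1, 0.05), 0)
  expect_identical(tr1$data, tr2$data)
  expect_identical(tr1$events, tr2$events)
  # phase bookkeeping: ticks partition into alternating phases
  r <- rle(tr1$data$phase)
  expect_true(all(r$values[seq(1, length(r$values), 2)] == "intersaccade"))
  expect_equal(sum(r$lengths), nrow(tr1$data))
  expect_equal(nrow(tr1$data) * cfg$dt_ms, max(tr1$data$t_ms))
})

test_that("with full weighting the box agent concentrates toward the centre", {
  env <- check_box(8)
  sc <- compile_scene(env)
  cfg <- sim_config("geometric", gain = 2, threshold = 0, max_time_s = 4,
                    seed = 3)
  tr <- simulate_agent(sc, cfg, c(0.13, 0.1), 0)
  expect_identical(tr$result, "timeout")
  r <- sqrt(tr$data$x_m^2 + tr$data$y_m^2)
  late <- r[tr$data$t_ms > 2000]
  expect_lt(mean(late), sqrt(0.13^2 + 0.1^2))
  expect_lt(max(late), 0.15)
})

test_that("a goal-seeking agent in the open reaches its goal", {
  # no obstacles, goal mode with W ~ 0: heading converges to the goal bearing
  env <- env_cubic_box(edge = 2, wall_texture = uniform_texture(),
                       floor_texture = uniform_texture(),
                       ceiling_texture = uniform_texture(), seed = 1)
  sc <- compile_scene(env)
  cfg <- sim_config("geometric", gain = 2, threshold = 1e9,
                    goal = c(0.6, 0.3), max_time_s = 30, seed = 4)
  tr <- simulate_agent(sc, cfg, c(-0.6, -0.3), 0)
  expect_identical(tr$result, "goal")
  end <- tail(tr$data, 1)
  expect_lt(sqrt((end$x_m - 0.6)^2 + (end$y_m - 0.3)^2), cfg$goal_radius)
})

test_that("start grids stay clear of surfaces", {
  env <- env_cluttered(seed = 3)
  sc <- compile_scene(env)
  pts <- start_grid(sc, 20, region = "end")
  expect_equal(nrow(pts), 20)
  z <- flight_height(env)
  for (i in seq_len(20))
    expect_gte(surface_distance(sc, c(pts[i, ], z)), 0.05)
  expect_true(all(pts[, 1] < -0.5))
})
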