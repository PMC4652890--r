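test_that("checkerboard textures are deterministic, balanced and correctly tiled", {
  a <- texture_checkerboard(1, c(400, 400), seed = 42)
  b <- texture_checkerboard(1, c(400, 400), seed = 42)
  expect_identical(a$grid, b$grid)
  expect_false(identical(
    a$grid, texture_checkerboard(1, c(400, 400), seed = 43)$grid))
  # binomial sampling: mean within 3 standard errors of 0.5
  se <- 0.5 / sqrt(400 * 400)
  expect_lt(abs(mean(a$grid) - 0.5), 3 * se)
  expect_true(all(a$grid %in% c(0, 1)))
  coarse <- texture_checkerboard(35, c(400, 400), seed = 1)
  expect_equal(dim(coarse$grid), c(ceiling(400 / 35), ceiling(400 / 35)))
  expect_error(texture_checkerboard(-1, c(400, 400), 1))
  expect_error(texture_checkerboard(1, c(0, 400), 1))
})

test_that("1/f textures are normalized, reproducible and have ~1/f spectra", {
  tex <- texture_one_over_f(c(512, 512), seed = 7)
  expect_gte(min(tex$grid), 0)
  expect_lte(max(tex$grid), 1)
  expect_identical(tex$grid, texture_one_over_f(c(512, 512), seed = 7)$grid)
  # radially averaged amplitude spectrum: log-log slope in [-1.3, -0.7]
  n <- 512
  amp <- Mod(fft(tex$grid))
  fx <- c(0:(n / 2), -(n / 2 - 1):-1) / n
  f <- sqrt(outer(fx^2, fx^2, `+`))
  bins <- cut(f[f > 0 & f <= 0.5], breaks = 2^seq(-8, -1, by = 0.5))
  m <- tapply(amp[f > 0 & f <= 0.5], bins, mean)
  ctr <- 2^(seq(-8, -1.5, by = 0.5) + 0.25)
  ok <- !is.na(m)
  slope <- coef(lm(log(m[ok]) ~ log(ctr[ok])))[2]
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})

test_that("cubic box has six textured faces and the right inner size", {
  env <- check_box()
  expect_length(env$wall_textures, 6)
  expect_equal(env$hi - env$lo, c(0.4, 0.4, 0.4))
  expect_length(env$obstacles, 0)
  tall <- env_cubic_box(height = 3.9)
  expect_equal((tall$hi - tall$lo)[3] * 1000, 3900)
})

test_that("object boxes place camouflaged 3 cm bars per layout", {
  e1 <- env_object_box(1)
  expect_length(e1$obstacles, 1)
  expect_equal(e1$obstacles[[1]]$center, c(0, 0))
  e4 <- env_object_box(4)
  expect_length(e4$obstacles, 4)
  expect_true(all(vapply(e4$obstacles, `[[`, numeric(1), "base_edge") ==
                    0.03))
  expect_true(all(vapply(e4$obstacles, `[[`, numeric(1), "height") == 0.4))
  e0 <- env_object_box(0)
  expect_length(e0$obstacles, 0)
  expect_equal(e0$hi - e0$lo, c(0.4, 0.4, 0.4))
  expect_error(env_object_box(3))
})

test_that("cluttered corridors follow the object roster and clearance rule", {
  env <- env_cluttered(seed = 5)
  expect_length(env$obstacles, 35)
  edges <- sort(vapply(env$obstacles, `[[`, numeric(1), "base_edge") * 1000)
  expect_equal(as.vector(table(edges)), c(5, 5, 5, 10, 5, 5))
  expect_equal(unique(edges), c(40, 48, 56, 64, 72, 80))
  heights <- vapply(env$obstacles, `[[`, numeric(1), "height")
  expect_equal(heights, 5 * vapply(env$obstacles, `[[`, numeric(1),
                                   "base_edge"))
  env2 <- env_cluttered(seed = 5, roster = "second")
  edges2 <- vapply(env2$obstacles, `[[`, numeric(1), "base_edge") * 1000
  expect_equal(sum(edges2 == 72), 10)
  expect_equal(sum(edges2 == 64), 5)
  # footprints never overlap (clearance >= 60 mm by construction)
  ctr <- t(vapply(env$obstacles, `[[`, numeric(2), "center"))
  ed <- vapply(env$obstacles, `[[`, numeric(1), "base_edge")
  for (i in 1:34) for (j in (i + 1):35) {
    gap <- max(abs(ctr[i, ] - ctr[j, ])) - (ed[i] + ed[j]) / 2
    expect_gte(gap, 0.060 - 1e-12)
  }
  # same seed reproduces the identical layout
  expect_equal(t(vapply(env_cluttered(seed = 5)$obstacles, `[[`, numeric(2),
                        "center")), ctr)
})

test_that("walled environments are watertight from any interior point", {
  env <- env_cluttered(seed = 2)
  sc <- compile_scene(env)
  withr::with_seed(9, {
    for (k in 1:5) {
      p <- c(runif(1, -0.9, 0.9), runif(1, -0.45, 0.45), runif(1, 0.05, 0.35))
      if (surface_distance(sc, p) <= 0) next
      d <- matrix(rnorm(300), ncol = 3)
      d <- d / sqrt(rowSums(d^2))
      r <- cast_ray(sc, p, d)
      expect_true(all(is.finite(r$distance)))
      expect_true(all(r$distance > 0))
    }
  })
  open_env <- env_cluttered(seed = 2, walls = FALSE)
  sco <- compile_scene(open_env)
  up <- cast_ray(sco, c(-0.95, 0.45, 0.2), c(0, 0, 1))
  expect_identical(up$distance, Inf)
})

test_that("environment recipes round-trip through the YAML config", {
  env <- env_cluttered(seed = 11, texel_size_mm = 4, goal = c(0.8, 0.1))
  path <- withr::local_tempfile(fileext = ".yml")
  write_environment(env, path)
  env2 <- read_environment(path)
  expect_equal(t(vapply(env2$obstacles, `[[`, numeric(2), "center")),
               t(vapply(env$obstacles, `[[`, numeric(2), "center")))
  expect_equal(env2$goal, env$goal)
  expect_identical(env2$wall_textures[[1]]$grid, env$wall_textures[[1]]$grid)
})

test_that("textures round-trip through PNG with sidecar metadata", {
  tex <- texture_checkerboard(4, c(64, 64), seed = 3)
  path <- withr::local_tempfile(fileext = ".png")
  write_texture(tex, path)
  back <- read_texture(path)
  expect_equal(back$grid, tex$grid, tolerance = 1 / 254)
  expect_equal(back$texel_size_mm, 4)
  expect_equal(back$seed, 3)
})
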