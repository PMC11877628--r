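test_that("particle sampling honours the population parameters", {
  mono <- sample_particles(50, population_config(sd_diameter = 0), seed = 1)
  expect_true(all(mono$diameter == 80))
  none <- sample_particles(200, population_config(aggregate_fraction = 0),
                           seed = 1)
  expect_false(any(none$is_aggregate))
  p <- sample_particles(10000, population_config(), seed = 7)
  # truncation at +/- 3 SD
  expect_true(all(p$diameter >= 53 & p$diameter <= 107))
  # sample mean within 3 standard errors of 80 (SE ~ 9/sqrt(1e4))
  expect_lt(abs(mean(p$diameter) - 80), 3 * 9 / sqrt(10000))
  expect_error(sample_particles(0), "n must be > 0")
})

test_that("sampling is reproducible under a fixed seed", {
  a <- sample_particles(500, seed = 123)
  b <- sample_particles(500, seed = 123)
  expect_identical(a, b)
  c <- sample_particles(500, seed = 124)
  expect_false(identical(a$diameter, c$diameter))
})

test_that("binding occupancy follows the isotherm", {
  bm <- binding_model(kd = 1, hill = 1)
  p <- sample_particles(4000, seed = 5)
  zero <- bind_analyte(p, 0, bm, seed = 5)
  expect_true(all(zero$shell == 1.67))
  expect_false(any(zero$bound))
  at_kd <- bind_analyte(p, 1, bm, seed = 5)
  # binomial: fraction bound within 4 SE of 0.5
  expect_lt(abs(mean(at_kd$bound) - 0.5), 4 * 0.5 / sqrt(4000))
  sat <- bind_analyte(p, 1e6, bm, seed = 5)
  expect_gt(mean(sat$bound), 0.999)
  expect_true(all(sat$shell == 1.77))
  expect_error(bind_analyte(p, -1, bm), ">= 0")
  expect_equal(bound_probability(bm, c(0, 1, 3)), c(0, 0.5, 0.75))
})

test_that("ground-truth gamma equals the contrast of the particle's band integrals", {
  pop <- population_config()
  p <- sample_particles(20, pop, seed = 3)
  p <- bind_analyte(p, 0, binding_model(), pop, seed = 4)
  p <- particle_band_signal(p, pop)
  # the lookup-table gamma must agree with a direct Mie computation
  direct <- vapply(seq_len(5), function(i) {
    m <- particle_model(p$diameter[i], p$shell[i])
    gamma_contrast(band_intensities(
      scattering_spectrum(m, seq(520, 650, by = 1))))
  }, numeric(1))
  expect_equal(p$gamma_true[1:5], direct, tolerance = 1e-4)
  expect_equal(p$gamma_true,
               gamma_contrast(p$r_int / ifelse(p$is_aggregate, 2, 1),
                              p$g_int / ifelse(p$is_aggregate, 2, 1)))
})

test_that("binding red-shifts the true gamma of every particle", {
  pop <- population_config()
  p <- sample_particles(200, pop, seed = 9)
  p$is_aggregate <- FALSE
  bound <- unbound <- p
  unbound$shell <- pop$base_shell
  bound$shell <- pop$bound_shell
  g0 <- particle_band_signal(unbound, pop)$gamma_true
  g1 <- particle_band_signal(bound, pop)$gamma_true
  expect_true(all(g1 > g0))
})

test_that("noise-only frames have the configured background statistics", {
  img <- tiny_imaging(background_level = 50, read_noise_sd = 3)
  # a zero-intensity particle renders one frame of pure noise
  fr <- render_frames(data.frame(r_int = 0, g_int = 0, is_aggregate = FALSE),
                      img, seed = 2)
  px <- as.numeric(fr$r[[1]])
  expect_equal(mean(px), 50, tolerance = 0.02)
  expect_equal(stats::var(px), 50 + 9, tolerance = 0.05)
})

test_that("a noiseless spot integrates to the commanded photon count", {
  img <- tiny_imaging(background_level = 0, read_noise_sd = 0)
  part <- data.frame(r_int = 1e5, g_int = 4e4, is_aggregate = FALSE)
  fr <- render_frames(part, img, seed = 3, noise = FALSE)
  scale <- img$photons_per_unit_cross_section
  expect_equal(sum(fr$r[[1]]), 1e5 * scale, tolerance = 5e-3)
  expect_equal(sum(fr$g[[1]]), 4e4 * scale, tolerance = 5e-3)
})

test_that("doubling the photon budget doubles background-subtracted intensity", {
  part <- data.frame(r_int = 1e5, g_int = 4e4, is_aggregate = FALSE)
  img1 <- tiny_imaging(background_level = 0, read_noise_sd = 0,
                       photons_per_unit_cross_section = 0.03)
  img2 <- tiny_imaging(background_level = 0, read_noise_sd = 0,
                       photons_per_unit_cross_section = 0.06)
  f1 <- render_frames(part, img1, seed = 4, noise = FALSE)
  f2 <- render_frames(part, img2, seed = 4, noise = FALSE)
  expect_equal(sum(f2$r[[1]]), 2 * sum(f1$r[[1]]), tolerance = 1e-10)
})

test_that("a bound particle renders redder than an unbound one", {
  pop <- population_config()
  base <- data.frame(id = 1, diameter = 80, is_aggregate = FALSE,
                     shell = pop$base_shell)
  bound <- transform(base, shell = pop$bound_shell)
  img <- tiny_imaging(background_level = 0, read_noise_sd = 0)
  g_of <- function(part) {
    part <- particle_band_signal(part, pop)
    fr <- render_frames(part, img, seed = 5, noise = FALSE)
    gamma_contrast(sum(fr$r[[1]]), sum(fr$g[[1]]))
  }
  expect_gt(g_of(bound), g_of(base))
})

test_that("dataset generation covers the requested spot count and is deterministic", {
  ds <- small_dataset(n_spots = 100, seed = 21)
  expect_gte(sum(!ds$truth$is_aggregate), 100)
  expect_gte(length(ds$frames$r), ceiling(100 / 15))
  ds2 <- small_dataset(n_spots = 100, seed = 21)
  expect_identical(ds$frames$r, ds2$frames$r)
  expect_identical(ds$frames$g, ds2$frames$g)
  expect_identical(ds$truth, ds2$truth)
  # default spot budget matches the assay's per-condition statistics
  expect_equal(formals(generate_dataset)$n_spots, 15000)
})

test_that("datasets round-trip through 16-bit TIFF and manifests", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(0.5, n_spots = 40, img = tiny_imaging(),
                         seed = 8, out_dir = dir)
  expect_true(file.exists(file.path(dir, "r_channel.tif")))
  expect_true(file.exists(file.path(dir, "g_channel.tif")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 8)
  expect_equal(man$concentration_pg_ml, 0.5)
  back <- read_stack(file.path(dir, "r_channel.tif"))
  expect_equal(length(back), length(ds$frames$r))
  expect_equal(back[[1]], ds$frames$r[[1]], tolerance = 1e-12)
})
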