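test_that("constant and invalid frames yield no or rejected detections", {
  flat <- matrix(100, 64, 64)
  expect_equal(nrow(detect_spots(flat)), 0)
  bad <- flat
  bad[5, 5] <- NA
  expect_error(detect_spots(bad), "finite")
  expect_error(detection_params(local_max_window = 4), "odd")
  expect_error(detection_params(measure_radius = 8,
                                background_annulus = c(7, 10)), "radii")
})

test_that("a single noiseless spot is found within a pixel of ground truth", {
  part <- particle_band_signal(
    data.frame(id = 1, diameter = 80, is_aggregate = FALSE, shell = 1.67))
  fr <- render_frames(part, tiny_imaging(read_noise_sd = 0), seed = 31,
                      noise = FALSE)
  peaks <- detect_spots(fr$r[[1]] + fr$g[[1]])
  expect_equal(nrow(peaks), 1)
  expect_lt(abs(peaks$row - fr$truth$row), 1)
  expect_lt(abs(peaks$col - fr$truth$col), 1)
})

test_that("well-separated spots are each detected exactly once", {
  img <- tiny_imaging(background_level = 0, read_noise_sd = 0)
  sig <- 1.4
  frame <- matrix(0, 128, 128)
  centres <- rbind(c(40, 40), c(40, 40 + 5 * sig + 2), c(90, 90))
  for (i in seq_len(nrow(centres))) {
    p <- nanochrome:::.spot_patch(c(128, 128), centres[i, 1], centres[i, 2],
                                  5000, sig)
    frame[p$rows, p$cols] <- frame[p$rows, p$cols] + p$patch
  }
  peaks <- detect_spots(frame)
  expect_equal(nrow(peaks), 3)
})

test_that("flat plateaus resolve to a single centred peak", {
  frame <- matrix(0, 64, 64)
  frame[30:31, 40:41] <- 500  # 2x2 plateau of tied maxima
  peaks <- detect_spots(frame)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$row, 30, tolerance = 0.51)
  expect_equal(peaks$col, 40, tolerance = 0.51)
})

test_that("photometry recovers the commanded photon integral on a dark field", {
  img <- tiny_imaging(background_level = 0, read_noise_sd = 0)
  part <- particle_band_signal(
    data.frame(id = 1, diameter = 90, is_aggregate = FALSE, shell = 1.67))
  fr <- render_frames(part, img, seed = 32, noise = FALSE)
  peak <- detect_spots(fr$r[[1]] + fr$g[[1]])
  spot <- measure_spot(fr$r[[1]], fr$g[[1]], peak[1, ])
  want_r <- part$r_int * img$photons_per_unit_cross_section
  want_g <- part$g_int * img$photons_per_unit_cross_section
  # the measurement disk holds the PSF core; a small tail falls outside
  expect_equal(spot$r_scat, want_r, tolerance = 0.01)
  expect_equal(spot$g_scat, want_g, tolerance = 0.01)
  expect_equal(spot$gamma, (want_r - want_g) / (want_r + want_g),
               tolerance = 1e-3)
  expect_false(spot$excluded)
})

test_that("identical channels give gamma zero for every spot", {
  ds <- small_dataset(n_spots = 60, seed = 33)
  res <- analyze_frames(ds$frames$r, ds$frames$r,
                        detection_params(max_area = Inf))
  expect_gt(nrow(res$spots), 0)
  expect_true(all(res$spots$gamma == 0))
})

test_that("peaks too close to the frame edge are flagged as edge exclusions", {
  frame <- matrix(0, 64, 64)
  p <- nanochrome:::.spot_patch(c(64, 64), 5, 5, 5000, 1.4)
  frame[p$rows, p$cols] <- frame[p$rows, p$cols] + p$patch
  peaks <- detect_spots(frame)
  expect_equal(nrow(peaks), 1)
  spot <- measure_spot(frame, frame, peaks[1, ])
  expect_true(spot$excluded)
  expect_equal(spot$reason, "edge")
})

test_that("oversize filtering flags aggregates and conserves counts", {
  spots <- data.frame(row = 1:4, col = 1:4, area = c(10, 20, 80, NA),
                      r_scat = 1, g_scat = 1, gamma = 0,
                      excluded = c(FALSE, FALSE, FALSE, TRUE),
                      reason = c("", "", "", "edge"))
  params <- detection_params(max_area = 50)
  filt <- filter_spots(spots, params)
  expect_equal(nrow(filt$kept), 2)
  expect_equal(filt$flagged$reason[3], "oversize")
  expect_equal(unname(filt$counts["detected"]),
               unname(filt$counts["kept"] + filt$counts["excluded_edge"] +
                        filt$counts["excluded_oversize"] +
                        filt$counts["excluded_nonpositive"]))
  # degenerate but legal: everything oversized
  all_out <- filter_spots(spots, detection_params(max_area = 0))
  expect_equal(nrow(all_out$kept), 0)
  # max_area must be calibrated before filtering
  expect_error(filter_spots(spots, detection_params()), "max_area")
})

test_that("simulated doublets are excluded as oversized", {
  pop <- population_config()
  part <- particle_band_signal(
    data.frame(id = 1:2, diameter = c(80, 80),
               is_aggregate = c(TRUE, FALSE), shell = 1.67), pop)
  fr <- render_frames(part, tiny_imaging(), seed = 35)
  ma <- calibrate_max_area(pop, tiny_imaging(), n = 300, seed = 36)
  res <- analyze_frames(fr$r, fr$g, detection_params(max_area = ma))
  m <- match_spots(res$all, fr$truth, radius = 3)
  expect_equal(nrow(res$all), 2)
  agg_row <- which.max(res$all$area)
  expect_equal(res$all$reason[agg_row], "oversize")
  expect_false(res$all$excluded[-agg_row])
})

test_that("detection on noiseless frames has high recall and no false positives", {
  ds <- small_dataset(n_spots = 200, seed = 37, noise = FALSE)
  ma <- calibrate_max_area(population_config(), tiny_imaging(),
                           n = 300, seed = 36)
  res <- analyze_frames(ds$frames$r, ds$frames$g,
                        detection_params(max_area = ma))
  truth_single <- ds$truth[!ds$truth$is_aggregate, ]
  m <- match_spots(res$spots, ds$truth, radius = 1)
  recall <- sum(!m$is_aggregate) / nrow(truth_single)
  expect_gte(recall, 0.95)
  # false positives: detections not matching any ground-truth particle
  m_all <- match_spots(res$all, ds$truth, radius = 3)
  fpr <- (nrow(res$all) - nrow(m_all)) / max(nrow(res$all), 1)
  expect_lte(fpr, 0.01)
})

test_that("measured gamma tracks ground-truth gamma at the default photon budget", {
  ds <- small_dataset(n_spots = 400, seed = 38)
  ma <- calibrate_max_area(population_config(), tiny_imaging(),
                           n = 300, seed = 36)
  res <- analyze_frames(ds$frames$r, ds$frames$g,
                        detection_params(max_area = ma))
  m <- match_spots(res$spots, ds$truth)
  expect_gt(nrow(m), 300)
  expect_gte(cor(m$gamma_true, m$gamma_measured, method = "spearman"), 0.8)
})

test_that("frame analysis is deterministic and bookkeeping is consistent", {
  ds <- small_dataset(n_spots = 100, seed = 39)
  params <- detection_params(max_area = 14)
  r1 <- analyze_frames(ds$frames$r, ds$frames$g, params)
  r2 <- analyze_frames(ds$frames$r, ds$frames$g, params)
  expect_identical(r1$spots, r2$spots)
  expect_identical(r1$counts, r2$counts)
  expect_equal(unname(r1$counts["detected"]),
               nrow(r1$spots) + sum(r1$all$excluded))
  # no spot both kept and excluded
  expect_false(any(r1$spots$excluded))
  expect_error(analyze_frames(ds$frames$r, ds$frames$g[-1], params),
               "differ in length")
  empty <- analyze_frames(list(), list(), params)
  expect_equal(nrow(empty$spots), 0)
})

test_that("dataset directories analyse end-to-end with artifacts", {
  dir <- withr::local_tempdir()
  generate_dataset(0, n_spots = 60, img = tiny_imaging(), seed = 41,
                   out_dir = dir)
  res <- analyze_dataset(dir, detection_params(max_area = 14))
  expect_true(file.exists(file.path(dir, "spots.csv")))
  expect_true(file.exists(file.path(dir, "analysis_summary.json")))
  tab <- utils::read.csv(file.path(dir, "spots.csv"))
  expect_equal(nrow(tab), unname(res$counts["detected"]))
  expect_error(analyze_dataset(withr::local_tempdir()), "not found")
})
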