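test_that("acquisition arithmetic matches the recording set-up", {
  acq <- acquisition_params(7000, 5)
  expect_equal(acq$n_frames, 35000)
  expect_equal(acq$frame_interval, 142.857e-6, tolerance = 1e-4)
  one <- acquisition_params(1, 1)
  expect_equal(one$frame_interval, 1)
  expect_equal(one$n_frames, 1)
  expect_error(acquisition_params(0, 5), "> 0")
  expect_error(acquisition_params(7000, -1), "> 0")
})

test_that("scale-bar calibration divides out and survives a render round-trip", {
  expect_equal(scale_from_bar(250, 500), 2)
  expect_equal(scale_from_bar(500, 500), 1)
  expect_error(scale_from_bar(0, 500), "> 0")
  img <- synth_spheroid_image(pixel_size = 1.6, seed = 21)
  bar_px <- locate_scale_bar(img$frame)
  expect_equal(scale_from_bar(bar_px, 500), 1.6, tolerance = 0.01)
})

test_that("droplet detection recovers planted droplets within 2 px", {
  gen <- synth_droplet_frames(n_frames = 1, droplets_per_frame = 3,
                              diameter_range = c(200, 300), seed = 3)
  det <- detect_droplets(gen$frames[[1]], frame_index = 1)
  expect_equal(nrow(det), 3)
  truth <- gen$truth[order(gen$truth$cx_px), ]
  det <- det[order(det$cx_px), ]
  px <- gen$frames[[1]]$pixel_size
  expect_true(all(abs(det$diameter_um - truth$diameter_um) <= 2 * px))
  expect_true(all(abs(det$cx_px - truth$cx_px) <= 2))
  expect_equal(det$diameter_um, 2 * sqrt(det$area_um2 / pi))
})

test_that("blank frames and the diameter floor behave as specified", {
  blank <- image_frame(matrix(0.8, 200, 200), pixel_size = 4)
  expect_equal(nrow(detect_droplets(blank)), 0)
  # a 100 um droplet is excluded by the default 120 um floor
  small <- synth_droplet_frames(n_frames = 1, droplets_per_frame = 1,
                                diameter_range = c(100, 100), seed = 4)
  expect_equal(nrow(detect_droplets(small$frames[[1]])), 0)
  expect_equal(nrow(detect_droplets(small$frames[[1]], min_diameter = 50)), 1)
  uncal <- image_frame(matrix(0.8, 50, 50))
  expect_error(detect_droplets(uncal), "uncalibrated")
})

test_that("diameter statistics are exact sample moments", {
  d <- data.frame(diameter_um = c(200, 250, 300))
  s <- droplet_diameter_stats(d)
  expect_equal(s[c("n", "mean", "min", "max")],
               data.frame(n = 3L, mean = 250, min = 200, max = 300))
  expect_equal(s$polydispersity, sd(c(200, 250, 300)) / 250)
  one <- droplet_diameter_stats(data.frame(diameter_um = 250))
  expect_equal(one$sd, 0)
  expect_false(one$sd_defined)
  none <- droplet_diameter_stats(data.frame(diameter_um = numeric(0)))
  expect_equal(none$n, 0L)
  expect_true(is.na(none$mean))
})

test_that("mean diameter of many planted droplets concentrates on the target", {
  gen <- synth_droplet_frames(n_frames = 12, droplets_per_frame = 6,
                              diameter_range = c(200, 300), seed = 9)
  det <- do.call(rbind, lapply(seq_along(gen$frames), function(i)
    detect_droplets(gen$frames[[i]], frame_index = i)))
  expect_gte(nrow(det), 0.95 * nrow(gen$truth))
  s <- droplet_diameter_stats(det)
  se <- (100 / sqrt(12)) / sqrt(s$n)  # sd of U(200,300) over sqrt(n)
  expect_lt(abs(s$mean - 250), 3 * se + 2 * gen$params$pixel_size)
})

test_that("spheroid segmentation applies the calibrated area rule", {
  ps <- 2
  px <- matrix(0.85, 400, 400)
  # discs of radius 35 um (area 3848) and 25 um (area 1963)
  for (spec in list(c(100, 100, 35 / ps), c(300, 300, 25 / ps))) {
    dy <- outer(seq_len(400) - spec[1], rep(1, 400))
    dx <- outer(rep(1, 400), seq_len(400) - spec[2])
    px[sqrt(dy^2 + dx^2) <= spec[3]] <- 0.45
  }
  recs <- segment_spheroids(image_frame(px, pixel_size = ps))
  recs <- recs[order(recs$area_um2), ]
  expect_equal(nrow(recs), 2)
  expect_equal(recs$area_um2[2], pi * 35^2, tolerance = 0.03)
  expect_equal(recs$area_um2[1], pi * 25^2, tolerance = 0.03)
  expect_true(recs$included[2])   # 3848 um^2 >= 3000
  expect_false(recs$included[1])  # 1963 um^2 < borderline band
  expect_true(all(recs$circularity > 0.8))  # rasterised discs stay round
  expect_error(segment_spheroids(image_frame(px)), "uncalibrated")
})

test_that("scattered debris below the borderline band is never included", {
  img <- synth_spheroid_image(n_spheroids = 0, n_debris = 20, seed = 6)
  recs <- segment_spheroids(img$frame)
  expect_false(any(recs$included))
})

test_that("inclusion is monotone in area at fixed circularity", {
  mk <- function(area, circ) data.frame(area_um2 = area, circularity = circ)
  rule <- function(df) df$area_um2 >= 3000 |
    (df$area_um2 >= 2500 & df$circularity >= 0.4)
  areas <- seq(1000, 5000, by = 100)
  for (circ in c(0.2, 0.4, 0.9)) {
    inc <- rule(mk(areas, circ))
    expect_true(all(diff(inc) >= 0))  # once included, stays included
  }
})

test_that("areas are invariant to the pixel-size / resolution trade-off", {
  mk_scene <- function(n, ps) {
    px <- matrix(0.85, n, n)
    r_um <- 40
    dy <- outer(seq_len(n) - n / 2, rep(1, n))
    dx <- outer(rep(1, n), seq_len(n) - n / 2)
    px[sqrt(dy^2 + dx^2) <= r_um / ps] <- 0.45
    segment_spheroids(image_frame(px, pixel_size = ps))
  }
  fine <- mk_scene(400, 2)
  coarse <- mk_scene(200, 4)
  expect_equal(coarse$area_um2, fine$area_um2, tolerance = 0.05)
})

test_that("dish/day summaries aggregate included spheroids exactly", {
  recs <- data.frame(area_um2 = c(4000, 6000, 1500, 5000),
                     included = c(TRUE, TRUE, FALSE, TRUE),
                     dish = c("d1", "d1", "d1", "d2"),
                     day = c(6, 6, 6, 6))
  s <- spheroid_area_summary(recs)
  d1 <- s$per_dish[s$per_dish$dish == "d1", ]
  expect_equal(d1$total_area_um2, 10000)
  expect_equal(d1$mean_area_um2, 5000)
  expect_equal(d1$n_spheroids, 2)
  expect_equal(s$per_day$mean_total_area_per_dish, (10000 + 5000) / 2)
  # an empty dish keeps its zero row
  empty <- data.frame(area_um2 = 4000, included = FALSE, dish = "d3", day = 2)
  s0 <- spheroid_area_summary(empty)
  expect_equal(s0$per_dish$total_area_um2, 0)
  expect_equal(s0$per_dish$n_spheroids, 0)
  expect_error(spheroid_area_summary(recs[c("area_um2", "dish")]),
               "lack column")
})
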