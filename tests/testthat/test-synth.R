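test_that("generators are deterministic under a fixed seed", {
  a <- synth_droplet_frames(n_frames = 2, seed = 7)
  b <- synth_droplet_frames(n_frames = 2, seed = 7)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  c <- synth_droplet_frames(n_frames = 2, seed = 8)
  expect_false(identical(a$frames[[1]]$pixels, c$frames[[1]]$pixels))
  s1 <- synth_spheroid_image(seed = 5)
  s2 <- synth_spheroid_image(seed = 5)
  expect_identical(s1$frame$pixels, s2$frame$pixels)
  expect_identical(synth_deg_table(seed = 3), synth_deg_table(seed = 3))
  expect_identical(synth_od_table(seed = 3), synth_od_table(seed = 3))
  expect_identical(synth_ct_table(noise_sd = 0.1, seed = 3),
                   synth_ct_table(noise_sd = 0.1, seed = 3))
})

test_that("the generator seed does not disturb the global RNG stream", {
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(runif(2))
  invisible(synth_droplet_frames(n_frames = 1, seed = 9))
  after <- runif(3)
  expect_identical(before[3:5], after)
})

test_that("droplet ground truth books every planted object exactly once", {
  gen <- synth_droplet_frames(n_frames = 4, droplets_per_frame = 5,
                              include_outliers = TRUE,
                              include_daughters = TRUE, seed = 13)
  expect_equal(sum(gen$truth$kind == "mother"), 4 * 5)
  expect_equal(sum(gen$truth$kind == "daughter"), 4 * 5)
  expect_true(all(gen$truth$diameter_um[gen$truth$kind == "outlier"] < 120))
  expect_true(all(gen$truth$diameter_um[gen$truth$kind == "daughter"] < 120))
  expect_setequal(unique(gen$truth$frame), 1:4)
  expect_error(synth_droplet_frames(diameter_range = c(5000, 6000),
                                    pixel_size = 4, seed = 1),
               "larger than the frame")
})

test_that("default droplet output is recovered at >= 95% by detection", {
  gen <- synth_droplet_frames(seed = 17)  # study defaults: 10 frames
  det <- do.call(rbind, lapply(seq_along(gen$frames), function(i)
    detect_droplets(gen$frames[[i]], frame_index = i)))
  expect_gte(nrow(det), ceiling(0.95 * nrow(gen$truth)))
  expect_lte(nrow(det), nrow(gen$truth))
})

test_that("planted spheroid areas are recovered within 5%", {
  img <- synth_spheroid_image(areas = c(4000, 8000), n_debris = 0,
                              wobble = 0, seed = 31)
  recs <- segment_spheroids(img$frame)
  recs <- recs[order(recs$area_um2), ]
  expect_equal(nrow(recs), 2)
  expect_equal(recs$area_um2, c(4000, 8000), tolerance = 0.05)
  expect_true(all(recs$included))
})

test_that("an image with no spheroids segments to no inclusions", {
  img <- synth_spheroid_image(n_spheroids = 0, seed = 2)
  expect_false(any(segment_spheroids(img$frame)$included))
})

test_that("growth factor orders the planted day totals", {
  study <- synth_spheroid_study(days = c(6, 14), images_per_day = 1,
                                growth_per_day = 1.1, seed = 19)
  tot <- tapply(study$truth$area_um2[study$truth$kind == "spheroid"],
                study$truth$day[study$truth$kind == "spheroid"], sum)
  expect_lt(tot[["6"]], tot[["14"]])
})

test_that("OD tables plant the study viabilities", {
  od <- synth_od_table(seed = 23)
  ctrl <- od$od[od$group == "control"]
  v10 <- viability_percent(od$od[od$group == "10 kV"], ctrl)
  v15 <- viability_percent(od$od[od$group == "15 kV"], ctrl)
  expect_equal(v10, 90, tolerance = 0.05)
  expect_equal(v15, 70, tolerance = 0.05)
})

test_that("Ct tables plant exact fold changes at zero noise", {
  ct <- synth_ct_table(fold_changes = c(GENE = 8), seed = 1)
  dd <- delta_delta_ct(ct, "GENE", "treated", "control")
  expect_equal(dd$ddct, -3)
  expect_equal(dd$fold_change, 8)
  ct2 <- synth_ct_table(seed = 1)  # default chondrogenesis panel
  expect_equal(delta_delta_ct(ct2, "ACAN", "treated", "control")$fold_change,
               8.7, tolerance = 1e-12)
})

test_that("DEG tables recover the planted panel through the filter", {
  deg <- synth_deg_table(seed = 41)
  flt <- deg_filter(deg)
  truth <- attr(deg, "truth")
  expect_true(all(truth$gene[truth$fold_change >= 2] %in% flt$upregulated))
  expect_true("ACAN" %in% flt$upregulated)
  deg10 <- synth_deg_table(voltage = "10kV", lfc_noise_sd = 0, seed = 41)
  expect_equal(deg10$fold_change[deg10$gene == "ACAN"], 4.4)
  # the default ontology term reproduces the 17 up / 3 down partition
  go <- go_term_summary(deg, attr(deg, "go_terms")[[1]])
  expect_equal(go[c("n_members", "n_up", "n_down", "n_unchanged")],
               data.frame(n_members = 20L, n_up = 17L, n_down = 3L,
                          n_unchanged = 0L))
})

test_that("all-null DEG tables yield the nominal false-positive rate", {
  deg <- synth_deg_table(n_null = 2000, planted = data.frame(
    gene = character(0), fold_change = numeric(0)), seed = 29)
  flt <- deg_filter(deg, fc_threshold = 1, p_threshold = 0.05)
  fp <- length(flt$upregulated) + length(flt$downregulated)
  # binomial(2000, 0.05): 3 sigma is about 29
  expect_lt(abs(fp - 100), 3 * sqrt(2000 * 0.05 * 0.95) + 1)
})
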