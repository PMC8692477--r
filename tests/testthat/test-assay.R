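test_that("viability percentage follows the mean-ratio formula", {
  expect_equal(viability_percent(c(0.5, 0.5), c(0.5, 0.5)), 100)
  ctrl <- c(0.41, 0.52, 0.47)
  expect_equal(viability_percent(0.9 * ctrl, ctrl), 90)
  # scaling every OD by a positive constant changes nothing
  expect_equal(viability_percent(3.7 * 0.9 * ctrl, 3.7 * ctrl), 90)
  set.seed(2)
  for (i in 1:10) {
    s <- runif(4); ct <- runif(4, 0.1, 1)
    expect_equal(viability_percent(s, ct), 100 * mean(s) / mean(ct),
                 tolerance = 1e-12)
  }
  expect_error(viability_percent(numeric(0), ctrl), "non-empty")
  expect_error(viability_percent(ctrl, c(0, 0)), "control mean OD is zero")
})

test_that("delta-delta-Ct matches the spreadsheet computation", {
  tab <- data.frame(sample = rep(c("cal", "trt"), each = 2),
                    gene = rep(c("GAPDH", "TG"), 2),
                    ct = c(16, 24, 16, 24))
  expect_equal(delta_delta_ct(tab, "TG", "trt", "cal")$fold_change, 1)
  tab$ct[4] <- 21  # treated target 3 cycles earlier: ddCt = -3
  dd <- delta_delta_ct(tab, "TG", "trt", "cal")
  expect_equal(dd$ddct, -3)
  expect_equal(dd$fold_change, 8)
  # swapping treated and calibrator inverts the fold change exactly
  inv <- delta_delta_ct(tab, "TG", "cal", "trt")
  expect_equal(inv$fold_change, 1 / dd$fold_change)
  # random tables against an independent brute-force evaluation
  set.seed(8)
  for (i in 1:10) {
    ct <- synth_ct_table(fold_changes = c(X = runif(1, 0.2, 10)),
                         noise_sd = 0.3, seed = i)
    got <- delta_delta_ct(ct, "X", "treated", "control")$fold_change
    pick <- function(s, g) ct$ct[ct$sample == s & ct$gene == g]
    want <- 2^(-((pick("treated", "X") - pick("treated", "GAPDH")) -
                   (pick("control", "X") - pick("control", "GAPDH"))))
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(delta_delta_ct(tab, "MISSING", "trt", "cal"),
               "gene 'MISSING' in sample 'trt'")
})

test_that("DEG filtering applies the documented boundary rules", {
  tab <- data.frame(gene = c("up", "weak", "down", "null", "edge"),
                    fold_change = c(8.7, 1.4, 0.4, 1.01, 1.5),
                    p_value = c(0.01, 0.001, 0.02, 0.5, 0.049))
  flt <- deg_filter(tab)
  expect_setequal(flt$upregulated, c("up", "edge"))  # FC boundary inclusive
  expect_equal(flt$downregulated, "down")
  expect_length(intersect(flt$upregulated, flt$downregulated), 0)
  tab$p_value[1] <- 0.05  # p boundary strict
  expect_false("up" %in% deg_filter(tab)$upregulated)
  expect_error(deg_filter(data.frame(gene = "g", fold_change = -1,
                                     p_value = 0.5)), "positive ratios")
})

test_that("DEG filtering equals a brute-force row scan and is monotone", {
  set.seed(12)
  tab <- data.frame(gene = sprintf("g%04d", 1:1000),
                    fold_change = 2^rnorm(1000, 0, 1),
                    p_value = runif(1000))
  flt <- deg_filter(tab)
  up <- character(0); down <- character(0)
  for (r in seq_len(nrow(tab))) {
    if (tab$p_value[r] < 0.05 && tab$fold_change[r] >= 1.5)
      up <- c(up, tab$gene[r])
    if (tab$p_value[r] < 0.05 && tab$fold_change[r] <= 1 / 1.5)
      down <- c(down, tab$gene[r])
  }
  expect_identical(flt$upregulated, up)
  expect_identical(flt$downregulated, down)
  stricter <- deg_filter(tab, fc_threshold = 2, p_threshold = 0.01)
  expect_true(all(stricter$upregulated %in% flt$upregulated))
  expect_true(all(stricter$downregulated %in% flt$downregulated))
})

test_that("GO tallies partition the term and warn about absent members", {
  set.seed(4)
  tab <- data.frame(gene = sprintf("g%02d", 1:40),
                    fold_change = 2^rnorm(40, 0, 1.2),
                    p_value = runif(40, 0, 0.2))
  term <- sprintf("g%02d", sample(40, 15))
  go <- go_term_summary(tab, term)
  expect_equal(go$n_up + go$n_down + go$n_unchanged, go$n_members)
  flt <- deg_filter(tab)
  expect_equal(go$n_up, length(intersect(term, flt$upregulated)))
  expect_equal(go$n_down, length(intersect(term, flt$downregulated)))
  expect_warning(out <- go_term_summary(tab, c("absent1", "absent2")),
                 "absent")
  expect_equal(out$n_unchanged, 2)
  expect_error(go_term_summary(tab, character(0)), "empty")
})

test_that("absorbance summaries report exact moments and control ratios", {
  tab <- data.frame(group = rep(c("control", "treated"), each = 3),
                    od = c(0.2, 0.2, 0.2, 0.4, 0.4, 0.4))
  s <- absorbance_summary(tab)
  expect_equal(s$ratio_to_control[s$group == "treated"], 2)
  expect_equal(s$ratio_to_control[s$group == "control"], 1)
  set.seed(6)
  tab2 <- data.frame(group = rep(c("control", "a", "b"), each = 4),
                     od = runif(12))
  s2 <- absorbance_summary(tab2)
  for (g in unique(tab2$group)) {
    v <- tab2$od[tab2$group == g]
    expect_equal(s2$mean_od[s2$group == g], mean(v), tolerance = 1e-12)
    expect_equal(s2$sd_od[s2$group == g], sd(v), tolerance = 1e-12)
  }
  expect_error(absorbance_summary(tab, control_group = "nope"),
               "not present")
})

test_that("group comparisons flag separation and not identity", {
  same <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  res <- group_compare(same, g)
  expect_equal(res$test, "Welch two-sample t-test")
  expect_gt(res$p_value, 0.9)
  expect_false(res$significant)
  set.seed(14)
  x <- c(rnorm(10, 0), rnorm(10, 5))
  res2 <- group_compare(x, rep(c("a", "b"), each = 10))
  expect_true(res2$significant)  # power at 5-sigma separation is ~ 1
  expect_error(group_compare(1:3, c("a", "a", "b")), "at least two replicates")
  expect_error(group_compare(1:4, rep("a", 4)), "at least two groups")
})

test_that("ANOVA layers behave under null and structured designs", {
  set.seed(15)
  # three equal-mean groups: type-I rate stays near alpha under resampling
  p <- replicate(300, {
    v <- rnorm(15)
    group_compare(v, rep(c("a", "b", "c"), each = 5), test = "anova",
                  posthoc = FALSE)$p_value
  })
  frac <- mean(p <= 0.05)
  expect_lt(frac, 0.12)
  expect_gt(mean(p), 0.35)  # roughly uniform p under the null
  # Tukey post hoc appears on a significant one-way ANOVA
  v <- c(rnorm(6, 0), rnorm(6, 4), rnorm(6, 8))
  res <- group_compare(v, rep(c("a", "b", "c"), each = 6), test = "anova")
  expect_true(res$significant)
  expect_s3_class(res$posthoc, "TukeyHSD")
  # two-way design reports per-term p-values
  d <- expand.grid(voltage = c("10kV", "15kV"), day = c("d6", "d14"),
                   rep = 1:3)
  y <- rnorm(nrow(d)) + 2 * (d$voltage == "15kV")
  res2 <- group_compare(y, d$voltage, d$day)
  expect_equal(res2$test, "two-way ANOVA")
  expect_length(res2$p_value, 3)  # main effects + interaction
})
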