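# Bulk-volume inference: omnibus tests, effect sizes, the three adjustment
# strategies, multiplicity control, and the battery.

two_group_table <- function(a, b, kt = c("XY", "XXY"), region = "amygdala") {
  toy_subjects(
    log_tbv = rep(3.1, length(a) + length(b)),
    log_region = log10(c(a, b)),
    sex = rep("M", length(a) + length(b)),
    karyotype = rep(kt, c(length(a), length(b))),
    region = region
  )
}

test_that("omnibus F is zero for identical constant groups", {
  d <- two_group_table(c(2, 2, 2), c(2, 2, 2))
  suppressWarnings(om <- omnibus_group_test(d, "amygdala"))
  expect_equal(om$F, 0)
})

test_that("omnibus type-I error is nominal under a common distribution", {
  rej <- vapply(1:400, function(s) {
    set.seed(s)
    v <- rnorm(40, 2.3, 0.2)
    d <- toy_subjects(rep(3.1, 40), log10(pmax(v, 0.1)),
                      karyotype = rep(c("XY", "XXY", "XYY", "XXYY"), 10),
                      sex = rep("M", 40))
    omnibus_group_test(d, "amygdala")$p < 0.05
  }, logical(1))
  # 99% binomial CI around 0.05 at n = 400: +/- 0.028
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("omnibus detects the calibrated karyotype volume shifts", {
  hits <- vapply(1:25, function(s) {
    core <- generate_subjects(sca_config(seed = 5000 + s))
    omnibus_group_test(core, "amygdala")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pooled two-sample t matches the hand-computed value", {
  res <- posthoc_raw_contrast(
    two_group_table(c(2.4, 2.5, 2.6), c(2.0, 2.1, 2.2), kt = c("XY", "XXY")),
    "amygdala", "XXY", "XY"
  )
  expect_equal(res$t, -4.898979, tolerance = 1e-5)
  expect_equal(res$p, 2 * pt(-4.898979, df = 4), tolerance = 1e-5)
  expect_lt(res$estimate, 0)

  # identical groups: t = 0, p = 1
  res0 <- posthoc_raw_contrast(
    two_group_table(c(2.0, 2.1, 2.2), c(2.0, 2.1, 2.2)),
    "amygdala", "XXY", "XY"
  )
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
})

test_that("effect size uses the reference-group SD and sign convention", {
  d <- two_group_table(c(2, 4), c(2, 2), kt = c("XY", "XXY"))
  expect_equal(effect_size_vs_reference(d, "XXY", "amygdala"),
               1 / sqrt(2), tolerance = 1e-10)
  expect_equal(effect_size_vs_reference(d, "XY", "amygdala"), 0)
  # group larger than reference => negative d
  d2 <- two_group_table(c(2, 4), c(5, 5), kt = c("XY", "XXY"))
  expect_lt(effect_size_vs_reference(d2, "XXY", "amygdala"), 0)
  expect_error(effect_size_vs_reference(
    two_group_table(c(2, 2), c(3, 3)), "XXY", "amygdala"), "zero SD")
})

test_that("Bonferroni is min(1, m*p) and monotone", {
  p <- c(0.001, 0.02, 0.2, 0.5, 0.9)
  expect_equal(bonferroni_adjust(p, 5), pmin(1, 5 * p))
  expect_true(all(diff(bonferroni_adjust(sort(p), 5)) >= 0))
})

test_that("allometric contrast equals pooled t on deviations and respects shifts", {
  cfg <- sca_config(seed = 31)
  core <- generate_subjects(cfg)
  norm <- generate_subjects(cfg, "normative")
  fit <- allom(norm, "amygdala", tier = "simple")
  res <- allometric_contrast(core, fit, "XXY", "XY")

  dev <- allometric_deviation(fit, core)
  a <- dev[core$karyotype == "XXY"]; b <- dev[core$karyotype == "XY"]
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(res$estimate, mean(a) - mean(b), tolerance = 1e-10)
  expect_equal(res$p_adj, min(1, 5 * res$p))

  # shift equivariance: subtracting delta from one group moves the estimate
  shifted <- as.data.frame(core)
  sel <- shifted$karyotype == "XXY"
  shifted$amygdala[sel] <- shifted$amygdala[sel] * 10^(-0.1)
  class(shifted) <- c("subject_table", "data.frame")
  attr(shifted, "sample_label") <- "core"
  res2 <- allometric_contrast(shifted, fit, "XXY", "XY")
  expect_equal(res2$estimate, res$estimate - 0.1, tolerance = 1e-10)
})

test_that("leakage guard refuses a model trained on the core sample", {
  core <- generate_subjects(sca_config(seed = 33))
  fit_core <- allom(core, "amygdala", tier = "simple")
  expect_error(allometric_contrast(core, fit_core, "XXY", "XY"), "leakage")
  expect_s3_class(
    allometric_contrast(core, fit_core, "XXY", "XY", allow_leakage = TRUE),
    "sca_contrast"
  )
})

test_that("covariation recovers an exactly linear group effect", {
  lt <- rep(c(3.05, 3.10, 3.15, 3.20), 2)
  tbv <- 10^lt
  grp <- rep(c("XY", "XXY"), each = 4)
  v <- 0.001 * tbv + 0.1 * (grp == "XXY")
  d <- toy_subjects(lt, log10(v), karyotype = grp, sex = rep("M", 8))
  # constructed exact fit: lm warns about the perfect fit by design
  suppressWarnings(res <- covariation_contrast(d, "amygdala", "XXY", "XY"))
  expect_equal(res$estimate, 0.1, tolerance = 1e-10)
  # identical groups: estimate 0
  d0 <- two_group_table(c(2.0, 2.2, 2.4), c(2.0, 2.2, 2.4))
  expect_equal(normalization_contrast(d0, "amygdala", "XXY", "XY")$estimate, 0,
               tolerance = 1e-12)
})

test_that("normalization flags a spurious effect under hypoallometry; allometric and covariation do not", {
  kt <- c("XX", "XY", "XXX", "XXY", "XYY", "XXYY", "XXXXY")
  zero <- setNames(rep(0, 7), kt)
  rates <- sapply(1:20, function(s) {
    cfg <- sca_config(
      group_n = setNames(c(0, 200, 0, 200, 0, 0, 0), kt),
      tbv_mean = setNames(c(1261, 1261, 1179, 1392, 1418, 1291, 1131), kt),
      offsets = list(amygdala = zero, hippocampus = zero),
      normative_n = 400, normative_n_female = 200,
      seed = 6000 + s
    )
    core <- generate_subjects(cfg)
    norm <- generate_subjects(cfg, "normative")
    fit <- allom(norm, "hippocampus", tier = "simple")
    c(
      norm_ = normalization_contrast(core, "hippocampus", "XXY", "XY", m = 1)$p < 0.05,
      allo = allometric_contrast(core, fit, "XXY", "XY", m = 1)$p < 0.05,
      cov = covariation_contrast(core, "hippocampus", "XXY", "XY", m = 1)$p < 0.05
    )
  })
  expect_gt(mean(rates["norm_", ]), 0.5)
  expect_lt(mean(rates["allo", ]), 0.2)
  expect_lt(mean(rates["cov", ]), 0.2)
})

test_that("the three methods agree under isometry with matched groups", {
  kt <- c("XX", "XY", "XXX", "XXY", "XYY", "XXYY", "XXXXY")
  zero <- setNames(rep(0, 7), kt)
  off <- zero; off["XXY"] <- -0.05
  cfg <- sca_config(
    group_n = setNames(c(0, 400, 0, 400, 0, 0, 0), kt),
    tbv_mean = setNames(rep(1300, 7), kt),
    tbv_sd = setNames(rep(110, 7), kt),
    beta1 = c(amygdala = 1, hippocampus = 1),
    offsets = list(amygdala = off, hippocampus = off),
    seed = 71
  )
  core <- generate_subjects(cfg)
  norm <- generate_subjects(cfg, "normative")
  fit <- allom(norm, "amygdala", tier = "simple")
  res <- list(
    normalization_contrast(core, "amygdala", "XXY", "XY", m = 1),
    allometric_contrast(core, fit, "XXY", "XY", m = 1),
    covariation_contrast(core, "amygdala", "XXY", "XY", m = 1)
  )
  expect_true(all(vapply(res, function(r) r$estimate < 0, logical(1))))
  expect_true(all(vapply(res, function(r) r$p < 0.05, logical(1))))
})

test_that("the battery covers all methods and contrasts in sorted order", {
  cfg <- sca_config(seed = 41)
  core <- generate_subjects(cfg)
  norm <- generate_subjects(cfg, "normative")
  bat <- run_volume_battery(core, norm)
  expect_equal(nrow(bat), 2 * 4 * 6)
  expect_setequal(unique(bat$method),
                  c("raw", "allometric", "normalization", "covariation"))
  expect_setequal(unique(bat$contrast),
                  c("XXX-XX", "XXY-XY", "XYY-XY", "XXYY-XY", "XXXXY-XY",
                    "XX-XY"))
  ord <- order(bat$region, bat$method, bat$contrast)
  expect_equal(ord, seq_len(nrow(bat)))

  # calibrated X-dosage amygdala deficits come out negative and significant
  amy <- bat[bat$region == "amygdala" & bat$method == "allometric" &
               bat$contrast %in% c("XXX-XX", "XXY-XY", "XXYY-XY"), ]
  expect_true(all(amy$estimate < 0))
  expect_true(all(amy$p_adj < 0.05))
  # raw XXX amygdala contrast negative (supernumerary X decreases volume)
  raw_xxx <- bat[bat$region == "amygdala" & bat$method == "raw" &
                   bat$contrast == "XXX-XX", ]
  expect_lt(raw_xxx$estimate, 0)

  grid <- contrast_grid(as.data.frame(bat))
  expect_equal(nrow(grid), 8)
  # grid sign convention: a significant deficit shows as a negative cell
  sig_neg <- bat$p_adj < 0.05 & bat$estimate < 0
  one <- bat[sig_neg, ][1, ]
  cell <- grid[grid$region == one$region & grid$method == one$method,
               paste0("signed_logp.", one$contrast)]
  expect_lt(cell, 0)
})

test_that("covariate-adjusted contrasts drop missing-Tanner subjects", {
  cfg <- sca_config(seed = 43)
  core <- generate_subjects(cfg)
  expect_message(
    res <- allometric_contrast(core, allom(generate_subjects(cfg, "normative"),
                                           "amygdala", tier = "simple"),
                               "XXY", "XY", covariates = c("age", "tanner")),
    "missing"
  )
  # 79 XY + 56 XXY minus 3 XY and 1 XXY with missing Tanner
  expect_equal(res$n_comparison + res$n_control, 131)
})

test_that("empty comparison groups raise an error", {
  d <- two_group_table(c(2.0, 2.1), c(2.2, 2.3), kt = c("XY", "XXY"))
  expect_error(posthoc_raw_contrast(d, "amygdala", "XYY", "XY"), "empty")
})
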