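# Vertex-wise surface allometry, deviation contrasts, FDR control,
# map correlation and robustness accounting.

make_vertex_fixture <- function(seed = 1, ...) {
  cfg <- small_cfg(seed = seed, ...)
  core <- generate_subjects(cfg)
  norm <- generate_subjects(cfg, "normative")
  mesh <- build_mesh(cfg)
  list(cfg = cfg, core = core, norm = norm, mesh = mesh,
       nv = generate_vertex_table(cfg, norm, mesh),
       cv = generate_vertex_table(cfg, core, mesh, seed = seed + 500))
}

test_that("vectorized per-vertex OLS matches lm at every vertex", {
  fx <- make_vertex_fixture(seed = 51)
  field <- fit_vertex_normative(fx$nv)
  Y <- log10(fx$nv$areas)
  logS <- log10(100 * fx$norm$amygdala_sa)
  idx <- which(fx$mesh$region == "amygdala")
  for (j in sample(idx, 5)) {
    ref <- lm(Y[, j] ~ logS)
    expect_equal(unname(field$coefficients["intercept", j]),
                 unname(coef(ref)[1]), tolerance = 1e-8)
    expect_equal(unname(field$coefficients["exponent", j]),
                 unname(coef(ref)[2]), tolerance = 1e-8)
    expect_equal(unname(field$exponent_se[j]),
                 unname(coef(summary(ref))[2, 2]), tolerance = 1e-8)
  }
})

test_that("noiseless uniform isometry recovers exponent 1 everywhere", {
  fx <- make_vertex_fixture(seed = 52, exponent_range = c(1, 1),
                            focal_amplitude = 0, sigma_vertex = 0)
  field <- fit_vertex_normative(fx$nv)
  expect_equal(unname(field$exponent), rep(1, nrow(fx$mesh)),
               tolerance = 1e-8)
})

test_that("the fitted exponent field correlates with the generating field", {
  rs <- vapply(1:5, function(s) {
    cfg <- sca_config(seed = 7000 + s)
    norm <- generate_subjects(cfg, "normative")
    nv <- generate_vertex_table(cfg, norm)
    field <- fit_vertex_normative(nv)
    cor(field$exponent, nv$true_exponent)
  }, numeric(1))
  expect_gte(mean(rs), 0.8)
})

test_that("training-sample vertex deviations average to zero", {
  fx <- make_vertex_fixture(seed = 53)
  field <- fit_vertex_normative(fx$nv)
  dev <- vertex_deviations(field, fx$nv)
  expect_lt(max(abs(colMeans(dev))), 1e-10)
})

test_that("doubling area and total leaves deviations unchanged only at isometry", {
  fx <- make_vertex_fixture(seed = 54, exponent_range = c(1, 1),
                            focal_amplitude = 0, sigma_vertex = 0)
  field <- fit_vertex_normative(fx$nv)
  doubled <- fx$nv
  doubled$areas <- doubled$areas * 2
  sub2 <- as.data.frame(doubled$subjects)
  sub2$amygdala_sa <- sub2$amygdala_sa * 2
  sub2$hippocampus_sa <- sub2$hippocampus_sa * 2
  class(sub2) <- c("subject_table", "data.frame")
  attr(sub2, "sample_label") <- "normative"
  doubled$subjects <- sub2
  dev0 <- vertex_deviations(field, fx$nv)
  dev2 <- vertex_deviations(field, doubled)
  expect_equal(dev2, dev0, tolerance = 1e-8)

  # with heterogeneous exponents the same doubling shifts the deviation at
  # vertex v by (1 - beta1_v) * log10(2): unchanged only where beta1_v = 1
  fx2 <- make_vertex_fixture(seed = 55)
  field2 <- fit_vertex_normative(fx2$nv)
  doubled2 <- fx2$nv
  doubled2$areas <- doubled2$areas * 2
  sub3 <- as.data.frame(doubled2$subjects)
  sub3$amygdala_sa <- sub3$amygdala_sa * 2
  sub3$hippocampus_sa <- sub3$hippocampus_sa * 2
  class(sub3) <- c("subject_table", "data.frame")
  attr(sub3, "sample_label") <- "normative"
  doubled2$subjects <- sub3
  diff2 <- vertex_deviations(field2, doubled2) -
    vertex_deviations(field2, fx2$nv)
  expect_equal(unname(diff2[1, ]),
               unname((1 - field2$exponent) * log10(2)),
               tolerance = 1e-8)
})

test_that("BH rejection in vertex_contrast reproduces the step-up rule", {
  # hand example: thresholds k*q/m = 0.0125, 0.025, 0.0375, 0.05
  p <- c(0.01, 0.02, 0.04, 0.5)
  expect_equal(bh_reject_oracle(p, 0.05), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(p.adjust(p, "BH") < 0.05), bh_reject_oracle(p, 0.05))
  # random vectors: p.adjust-based rejections equal the brute-force oracle
  set.seed(99)
  for (i in 1:200) {
    pv <- runif(sample(3:60, 1))^sample(1:3, 1)
    expect_equal(unname(p.adjust(pv, "BH") < 0.05), bh_reject_oracle(pv, 0.05))
  }
})

test_that("identical groups give an empty mask and zero t", {
  fx <- make_vertex_fixture(seed = 56)
  dev <- vertex_deviations(fit_vertex_normative(fx$nv), fx$cv)
  # duplicate the XY rows as a fake comparison group
  sel <- fx$core$karyotype == "XY"
  dev2 <- rbind(dev[sel, ], dev[sel, ])
  sub2 <- as.data.frame(rbind(fx$core[sel, ], fx$core[sel, ]))
  sub2$karyotype <- rep(c("XY", "XXY"), each = sum(sel))
  sub2$sex <- "M"
  sub2$subject <- sprintf("dup_%03d", seq_len(nrow(sub2)))
  class(sub2) <- c("subject_table", "data.frame")
  map <- vertex_contrast(dev2, sub2, fx$mesh, "XXY", "XY")
  expect_lt(max(abs(map$t)), 1e-8)
  expect_false(any(map$mask))
})

test_that("masks concentrate on the focal fields and XYY is attenuated", {
  fx <- make_vertex_fixture(seed = 57)
  field <- fit_vertex_normative(fx$nv)
  dev <- vertex_deviations(field, fx$cv)
  xxy <- vertex_contrast(dev, fx$core, fx$mesh, "XXY", "XY")
  xyy <- vertex_contrast(dev, fx$core, fx$mesh, "XYY", "XY")
  bump <- abs(fx$cv$focal[, "XXY"]) > 0.02
  expect_gt(mean(xxy$mask[bump]), mean(xxy$mask[!bump]))
  expect_lt(sum(xyy$mask), sum(xxy$mask))
  # mask implies q below level; direction is sign-consistent with t
  expect_true(all(xxy$q[xxy$mask] < 0.05))
  expect_true(all((xxy$direction == "contraction") == (xxy$t < 0)))
})

test_that("map correlation is exact on constructed vectors and invariant to reordering", {
  mk_map <- function(tv, mesh) {
    structure(list(contrast = "a-b", mesh = mesh, t = tv,
                   p = rep(0.5, length(tv)), q = rep(0.5, length(tv)),
                   mask = rep(FALSE, length(tv)),
                   direction = ifelse(tv < 0, "contraction", "expansion"),
                   q_level = 0.05), class = "vertex_map")
  }
  mesh <- data.frame(structure = rep("s", 3), region = rep("r", 3),
                     vertex = 0:2)
  m1 <- mk_map(c(1, 2, 3), mesh)
  m2 <- mk_map(c(2, 4, 6.5), mesh)
  mc <- map_correlation(list(a = m1, b = m2), by = "region")
  expect_equal(mc$r["a-b", "a-b"], 1)
  # direct Pearson on the constructed vectors: 0.9979487
  expect_equal(unname(mc$r[1, 2]), 0.9979487, tolerance = 1e-6)
  # self and negation
  mc2 <- map_correlation(list(a = m1, b = mk_map(c(-1, -2, -3), mesh)))
  expect_equal(unname(mc2$r[1, 2]), -1)

  # consistent vertex reordering leaves correlations unchanged
  fx <- make_vertex_fixture(seed = 58)
  dev <- vertex_deviations(fit_vertex_normative(fx$nv), fx$cv)
  a <- vertex_contrast(dev, fx$core, fx$mesh, "XXY", "XY")
  b <- vertex_contrast(dev, fx$core, fx$mesh, "XXX", "XX")
  r0 <- map_correlation(list(a = a, b = b))
  perm <- sample(seq_len(nrow(fx$mesh)))
  ap <- a; bp <- b
  ap$t <- a$t[perm]; bp$t <- b$t[perm]
  ap$mesh <- a$mesh[perm, ]; bp$mesh <- b$mesh[perm, ]
  rp <- map_correlation(list(a = ap, b = bp))
  expect_equal(rp$amygdala[1, 2], r0$amygdala[1, 2], tolerance = 1e-12)

  # constant map warns and reports NA
  expect_warning(
    mcc <- map_correlation(list(a = m1, b = mk_map(c(1, 1, 1), mesh))),
    "constant"
  )
  expect_true(is.na(mcc$r[1, 2]))
})

test_that("shared focal locations drive inter-contrast map correlation", {
  mean_off_diag <- function(m) mean(m[upper.tri(m)])
  pair_r <- function(shared, seed) {
    kt <- c("XX", "XY", "XXX", "XXY", "XYY", "XXYY", "XXXXY")
    zero <- setNames(rep(0, 7), kt)
    cfg <- small_cfg(
      seed = seed,
      tbv_mean = setNames(rep(1300, 7), kt),
      tbv_sd = setNames(rep(110, 7), kt),
      offsets = list(amygdala = zero, hippocampus = zero),
      focal_shared = shared
    )
    core <- generate_subjects(cfg)
    norm <- generate_subjects(cfg, "normative")
    mesh <- build_mesh(cfg)
    nv <- generate_vertex_table(cfg, norm, mesh)
    cv <- generate_vertex_table(cfg, core, mesh, seed = seed + 900)
    dev <- vertex_deviations(fit_vertex_normative(nv), cv)
    ctr <- list(XXX = "XX", XXY = "XY", XXYY = "XY")
    maps <- lapply(names(ctr), function(k)
      vertex_contrast(dev, core, mesh, k, ctr[[k]]))
    mc <- map_correlation(maps)
    mean(c(mean_off_diag(mc$amygdala), mean_off_diag(mc$hippocampus)))
  }
  shared <- mean(vapply(1:3, function(s) pair_r(TRUE, 8000 + s), numeric(1)))
  reloc <- mean(vapply(1:3, function(s) pair_r(FALSE, 8000 + s), numeric(1)))
  expect_gt(shared, 0)
  expect_gt(shared, reloc)
})

test_that("robustness survival counts per contrast and pooled", {
  m1 <- list(a = c(TRUE, TRUE, TRUE, FALSE), b = rep(TRUE, 4))
  m2 <- list(a = c(TRUE, FALSE, TRUE, FALSE), b = rep(FALSE, 4))
  out <- robustness_vertex_survival(m1, m2)
  expect_equal(out$fraction[out$contrast == "a"], 2 / 3)
  expect_equal(out$fraction[out$contrast == "b"], 0)
  expect_equal(out$fraction[out$contrast == "pooled"], 2 / 7)
  # identical runs: fraction 1
  out2 <- robustness_vertex_survival(m1, m1)
  expect_true(all(out2$fraction == 1))
})

test_that("covariate-adjusted vertex contrasts retain most significant vertices", {
  fx <- make_vertex_fixture(seed = 59)
  field <- fit_vertex_normative(fx$nv)
  dev <- vertex_deviations(field, fx$cv)
  main <- vertex_contrast(dev, fx$core, fx$mesh, "XXY", "XY")
  suppressMessages(
    adj <- vertex_contrast(dev, fx$core, fx$mesh, "XXY", "XY",
                           covariates = c("age", "tanner"))
  )
  surv <- robustness_vertex_survival(list(XXY = main), list(XXY = adj))
  expect_gt(surv$fraction[surv$contrast == "XXY"], 0.7)
})

test_that("group-size and mesh-mismatch preconditions are enforced", {
  fx <- make_vertex_fixture(seed = 60)
  field <- fit_vertex_normative(fx$nv)
  dev <- vertex_deviations(field, fx$cv)
  drop_idx <- which(fx$core$karyotype == "XYY")[-1]
  expect_error(
    vertex_contrast(dev[-drop_idx, ], fx$core[-drop_idx, ], fx$mesh,
                    "XYY", "XY"),
    ">= 2")
  other <- generate_vertex_table(small_cfg(seed = 61,
                                           vertex_counts = c(50, 50, 50, 50)),
                                 fx$core)
  expect_error(vertex_deviations(field, other), "mesh")
})
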