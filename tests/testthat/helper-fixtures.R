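# Shared fixtures: small configurations and hand-built tables.

# Reduced mesh keeps vertex-wise tests fast; geometry/statistics unchanged.
small_cfg <- function(seed = 1, vertex_counts = c(60, 60, 60, 60), ...) {
  sca_config(vertex_counts = vertex_counts, seed = seed, ...)
}

# Config with every group-level effect switched off and a single shared TBV
# distribution: data generated from it satisfy the downstream null for both
# the deviation contrasts and the vertex FDR machinery.
null_cfg <- function(seed = 1, ...) {
  kt <- c("XX", "XY", "XXX", "XXY", "XYY", "XXYY", "XXXXY")
  zero <- setNames(rep(0, 7), kt)
  sca_config(
    tbv_mean = setNames(rep(1300, 7), kt),
    tbv_sd = setNames(rep(110, 7), kt),
    offsets = list(amygdala = zero, hippocampus = zero),
    focal_amplitude = 0,
    seed = seed, ...
  )
}

# Deterministic toy subject table built by hand (no generator involvement).
toy_subjects <- function(log_tbv, log_region, sex = NULL, region = "amygdala",
                         karyotype = NULL) {
  n <- length(log_tbv)
  if (is.null(sex)) sex <- rep("M", n)
  if (is.null(karyotype)) karyotype <- ifelse(sex == "F", "XX", "XY")
  other <- setdiff(c("amygdala", "hippocampus"), region)
  d <- data.frame(
    subject = sprintf("toy_%02d", seq_len(n)),
    karyotype = karyotype, sex = sex,
    age = rep(12, n), tanner = rep(3L, n),
    tbv = 10^log_tbv, stringsAsFactors = FALSE
  )
  d[[region]] <- 10^log_region
  d[[other]] <- rep(1, n)
  d$amygdala_sa <- rep(18, n)
  d$hippocampus_sa <- rep(27, n)
  as_subject_table(d, sample_label = "toy")
}

# Independent Benjamini-Hochberg step-up oracle: brute-force enumeration of
# the largest k with p_(k) <= k*q/m.
bh_reject_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Closed-form OLS via normal equations, independent of lm().
ols_oracle <- function(X, y) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  list(beta = drop(beta), se = sqrt(diag(XtXi) * s2), df = df)
}
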