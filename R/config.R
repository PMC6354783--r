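## Study-design constants and the generator configuration object.

# Karyotype groups of the core cohort, in canonical order.
KARYOTYPES <- c("XX", "XY", "XXX", "XXY", "XYY", "XXYY", "XXXXY")

# Gonadal sex implied by karyotype: XX-like karyotypes without a Y are female.
KARYOTYPE_SEX <- c(
  XX = "F", XY = "M", XXX = "F", XXY = "M", XYY = "M",
  XXYY = "M", XXXXY = "M"
)

# Gonadal control for each SCA contrast: XXX vs XX, Y-bearing SCAs vs XY.
SCA_CONTRASTS <- list(
  XXX   = "XX",
  XXY   = "XY",
  XYY   = "XY",
  XXYY  = "XY",
  XXXXY = "XY"
)

REGIONS <- c("amygdala", "hippocampus")

# Published descriptive statistics of the reference cohort: group sizes and
# per-group mean / SEM of total brain volume and bilateral regional volumes
# (cm^3). These anchor the synthetic generator's default calibration.
COHORT_TABLE <- local({
  d <- data.frame(
    karyotype = KARYOTYPES,
    n         = c(87, 79, 28, 56, 25, 19, 5),
    tbv_mean  = c(1261, 1392, 1179, 1287, 1418, 1291, 1131),
    tbv_sem   = c(9.74, 13.8, 22.8, 17.8, 24.9, 29.7, 36.1),
    amy_mean  = c(2.32, 2.54, 2.05, 2.26, 2.43, 2.19, 1.86),
    amy_sem   = c(0.02, 0.03, 0.04, 0.03, 0.06, 0.05, 0.06),
    hip_mean  = c(4.30, 4.57, 3.98, 4.32, 4.68, 4.33, 3.82),
    hip_sem   = c(0.04, 0.05, 0.07, 0.07, 0.12, 0.12, 0.13),
    stringsAsFactors = FALSE
  )
  rownames(d) <- d$karyotype
  d
})

# Surface mesh composition: local-area vertices per structure.
MESH_COUNTS <- c(
  amygdala_right    = 1405,
  amygdala_left     = 1473,
  hippocampus_right = 1215,
  hippocampus_left  = 1152
)

#' Synthetic cohort generator configuration
#'
#' Builds the configuration object consumed by [generate_subjects()] and
#' [generate_vertex_table()]. Defaults emulate a cross-sectional
#' sex-chromosome-aneuploidy (SCA) study design: a core cohort of 298
#' subjects across seven karyotypes calibrated to published per-group total
#' brain volume (TBV) and regional volume statistics, plus an independent
#' normative sample of 79 typically developing XX/XY subjects used to fit
#' allometric scaling rules.
#'
#' Regional volumes follow the normative power law
#' \deqn{\log_{10} V_{region} = \beta_0 + \beta_1 \log_{10} V_{tbv} +
#'   \delta_k + \epsilon}
#' with hypoallometric default exponents (amygdala 0.89, hippocampus 0.76),
#' additive karyotype offsets \eqn{\delta_k} (exactly 0 for XX and XY) derived
#' from the published group means, and Gaussian residual noise. Total
#' bilateral surface area per region is linked to volume by a geometric
#' power law \eqn{S \propto V^{2/3}} with log-normal coupling noise whose SD
#' is computed in closed form so that the volume--surface Pearson correlation
#' in a default core sample matches the configured targets (0.97 amygdala,
#' 0.89 hippocampus).
#'
#' @param group_n named integer vector of core-sample sizes per karyotype.
#' @param tbv_mean,tbv_sd named numeric vectors (cm^3) of per-karyotype TBV
#'   mean and SD. Default SDs are published SEM times sqrt(n).
#' @param beta1 named numeric vector of true scaling exponents per region.
#' @param beta0 named numeric vector of true intercepts (log10 cm^3);
#'   defaults anchor the XY group mean exactly on the law.
#' @param offsets named list (per region) of per-karyotype additive offsets
#'   in log10 units; defaults derived from the published group means, with
#'   XX and XY forced to 0.
#' @param sigma_logvol named numeric vector, residual SD of log10 regional
#'   volume per region (log10 units).
#' @param sex_effect,sex_size_interaction per-region additive sex effect and
#'   sex-by-size interaction magnitudes (log10 units; male coded 1). Default
#'   0, matching the absence of normative sex effects.
#' @param surface_r_target per-region target Pearson correlation between
#'   regional volume and total regional surface area; drives the coupling
#'   noise calibration.
#' @param surface_coef surface link constant c in S = c * V^(2/3) (cm^2 per
#'   cm^2).
#' @param vertex_counts named integer vector of vertices per structure;
#'   defaults sum to 5245.
#' @param exponent_range length-2 numeric, hypo-to-hyper range of the true
#'   local scaling-exponent field.
#' @param smoothness_length Gaussian kernel length scale (mesh units,
#'   mm-like) of the smooth exponent field.
#' @param focal_amplitude peak amplitude (log10 units, negative =
#'   contraction) of the shared focal shape fields for X-dosage SCAs; XYY
#'   uses half this amplitude.
#' @param focal_extent Gaussian spatial extent (mesh units) of focal fields.
#' @param focal_shared if `TRUE` (default) all SCA karyotypes share the same
#'   focal-field locations (convergent shape effects); if `FALSE` each SCA
#'   karyotype receives independently relocated fields (used to probe how
#'   location sharing drives inter-contrast map correlation).
#' @param sigma_vertex residual SD of log10 vertex area (log10 units).
#' @param normative_n,normative_n_female size and female count of the
#'   normative sample.
#' @param age_mean,age_sd,age_range core-sample age model (years, truncated
#'   normal).
#' @param normative_age_range age range of the normative sample (years).
#' @param tanner_missing named integer vector, number of subjects per
#'   karyotype with missing Tanner stage.
#' @param seed integer root random seed; all generator randomness derives
#'   from it deterministically.
#'
#' @return An object of class `"sca_config"` (a validated list). Derived
#'   fields: `offsets` (if defaulted) and `sigma_coupling`, the calibrated
#'   per-region surface coupling noise SD.
#' @examples
#' cfg <- sca_config(seed = 1)
#' round(cfg$sigma_coupling, 4)
#' @export
sca_config <- function(group_n = NULL,
                       tbv_mean = NULL,
                       tbv_sd = NULL,
                       beta1 = c(amygdala = 0.89, hippocampus = 0.76),
                       beta0 = NULL,
                       offsets = NULL,
                       sigma_logvol = c(amygdala = 0.030, hippocampus = 0.031),
                       sex_effect = c(amygdala = 0, hippocampus = 0),
                       sex_size_interaction = c(amygdala = 0, hippocampus = 0),
                       surface_r_target = c(amygdala = 0.97, hippocampus = 0.89),
                       surface_coef = 10,
                       vertex_counts = MESH_COUNTS,
                       exponent_range = c(0.6, 1.4),
                       smoothness_length = 5,
                       focal_amplitude = -0.04,
                       focal_extent = 6,
                       focal_shared = TRUE,
                       sigma_vertex = 0.03,
                       normative_n = 79,
                       normative_n_female = 34,
                       age_mean = 12.7,
                       age_sd = 5.0,
                       age_range = c(5, 26),
                       normative_age_range = c(12, 14),
                       tanner_missing = c(XY = 3, XX = 1, XXY = 1),
                       seed = 1L) {
  tab <- COHORT_TABLE
  if (is.null(group_n)) group_n <- stats::setNames(tab$n, tab$karyotype)
  if (is.null(tbv_mean)) tbv_mean <- stats::setNames(tab$tbv_mean, tab$karyotype)
  if (is.null(tbv_sd)) {
    tbv_sd <- stats::setNames(tab$tbv_sem * sqrt(tab$n), tab$karyotype)
  }

  group_n <- group_n[KARYOTYPES]
  tbv_mean <- tbv_mean[KARYOTYPES]
  tbv_sd <- tbv_sd[KARYOTYPES]
  if (anyNA(group_n) || anyNA(tbv_mean) || anyNA(tbv_sd)) {
    stop("group_n, tbv_mean and tbv_sd must be named for every karyotype: ",
         paste(KARYOTYPES, collapse = ", "), call. = FALSE)
  }
  if (any(group_n < 0)) stop("group sizes must be >= 0", call. = FALSE)
  if (any(tbv_sd < 0) || any(sigma_logvol < 0) || sigma_vertex < 0) {
    stop("all SDs must be >= 0", call. = FALSE)
  }
  if (any(tbv_mean <= 0)) stop("TBV means must be positive", call. = FALSE)

  beta1 <- beta1[REGIONS]
  sigma_logvol <- sigma_logvol[REGIONS]
  sex_effect <- sex_effect[REGIONS]
  sex_size_interaction <- sex_size_interaction[REGIONS]
  surface_r_target <- surface_r_target[REGIONS]
  if (anyNA(beta1) || anyNA(sigma_logvol)) {
    stop("beta1 and sigma_logvol must be named for regions: ",
         paste(REGIONS, collapse = ", "), call. = FALSE)
  }

  # Intercepts anchor the XY reference group exactly on the normative law.
  if (is.null(beta0)) {
    beta0 <- c(
      amygdala = log10(tab["XY", "amy_mean"]) -
        beta1[["amygdala"]] * log10(tab["XY", "tbv_mean"]),
      hippocampus = log10(tab["XY", "hip_mean"]) -
        beta1[["hippocampus"]] * log10(tab["XY", "tbv_mean"])
    )
  }
  beta0 <- beta0[REGIONS]

  # Per-karyotype offsets from the law, reproducing published group means;
  # the euploid reference karyotypes sit on the law by definition.
  if (is.null(offsets)) {
    offsets <- lapply(stats::setNames(REGIONS, REGIONS), function(r) {
      mcol <- if (r == "amygdala") "amy_mean" else "hip_mean"
      off <- log10(tab[KARYOTYPES, mcol]) -
        (beta0[[r]] + beta1[[r]] * log10(tab[KARYOTYPES, "tbv_mean"]))
      off <- stats::setNames(off, KARYOTYPES)
      off[c("XX", "XY")] <- 0
      off
    })
  } else {
    offsets <- lapply(offsets[REGIONS], function(off) off[KARYOTYPES])
    bad <- vapply(offsets, function(off) {
      anyNA(off) || any(off[c("XX", "XY")] != 0)
    }, logical(1))
    if (any(bad)) {
      stop("offsets must cover every karyotype and be exactly 0 for XX and XY",
           call. = FALSE)
    }
  }

  vertex_counts <- as.integer(vertex_counts)
  names(vertex_counts) <- names(MESH_COUNTS)
  if (any(vertex_counts <= 0)) stop("vertex counts must be positive", call. = FALSE)
  if (length(exponent_range) != 2 || diff(exponent_range) < 0) {
    stop("exponent_range must be an increasing length-2 numeric", call. = FALSE)
  }
  if (normative_n_female < 0 || normative_n_female > normative_n) {
    stop("normative_n_female must lie in [0, normative_n]", call. = FALSE)
  }

  cfg <- structure(list(
    group_n = group_n,
    tbv_mean = tbv_mean,
    tbv_sd = tbv_sd,
    beta1 = beta1,
    beta0 = beta0,
    offsets = offsets,
    sigma_logvol = sigma_logvol,
    sex_effect = sex_effect,
    sex_size_interaction = sex_size_interaction,
    surface_r_target = surface_r_target,
    surface_coef = surface_coef,
    vertex_counts = vertex_counts,
    mesh_total = sum(vertex_counts),
    exponent_range = exponent_range,
    smoothness_length = smoothness_length,
    focal_amplitude = focal_amplitude,
    focal_extent = focal_extent,
    focal_shared = isTRUE(focal_shared),
    sigma_vertex = sigma_vertex,
    normative_n = as.integer(normative_n),
    normative_n_female = as.integer(normative_n_female),
    age_mean = age_mean,
    age_sd = age_sd,
    age_range = age_range,
    normative_age_range = normative_age_range,
    tanner_missing = tanner_missing,
    seed = as.integer(seed)
  ), class = "sca_config")

  cfg$sigma_coupling <- calibrate_coupling_sd(cfg)
  cfg
}

# Delta-method mixture SD of log10 regional volume across the core cohort.
# Within-group variance: beta1^2 * var(log10 TBV) + sigma_logvol^2, with
# var(log10 TBV) ~= (sd/mean)^2 / ln(10)^2; between-group variance from the
# spread of the per-group means implied by the law + offsets.
mixture_logvol_sd <- function(cfg, region) {
  w <- cfg$group_n / sum(cfg$group_n)
  lt <- log10(cfg$tbv_mean)
  sig_lt <- (cfg$tbv_sd / cfg$tbv_mean) / log(10)
  mu <- cfg$beta0[[region]] + cfg$beta1[[region]] * lt +
    cfg$offsets[[region]]
  within <- cfg$beta1[[region]]^2 * sig_lt^2 + cfg$sigma_logvol[[region]]^2
  mbar <- sum(w * mu)
  sqrt(sum(w * (within + (mu - mbar)^2)))
}

# Closed-form coupling noise SD hitting the target volume-surface Pearson
# correlation on the log scale: r = b*sx / sqrt(b^2 sx^2 + tau^2) with
# b = 2/3 the geometric link exponent.
calibrate_coupling_sd <- function(cfg) {
  vapply(stats::setNames(REGIONS, REGIONS), function(r) {
    rt <- cfg$surface_r_target[[r]]
    if (is.na(rt) || rt <= 0 || rt >= 1) return(0)
    sx <- mixture_logvol_sd(cfg, r)
    (2 / 3) * sx * sqrt(1 / rt^2 - 1)
  }, numeric(1))
}

#' @export
print.sca_config <- function(x, ...) {
  cat("Synthetic SCA cohort configuration\n")
  cat(sprintf("  core sample: n = %d across %d karyotypes\n",
              sum(x$group_n), sum(x$group_n > 0)))
  cat(sprintf("  normative sample: n = %d (%d F)\n",
              x$normative_n, x$normative_n_female))
  cat(sprintf("  scaling exponents: amygdala %.2f, hippocampus %.2f\n",
              x$beta1[["amygdala"]], x$beta1[["hippocampus"]]))
  cat(sprintf("  mesh: %d vertices (%s)\n", x$mesh_total,
              paste(x$vertex_counts, collapse = "/")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Deterministic sub-seed derivation: every consumer of randomness offsets the
# root seed by a fixed stream id, keeping results reproducible and streams
# independent-ish while staying inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stream) %% 1000L
}
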