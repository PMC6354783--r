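## Bulk-volume group inference: omnibus tests, pairwise contrasts under the
## three brain-size adjustment strategies, effect sizes, multiplicity control.

#' Bonferroni adjustment with explicit family size
#'
#' @param p numeric vector of p-values.
#' @param m family size (need not equal `length(p)`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m) pmin(1, m * p)

#' Omnibus one-way ANOVA across karyotype groups
#'
#' Fixed-effects one-way ANOVA of a measure across all karyotype groups
#' present in the sample. Groups with fewer than 2 subjects are excluded
#' with a warning.
#'
#' @param core a `subject_table`.
#' @param measure column name (e.g. `"amygdala"`, `"hippocampus"`, `"tbv"`).
#' @return list with `F`, `p`, `df`, `groups`.
#' @examples
#' core <- generate_subjects(sca_config(seed = 1))
#' omnibus_group_test(core, "amygdala")$F
#' @export
omnibus_group_test <- function(core, measure) {
  cnt <- table(core$karyotype)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 subjects: ",
            paste(small, collapse = ", "))
    core <- core[!core$karyotype %in% small, ]
  }
  if (length(unique(core$karyotype)) < 2) {
    stop("need at least 2 groups with >= 2 subjects", call. = FALSE)
  }
  fit <- stats::lm(core[[measure]] ~ factor(core$karyotype))
  a <- stats::anova(fit)
  Fst <- a[1, "F value"]; p <- a[1, "Pr(>F)"]
  # no between-group variation (guard the degenerate 0/0 constant case)
  sst <- a[1, "Sum Sq"] + a[2, "Sum Sq"]
  if (a[1, "Sum Sq"] <= 1e-10 * max(sst, .Machine$double.eps)) {
    Fst <- 0; p <- 1
  }
  list(F = Fst, p = p,
       df = c(a[1, "Df"], a[2, "Df"]),
       groups = sort(unique(core$karyotype)))
}

#' Effect size of a group shift relative to the XY reference
#'
#' Computes `(mean(reference) - mean(group)) / SD(reference)` with the
#' reference group's sample SD (n - 1 denominator). Positive values mean the
#' comparison group is smaller than the reference.
#'
#' @param core a `subject_table`.
#' @param group comparison karyotype.
#' @param measure column name.
#' @param reference reference karyotype (default `"XY"`).
#' @return numeric effect size d.
#' @export
effect_size_vs_reference <- function(core, group, measure, reference = "XY") {
  ref <- core[[measure]][core$karyotype == reference]
  cmp <- core[[measure]][core$karyotype == group]
  if (length(ref) < 2) stop("reference group needs >= 2 subjects", call. = FALSE)
  if (!length(cmp)) stop("empty comparison group: ", group, call. = FALSE)
  s <- stats::sd(ref)
  if (s == 0) stop("zero SD in reference group", call. = FALSE)
  (mean(ref) - mean(cmp)) / s
}

# Shared engine: two-group OLS of `response` on a 0/1 group indicator
# (comparison = 1), optionally with covariates; equivalent to the pooled
# two-sample t-test when no covariates are present. Missing covariate rows
# are dropped listwise with a message.
group_model <- function(response, sub, comparison, control,
                        covariates = NULL) {
  keep <- sub$karyotype %in% c(comparison, control)
  if (!any(sub$karyotype == comparison) || !any(sub$karyotype == control)) {
    stop(sprintf("empty group in contrast %s vs %s", comparison, control),
         call. = FALSE)
  }
  y <- response[keep]
  g <- as.numeric(sub$karyotype[keep] == comparison)
  d <- data.frame(y = y, g = g)
  form <- y ~ g
  if (!is.null(covariates)) {
    for (cv in covariates) d[[cv]] <- sub[[cv]][keep]
    ok <- stats::complete.cases(d)
    if (any(!ok)) {
      message(sprintf("dropping %d subject(s) with missing %s",
                      sum(!ok), paste(covariates, collapse = "/")))
      d <- d[ok, ]
    }
    form <- stats::reformulate(c("g", covariates), response = "y")
  }
  fit <- stats::lm(form, data = d)
  ct <- stats::coef(summary(fit))
  list(estimate = ct["g", "Estimate"], se = ct["g", "Std. Error"],
       t = ct["g", "t value"], p = ct["g", "Pr(>|t|)"],
       n_comparison = sum(d$g == 1), n_control = sum(d$g == 0))
}

contrast_result <- function(region, method, comparison, control, gm, m,
                            effect_d = NA_real_) {
  structure(data.frame(
    region = region, method = method,
    contrast = paste0(comparison, "-", control),
    n_comparison = gm$n_comparison, n_control = gm$n_control,
    estimate = gm$estimate, se = gm$se, t = gm$t, p = gm$p,
    p_adj = bonferroni_adjust(gm$p, m),
    effect_size_d = effect_d,
    stringsAsFactors = FALSE
  ), class = c("sca_contrast", "data.frame"))
}

#' Pairwise raw-volume contrast
#'
#' Two-sided pooled-variance two-sample comparison of raw volumes between a
#' comparison karyotype and its control (OLS on a group indicator). Family
#' correction for the raw post-hoc battery is applied across contrasts by
#' [run_volume_battery()] (BH within region); the `p_adj` column here is the
#' Bonferroni value at family size `m` for standalone use.
#'
#' @param core a `subject_table`.
#' @param region `"amygdala"`, `"hippocampus"` or `"tbv"`.
#' @param comparison,control karyotype labels.
#' @param m Bonferroni family size.
#' @param covariates optional character vector of covariate columns
#'   (e.g. `c("age", "tanner")`).
#' @return one-row `sca_contrast` data frame. Negative estimates mean
#'   smaller volumes in the comparison group.
#' @export
posthoc_raw_contrast <- function(core, region, comparison, control,
                                 m = 5, covariates = NULL) {
  gm <- group_model(core[[region]], core, comparison, control, covariates)
  d <- tryCatch(effect_size_vs_reference(core, comparison, region),
                error = function(e) NA_real_)
  contrast_result(region, "raw", comparison, control, gm, m, d)
}

#' Group contrast on allometric deviations
#'
#' Compares observed-minus-predicted log10 regional volume (deviation from a
#' normative allometric model fitted in an independent sample) between a
#' comparison group and its control via two-group OLS, Bonferroni-adjusted
#' at family size `m`.
#'
#' The normative model must not have been fitted on the core sample; fitting
#' and testing on the same subjects invalidates the deviation distribution.
#' This is enforced by comparing subject ids (override with
#' `allow_leakage = TRUE`).
#'
#' @param core a `subject_table`.
#' @param model an `allom` model fitted on the independent normative sample.
#' @param comparison,control karyotype labels.
#' @param m Bonferroni family size (default 5, the SCA contrast family).
#' @param covariates optional covariate columns added to the group model.
#' @param allow_leakage set TRUE to bypass the train/test overlap guard.
#' @return one-row `sca_contrast` data frame (estimate in log10 units).
#' @examples
#' cfg <- sca_config(seed = 5)
#' core <- generate_subjects(cfg)
#' norm <- generate_subjects(cfg, sample = "normative")
#' fit <- allom(norm, "amygdala")
#' allometric_contrast(core, fit, "XXY", "XY")
#' @export
allometric_contrast <- function(core, model, comparison, control,
                                m = 5, covariates = NULL,
                                allow_leakage = FALSE) {
  stopifnot(inherits(model, "allom"))
  if (!allow_leakage && length(intersect(model$subjects, core$subject))) {
    stop("normative model was fitted on subjects present in the core ",
         "sample; refusing to compute deviations (set allow_leakage = TRUE ",
         "to override)", call. = FALSE)
  }
  dev <- allometric_deviation(model, core)
  gm <- group_model(dev, core, comparison, control, covariates)
  contrast_result(model$region, "allometric", comparison, control, gm, m)
}

#' Group contrast on TBV-normalized volumes
#'
#' Tests group differences in the regional volume fraction of total brain
#' volume (normalization by division), via two-group OLS.
#'
#' @inheritParams posthoc_raw_contrast
#' @return one-row `sca_contrast` data frame (estimate is a volume fraction).
#' @export
normalization_contrast <- function(core, region, comparison, control,
                                   m = 5, covariates = NULL) {
  gm <- group_model(core[[region]] / core$tbv, core, comparison, control,
                    covariates)
  contrast_result(region, "normalization", comparison, control, gm, m)
}

#' Group contrast with TBV as a linear covariate
#'
#' Tests group differences in raw regional volume with total brain volume
#' included as a linear covariate (covariation adjustment).
#'
#' @inheritParams posthoc_raw_contrast
#' @return one-row `sca_contrast` data frame (estimate in cm^3).
#' @export
covariation_contrast <- function(core, region, comparison, control,
                                 m = 5, covariates = NULL) {
  gm <- group_model(core[[region]], core, comparison, control,
                    c("tbv", covariates))
  contrast_result(region, "covariation", comparison, control, gm, m)
}

#' Run the full bulk-volume contrast battery
#'
#' For each region and each method (raw, allometric, normalization,
#' covariation) runs the five SCA-vs-gonadal-control contrasts plus the
#' XX-vs-XY sex contrast. Allometric contrasts use deviations from the
#' tier-selected normative model fitted in `normative`; the raw battery is
#' BH-adjusted within region across its contrast family; the adjusted
#' batteries use Bonferroni at family size `m`. Sex contrasts for
#' normalization and covariation are evaluated in the normative sample
#' (group = sex); raw and allometric sex contrasts are evaluated in the
#' core sample.
#'
#' @param core core `subject_table`.
#' @param normative independent normative `subject_table`.
#' @param m Bonferroni family size for the adjusted methods.
#' @param covariates optional covariate columns (e.g. `c("age", "tanner")`)
#'   for a robustness run; subjects with missing values are dropped
#'   listwise.
#' @param alpha tier-selection level for the normative models.
#' @return `sca_contrast` data frame, sorted by (region, method, contrast),
#'   with the fitted normative models in attribute `"models"`.
#' @export
run_volume_battery <- function(core, normative, m = 5, covariates = NULL,
                               alpha = 0.05) {
  models <- lapply(stats::setNames(REGIONS, REGIONS), function(r) {
    allom(normative, r, tier = "auto", alpha = alpha)
  })
  rows <- list()
  for (r in REGIONS) {
    fam <- list()
    for (cmp in names(SCA_CONTRASTS)) {
      ctrl <- SCA_CONTRASTS[[cmp]]
      fam[[length(fam) + 1]] <-
        posthoc_raw_contrast(core, r, cmp, ctrl, m = m,
                             covariates = covariates)
      rows[[length(rows) + 1]] <-
        allometric_contrast(core, models[[r]], cmp, ctrl, m = m,
                            covariates = covariates)
      rows[[length(rows) + 1]] <-
        normalization_contrast(core, r, cmp, ctrl, m = m,
                               covariates = covariates)
      rows[[length(rows) + 1]] <-
        covariation_contrast(core, r, cmp, ctrl, m = m,
                             covariates = covariates)
    }
    # Sex contrast: raw + allometric in core; normalization/covariation in
    # the normative sample.
    fam[[length(fam) + 1]] <-
      posthoc_raw_contrast(core, r, "XX", "XY", m = m,
                           covariates = covariates)
    rows[[length(rows) + 1]] <-
      allometric_contrast(core, models[[r]], "XX", "XY", m = m,
                          covariates = covariates)
    rows[[length(rows) + 1]] <-
      normalization_contrast(normative, r, "XX", "XY", m = m,
                             covariates = covariates)
    rows[[length(rows) + 1]] <-
      covariation_contrast(normative, r, "XX", "XY", m = m,
                           covariates = covariates)
    # BH family correction for the raw battery, within region.
    fam_df <- do.call(rbind, fam)
    fam_df$p_adj <- stats::p.adjust(fam_df$p, method = "BH")
    rows[[length(rows) + 1]] <- fam_df
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$region, out$method, out$contrast), ]
  rownames(out) <- NULL
  class(out) <- c("sca_contrast", "data.frame")
  attr(out, "models") <- models
  out
}

#' Signed -log10(p) summary grid
#'
#' Reshapes a contrast battery into a (region x method) by contrast grid of
#' signed -log10 adjusted p-values: negative entries mean smaller volume in
#' the comparison group, and magnitude is evidence strength.
#'
#' @param battery output of [run_volume_battery()].
#' @return data frame grid.
#' @export
contrast_grid <- function(battery) {
  battery$signed_logp <- sign(battery$estimate) * -log10(battery$p_adj)
  stats::reshape(
    battery[, c("region", "method", "contrast", "signed_logp")],
    idvar = c("region", "method"), timevar = "contrast",
    direction = "wide"
  )
}

#' @export
print.sca_contrast <- function(x, ...) {
  cat(sprintf("Volume contrasts: %d result(s)\n", nrow(x)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
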