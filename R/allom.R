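## Normative log-log allometric models of regional volume on total brain
## volume, with tiered sex-term selection and scaling classification.

ALLOM_TIERS <- c("simple", "additive_sex", "interaction")

tier_formula <- function(tier) {
  switch(tier,
    simple       = log_volume ~ log_tbv,
    additive_sex = log_volume ~ log_tbv + male,
    interaction  = log_volume ~ log_tbv * male,
    stop("unknown tier: ", tier, call. = FALSE)
  )
}

allom_frame <- function(sample, region) {
  if (!region %in% REGIONS) {
    stop("region must be one of: ", paste(REGIONS, collapse = ", "),
         call. = FALSE)
  }
  v <- sample[[region]]
  bad <- which(!is.finite(v) | v <= 0 | !is.finite(sample$tbv) |
                 sample$tbv <= 0)
  if (length(bad)) {
    stop("non-positive volume for subject(s): ",
         paste(utils::head(sample$subject[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    log_volume = log10(v),
    log_tbv = log10(sample$tbv),
    male = as.numeric(sample$sex == "M"),
    row.names = sample$subject
  )
}

#' Fit a normative allometric scaling model
#'
#' Fits the log-log power-law model of bilateral regional volume on total
#' brain volume by ordinary least squares,
#' \deqn{\log_{10} V_{region} = \beta_0 + \beta_1 \log_{10} V_{tbv} +
#'   [\beta_2 Sex] + [\beta_3 \log_{10} V_{tbv} \times Sex] + \epsilon,}
#' at one of three tiers of sex-term complexity, or (default) selects the
#' tier by sequential backward testing: the interaction model is fitted
#' first; if the sex-by-size interaction is not significant (two-sided Wald
#' p > `alpha`) the additive-sex model is fitted; if the sex main effect is
#' also non-significant the simple model is retained.
#'
#' Sex is coded female = 0, male = 1.
#'
#' @param sample a `subject_table` (the normative/allometric sample).
#' @param region `"amygdala"` or `"hippocampus"`.
#' @param tier `"auto"` (sequential selection) or one of `"simple"`,
#'   `"additive_sex"`, `"interaction"`.
#' @param alpha significance level for the sequential tier tests.
#' @return An object of class `"allom"`: the OLS fit with tier, coefficient
#'   table, residual SD, and the identity of the fitting sample (used by
#'   downstream leakage guards).
#' @examples
#' norm <- generate_subjects(sca_config(seed = 2), sample = "normative")
#' fit <- allom(norm, "amygdala")
#' coef(fit)
#' classify_scaling(fit)
#' @export
allom <- function(sample, region, tier = "auto", alpha = 0.05) {
  stopifnot(is.data.frame(sample))
  d <- allom_frame(sample, region)
  single_sex <- length(unique(d$male)) < 2

  if (tier == "auto") {
    if (single_sex) {
      warning("single-sex sample: skipping sex tiers, fitting simple model")
      return(allom(sample, region, tier = "simple", alpha = alpha))
    }
    fit_int <- allom(sample, region, tier = "interaction", alpha = alpha)
    p_int <- fit_int$coefficients["log_tbv:male", "p"]
    if (is.finite(p_int) && p_int <= alpha) return(fit_int)
    fit_add <- allom(sample, region, tier = "additive_sex", alpha = alpha)
    p_sex <- fit_add$coefficients["male", "p"]
    if (is.finite(p_sex) && p_sex <= alpha) return(fit_add)
    return(allom(sample, region, tier = "simple", alpha = alpha))
  }

  tier <- match.arg(tier, ALLOM_TIERS)
  k <- switch(tier, simple = 2L, additive_sex = 3L, interaction = 4L)
  if (nrow(d) < k + 1) {
    stop(sprintf("need at least %d subjects to fit the %s tier", k + 1, tier),
         call. = FALSE)
  }
  if (tier != "simple" && single_sex) {
    stop("rank-deficient design: sex term requested in a single-sex sample",
         call. = FALSE)
  }

  fit <- stats::lm(tier_formula(tier), data = d)
  sm <- summary(fit)
  ct <- stats::coef(sm)
  coefs <- data.frame(
    estimate = ct[, "Estimate"],
    se = ct[, "Std. Error"],
    t = ct[, "t value"],
    p = ct[, "Pr(>|t|)"]
  )
  rownames(coefs) <- rownames(ct)

  structure(list(
    region = region,
    tier = tier,
    coefficients = coefs,
    sigma = sm$sigma,
    df_residual = fit$df.residual,
    n = nrow(d),
    r_squared = sm$r.squared,
    fitted = stats::fitted(fit),
    residuals = stats::residuals(fit),
    sample_label = attr(sample, "sample_label") %||% "unknown",
    subjects = sample$subject,
    lm = fit
  ), class = "allom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a fixed-tier log-log model
#'
#' Thin wrapper over [allom()] with an explicit tier (no selection).
#' @inheritParams allom
#' @export
fit_loglog <- function(sample, region, tier = "simple") {
  allom(sample, region, tier = tier)
}

#' Sequential sex-tier selection
#'
#' Wrapper over [allom()] with `tier = "auto"`.
#' @inheritParams allom
#' @export
select_tier <- function(sample, region, alpha = 0.05) {
  allom(sample, region, tier = "auto", alpha = alpha)
}

#' @export
coef.allom <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))
}

#' @export
residuals.allom <- function(object, ...) object$residuals

#' @export
confint.allom <- function(object, parm = "log_tbv", level = 0.95, ...) {
  cf <- object$coefficients[parm, , drop = FALSE]
  tq <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  out <- cbind(cf$estimate - tq * cf$se, cf$estimate + tq * cf$se)
  dimnames(out) <- list(parm, sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                         1 - (1 - level) / 2)))
  out
}

#' Predict log10 regional volume for new subjects
#'
#' Applies the retained normative model's linear predictor. The sex term is
#' used only when the model's tier includes it.
#'
#' @param object an `allom` model.
#' @param newdata a `subject_table` (needs `tbv`, and `sex` if the tier
#'   includes sex terms).
#' @param ... unused.
#' @return named numeric vector of predicted log10 volumes (log10 cm^3).
#' @export
predict.allom <- function(object, newdata, ...) {
  cf <- coef(object)
  ltbv <- log10(newdata$tbv)
  pred <- cf[["(Intercept)"]] + cf[["log_tbv"]] * ltbv
  if (object$tier != "simple") {
    if (!"sex" %in% names(newdata) || anyNA(newdata$sex)) {
      bad <- if ("sex" %in% names(newdata)) {
        newdata$subject[is.na(newdata$sex)]
      } else newdata$subject
      stop("model tier requires sex but it is missing for subject(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    male <- as.numeric(newdata$sex == "M")
    pred <- pred + cf[["male"]] * male
    if (object$tier == "interaction") {
      pred <- pred + cf[["log_tbv:male"]] * male * ltbv
    }
  }
  stats::setNames(pred, newdata$subject)
}

#' Predicted log10 regional volume (module-surface alias)
#'
#' Equivalent to `predict(model, subjects)`.
#' @inheritParams predict.allom
#' @param subjects a `subject_table`.
#' @export
predict_log_volume <- function(object, subjects) {
  predict(object, subjects)
}

#' Deviations from normative scaling
#'
#' Observed minus predicted log10 regional volume under a normative model:
#' the brain-size-adjusted quantity compared across groups by
#' [allometric_contrast()].
#'
#' @param model an `allom` model.
#' @param subjects a `subject_table`.
#' @return named numeric vector of deviations (log10 units).
#' @export
allometric_deviation <- function(model, subjects) {
  obs <- log10(subjects[[model$region]])
  obs - predict(model, subjects)
}

#' Simulate volumes from a fitted allometric model
#'
#' Draws new log10 regional volumes from the fitted linear predictor plus
#' Gaussian residual noise at the fitted residual SD, conditional on the
#' subjects' total brain volume (and sex, if the tier uses it).
#'
#' @param object an `allom` model.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param newdata a `subject_table`; defaults to refusing silently absent data.
#' @param ... unused.
#' @return data frame, one column per simulation, of regional volumes (cm^3).
#' @export
simulate.allom <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, newdata)
  out <- as.data.frame(replicate(nsim, {
    10^(mu + stats::rnorm(length(mu), 0, object$sigma))
  }, simplify = TRUE))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- newdata$subject
  out
}

#' @export
print.allom <- function(x, ...) {
  cat(sprintf("Normative allometric model: %s (tier: %s)\n", x$region, x$tier))
  cat(sprintf("  log10(V_%s) ~ log10(V_tbv)%s,  n = %d (%s sample)\n",
              x$region,
              switch(x$tier, simple = "",
                     additive_sex = " + sex",
                     interaction = " * sex"),
              x$n, x$sample_label))
  cat(sprintf("  beta1 (scaling exponent) = %.3f (SE %.3f)\n",
              x$coefficients["log_tbv", "estimate"],
              x$coefficients["log_tbv", "se"]))
  invisible(x)
}

#' @export
summary.allom <- function(object, alpha = 0.05, ...) {
  structure(list(model = object,
                 scaling = classify_scaling(object, alpha = alpha)),
            class = "summary.allom")
}

#' @export
print.summary.allom <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients:\n")
  print(round(x$model$coefficients, 4))
  cat(sprintf("\nResidual SD: %.4f on %d df,  R^2 = %.3f\n",
              x$model$sigma, x$model$df_residual, x$model$r_squared))
  print(x$scaling)
  invisible(x)
}

#' Plot a fitted allometric model
#'
#' Log-log scatter of regional volume against total brain volume with the
#' fitted scaling line and the isometric reference slope.
#'
#' @param x an `allom` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.allom <- function(x, ...) {
  d <- stats::model.frame(x$lm)
  graphics::plot(d$log_tbv, d$log_volume,
                 xlab = "log10 total brain volume (cm^3)",
                 ylab = sprintf("log10 %s volume (cm^3)", x$region),
                 main = sprintf("%s allometry (beta1 = %.2f)", x$region,
                                coef(x)[["log_tbv"]]), ...)
  graphics::abline(coef(x)[["(Intercept)"]], coef(x)[["log_tbv"]], col = 2)
  mx <- mean(d$log_tbv); my <- mean(d$log_volume)
  graphics::abline(my - mx, 1, col = "grey60", lty = 2)
  graphics::legend("topleft", c("fitted", "isometric"), lty = c(1, 2),
                   col = c(2, "grey60"), bty = "n")
  invisible(x)
}

#' Classify allometric scaling against isometry
#'
#' Wald test of H0: beta1 = 1 with t-distribution confidence interval.
#' Scaling is hypoallometric when the upper CI bound is below 1,
#' hyperallometric when the lower bound exceeds 1, isometric otherwise.
#'
#' @param model an `allom` model (or any list with a `coefficients` table
#'   containing a `log_tbv` row and `df_residual`).
#' @param alpha two-sided test level (CI at 1 - alpha).
#' @return object of class `scaling_class` with fields `label`, `beta1`,
#'   `ci`, `p`.
#' @export
classify_scaling <- function(model, alpha = 0.05) {
  b1 <- model$coefficients["log_tbv", "estimate"]
  se <- model$coefficients["log_tbv", "se"]
  df <- model$df_residual
  if (se == 0) {
    if (b1 != 1) {
      warning("zero standard error: classifying by point estimate with a ",
              "degenerate confidence interval")
    }
    ci <- c(b1, b1)
    p <- if (b1 == 1) 1 else 0
  } else {
    tq <- stats::qt(1 - alpha / 2, df)
    ci <- c(b1 - tq * se, b1 + tq * se)
    p <- 2 * stats::pt(-abs((b1 - 1) / se), df)
  }
  label <- if (ci[2] < 1) "hypoallometric"
           else if (ci[1] > 1) "hyperallometric"
           else "isometric"
  structure(list(label = label, beta1 = b1, ci = ci, p = p,
                 alpha = alpha),
            class = "scaling_class")
}

#' @export
print.scaling_class <- function(x, ...) {
  cat(sprintf("Scaling: %s (beta1 = %.3f, %d%% CI [%.3f, %.3f], p[beta1=1] = %.3g)\n",
              x$label, x$beta1, round(100 * (1 - x$alpha)),
              x$ci[1], x$ci[2], x$p))
  invisible(x)
}
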