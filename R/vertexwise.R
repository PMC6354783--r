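## Mass-univariate vertex-wise surface allometry and group contrasts.

# Vectorized OLS over many response columns sharing one design matrix.
# Returns per-column coefficient estimate, SE, t and two-sided p for the
# requested coefficient. Equivalent to lm() column by column (tested).
ols_many <- function(X, Y, coef_index) {
  XtX <- crossprod(X)
  XtXi <- solve(XtX)
  B <- XtXi %*% crossprod(X, Y)                     # k x V
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(XtXi[coef_index, coef_index] * sigma2)
  est <- B[coef_index, ]
  t <- ifelse(se > 0, est / se, 0)
  p <- 2 * stats::pt(-abs(t), df)
  list(estimate = est, se = se, t = t, p = p, df = df,
       coefficients = B, residuals = resid)
}

vertex_design <- function(logS, male, tier) {
  switch(tier,
    simple       = cbind(1, logS),
    additive_sex = cbind(1, logS, male),
    interaction  = cbind(1, logS, male, logS * male)
  )
}

#' Fit the vertex-wise normative surface allometry field
#'
#' At every vertex, models log10 local surface area on log10 total bilateral
#' regional surface area (each structure's vertices use its own region's
#' total area) in the normative sample, with the same tiered sex-term
#' structure as the bulk-volume models — but gated by FDR across vertices:
#' the interaction model is fitted at every vertex and its interaction-term
#' p-values are BH-corrected across all vertices as one family; if any
#' vertex survives at `alpha_fdr`, the interaction tier is retained for all
#' vertices (a single shared model keeps coefficients comparable across the
#' surface). Otherwise the additive-sex model is gated the same way, and
#' failing that the simple model is retained. Set `gate_per_region = TRUE`
#' to run the gate corrections within each bilateral region instead.
#'
#' Vertices with zero response variance are excluded from the gate and
#' flagged; their fits are still returned (degenerate, SE may be 0).
#'
#' @param normative_vertices a `vertex_table` for the normative sample.
#' @param alpha_fdr FDR level of the tier gates.
#' @param gate_per_region correct gate p-values within each bilateral
#'   region rather than across the whole surface.
#' @return object of class `vertex_field`: per-vertex coefficients of the
#'   retained tier (`intercept`, `exponent`, optional sex terms), the chosen
#'   `tier`, per-vertex gate p/q values, residual matrix, and the mesh.
#' @examples
#' cfg <- sca_config(vertex_counts = c(30, 30, 30, 30), seed = 4)
#' nv <- generate_vertex_table(cfg, generate_subjects(cfg, "normative"))
#' field <- fit_vertex_normative(nv)
#' field$tier
#' @export
fit_vertex_normative <- function(normative_vertices, alpha_fdr = 0.05,
                                 gate_per_region = FALSE) {
  vt <- normative_vertices
  stopifnot(inherits(vt, "vertex_table"))
  sub <- vt$subjects
  if (length(unique(sub$sex)) < 2) {
    stop("vertex normative sample must contain both sexes", call. = FALSE)
  }
  mesh <- vt$mesh
  Y <- log10(vt$areas)
  male <- as.numeric(sub$sex == "M")
  logS <- log10(100 * as.matrix(sub[, paste0(REGIONS, "_sa")]))
  colnames(logS) <- REGIONS

  degenerate <- apply(Y, 2, stats::sd) == 0
  if (any(degenerate)) {
    warning(sprintf("%d zero-variance vertices excluded from tier gates",
                    sum(degenerate)))
  }

  gate <- function(tier, coef_index) {
    # BH over the gate term's p-values (whole surface by default);
    # fires when any corrected value falls below alpha_fdr.
    p <- rep(NA_real_, nrow(mesh))
    for (s in unique(mesh$structure)) {
      idx <- which(mesh$structure == s & !degenerate)
      if (!length(idx)) next
      X <- vertex_design(logS[, mesh$region[idx[1]]], male, tier)
      p[idx] <- ols_many(X, Y[, idx, drop = FALSE], coef_index)$p
    }
    q <- rep(NA_real_, length(p))
    if (gate_per_region) {
      for (r in unique(mesh$region)) {
        idx <- which(mesh$region == r & !degenerate)
        q[idx] <- stats::p.adjust(p[idx], method = "BH")
      }
    } else {
      q[!degenerate] <- stats::p.adjust(p[!degenerate], method = "BH")
    }
    list(p = p, q = q, fire = any(q < alpha_fdr, na.rm = TRUE))
  }

  g_sex <- NULL
  g_int <- gate("interaction", 4L)
  if (g_int$fire) {
    tier <- "interaction"
  } else {
    g_sex <- gate("additive_sex", 3L)
    tier <- if (g_sex$fire) "additive_sex" else "simple"
  }

  k <- switch(tier, simple = 2L, additive_sex = 3L, interaction = 4L)
  coefs <- matrix(NA_real_, k, nrow(mesh))
  resid <- matrix(NA_real_, nrow(Y), nrow(mesh))
  se_exp <- numeric(nrow(mesh))
  for (s in unique(mesh$structure)) {
    idx <- which(mesh$structure == s)
    X <- vertex_design(logS[, mesh$region[idx[1]]], male, tier)
    fit <- ols_many(X, Y[, idx, drop = FALSE], 2L)
    coefs[, idx] <- fit$coefficients
    resid[, idx] <- fit$residuals
    se_exp[idx] <- fit$se
  }
  rownames(coefs) <- switch(tier,
    simple = c("intercept", "exponent"),
    additive_sex = c("intercept", "exponent", "male"),
    interaction = c("intercept", "exponent", "male", "exponent_male"))

  structure(list(
    mesh = mesh, tier = tier, coefficients = coefs,
    exponent = coefs["exponent", ], exponent_se = se_exp,
    gate_interaction = g_int,
    gate_sex = g_sex,
    degenerate = degenerate,
    residuals = resid,
    alpha_fdr = alpha_fdr,
    sample_label = attr(sub, "sample_label"),
    subjects = sub$subject,
    n = nrow(Y)
  ), class = "vertex_field")
}

#' @export
print.vertex_field <- function(x, ...) {
  cat(sprintf("Vertex-wise normative allometry: %d vertices, tier = %s\n",
              nrow(x$mesh), x$tier))
  cat(sprintf("  exponent range [%.2f, %.2f], n = %d (%s sample)\n",
              min(x$exponent), max(x$exponent), x$n, x$sample_label))
  invisible(x)
}

#' Vertex-wise deviations from normative surface scaling
#'
#' Observed minus predicted log10 local surface area for every subject and
#' vertex under the retained vertex-wise normative model.
#'
#' @param field a `vertex_field` fitted on the normative sample.
#' @param vertices a `vertex_table` (e.g. the core sample).
#' @return subjects x vertices matrix of deviations (log10 units).
#' @export
vertex_deviations <- function(field, vertices) {
  stopifnot(inherits(field, "vertex_field"),
            inherits(vertices, "vertex_table"))
  mesh <- vertices$mesh
  if (nrow(mesh) != nrow(field$mesh) ||
      !identical(mesh$structure, field$mesh$structure)) {
    stop("mesh mismatch between field and vertex table", call. = FALSE)
  }
  sub <- vertices$subjects
  Y <- log10(vertices$areas)
  male <- as.numeric(sub$sex == "M")
  logS <- log10(100 * as.matrix(sub[, paste0(REGIONS, "_sa")]))
  colnames(logS) <- REGIONS

  pred <- matrix(NA_real_, nrow(Y), nrow(mesh),
                 dimnames = dimnames(Y))
  for (s in unique(mesh$structure)) {
    idx <- which(mesh$structure == s)
    X <- vertex_design(logS[, mesh$region[idx[1]]], male, field$tier)
    pred[, idx] <- X %*% field$coefficients[, idx, drop = FALSE]
  }
  Y - pred
}

#' Vertex-wise group contrast with BH FDR control
#'
#' Per-vertex two-group OLS of deviations on a 0/1 group indicator
#' (comparison = 1), optionally with covariates; p-values are BH-corrected
#' separately for this contrast within each bilateral region (`family =
#' "region"`, the default; `"structure"` and `"pooled"` also available),
#' and vertices with `q < q_level` form the significance mask. Direction is
#' `"contraction"` where the comparison group's deviations are smaller
#' (t < 0), `"expansion"` otherwise.
#'
#' @param deviations subjects x vertices deviation matrix from
#'   [vertex_deviations()].
#' @param subjects the `subject_table` matching the deviation rows.
#' @param mesh the `mesh_spec` matching the deviation columns.
#' @param comparison,control karyotype labels.
#' @param q_level FDR level (default 0.05).
#' @param covariates optional covariate columns (e.g. `c("age", "tanner")`);
#'   subjects with missing values are dropped listwise.
#' @param family FDR family: `"region"` (default), `"structure"`, or
#'   `"pooled"` across the whole surface.
#' @param fdr_method `"BH"` (default) or `"BY"`.
#' @return object of class `vertex_map`: per-vertex `t`, `p`, `q`, `mask`,
#'   `direction`, plus the contrast label and mesh.
#' @export
vertex_contrast <- function(deviations, subjects, mesh, comparison, control,
                            q_level = 0.05, covariates = NULL,
                            family = c("region", "structure", "pooled"),
                            fdr_method = c("BH", "BY")) {
  fdr_method <- match.arg(fdr_method)
  family <- match.arg(family)
  keep <- subjects$karyotype %in% c(comparison, control)
  if (sum(subjects$karyotype == comparison) < 2 ||
      sum(subjects$karyotype == control) < 2) {
    stop(sprintf("each group needs >= 2 subjects in contrast %s vs %s",
                 comparison, control), call. = FALSE)
  }
  sub <- subjects[keep, ]
  D <- deviations[keep, , drop = FALSE]
  g <- as.numeric(sub$karyotype == comparison)
  X <- cbind(1, g)
  if (!is.null(covariates)) {
    cv <- as.matrix(sapply(covariates, function(v) as.numeric(sub[[v]])))
    ok <- stats::complete.cases(cv)
    if (any(!ok)) {
      message(sprintf("dropping %d subject(s) with missing %s",
                      sum(!ok), paste(covariates, collapse = "/")))
      X <- X[ok, , drop = FALSE]; cv <- cv[ok, , drop = FALSE]
      D <- D[ok, , drop = FALSE]
    }
    X <- cbind(X, cv)
  }
  fit <- ols_many(X, D, 2L)
  q <- rep(NA_real_, ncol(D))
  if (family == "pooled") {
    q <- stats::p.adjust(fit$p, method = fdr_method)
  } else {
    for (s in unique(mesh[[family]])) {
      idx <- mesh[[family]] == s
      q[idx] <- stats::p.adjust(fit$p[idx], method = fdr_method)
    }
  }
  structure(list(
    contrast = paste0(comparison, "-", control),
    mesh = mesh,
    t = unname(fit$t), p = unname(fit$p), q = unname(q),
    mask = unname(q < q_level),
    direction = ifelse(fit$t < 0, "contraction", "expansion"),
    estimate = unname(fit$estimate),
    q_level = q_level,
    n = nrow(D)
  ), class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  cat(sprintf("Vertex contrast %s: %d/%d vertices significant at q < %g\n",
              x$contrast, sum(x$mask), length(x$mask), x$q_level))
  if (any(x$mask)) {
    tb <- table(x$direction[x$mask])
    cat("  ", paste(names(tb), tb, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Spatial correlation of uncorrected t-statistic maps
#'
#' Pearson correlation between the uncorrected per-vertex t-vectors of each
#' pair of contrasts, computed separately per region (or structure).
#' Quantifies spatial convergence of group effects irrespective of which
#' vertices pass FDR correction.
#'
#' @param maps named list of `vertex_map` objects sharing one mesh.
#' @param by `"region"` (default) or `"structure"`.
#' @return object of class `map_cor`: a list (per region/structure) of
#'   symmetric correlation matrices.
#' @export
map_correlation <- function(maps, by = c("region", "structure")) {
  by <- match.arg(by)
  stopifnot(length(maps) >= 1)
  mesh <- maps[[1]]$mesh
  for (m in maps) {
    if (!identical(m$mesh$structure, mesh$structure)) {
      stop("maps must share a mesh", call. = FALSE)
    }
  }
  labels <- vapply(maps, `[[`, character(1), "contrast")
  groups <- unique(mesh[[by]])
  out <- lapply(stats::setNames(groups, groups), function(gr) {
    idx <- mesh[[by]] == gr
    M <- sapply(maps, function(m) m$t[idx])
    const <- apply(M, 2, stats::sd) == 0
    if (any(const)) {
      warning("constant t-map(s) in ", gr, ": correlations reported as NA")
    }
    r <- suppressWarnings(stats::cor(M))
    dimnames(r) <- list(labels, labels)
    diag(r) <- 1
    r
  })
  structure(out, class = "map_cor")
}

#' @export
print.map_cor <- function(x, ...) {
  for (nm in names(x)) {
    cat(nm, ":\n", sep = "")
    print(round(unclass(x[[nm]]), 3))
  }
  invisible(x)
}

#' Fraction of significant vertices surviving covariate adjustment
#'
#' Given significance masks from a main run and from a covariate-adjusted
#' robustness run, counts the vertices significant in the main run that
#' remain significant after adjustment, per contrast and pooled.
#'
#' @param masks_main,masks_covaried named lists of logical vertex masks (or
#'   of `vertex_map` objects) over the same mesh and contrasts.
#' @return data frame with per-contrast and pooled `n_main`, `n_surviving`,
#'   `fraction`.
#' @export
robustness_vertex_survival <- function(masks_main, masks_covaried) {
  get_mask <- function(x) if (inherits(x, "vertex_map")) x$mask else x
  stopifnot(identical(names(masks_main), names(masks_covaried)))
  rows <- lapply(names(masks_main), function(nm) {
    a <- get_mask(masks_main[[nm]]); b <- get_mask(masks_covaried[[nm]])
    if (length(a) != length(b)) stop("mesh mismatch in ", nm, call. = FALSE)
    data.frame(contrast = nm, n_main = sum(a), n_surviving = sum(a & b),
               fraction = if (sum(a)) sum(a & b) / sum(a) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled <- data.frame(contrast = "pooled",
                       n_main = sum(out$n_main),
                       n_surviving = sum(out$n_surviving),
                       fraction = if (sum(out$n_main) > 0)
                         sum(out$n_surviving) / sum(out$n_main) else NA_real_,
                       stringsAsFactors = FALSE)
  rbind(out, pooled)
}
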