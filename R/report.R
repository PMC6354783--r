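## Descriptive summaries and report artifacts.

#' Per-karyotype descriptive grid with omnibus tests
#'
#' Mean and SEM of total brain volume, amygdala and hippocampus volume per
#' karyotype group, plus the one-way omnibus F statistic and -log10(p) per
#' measure — the layout of a cohort descriptive table.
#'
#' @param core a `subject_table`.
#' @return data frame: one row per (measure, statistic), one column per
#'   karyotype, plus `F` and `neg_log10_p` columns; empty karyotype groups
#'   are omitted with a warning.
#' @export
summarize_cohort <- function(core) {
  measures <- c(tbv = "Total brain volume, cm^3",
                amygdala = "Amygdala, cm^3",
                hippocampus = "Hippocampus, cm^3")
  groups <- KARYOTYPES[KARYOTYPES %in% core$karyotype]
  absent <- setdiff(KARYOTYPES, groups)
  if (length(absent)) {
    warning("empty karyotype group(s) omitted: ",
            paste(absent, collapse = ", "))
  }
  rows <- list()
  for (m in names(measures)) {
    mu <- vapply(groups, function(k) mean(core[[m]][core$karyotype == k]),
                 numeric(1))
    sem <- vapply(groups, function(k) {
      v <- core[[m]][core$karyotype == k]
      stats::sd(v) / sqrt(length(v))
    }, numeric(1))
    om <- omnibus_group_test(core, m)
    rows[[m]] <- data.frame(
      measure = measures[[m]], statistic = c("mean", "sem"),
      rbind(mu, sem),
      F = c(om$F, NA), neg_log10_p = c(-log10(om$p), NA),
      row.names = NULL, check.names = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effect-size shift summary relative to the XY reference
#'
#' Per-karyotype effect-size shifts (in XY-SD units) for TBV and both
#' regional volumes: the data behind a ridgeline-style shift figure.
#'
#' @param core a `subject_table`.
#' @return data frame (karyotype x measure) of effect sizes d.
#' @export
effect_size_table <- function(core) {
  groups <- KARYOTYPES[KARYOTYPES %in% core$karyotype]
  measures <- c("tbv", "amygdala", "hippocampus")
  rows <- lapply(groups, function(k) {
    d <- vapply(measures, function(m) {
      effect_size_vs_reference(core, k, m)
    }, numeric(1))
    data.frame(karyotype = k, t(d), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write analysis report artifacts
#'
#' Writes plain-data report files for a full run: the effect-size shift
#' table, the signed -log10(p) contrast grid, binarized vertex significance
#' masks keyed by vertex id, and per-region map correlation matrices.
#' Missing sections are skipped with a message.
#'
#' @param dir output directory (created if needed).
#' @param core a `subject_table` (for the effect-size table), or NULL.
#' @param battery a [run_volume_battery()] result, or NULL.
#' @param maps named list of `vertex_map` objects, or NULL.
#' @param map_cor a [map_correlation()] result, or NULL.
#' @return invisible character vector of files written.
#' @export
render_reports <- function(dir, core = NULL, battery = NULL, maps = NULL,
                           map_cor = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(format(df, digits = 10, trim = TRUE), p,
                     row.names = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(core)) {
    emit(effect_size_table(core), "effect_sizes.csv")
    emit(summarize_cohort(core), "cohort_summary.csv")
  } else message("no core sample: skipping effect-size table")
  if (!is.null(battery)) {
    emit(as.data.frame(battery), "volume_contrasts.csv")
    emit(contrast_grid(as.data.frame(battery)), "contrast_grid.csv")
  } else message("no volume battery: skipping contrast grid")
  if (!is.null(maps)) {
    mask_df <- data.frame(
      structure = maps[[1]]$mesh$structure,
      vertex = maps[[1]]$mesh$vertex
    )
    for (nm in names(maps)) {
      mask_df[[paste0("t_", nm)]] <- maps[[nm]]$t
      mask_df[[paste0("q_", nm)]] <- maps[[nm]]$q
      mask_df[[paste0("sig_", nm)]] <-
        as.integer(maps[[nm]]$mask) *
        ifelse(maps[[nm]]$direction == "contraction", -1L, 1L)
    }
    emit(mask_df, "vertex_masks.csv")
  } else message("no vertex maps: skipping mask export")
  if (!is.null(map_cor)) {
    rows <- lapply(names(map_cor), function(g) {
      m <- map_cor[[g]]
      data.frame(region = g,
                 contrast_a = rep(rownames(m), ncol(m)),
                 contrast_b = rep(colnames(m), each = nrow(m)),
                 r = as.vector(m), stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, rows), "map_correlations.csv")
  } else message("no map correlations: skipping")
  invisible(written)
}
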