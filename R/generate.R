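## Synthetic cohort and vertex-wise surface data generators.

# Truncated-normal draws by inverse-CDF; avoids rejection loops and keeps
# one runif call per draw for reproducibility.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Tanner stage from age: a noisy monotone staging rule, clamped to 1..5.
tanner_from_age <- function(age) {
  raw <- round((age - 7) / 2.4 + stats::rnorm(length(age), 0, 0.7))
  pmin(pmax(raw, 1), 5)
}

#' Generate a synthetic subject table
#'
#' Draws a per-subject table of demographics, total brain volume, bilateral
#' regional volumes and total bilateral regional surface areas under the
#' configured normative allometric law with karyotype offsets.
#'
#' `sample = "core"` produces the SCA cohort (all seven karyotype groups at
#' the configured sizes). `sample = "normative"` produces the independent
#' typically developing XX/XY sample used to fit normative scaling rules
#' (karyotype offsets do not apply there by construction, as both its
#' karyotypes have zero offset).
#'
#' log10 TBV is Gaussian with moments matched to the configured mean/SD by
#' the delta method, guaranteeing positive volumes. log10 regional volume is
#' `beta0 + beta1*log10(TBV) + sex terms + offset + noise`; surface area is
#' `c * V^(2/3) * 10^eps` with calibrated coupling noise `eps`.
#'
#' @param config an [sca_config()] object.
#' @param sample `"core"` or `"normative"`.
#' @param seed optional integer overriding `config$seed`.
#' @return A `subject_table` data frame (one row per subject) with columns
#'   `subject`, `karyotype`, `sex`, `age`, `tanner`, `tbv`,
#'   `amygdala`, `hippocampus`, `amygdala_sa`, `hippocampus_sa`.
#'   Volumes cm^3, surface areas cm^2, age years.
#' @examples
#' core <- generate_subjects(sca_config(seed = 7))
#' aggregate(tbv ~ karyotype, core, mean)
#' @export
generate_subjects <- function(config, sample = c("core", "normative"),
                              seed = NULL) {
  stopifnot(inherits(config, "sca_config"))
  sample <- match.arg(sample)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  set.seed(derive_seed(seed, if (sample == "core") 1L else 2L))

  if (sample == "core") {
    kt <- rep(KARYOTYPES, times = config$group_n)
    if (length(kt) == 0) stop("all group sizes are zero", call. = FALSE)
    prefix <- "core"
  } else {
    nf <- config$normative_n_female
    nm <- config$normative_n - nf
    kt <- c(rep("XX", nf), rep("XY", nm))
    prefix <- "norm"
  }
  n <- length(kt)
  sex <- unname(KARYOTYPE_SEX[kt])
  male <- as.numeric(sex == "M")

  # log10 TBV per group: Gaussian on the log scale, delta-method moment
  # matching so the raw-scale mean equals the configured group mean
  # (log-normal mean correction: E[10^X] = 10^(mu + s^2 ln(10)/2)).
  sd_log <- (config$tbv_sd[kt] / config$tbv_mean[kt]) / log(10)
  mu_log <- log10(config$tbv_mean[kt]) - sd_log^2 * log(10) / 2
  ltbv <- stats::rnorm(n, mu_log, sd_log)
  tbv <- 10^ltbv

  # Ages: wide truncated normal for the core cohort, narrow uniform-ish
  # window for the normative sample.
  if (sample == "core") {
    age <- rtruncnorm(n, config$age_mean, config$age_sd,
                      config$age_range[1], config$age_range[2])
  } else {
    r <- config$normative_age_range
    age <- stats::runif(n, r[1], r[2])
  }
  tanner <- tanner_from_age(age)

  out <- data.frame(
    subject = sprintf("%s_%03d", prefix, seq_len(n)),
    karyotype = kt, sex = sex, age = age, tanner = tanner,
    tbv = tbv, stringsAsFactors = FALSE
  )

  for (r in REGIONS) {
    lv <- config$beta0[[r]] + config$beta1[[r]] * ltbv +
      config$sex_effect[[r]] * male +
      config$sex_size_interaction[[r]] * male * ltbv +
      config$offsets[[r]][kt] +
      stats::rnorm(n, 0, config$sigma_logvol[[r]])
    v <- 10^lv
    eps <- stats::rnorm(n, 0, config$sigma_coupling[[r]])
    sa <- config$surface_coef * v^(2 / 3) * 10^eps
    out[[r]] <- unname(v)
    out[[paste0(r, "_sa")]] <- unname(sa)
  }

  # Tanner missingness mirrors the study's robustness-analysis exclusions.
  if (sample == "core" && length(config$tanner_missing)) {
    for (k in names(config$tanner_missing)) {
      idx <- which(out$karyotype == k)
      nmiss <- min(config$tanner_missing[[k]], length(idx))
      if (nmiss > 0) out$tanner[idx[seq_len(nmiss)]] <- NA_integer_
    }
  }

  as_subject_table(out, sample_label = sample)
}

#' Coerce and validate a subject table
#'
#' @param x data frame with the `subject_table` schema.
#' @param sample_label label recorded for leakage guards
#'   (e.g. "core", "normative").
#' @return validated `subject_table`.
#' @export
as_subject_table <- function(x, sample_label = "unknown") {
  req <- c("subject", "karyotype", "sex", "age", "tanner", "tbv",
           "amygdala", "hippocampus", "amygdala_sa", "hippocampus_sa")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("subject table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$subject)) stop("duplicate subject ids", call. = FALSE)
  bad_kt <- setdiff(unique(x$karyotype), KARYOTYPES)
  if (length(bad_kt)) {
    stop("unknown karyotype label(s): ", paste(bad_kt, collapse = ", "),
         call. = FALSE)
  }
  expect_sex <- unname(KARYOTYPE_SEX[x$karyotype])
  if (!all(x$sex == expect_sex)) {
    stop("sex must match karyotype (F for XX/XXX, M otherwise)", call. = FALSE)
  }
  num <- c("tbv", "amygdala", "hippocampus", "amygdala_sa", "hippocampus_sa")
  for (cl in num) {
    if (any(!is.finite(x[[cl]])) || any(x[[cl]] <= 0)) {
      bad <- x$subject[which(!is.finite(x[[cl]]) | x[[cl]] <= 0)[1]]
      stop(sprintf("non-positive or non-finite %s for subject %s", cl, bad),
           call. = FALSE)
    }
  }
  x <- x[, req]
  rownames(x) <- NULL
  structure(x, class = c("subject_table", "data.frame"),
            sample_label = sample_label)
}

#' @export
print.subject_table <- function(x, ...) {
  cat(sprintf("Subject table (%s sample): %d subjects\n",
              attr(x, "sample_label"), nrow(x)))
  tab <- table(factor(x$karyotype, levels = KARYOTYPES))
  print(tab[tab > 0])
  NextMethod()
}

## ---- mesh -----------------------------------------------------------------

# Quasi-uniform Fibonacci lattice on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

# Structure geometry: ellipsoid semi-axes (mesh units, mm-like) and centres.
# Hippocampus is elongated along x (its rostro-caudal principal axis);
# x increases rostrally for both structures.
STRUCT_GEOM <- list(
  amygdala_right    = list(axes = c(10, 8, 7),  centre = c(0, -25, 0)),
  amygdala_left     = list(axes = c(10, 8, 7),  centre = c(0,  25, 0)),
  hippocampus_right = list(axes = c(22, 8, 6),  centre = c(-15, -25, -10)),
  hippocampus_left  = list(axes = c(22, 8, 6),  centre = c(-15,  25, -10))
)

#' Build the synthetic surface mesh
#'
#' Deterministically lays out each structure's vertices as a quasi-uniform
#' point cloud on an ellipsoid. Coordinates are arbitrary mm-like units used
#' only to define spatial smoothness of generated fields.
#'
#' @param config an [sca_config()] object (supplies per-structure counts).
#' @return `mesh_spec`: data frame with `vertex` (0-based, contiguous per
#'   structure), `structure`, `region`, `hemisphere`, `x`, `y`, `z`.
#' @examples
#' mesh <- build_mesh(sca_config())
#' table(mesh$structure)
#' @export
build_mesh <- function(config) {
  stopifnot(inherits(config, "sca_config"))
  parts <- lapply(names(config$vertex_counts), function(s) {
    nv <- config$vertex_counts[[s]]
    g <- STRUCT_GEOM[[s]]
    pts <- fibonacci_sphere(nv)
    pts <- sweep(pts, 2, g$axes, `*`)
    pts <- sweep(pts, 2, g$centre, `+`)
    data.frame(
      vertex = seq_len(nv) - 1L,
      structure = s,
      region = sub("_(left|right)$", "", s),
      hemisphere = sub("^.*_", "", s),
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      stringsAsFactors = FALSE
    )
  })
  mesh <- do.call(rbind, parts)
  rownames(mesh) <- NULL
  structure(mesh, class = c("mesh_spec", "data.frame"))
}

#' @export
print.mesh_spec <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices across %d structures\n",
              nrow(x), length(unique(x$structure))))
  print(table(x$structure))
  invisible(x)
}

# Smooth scalar field on a structure's point cloud: sum of Gaussian bumps at
# random control vertices, standardized to mean 0 / SD 1.
smooth_field <- function(coords, length_scale, n_bumps = 8) {
  n <- nrow(coords)
  ctr <- sample.int(n, n_bumps, replace = TRUE)
  w <- stats::rnorm(n_bumps)
  f <- numeric(n)
  for (j in seq_len(n_bumps)) {
    d2 <- rowSums(sweep(coords, 2, unlist(coords[ctr[j], ]), `-`)^2)
    f <- f + w[j] * exp(-d2 / (2 * length_scale^2))
  }
  s <- stats::sd(f)
  if (s == 0) return(numeric(n))
  (f - mean(f)) / s
}

# Vertex nearest to a fractional position along a structure's rostro-caudal
# (x) axis; used to anchor focal shape fields at fixed anatomy-like spots.
anchor_vertex <- function(coords, frac) {
  tgt <- stats::quantile(coords$x, frac)
  which.min((coords$x - tgt)^2 + (coords$y - stats::median(coords$y))^2)
}

# Focal field templates: centre (fractional position along the principal
# axis) and sign per bump. Amygdala: rostral contraction. Hippocampus:
# mid-body + caudal contraction bands and a small caudal expansion patch.
FOCAL_TEMPLATE <- list(
  amygdala    = list(list(frac = 0.85, sign = -1)),
  hippocampus = list(list(frac = 0.50, sign = -1),
                     list(frac = 0.10, sign = -1),
                     list(frac = 0.05, sign = +0.5))
)

#' Generate vertex-wise surface areas for a subject table
#'
#' Builds the mesh, draws a spatially smooth per-vertex true scaling-exponent
#' field spanning the configured hypo-to-hyper range, adds karyotype-specific
#' focal shape fields (spatially smooth contraction/expansion bumps shared in
#' location across SCA karyotypes, with XYY at half amplitude), Gaussian
#' vertex noise, and renormalizes each subject's vertex areas so they sum to
#' the subject's total bilateral regional surface area (cm^2 -> mm^2).
#'
#' The per-vertex generating model before renormalization is
#' \deqn{\log_{10} A_{v} = \alpha_v + e_v \log_{10} S_{region} +
#'   f_{k}(v) + \epsilon_v}
#' where `e_v` is the local exponent field and `f_k` the focal field of the
#' subject's karyotype (zero for XX/XY).
#'
#' @param config an [sca_config()] object.
#' @param subjects a `subject_table`.
#' @param mesh optional pre-built `mesh_spec` (must match the config counts).
#' @param seed optional integer overriding `config$seed`.
#' @return list of class `vertex_table` with elements `mesh`, `areas`
#'   (subjects x vertices matrix, mm^2, rows named by subject id),
#'   `subjects` (the input table), `true_exponent` (per-vertex generating
#'   exponents) and `focal` (per-karyotype generating focal fields).
#' @examples
#' cfg <- sca_config(vertex_counts = c(40, 40, 40, 40), seed = 3)
#' vt <- generate_vertex_table(cfg, generate_subjects(cfg))
#' dim(vt$areas)
#' @export
generate_vertex_table <- function(config, subjects, mesh = NULL, seed = NULL) {
  stopifnot(inherits(config, "sca_config"),
            inherits(subjects, "subject_table"))
  if (is.null(mesh)) mesh <- build_mesh(config)
  if (nrow(mesh) != config$mesh_total) {
    stop("mesh vertex count does not match configuration", call. = FALSE)
  }
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  set.seed(derive_seed(seed, 3L))

  nv <- nrow(mesh)
  n <- nrow(subjects)

  # True local exponent field, smooth within structure, centred on isometry.
  half <- diff(config$exponent_range) / 2
  exponent <- numeric(nv)
  for (s in unique(mesh$structure)) {
    idx <- mesh$structure == s
    g <- smooth_field(mesh[idx, c("x", "y", "z")], config$smoothness_length)
    e <- mean(config$exponent_range) + (half / 2) * g
    exponent[idx] <- pmin(pmax(e, config$exponent_range[1]),
                          config$exponent_range[2])
  }

  # Focal fields: shared locations across SCA karyotypes by default
  # (convergent shape effects); optionally independently relocated bumps
  # per karyotype. Amplitude is karyotype-specific, XYY at half strength.
  amp <- c(XX = 0, XY = 0, XXX = 1, XXY = 1, XYY = 0.5, XXYY = 1, XXXXY = 1) *
    config$focal_amplitude
  focal_shape_for <- function(relocate) {
    shape <- numeric(nv)
    for (r in REGIONS) {
      for (s in unique(mesh$structure[mesh$region == r])) {
        idx <- which(mesh$structure == s)
        co <- mesh[idx, c("x", "y", "z")]
        for (b in FOCAL_TEMPLATE[[r]]) {
          cv <- if (relocate) sample.int(nrow(co), 1) else
            anchor_vertex(co, b$frac)
          d2 <- rowSums(sweep(co, 2, unlist(co[cv, ]), `-`)^2)
          shape[idx] <- shape[idx] +
            b$sign * exp(-d2 / (2 * config$focal_extent^2))
        }
      }
    }
    shape
  }
  if (config$focal_shared) {
    focal_shape <- focal_shape_for(relocate = FALSE)
    focal <- vapply(KARYOTYPES, function(k) amp[[k]] * focal_shape,
                    numeric(nv))
  } else {
    focal <- vapply(KARYOTYPES, function(k) {
      if (amp[[k]] == 0) numeric(nv) else
        amp[[k]] * focal_shape_for(relocate = TRUE)
    }, numeric(nv))
  }

  # Template vertex-area fractions at the reference total area: proportional
  # to the quasi-uniform lattice (equal share within structure, structures
  # weighted by their ellipsoid size via vertex count).
  region_cols <- paste0(mesh$region, "_sa")
  logS <- log10(100 * as.matrix(subjects[, c("amygdala_sa", "hippocampus_sa")]))
  colnames(logS) <- REGIONS
  # Reference total area per region (mm^2): generator-mean area, so alpha_v
  # centres the template at a realistic size.
  refS <- vapply(stats::setNames(REGIONS, REGIONS), function(r) {
    stats::median(100 * subjects[[paste0(r, "_sa")]])
  }, numeric(1))
  frac <- numeric(nv)
  for (r in REGIONS) {
    idx <- mesh$region == r
    frac[idx] <- 1 / sum(idx)
  }
  alpha <- log10(frac * refS[mesh$region]) - exponent * log10(refS[mesh$region])

  logA <- matrix(0, n, nv, dimnames = list(subjects$subject, NULL))
  kt <- subjects$karyotype
  for (i in seq_len(n)) {
    logA[i, ] <- alpha + exponent * logS[i, mesh$region] + focal[, kt[i]]
  }
  logA <- logA + matrix(stats::rnorm(n * nv, 0, config$sigma_vertex), n, nv)
  areas <- 10^logA

  # Renormalize per subject and bilateral region: sum of vertex areas (mm^2)
  # equals 100 * S_region (cm^2).
  for (r in REGIONS) {
    idx <- mesh$region == r
    target <- 100 * subjects[[paste0(r, "_sa")]]
    scale <- target / rowSums(areas[, idx, drop = FALSE])
    areas[, idx] <- areas[, idx, drop = FALSE] * scale
  }

  structure(list(mesh = mesh, areas = areas, subjects = subjects,
                 true_exponent = exponent, focal = focal),
            class = "vertex_table")
}

#' @export
print.vertex_table <- function(x, ...) {
  cat(sprintf("Vertex table: %d subjects x %d vertices (%s sample)\n",
              nrow(x$areas), ncol(x$areas),
              attr(x$subjects, "sample_label")))
  invisible(x)
}
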