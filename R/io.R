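## Readers/writers, validation, configuration files, run manifests.

#' Read a subject table from CSV
#'
#' Validates the schema: known karyotypes, sex consistent with karyotype,
#' strictly positive volumes/areas, unique subject ids. Volumes are expected
#' in cm^3; values whose magnitude suggests mm^3 (TBV > 100,000) are
#' rejected unless `assume_cm3 = TRUE`. Missing Tanner stages (blank fields)
#' are preserved and their count reported.
#'
#' @param path CSV path.
#' @param sample_label label recorded on the table (e.g. `"core"`).
#' @param assume_cm3 skip the unit plausibility check.
#' @return a `subject_table`.
#' @export
read_subject_table <- function(path, sample_label = "file",
                               assume_cm3 = FALSE) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject = "character"))
  if (!assume_cm3 && "tbv" %in% names(x) && any(x$tbv > 1e5, na.rm = TRUE)) {
    stop("total brain volumes look like mm^3 (values > 1e5); convert to ",
         "cm^3 or pass assume_cm3 = TRUE", call. = FALSE)
  }
  if ("tanner" %in% names(x)) {
    nmiss <- sum(is.na(x$tanner))
    if (nmiss > 0) message(sprintf("%d subject(s) with missing Tanner stage",
                                   nmiss))
  }
  as_subject_table(x, sample_label = sample_label)
}

#' Write a subject table to CSV
#'
#' Missing Tanner stages are written as empty fields.
#' @param x a `subject_table`.
#' @param path output CSV path.
#' @export
write_subject_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read a vertex table
#'
#' Wide CSV: `subject` id column plus one column per vertex
#' (`v<structure index>_<vertex id>` keyed to the mesh row order). The mesh
#' is serialized separately as JSON by [write_mesh()].
#'
#' @param vt a `vertex_table`.
#' @param path output CSV path.
#' @export
write_vertex_table <- function(vt, path) {
  df <- data.frame(subject = rownames(vt$areas), vt$areas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("subject", sprintf("%s_%d", vt$mesh$structure,
                                    vt$mesh$vertex))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vertex_table
#' @param subjects the matching `subject_table`.
#' @param mesh the matching `mesh_spec`.
#' @export
read_vertex_table <- function(path, subjects, mesh) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = c(subject = "character"))
  areas <- as.matrix(df[, -1, drop = FALSE])
  rownames(areas) <- df$subject
  if (ncol(areas) != nrow(mesh)) {
    stop("vertex table has ", ncol(areas), " columns but mesh has ",
         nrow(mesh), " vertices", call. = FALSE)
  }
  if (!identical(rownames(areas), subjects$subject)) {
    areas <- areas[subjects$subject, , drop = FALSE]
  }
  if (any(areas <= 0)) stop("vertex areas must be positive", call. = FALSE)
  structure(list(mesh = mesh, areas = areas, subjects = subjects,
                 true_exponent = NULL, focal = NULL),
            class = "vertex_table")
}

#' Write / read a mesh specification as JSON
#'
#' @param mesh a `mesh_spec`.
#' @param path JSON path.
#' @export
write_mesh <- function(mesh, path) {
  jsonlite::write_json(as.data.frame(mesh), path, digits = NA)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  mesh <- jsonlite::fromJSON(path)
  req <- c("vertex", "structure", "region", "hemisphere", "x", "y", "z")
  if (!all(req %in% names(mesh))) {
    stop("mesh JSON missing fields: ",
         paste(setdiff(req, names(mesh)), collapse = ", "), call. = FALSE)
  }
  mesh$vertex <- as.integer(mesh$vertex)
  structure(mesh[, req], class = c("mesh_spec", "data.frame"))
}

#' Write / read a generator configuration as YAML
#'
#' Serializes the full [sca_config()] (including derived calibration
#' fields, which are recomputed and cross-checked on read).
#'
#' @param config an `sca_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$schema_version <- 1L
  # yaml serializes atomic vectors as plain sequences; keep names by
  # writing named vectors as maps
  namedify <- function(v) {
    if (is.list(v)) lapply(v, namedify)
    else if (!is.null(names(v))) as.list(v)
    else v
  }
  # precision 17 round-trips IEEE doubles exactly
  yaml::write_yaml(lapply(x, namedify), path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  to_named <- function(v) if (is.list(v)) unlist(v) else v
  cfg <- sca_config(
    group_n = to_named(x$group_n),
    tbv_mean = to_named(x$tbv_mean),
    tbv_sd = to_named(x$tbv_sd),
    beta1 = to_named(x$beta1),
    beta0 = to_named(x$beta0),
    offsets = lapply(x$offsets, to_named),
    sigma_logvol = to_named(x$sigma_logvol),
    sex_effect = to_named(x$sex_effect),
    sex_size_interaction = to_named(x$sex_size_interaction),
    surface_r_target = to_named(x$surface_r_target),
    surface_coef = x$surface_coef,
    vertex_counts = to_named(x$vertex_counts),
    exponent_range = to_named(x$exponent_range),
    smoothness_length = x$smoothness_length,
    focal_amplitude = x$focal_amplitude,
    focal_extent = x$focal_extent,
    focal_shared = x$focal_shared,
    sigma_vertex = x$sigma_vertex,
    normative_n = x$normative_n,
    normative_n_female = x$normative_n_female,
    age_mean = x$age_mean,
    age_sd = x$age_sd,
    age_range = to_named(x$age_range),
    normative_age_range = to_named(x$normative_age_range),
    tanner_missing = to_named(x$tanner_missing),
    seed = x$seed
  )
  cfg
}

#' Hash and run manifest
#'
#' Records everything needed to reproduce a run: the configuration hash,
#' seed, package version, input checksums, and the ordered operation list.
#'
#' @param config an `sca_config`.
#' @param operations character vector of operations executed, in order.
#' @param inputs optional character vector of input file paths to checksum.
#' @return object of class `run_manifest`.
#' @export
run_manifest <- function(config, operations = character(), inputs = character()) {
  structure(list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("neuroallom")),
    input_checksums = if (length(inputs)) {
      stats::setNames(unname(tools::md5sum(inputs)), basename(inputs))
    } else NULL,
    operations = operations,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  x <- unclass(config)
  saveRDS(x[order(names(x))], tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest\n")
  cat("  config hash:", x$config_hash, "\n")
  cat("  seed:", x$seed, "  package:", x$package_version, "\n")
  if (length(x$operations)) {
    cat("  operations:", paste(x$operations, collapse = " -> "), "\n")
  }
  invisible(x)
}
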