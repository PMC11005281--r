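# Table I/O: landmark tables (CSV or JSON), angle tables, run configs.

landmark_cols <- c("image_id", "side", "landmark", "x", "y", "spacing_mm")

#' Read a landmark table
#'
#' Accepts CSV (columns `image_id`, `side`, `landmark`, `x`, `y` and
#' optionally `spacing_mm`) or JSON (an array of objects with the same
#' fields, or an object of per-image records). The format is chosen by
#' file extension.
#'
#' @param path File path.
#' @return Tibble in the landmark schema.
#' @export
read_landmarks <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  req <- setdiff(landmark_cols, "spacing_mm")
  if (!all(req %in% names(df)))
    abort(paste("Landmark table must have columns:", paste(req, collapse = ", ")),
          class = "limbalign_io_error")
  if (!"spacing_mm" %in% names(df)) df$spacing_mm <- NA_real_
  df[, landmark_cols]
}

#' Write a landmark table
#'
#' @param landmarks Data frame in the landmark schema.
#' @param path Destination (`.csv` or `.json`).
#' @export
write_landmarks <- function(landmarks, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(landmarks, path, auto_unbox = FALSE, digits = NA)
  else readr::write_csv(landmarks, path)
  invisible(path)
}

#' Read / write an angle table
#'
#' One row per limb: `image_id`, `side`, the five angles and `alignment`.
#'
#' @param path File path.
#' @export
read_angles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("image_id", "side") %in% names(df)))
    abort("Angle table must have `image_id` and `side` columns.",
          class = "limbalign_io_error")
  df
}

#' @rdname read_angles
#' @param angles Data frame of angles.
#' @export
write_angles <- function(angles, path) {
  readr::write_csv(angles, path)
  invisible(path)
}

#' Published clinical per-landmark mean radial errors
#'
#' The per-landmark MREs of the reference clinical evaluation (validation
#' and test sets of the source model), bundled as a plain-text table for
#' demonstrating and validating the [mre] machinery.
#'
#' @return Tibble with columns `dataset`, `landmark`, `mre`.
#' @export
clinical_landmark_mre <- function() {
  readr::read_csv(system.file("extdata", "clinical_landmark_mre.csv",
                              package = "limbalign"),
                  show_col_types = FALSE)
}

#' Published clinical subgroup accuracy tables
#'
#' Accuracy/inaccuracy counts of HKA measurement (accuracy = angle
#' deviation < 1 degree) across alignment, sex, BMI and age subgroups, for
#' native and prosthetic knees, bundled as a plain-text table for the
#' chi-square machinery.
#'
#' @return Tibble with columns `joint_type`, `variable`, `level`,
#'   `accurate`, `inaccurate`.
#' @export
clinical_subgroup_counts <- function() {
  readr::read_csv(system.file("extdata", "clinical_subgroup_counts.csv",
                              package = "limbalign"),
                  show_col_types = FALSE)
}

#' Contingency matrices from the bundled subgroup counts
#'
#' @param counts Tibble as returned by [clinical_subgroup_counts].
#' @return Named list of count matrices (one per joint type x variable).
#' @export
subgroup_count_matrices <- function(counts = clinical_subgroup_counts()) {
  keys <- dplyr::distinct(counts, .data$joint_type, .data$variable)
  out <- purrr::pmap(keys, function(joint_type, variable) {
    sub <- counts[counts$joint_type == joint_type &
                    counts$variable == variable, ]
    m <- as.matrix(sub[, c("accurate", "inaccurate")])
    rownames(m) <- sub$level
    m
  })
  names(out) <- paste(keys$joint_type, keys$variable, sep = "_")
  out
}

#' Read a run configuration
#'
#' YAML file with optional blocks `phantom`, `detector`, `evaluation`;
#' unknown keys are rejected so typos fail loudly. Flag-style overrides
#' (named list) win over file values.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @param overrides Named list of `block.key = value` overrides.
#' @return Nested list with the three blocks.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(phantom = list(), detector = list(), evaluation = list(),
              seed = 1L)
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    bad <- setdiff(names(y), names(cfg))
    if (length(bad))
      abort(paste("Unknown config blocks:", paste(bad, collapse = ", ")),
            class = "limbalign_config_error")
    cfg[names(y)] <- y
  }
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) cfg[[parts[1]]][[parts[2]]] <- overrides[[nm]]
    else cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

#' Write the effective configuration snapshot next to run outputs
#'
#' @param cfg Nested config list.
#' @param dir Output directory.
#' @export
write_config_snapshot <- function(cfg, dir) {
  yaml::write_yaml(cfg, file.path(dir, "effective-config.yaml"))
  invisible(file.path(dir, "effective-config.yaml"))
}
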