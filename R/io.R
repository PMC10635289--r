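BUNDLE_SCHEMA_VERSION <- 1L

#' Save / load result bundles
#'
#' Persists the package's result objects (dictionaries, bases,
#' orthogonalized-derivative sets, CRB tables, Monte-Carlo reports, ...) as
#' schema-versioned single-file bundles. Complex arrays round-trip
#' bit-for-bit. Files are R serialization under a small schema wrapper; a
#' truncated or foreign file raises a schema error rather than yielding a
#' partial object.
#'
#' @param object Object to persist.
#' @param path File path (conventionally `.rds`).
#' @return `save_bundle()` returns `path` invisibly; `load_bundle()` returns
#'   the restored object.
#' @export
save_bundle <- function(object, path) {
  wrapper <- list(schema = "crbsvd-bundle",
                  version = BUNDLE_SCHEMA_VERSION,
                  class = class(object)[1L],
                  object = object)
  saveRDS(wrapper, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  wrapper <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("not a readable bundle (corrupt or truncated): ", path))
  })
  if (!is.list(wrapper) || !identical(wrapper$schema, "crbsvd-bundle")) {
    abort("schema mismatch: expected a crbsvd-bundle file")
  }
  if (!identical(wrapper$version, BUNDLE_SCHEMA_VERSION)) {
    abort(paste0("schema mismatch: expected version ", BUNDLE_SCHEMA_VERSION,
                 ", found ", wrapper$version %||% "<missing>"))
  }
  wrapper$object
}

#' Read / write flip-angle trains as single-column CSV (degrees)
#'
#' @param path CSV path; one header line (`flip_deg`) and one angle per row.
#' @param flip_train Flip angles in radians.
#' @return `read_flip_train_csv()` returns radians.
#' @export
read_flip_train_csv <- function(path) {
  tab <- utils::read.csv(path)
  as.numeric(tab[[1L]]) * pi / 180
}

#' @rdname read_flip_train_csv
#' @export
write_flip_train_csv <- function(flip_train, path) {
  utils::write.csv(data.frame(flip_deg = flip_train * 180 / pi), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' A run configuration collects everything needed to reproduce a pipeline
#' run: model/sequence choice, grid ranges (ms for `t1`/`t2` axes), the
#' lambda and `N_c` lists, SNR, repetition count and explicit seeds. Flip
#' angles given in the YAML are in degrees and converted to radians; a
#' `flip_train_csv` path may be given instead.
#'
#' @param path YAML file path.
#' @return A validated list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  needed <- c("model", "grid", "lambda", "n_c", "snr", "reps", "seed")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) {
    abort(paste0("run config missing field(s): ", paste(missing, collapse = ", ")))
  }
  if (!cfg$model %in% c("toy", "fisp")) abort("model must be 'toy' or 'fisp'")
  if (!is.null(cfg$flip_train_csv)) {
    cfg$flip_train <- read_flip_train_csv(cfg$flip_train_csv)
  } else if (!is.null(cfg$flip_train_deg)) {
    cfg$flip_train <- as.numeric(cfg$flip_train_deg) * pi / 180
  }
  structure(cfg, class = "run_config")
}

# Build the model object a run config describes.
config_model <- function(cfg) {
  if (cfg$model == "toy") return(toy_model())
  spec_args <- list()
  if (!is.null(cfg$flip_train)) spec_args$flip_train <- cfg$flip_train
  for (f in c("tr", "te", "ti", "inv_efficiency", "n_isochromats")) {
    if (!is.null(cfg[[f]])) spec_args[[f]] <- cfg[[f]]
  }
  fisp_model(do.call(fisp_spec, spec_args))
}

# Build the parameter grid a run config describes (ms for t1/t2 axes).
config_grid <- function(cfg) {
  do.call(parameter_grid, lapply(cfg$grid, function(r) as.numeric(r)))
}

#' Export a CRB table to CSV and a JSON summary
#'
#' @param table A [crb_table()].
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return The summary list, invisibly.
#' @export
export_crb_report <- function(table, csv_path = NULL, json_path = NULL) {
  losses <- crb_losses(table)
  summary <- list(delta_b_ac = losses$delta_b_ac,
                  delta_b_ec = losses$delta_b_ec,
                  r = optimality_ratio(table),
                  per_parameter = losses$per_parameter)
  if (!is.null(csv_path)) utils::write.csv(table, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(summary)
}

#' Write parameter maps as NIfTI volumes
#'
#' One single-slice volume per map (`t1_ms`, `t2_ms`, `m0_mod`); background
#' voxels are written as zero.
#'
#' @param maps A [fit_maps()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of file paths, invisibly.
#' @export
write_parameter_maps_nifti <- function(maps, dir, prefix = "map") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("t1_ms", "t2_ms", "m0_mod")) {
    vol <- maps[[nm]]
    vol[is.na(vol)] <- 0
    p <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    RNifti::writeNifti(array(vol, dim = c(dim(vol), 1L)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
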