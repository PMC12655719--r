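# Typed readers/writers for component, mixture and solubility-curve tables and
# for JSON run artifacts. All tables are plain comma-separated UTF-8 files with
# a mandatory header and "." as decimal mark.

ARTIFACT_VERSION <- "1.0"

#' Construct a per-molecule COSMO-RS descriptor record
#'
#' Holds the five interaction-energy / chemical-potential descriptors of one
#' molecule (solute or solvent) and, optionally, its sigma-potential curve
#' sampled on the fixed 61-point charge-density grid (see [sigma_grid()]).
#'
#' @param molecule_id character identifier.
#' @param e_int total intermolecular interaction energy.
#' @param e_misfit electrostatic misfit component.
#' @param e_hb hydrogen-bonding component.
#' @param e_vdw van der Waals component.
#' @param mu chemical potential.
#' @param sigma_potential optional numeric vector of exactly 61 values on the
#'   implicit grid -0.03 ... +0.03 e/A^2 (step 0.001); the grid itself is never
#'   stored.
#' @return An object of class `component_descriptors`.
#' @export
component_descriptors <- function(molecule_id, e_int, e_misfit, e_hb, e_vdw, mu,
                                  sigma_potential = NULL) {
  if (!is.character(molecule_id) || length(molecule_id) != 1L || is.na(molecule_id)) {
    stop_dooit("'molecule_id' must be a single string", "dooit_validation_error")
  }
  vals <- c(e_int = e_int, e_misfit = e_misfit, e_hb = e_hb, e_vdw = e_vdw, mu = mu)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    bad <- names(vals)[!is.finite(vals)]
    stop_dooit(sprintf("non-finite descriptor value(s) for '%s': %s",
                       molecule_id, paste(bad, collapse = ", ")),
               "dooit_validation_error")
  }
  if (!is.null(sigma_potential)) {
    if (!is.numeric(sigma_potential) || length(sigma_potential) != 61L) {
      stop_dooit(sprintf("sigma_potential for '%s': expected 61 values, got %d",
                         molecule_id, length(sigma_potential)),
                 "dooit_schema_error")
    }
    if (any(!is.finite(sigma_potential))) {
      stop_dooit(sprintf("non-finite sigma_potential value(s) for '%s'", molecule_id),
                 "dooit_validation_error")
    }
    sigma_potential <- as.numeric(sigma_potential)
  }
  structure(
    list(molecule_id = molecule_id,
         e_int = as.numeric(e_int), e_misfit = as.numeric(e_misfit),
         e_hb = as.numeric(e_hb), e_vdw = as.numeric(e_vdw), mu = as.numeric(mu),
         sigma_potential = sigma_potential),
    class = "component_descriptors"
  )
}

#' @export
print.component_descriptors <- function(x, ...) {
  cat(sprintf("<component_descriptors> %s\n", x$molecule_id))
  cat(sprintf("  e_int=%.4g e_misfit=%.4g e_hb=%.4g e_vdw=%.4g mu=%.4g\n",
              x$e_int, x$e_misfit, x$e_hb, x$e_vdw, x$mu))
  cat(if (is.null(x$sigma_potential)) "  sigma-potential: absent\n"
      else "  sigma-potential: 61-point curve\n")
  invisible(x)
}

SIGMA_COLS <- sprintf("sigma_%03d", 0:60)
COMPONENT_COLS <- c("molecule_id", "e_int", "e_misfit", "e_hb", "e_vdw", "mu")

#' Read a component descriptor table
#'
#' Expects columns `molecule_id, e_int, e_misfit, e_hb, e_vdw, mu` and,
#' optionally, the full block `sigma_000 ... sigma_060` (all 61 or none).
#'
#' @param path CSV file path.
#' @return A named list of [component_descriptors()] records (class
#'   `component_table`), keyed by molecule id.
#' @export
read_component_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(COMPONENT_COLS, names(df))
  if (length(missing_cols)) {
    stop_dooit(sprintf("component table '%s': missing mandatory column(s): %s",
                       path, paste(missing_cols, collapse = ", ")),
               "dooit_schema_error")
  }
  sig_present <- grep("^sigma_[0-9]+$", names(df), value = TRUE)
  has_sigma <- length(sig_present) > 0L
  if (has_sigma && !identical(sort(sig_present), sort(SIGMA_COLS))) {
    stop_dooit(sprintf(
      "component table '%s': expected 61 sigma columns (sigma_000..sigma_060), found %d",
      path, length(sig_present)), "dooit_schema_error")
  }
  if (nrow(df) == 0L) {
    dooit_log("warn", "component table '", path, "' has no data rows")
  }
  recs <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    vals <- as.numeric(row[, COMPONENT_COLS[-1]])
    if (any(!is.finite(vals))) {
      stop_dooit(sprintf("component table '%s': non-finite value in row %d", path, i),
                 "dooit_validation_error")
    }
    sig <- if (has_sigma) as.numeric(row[, SIGMA_COLS]) else NULL
    if (has_sigma && any(!is.finite(sig))) {
      stop_dooit(sprintf("component table '%s': non-finite sigma value in row %d", path, i),
                 "dooit_validation_error")
    }
    component_descriptors(as.character(row$molecule_id),
                          vals[1], vals[2], vals[3], vals[4], vals[5],
                          sigma_potential = sig)
  })
  names(recs) <- vapply(recs, `[[`, "", "molecule_id")
  structure(recs, class = "component_table")
}

#' Write a component descriptor table
#'
#' Inverse of [read_component_table()].
#'
#' @param components a `component_table` or list of `component_descriptors`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(components, path) {
  has_sigma <- vapply(components, function(r) !is.null(r$sigma_potential), TRUE)
  if (any(has_sigma) && !all(has_sigma)) {
    stop_dooit("sigma curves must be present on all components or none",
               "dooit_schema_error")
  }
  base <- do.call(rbind, lapply(components, function(r) {
    data.frame(molecule_id = r$molecule_id, e_int = r$e_int, e_misfit = r$e_misfit,
               e_hb = r$e_hb, e_vdw = r$e_vdw, mu = r$mu, stringsAsFactors = FALSE)
  }))
  if (all(has_sigma) && length(components)) {
    sig <- do.call(rbind, lapply(components, function(r) {
      stats::setNames(as.data.frame(as.list(r$sigma_potential)), SIGMA_COLS)
    }))
    base <- cbind(base, sig)
  }
  utils::write.csv(base, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

MIXTURE_COLS <- c("solute_id", "solvent1_id", "solvent2_id", "x2_star",
                  "temperature_K", "log_x_exp", "log_x_cosmo", "category")

#' Read a mixture observation table
#'
#' One row per (solute, solvent1, solvent2, composition, temperature)
#' observation. Solubility is carried as the decadic log of the solute mole
#' fraction; `log_x_exp` may be empty for prediction-only rows. `x2_star` is
#' the mole fraction of the second (organic) solvent in the solute-free
#' mixture.
#'
#' @param path CSV file path with columns
#'   `solute_id, solvent1_id, solvent2_id, x2_star, temperature_K, log_x_exp,
#'   log_x_cosmo, category`.
#' @return A validated `data.frame` (class `mixture_table`).
#' @export
read_mixture_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(MIXTURE_COLS, names(df))
  if (length(missing_cols)) {
    stop_dooit(sprintf("mixture table '%s': missing mandatory column(s): %s",
                       path, paste(missing_cols, collapse = ", ")),
               "dooit_schema_error")
  }
  if (nrow(df) == 0L) {
    dooit_log("warn", "mixture table '", path, "' has no data rows")
    return(structure(df[, MIXTURE_COLS], class = c("mixture_table", "data.frame")))
  }
  num_cols <- c("x2_star", "temperature_K", "log_x_exp", "log_x_cosmo")
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  validate_mixture_rows(df, path)
  structure(df[, MIXTURE_COLS], class = c("mixture_table", "data.frame"))
}

validate_mixture_rows <- function(df, origin = "mixture table") {
  bad <- which(!is.finite(df$x2_star) | df$x2_star < 0 | df$x2_star > 1)
  if (length(bad)) {
    stop_dooit(sprintf("%s: x2_star outside [0,1] in row(s) %s",
                       origin, paste(bad, collapse = ", ")),
               "dooit_validation_error")
  }
  bad <- which(!is.finite(df$temperature_K) | df$temperature_K <= 0)
  if (length(bad)) {
    stop_dooit(sprintf("%s: temperature_K must be > 0; offending row(s) %s",
                       origin, paste(bad, collapse = ", ")),
               "dooit_validation_error")
  }
  bad <- which(is.finite(df$log_x_exp) & df$log_x_exp > 0)
  if (length(bad)) {
    stop_dooit(sprintf("%s: log_x_exp > 0 (mole fraction > 1) in row(s) %s",
                       origin, paste(bad, collapse = ", ")),
               "dooit_validation_error")
  }
  bad <- which(is.finite(df$log_x_cosmo) & df$log_x_cosmo > 0)
  if (length(bad)) {
    stop_dooit(sprintf("%s: log_x_cosmo > 0 (mole fraction > 1) in row(s) %s",
                       origin, paste(bad, collapse = ", ")),
               "dooit_validation_error")
  }
  if (!all(is.na(df$category))) {
    bad <- which(!is.na(df$category) & !(df$category %in% 1:4))
    if (length(bad)) {
      stop_dooit(sprintf("%s: category must be 1..4; offending row(s) %s",
                         origin, paste(bad, collapse = ", ")),
                 "dooit_validation_error")
    }
  }
  invisible(df)
}

CURVE_COLS <- c("solute_id", "solvent1_id", "solvent2_id",
                "temperature_K", "x2_star", "x1")

#' Read raw solubility curves for curation
#'
#' One row per measured point `(temperature, x2_star, x1)`, grouped by
#' (solute, solvent pair) into solubility curves. `x1` is the mole-fraction
#' solubility in (0, 1].
#'
#' @param path CSV file with columns
#'   `solute_id, solvent1_id, solvent2_id, temperature_K, x2_star, x1`.
#' @return A list of per-system data frames (class `solubility_curves`), each
#'   with attributes `solute_id`, `solvent1_id`, `solvent2_id`.
#' @export
read_solubility_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(CURVE_COLS, names(df))
  if (length(missing_cols)) {
    stop_dooit(sprintf("solubility curve table '%s': missing column(s): %s",
                       path, paste(missing_cols, collapse = ", ")),
               "dooit_schema_error")
  }
  if (nrow(df) == 0L) {
    stop_dooit(sprintf("solubility curve table '%s': no data rows", path),
               "dooit_validation_error")
  }
  bad <- which(!is.finite(df$x1) | df$x1 <= 0 | df$x1 > 1)
  if (length(bad)) {
    stop_dooit(sprintf("solubility curve table '%s': x1 outside (0,1] in row(s) %s",
                       path, paste(bad, collapse = ", ")),
               "dooit_validation_error")
  }
  key <- interaction(df$solute_id, df$solvent1_id, df$solvent2_id, drop = TRUE)
  curves <- lapply(split(df, key), function(g) {
    dup <- duplicated(g[, c("temperature_K", "x2_star")])
    if (any(dup)) {
      stop_dooit(sprintf(
        "solubility curves '%s/%s/%s': duplicate (temperature, x2_star) pairs",
        g$solute_id[1], g$solvent1_id[1], g$solvent2_id[1]),
        "dooit_validation_error")
    }
    out <- g[, c("temperature_K", "x2_star", "x1")]
    rownames(out) <- NULL
    attr(out, "solute_id") <- g$solute_id[1]
    attr(out, "solvent1_id") <- g$solvent1_id[1]
    attr(out, "solvent2_id") <- g$solvent2_id[1]
    out
  })
  structure(curves, class = "solubility_curves")
}

#' Assemble a run artifact
#'
#' A run artifact captures everything needed to reproduce and audit one
#' DOO-IT run: seeds, configuration echo, per-level trial tables, the pruning
#' trace, and the train/test partition. It round-trips losslessly through
#' [write_run_artifact()] / [read_run_artifact()].
#'
#' @param run_id character run identifier.
#' @param seed integer master seed of the run.
#' @param pool_name name of the descriptor pool (e.g. "set1").
#' @param config named list echoing the run configuration.
#' @param trials per-level list of trial data frames.
#' @param trace pruning trace (list of candidate summaries).
#' @param train_idx,test_idx integer index vectors of the 80/20 partition.
#' @return An object of class `run_artifact`.
#' @export
run_artifact <- function(run_id, seed, pool_name, config, trials, trace,
                         train_idx, test_idx) {
  structure(
    list(version = ARTIFACT_VERSION, run_id = as.character(run_id),
         seed = as.integer(seed), pool_name = as.character(pool_name),
         config = config, trials = trials, trace = trace,
         train_idx = as.integer(train_idx), test_idx = as.integer(test_idx)),
    class = "run_artifact"
  )
}

#' Write a run artifact to JSON
#'
#' Floating-point values are serialized with 17 significant digits so the
#' write/read round trip is the identity; output carries no timestamps, so a
#' rerun with identical seeds produces a byte-identical file.
#'
#' @param artifact a [run_artifact()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_artifact <- function(artifact, path) {
  stopifnot(inherits(artifact, "run_artifact"))
  json <- jsonlite::toJSON(unclass(artifact), digits = NA, auto_unbox = TRUE,
                           null = "null", na = "null", pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a run artifact from JSON
#'
#' @param path JSON file written by [write_run_artifact()].
#' @return A [run_artifact()].
#' @export
read_run_artifact <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    error = function(e) stop_dooit(sprintf("malformed JSON in '%s': %s",
                                           path, conditionMessage(e)),
                                   "dooit_parse_error")
  )
  required <- c("version", "run_id", "seed", "pool_name", "config",
                "trials", "trace", "train_idx", "test_idx")
  missing_f <- setdiff(required, names(obj))
  if (length(missing_f)) {
    stop_dooit(sprintf("run artifact '%s': missing field: %s",
                       path, paste(missing_f, collapse = ", ")),
               "dooit_schema_error")
  }
  if (!identical(as.character(obj$version), ARTIFACT_VERSION)) {
    stop_dooit(sprintf("run artifact '%s': version mismatch (file %s, supported %s)",
                       path, obj$version, ARTIFACT_VERSION),
               "dooit_version_error")
  }
  trials <- lapply(obj$trials, function(level) {
    do.call(rbind, lapply(level, function(row) {
      as.data.frame(lapply(row, function(v) if (is.null(v)) NA else v))
    }))
  })
  run_artifact(obj$run_id, obj$seed, obj$pool_name, obj$config,
               trials, obj$trace, obj$train_idx, obj$test_idx)
}
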