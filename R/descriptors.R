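# Construction of the set-1 (16-feature) and set-2 (28-feature) descriptor
# vectors for mixture records from per-molecule COSMO-RS data.

ENERGY_FIELDS <- c("e_int", "e_misfit", "e_hb", "e_vdw", "mu")

SIGMA_BIN_NAMES <- c(sprintf("hbd%d", 1:4), sprintf("hh%d", 1:4), sprintf("hba%d", 1:4))

#' The fixed sigma-potential sampling grid
#'
#' Screening charge density grid on which every sigma-potential curve is
#' sampled: 61 points from -0.03 to +0.03 e/A^2 in steps of 0.001. The grid is
#' implicit everywhere; files and records carry only the 61 values.
#'
#' @return Numeric vector of length 61.
#' @export
sigma_grid <- function() seq(-0.03, 0.03, by = 0.001)

#' Mole-fraction-weighted solvent descriptors
#'
#' Descriptors of the solute-free binary solvent mixture: every field of the
#' two components is combined as `(1 - x2_star) * comp1 + x2_star * comp2`,
#' applied element-wise to the sigma-potential curves when present. The
#' weighting is symmetric in `(comp1, 1 - x2_star)` / `(comp2, x2_star)`;
#' neither component is assumed to be water.
#'
#' @param comp1 [component_descriptors()] of the first solvent.
#' @param comp2 [component_descriptors()] of the second (organic) solvent.
#' @param x2_star mole fraction of `comp2` in the solute-free mixture, in
#'   \[0, 1\].
#' @return A [component_descriptors()] for the mixture.
#' @export
weight_solvent_descriptors <- function(comp1, comp2, x2_star) {
  stopifnot(inherits(comp1, "component_descriptors"),
            inherits(comp2, "component_descriptors"))
  assert_scalar_number(x2_star, "x2_star")
  if (x2_star < 0 || x2_star > 1) {
    stop_dooit("x2_star must lie in [0, 1]", "dooit_validation_error")
  }
  s1 <- comp1$sigma_potential
  s2 <- comp2$sigma_potential
  if (is.null(s1) != is.null(s2)) {
    stop_dooit(sprintf(
      "sigma-potential present on only one of '%s', '%s'; cannot weight",
      comp1$molecule_id, comp2$molecule_id), "dooit_validation_error")
  }
  w1 <- 1 - x2_star
  mix_sigma <- if (is.null(s1)) NULL else w1 * s1 + x2_star * s2
  component_descriptors(
    sprintf("%s+%s@%g", comp1$molecule_id, comp2$molecule_id, x2_star),
    e_int = w1 * comp1$e_int + x2_star * comp2$e_int,
    e_misfit = w1 * comp1$e_misfit + x2_star * comp2$e_misfit,
    e_hb = w1 * comp1$e_hb + x2_star * comp2$e_hb,
    e_vdw = w1 * comp1$e_vdw + x2_star * comp2$e_vdw,
    mu = w1 * comp1$mu + x2_star * comp2$mu,
    sigma_potential = mix_sigma
  )
}

#' Solute-minus-solvent descriptor differences
#'
#' The relative difference between each solute and solvent descriptor,
#' implemented as the arithmetic difference (solute minus solvent); ratios are
#' ill-defined near zero. Set `mode = "ratio"` for exploratory ratio features.
#'
#' @param api [component_descriptors()] of the solute.
#' @param solvent_mix [component_descriptors()] of the (mixed) solvent.
#' @param mode `"difference"` (default) or `"ratio"`.
#' @return Named numeric vector `d_e_int, d_e_misfit, d_e_hb, d_e_vdw, d_mu`.
#' @export
diff_descriptors <- function(api, solvent_mix, mode = c("difference", "ratio")) {
  stopifnot(inherits(api, "component_descriptors"),
            inherits(solvent_mix, "component_descriptors"))
  mode <- match.arg(mode)
  a <- unlist(api[ENERGY_FIELDS])
  s <- unlist(solvent_mix[ENERGY_FIELDS])
  out <- if (mode == "difference") a - s else a / s
  names(out) <- paste0("d_", ENERGY_FIELDS)
  out
}

#' Condense a sigma-potential curve into 12 region bins
#'
#' Averages the 61-point curve over 0.005 e/A^2 intervals, producing a 12-step
#' function over the hydrogen-bond-donor (HBD1-4, -0.03 to -0.01), hydrophobic
#' (HH1-4, -0.01 to +0.01) and hydrogen-bond-acceptor (HBA1-4, +0.01 to +0.03)
#' regions. Bins are half-open `[lo, lo + 0.005)`; the single grid point at
#' exactly +0.03 belongs to the last bin (which therefore averages 6 points,
#' all others 5), so no grid point is lost.
#'
#' @param sigma numeric vector of length 61 on the fixed grid.
#' @return Named numeric vector of 12 bin means, ordered
#'   `hbd1..hbd4, hh1..hh4, hba1..hba4` (i.e. from -0.03 to +0.03).
#' @export
bin_sigma_potential <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 61L) {
    stop_dooit(sprintf("sigma-potential curve: expected 61 values, got %d",
                       length(sigma)), "dooit_schema_error")
  }
  k <- 0:60
  bin <- pmin(k %/% 5L, 11L)  # 5 points per bin; the +0.03 endpoint joins bin 12
  means <- vapply(0:11, function(b) mean(sigma[bin == b]), 0)
  stats::setNames(means, SIGMA_BIN_NAMES)
}

set2_block_names <- function(sigma_block) {
  switch(sigma_block,
         difference = paste0("d_sigma_", SIGMA_BIN_NAMES),
         api = paste0("sigma_", SIGMA_BIN_NAMES, "_api"),
         solvent = paste0("sigma_", SIGMA_BIN_NAMES, "_solv"))
}

#' Build the feature vector of one mixture record
#'
#' Set 1 (16 features): the COSMO-RS predicted log-solubility, the five solute
#' descriptors, the five mole-fraction-weighted solvent-mixture descriptors
#' and the five solute-minus-solvent differences. Set 2 (28 features) appends
#' twelve condensed sigma-potential bins; all three 12-bin blocks (solute,
#' solvent mixture, difference) are computed internally and `sigma_block`
#' selects which one enters the feature vector (default: the difference
#' block).
#'
#' @param record one-row data frame (or list) with fields `solute_id`,
#'   `solvent1_id`, `solvent2_id`, `x2_star`, `log_x_cosmo`.
#' @param components a `component_table` (named list of
#'   [component_descriptors()]) resolving all three molecule ids.
#' @param set `"set1"` or `"set2"`.
#' @param sigma_block which sigma bin block enters set 2:
#'   `"difference"` (default), `"api"` or `"solvent"`.
#' @return Named numeric vector of length 16 (`set1`) or 28 (`set2`), in
#'   deterministic name order.
#' @export
build_features <- function(record, components, set = c("set1", "set2"),
                           sigma_block = c("difference", "api", "solvent")) {
  set <- match.arg(set)
  sigma_block <- match.arg(sigma_block)
  ids <- c(record$solute_id, record$solvent1_id, record$solvent2_id)
  unknown <- setdiff(ids, names(components))
  if (length(unknown)) {
    stop_dooit(sprintf("unknown molecule id(s): %s", paste(unknown, collapse = ", ")),
               "dooit_lookup_error")
  }
  api <- components[[record$solute_id]]
  mix <- weight_solvent_descriptors(components[[record$solvent1_id]],
                                    components[[record$solvent2_id]],
                                    record$x2_star)
  if (!is_scalar_number(record$log_x_cosmo)) {
    stop_dooit("record lacks a finite log_x_cosmo", "dooit_validation_error")
  }
  out <- c(
    log_x_cosmo = as.numeric(record$log_x_cosmo),
    stats::setNames(unlist(api[ENERGY_FIELDS]), paste0(ENERGY_FIELDS, "_api")),
    stats::setNames(unlist(mix[ENERGY_FIELDS]), paste0(ENERGY_FIELDS, "_solv")),
    diff_descriptors(api, mix)
  )
  if (set == "set2") {
    if (is.null(api$sigma_potential) || is.null(mix$sigma_potential)) {
      stop_dooit("set2 requested but sigma-potential curves are absent",
                 "dooit_validation_error")
    }
    bins_api <- bin_sigma_potential(api$sigma_potential)
    bins_solv <- bin_sigma_potential(mix$sigma_potential)
    block <- switch(sigma_block,
                    difference = bins_api - bins_solv,
                    api = bins_api,
                    solvent = bins_solv)
    out <- c(out, stats::setNames(block, set2_block_names(sigma_block)))
  }
  out
}

#' Build a feature table for a whole mixture table
#'
#' Applies [build_features()] to every row and returns the mixture key
#' columns, the feature columns and the experimental target.
#'
#' @inheritParams build_features
#' @param mixtures a `mixture_table` from [read_mixture_table()].
#' @return A `data.frame` with key columns
#'   (`solute_id, solvent1_id, solvent2_id, x2_star, temperature_K`), one
#'   column per feature, and `log_x_exp`.
#' @export
build_feature_table <- function(mixtures, components, set = c("set1", "set2"),
                                sigma_block = c("difference", "api", "solvent")) {
  set <- match.arg(set)
  sigma_block <- match.arg(sigma_block)
  feats <- t(vapply(seq_len(nrow(mixtures)), function(i) {
    build_features(mixtures[i, ], components, set, sigma_block)
  }, numeric(if (set == "set1") 16L else 28L)))
  cbind(mixtures[, c("solute_id", "solvent1_id", "solvent2_id",
                     "x2_star", "temperature_K")],
        as.data.frame(feats),
        log_x_exp = mixtures$log_x_exp)
}
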