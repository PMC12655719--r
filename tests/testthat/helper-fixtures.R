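# Shared in-code fixtures: small component/mixture tables and independent
# oracles used across test files.

make_component <- function(id, base = 0, sigma = NULL) {
  component_descriptors(id, e_int = base - 10, e_misfit = base + 2,
                        e_hb = base - 4, e_vdw = base - 6, mu = base + 1,
                        sigma_potential = sigma)
}

make_component_table <- function(with_sigma = FALSE, seed = 1) {
  sig <- function(s) if (with_sigma) gen_sigma_curve(seed = s) else NULL
  comps <- list(make_component("CAF", 0, sig(1)),
                make_component("water", 1, sig(2)),
                make_component("DMSO", -1, sig(3)))
  names(comps) <- vapply(comps, `[[`, "", "molecule_id")
  structure(comps, class = "component_table")
}

make_mixture_df <- function(n = 3) {
  m <- max(n, 1L)
  df <- data.frame(solute_id = "CAF", solvent1_id = "water", solvent2_id = "DMSO",
                   x2_star = seq(0, 1, length.out = m),
                   temperature_K = 298.15,
                   log_x_exp = log10(seq(0.01, 0.3, length.out = m)),
                   log_x_cosmo = log10(seq(0.02, 0.25, length.out = m)),
                   category = 1L, stringsAsFactors = FALSE)
  df[seq_len(n), ]
}

write_mixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# independent brute-force binning oracle: assign each grid point to its
# 0.005-wide interval by explicit comparison against bin edges
oracle_bin_sigma <- function(values) {
  grid <- seq(-0.03, 0.03, by = 0.001)
  edges <- seq(-0.03, 0.03, by = 0.005)
  out <- numeric(12)
  for (b in 1:12) {
    lo <- edges[b]; hi <- edges[b + 1]
    member <- if (b < 12) grid >= lo - 1e-12 & grid < hi - 1e-12
              else grid >= lo - 1e-12 & grid <= hi + 1e-12
    out[b] <- mean(values[member])
  }
  out
}

# independent all-pairs domination oracle over (mae, svr) minimization
oracle_pareto_mask <- function(mae, svr) {
  n <- length(mae)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i &&
          mae[j] <= mae[i] && svr[j] <= svr[i] &&
          (mae[j] < mae[i] || svr[j] < svr[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# wrap bare objective values as trial records accepted by pareto_front()
fake_trials <- function(mae, svr, se = rep(0.001, length(mae))) {
  structure(lapply(seq_along(mae), function(i) {
    structure(list(trial_id = i, nu = 0.5, cost = 1, log10_gamma_scale = 0,
                   cv_mae = mae[i], cv_mae_se = se[i], sv_ratio = svr[i],
                   failed = FALSE), class = "dooit_trial")
  }), class = "dooit_trials")
}

# hand-built pruning-trace candidate for selection-rule tests
fake_candidate <- function(n_features, mae_test, cv_mae_se = 0.003,
                           mae_train = mae_test - 0.01, r2_test = 0.9,
                           feature_names = sprintf("f%02d", seq_len(n_features))) {
  structure(list(n_features = as.integer(n_features),
                 feature_names = feature_names,
                 nu = 0.3, cost = 10, log10_gamma_scale = 0,
                 cv_mae = mae_test, cv_mae_se = cv_mae_se,
                 sv_ratio = 0.4, mae_train = mae_train,
                 mae_test = mae_test, r2_test = r2_test,
                 eliminated = NA_character_),
            class = "dooit_candidate")
}

small_qspr <- function(seed = 1, n = 150, inf = 2, noise = 3) {
  gen_qspr_table(synthetic_spec(n_samples = n, n_informative = inf,
                                n_noise = noise, seed = seed))
}
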