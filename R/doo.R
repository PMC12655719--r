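# Dual-objective optimization: seeded samplers over the (nu, C, gamma-scale)
# box, Pareto-front extraction under joint minimization of CV MAE and SV
# ratio, one-standard-error candidate selection, permutation importance, and
# the iterative backward-pruning loop.

HP_BOX <- list(nu = c(0.01, 0.999), log10_cost = c(-2, 3), log10_gamma_scale = c(-2, 2))

clip <- function(v, lo, hi) pmin(hi, pmax(lo, v))

draw_uniform_hp <- function() {
  c(nu = stats::runif(1, HP_BOX$nu[1], HP_BOX$nu[2]),
    log10_cost = stats::runif(1, HP_BOX$log10_cost[1], HP_BOX$log10_cost[2]),
    log10_gamma_scale = stats::runif(1, HP_BOX$log10_gamma_scale[1],
                                     HP_BOX$log10_gamma_scale[2]))
}

perturb_hp <- function(h) {
  c(nu = clip(h[["nu"]] + stats::rnorm(1, 0, 0.08), HP_BOX$nu[1], HP_BOX$nu[2]),
    log10_cost = clip(h[["log10_cost"]] + stats::rnorm(1, 0, 0.25),
                      HP_BOX$log10_cost[1], HP_BOX$log10_cost[2]),
    log10_gamma_scale = clip(h[["log10_gamma_scale"]] + stats::rnorm(1, 0, 0.2),
                             HP_BOX$log10_gamma_scale[1], HP_BOX$log10_gamma_scale[2]))
}

nondominated_mask <- function(mae, svr) {
  n <- length(mae)
  keep <- logical(n)
  for (i in seq_len(n)) {
    keep[i] <- !any(mae <= mae[i] & svr <= svr[i] & (mae < mae[i] | svr < svr[i]))
  }
  keep
}

#' Run one dual-objective hyperparameter search
#'
#' Evaluates `n_trials` nuSVR configurations over the box nu in \[0.01, 1),
#' C in \[1e-2, 1e3\] (log scale) and log10 gamma scale in \[-2, 2\], each by
#' k-fold cross-validation ([evaluate_trial()]), minimizing (CV MAE, SV
#' ratio) jointly. The default sampler is a seeded multi-objective local
#' refinement scheme: after a uniform warm-up (10 percent of the trial
#' budget, at least 20 trials) it perturbs randomly chosen members of the
#' current non-dominated set in a Gaussian neighbourhood, with a 10 percent
#' random-exploration fallback; `sampler = "random"` gives plain seeded
#' uniform search.
#'
#' @inheritParams evaluate_trial
#' @param pool character vector of feature columns to use (subset of
#'   `colnames(x)`).
#' @param n_trials number of trials (default 200).
#' @param sampler `"pareto-local"` (default) or `"random"`.
#' @param sampler_seed seed driving all hyperparameter draws.
#' @return An object of class `dooit_trials`: list of `dooit_trial` records
#'   plus the objective matrix as attribute `objectives`.
#' @export
run_doo <- function(x, y, pool = colnames(x), n_trials = 200L,
                    sampler = c("pareto-local", "random"),
                    sampler_seed = 1L, k_folds = 5L, fold_seed = 1L,
                    context = NULL) {
  sampler <- match.arg(sampler)
  if (length(pool) == 0L) stop_dooit("empty feature pool", "dooit_validation_error")
  x <- as.matrix(x)[, pool, drop = FALSE]
  ctx <- context %||% fold_context(x, y, k_folds, fold_seed)
  n_warm <- max(20L, ceiling(0.1 * n_trials))
  trials <- vector("list", n_trials)
  mae <- svr <- rep(NA_real_, n_trials)
  with_seed(sampler_seed, {
    for (i in seq_len(n_trials)) {
      ok <- which(!is.na(mae[seq_len(i - 1L)]))
      if (sampler == "random" || i <= n_warm || length(ok) == 0L ||
          stats::runif(1) < 0.10) {
        h <- draw_uniform_hp()
      } else {
        front <- ok[nondominated_mask(mae[ok], svr[ok])]
        pick <- trials[[front[sample.int(length(front), 1L)]]]
        h <- perturb_hp(c(nu = pick$nu, log10_cost = log10(pick$cost),
                          log10_gamma_scale = pick$log10_gamma_scale))
      }
      tr <- evaluate_trial(x, y, nu = h[["nu"]], cost = 10^h[["log10_cost"]],
                           log10_gamma_scale = h[["log10_gamma_scale"]],
                           context = ctx, trial_id = i)
      trials[[i]] <- tr
      if (!tr$failed) {
        mae[i] <- tr$cv_mae
        svr[i] <- tr$sv_ratio
      }
      dooit_log("debug", sprintf("trial %d: nu=%.3f C=%.3g scale=%.2f mae=%.4g svr=%.3f",
                                 i, h[["nu"]], 10^h[["log10_cost"]],
                                 h[["log10_gamma_scale"]],
                                 if (tr$failed) NA else tr$cv_mae,
                                 if (tr$failed) NA else tr$sv_ratio))
    }
  })
  structure(trials, class = "dooit_trials",
            objectives = cbind(cv_mae = mae, sv_ratio = svr))
}

#' Extract the Pareto front of a trial set
#'
#' Returns exactly the non-dominated trials under joint minimization of
#' (CV MAE, SV ratio): a trial is dominated if some other trial is at least
#' as good in both objectives and strictly better in one. Trials that are
#' duplicated on both objectives are all retained; failed trials are
#' excluded.
#'
#' @param trials a `dooit_trials` object or list of `dooit_trial` records.
#' @return The non-dominated subset, as a `dooit_trials` object.
#' @export
pareto_front <- function(trials) {
  trials <- Filter(function(t) !isTRUE(t$failed), unclass(trials))
  if (length(trials) == 0L) {
    stop_dooit("no successful trials to form a Pareto front", "dooit_validation_error")
  }
  mae <- vapply(trials, `[[`, 0, "cv_mae")
  svr <- vapply(trials, `[[`, 0, "sv_ratio")
  keep <- nondominated_mask(mae, svr)
  structure(trials[keep], class = "dooit_trials",
            objectives = cbind(cv_mae = mae[keep], sv_ratio = svr[keep]))
}

#' One-standard-error candidate selection on a Pareto front
#'
#' Identifies the most accurate front member, sets the threshold
#' `min CV MAE + its standard error`, and among front members within the
#' threshold returns the simplest one (lowest SV ratio). Ties break toward
#' lower CV MAE, then lower trial id.
#'
#' @param front a `dooit_trials` object (typically from [pareto_front()]).
#' @return The selected `dooit_trial`.
#' @export
select_1se <- function(front) {
  front <- Filter(function(t) !isTRUE(t$failed), unclass(front))
  if (length(front) == 0L) stop_dooit("empty front", "dooit_validation_error")
  mae <- vapply(front, `[[`, 0, "cv_mae")
  se <- vapply(front, `[[`, 0, "cv_mae_se")
  svr <- vapply(front, `[[`, 0, "sv_ratio")
  id <- vapply(front, function(t) as.integer(t$trial_id), 0L)
  best <- which.min(mae)
  threshold <- mae[best] + se[best]
  band <- which(mae <= threshold)
  ord <- band[order(svr[band], mae[band], id[band])]
  front[[ord[1L]]]
}

#' Permutation importance of a fitted model
#'
#' Importance of a feature is the mean increase in validation MAE when that
#' feature's column is randomly permuted, over `n_repeats` seeded
#' permutations.
#'
#' @param model an object with a `predict(model, newdata)` method, or a
#'   function `f(newdata)` returning predictions.
#' @param x validation feature matrix (>= 2 rows).
#' @param y validation target.
#' @param n_repeats number of permutations per feature (default 10).
#' @param seed permutation seed.
#' @return List with `mean` (named importance vector) and `repeats`
#'   (n_repeats x n_features matrix of per-repeat importances).
#' @export
permutation_importance <- function(model, x, y, n_repeats = 10L, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop_dooit("permutation importance needs >= 2 validation rows",
               "dooit_validation_error")
  }
  predf <- if (is.function(model)) model else function(nd) stats::predict(model, nd)
  base <- mean(abs(predf(x) - y))
  p <- ncol(x)
  rep_mat <- matrix(NA_real_, n_repeats, p,
                    dimnames = list(NULL, colnames(x)))
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      for (j in seq_len(p)) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(x)), j]
        rep_mat[r, j] <- mean(abs(predf(xp) - y)) - base
      }
    }
  })
  list(mean = colMeans(rep_mat), repeats = rep_mat, baseline_mae = base)
}

# Out-of-fold permutation importance at fixed hyperparameters: refit the
# candidate in each fold of the context and score permutations on that fold's
# held-out block, averaging fold-wise so no importance is measured on rows
# the model was fitted to.
oof_permutation_importance <- function(ctx, nu, cost, log10_gamma_scale,
                                       n_repeats = 10L, seed = 1L) {
  p <- ncol(ctx[[1L]]$xs)
  acc <- matrix(0, n_repeats, p, dimnames = list(NULL, colnames(ctx[[1L]]$xs)))
  for (f in ctx) {
    m <- fit_nusvr(f$xs, f$ys, nu, cost, f$gamma_base * 10^log10_gamma_scale)
    pi <- permutation_importance(m, f$xt, f$yt, n_repeats = n_repeats, seed = seed)
    acc <- acc + pi$repeats
  }
  acc <- acc / length(ctx)
  list(mean = colMeans(acc), repeats = acc)
}

# Refit a candidate on the whole training split and score the run's held-out
# test rows; returns the fitted model plus train/test metrics.
refit_candidate <- function(x_train, y_train, x_test, y_test,
                            features, nu, cost, log10_gamma_scale) {
  xtr <- as.matrix(x_train)[, features, drop = FALSE]
  std <- standardize(xtr)
  gb <- gamma_base(std$scaled)
  m <- fit_nusvr(std$scaled, y_train, nu, cost, gb * 10^log10_gamma_scale)
  pred_tr <- stats::predict(m, std$scaled)
  xte <- std_apply(std$transform, as.matrix(x_test)[, features, drop = FALSE])
  pred_te <- stats::predict(m, xte)
  r2 <- 1 - sum((y_test - pred_te)^2) / sum((y_test - mean(y_test))^2)
  list(model = m, transform = std$transform, gamma_base = gb,
       gamma = gb * 10^log10_gamma_scale,
       mae_train = mean(abs(pred_tr - y_train)),
       mae_test = mean(abs(pred_te - y_test)),
       r2_test = r2)
}
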