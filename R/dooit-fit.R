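# The user-facing fitting interface: one DOO-IT run as a classed model
# object, with the usual print/summary/plot/coef/predict/residuals methods.

#' Fit a DOO-IT model-selection run
#'
#' One complete run of Dual-Objective Optimization with ITerative feature
#' pruning: the data are split 80/20, and at each pruning level a full
#' dual-objective nuSVR hyperparameter search ([run_doo()]) is performed on
#' the training split, the Pareto front is extracted ([pareto_front()]), a
#' candidate is selected by the one-standard-error rule ([select_1se()]),
#' refit, ranked by out-of-fold permutation importance (10 repeats), and its
#' least important feature is eliminated. The cycle repeats down to
#' `min_features`, producing one candidate model per feature count.
#'
#' All randomness (split, folds, sampler, permutations) is derived from
#' `seed`; identical calls are fully reproducible, down to the JSON artifact
#' ([as_run_artifact()]).
#'
#' @param formula model formula, e.g. `log_x_exp ~ .`; the response is the
#'   (log) solubility target, the right-hand side the descriptor pool.
#'   Non-numeric columns matched by `.` are dropped with a message.
#' @param data data frame holding target and descriptors.
#' @param n_trials trials per optimization cycle (default 200).
#' @param k_folds cross-validation folds per trial (default 5).
#' @param min_features pruning floor (default 5).
#' @param test_fraction held-out fraction of rows (default 0.2).
#' @param sampler `"pareto-local"` (default) or `"random"`; see [run_doo()].
#' @param seed master seed of the run.
#' @param pool_name label for the descriptor pool (e.g. `"set1"`), carried
#'   into artifacts.
#' @param run_id optional run identifier (defaults to `"run-<seed>"`).
#' @return An object of class `dooit` with the pruning trace (one candidate
#'   per feature count), per-level trial tables, the train/test partition and
#'   the full configuration.
#' @seealso [dooit_stability()] for aggregating several runs into a champion,
#'   [gen_qspr_table()] for synthetic input tables.
#' @examples
#' tab <- gen_qspr_table(synthetic_spec(n_samples = 150, n_informative = 2,
#'                                      n_noise = 2, seed = 1))
#' fit <- dooit(log_x_exp ~ ., tab$table, n_trials = 15, min_features = 2, seed = 1)
#' summary(fit)
#' @export
dooit <- function(formula, data, n_trials = 200L, k_folds = 5L,
                  min_features = 5L, test_fraction = 0.2,
                  sampler = c("pareto-local", "random"), seed = 1L,
                  pool_name = "pool", run_id = NULL) {
  sampler <- match.arg(sampler)
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  target <- names(mf)[1L]
  y <- mf[[1L]]
  if (!is.numeric(y)) stop_dooit("target must be numeric", "dooit_validation_error")
  pred_names <- attr(stats::terms(mf), "term.labels")
  numeric_ok <- vapply(pred_names, function(nm) is.numeric(mf[[nm]]), TRUE)
  if (any(!numeric_ok)) {
    dooit_log("info", "dropping non-numeric predictor(s): ",
              paste(pred_names[!numeric_ok], collapse = ", "))
    pred_names <- pred_names[numeric_ok]
  }
  if (length(pred_names) <= min_features) {
    stop_dooit("feature pool must be larger than min_features", "dooit_validation_error")
  }
  x <- as.matrix(mf[pred_names])
  n <- nrow(x)
  split <- split_train_test(n, test_fraction, seed = seed)
  xtr <- x[split$train, , drop = FALSE]
  ytr <- y[split$train]
  xte <- x[split$test, , drop = FALSE]
  yte <- y[split$test]
  fold_seed <- seed + 1L

  feats <- pred_names
  trace <- list()
  level_trials <- list()
  repeat {
    p <- length(feats)
    dooit_log("info", sprintf("level %d: DOO over %d features, %d trials", p, p, n_trials))
    ctx <- fold_context(xtr[, feats, drop = FALSE], ytr, k_folds, fold_seed,
                        row_idx = split$train)
    trials <- run_doo(xtr, ytr, pool = feats, n_trials = n_trials,
                      sampler = sampler, sampler_seed = seed + 1000L + p,
                      k_folds = k_folds, fold_seed = fold_seed, context = ctx)
    pick <- select_1se(pareto_front(trials))
    refit <- refit_candidate(xtr, ytr, xte, yte, feats,
                             pick$nu, pick$cost, pick$log10_gamma_scale)
    imp <- oof_permutation_importance(ctx, pick$nu, pick$cost,
                                      pick$log10_gamma_scale,
                                      n_repeats = 10L, seed = seed + 2000L + p)
    eliminated <- if (p > min_features) names(which.min(imp$mean)) else NA_character_
    dooit_log("info", sprintf(
      "level %d: picked trial %d (nu=%.3f, C=%.3g, scale=%.2f) cv_mae=%.4g; %s",
      p, pick$trial_id, pick$nu, pick$cost, pick$log10_gamma_scale, pick$cv_mae,
      if (is.na(eliminated)) "floor reached" else paste0("eliminating ", eliminated)))
    trace[[length(trace) + 1L]] <- structure(
      list(n_features = p, feature_names = feats,
           nu = pick$nu, cost = pick$cost,
           log10_gamma_scale = pick$log10_gamma_scale,
           trial_id = pick$trial_id,
           cv_mae = pick$cv_mae, cv_mae_se = pick$cv_mae_se,
           sv_ratio = pick$sv_ratio,
           importance = imp$mean, importance_repeats = imp$repeats,
           mae_train = refit$mae_train, mae_test = refit$mae_test,
           r2_test = refit$r2_test,
           eliminated = eliminated),
      class = "dooit_candidate")
    level_trials[[as.character(p)]] <- trials_table(trials)
    if (p == min_features) break
    feats <- setdiff(feats, eliminated)
  }

  structure(
    list(call = cl, target = target, pool = pred_names,
         config = list(n_trials = as.integer(n_trials),
                       k_folds = as.integer(k_folds),
                       min_features = as.integer(min_features),
                       test_fraction = test_fraction, sampler = sampler,
                       seed = as.integer(seed), pool_name = pool_name),
         run_id = run_id %||% sprintf("run-%d", as.integer(seed)),
         train_idx = split$train, test_idx = split$test,
         x = x, y = y, trace = trace, level_trials = level_trials),
    class = "dooit"
  )
}

trials_table <- function(trials) {
  do.call(rbind, lapply(unclass(trials), function(t) {
    data.frame(trial_id = t$trial_id, nu = t$nu, cost = t$cost,
               log10_gamma_scale = t$log10_gamma_scale,
               cv_mae = if (t$failed) NA_real_ else t$cv_mae,
               cv_mae_se = if (t$failed) NA_real_ else t$cv_mae_se,
               sv_ratio = if (t$failed) NA_real_ else t$sv_ratio,
               failed = t$failed)
  }))
}

#' Run-level candidate choice (parsimony within one standard error)
#'
#' Among a run's trace candidates, finds the minimum held-out test MAE and
#' returns the candidate with the smallest feature count whose test MAE lies
#' within one standard error (the fold-level SE of the best candidate) of
#' that minimum: the count this run "votes" for in the cross-run stability
#' analysis.
#'
#' @param fit a `dooit` object (or its trace list).
#' @return The chosen `dooit_candidate`.
#' @export
run_level_choice <- function(fit) {
  trace <- if (inherits(fit, "dooit")) fit$trace else fit
  mae <- vapply(trace, `[[`, 0, "mae_test")
  counts <- vapply(trace, `[[`, 0L, "n_features")
  best <- which.min(mae)
  threshold <- mae[best] + trace[[best]]$cv_mae_se
  admissible <- which(mae <= threshold)
  trace[[admissible[which.min(counts[admissible])]]]
}

#' @export
print.dooit <- function(x, ...) {
  ch <- run_level_choice(x)
  cat(sprintf("DOO-IT run '%s' (seed %d, sampler %s)\n", x$run_id,
              x$config$seed, x$config$sampler))
  cat(sprintf("  pool: %d features ('%s'); pruned to %d; %d trials/level\n",
              length(x$pool), x$config$pool_name, x$config$min_features,
              x$config$n_trials))
  cat(sprintf("  run-level choice: %d features, test MAE %.4g, R2 %.3f\n",
              ch$n_features, ch$mae_test, ch$r2_test))
  invisible(x)
}

#' @export
summary.dooit <- function(object, ...) {
  tr <- object$trace
  tab <- data.frame(
    n_features = vapply(tr, `[[`, 0L, "n_features"),
    nu = vapply(tr, `[[`, 0, "nu"),
    cost = vapply(tr, `[[`, 0, "cost"),
    log10_gamma_scale = vapply(tr, `[[`, 0, "log10_gamma_scale"),
    cv_mae = vapply(tr, `[[`, 0, "cv_mae"),
    sv_ratio = vapply(tr, `[[`, 0, "sv_ratio"),
    mae_train = vapply(tr, `[[`, 0, "mae_train"),
    mae_test = vapply(tr, `[[`, 0, "mae_test"),
    r2_test = vapply(tr, `[[`, 0, "r2_test"),
    eliminated = vapply(tr, `[[`, "", "eliminated")
  )
  choice <- run_level_choice(object)
  structure(list(table = tab, choice = choice, run_id = object$run_id),
            class = "summary.dooit")
}

#' @export
print.summary.dooit <- function(x, ...) {
  cat(sprintf("DOO-IT pruning trace '%s':\n", x$run_id))
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("run-level choice: %d features (%s)\n", x$choice$n_features,
              paste(x$choice$feature_names, collapse = ", ")))
  invisible(x)
}

#' @export
plot.dooit <- function(x, ...) {
  tr <- x$trace
  counts <- vapply(tr, `[[`, 0L, "n_features")
  mtr <- vapply(tr, `[[`, 0, "mae_train")
  mte <- vapply(tr, `[[`, 0, "mae_test")
  ylim <- range(c(mtr, mte))
  graphics::plot(counts, mte, type = "b", pch = 19, ylim = ylim,
                 xlab = "number of descriptors", ylab = "MAE (log x units)",
                 main = sprintf("DOO-IT pruning trace '%s'", x$run_id), ...)
  graphics::lines(counts, mtr, type = "b", pch = 1, lty = 2)
  ch <- run_level_choice(x)
  graphics::points(ch$n_features, ch$mae_test, pch = 17, cex = 1.6,
                   col = "red")
  graphics::legend("topright", legend = c("test", "train", "chosen"),
                   pch = c(19, 1, 17), lty = c(1, 2, NA),
                   col = c("black", "black", "red"), bty = "n")
  invisible(x)
}

#' @export
coef.dooit <- function(object, n_features = NULL, ...) {
  cand <- candidate_at(object, n_features)
  c(nu = cand$nu, cost = cand$cost, log10_gamma_scale = cand$log10_gamma_scale)
}

candidate_at <- function(fit, n_features = NULL) {
  if (is.null(n_features)) return(run_level_choice(fit))
  counts <- vapply(fit$trace, `[[`, 0L, "n_features")
  idx <- match(n_features, counts)
  if (is.na(idx)) {
    stop_dooit(sprintf("no candidate with %d features in the trace", n_features),
               "dooit_validation_error")
  }
  fit$trace[[idx]]
}

#' Materialize one candidate of a run as a standalone fitted model
#'
#' Refits the candidate (by default the run-level choice) on the run's
#' training split with its frozen standardization and gamma anchor.
#'
#' @param fit a `dooit` object.
#' @param n_features which trace level to use (default: the run-level
#'   choice).
#' @return An object of class `dooit_model`.
#' @export
dooit_model <- function(fit, n_features = NULL) {
  cand <- candidate_at(fit, n_features)
  refit <- refit_candidate(fit$x[fit$train_idx, , drop = FALSE],
                           fit$y[fit$train_idx],
                           fit$x[fit$test_idx, , drop = FALSE],
                           fit$y[fit$test_idx],
                           cand$feature_names, cand$nu, cand$cost,
                           cand$log10_gamma_scale)
  structure(
    list(features = cand$feature_names, target = fit$target,
         nu = cand$nu, cost = cand$cost,
         log10_gamma_scale = cand$log10_gamma_scale,
         gamma = refit$gamma, transform = refit$transform,
         svm = refit$model,
         mae_train = refit$mae_train, mae_test = refit$mae_test,
         r2_test = refit$r2_test,
         sv_ratio = refit$model$tot.nSV / length(fit$train_idx),
         importance = cand$importance,
         run_id = fit$run_id, n_features = cand$n_features),
    class = "dooit_model"
  )
}

#' @export
print.dooit_model <- function(x, ...) {
  cat(sprintf("nuSVR model (%d descriptors, run '%s')\n", x$n_features, x$run_id))
  cat(sprintf("  nu = %.4f, C = %.4g, log10 gamma scale = %.3f (gamma = %.4g)\n",
              x$nu, x$cost, x$log10_gamma_scale, x$gamma))
  cat(sprintf("  train MAE %.4g | test MAE %.4g | test R2 %.4f | SV ratio %.3f\n",
              x$mae_train, x$mae_test, x$r2_test, x$sv_ratio))
  cat("  descriptors:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.dooit_model <- function(object, newdata, ...) {
  nd <- if (is.data.frame(newdata)) as.matrix(newdata[object$features]) else {
    as.matrix(newdata)[, object$features, drop = FALSE]
  }
  as.numeric(stats::predict(object$svm, std_apply(object$transform, nd)))
}

#' @export
predict.dooit <- function(object, newdata = NULL, n_features = NULL, ...) {
  mod <- dooit_model(object, n_features)
  if (is.null(newdata)) {
    newdata <- as.data.frame(object$x)
  }
  predict(mod, newdata)
}

#' @export
residuals.dooit <- function(object, n_features = NULL, ...) {
  object$y - predict(object, n_features = n_features)
}

#' Export a run as a reproducible artifact
#'
#' Collects seeds, configuration, per-level trial tables, the pruning trace
#' and the train/test partition into a [run_artifact()] suitable for
#' [write_run_artifact()]. Two runs with identical configuration produce
#' byte-identical artifact files.
#'
#' @param fit a `dooit` object.
#' @return A `run_artifact`.
#' @export
as_run_artifact <- function(fit) {
  stopifnot(inherits(fit, "dooit"))
  trace <- lapply(fit$trace, function(cand) {
    list(n_features = cand$n_features, feature_names = cand$feature_names,
         nu = cand$nu, cost = cand$cost,
         log10_gamma_scale = cand$log10_gamma_scale,
         trial_id = cand$trial_id, cv_mae = cand$cv_mae,
         cv_mae_se = cand$cv_mae_se, sv_ratio = cand$sv_ratio,
         importance = as.list(cand$importance),
         mae_train = cand$mae_train, mae_test = cand$mae_test,
         r2_test = cand$r2_test, eliminated = cand$eliminated)
  })
  run_artifact(fit$run_id, fit$config$seed, fit$config$pool_name,
               fit$config, fit$level_trials, trace,
               fit$train_idx, fit$test_idx)
}
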