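# Low-level machinery for one DOO trial: train/test splitting, frozen
# standardization, the median-distance gamma anchor, and cross-validated
# nuSVR evaluation. Standardization and the gamma anchor are always computed
# from fold-training rows only; fold contexts record the row provenance so
# leakage can be audited.

#' Random 80/20 train/test partition
#'
#' @param n number of rows (>= 10).
#' @param test_fraction fraction held out (default 0.2); the test set has
#'   `round(test_fraction * n)` rows.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return List with sorted integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(n, test_fraction = 0.2, seed = 1L) {
  if (n < 10L) stop_dooit("need at least 10 rows to split", "dooit_validation_error")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_dooit("test_fraction must lie in (0, 1)", "dooit_validation_error")
  }
  n_test <- round(test_fraction * n)
  test <- with_seed(seed, sort(sample.int(n, n_test)))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Standardize a training matrix (zero mean, unit variance)
#'
#' Centers and scales every column using the population variance (divide by
#' n), matching the usual machine-learning scaler convention. The returned
#' transform is frozen: apply it to later matrices (e.g. a test set) with
#' [std_apply()]; it is never refitted.
#'
#' @param x numeric matrix (training rows only).
#' @return List with `transform` (center/scale/column names) and `scaled`
#'   (the standardized training matrix).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2L, center)^2))
  zero <- which(scale <= 0 | !is.finite(scale))
  if (length(zero)) {
    nm <- colnames(x)[zero] %||% as.character(zero)
    stop_dooit(sprintf("zero-variance column(s): %s", paste(nm, collapse = ", ")),
               "dooit_validation_error")
  }
  transform <- list(center = center, scale = scale, columns = colnames(x))
  list(transform = transform, scaled = std_apply(transform, x))
}

#' Apply a frozen standardization transform
#'
#' @param transform the `transform` element returned by [standardize()].
#' @param x matrix with the same columns as the training matrix.
#' @return Standardized matrix.
#' @export
std_apply <- function(transform, x) {
  x <- as.matrix(x)
  if (!is.null(transform$columns) && !is.null(colnames(x))) {
    x <- x[, transform$columns, drop = FALSE]
  }
  sweep(sweep(x, 2L, transform$center), 2L, transform$scale, "/")
}

#' Median-distance RBF gamma anchor
#'
#' Heuristic baseline kernel width determined from the training rows:
#' `1 / median(||x_i - x_j||^2)` over all pairs i < j. The optimizer then
#' searches a logarithmic scaling factor around this anchor, so an effective
#' gamma of `gamma_base * 10^scale` with scale near 0 sits at the natural
#' scale of the data.
#'
#' @param x numeric matrix of training rows (>= 2 distinct rows).
#' @return Positive scalar.
#' @export
gamma_base <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_dooit("gamma_base needs >= 2 rows", "dooit_validation_error")
  med <- stats::median(stats::dist(x)^2)
  if (!is.finite(med) || med <= 0) {
    stop_dooit("median pairwise distance is zero (all rows identical)",
               "dooit_degenerate_error")
  }
  1 / med
}

# libsvm KKT tolerance, scaled with C: the absolute default (1e-3) is
# needlessly strict at the large-C end of the search box, where dual
# gradients scale with C and iteration counts blow up with no measurable
# effect on held-out error.
svr_tolerance <- function(cost) max(0.01, 1e-4 * cost)

fit_nusvr <- function(x, y, nu, cost, gamma) {
  e1071::svm(x, y, type = "nu-regression", kernel = "radial",
             nu = nu, cost = cost, gamma = gamma,
             scale = FALSE, fitted = FALSE, tolerance = svr_tolerance(cost))
}

#' Build a k-fold evaluation context
#'
#' Partitions rows into k folds and, per fold, fits the standardization
#' transform and gamma anchor on the fold-training rows only, keeping the
#' global row indices used so the absence of leakage is auditable.
#'
#' @param x numeric feature matrix.
#' @param y numeric target.
#' @param k_folds number of folds (default 5).
#' @param fold_seed seed for the fold assignment.
#' @param row_idx optional global row indices of `x` (for provenance; defaults
#'   to `1:nrow(x)`).
#' @return List of per-fold contexts (class `fold_context`); each fold holds
#'   standardized train/test blocks, the frozen transform, `gamma_base`, and
#'   the global `train_rows` / `test_rows` it was built from.
#' @export
fold_context <- function(x, y, k_folds = 5L, fold_seed = 1L,
                         row_idx = seq_len(nrow(x))) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L * k_folds) {
    stop_dooit("too few rows for the requested number of folds", "dooit_validation_error")
  }
  perm <- with_seed(fold_seed, sample.int(n))
  assignment <- rep(seq_len(k_folds), length.out = n)[order(perm)]
  folds <- lapply(seq_len(k_folds), function(f) {
    te <- which(assignment == f)
    tr <- which(assignment != f)
    std <- standardize(x[tr, , drop = FALSE])
    list(train = tr, test = te,
         train_rows = row_idx[tr], test_rows = row_idx[te],
         transform = std$transform,
         xs = std$scaled,
         ys = y[tr],
         xt = std_apply(std$transform, x[te, , drop = FALSE]),
         yt = y[te],
         gamma_base = gamma_base(std$scaled))
  })
  structure(folds, class = "fold_context", n = n, k_folds = k_folds,
            fold_seed = fold_seed)
}

#' Evaluate one nuSVR trial by k-fold cross-validation
#'
#' Per fold: standardize on the fold-training rows, anchor the kernel width
#' to that fold's [gamma_base()], fit a nuSVR with RBF kernel, and record the
#' fold MAE and support-vector count. The trial's accuracy objective is the
#' mean fold MAE; its complexity objective is the mean support-vector ratio
#' (support vectors / fold-training rows).
#'
#' @param x,y training data (the 80 percent split; never the held-out test
#'   rows).
#' @param nu nuSVR nu parameter in (0, 1); lower-bounds the support-vector
#'   fraction.
#' @param cost regularization parameter C, > 0.
#' @param log10_gamma_scale log10 scaling factor applied to the gamma anchor.
#' @param k_folds,fold_seed cross-validation controls.
#' @param context optional prebuilt [fold_context()] (reused across trials of
#'   one optimization cycle, since it does not depend on the hyperparameters).
#' @param trial_id integer identifier carried into the result.
#' @return An object of class `dooit_trial`: `nu`, `cost`,
#'   `log10_gamma_scale`, `gamma` (mean effective width), `cv_mae`,
#'   `cv_mae_se` (sd of fold MAEs / sqrt(k)), `sv_ratio`, per-fold records,
#'   and `failed` (with `cause`) if the fit failed.
#' @export
evaluate_trial <- function(x, y, nu, cost, log10_gamma_scale,
                           k_folds = 5L, fold_seed = 1L, context = NULL,
                           trial_id = NA_integer_) {
  if (nu <= 0 || nu >= 1) stop_dooit("nu must lie in (0, 1)", "dooit_validation_error")
  if (cost <= 0) stop_dooit("cost must be > 0", "dooit_validation_error")
  ctx <- context %||% fold_context(x, y, k_folds, fold_seed)
  k <- length(ctx)
  fold_mae <- fold_svr <- fold_gamma <- fold_nsv <- numeric(k)
  res <- tryCatch({
    for (i in seq_len(k)) {
      f <- ctx[[i]]
      g <- f$gamma_base * 10^log10_gamma_scale
      m <- fit_nusvr(f$xs, f$ys, nu, cost, g)
      pred <- stats::predict(m, f$xt)
      fold_mae[i] <- mean(abs(pred - f$yt))
      fold_nsv[i] <- m$tot.nSV
      fold_svr[i] <- m$tot.nSV / nrow(f$xs)
      fold_gamma[i] <- g
    }
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(res)) {
    dooit_log("debug", "trial ", trial_id, " failed: ", res)
    return(structure(list(trial_id = trial_id, nu = nu, cost = cost,
                          log10_gamma_scale = log10_gamma_scale,
                          failed = TRUE, cause = res),
                     class = "dooit_trial"))
  }
  structure(
    list(trial_id = trial_id, nu = nu, cost = cost,
         log10_gamma_scale = log10_gamma_scale,
         gamma = mean(fold_gamma),
         cv_mae = mean(fold_mae),
         cv_mae_se = stats::sd(fold_mae) / sqrt(k),
         sv_ratio = mean(fold_svr),
         folds = list(mae = fold_mae, sv_ratio = fold_svr,
                      n_sv = fold_nsv, gamma = fold_gamma),
         failed = FALSE),
    class = "dooit_trial"
  )
}

#' Leave-one-compound-out splits
#'
#' One train/test split per unique solute, with all rows of that solute
#' reserved for testing; the stringent, extrapolative counterpart to random
#' splitting.
#'
#' @param solute_id character/factor vector of per-row solute identifiers
#'   (>= 2 distinct solutes).
#' @return Named list (one element per solute) of lists with integer `train`
#'   and `test` indices.
#' @export
loco_splits <- function(solute_id) {
  ids <- unique(as.character(solute_id))
  if (length(ids) < 2L) {
    stop_dooit("LOCO needs at least 2 distinct solutes", "dooit_validation_error")
  }
  out <- lapply(ids, function(id) {
    te <- which(as.character(solute_id) == id)
    list(train = setdiff(seq_along(solute_id), te), test = te)
  })
  stats::setNames(out, ids)
}
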