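test_that("train/test splitting is a seeded partition with the right sizes", {
  sp <- split_train_test(100, 0.2, seed = 3)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, split_train_test(100, 0.2, seed = 3))
  expect_false(identical(sp$test, split_train_test(100, 0.2, seed = 4)$test))
  expect_error(split_train_test(5), class = "dooit_validation_error")
})

test_that("standardization uses population variance and freezes its transform", {
  s <- standardize(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(s$scaled), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(mean(s$scaled), 0, tolerance = 1e-12)
  expect_equal(mean(s$scaled^2), 1, tolerance = 1e-12)

  # idempotence: an already standardized column passes through unchanged
  s2 <- standardize(s$scaled)
  expect_equal(s2$scaled, s$scaled, tolerance = 1e-12)

  # the frozen transform is applied verbatim to new data
  m <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  s3 <- standardize(m)
  new <- matrix(c(100, -100), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(as.numeric(std_apply(s3$transform, new)),
               unname((c(100, -100) - s3$transform$center) / s3$transform$scale))

  mm <- cbind(m, const = 5)
  expect_error(standardize(mm), "const", class = "dooit_validation_error")
})

test_that("the gamma anchor is the inverse median pairwise squared distance", {
  corners <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(gamma_base(corners), 1)  # distances^2 {1,1,1,1,2,2}, median 1
  set.seed(1)
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(gamma_base(2 * m), gamma_base(m) / 4, tolerance = 1e-12)
  expect_error(gamma_base(rbind(c(1, 2), c(1, 2))), class = "dooit_degenerate_error")
})

test_that("trial evaluation is deterministic and honors the nu property", {
  set.seed(42)
  x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(200, 0, 0.05)

  t1 <- evaluate_trial(x, y, nu = 0.3, cost = 10, log10_gamma_scale = 0,
                       fold_seed = 7, trial_id = 1L)
  t2 <- evaluate_trial(x, y, nu = 0.3, cost = 10, log10_gamma_scale = 0,
                       fold_seed = 7, trial_id = 1L)
  expect_identical(t1, t2)
  expect_gt(t1$sv_ratio, 0)
  expect_lte(t1$sv_ratio, 1)
  expect_equal(t1$cv_mae_se, sd(t1$folds$mae) / sqrt(5))

  # nu lower-bounds the support-vector fraction on every fold
  t_hi <- evaluate_trial(x, y, nu = 0.8, cost = 10, log10_gamma_scale = 0,
                         fold_seed = 7)
  expect_true(all(t_hi$folds$sv_ratio >= 0.75))

  # a noise-free linear target with generous C is fit nearly perfectly
  y_lin <- x[, 1]
  t_lin <- evaluate_trial(x, y_lin, nu = 0.7, cost = 100, log10_gamma_scale = -1,
                          fold_seed = 7)
  expect_lt(t_lin$cv_mae, 0.05)
})

test_that("fold contexts never see held-out rows", {
  set.seed(5)
  x <- matrix(rnorm(120 * 4), 120, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rowSums(x[, 1:2])
  ctx <- fold_context(x, y, k_folds = 5, fold_seed = 11)
  for (f in ctx) {
    expect_length(intersect(f$train_rows, f$test_rows), 0L)
    expect_setequal(c(f$train_rows, f$test_rows), 1:120)
    # scaler and anchor recomputed from the recorded training rows only
    redo <- standardize(x[f$train_rows, , drop = FALSE])
    expect_equal(f$transform$center, redo$transform$center, tolerance = 1e-14)
    expect_equal(f$gamma_base, gamma_base(redo$scaled), tolerance = 1e-14)
  }
  # perturbing held-out rows leaves every fold's scaler and anchor untouched
  for (f in ctx) {
    x2 <- x
    x2[f$test_rows, ] <- x2[f$test_rows, ] + 100
    ctx2 <- fold_context(x2, y, k_folds = 5, fold_seed = 11)
    f2 <- ctx2[[which(vapply(ctx2, function(g) identical(g$test, f$test), TRUE))]]
    expect_equal(f2$transform$center, f$transform$center, tolerance = 1e-14)
    expect_equal(f2$transform$scale, f$transform$scale, tolerance = 1e-14)
    expect_equal(f2$gamma_base, f$gamma_base, tolerance = 1e-14)
  }
})

test_that("run_doo produces the requested seeded trials with finite objectives", {
  set.seed(9)
  x <- matrix(rnorm(100 * 4), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- x[, 1] - x[, 2] + rnorm(100, 0, 0.05)
  tr <- run_doo(x, y, n_trials = 10, sampler_seed = 1, fold_seed = 1)
  expect_length(tr, 10L)
  ok <- !vapply(tr, `[[`, TRUE, "failed")
  expect_true(all(vapply(tr[ok], function(t) is.finite(t$cv_mae), TRUE)))
  expect_true(all(vapply(tr, function(t) isTRUE(t$failed) || is.finite(t$sv_ratio), TRUE)))

  # running-minimum monotonicity under a shared random stream prefix
  long <- run_doo(x, y, n_trials = 100, sampler = "random", sampler_seed = 3,
                  fold_seed = 1)
  short <- run_doo(x, y, n_trials = 25, sampler = "random", sampler_seed = 3,
                   fold_seed = 1)
  best <- function(tt) min(vapply(Filter(function(t) !t$failed, unclass(tt)),
                                  `[[`, 0, "cv_mae"))
  expect_lte(best(long), best(short))
})

test_that("the Pareto front equals the all-pairs domination oracle", {
  single <- fake_trials(0.1, 0.5)
  expect_length(pareto_front(single), 1L)

  two <- fake_trials(c(0.1, 0.2), c(0.2, 0.3))
  fr <- pareto_front(two)
  expect_length(fr, 1L)
  expect_equal(fr[[1]]$trial_id, 1L)

  for (case in 1:20) {
    set.seed(case)
    n <- sample(1:300, 1)
    mae <- round(runif(n, 0.05, 0.3), sample(2:4, 1))  # rounding forces ties
    svr <- round(runif(n, 0.1, 1), 2)
    fr <- pareto_front(fake_trials(mae, svr))
    ids <- sort(vapply(unclass(fr), `[[`, 0L, "trial_id"))
    expect_identical(ids, which(oracle_pareto_mask(mae, svr)))
  }
})

test_that("the 1-SE rule picks the simplest statistically equivalent model", {
  # worked example: threshold = 0.070 + 0.004 admits both; lower SV wins
  fr <- fake_trials(c(0.070, 0.0735), c(0.50, 0.30), se = c(0.004, 0.004))
  expect_equal(select_1se(fr)$trial_id, 2L)

  expect_equal(select_1se(fake_trials(0.1, 0.9))$trial_id, 1L)

  # ties on SV ratio inside the band: lower MAE wins
  fr <- fake_trials(c(0.070, 0.071), c(0.4, 0.4), se = c(0.005, 0.005))
  expect_equal(select_1se(fr)$trial_id, 1L)

  # the pick always satisfies its own threshold and minimal-SV condition
  for (case in 1:20) {
    set.seed(case + 100)
    n <- sample(2:50, 1)
    fr <- pareto_front(fake_trials(runif(n, 0.05, 0.2), runif(n, 0.1, 1),
                                   se = runif(n, 0.001, 0.01)))
    pick <- select_1se(fr)
    mae <- vapply(unclass(fr), `[[`, 0, "cv_mae")
    se <- vapply(unclass(fr), `[[`, 0, "cv_mae_se")
    svr <- vapply(unclass(fr), `[[`, 0, "sv_ratio")
    thr <- min(mae) + se[which.min(mae)]
    expect_lte(pick$cv_mae, thr)
    expect_lte(pick$sv_ratio, min(svr[mae <= thr]))
  }
})

test_that("permutation importance flags planted features and not noise", {
  # a model that ignores its inputs has zero importance everywhere
  set.seed(1)
  xv <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  yv <- rnorm(20)
  pi0 <- permutation_importance(function(nd) rep(1, nrow(nd)), xv, yv,
                                n_repeats = 10, seed = 2)
  expect_equal(unname(pi0$mean), rep(0, 3))
  expect_equal(dim(pi0$repeats), c(10L, 3L))

  # target equals f1 exactly; a perfect model leans only on f1
  y_exact <- xv[, 1]
  pi1 <- permutation_importance(function(nd) nd[, 1], xv, y_exact,
                                n_repeats = 10, seed = 2)
  expect_gt(pi1$mean["f1"], 10 * abs(pi1$mean["f2"]))
  expect_equal(unname(pi1$mean["f3"]), 0)

  expect_error(permutation_importance(function(nd) rep(1, nrow(nd)),
                                      xv[1, , drop = FALSE], yv[1]),
               class = "dooit_validation_error")
})

test_that("LOCO splits reserve exactly one solute per test fold", {
  ids <- rep(sprintf("S%02d", 1:11), times = 3)
  sp <- loco_splits(ids)
  expect_length(sp, 11L)
  all_test <- unname(unlist(lapply(sp, `[[`, "test")))
  expect_identical(sort(all_test), seq_along(ids))  # each row tested once
  for (s in names(sp)) {
    expect_true(all(ids[sp[[s]]$test] == s))
    expect_false(s %in% ids[sp[[s]]$train])
  }
  expect_error(loco_splits(rep("A", 5)), class = "dooit_validation_error")
})
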