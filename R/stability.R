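# Cross-run aggregation: architecture choice by frequency + one-standard-
# error stability, composite scoring, and champion selection.

#' Composite deployment score
#'
#' Balances predictive accuracy (weight 0.5, via test MAE), explanatory power
#' (0.3, via test R2) and generalization (0.2, via the train-test MAE gap).
#' Each component is min-max normalized over the candidate pool so the
#' weights are comparable across unit-bearing quantities; when a component is
#' constant across the pool it contributes a neutral 0.5 of its weight to
#' every candidate.
#'
#' @param mae_test,r2_test,gap numeric vectors over the candidate pool (gap =
#'   `|mae_train - mae_test|`).
#' @param weights length-3 weights for (accuracy, explanatory power,
#'   generalization); must sum to 1.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
composite_score <- function(mae_test, r2_test, gap, weights = c(0.5, 0.3, 0.2)) {
  if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-8) {
    stop_dooit("weights must be three numbers summing to 1", "dooit_validation_error")
  }
  n <- length(mae_test)
  if (length(r2_test) != n || length(gap) != n) {
    stop_dooit("component vectors must have equal length", "dooit_validation_error")
  }
  norm01 <- function(v, higher_better) {
    if (!higher_better) v <- -v
    rng <- range(v)
    if (diff(rng) <= 0) return(rep(0.5, length(v)))
    (v - rng[1]) / diff(rng)
  }
  weights[1] * norm01(mae_test, FALSE) +
    weights[2] * norm01(r2_test, TRUE) +
    weights[3] * norm01(abs(gap), FALSE)
}

#' Aggregate independent DOO-IT runs into a stability report and champion
#'
#' Each run votes for a feature count via [run_level_choice()] (smallest
#' count within one standard error of the run's best test MAE). A count is
#' admissible as the final architecture if (i) its vote frequency is at least
#' `freq_threshold` and (ii) its mean test MAE lies within one cross-run
#' standard error of the global minimum mean (SE = sd of the best count's
#' test MAEs / sqrt(number of its votes)). The architecture is the admissible
#' count with the best mean test MAE (ties toward the smaller count). The
#' champion is then the candidate at that architecture with the highest
#' [composite_score()]; ties break toward higher summed per-descriptor
#' selection frequency, then lower test MAE.
#'
#' @param runs list of at least two `dooit` objects (independent seeds).
#' @param freq_threshold minimum vote frequency per count (default 0.30).
#' @param weights composite-score weights (default `c(0.5, 0.3, 0.2)`).
#' @return An object of class `dooit_stability` with the per-count report,
#'   admissible counts, chosen architecture, per-descriptor frequencies, and
#'   the champion as a [dooit_model()].
#' @export
dooit_stability <- function(runs, freq_threshold = 0.30,
                            weights = c(0.5, 0.3, 0.2)) {
  if (!is.list(runs) || length(runs) < 2L) {
    stop_dooit("need >= 2 runs to form cross-run statistics", "dooit_validation_error")
  }
  choices <- lapply(runs, run_level_choice)
  agg <- aggregate_choices(choices, vapply(runs, `[[`, "", "run_id"),
                           freq_threshold, weights)
  champ_run <- runs[[agg$champion_run_index]]
  champion <- dooit_model(champ_run, agg$architecture)
  champion$composite_score <- agg$champion_score

  structure(
    c(agg[c("report", "admissible", "architecture", "descriptor_freq",
            "scores")],
      list(champion = champion, freq_threshold = freq_threshold,
           weights = weights, n_runs = length(runs))),
    class = "dooit_stability"
  )
}

# Core cross-run aggregation over run-level choice records; shared by
# dooit_stability() (on fitted runs) and the CLI (on stored artifacts).
aggregate_choices <- function(choices, run_ids, freq_threshold = 0.30,
                              weights = c(0.5, 0.3, 0.2)) {
  counts <- vapply(choices, `[[`, 0L, "n_features")
  mae <- vapply(choices, `[[`, 0, "mae_test")
  mae_tr <- vapply(choices, `[[`, 0, "mae_train")

  uc <- sort(unique(counts))
  report <- data.frame(
    n_features = uc,
    frequency = vapply(uc, function(cn) mean(counts == cn), 0),
    mean_mae_test = vapply(uc, function(cn) mean(mae[counts == cn]), 0),
    sd_mae_test = vapply(uc, function(cn) {
      v <- mae[counts == cn]; if (length(v) > 1L) stats::sd(v) else 0
    }, 0),
    mean_mae_train = vapply(uc, function(cn) mean(mae_tr[counts == cn]), 0),
    n_votes = vapply(uc, function(cn) sum(counts == cn), 0L)
  )
  gbest <- which.min(report$mean_mae_test)
  # cross-run SE over all run-level choices; a per-count SE would collapse
  # to zero whenever the best count holds a single vote
  g_se <- stats::sd(mae) / sqrt(length(mae))
  admissible <- report$n_features[
    report$frequency >= freq_threshold &
      report$mean_mae_test <= report$mean_mae_test[gbest] + g_se]
  if (length(admissible) == 0L) {
    stop_dooit(sprintf(
      "no feature count passes the stability filter (frequency >= %.2f within 1 SE); consider relaxing freq_threshold",
      freq_threshold), "dooit_validation_error")
  }
  adm_rows <- report[report$n_features %in% admissible, ]
  architecture <- adm_rows$n_features[order(adm_rows$mean_mae_test,
                                            adm_rows$n_features)][1L]

  at_arch <- which(counts == architecture)
  feat_lists <- lapply(choices[at_arch], `[[`, "feature_names")
  sel <- select_champion(mae[at_arch],
                         vapply(choices[at_arch], `[[`, 0, "r2_test"),
                         mae_tr[at_arch], feat_lists, weights)
  list(report = report, admissible = admissible, architecture = architecture,
       descriptor_freq = sel$descriptor_freq,
       scores = data.frame(run = run_ids[at_arch], mae_test = mae[at_arch],
                           r2_test = vapply(choices[at_arch], `[[`, 0, "r2_test"),
                           gap = abs(mae_tr[at_arch] - mae[at_arch]),
                           composite = sel$scores),
       champion_run_index = at_arch[sel$index],
       champion_score = sel$scores[sel$index])
}

#' Champion selection among candidates at a fixed architecture
#'
#' Standalone version of the final selection step of [dooit_stability()]:
#' scores a pool of candidate summaries and applies the tie-breaking rules.
#'
#' @param mae_test,r2_test,mae_train metric vectors over the pool.
#' @param feature_lists list of feature-name vectors, one per candidate.
#' @param weights composite weights.
#' @return List with `index` of the champion, `scores`, and the
#'   `descriptor_freq` table.
#' @export
select_champion <- function(mae_test, r2_test, mae_train, feature_lists,
                            weights = c(0.5, 0.3, 0.2)) {
  all_feats <- sort(unique(unlist(feature_lists)))
  descriptor_freq <- vapply(all_feats, function(f) {
    mean(vapply(feature_lists, function(fl) f %in% fl, TRUE))
  }, 0)
  scores <- composite_score(mae_test, r2_test, abs(mae_train - mae_test), weights)
  freq_sum <- vapply(feature_lists, function(fl) sum(descriptor_freq[fl]), 0)
  idx <- order(-scores, -freq_sum, mae_test)[1L]
  list(index = idx, scores = scores, descriptor_freq = descriptor_freq)
}

#' @export
print.dooit_stability <- function(x, ...) {
  cat(sprintf("DOO-IT stability analysis over %d runs\n", x$n_runs))
  print(x$report, digits = 4, row.names = FALSE)
  cat(sprintf("admissible counts (freq >= %.0f%%, within 1 SE): %s\n",
              100 * x$freq_threshold, paste(x$admissible, collapse = ", ")))
  cat(sprintf("chosen architecture: %d descriptors\n", x$architecture))
  cat("champion:\n")
  print(x$champion)
  invisible(x)
}

#' @export
summary.dooit_stability <- function(object, ...) {
  cat(sprintf("Champion descriptor stability (architecture = %d):\n",
              object$architecture))
  df <- sort(object$descriptor_freq, decreasing = TRUE)
  print(data.frame(descriptor = names(df), frequency = unname(df)),
        row.names = FALSE)
  invisible(object)
}

#' @export
plot.dooit_stability <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(x$report$frequency, names.arg = x$report$n_features,
                    xlab = "number of descriptors", ylab = "vote frequency",
                    main = "architecture votes")
  graphics::abline(h = x$freq_threshold, lty = 2, col = "red")
  ord <- order(x$report$n_features)
  graphics::plot(x$report$n_features[ord], x$report$mean_mae_test[ord],
                 type = "b", pch = 19, xlab = "number of descriptors",
                 ylab = "mean test MAE", main = "accuracy by architecture")
  graphics::points(x$architecture,
                   x$report$mean_mae_test[x$report$n_features == x$architecture],
                   pch = 17, col = "red", cex = 1.6)
  invisible(x)
}
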