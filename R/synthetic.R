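# Seeded synthetic-data generators: planted-feature QSPR tables,
# sigma-potential curves, and model-generated solubility curves. Every
# generator is a pure function of (spec, seed), so the whole pipeline is
# testable without external data.

#' Specification for a synthetic QSPR table
#'
#' Describes a planted-feature regression table emulating the structure of a
#' binary-mixture solubility dataset: a handful of informative descriptors
#' driving a scalar log-solubility target through a smooth nonlinearity,
#' padded with pure-noise descriptors, grouped by solute for LOCO splitting.
#' Defaults mirror the set-1 study conditions: 16 features of which 5 are
#' informative, 400 rows, 11 solutes, RBF-mixture nonlinearity, target noise
#' 0.05 log units (so attainable MAE values are on the scale reported for
#' real solubility tables, roughly 0.05-0.3).
#'
#' @param n_samples number of rows (default 400).
#' @param n_informative number of informative features (default 5).
#' @param n_noise number of pure-noise features (default 11).
#' @param n_solutes number of solute groups (default 11).
#' @param nonlinearity `"rbf-mixture"` (sum of 3 seeded Gaussian bumps over
#'   the informative subspace; default) or `"linear"`.
#' @param noise_sd Gaussian noise sd on the target (default 0.05).
#' @param seed generator seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 400L, n_informative = 5L, n_noise = 11L,
                           n_solutes = 11L,
                           nonlinearity = c("rbf-mixture", "linear"),
                           noise_sd = 0.05, seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  if (n_informative == 0L) {
    stop_dooit("n_informative must be >= 1", "dooit_validation_error")
  }
  if (n_solutes < 1L) stop_dooit("n_solutes must be >= 1", "dooit_validation_error")
  structure(list(n_samples = as.integer(n_samples),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 n_solutes = as.integer(n_solutes),
                 nonlinearity = nonlinearity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a planted-feature QSPR table
#'
#' Feature columns are independent standard normals; the target is driven by
#' the informative subset only (plus small per-solute offsets and seeded
#' Gaussian noise), so the informative set is exact ground truth for
#' feature-selection experiments and the returned `oracle` function attains
#' the noise floor by construction.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `table` (data.frame: `solute_id`, shuffled feature
#'   columns `f01...`, target `log_x_exp`) and `truth` (informative feature
#'   names, generating parameters, per-solute offsets, and the noise-free
#'   `oracle(table)` prediction function).
#' @export
gen_qspr_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$n_informative + spec$n_noise
  with_seed(spec$seed, {
    x <- matrix(stats::rnorm(spec$n_samples * p), spec$n_samples, p)
    colnames(x) <- sprintf("f%02d", seq_len(p))
    pos <- sample.int(p, spec$n_informative)  # where the informative columns sit
    informative <- sort(colnames(x)[pos])
    solute_id <- sprintf("S%02d", sample.int(spec$n_solutes, spec$n_samples,
                                             replace = TRUE))
    offsets <- stats::setNames(stats::rnorm(spec$n_solutes, 0, 0.1),
                               sprintf("S%02d", seq_len(spec$n_solutes)))
    if (spec$nonlinearity == "rbf-mixture") {
      n_bumps <- 3L
      centers <- matrix(stats::rnorm(n_bumps * spec$n_informative),
                        n_bumps, spec$n_informative)
      amplitudes <- c(1.2, -0.8, 1.0)[seq_len(n_bumps)]
      lengthscales <- c(1.5, 2.0, 1.8)[seq_len(n_bumps)]
      signal_fun <- function(xi) {
        out <- numeric(nrow(xi))
        for (m in seq_len(n_bumps)) {
          d2 <- rowSums(sweep(xi, 2L, centers[m, ])^2)
          out <- out + amplitudes[m] * exp(-d2 / (2 * lengthscales[m]^2))
        }
        out
      }
      params <- list(centers = centers, amplitudes = amplitudes,
                     lengthscales = lengthscales)
    } else {
      beta <- stats::runif(spec$n_informative, 0.4, 1.0) *
        sample(c(-1, 1), spec$n_informative, replace = TRUE)
      signal_fun <- function(xi) as.numeric(xi %*% beta)
      params <- list(beta = beta)
    }
    signal <- signal_fun(x[, informative, drop = FALSE])
    y <- unname(signal + offsets[solute_id] +
                  stats::rnorm(spec$n_samples, 0, spec$noise_sd))
    oracle <- function(table) {
      xi <- as.matrix(table[informative])
      unname(signal_fun(xi) + offsets[as.character(table$solute_id)])
    }
    list(table = data.frame(solute_id = solute_id, x,
                            log_x_exp = y, stringsAsFactors = FALSE),
         truth = list(informative = informative, params = params,
                      offsets = offsets, noise_sd = spec$noise_sd,
                      nonlinearity = spec$nonlinearity, oracle = oracle))
  })
}

#' Generate a synthetic sigma-potential curve
#'
#' A smooth parabola-plus-wings shape evaluated on the fixed 61-point grid:
#' `a0 + a1*s + a2*s^2` plus quadratic wings beyond +/- 0.01 e/A^2 (the
#' hydrogen-bonding regions). With all coefficients zero the curve is
#' identically zero; with `a1 = 1` and the rest zero it is the identity ramp
#' used as a binning oracle. If `seed` is given, unset coefficients are drawn
#' randomly (reproducibly) instead of defaulting to zero.
#'
#' @param a0,a1,a2 polynomial coefficients.
#' @param wing_neg,wing_pos wing curvatures on the donor/acceptor sides.
#' @param seed optional seed; when supplied, coefficients are drawn as
#'   standard normals (scaled to typical sigma-potential magnitudes).
#' @return Numeric vector of length 61.
#' @export
gen_sigma_curve <- function(a0 = 0, a1 = 0, a2 = 0, wing_neg = 0, wing_pos = 0,
                            seed = NULL) {
  if (!is.null(seed)) {
    cf <- with_seed(seed, stats::rnorm(5))
    a0 <- cf[1] * 0.1; a1 <- cf[2]; a2 <- cf[3] * 100
    wing_neg <- cf[4] * 1e4; wing_pos <- cf[5] * 1e4
  }
  s <- sigma_grid()
  a0 + a1 * s + a2 * s^2 +
    wing_neg * pmax(0, -(s + 0.01))^2 + wing_pos * pmax(0, s - 0.01)^2
}

#' Generate model-based solubility curves
#'
#' Forward-evaluates one of the three curation models on a design grid and
#' adds seeded Gaussian noise on ln x, recording the generating truth, so the
#' fitters can be exercised on data with known parameters.
#'
#' @param model `"lh"` (Buchowski-Ksiazczak lambda-h), `"vh3"`
#'   (three-parameter van't Hoff) or `"ja"` (Jouyban-Acree).
#' @param params named list of generating parameters:
#'   lh: `lam, h, t_m`; vh3: `a, b, c`; ja: `j (length 3), ln_x1, ln_x2,
#'   temperature`.
#' @param design numeric vector of design points: temperatures (K) for
#'   `"lh"`/`"vh3"`, compositions `w1` for `"ja"`.
#' @param noise_sd Gaussian noise sd on ln x (default 0).
#' @param seed noise seed.
#' @return A data.frame of design points and solubilities with attribute
#'   `truth` echoing `params`; columns are `(temperature_K, x)` for the
#'   temperature models and `(w1, ln_x_mix)` for Jouyban-Acree.
#' @export
gen_solubility_curves <- function(model = c("lh", "vh3", "ja"), params, design,
                                  noise_sd = 0, seed = 1L) {
  model <- match.arg(model)
  noise <- with_seed(seed, stats::rnorm(length(design), 0, noise_sd))
  out <- switch(model,
    lh = {
      x <- lambda_h_forward(params$lam, params$h, params$t_m, design)
      data.frame(temperature_K = design, x = exp(log(x) + noise))
    },
    vh3 = {
      x <- vanthoff3_forward(params$a, params$b, params$c, design)
      data.frame(temperature_K = design, x = exp(log(x) + noise))
    },
    ja = {
      lnx <- jouyban_acree_forward(params$j, design, params$ln_x1,
                                   params$ln_x2, params$temperature)
      data.frame(w1 = design, ln_x_mix = lnx + noise)
    })
  structure(out, truth = params, model = model)
}
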