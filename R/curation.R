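# Thermodynamic standardization models used to harmonize literature
# solubility tables, and the four-way consistency classifier. All fitting is
# least squares on ln x: mole-fraction solubilities span several orders of
# magnitude, so residuals on x would be dominated by the most soluble points.

#' Buchowski-Ksiazczak lambda-h solubility model (forward)
#'
#' Solves the implicit lambda-h equation
#' `ln(1 + lam * (1 - x) / x) = lam * h * (1/T - 1/t_m)`
#' for the mole-fraction solubility; the solution is available in closed form,
#' `x = lam / (exp(lam * h * (1/T - 1/t_m)) + lam - 1)`.
#'
#' @param lam dimensionless lambda parameter, > 0.
#' @param h temperature-scaled parameter (K).
#' @param t_m melting temperature (K); a known constant, not fitted.
#' @param temperature absolute temperature(s) (K), each <= `t_m`.
#' @return Mole-fraction solubility x in (0, 1], vectorized over
#'   `temperature`.
#' @export
lambda_h_forward <- function(lam, h, t_m, temperature) {
  assert_scalar_number(lam, "lam"); assert_scalar_number(h, "h")
  assert_scalar_number(t_m, "t_m")
  if (lam <= 0) stop_dooit("lam must be > 0", "dooit_domain_error")
  if (any(!is.finite(temperature) | temperature <= 0)) {
    stop_dooit("temperatures must be finite and > 0", "dooit_domain_error")
  }
  if (any(temperature > t_m + 1e-9)) {
    stop_dooit("temperature exceeds the melting temperature t_m", "dooit_domain_error")
  }
  denom <- exp(lam * h * (1 / temperature - 1 / t_m)) + lam - 1
  if (any(denom <= 0)) {
    stop_dooit("lambda-h denominator <= 0 for the given parameters", "dooit_domain_error")
  }
  lam / denom
}

#' Fit the lambda-h model to (temperature, solubility) points
#'
#' Nonlinear least squares on ln x residuals with the melting temperature held
#' fixed. Needs as few as three measurements (two free parameters). Starting
#' values come from the ideal (`lam = 1`) van't Hoff slope.
#'
#' @param temperature temperatures (K), all <= `t_m`.
#' @param x mole-fraction solubilities in (0, 1].
#' @param t_m melting temperature (K).
#' @return An object of class `lambda_h_fit` with elements `lam`, `h`, `t_m`,
#'   `rmse_lnx`, `fitted`.
#' @export
fit_lambda_h <- function(temperature, x, t_m) {
  if (length(temperature) != length(x)) {
    stop_dooit("temperature and x must have equal length", "dooit_validation_error")
  }
  if (length(x) < 3L) {
    stop_dooit("lambda-h fit: at least 3 measurements required", "dooit_validation_error")
  }
  if (any(x <= 0 | x > 1)) stop_dooit("x must lie in (0, 1]", "dooit_validation_error")
  if (any(temperature > t_m + 1e-9)) {
    stop_dooit("all temperatures must be <= t_m", "dooit_domain_error")
  }
  lnx <- log(x)
  u <- 1 / temperature - 1 / t_m
  h0 <- unname(-stats::coef(stats::lm(lnx ~ u))[2])  # lam = 1 reduction
  if (!is.finite(h0) || h0 == 0) h0 <- 1000
  dat <- data.frame(lnx = lnx, temperature = temperature)
  # the (lam, h) surface is banana-shaped at small lam; a small multi-start
  # over lam keeps the optimizer off the lam -> 0 boundary
  starts <- expand.grid(lam0 = c(0.05, 0.2, 1, 3), hscale = c(1, NA))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    lam0 <- starts$lam0[i]
    hstart <- if (is.na(starts$hscale[i])) h0 / lam0 else h0
    tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        lnx ~ log(lam) - log(exp(lam * h * (1 / temperature - 1 / t_m)) + lam - 1),
        data = dat, start = list(lam = lam0, h = hstart),
        lower = c(lam = 1e-8, h = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15))),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) {
    stop_dooit("lambda-h fit failed to converge from all starting values",
               "dooit_convergence_error")
  }
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), 0)
  cf <- stats::coef(fits[[which.min(rss)]])
  fitted_x <- lambda_h_forward(cf[["lam"]], cf[["h"]], t_m, temperature)
  structure(
    list(lam = cf[["lam"]], h = cf[["h"]], t_m = t_m,
         rmse_lnx = sqrt(mean((log(fitted_x) - lnx)^2)),
         fitted = fitted_x),
    class = "lambda_h_fit"
  )
}

#' @export
print.lambda_h_fit <- function(x, ...) {
  cat(sprintf("lambda-h fit: lam = %.6g, h = %.6g K, t_m = %.6g K (rmse ln x = %.3g)\n",
              x$lam, x$h, x$t_m, x$rmse_lnx))
  invisible(x)
}

#' Three-parameter van't Hoff model (forward)
#'
#' `ln x = a + b / T + c * ln T`.
#'
#' @param a,b,c model coefficients.
#' @param temperature absolute temperature(s) (K).
#' @return Mole-fraction solubility, vectorized over `temperature`.
#' @export
vanthoff3_forward <- function(a, b, c, temperature) {
  exp(a + b / temperature + c * log(temperature))
}

#' Fit the three-parameter van't Hoff model
#'
#' Ordinary linear least squares of ln x on (1, 1/T, ln T). Unlike the
#' lambda-h model it needs no melting temperature, but requires at least four
#' data points at distinct temperatures.
#'
#' @inheritParams fit_lambda_h
#' @return An object of class `vanthoff3_fit` with `a`, `b`, `c`, `rmse_lnx`,
#'   `fitted`.
#' @export
fit_vanthoff3 <- function(temperature, x) {
  if (length(temperature) != length(x)) {
    stop_dooit("temperature and x must have equal length", "dooit_validation_error")
  }
  if (length(x) < 4L) {
    stop_dooit("van't Hoff 3-parameter fit: at least four data points required",
               "dooit_validation_error")
  }
  if (any(x <= 0 | x > 1)) stop_dooit("x must lie in (0, 1]", "dooit_validation_error")
  u <- 1 / temperature
  v <- log(temperature)
  # centering the regressors keeps the near-collinear (1, 1/T, ln T) basis
  # numerically well conditioned; coefficients are mapped back analytically
  Xc <- cbind(1, u - mean(u), v - mean(v))
  if (qr(Xc)$rank < 3L) {
    stop_dooit("van't Hoff 3-parameter fit: rank-deficient design (need >= 3 distinct temperatures)",
               "dooit_validation_error")
  }
  cfc <- qr.solve(Xc, log(x))
  cf <- c(cfc[1] - cfc[2] * mean(u) - cfc[3] * mean(v), cfc[2], cfc[3])
  fitted_x <- vanthoff3_forward(cf[1], cf[2], cf[3], temperature)
  structure(
    list(a = cf[1], b = cf[2], c = cf[3],
         rmse_lnx = sqrt(mean((log(fitted_x) - log(x))^2)),
         fitted = fitted_x),
    class = "vanthoff3_fit"
  )
}

#' @export
print.vanthoff3_fit <- function(x, ...) {
  cat(sprintf("van't Hoff (3p) fit: a = %.6g, b = %.6g, c = %.6g (rmse ln x = %.3g)\n",
              x$a, x$b, x$c, x$rmse_lnx))
  invisible(x)
}

#' Jouyban-Acree cosolvency model (forward)
#'
#' `ln x_m = w1 ln x1 + w2 ln x2 + (w1 w2 / T) * sum_i J_i (w1 - w2)^i`,
#' with `w2 = 1 - w1` and i = 0, 1, 2. At `w1` of 0 or 1 the model reproduces
#' the neat-solvent solubilities exactly for any interaction coefficients.
#'
#' @param j numeric vector `c(j0, j1, j2)` of interaction coefficients.
#' @param w1 composition fraction(s) of solvent 1, in \[0, 1\].
#' @param ln_x1,ln_x2 natural-log solubilities in the two neat solvents at
#'   temperature `temperature`.
#' @param temperature isotherm temperature (K), > 0.
#' @return `ln x` of the mixture, vectorized over `w1`.
#' @export
jouyban_acree_forward <- function(j, w1, ln_x1, ln_x2, temperature) {
  if (length(j) != 3L) stop_dooit("j must have length 3", "dooit_validation_error")
  if (any(w1 < 0 | w1 > 1)) stop_dooit("w1 must lie in [0, 1]", "dooit_validation_error")
  if (temperature <= 0) stop_dooit("temperature must be > 0", "dooit_domain_error")
  w2 <- 1 - w1
  d <- w1 - w2
  w1 * ln_x1 + w2 * ln_x2 + (w1 * w2 / temperature) * (j[1] + j[2] * d + j[3] * d^2)
}

#' Fit the Jouyban-Acree model to one isotherm
#'
#' Moves the known log-linear blending part to the left-hand side and solves
#' for (J0, J1, J2) by linear least squares on the three-term basis
#' `(w1 w2 / T) (w1 - w2)^i`. Exact on model-generated data.
#'
#' @param w1 interior composition fractions (0 < w1 < 1); endpoints carry no
#'   information on the J's and are ignored with a message.
#' @param ln_x_mix natural-log mixture solubilities at `w1`.
#' @inheritParams jouyban_acree_forward
#' @return An object of class `jouyban_acree_fit` with `j0`, `j1`, `j2`,
#'   `rmse_lnx`.
#' @export
fit_jouyban_acree <- function(w1, ln_x_mix, ln_x1, ln_x2, temperature) {
  if (length(w1) != length(ln_x_mix)) {
    stop_dooit("w1 and ln_x_mix must have equal length", "dooit_validation_error")
  }
  interior <- w1 > 0 & w1 < 1
  if (any(!interior)) {
    dooit_log("info", "dropping ", sum(!interior),
              " endpoint composition(s) from Jouyban-Acree fit")
  }
  w1i <- w1[interior]; yi <- ln_x_mix[interior]
  if (length(w1i) < 3L) {
    stop_dooit("Jouyban-Acree fit: at least 3 interior compositions required",
               "dooit_validation_error")
  }
  w2i <- 1 - w1i
  d <- w1i - w2i
  lhs <- yi - w1i * ln_x1 - w2i * ln_x2
  X <- cbind(j0 = w1i * w2i / temperature,
             j1 = w1i * w2i * d / temperature,
             j2 = w1i * w2i * d^2 / temperature)
  cf <- qr.solve(X, lhs)
  fitted_ln <- jouyban_acree_forward(unname(cf), w1i, ln_x1, ln_x2, temperature)
  structure(
    list(j0 = cf[["j0"]], j1 = cf[["j1"]], j2 = cf[["j2"]],
         rmse_lnx = sqrt(mean((fitted_ln - yi)^2)),
         w1 = w1i, fitted_lnx = fitted_ln),
    class = "jouyban_acree_fit"
  )
}

#' @export
print.jouyban_acree_fit <- function(x, ...) {
  cat(sprintf("Jouyban-Acree fit: J0 = %.6g, J1 = %.6g, J2 = %.6g (rmse ln x = %.3g)\n",
              x$j0, x$j1, x$j2, x$rmse_lnx))
  invisible(x)
}

# grid comparison helpers: literature tables round compositions to ~1e-6 and
# temperatures to ~0.01 K
same_set <- function(a, b, tol) {
  a <- sort(unique(a)); b <- sort(unique(b))
  length(a) == length(b) && all(abs(a - b) <= tol)
}

#' Classify a solubility curve set into consistency categories
#'
#' Literature solubility tables are grouped into four curation categories
#' before model fitting:
#' \describe{
#'   \item{1}{complete and coherent: pure-solvent and mixture measurements
#'     share the same temperatures, and every temperature shares one
#'     composition grid;}
#'   \item{2}{compositions consistent across temperatures, but pure-solvent
#'     and mixture temperatures mismatch (fixed via lambda-h or van't Hoff
#'     back-computation);}
#'   \item{3}{temperatures consistent, but composition grids differ (fixed via
#'     Jouyban-Acree standardization);}
#'   \item{4}{both inconsistent; requires full model-based smoothing.}
#' }
#' Pure-solvent rows are those with `x2_star` equal to 0 or 1. A system with
#' no pure-solvent rows is flagged `incomplete`; supplying `neat_reference`
#' (rows of averaged neat-solvent values with the same columns) substitutes
#' those values before classification.
#'
#' @param curves a `solubility_curves` list from [read_solubility_curves()],
#'   or a single per-system data frame with columns
#'   `temperature_K, x2_star, x1`.
#' @param neat_reference optional data frame of averaged neat-solvent rows.
#' @param comp_tol,temp_tol equality tolerances for composition (absolute,
#'   default 1e-6) and temperature (default 0.01 K).
#' @return Integer category 1-4 per system (named vector for curve sets),
#'   with attribute `incomplete` marking systems lacking pure-solvent data.
#' @export
categorize <- function(curves, neat_reference = NULL,
                       comp_tol = 1e-6, temp_tol = 0.01) {
  if (is.data.frame(curves)) {
    return(categorize_system(curves, neat_reference, comp_tol, temp_tol))
  }
  out <- vapply(curves, function(g) {
    categorize_system(g, neat_reference, comp_tol, temp_tol)
  }, 0L)
  incomplete <- vapply(curves, function(g) {
    isTRUE(attr(categorize_system(g, neat_reference, comp_tol, temp_tol), "incomplete"))
  }, TRUE)
  structure(out, incomplete = incomplete)
}

categorize_system <- function(g, neat_reference = NULL,
                              comp_tol = 1e-6, temp_tol = 0.01) {
  is_pure <- g$x2_star <= comp_tol | g$x2_star >= 1 - comp_tol
  incomplete <- !any(is_pure)
  if (incomplete) {
    if (is.null(neat_reference)) {
      stop_dooit("system lacks pure-solvent data; supply averaged neat values via 'neat_reference'",
                 "dooit_incomplete_error")
    }
    g <- rbind(g[, c("temperature_K", "x2_star", "x1")],
               neat_reference[, c("temperature_K", "x2_star", "x1")])
    is_pure <- g$x2_star <= comp_tol | g$x2_star >= 1 - comp_tol
  }
  pure_T <- g$temperature_K[is_pure]
  mix <- g[!is_pure, , drop = FALSE]
  if (nrow(mix) == 0L) {
    stop_dooit("system has no mixture measurements", "dooit_validation_error")
  }
  temps_ok <- same_set(pure_T, mix$temperature_K, temp_tol)
  grids <- lapply(split(mix$x2_star, round(mix$temperature_K / temp_tol)),
                  function(v) sort(unique(v)))
  ref <- grids[[1]]
  comps_ok <- all(vapply(grids, function(gr) same_set(gr, ref, comp_tol), TRUE))
  cat_n <- if (temps_ok && comps_ok) 1L else if (comps_ok) 2L else if (temps_ok) 3L else 4L
  structure(cat_n, incomplete = incomplete)
}
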