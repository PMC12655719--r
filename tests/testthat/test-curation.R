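test_that("lambda-h closed form matches its implicit equation and limits", {
  # ideal-melt limit
  expect_equal(lambda_h_forward(0.7, 2500, 500, 500), 1)
  # lam = 1 reduces to the ideal van't Hoff form
  Tt <- 300
  expect_equal(lambda_h_forward(1, 3000, 500, Tt),
               exp(-3000 * (1 / Tt - 1 / 500)), tolerance = 1e-12)
  # closed form agrees with numerical root finding of the implicit equation
  for (lam in c(0.2, 0.4, 1, 2.5, 5)) {
    for (h in c(500, 3000, 8000)) {
      for (Tt in c(280, 300, 350, 450)) {
        x_closed <- lambda_h_forward(lam, h, 500, Tt)
        # root-find the implicit equation in ln x for uniform relative accuracy
        g <- function(l) log1p(lam * (1 - exp(l)) / exp(l)) -
          lam * h * (1 / Tt - 1 / 500)
        l_root <- uniroot(g, c(-700, 0), tol = 1e-13)$root
        expect_equal(x_closed, exp(l_root), tolerance = 1e-10)
      }
    }
  }
  expect_error(lambda_h_forward(0.4, 3000, 500, 510), class = "dooit_domain_error")
  expect_error(lambda_h_forward(-1, 3000, 500, 300), class = "dooit_domain_error")
})

test_that("lambda-h fitter recovers generating parameters exactly", {
  curve <- gen_solubility_curves("lh", list(lam = 0.4, h = 3000, t_m = 500),
                                 design = seq(280, 320, by = 10))
  fit <- fit_lambda_h(curve$temperature_K, curve$x, 500)
  expect_equal(fit$lam, 0.4, tolerance = 1e-6)
  expect_equal(fit$h, 3000, tolerance = 1e-6)
  expect_lt(fit$rmse_lnx, 1e-8)
  expect_error(fit_lambda_h(c(280, 300), c(0.01, 0.02), 500),
               "at least 3", class = "dooit_validation_error")
})

test_that("three-parameter van't Hoff fit is exact and checks its preconditions", {
  curve <- gen_solubility_curves("vh3", list(a = 10, b = -3500, c = -1),
                                 design = c(280, 295, 310, 325))
  fit <- fit_vanthoff3(curve$temperature_K, curve$x)
  expect_equal(fit$a, 10, tolerance = 1e-9)
  expect_equal(fit$b, -3500, tolerance = 1e-9)
  expect_equal(fit$c, -1, tolerance = 1e-9)

  # nested-model consistency: c = 0 data recovers a plain van't Hoff line
  curve2 <- gen_solubility_curves("vh3", list(a = 5, b = -2500, c = 0),
                                  design = c(280, 295, 310, 325))
  fit2 <- fit_vanthoff3(curve2$temperature_K, curve2$x)
  expect_equal(fit2$c, 0, tolerance = 1e-8)
  vh2 <- lm(log(curve2$x) ~ I(1 / curve2$temperature_K))
  expect_equal(fit2$a, unname(coef(vh2)[1]), tolerance = 1e-6)
  expect_equal(fit2$b, unname(coef(vh2)[2]), tolerance = 1e-6)

  expect_error(fit_vanthoff3(c(280, 300, 320), c(.01, .02, .03)),
               "at least four", class = "dooit_validation_error")
  expect_error(fit_vanthoff3(rep(300, 4), c(.01, .02, .03, .04)),
               "rank", class = "dooit_validation_error")
})

test_that("Jouyban-Acree model interpolates endpoints exactly and sums terms", {
  # endpoint interpolation holds for arbitrary interaction coefficients
  for (case in 1:20) {
    set.seed(case)
    j <- rnorm(3, 0, 1000)
    expect_equal(jouyban_acree_forward(j, 1, -2, -6, 298.15), -2)
    expect_equal(jouyban_acree_forward(j, 0, -2, -6, 298.15), -6)
  }
  # zero interaction: log-linear blending
  expect_equal(jouyban_acree_forward(c(0, 0, 0), 0.25, -2, -6, 300),
               0.25 * -2 + 0.75 * -6)
  # term-by-term oracle at one interior point
  j <- c(500, -200, 100); w1 <- 0.3; Tt <- 298.15
  w2 <- 1 - w1
  expected <- w1 * -2 + w2 * -6 +
    (w1 * w2 / Tt) * (j[1] * (w1 - w2)^0 + j[2] * (w1 - w2)^1 + j[3] * (w1 - w2)^2)
  expect_equal(jouyban_acree_forward(j, w1, -2, -6, Tt), expected, tolerance = 1e-12)
})

test_that("Jouyban-Acree fitter recovers coefficients and curve shape", {
  curve <- gen_solubility_curves("ja", list(j = c(800, 300, -150), ln_x1 = -2,
                                            ln_x2 = -6, temperature = 298.15),
                                 design = seq(0.1, 0.9, by = 0.1))
  fit <- fit_jouyban_acree(curve$w1, curve$ln_x_mix, -2, -6, 298.15)
  expect_equal(fit$j0, 800, tolerance = 1e-8)
  expect_equal(fit$j1, 300, tolerance = 1e-8)
  expect_equal(fit$j2, -150, tolerance = 1e-8)

  zero <- fit_jouyban_acree(seq(0.2, 0.8, 0.2),
                            jouyban_acree_forward(c(0, 0, 0), seq(0.2, 0.8, 0.2),
                                                  -1, -5, 300),
                            -1, -5, 300)
  expect_equal(abs(c(zero$j0, zero$j1, zero$j2)), rep(0, 3), tolerance = 1e-8)

  # strong positive synergy produces an interior solubility maximum, as seen
  # for ferulic acid in DMF/water-like systems
  syn <- gen_solubility_curves("ja", list(j = c(2500, 500, 0), ln_x1 = -0.9,
                                          ln_x2 = -9, temperature = 298.15),
                               design = seq(0.1, 0.9, by = 0.1))
  fit_syn <- fit_jouyban_acree(syn$w1, syn$ln_x_mix, -0.9, -9, 298.15)
  grid <- seq(0, 1, by = 0.001)
  pred <- jouyban_acree_forward(c(fit_syn$j0, fit_syn$j1, fit_syn$j2),
                                grid, -0.9, -9, 298.15)
  peak <- grid[which.max(pred)]
  expect_gt(peak, 0)
  expect_lt(peak, 1)
  expect_gt(max(pred), max(-0.9, -9))

  expect_error(fit_jouyban_acree(c(0, 0.5, 1), c(-6, -3, -2), -2, -6, 298.15),
               "interior", class = "dooit_validation_error")
})

test_that("all three fitters invert their forward models on random draws", {
  for (case in 1:30) {
    set.seed(case)
    lam <- runif(1, 0.1, 3); h <- runif(1, 500, 8000)
    c_lh <- gen_solubility_curves("lh", list(lam = lam, h = h, t_m = 500),
                                  design = seq(278, 323, 5))
    f <- fit_lambda_h(c_lh$temperature_K, c_lh$x, 500)
    expect_equal(f$lam, lam, tolerance = 1e-6)
    expect_equal(f$h, h, tolerance = 1e-6)

    ab <- c(runif(1, 20, 120), runif(1, -12000, -3000), runif(1, -20, -2))
    c_vh <- gen_solubility_curves("vh3", list(a = ab[1], b = ab[2], c = ab[3]),
                                  design = seq(273, 353, 10))
    if (all(c_vh$x <= 1)) {
      f <- fit_vanthoff3(c_vh$temperature_K, c_vh$x)
      expect_equal(c(f$a, f$b, f$c), ab, tolerance = 1e-6)
    }

    j <- rnorm(3, 0, 1500)
    c_ja <- gen_solubility_curves("ja", list(j = j, ln_x1 = -2, ln_x2 = -6,
                                             temperature = 298.15),
                                  design = seq(0.1, 0.9, 0.1))
    f <- fit_jouyban_acree(c_ja$w1, c_ja$ln_x_mix, -2, -6, 298.15)
    expect_equal(c(f$j0, f$j1, f$j2), j, tolerance = 1e-6)
  }
})

test_that("consistency categories follow the temperature/composition rules", {
  sys <- function(mix_T, grids, pure_T = mix_T) {
    mix <- do.call(rbind, lapply(seq_along(mix_T), function(i) {
      data.frame(temperature_K = mix_T[i], x2_star = grids[[i]],
                 x1 = 0.01 + 0.001 * seq_along(grids[[i]]))
    }))
    pure <- expand.grid(temperature_K = pure_T, x2_star = c(0, 1))
    pure$x1 <- 0.005
    rbind(mix, pure)
  }
  g <- seq(0.1, 0.9, 0.2)

  expect_equal(as.integer(categorize(sys(c(298, 308), list(g, g)))), 1L)
  # pure-solvent temperatures shifted by 5 K -> temperature inconsistency
  expect_equal(as.integer(categorize(sys(c(298, 308), list(g, g),
                                         pure_T = c(303, 313)))), 2L)
  # same temperatures, two different composition grids
  expect_equal(as.integer(categorize(sys(c(298, 308), list(g, g + 0.05)))), 3L)
  # both inconsistent
  expect_equal(as.integer(categorize(sys(c(298, 308), list(g, g + 0.05),
                                         pure_T = c(303, 313)))), 4L)

  # incomplete systems need substituted neat values
  mix_only <- sys(298, list(g))
  mix_only <- mix_only[mix_only$x2_star > 0 & mix_only$x2_star < 1, ]
  expect_error(categorize(mix_only), "neat", class = "dooit_incomplete_error")
  neat <- data.frame(temperature_K = 298, x2_star = c(0, 1), x1 = 0.004)
  cat1 <- categorize(mix_only, neat_reference = neat)
  expect_equal(as.integer(cat1), 1L)
  expect_true(attr(cat1, "incomplete"))
})
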