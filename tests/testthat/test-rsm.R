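test_that("R-squared family matches an independent residual computation", {
  for (spec in list(list(resp = "yield", order = "2FI"),
                    list(resp = "solubility", order = "quadratic"))) {
    fit <- rsm_fit(gp_design(), gp_response(spec$resp), spec$order)
    d <- oracle_gp()
    y <- if (spec$resp == "yield") d$yield else d$sol
    # rebuild predictions by direct polynomial evaluation of the coefficients
    A <- (d$P - 21) / 3; B <- (d$T - 65) / 5; C <- (d$W - 20) / 10
    cf <- coef(fit)
    pred <- cf["(Intercept)"] + cf["A"] * A + cf["B"] * B + cf["C"] * C +
      cf["AB"] * A * B + cf["AC"] * A * C + cf["BC"] * B * C
    if (spec$order == "quadratic")
      pred <- pred + cf["A2"] * A^2 + cf["B2"] * B^2 + cf["C2"] * C^2
    r2_indep <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    expect_equal(fit$r2, r2_indep, tolerance = 1e-10)
    # fitted values obey the hat-matrix identity at the design points
    expect_equal(predict(fit), unname(pred), tolerance = 1e-10)
    # ordering of the R-squared family
    expect_lte(fit$pred_r2, fit$adj_r2)
    expect_lte(fit$adj_r2, fit$r2)
    expect_gte(fit$press, 0)
  }
})

test_that("zero-noise synthetic responses are recovered exactly", {
  des <- toy_design(n_center = 4L)
  truth <- c("(Intercept)" = 5, A = 3.2, B = -1.1, C = 3.1, AB = 0.4,
             AC = 2.1, BC = -0.8, A2 = 1.5, B2 = -0.6, C2 = 0.9)
  y <- synth_response(des, truth, order = "quadratic", noise_sd = 0)
  fit <- suppressWarnings(rsm_fit(des, y, "quadratic"))
  expect_equal(coef(fit), truth, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("coefficient recovery error is monotone in the noise level", {
  des <- toy_design(n_center = 6L)
  truth <- c("(Intercept)" = 6, A = 3, B = 1, C = 3, AB = 0, AC = 2, BC = 1)
  sds <- c(0.5, 0.1, 0.01)
  rmse <- vapply(seq_along(sds), function(k) {
    errs <- vapply(1:50, function(s) {
      y <- synth_response(des, truth, "2FI", noise_sd = sds[k],
                          seed = 1000 * k + s)
      sqrt(mean((coef(rsm_fit(des, y, "2FI")) - truth)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(rmse[1] > rmse[2])
  expect_true(rmse[2] > rmse[3])
})

test_that("pure-noise responses reject terms at about the nominal 5% rate", {
  des <- toy_design(n_center = 6L)
  set.seed(42)
  rejections <- replicate(100, {
    y <- rnorm(nrow(des$points))
    sum(rsm_fit(des, y, "2FI")$term_p < 0.05)
  })
  rate <- sum(rejections) / (100 * 6)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("lack-of-fit test uses replicate pure error", {
  fit <- rsm_fit(gp_design(), gp_response("yield"), "2FI")
  expect_true(fit$lack_of_fit$available)
  # 6 centre replicates give 5 pure-error degrees of freedom
  expect_equal(fit$lack_of_fit$df_pe, 5L)
  expect_gt(fit$lack_of_fit$p, 0.05)  # 2FI adequate for yield

  # no replicates: lack of fit reported unavailable, not silently NaN
  des1 <- toy_design(n_center = 1L)
  y <- synth_response(des1, c(1, 1, 1, 1), order = "linear", noise_sd = 0.5,
                      seed = 7)
  f1 <- rsm_fit(des1, y, "linear")
  expect_false(f1$lack_of_fit$available)
  expect_match(f1$lack_of_fit$reason, "replicate")
})

test_that("significant terms for the case-study fits include A, C and AC", {
  fy <- rsm_fit(gp_design(), gp_response("yield"), "2FI")
  expect_lt(fy$model_p, 0.0001)
  expect_true(all(c("A", "C", "AC") %in% fy$significant_terms))
  fs <- rsm_fit(gp_design(), gp_response("solubility"), "quadratic")
  expect_lt(fs$model_p, 0.05)
  expect_true(all(c("A", "C", "AC") %in% fs$significant_terms))
})

test_that("degenerate and misspecified inputs fail loudly", {
  des <- toy_design(n_center = 2L)
  w <- capture_warnings(fit <- rsm_fit(des, rep(2.5, nrow(des$points)), "2FI"))
  expect_match(w, "constant response", all = FALSE)
  expect_true(is.na(fit$r2))
  expect_equal(unname(coef(fit)["(Intercept)"]), 2.5)
  expect_true(all(abs(coef(fit)[-1]) < 1e-12))

  # collapsing a factor to a single level makes the matrix rank-deficient
  f <- toy_factors()
  pts <- des$points
  pts$x3 <- 100
  broken <- structure(list(factors = f, points = pts), class = "ccd_design")
  expect_error(rsm_fit(broken, rnorm(nrow(pts)), "2FI"), "collinear")

  # more terms than runs
  tiny <- structure(list(factors = f, points = des$points[1:5, ]),
                    class = "ccd_design")
  expect_error(rsm_fit(tiny, rnorm(5), "quadratic"), "more runs")

  expect_error(rsm_fit(des, data.frame(run_id = 1, value = 1), "2FI"),
               "missing run_id")
})

test_that("prediction codes points and flags extrapolation", {
  fit <- rsm_fit(gp_design(), gp_response("solubility"), "quadratic")
  # centre point: all coded terms vanish, prediction = intercept
  expect_equal(predict(fit, c(21, 65, 20)),
               unname(coef(fit)["(Intercept)"]))
  # inside the region, no warning
  expect_silent(predict(fit, c(22, 66, 25)))
  # outside the axial box: warn, don't fail
  expect_warning(p <- predict(fit, c(30, 65, 20)), "extrapolates")
  expect_true(is.finite(p))
})

test_that("optimizer matches a brute-force grid and closed forms", {
  des <- toy_design(n_center = 4L)
  # concave toy quadratic -A^2 - B^2 - C^2 + 2A has argmax at coded (1,0,0)
  truth <- c("(Intercept)" = 0, A = 2, B = 0, C = 0, AB = 0, AC = 0,
             BC = 0, A2 = -1, B2 = -1, C2 = -1)
  y <- synth_response(des, truth, "quadratic", noise_sd = 0)
  opt <- rsm_optimize(suppressWarnings(rsm_fit(des, y, "quadratic")))
  expect_equal(unname(opt$coded), c(1, 0, 0), tolerance = 1e-6)
  expect_equal(opt$value, 1, tolerance = 1e-8)

  # random quadratics: optimum at least as good as a 51^3 grid search
  box <- rbind(c(-1.5, -1.5, -1.5), c(1.5, 1.5, 1.5))
  g <- seq(-1.5, 1.5, length.out = 51)
  grid <- as.matrix(expand.grid(A = g, B = g, C = g))
  mm <- cbind(1, grid, grid[, 1] * grid[, 2], grid[, 1] * grid[, 3],
              grid[, 2] * grid[, 3], grid^2)
  set.seed(99)
  for (rep in 1:5) {
    beta <- round(rnorm(10), 2)
    names(beta) <- c("(Intercept)", "A", "B", "C", "AB", "AC", "BC",
                     "A2", "B2", "C2")
    y <- synth_response(des, beta, "quadratic", noise_sd = 0)
    fit <- suppressWarnings(rsm_fit(des, y, "quadratic"))
    opt <- rsm_optimize(fit, bounds = box)
    grid_max <- max(drop(mm %*% beta))
    expect_gte(opt$value, grid_max - 1e-6)
  }
})

test_that("simulate() reproduces the fitted surface plus residual noise", {
  fit <- rsm_fit(gp_design(), gp_response("yield"), "2FI")
  s1 <- simulate(fit, nsim = 3, seed = 5)
  s2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(20L, 3L))
})
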