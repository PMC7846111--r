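test_that("the mixture fit recovers known generating parameters", {
  gen_means <- c(0.37, 0.53, 0.64, 0.71)
  x <- make_fatps_samples(gen_means, sds = 0.02, zero_weight = 0,
                          n = 2000, seed = 42)
  fit <- fit_fatps_mixture(x)
  expect_true(fit$converged)
  expect_equal(fit$zero_peak_weight, 0)
  expect_equal(fit$means, gen_means, tolerance = 0.01)
  expect_true(all(diff(fit$means) > 0))
  expect_equal(sum(fit$weights) + fit$zero_peak_weight, 1,
               tolerance = 1e-9)
})

test_that("degenerate mixture inputs are handled", {
  fit0 <- fit_fatps_mixture(rep(0, 100))
  expect_equal(fit0$zero_peak_weight, 1)
  expect_equal(fit0$k, 0L)
  expect_error(fit_fatps_mixture(c(rep(0, 60), runif(20, 0.3, 0.8))),
               "at least 50")
  expect_error(fit_fatps_mixture(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("the mixture fit is invariant to duplicating the data", {
  x <- make_fatps_samples(n = 600, seed = 9)
  f1 <- fit_fatps_mixture(x)
  f2 <- fit_fatps_mixture(rep(x, 2))
  # identical up to the EM convergence tolerance
  expect_equal(f1$means, f2$means, tolerance = 1e-5)
  expect_equal(f1$sds, f2$sds, tolerance = 1e-4)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-4)
})

test_that("aero-types follow the maximum-posterior rule", {
  fit <- reference_aerotype_fit()
  expect_equal(assign_aerotype(0, fit), "i")
  expect_equal(assign_aerotype(0.019, fit), "i")  # zero-peak threshold
  expect_equal(assign_aerotype(0.37, fit), "ii")
  expect_equal(assign_aerotype(0.53, fit), "iii")
  expect_equal(assign_aerotype(0.64, fit), "iv")
  expect_equal(assign_aerotype(0.71, fit), "v")
  expect_equal(assign_aerotype(c(0, 0.37, 0.71), fit),
               c("i", "ii", "v"))
  expect_error(assign_aerotype(1.2, fit), "\\[0, 1\\]")

  # at the exact posterior crossing the lower label wins
  sym <- reference_aerotype_fit(means = c(0.4, 0.6), sds = 0.02,
                                weights = c(0.45, 0.45),
                                zero_peak_weight = 0.1)
  expect_equal(assign_aerotype(0.5, sym, labels = c("i", "ii", "iii")),
               "ii")
})

test_that("forward stepwise selection behaves", {
  set.seed(21)
  n <- 200
  X <- as.data.frame(matrix(runif(n * 8), n,
                            dimnames = list(NULL, paste0("f_", 1:8))))
  # response exactly linear in one predictor (suppress R's perfect-fit
  # warnings, which are the point of the case)
  rep1 <- suppressWarnings(stepwise_regression(X, 3 * X$f_1))
  expect_equal(rep1$steps$predictor[1], "f_1")
  expect_equal(rep1$final_r2, 1, tolerance = 1e-9)
  expect_true(all(diff(rep1$steps$cum_r2) >= -1e-12))

  # a pure-noise predictor is never selected (simulation oracle, n = 1000)
  set.seed(22)
  n2 <- 1000
  X2 <- data.frame(signal = runif(n2), noise = runif(n2))
  y2 <- 2 * X2$signal + rnorm(n2, 0, 0.05)
  rep2 <- stepwise_regression(cbind(X2, pad = runif(n2)), y2)
  expect_false("noise" %in% rep2$steps$predictor)

  # monotone inclusion: the full model's R2 bounds any stepwise R2
  full <- summary(stats::lm(y2 ~ ., data = X2))$r.squared
  expect_lte(rep2$final_r2, full + 1e-12)

  # a duplicated (rank-deficient) predictor is skipped with a record
  X3 <- X2
  X3$dup <- X3$signal
  rep3 <- suppressWarnings(stepwise_regression(X3, y2))
  expect_true(!"dup" %in% rep3$steps$predictor ||
                !"signal" %in% rep3$steps$predictor)
})

test_that("proteome complexity counts expressed enzymes", {
  m <- calibrated_model()
  sol <- wt_solution()
  cx <- proteome_complexity(sol, m)
  expect_gte(cx$avg_subunits, 1)
  expect_gt(cx$n_genes_expressed, 10)

  none <- sol
  none$enzyme_phi[] <- 0
  expect_equal(proteome_complexity(none, m),
               list(n_genes_expressed = 0L, avg_subunits = 0))

  one <- none
  one$enzyme_phi["Nuo"] <- 0.01
  cx1 <- proteome_complexity(one, m)
  expect_equal(cx1$avg_subunits, 13)
  expect_equal(cx1$n_genes_expressed, 13L)
})

test_that("flux PCA is a standardized decomposition", {
  tab <- default_run()
  p <- suppressWarnings(flux_pca(tab))
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  # duplicating all rows leaves the loadings unchanged up to sign
  p2 <- suppressWarnings(flux_pca(rbind(tab, tab)))
  for (j in 1:3) {
    a <- p$loadings[, j]; b <- p2$loadings[, j]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-6)
  }
  expect_error(flux_pca(tab[1:2, ]), "at least 3")
})

test_that("the feasibility envelope matches closed-form lines", {
  # perfectly linear synthetic isoclines
  f <- seq(0.1, 0.8, length.out = 20)
  mk <- function(mu, a, b, c, d) data.frame(
    mu_target = mu, feasible = TRUE, f_ATPS = f,
    Y = a + b * f, q_glc = c + d * f)
  tab <- rbind(mk(0.3, 0.1, 0.5, 14, -9), mk(0.5, 0.15, 0.55, 16, -10))
  env <- feasibility_envelope(tab)
  expect_equal(env$slope_Y, c(0.5, 0.55), tolerance = 1e-9)
  expect_equal(env$slope_q, c(-9, -10), tolerance = 1e-9)
  expect_equal(env$Y_at_0, c(0.1, 0.15), tolerance = 1e-9)
  expect_equal(env$Y_at_fmax, c(0.1 + 0.5 * 0.83, 0.15 + 0.55 * 0.83),
               tolerance = 1e-9)
  expect_true(all(env$Y_at_fmax > env$Y_at_0))
  # sparse isoclines are skipped with a warning
  tab2 <- rbind(tab, mk(0.9, 0, 1, 10, -5)[1:3, ])
  expect_warning(env2 <- feasibility_envelope(tab2), "skipped")
  expect_equal(nrow(env2), 2)
})
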