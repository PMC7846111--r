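test_that("ATP fractions follow the registry accounting", {
  m <- calibrated_model()
  sol <- wt_solution()

  # brute-force oracle on random signed flux vectors
  set.seed(3)
  reg <- m$atp_registry
  w <- vapply(m$reactions[reg], `[[`, 0, "atp_produced")
  for (i in 1:25) {
    fake <- sol
    fake$fluxes[reg] <- stats::rnorm(8, 2, 3)
    fr <- compute_fractions(fake, m)
    prod <- w * pmax(0, fake$fluxes[reg])
    if (sum(prod) > 0) {
      got <- unlist(fr[c("f_ATPS", "f_PGK", "f_PYK", "f_ACKr", "f_PPKr",
                         "f_PPK2r", "f_SUCOAS", "f_PRPPS")])
      expect_equal(unname(got), unname(prod / sum(prod)),
                   tolerance = 1e-12)
      expect_equal(sum(got), 1, tolerance = 1e-9)
    } else {
      expect_true(compute_fractions(fake, m)$degenerate)
    }
  }

  # only the synthase produces -> f_ATPS = 1
  fake <- sol
  fake$fluxes[reg] <- c(5, 0, 0, 0, 0, 0, 0, 0)
  fr <- compute_fractions(fake, m)
  expect_equal(fr$f_ATPS, 1)
  expect_equal(fr$f_PGK + fr$f_PYK + fr$f_ACKr, 0)

  # all-zero fluxes -> degenerate zero vector
  fake$fluxes[reg] <- 0
  fr0 <- compute_fractions(fake, m)
  expect_true(fr0$degenerate)
  expect_equal(fr0$f_ATPS, 0)
})

test_that("the constrained-fraction coupling realizes its target", {
  expect_error(build_fatps_constraint(1.2), "\\[0, 1\\]")
  expect_error(build_fatps_constraint(-0.1), "\\[0, 1\\]")
  m <- calibrated_model()
  # p = 0 forces zero synthase flux
  s0 <- solve_growth(m, growth_condition(37, fatps = 0))
  expect_true(s0$feasible)
  expect_lte(abs(s0$fluxes[["ATPS4rpp"]]), 1e-9)
  # p = 0.5: synthase ATP equals all other registry ATP
  s5 <- solve_growth(m, growth_condition(37, fatps = 0.5))
  f5 <- compute_fractions(s5, m)
  expect_equal(f5$f_ATPS, 0.5, tolerance = 1e-6)
  # the highest stated peak value is realizable
  s71 <- solve_growth(m, growth_condition(37, fatps = 0.71))
  f71 <- compute_fractions(s71, m)
  expect_equal(f71$f_ATPS, 0.71, tolerance = 1e-6)
})

test_that("yield follows Y = mu / (q m)", {
  expect_equal(compute_yield(0, 8), 0)
  expect_equal(compute_yield(0.72, 8, 0.18016), 0.72 / (8 * 0.18016),
               tolerance = 1e-12)           # 0.49956 gDW/g by hand
  expect_equal(compute_yield(0.72, 16), compute_yield(0.72, 8) / 2)
  expect_error(compute_yield(0.5, 0), "positive")
})

test_that("phenotypic distance is relative to the reference", {
  ref <- c(q_glc = 8, q_ac = 4, mu = 0.8, Y = 0.5, q_o2 = 12)
  expect_equal(phenotype_distance(ref, ref), 0)
  # doubling two components gives sqrt(2) on the relative scale
  x <- ref; x["q_glc"] <- 16; x["mu"] <- 1.6
  expect_equal(phenotype_distance(x, ref), sqrt(2), tolerance = 1e-12)
  # the auxiliary oxygen component is ignored
  x2 <- x; x2["q_o2"] <- 99
  expect_equal(phenotype_distance(x2, ref), phenotype_distance(x, ref))
  bad <- ref; bad["Y"] <- 0
  expect_error(phenotype_distance(x, bad), "positive")
})

test_that("P/O ratio counts ATP per atomic oxygen", {
  sol <- wt_solution()
  fake <- sol
  fake$fluxes[["ATPS4rpp"]] <- 20
  fake$fluxes[["O2t"]] <- 8
  expect_equal(compute_po_ratio(fake), 1.25)
  fake$fluxes[["ATPS4rpp"]] <- 30
  expect_gt(compute_po_ratio(fake), 1.25)
  ferment <- sol
  ferment$fluxes[["O2t"]] <- 0
  expect_error(compute_po_ratio(ferment), "oxygen")
})

test_that("yield is negatively rank-correlated with f_ACKr/f_PGK at fixed p", {
  ct <- constrained_run()
  for (p in c(0.37, 0.53)) {
    d <- ct[ct$feasible & ct$p_target == p & ct$f_PGK > 0, ]
    rho <- stats::cor(d$Y, d$f_ACKr / d$f_PGK, method = "spearman")
    expect_lt(rho, 0)
  }
})
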