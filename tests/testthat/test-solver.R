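test_that("a zero proteome budget cannot grow", {
  m <- build_default_model(list(phi_max = 0))
  sol <- solve_growth(m, growth_condition(37))
  expect_true(!sol$feasible || sol$mu == 0)
})

test_that("the toy model reaches its closed-form optimum", {
  toy <- make_toy_model()
  sol <- solve_growth(toy, growth_condition(37))
  expect_true(sol$feasible)
  expect_equal(sol$mu, toy_mu_star(toy), tolerance = 1e-4)
  # the ATP generator carries exactly gam*mu + ngam
  expect_equal(unname(sol$fluxes["ATPS4rpp"]),
               toy$params$gam * sol$mu + toy$params$ngam,
               tolerance = 1e-4)
})

test_that("feasible solutions satisfy mass balance and the budget", {
  m <- calibrated_model()
  for (Tc in c(25, 37, 44)) {
    sol <- solve_growth(m, growth_condition(Tc))
    expect_true(sol$feasible)
    # budget: enzymes + ribosome within phi_max
    expect_lte(sum(sol$enzyme_phi) + sol$ribosome_phi,
               m$params$phi_max + 1e-9)
    # mass balance residual, recomputed from the reported net fluxes
    S <- sapply(names(m$reactions), function(id) {
      st <- m$reactions[[id]]$stoichiometry
      st <- st[!grepl("_e$", names(st))]
      v <- stats::setNames(numeric(length(m$metabolites)), m$metabolites)
      v[names(st)] <- st
      v
    })
    v <- sol$fluxes[colnames(S)]
    v[is.na(v)] <- 0
    resid <- S %*% v
    expect_lte(max(abs(resid)), 1e-8 * max(1, sum(abs(v))))
  }
})

test_that("the solver is deterministic", {
  m <- calibrated_model()
  s1 <- solve_growth(m, growth_condition(40))
  s2 <- solve_growth(m, growth_condition(40))
  expect_identical(s1$fluxes, s2$fluxes)
  expect_identical(s1$mu, s2$mu)
})

test_that("growth is monotone in the proteome budget", {
  mus <- vapply(c(0.2, 0.3, 0.4, 0.5), function(phi) {
    solve_growth(build_default_model(list(phi_max = phi)),
                 growth_condition(37))$mu
  }, 0)
  expect_true(all(diff(mus) > -1e-9))
})

test_that("fixed growth rates are honored or flagged infeasible", {
  m <- calibrated_model()
  opt <- wt_solution()$mu
  ok <- solve_growth(m, growth_condition(37, fixed_growth_rate = 0.5 * opt))
  expect_true(ok$feasible)
  expect_equal(ok$mu, 0.5 * opt, tolerance = 1e-12)
  too_fast <- solve_growth(m, growth_condition(37,
                                               fixed_growth_rate = 1.2 * opt))
  expect_false(too_fast$feasible)
  expect_equal(too_fast$mu, 0)
})

test_that("calibration hits its anchors and is idempotent", {
  m <- calibrated_model()
  expect_equal(max_fatps(m), 0.83, tolerance = 1e-3)
  f <- compute_fractions(wt_solution(), m)
  expect_gte(f$f_ATPS, 0.60)
  m2 <- calibrate_wildtype(build_default_model())
  expect_equal(m2$params$charge_per_atp, m$params$charge_per_atp,
               tolerance = 1e-9)
  m3 <- calibrate_wildtype(m2)
  expect_equal(m3$params$charge_per_atp, m2$params$charge_per_atp,
               tolerance = 1e-9)
})
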