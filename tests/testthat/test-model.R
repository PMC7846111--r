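test_that("default model satisfies the structural invariants", {
  m <- build_default_model()
  expect_length(m$atp_registry, 8)
  expect_identical(m$atp_registry,
                   c("ATPS4rpp", "PGK", "PYK", "ACKr", "PPKr", "PPK2r",
                     "SUCOAS", "PRPPS"))
  # every registry reaction produces ATP; nothing else does
  for (r in m$reactions) {
    if (r$id %in% m$atp_registry) expect_gt(r$atp_produced, 0)
    else expect_equal(r$atp_produced, 0)
  }
  # both NADH dehydrogenases catalyze the same quinone-reduction step
  nuo <- m$reactions$NADH16pp$stoichiometry
  ndh <- m$reactions$NADH5$stoichiometry
  expect_equal(nuo[["nadh"]], ndh[["nadh"]])
  expect_equal(nuo[["q8h2"]], ndh[["q8h2"]])
  expect_gt(nuo[["chg"]], 0)          # complex I translocates
  expect_false("chg" %in% names(ndh)) # Ndh does not
  # alternative terminal oxidases differ in translocation and size
  expect_gt(m$reactions$CYTBO3$stoichiometry[["chg"]],
            m$reactions$CYTBD$stoichiometry[["chg"]])
  expect_gt(m$enzymes$Cyo$mw, m$enzymes$Cyd$mw)
  # every metabolite in every stoichiometry resolves
  for (r in m$reactions) {
    internal <- names(r$stoichiometry)[!grepl("_e$", names(r$stoichiometry))]
    expect_true(all(internal %in% m$metabolites), info = r$id)
  }
})

test_that("unknown override keys are a configuration error", {
  expect_error(build_default_model(list(not_a_param = 1)), "not_a_param")
  m <- build_default_model(list(ngam = 7))
  expect_equal(m$params$ngam, 7)
})

test_that("a closed system admits only the trivial solution", {
  # no glucose uptake, no electron acceptor: positive maintenance demand
  # cannot be met ...
  m <- build_default_model()
  no_uptake <- strain_genotype(knockouts = "PtsG")
  closed <- apply_genotype(m, no_uptake)
  sol <- solve_growth(closed, growth_condition(37, "none"))
  expect_false(sol$feasible)
  # ... and with zero maintenance the returned steady state is all-zero
  m0 <- build_default_model(list(ngam = 0))
  closed0 <- apply_genotype(m0, no_uptake)
  sol0 <- solve_growth(closed0, growth_condition(37, "none"))
  expect_equal(sol0$mu, 0)
  expect_lte(max(abs(sol0$fluxes)), 1e-9)
})

test_that("genotypes perturb enzymes and compose per gene", {
  m <- build_default_model()
  # empty genotype: field-wise identity
  expect_identical(apply_genotype(m, strain_genotype()), m)

  # doubling k_eff on the PGK lump halves its proteome cost per unit flux
  g <- strain_genotype(mutations = data.frame(gene_id = "pgk",
                                              keff_factor = 2,
                                              dG_offset = 0))
  m2 <- apply_genotype(m, g)
  cost <- function(mm) {
    e <- mm$enzymes$Gap
    e$mw / (e$k_eff * 3600 * folded_fraction(e$dG_ref, 37))
  }
  expect_equal(cost(m2), cost(m) / 2, tolerance = 1e-12)
  expect_equal(m2$enzymes$Gap$dG_ref, m$enzymes$Gap$dG_ref)

  # two mutations on genes of one enzyme compose multiplicatively /
  # additively (compose-by-hand oracle)
  g2 <- strain_genotype(mutations = data.frame(
    gene_id = c("gapA", "eno"), keff_factor = c(1.5, 1.2),
    dG_offset = c(-0.4, 0.9)))
  m3 <- apply_genotype(m, g2)
  expect_equal(m3$enzymes$Gap$k_eff, m$enzymes$Gap$k_eff * 1.5 * 1.2)
  expect_equal(m3$enzymes$Gap$dG_ref, m$enzymes$Gap$dG_ref - 0.4 + 0.9)

  # composed fold change is clipped to the configured range
  g3 <- strain_genotype(mutations = data.frame(
    gene_id = c("gapA", "eno"), keff_factor = c(1.9, 1.9),
    dG_offset = c(-1, -1)))
  m4 <- apply_genotype(m, g3)
  expect_equal(m4$enzymes$Gap$k_eff, m$enzymes$Gap$k_eff * 2)

  # catalog genes absent from the model are silent
  g4 <- strain_genotype(mutations = data.frame(gene_id = "y0001",
                                               keff_factor = 2,
                                               dG_offset = -1))
  expect_identical(apply_genotype(m, g4), m)

  # unknown enzymes in the knockout set are an input error
  expect_error(apply_genotype(m, strain_genotype(knockouts = "NoSuch")),
               "NoSuch")
})

test_that("gene names resolve to whole complexes", {
  m <- build_default_model()
  expect_equal(genes_to_enzymes(m, "cyoB"), "Cyo")
  expect_setequal(genes_to_enzymes(m, c("ndh", "cydA", "cydB")),
                  c("Ndh", "Cyd"))
  expect_error(genes_to_enzymes(m, "nosuchgene"), "valid names")
})

test_that("model validation names the violated field", {
  m <- build_default_model()
  bad <- m
  bad$atp_registry <- bad$atp_registry[1:7]
  expect_error(validate_model(bad), "atp_registry")
  bad2 <- m
  bad2$reactions$PFK$atp_produced <- 1
  expect_error(validate_model(bad2), "outside the ATP registry")
})
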