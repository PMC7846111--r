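# Shared fixtures, built once per session and memoised: the calibrated
# model, the synthetic mutation-frequency table, and the standard pipeline
# runs that several test files interrogate.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, envir = fixture_env))
    assign(name, fun(), envir = fixture_env)
  get(name, envir = fixture_env)
}

calibrated_model <- function() {
  fixture("model", function() load_model_spec(default_model_path()))
}

default_freq <- function() {
  fixture("freq", function()
    make_mutation_frequency_table(synthetic_config(), seed = 1))
}

wt_solution <- function() {
  fixture("wt", function()
    solve_growth(calibrated_model(), growth_condition(37, "oxygen")))
}

# the default 2,200-strain aerobic sweep (about half a minute)
default_run <- function() {
  fixture("run2200", function()
    sample_strains(calibrated_model(), default_freq(),
                   sampler_config(master_seed = 11)))
}

default_fit <- function() {
  fixture("fit2200", function() {
    tab <- default_run()
    fit_fatps_mixture(tab$f_ATPS[tab$feasible])
  })
}

constrained_run <- function() {
  fixture("constrained", function()
    run_constrained_sampling(calibrated_model(), default_freq(),
                             config = sampler_config(n_per_temperature = 24,
                                                     master_seed = 2)))
}

fixmu_run <- function() {
  fixture("fixmu", function()
    run_fixed_growth_sampling(calibrated_model(), default_freq(),
                              config = sampler_config(n_per_temperature = 60,
                                                      master_seed = 5)))
}

nitrate_run <- function() {
  fixture("nitrate", function()
    run_nitrate_experiment(calibrated_model(), default_freq(),
                           sampler_config(n_per_temperature = 25,
                                          master_seed = 4)))
}

knockout_run <- function() {
  fixture("knockout", function()
    run_knockout_panel(calibrated_model()))
}

expr_fixture <- function() {
  fixture("expr", function()
    make_expression_fixture(synthetic_config(), seed = 1))
}

expr_logtpm <- function() {
  fixture("logtpm", function() {
    fx <- expr_fixture()
    counts_to_logtpm(fx$counts, fx$lengths)
  })
}

# hand-checkable toy: uptake -> ATP -> biomass with one enzyme per step and
# seven dead-ended registry reactions to satisfy the registry invariant
make_toy_model <- function(phi_max = 0.1, kappa_t = 5, gam = 10,
                           ngam = 0.5, k_up = 20, k_atp = 50) {
  registry_dummies <- lapply(setdiff(ATP_REGISTRY_IDS(), "ATPS4rpp"),
    function(id) reaction_spec(id, paste("dummy", id),
                               stats::setNames(c(-1, 1),
                                               c(paste0("dead_", id),
                                                 "atp")),
                               atp_produced = 1, pathway = "biosynthesis"))
  reactions <- c(list(
    reaction_spec("UPT", "substrate uptake", c(s_e = -1, x = 1),
                  enzyme = "E_up", pathway = "exchange"),
    reaction_spec("ATPS4rpp", "ATP generator", c(x = -1, atp = 1),
                  atp_produced = 1, enzyme = "E_atp", pathway = "oxphos"),
    reaction_spec("ATPM", "maintenance", c(atp = -1), pathway = "biomass"),
    reaction_spec("BIOMASS", "biomass", c(atp = -gam, biomass_e = 1),
                  pathway = "biomass")),
    registry_dummies)
  enzymes <- list(
    enzyme_spec("E_up", "gUp", 100, 1, k_up, 20),
    enzyme_spec("E_atp", "gAtp", 100, 1, k_atp, 20))
  model_spec(reactions, enzymes,
             list(phi_max = phi_max, kappa_t = kappa_t, gam = gam,
                  ngam = ngam, substrate_mw = 0.18016,
                  charge_per_atp = 3))
}

ATP_REGISTRY_IDS <- function() c("ATPS4rpp", "PGK", "PYK", "ACKr",
                                 "PPKr", "PPK2r", "SUCOAS", "PRPPS")

# closed-form optimum of the toy model (enzyme costs per unit flux at T)
toy_mu_star <- function(toy, T_celsius = 37) {
  c_up <- 100 / (toy$enzymes$E_up$k_eff * 3600 *
                   folded_fraction(20, T_celsius))
  c_atp <- 100 / (toy$enzymes$E_atp$k_eff * 3600 *
                    folded_fraction(20, T_celsius))
  p <- toy$params
  (p$phi_max - p$ngam * (c_up + c_atp)) /
    (p$gam * (c_up + c_atp) + 1 / p$kappa_t)
}
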