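# Drivers for the in-silico experiments: the electron-transport-chain
# knockout panel, constrained-f_ATPS sampling, fixed-growth-rate sampling,
# and the anaerobic nitrate variant.

# Genes of the terminal oxidases plus the quinol monooxygenase; removing
# all of them leaves a strain unable to respire oxygen.
OXIDASE_GENES <- c("cydA", "cydB", "cyoA", "cyoB", "cyoC", "cyoD",
                   "appB", "appC", "ygiN")

#' Default ETC knockout panel
#'
#' The four single and four double knockouts of the dehydrogenase
#' (`ndh`, `nuoB`) and cytochrome-oxidase (`cydB`, `cyoB`) genes, the
#' all-oxidase knockout (oxidases plus `ygiN`), and the wild type.
#'
#' @return named list of gene-name vectors.
#' @export
default_knockout_panel <- function() {
  list(wt = character(0),
       ndh = "ndh", nuoB = "nuoB", cydB = "cydB", cyoB = "cyoB",
       ndh_cydB = c("ndh", "cydB"), ndh_cyoB = c("ndh", "cyoB"),
       nuoB_cydB = c("nuoB", "cydB"), nuoB_cyoB = c("nuoB", "cyoB"),
       all_oxidases = OXIDASE_GENES)
}

#' Run the ETC knockout panel
#'
#' Solves the model once per knockout set and temperature under oxygen.
#' Knocking out any subunit gene disables the whole complex (all subunits
#' are required for assembly). Aero-types are predicted from the realised
#' f_ATPS with the supplied mixture classifier.
#'
#' @param model a calibrated `aero_model`.
#' @param panel named list of gene-name vectors (default
#'   [default_knockout_panel()]).
#' @param temperatures degC to characterise at.
#' @param fit `fatps_mixture` used for aero-type assignment (default the
#'   reference classifier at the canonical peak positions).
#' @return an `aero_sample_table` with one row per (knockout set,
#'   temperature) and aero-type predictions filled in.
#' @export
run_knockout_panel <- function(model, panel = default_knockout_panel(),
                               temperatures = 37,
                               fit = reference_aerotype_fit()) {
  stopifnot(inherits(model, "aero_model"))
  flux_ids <- names(model$reactions)
  rows <- list()
  for (nm in names(panel)) {
    enz <- if (length(panel[[nm]])) genes_to_enzymes(model, panel[[nm]])
           else character(0)
    genotype <- strain_genotype(strain_id = nm, knockouts = enz)
    pm <- apply_genotype(model, genotype)
    for (temp in temperatures) {
      sol <- solve_growth(pm, growth_condition(temp, "oxygen"))
      rows[[length(rows) + 1L]] <- strain_row(sol, pm, genotype, temp,
                                              flux_ids)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$aerotype <- assign_aerotype(out$f_ATPS, fit)
  class(out) <- c("aero_sample_table", "data.frame")
  out
}

#' Strain sampling with the ATP-synthase fraction constrained
#'
#' Repeats the sampling procedure with the fraction of ATP produced by ATP
#' synthase pinned at each value of `p_values`. The strong constraint is
#' incompatible with many sampled genotypes; infeasible draws are recorded
#' (`feasible = FALSE`) and excluded from the per-band statistics.
#'
#' @param model calibrated `aero_model`.
#' @param freq mutation-frequency table.
#' @param p_values fractions to constrain at (default the five peak
#'   values).
#' @param config sampler configuration (default 24 strains per
#'   temperature).
#' @return an `aero_sample_table` with a `p_target` column; attribute
#'   `"band_stats"` holds, per band, the Spearman correlation of `q_glc`
#'   and `Y` and the mean yield over feasible rows.
#' @export
run_constrained_sampling <- function(model, freq,
                                     p_values = c(0, 0.37, 0.53, 0.64,
                                                  0.71),
                                     config = sampler_config(
                                       n_per_temperature = 24)) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  tabs <- lapply(p_values, function(p) {
    tab <- sample_strains(model, freq, config, fatps = p)
    tab$p_target <- p
    tab
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  band <- lapply(split(out, out$p_target), function(d) {
    d <- d[d$feasible, , drop = FALSE]
    data.frame(p_target = if (nrow(d)) d$p_target[1] else NA,
               n_feasible = nrow(d),
               spearman_q_Y = if (nrow(d) >= 3)
                 stats::cor(d$q_glc, d$Y, method = "spearman") else NA,
               mean_Y = if (nrow(d)) mean(d$Y) else NA)
  })
  attr(out, "band_stats") <- do.call(rbind, band)
  class(out) <- c("aero_sample_table", "data.frame")
  out
}

#' Strain sampling at fixed growth rates
#'
#' Samples at a single temperature (30 degC) with the growth rate pinned to
#' stated multiples of the wild-type optimum at 37 degC, which removes the
#' growth-rate differences that the temperature sweep induces. The pooled
#' f_ATPS distribution over all isoclines is fitted with the standard
#' zero-peak + 4-Gaussian mixture.
#'
#' @param model calibrated `aero_model`.
#' @param freq mutation-frequency table.
#' @param rates growth rates relative to the wild-type optimum at 37 degC.
#' @param config sampler configuration (strains per rate via
#'   `n_per_temperature`).
#' @param temperature degC of the fixed-rate solves.
#' @return list with `table` (an `aero_sample_table` with `mu_target` and
#'   `rel_rate` columns), `mu_wt` (the 37 degC wild-type optimum) and
#'   `fit` (the pooled mixture fit, `NULL` when too few feasible rows).
#' @export
run_fixed_growth_sampling <- function(model, freq,
                                      rates = c(0.18, 0.22, 0.36, 0.44,
                                                0.47, 0.65),
                                      config = sampler_config(
                                        n_per_temperature = 60),
                                      temperature = 30) {
  mu_wt <- solve_growth(model, growth_condition(37, "oxygen"))$mu
  tabs <- lapply(rates, function(r) {
    cfg <- config
    cfg$temperatures <- temperature
    tab <- sample_strains(model, freq, cfg,
                          fixed_growth_rate = r * mu_wt)
    tab$rel_rate <- r
    tab$mu_target <- r * mu_wt
    tab
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  class(out) <- c("aero_sample_table", "data.frame")
  f <- out$f_ATPS[out$feasible & !is.na(out$f_ATPS)]
  fit <- if (sum(f >= 0.02) >= 50) fit_fatps_mixture(f) else NULL
  list(table = out, mu_wt = mu_wt, fit = fit)
}

#' The nitrate (anaerobic) sampling experiment
#'
#' All terminal cytochrome oxidases and the quinol monooxygenase are
#' disabled, the oxygen exchange is closed, and nitrate is supplied as the
#' terminal electron acceptor. Strain sampling then proceeds as in the
#' aerobic driver; the f_ATPS distribution is fitted with a zero peak plus
#' three Gaussians, and nitro-types i..iii are assigned in ascending order
#' of the component means (the zero peak joins the lowest class).
#'
#' @param model calibrated `aero_model`.
#' @param freq mutation-frequency table.
#' @param config sampler configuration; the default 25 strains per
#'   temperature over 25..46 degC gives 550 records.
#' @return list with `table` (nitro-type-annotated `aero_sample_table`)
#'   and `fit` (zero-peak + 3-Gaussian `fatps_mixture`).
#' @export
run_nitrate_experiment <- function(model, freq,
                                   config = sampler_config(
                                     n_per_temperature = 25)) {
  enz <- genes_to_enzymes(model, OXIDASE_GENES)
  pm <- apply_genotype(model, strain_genotype(strain_id = "nitrate_host",
                                              knockouts = enz))
  tab <- sample_strains(pm, freq, config, electron_acceptor = "nitrate")
  f <- tab$f_ATPS[tab$feasible & !is.na(tab$f_ATPS)]
  fit <- fit_fatps_mixture(f, k = 3)
  tab$aerotype <- NA_character_
  ok <- tab$feasible & !is.na(tab$f_ATPS)
  tab$aerotype[ok] <- assign_nitrotype(tab$f_ATPS[ok], fit)
  list(table = tab, fit = fit)
}
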