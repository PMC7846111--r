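# In-silico strain sampling: the two-step procedure (select genes by
# mutation frequency, then draw a small random effect on catalytic
# efficiency and folding stability with opposite signs) applied across a
# temperature sweep.

#' Sampler configuration
#'
#' @param n_per_temperature strains per temperature (default 100).
#' @param temperatures degC (default the integer sweep 25..46).
#' @param selection_mode how genes are chosen for mutation: `"frequency"`
#'   (independent per-gene Bernoulli draws with the mutation-frequency
#'   table's probabilities), `"fixed_fraction"` (exactly
#'   `floor(fraction * catalog size)` genes, uniformly at random), or
#'   `"uniform"` (Bernoulli with equal probability `1/n_genes` per gene).
#' @param fixed_fraction fraction of genes mutated under
#'   `"fixed_fraction"` (0.1, 0.2 or 0.3 in the sensitivity variants).
#' @param effect_mode `"both"`, `"keff_only"` or `"dG_only"`: which effect
#'   channel a mutation carries.
#' @param keff_fold_range fold-change range for the catalytic efficiency
#'   (default `c(0.5, 2)`; sensitivity variants `c(0.1, 10)`,
#'   `c(0.01, 100)`).
#' @param master_seed integer master seed; every strain derives its own
#'   substream from it.
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(n_per_temperature = 100, temperatures = 25:46,
                           selection_mode = c("frequency", "fixed_fraction",
                                              "uniform"),
                           fixed_fraction = 0.1,
                           effect_mode = c("both", "keff_only", "dG_only"),
                           keff_fold_range = c(0.5, 2),
                           master_seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  effect_mode <- match.arg(effect_mode)
  stopifnot(n_per_temperature >= 1,
            length(keff_fold_range) == 2,
            keff_fold_range[1] < 1, keff_fold_range[2] > 1)
  structure(list(n_per_temperature = as.integer(n_per_temperature),
                 temperatures = temperatures,
                 selection_mode = selection_mode,
                 fixed_fraction = fixed_fraction,
                 effect_mode = effect_mode,
                 keff_fold_range = as.numeric(keff_fold_range),
                 master_seed = as.integer(master_seed)),
            class = "sampler_config")
}

#' Select genes for mutation
#'
#' One independent Bernoulli draw per catalog gene against its mutation
#' frequency: the gene is mutated when a uniform random number falls below
#' its per-gene probability. Uses the current RNG stream.
#'
#' @param freq a mutation-frequency table (see
#'   [make_mutation_frequency_table()]): data frame with columns `gene_id`
#'   and `prob`.
#' @return character vector of selected gene ids.
#' @export
select_mutated_genes <- function(freq) {
  stopifnot(is.data.frame(freq), all(c("gene_id", "prob") %in% names(freq)))
  if (any(freq$prob < 0 | freq$prob > 1))
    stop("mutation probabilities must lie in [0, 1]")
  freq$gene_id[stats::runif(nrow(freq)) < freq$prob]
}

#' Draw mutation effects
#'
#' The fold change on catalytic efficiency is exponentially distributed on
#' the log scale (many small effects, few large ones), symmetric in
#' direction, and truncated to the configured fold range:
#' `factor = exp(s * e)` with `e ~ Exp(rate)` truncated to
#' `[0, log(upper)]` and `s = +/-1` equiprobable. The rate is scaled so
#' the shape is preserved across variant fold ranges
#' (`rate * log(upper) = 5 log 2`). The stability offset magnitude is
#' uniform on (0, 2] kcal/mol with sign opposite to the efficiency change
#' (pleiotropy: a faster enzyme is less stable, and vice versa).
#' `effect_mode` suppresses the unused channel.
#'
#' @param config a [sampler_config()].
#' @param n number of independent draws.
#' @return data frame with columns `keff_factor`, `dG_offset`.
#' @export
draw_mutation_effect <- function(config, n = 1) {
  lo <- config$keff_fold_range[1]
  up <- config$keff_fold_range[2]
  s <- sample(c(-1, 1), n, replace = TRUE)
  emax <- ifelse(s > 0, log(up), -log(lo))
  rate <- 5 * log(2) / emax   # lambda = 5 for the default two-fold range
  u <- stats::runif(n)
  e <- -log(1 - u * (1 - exp(-rate * emax))) / rate
  factor <- exp(s * e)
  offset <- -s * stats::runif(n, 0, 2)
  if (config$effect_mode == "keff_only") offset <- rep(0, n)
  if (config$effect_mode == "dG_only") factor <- rep(1, n)
  data.frame(keff_factor = factor, dG_offset = offset)
}

# Deterministic per-strain substream seed (kept below 2^31).
strain_seed <- function(master_seed, t_index, replicate) {
  (as.numeric(master_seed) * 1009 + t_index * 131071 + replicate * 8191) %%
    2147483647
}

# Build one genotype from the current config at a given substream.
build_genotype <- function(freq, config, t_index, replicate) {
  seed <- strain_seed(config$master_seed, t_index, replicate)
  set.seed(seed)
  genes <- switch(config$selection_mode,
    frequency = select_mutated_genes(freq),
    uniform = {
      u <- freq
      u$prob <- rep(1 / nrow(freq), nrow(freq))
      select_mutated_genes(u)
    },
    fixed_fraction = {
      n_mut <- floor(config$fixed_fraction * nrow(freq))
      sample(freq$gene_id, n_mut)
    })
  eff <- draw_mutation_effect(config, length(genes))
  strain_genotype(strain_id = sprintf("T%02d_r%03d", t_index, replicate),
                  mutations = data.frame(gene_id = genes,
                                         keff_factor = eff$keff_factor,
                                         dG_offset = eff$dG_offset),
                  keff_fold_range = config$keff_fold_range,
                  seed_path = seed)
}

# Assemble one row of a sample table from a solved strain.
strain_row <- function(sol, model, genotype, temperature, flux_ids) {
  if (sol$feasible) {
    ph <- phenotype_vector(sol, model)
    fr <- compute_fractions(sol, model)
    cx <- proteome_complexity(sol, model)
    fl <- sol$fluxes[flux_ids]
    fl[is.na(fl)] <- 0
    names(fl) <- flux_ids
  } else {
    ph <- c(q_glc = NA_real_, q_ac = NA_real_, mu = 0, Y = NA_real_,
            q_o2 = NA_real_)
    fr <- list(f_ATPS = NA_real_, f_PGK = NA_real_, f_PYK = NA_real_,
               f_ACKr = NA_real_, f_PPKr = NA_real_, f_PPK2r = NA_real_,
               f_SUCOAS = NA_real_, f_PRPPS = NA_real_)
    cx <- list(n_genes_expressed = NA_integer_, avg_subunits = NA_real_)
    fl <- stats::setNames(rep(NA_real_, length(flux_ids)), flux_ids)
  }
  row <- data.frame(strain_id = genotype$strain_id,
                    T = temperature, feasible = sol$feasible,
                    mu = sol$mu, q_glc = unname(ph["q_glc"]),
                    q_ac = unname(ph["q_ac"]), q_o2 = unname(ph["q_o2"]),
                    Y = unname(ph["Y"]),
                    f_ATPS = fr$f_ATPS, f_PGK = fr$f_PGK,
                    f_PYK = fr$f_PYK, f_ACKr = fr$f_ACKr,
                    f_PPKr = fr$f_PPKr, f_PPK2r = fr$f_PPK2r,
                    f_SUCOAS = fr$f_SUCOAS, f_PRPPS = fr$f_PRPPS,
                    n_genes_expressed = cx$n_genes_expressed,
                    avg_subunits = cx$avg_subunits,
                    aerotype = NA_character_,
                    stringsAsFactors = FALSE)
  cbind(row, as.data.frame(as.list(fl), col.names = paste0("v_", flux_ids)))
}

#' Sample in-silico strains across a temperature sweep
#'
#' For every temperature and replicate: build a genotype (select genes,
#' draw effects, map to enzymes), apply it to the model, maximise growth,
#' and record the phenotype, the eight ATP-production fractions, and the
#' proteome-complexity metrics. Fully reproducible from the master seed:
#' each strain draws from its own substream, so changing one replicate
#' index changes only that strain's genotype.
#'
#' @param model a calibrated `aero_model`.
#' @param freq mutation-frequency table.
#' @param config a [sampler_config()]. The default (100 strains at each of
#'   25..46 degC) produces 2,200 records.
#' @param electron_acceptor condition for all solves.
#' @param fixed_growth_rate optional fixed growth rate (1/h) imposed on
#'   every solve.
#' @param fatps optional constrained ATP-synthase fraction (Eq.-style
#'   coupling) imposed on every solve.
#' @param progress print a line per temperature to stderr.
#' @return a data frame (`aero_sample_table`) with one row per strain:
#'   `strain_id, T, feasible, mu, q_glc, q_ac, q_o2, Y, f_ATPS, f_PGK,
#'   f_PYK, f_ACKr, f_PPKr, f_PPK2r, f_SUCOAS, f_PRPPS,
#'   n_genes_expressed, avg_subunits, aerotype`, followed by the net
#'   fluxes as `v_<reaction>` columns. Infeasible strains carry
#'   `feasible = FALSE` and `NA` phenotypes.
#' @export
sample_strains <- function(model, freq, config = sampler_config(),
                           electron_acceptor = "oxygen",
                           fixed_growth_rate = NULL, fatps = NULL,
                           progress = FALSE) {
  stopifnot(inherits(model, "aero_model"), inherits(config, "sampler_config"))
  flux_ids <- names(model$reactions)
  rows <- vector("list", length(config$temperatures) *
                   config$n_per_temperature)
  k <- 0L
  for (ti in seq_along(config$temperatures)) {
    temp <- config$temperatures[ti]
    cond <- growth_condition(temp, electron_acceptor,
                             fixed_growth_rate = fixed_growth_rate,
                             fatps = fatps)
    for (i in seq_len(config$n_per_temperature)) {
      genotype <- build_genotype(freq, config, ti, i)
      pm <- apply_genotype(model, genotype)
      sol <- tryCatch(solve_growth(pm, cond), error = function(e)
        stop("solver error for strain ", genotype$strain_id, " at T = ",
             temp, ": ", conditionMessage(e)))
      k <- k + 1L
      rows[[k]] <- strain_row(sol, pm, genotype, temp, flux_ids)
    }
    if (progress)
      message(sprintf("sampled T=%g (%d strains)", temp,
                      config$n_per_temperature))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("aero_sample_table", "data.frame")
  out
}
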