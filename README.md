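# aerotype

Stratified rate-yield fitness landscapes from proteome allocation in
*Escherichia coli*.

## The problem

When *E. coli* phenotypes are placed on the rate-yield plane — substrate
uptake rate `q` (mmol/gDW/h) against biomass yield `Y` (gDW/g) — they do
not fill the plane uniformly. Measured and simulated growth phenotypes
cluster along a few hyperbolic bands, with near-empty regions in between.
This package implements, at desk scale, the systems-biology explanation of
that stratification: cells choose among a small number of discrete ATP
production strategies, and the fraction of total ATP made by ATP synthase,

```
f_ATPS = w V_ATPS / (w V_ATPS + sum_r w_r V_r),   r in {PGK, PYK, ACKr,
                                                        PPKr, PPK2r,
                                                        SUCOAS, PRPPS}
```

is a one-dimensional coordinate for the strategy. Each band on the
rate-yield plane corresponds to a mode of the multimodal `f_ATPS`
distribution; the modes are called **aero-types** i–v (and, under
anaerobic nitrate respiration, **nitro-types** i–iii). The discreteness
arises from a proteome-allocation trade-off: high-`f_ATPS` strategies use
large multi-subunit respiratory complexes (Nuo, Cyo, ATP synthase) that
yield more ATP per glucose but cost more proteome per unit flux, while
low-`f_ATPS` strategies run cheap single-subunit enzymes (Ndh, Cyd,
acetate/lactate overflow) at high substrate throughput.

## What the package provides

- A coarse-grained (~30 reaction) model of *E. coli* central carbon and
  energy metabolism with explicit alternatives at every
  electron-transport step, a two-state folding model giving each enzyme a
  temperature-dependent active fraction, and a proteome budget coupling
  flux to enzyme cost. Growth is maximised by bisection over a linear
  feasibility program (`solve_growth`), solved by a compiled dense
  simplex.
- In-silico strain sampling (`sample_strains`): genes are mutated with
  the per-gene frequencies observed across a 1,765-strain panel and each
  mutation perturbs catalytic efficiency (exponential small effects,
  0.5–2 fold) and folding stability (±2 kcal/mol, opposite sign), across
  a 25–46 °C sweep; the default run emits 2,200 strains.
- ATP accounting (`compute_fractions`), the linear coupling that pins
  `f_ATPS` to a chosen value during a solve (`build_fatps_constraint`,
  via `growth_condition(fatps = p)`), yields, phenotypic distance and the
  P/O ratio.
- Landscape statistics: zero-peak + Gaussian mixture fitting of `f_ATPS`
  (`fit_fatps_mixture`), BIC scans, aero-type assignment, forward
  stepwise variance decomposition, proteome-complexity metrics, flux PCA
  and the rate-yield feasibility envelope.
- The in-silico experiments: ETC knockout panel (`run_knockout_panel`),
  constrained-`f_ATPS` sampling (`run_constrained_sampling`),
  fixed-growth-rate sampling (`run_fixed_growth_sampling`) and the
  nitrate/nitro-type experiment (`run_nitrate_experiment`).
- Downstream expression statistics from a counts matrix: TPM/log-TPM,
  replicate QC, phenotype-correlated gene selection, exact one-sided
  binomial gene-set enrichment, hierarchical clustering.
- Synthetic-data generators for every input (mutation-frequency table,
  `f_ATPS` samples, expression fixture with planted ground truth), so the
  whole pipeline runs without downloads.

## Worked example

```r
library(aerotype)

model <- load_model_spec(default_model_path())   # shipped calibrated model
sol <- solve_growth(model, growth_condition(temperature = 37))
print(sol)
#> Flux solution: mu = 0.8713 1/h (feasible), T = 37 degC, oxygen
phenotype_vector(sol, model)
#>      q_glc       q_ac         mu          Y       q_o2
#>  9.3867156  7.5361236  0.8713343  0.5152438 12.6334290
f <- compute_fractions(sol, model)
f$f_ATPS
#> [1] 0.6472743
```

The wild type at 37 °C grows at 0.87/h on 9.4 mmol/gDW/h glucose with
yield 0.52 gDW/g, running the proton-pumping chain (Nuo + Cyo) with
moderate acetate overflow; ATP synthase makes 65% of its ATP. The ETC
knockout panel shows the aero-type logic — removing the proton-pumping
branch lowers `f_ATPS`, yield and aero-type, and removing every terminal
oxidase leaves a fermentative aero-type i strain:

```r
run_knockout_panel(model)[, c("strain_id", "mu", "q_glc", "Y",
                              "f_ATPS", "aerotype")]
#>       strain_id    mu q_glc     Y f_ATPS aerotype
#> 1            wt 0.871  9.39 0.515  0.647       iv
#> 3          nuoB 0.857 12.26 0.388  0.461      iii
#> 5          cyoB 0.814  9.95 0.454  0.570      iii
#> 9     nuoB_cyoB 0.765 13.67 0.311  0.293       ii
#> 10 all_oxidases 0.483 24.40 0.110  0.000        i
```

The full landscape comes from the default sweep (about half a minute):

```r
freq <- make_mutation_frequency_table(synthetic_config(), seed = 1)
tab <- sample_strains(model, freq, sampler_config(master_seed = 11))
fit <- fit_fatps_mixture(tab$f_ATPS[tab$feasible])
tab$aerotype <- assign_aerotype(tab$f_ATPS, fit)
```

A command-line interface wraps the same functions
(`exec/aerotype <subcommand>`): `synth`, `sample`, `constrain`, `fixmu`,
`knockout`, `nitrate`, `analyze`, `expression`; every run writes a
manifest with seeds and file digests.

## Acceptance script

`scripts/acceptance.R` recomputes the acceptance targets from scratch with
the installed package — it draws synthetic `f_ATPS` samples at the four
published peak positions and reports the largest fitted mixture mean, and
solves the calibrated wild type at 37 °C with the coupling constraint at
the median peak value and reports the realised `f_ATPS`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Limitations

The model is a deliberate coarse-graining: ~30 lumped reactions instead of
a genome-scale reconstruction, spontaneous two-state folding without
chaperones, and temperature acting only through folding. Mode positions of
the `f_ATPS` mixture are therefore calibration-dependent; the package's
claims are the structural ones (stratification, ordering, signs and
monotonicity), not the genome-scale peak coordinates. See the methods
vignette (`vignettes/aerotype-methods.Rmd`) for the full model description
and design rationale.
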