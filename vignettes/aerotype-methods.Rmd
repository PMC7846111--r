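---
title: "Methods: the coarse proteome-allocation model and the aero-type pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coarse proteome-allocation model and the aero-type pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind the package, the assumptions and
numerical choices it makes, and what its synthetic data do and do not
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The growth model

Growth is modelled as a linear program over net reaction fluxes
`v` (mmol/gDW/h) of a ~30-reaction lumped network of *E. coli* central
carbon and energy metabolism, subject to:

1. **Steady-state mass balance** on every internal metabolite, with the
   biomass reaction fixed at flux `mu` (1/h) and a constant maintenance
   drain (NGAM).
2. **Proteome coupling**: each catalysed reaction consumes enzyme in
   proportion to its flux,
   `sum_i |v_i| MW_i / (k_eff_i * 3600 * f_fold_i(T)) + mu / kappa_t <= phi_max`,
   with MW in kDa (= g/mmol), `k_eff` in 1/s, and `mu / kappa_t` the
   ribosome share of the budget.
3. Optionally, a **fixed growth rate** and/or the **f_ATPS coupling**
   `(1 - p) w V_ATPS = p * sum_(r != ATPS) w_r V_r` over the
   eight-reaction ATP-production registry (all weights `w` are 1 in the
   default network). The coupling acts on net (forward minus backward)
   fluxes so that futile forward/backward cycling cannot fake ATP
   production; since no registry reaction can run net-backward in this
   network, the constraint coincides exactly with the realised fraction.

`solve_growth()` maximises `mu` by bisection (tolerance 1e-6 1/h, at most
60 iterations) with a linear feasibility program at each trial value, then
re-solves at the optimum minimising total enzyme mass so that alternate
optima are resolved deterministically (a vanishing uniform flux penalty,
1e-9, additionally suppresses zero-cost cycles). The LP is solved by a
dense two-phase simplex with Bland's anti-cycling rule (compiled,
`src/simplex.cpp`), with rows equilibrated to unit max-norm because
stoichiometric coefficients (order 1–100) and enzyme costs (order 1e-4)
would otherwise share pivot tolerances badly. The simplex is
property-tested against a brute-force basic-solution enumerator and
against `boot::simplex`.

### Network content

Every reaction whose ATP output is tracked individually is explicit: the
registry `ATPS4rpp, PGK, PYK, ACKr, PPKr, PPK2r, SUCOAS, PRPPS` in the
fixed order. So is every electron-transport alternative whose usage
defines the aero-type: NADH dehydrogenases Nuo (13 subunits, 4 charges per
NADH) versus Ndh (single subunit, no translocation); terminal oxidases Cyo
(4 charges per quinol) versus Cyd/App (2) versus the quinol monooxygenase
YgiN (0); and the nitrate branch Nar (2 charges), Fdn (formate to quinol,
2 charges) and the NADH-nitrite reductase NirAB. Proton-motive bookkeeping
uses a single pseudo-metabolite, translocated charge, consumed by ATP
synthase at `charge_per_atp` per ATP.

Three valves keep fermentative redox balance honest:

- **PFL** (pyruvate formate-lyase) is only active without oxygen — the
  glycyl-radical enzyme is destroyed by O2 in vivo.
- **LDH** (lactate overflow) is the NADH sink that lets oxidase-free
  mutants grow aerobically, as cytochrome-oxidase deletion strains do.
- **FRD**, a lump of the reductive succinate branch (PEP carboxylase,
  malate dehydrogenase, fumarase, fumarate reductase), disposes of the
  redox generated en route to biosynthetic precursors. Fumarate reduction
  runs on the menaquinol pool, which is folded into the lump, so it does
  not couple to the proton-pumping ubiquinol chain: with every oxidase
  removed, ATP synthase flux is exactly zero.

Two deliberate simplifications avoid degenerate optima: the NADPH made by
isocitrate dehydrogenase is lumped into NADH inside the TCA oxidative arm,
and no transhydrogenases are modelled. With a reversible transhydrogenase
the cyclic oxidative pentose-phosphate pathway could oxidise glucose fully
with no substrate-level ATP, pushing the maximal stoichiometric f_ATPS to
~0.95 and making the 0.83 calibration anchor unreachable; with NADPH's
only sink being biomass, the cyclic flux is capped by biosynthetic demand.
Acetate is secretion-only (no external acetate exists on glucose minimal
medium), which also removes a spurious f_ATPS-raising import route.

### Temperature

Temperature acts only through folding. Each enzyme carries one stability
number, `dG_ref` (kcal/mol at 37 °C); the full curve is Gibbs–Helmholtz
with a fixed heat-capacity change (2 kcal/mol/K) and melting temperature
`Tm = 310.15 K + 2 * dG_ref`, and the active fraction is the two-state
equilibrium `1 / (1 + exp(-dG(T) / RT))`. Catalytic turnover itself is
temperature-independent — a stated simplification; it flattens the
low-temperature side of the fitness curve but preserves the qualitative
25–46 °C behaviour, which is what the analyses use. The stability ladder
is chosen so the large respiratory complexes fail first as temperature
rises (Nuo ~43 °C, Cyo ~44 °C, the TCA lumps ~45 °C), producing the
strategy switches that stratify the temperature sweep.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `phi_max` | 0.40 | mass fraction | enzyme + ribosome budget |
| `kappa_t` | 4.5 | 1/h per mass fraction | translation capacity |
| `gam` | 70 | mmol ATP/gDW | growth-associated ATP cost (includes biosynthesis ATP not modelled explicitly) |
| `ngam` | 5 | mmol ATP/gDW/h | maintenance |
| `substrate_mw` | 0.18016 | g/mmol | glucose mass for yields |
| `charge_per_atp` | calibrated (≈4.26) | — | ATP synthase stoichiometry |

`calibrate_wildtype()` fixes the single free constant, `charge_per_atp`,
by monotone root finding so that the maximal stoichiometric f_ATPS over
the flux polytope equals 0.83, and verifies that the wild-type optimum at
37 °C lies in the highest-f_ATPS regime (f_ATPS ≥ 0.60). Because the root
find always starts from the same bracket, calibration is deterministic and
idempotent. The budget, translation and maintenance constants keep their
defaults, which already satisfy the wild-type placement target. Enzyme
turnover numbers are effective in vivo values tuned once so that the
competing ATP strategies are within ~5% of each other in proteome cost per
ATP at 37 °C — the regime in which small (0.5–2 fold) mutations and
folding losses flip strategies and stratify the landscape. The shipped
`inst/extdata/ecoli_coarse_model.json` is the calibrated model.

## Strain sampling

The two-step procedure: (1) each catalog gene is mutated independently
with its per-strain mutation probability; (2) each mutated gene perturbs
its enzyme's `k_eff` by `exp(s e)` with `e ~ Exp(5)` truncated to
`[0, log 2]` and `s = ±1` equiprobable (rescaled for the wider
sensitivity-variant fold ranges so the shape is preserved), and its
`dG_ref` by a uniform amount up to 2 kcal/mol with the opposite sign.
Multiple mutated genes of one enzyme compose multiplicatively (factors,
clipped to the configured range) and additively (offsets); catalog genes
not in the coarse model are silent. 100 strains at each integer
temperature 25–46 °C give the default 2,200 records.

Two readings of the written sampling rule were possible. The mutation
frequency of a gene could be its share of all 266,940 observed mutations
(summing to 1 over genes, hence about one mutated gene per strain) or its
per-strain frequency across the 1,765-strain panel (count/1765, about 150
mutated genes per strain). The package uses the per-strain frequency: it
is what "probability of harboring a mutation per sampled strain" means, it
matches the mutated-gene load natural isolates actually carry, and it
gives strains the genotypic diversity that the fixed-growth-rate analyses
(variation along an isocline) require. The exponential effect draw is
implemented on the log scale of the fold change, which honours both the
stated bounds and the motivation of many small and few large effects.

Reproducibility: every strain derives its own substream seed from
(master seed, temperature index, replicate index), so changing one
replicate's index changes only that strain's genotype.

## Mixture fitting and aero-types

Values below 0.02 form the fermentative point mass at zero (the paper-gap
choice of a tolerance for "f_ATPS = 0 as one peak"); the rest are fitted
with k Gaussians (k = 4 aerobic, k = 3 nitrate) by EM with a standard
deviation floor of 1e-4 (the coarse model produces genuinely atomic
strategy vertices, so near-degenerate components are legitimate), a
relative log-likelihood tolerance of 1e-10, and 50 deterministic restarts.
Restart r initialises component means at data quantiles on a shifted
probability grid refined by k-means with explicit starting centres; this
is deterministic and invariant to duplicating the input. Components are
reported sorted by mean; aero-types map the zero peak to class i and each
value to its maximum-posterior component (ties to the lower label).
Nitro-types use the same rule with three components, the zero peak joining
the lowest class. For knockout predictions, where no sampling run is in
hand, `reference_aerotype_fit()` provides the fixed classifier at the
canonical peak positions (0.37, 0.53, 0.64, 0.71, sd 0.02).

Other analysis choices: forward stepwise regression enters the predictor
with the smallest partial-F p-value below 0.05 and stops when none
qualifies, with rank-deficient additions skipped and recorded; the
regression response pools all temperatures (the per-temperature
alternative was considered and rejected for sample-size reasons);
phenotypic distance divides the four-element vector (q_glc, q_ac, mu, Y)
by the wild-type reference before taking the Euclidean norm, since raw
units are incommensurable; `avg_subunits` is the unweighted mean over
expressed enzymes (the axis label reads "average number of subunits per
enzyme", and concentration weighting is not stated); yields are
`Y = mu / (q m)` — the only reading with units gDW/g; "not correlated with
growth rate" in gene selection means Pearson p ≥ 0.01, the same threshold
as the positive criteria. Gene-set enrichment uses the exact binomial
upper tail with the selected/universe proportion as the null (the only
proportions printed; whether a different background was used is unknown,
so the report states this assumption).

## What the synthetic data emulate — and what they do not

- The **mutation-frequency table** draws per-gene counts from a negative
  binomial (dispersion 0.5) rescaled to exactly 266,940, giving a heavy
  tail in which the top decile of genes carries >40% of mutations. It
  emulates the shape of the observed per-gene distribution, not its
  actual gene identities: which biological gene is highly mutated is
  random under the seed.
- The **expression fixture** plants two yield-separated strain groups,
  50 signal genes tracking yield (and therefore acetate production) but
  not growth rate, duplicate replicates, and counts generated by
  inverting the TPM definition at 5e6 reads/sample. At the spec's 1e6
  depth the count noise of short low-expressed genes caps replicate
  log-TPM R² at ~0.969, just below the stated >0.97 QC target, so the
  default depth is 5e6 (typical for bacterial RNA-seq); the replicate
  noise sd (0.05) is the designated calibration knob for that target.
  A green test on the fixture establishes that the statistics recover a
  known planted structure — not that real expression data have that
  structure.
- Synthetic **f_ATPS samples** are a stated mixture with a point mass at
  zero, truncated to (0, 0.9]; they validate the fitting stage's
  parameter recovery, nothing about the model.

## Known limitations

- Mode positions of the coarse model's f_ATPS mixture are
  calibration-dependent; only the structure (number of modes, ordering,
  slope signs, monotonicity of complexity) is claimed. The genome-scale
  peak coordinates are not reproduced, by design.
- Because LP optima sit on vertices, strategies are atomic: within one
  strategy the fitted component standard deviations can hit the 1e-4
  floor. The genome-scale system's smooth peaks come from heterogeneity a
  30-reaction lump cannot represent.
- Growth below 37 °C is temperature-independent (no Arrhenius scaling of
  turnover), so the low-temperature shrinkage of the accessible rate-yield
  region is not reproduced.
- The constrained-sampling feasibility count of the original study is
  model-dependent and out of scope; the package reports its own
  feasibility per band.
- The polyphosphate kinases and PRPP synthetase are present and allowed to
  produce ATP but carry no net flux in the default network (PRPP demand is
  lumped into the r5p biomass draw so that no registry reaction runs
  net-backward, keeping the fraction constraint exact).
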