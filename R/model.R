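# Coarse-grained proteome-allocation model of E. coli energy metabolism.
#
# The network lumps central carbon metabolism into ~30 reactions while
# keeping explicit every reaction whose ATP output is tracked individually
# (the eight-reaction ATP-production registry) and every electron-transport
# alternative whose usage defines the aero-type (Nuo/Ndh, Cyo/Cyd/App/YgiN,
# Nar/Fdn/NirAB). Proton-motive bookkeeping uses a single pseudo-metabolite
# "chg" (translocated charge) produced by translocating ETC complexes and
# consumed by ATP synthase.

ATP_REGISTRY <- c("ATPS4rpp", "PGK", "PYK", "ACKr",
                  "PPKr", "PPK2r", "SUCOAS", "PRPPS")

#' Construct a reaction specification
#'
#' @param id short reaction identifier.
#' @param name free-text name.
#' @param stoichiometry named numeric vector, metabolite -> signed
#'   coefficient (mmol per unit flux). Metabolites suffixed `_e` are
#'   external and not mass-balanced.
#' @param atp_produced mol ATP produced per unit forward flux (only
#'   reactions in the ATP registry may have a positive value).
#' @param reversible logical.
#' @param enzyme id of the catalysing enzyme, or `NA` for spontaneous
#'   transport/exchange steps.
#' @param pathway one of glycolysis, oxPPP, TCA, fermentation, oxphos,
#'   biosynthesis, exchange, biomass.
#' @return a list of class `aero_reaction`.
#' @export
reaction_spec <- function(id, name, stoichiometry, atp_produced = 0,
                          reversible = FALSE, enzyme = NA_character_,
                          pathway = "exchange") {
  pathways <- c("glycolysis", "oxPPP", "TCA", "fermentation", "oxphos",
                "biosynthesis", "exchange", "biomass")
  stopifnot(is.character(id), length(id) == 1L,
            is.numeric(stoichiometry), !is.null(names(stoichiometry)),
            atp_produced >= 0, is.logical(reversible))
  if (!pathway %in% pathways)
    stop("unknown pathway tag '", pathway, "'")
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 atp_produced = as.numeric(atp_produced),
                 reversible = isTRUE(reversible),
                 enzyme = enzyme, pathway = pathway),
            class = "aero_reaction")
}

#' Construct an enzyme specification
#'
#' @param id enzyme (complex) identifier.
#' @param genes character vector of catalog gene identifiers.
#' @param mw molecular weight of the functional complex (kDa).
#' @param n_subunits number of polypeptide chains in the complex
#'   (distinct polypeptides times copy number).
#' @param k_eff effective catalytic turnover (1/s).
#' @param dG_ref unfolding free energy at 37 degC (kcal/mol, > 0 stable).
#' @param category one of dehydrogenase, oxidase, reductase, synthase,
#'   soluble.
#' @return a list of class `aero_enzyme`.
#' @export
enzyme_spec <- function(id, genes, mw, n_subunits, k_eff, dG_ref,
                        category = "soluble") {
  categories <- c("dehydrogenase", "oxidase", "reductase", "synthase",
                  "soluble")
  if (!category %in% categories)
    stop("unknown enzyme category '", category, "'")
  if (mw <= 0 || k_eff <= 0 || n_subunits < 1)
    stop("enzyme '", id, "': require mw > 0, k_eff > 0, n_subunits >= 1")
  structure(list(id = id, genes = as.character(genes), mw = as.numeric(mw),
                 n_subunits = as.integer(n_subunits),
                 k_eff = as.numeric(k_eff), dG_ref = as.numeric(dG_ref),
                 category = category),
            class = "aero_enzyme")
}

#' Assemble and validate a model
#'
#' @param reactions list of [reaction_spec()] objects.
#' @param enzymes list of [enzyme_spec()] objects.
#' @param params named list of global parameters: `phi_max` (enzyme +
#'   ribosome proteome budget, mass fraction), `kappa_t` (translation
#'   capacity, 1/h per ribosome mass fraction), `gam` (growth-associated
#'   ATP cost, mmol/gDW), `ngam` (maintenance, mmol/gDW/h), `substrate_mw`
#'   (g/mmol), `charge_per_atp` (translocated charges consumed per ATP by
#'   ATP synthase).
#' @param atp_registry ordered ids of the eight ATP-producing reactions.
#' @return a list of class `aero_model`.
#' @export
model_spec <- function(reactions, enzymes, params,
                       atp_registry = ATP_REGISTRY) {
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  names(enzymes) <- vapply(enzymes, `[[`, "", "id")
  mets <- sort(unique(unlist(lapply(reactions, function(r)
    names(r$stoichiometry)))))
  internal <- mets[!grepl("_e$", mets)]
  model <- structure(list(metabolites = internal, reactions = reactions,
                          enzymes = enzymes, atp_registry = atp_registry,
                          params = params),
                     class = "aero_model")
  validate_model(model)
  model
}

#' Validate model invariants
#'
#' Checks the structural invariants of an `aero_model`: the eight-entry
#' ATP registry in fixed order, ATP production restricted to registry
#' reactions, enzyme references resolving, positive enzyme parameters, and
#' network connectivity (a nonzero steady-state flux with glucose uptake
#' exists).
#'
#' @param model an `aero_model`.
#' @return the model, invisibly; errors name the violated field.
#' @export
validate_model <- function(model) {
  if (length(model$atp_registry) != 8L ||
      !identical(as.character(model$atp_registry), ATP_REGISTRY))
    stop("atp_registry: must contain exactly the 8 registry reactions ",
         "in the fixed order ", paste(ATP_REGISTRY, collapse = ", "))
  rids <- names(model$reactions)
  missing <- setdiff(model$atp_registry, rids)
  if (length(missing))
    stop("atp_registry: reactions absent from the model: ",
         paste(missing, collapse = ", "))
  for (r in model$reactions) {
    if (r$atp_produced > 0 && !r$id %in% model$atp_registry)
      stop("reaction ", r$id,
           ": atp_produced > 0 outside the ATP registry")
    if (!is.na(r$enzyme) && !r$enzyme %in% names(model$enzymes))
      stop("reaction ", r$id, ": unknown enzyme '", r$enzyme, "'")
  }
  for (e in model$enzymes)
    if (e$mw <= 0 || e$k_eff <= 0 || e$n_subunits < 1)
      stop("enzyme ", e$id, ": invalid mw/k_eff/n_subunits")
  req <- c("phi_max", "kappa_t", "gam", "ngam", "substrate_mw",
           "charge_per_atp")
  miss <- setdiff(req, names(model$params))
  if (length(miss))
    stop("params: missing ", paste(miss, collapse = ", "))
  invisible(model)
}

#' @export
print.aero_model <- function(x, ...) {
  cat("Coarse proteome-allocation model:",
      length(x$reactions), "reactions,",
      length(x$metabolites), "internal metabolites,",
      length(x$enzymes), "enzymes\n")
  cat("ATP registry:", paste(x$atp_registry, collapse = ", "), "\n")
  cat(sprintf("phi_max = %.3f, kappa_t = %.2f /h, GAM = %.1f, NGAM = %.2f, charge/ATP = %.3f\n",
              x$params$phi_max, x$params$kappa_t, x$params$gam,
              x$params$ngam, x$params$charge_per_atp))
  invisible(x)
}

# Default enzyme table. MW (kDa) and subunit counts follow the E. coli
# complexes they stand for; k_eff values are effective in vivo turnovers
# tuned so that the wild-type optimum at 37 degC is fully respiratory while
# alternative electron-transport strategies remain within reach of small
# (0.5-2 fold) efficiency perturbations. dG_ref sets the temperature at
# which each complex is lost: the large respiratory complexes (Nuo, Cyo)
# unfold first, the small single-gene enzymes last.
default_enzymes <- function() {
  E <- list(
    enzyme_spec("PtsG",  c("ptsG", "crr"), 78, 2, 5, 8, "soluble"),
    enzyme_spec("Pfk",   c("pgi", "pfkA", "fbaA", "tpiA"), 160, 4, 30, 8,
                "soluble"),
    enzyme_spec("Gap",   c("gapA", "pgk", "gpmA", "eno"), 170, 4, 25, 9,
                "dehydrogenase"),
    enzyme_spec("PykF",  "pykF", 204, 4, 40, 8, "soluble"),
    enzyme_spec("Pdh",   c("aceE", "aceF", "lpdA"), 450, 3, 60, 6,
                "dehydrogenase"),
    enzyme_spec("PflB",  "pflB", 85, 1, 40, 8, "soluble"),
    enzyme_spec("AckA",  c("pta", "ackA"), 130, 2, 60, 9, "soluble"),
    enzyme_spec("AdhE",  "adhE", 96, 1, 35, 8, "dehydrogenase"),
    enzyme_spec("LdhA",  "ldhA", 140, 4, 50, 8, "dehydrogenase"),
    enzyme_spec("Frd",   c("frdA", "frdB", "frdC", "frdD"), 120, 4, 50, 7,
                "reductase"),
    # the AKGDH multienzyme core dominates the subunit count of this lump
    enzyme_spec("Tca1",  c("gltA", "acnA", "acnB", "icd", "sucA", "sucB"),
                480, 18, 32, 4, "dehydrogenase"),
    enzyme_spec("SucCD", c("sucC", "sucD"), 142, 4, 40, 6, "soluble"),
    enzyme_spec("Tca2",  c("sdhA", "sdhB", "sdhC", "sdhD", "fumA", "fumB",
                           "fumC", "mdh"), 400, 8, 32, 4, "dehydrogenase"),
    enzyme_spec("Zwf",   c("zwf", "pgl", "gnd"), 190, 3, 35, 7,
                "dehydrogenase"),
    enzyme_spec("Tkt",   c("tktA", "tktB", "talB"), 150, 3, 50, 8,
                "soluble"),
    enzyme_spec("Prs",   "prs", 210, 6, 20, 8, "soluble"),
    enzyme_spec("Ppk",   "ppk", 320, 4, 15, 8, "soluble"),
    enzyme_spec("Ppk2",  "ppk2", 120, 2, 15, 8, "soluble"),
    enzyme_spec("Nuo",   paste0("nuo", LETTERS[1:13]), 536, 13, 90, 3,
                "dehydrogenase"),
    enzyme_spec("Ndh",   "ndh", 47, 1, 120, 9, "dehydrogenase"),
    enzyme_spec("Cyo",   c("cyoA", "cyoB", "cyoC", "cyoD"), 144, 4, 150, 3.5,
                "oxidase"),
    enzyme_spec("Cyd",   c("cydA", "cydB"), 100, 2, 90, 7, "oxidase"),
    enzyme_spec("App",   c("appB", "appC"), 110, 2, 60, 7, "oxidase"),
    enzyme_spec("YgiN",  "ygiN", 12, 1, 80, 8, "oxidase"),
    enzyme_spec("AtpSyn", paste0("atp", LETTERS[1:8]), 530, 22, 200, 6,
                "synthase"),
    enzyme_spec("Nar",   c("narG", "narH", "narI"), 230, 3, 110, 6,
                "reductase"),
    enzyme_spec("Fdn",   c("fdnG", "fdnH", "fdnI"), 166, 3, 90, 4,
                "dehydrogenase"),
    enzyme_spec("NirAB", c("nirB", "nirD"), 105, 2, 60, 7, "reductase"),
    enzyme_spec("NarK",  "narK", 50, 1, 20, 8, "soluble")
  )
  names(E) <- vapply(E, `[[`, "", "id")
  E
}

default_reactions <- function(gam, charge_per_atp) {
  list(
    # glucose import by the PTS: phosphotransfer from PEP
    reaction_spec("GLCpts", "glucose PTS uptake",
                  c(glc_e = -1, pep = -1, g6p = 1, pyr = 1),
                  enzyme = "PtsG", pathway = "glycolysis"),
    # upper glycolysis lump (PGI..TPI): one ATP invested at PFK
    reaction_spec("PFK", "upper glycolysis (PGI+PFK+FBA+TPI)",
                  c(g6p = -1, atp = -1, g3p = 2),
                  enzyme = "Pfk", pathway = "glycolysis"),
    # lower glycolysis lump with the PGK substrate-level phosphorylation
    reaction_spec("PGK", "lower glycolysis (GAPD+PGK+PGM+ENO)",
                  c(g3p = -1, nadh = 1, atp = 1, pep = 1),
                  atp_produced = 1, enzyme = "Gap", pathway = "glycolysis"),
    reaction_spec("PYK", "pyruvate kinase",
                  c(pep = -1, atp = 1, pyr = 1),
                  atp_produced = 1, enzyme = "PykF", pathway = "glycolysis"),
    reaction_spec("PDH", "pyruvate dehydrogenase",
                  c(pyr = -1, nadh = 1, accoa = 1, co2_e = 1),
                  enzyme = "Pdh", pathway = "TCA"),
    reaction_spec("PFL", "pyruvate formate-lyase",
                  c(pyr = -1, accoa = 1, fora = 1),
                  enzyme = "PflB", pathway = "fermentation"),
    # acetate overflow lump (PTA+ACKr); secretion only, since no external
    # acetate is available on glucose minimal medium
    reaction_spec("ACKr", "acetate overflow (PTA+ACKr)",
                  c(accoa = -1, atp = 1, ac_e = 1),
                  atp_produced = 1, enzyme = "AckA",
                  pathway = "fermentation"),
    reaction_spec("ADHEr", "ethanol fermentation (ALDH+ADH)",
                  c(accoa = -1, nadh = -2, etoh_e = 1),
                  enzyme = "AdhE", pathway = "fermentation"),
    # homolactic overflow: the NADH sink of oxidase-free aerobic mutants
    reaction_spec("LDH", "D-lactate dehydrogenase",
                  c(pyr = -1, nadh = -1, lac_e = 1),
                  enzyme = "LdhA", pathway = "fermentation"),
    # reductive succinate branch (PPC+MDH+FUM+FRD lump): disposes of the
    # redox generated en route to biosynthetic precursors. Fumarate
    # reduction runs on the menaquinol pool, which is folded into the lump
    # (no translocated charge), separate from the ubiquinol pool q8h2.
    reaction_spec("FRD", "fumarate reductase branch (PPC+MDH+FUM+FRD)",
                  c(pep = -1, nadh = -2, succ_e = 1),
                  enzyme = "Frd", pathway = "fermentation"),
    # oxidative TCA arm: CS..AKGDH; ICDH's NADPH is lumped into NADH so
    # that the arm is not conditioned on a biosynthetic NADPH sink
    reaction_spec("TCA1", "TCA oxidative arm (CS+ACN+ICD+AKGDH)",
                  c(accoa = -1, succoa = 1, nadh = 3, co2_e = 2),
                  enzyme = "Tca1", pathway = "TCA"),
    reaction_spec("SUCOAS", "succinyl-CoA synthetase",
                  c(succoa = -1, succ = 1, atp = 1),
                  atp_produced = 1, reversible = TRUE,
                  enzyme = "SucCD", pathway = "TCA"),
    # reductive arm back to oxaloacetate: SDH feeds the quinone pool
    reaction_spec("TCA2", "TCA reductive arm (SDH+FUM+MDH)",
                  c(succ = -1, q8h2 = 1, nadh = 1),
                  enzyme = "Tca2", pathway = "TCA"),
    reaction_spec("OXPPP", "oxidative pentose-phosphate lump (G6PDH+PGL+GND)",
                  c(g6p = -1, r5p = 1, nadph = 2, co2_e = 1),
                  enzyme = "Zwf", pathway = "oxPPP"),
    # non-oxidative PPP lump: pentose recycled to hexose equivalents
    reaction_spec("TKT", "non-oxidative PPP (TKT+TAL)",
                  c(r5p = -1, g6p = 5 / 6),
                  enzyme = "Tkt", pathway = "oxPPP"),
    # written in the ATP-producing direction; physiological flux is reverse
    reaction_spec("PRPPS", "ribose-phosphate diphosphokinase",
                  c(prpp = -1, r5p = 1, atp = 1),
                  atp_produced = 1, reversible = TRUE,
                  enzyme = "Prs", pathway = "biosynthesis"),
    reaction_spec("PPKr", "polyphosphate kinase",
                  c(polyp = -1, atp = 1),
                  atp_produced = 1, reversible = TRUE,
                  enzyme = "Ppk", pathway = "oxphos"),
    reaction_spec("PPK2r", "polyphosphate kinase 2",
                  c(polyp = -1, atp = 1),
                  atp_produced = 1, reversible = TRUE,
                  enzyme = "Ppk2", pathway = "oxphos"),
    # NADH -> quinone, proton-translocating complex I
    reaction_spec("NADH16pp", "NADH:quinone oxidoreductase I (Nuo)",
                  c(nadh = -1, q8h2 = 1, chg = 4),
                  enzyme = "Nuo", pathway = "oxphos"),
    # NADH -> quinone, non-translocating single-subunit dehydrogenase
    reaction_spec("NADH5", "NADH dehydrogenase II (Ndh)",
                  c(nadh = -1, q8h2 = 1),
                  enzyme = "Ndh", pathway = "oxphos"),
    reaction_spec("CYTBO3", "cytochrome bo oxidase",
                  c(q8h2 = -1, o2 = -0.5, chg = 4),
                  enzyme = "Cyo", pathway = "oxphos"),
    reaction_spec("CYTBD", "cytochrome bd-I oxidase",
                  c(q8h2 = -1, o2 = -0.5, chg = 2),
                  enzyme = "Cyd", pathway = "oxphos"),
    reaction_spec("CYTBD2", "cytochrome bd-II oxidase",
                  c(q8h2 = -1, o2 = -0.5, chg = 2),
                  enzyme = "App", pathway = "oxphos"),
    reaction_spec("QMO", "quinol monooxygenase (YgiN)",
                  c(q8h2 = -1, o2 = -0.5),
                  enzyme = "YgiN", pathway = "oxphos"),
    reaction_spec("ATPS4rpp", "ATP synthase",
                  c(chg = -charge_per_atp, atp = 1),
                  atp_produced = 1, enzyme = "AtpSyn", pathway = "oxphos"),
    reaction_spec("NAR", "nitrate reductase A/Z",
                  c(q8h2 = -1, no3 = -1, no2 = 1, chg = 2),
                  enzyme = "Nar", pathway = "oxphos"),
    reaction_spec("FDN", "formate dehydrogenase N/O",
                  c(fora = -1, q8h2 = 1, chg = 2, co2_e = 1),
                  enzyme = "Fdn", pathway = "oxphos"),
    reaction_spec("NIRAB", "NADH-nitrite reductase (NirAB)",
                  c(no2 = -1, nadh = -3, nh4_e = 1),
                  enzyme = "NirAB", pathway = "oxphos"),
    reaction_spec("O2t", "oxygen uptake", c(o2 = 1, o2_e = -1),
                  pathway = "exchange"),
    reaction_spec("NO3t", "nitrate uptake", c(no3 = 1, no3_e = -1),
                  pathway = "exchange"),
    # nitrite leaves through the NarK antiporter, so disposing of it by
    # export competes on proteome cost with reduction through NirAB
    reaction_spec("NO2t", "nitrite export (NarK)", c(no2 = -1, no2_e = 1),
                  enzyme = "NarK", pathway = "exchange"),
    reaction_spec("FORt", "formate export", c(fora = -1, for_e = 1),
                  pathway = "exchange"),
    reaction_spec("ATPM", "non-growth maintenance drain",
                  c(atp = -1), pathway = "biomass"),
    # biomass: precursor demands (mmol/gDW) plus the growth-associated
    # ATP cost; flux equals the growth rate (1/h)
    # nucleotide demand is drawn as r5p; PRPP synthesis is lumped into it
    # so that no registry reaction runs net-backward physiologically
    reaction_spec("BIOMASS", "biomass assembly",
                  c(g6p = -0.3, g3p = -0.13, pep = -1.5, pyr = -2.8,
                    accoa = -3.7, r5p = -1.3, nadph = -12,
                    atp = -gam, biomass_e = 1),
                  pathway = "biomass")
  )
}

#' Build the default coarse model
#'
#' Constructs the shipped ~30-reaction lumped network of *E. coli* central
#' carbon and energy metabolism: PTS uptake, upper/lower glycolysis with
#' explicit PGK and PYK, oxidative PPP, a two-arm TCA lump with explicit
#' SUCOAS, acetate and ethanol fermentation, the polyphosphate and PRPP
#' kinases, both NADH dehydrogenases (Nuo/Ndh), four terminal oxidases
#' (Cyo/Cyd/App/YgiN), ATP synthase, and the nitrate branch (Nar, Fdn,
#' NirAB) which only carries flux when nitrate is the electron acceptor.
#'
#' @param overrides optional named list of parameter overrides; names must
#'   be existing global parameters (see [model_spec()]).
#' @return an `aero_model`.
#' @examples
#' m <- build_default_model()
#' m$atp_registry
#' @export
build_default_model <- function(overrides = NULL) {
  params <- list(phi_max = 0.40, kappa_t = 4.5, gam = 70, ngam = 5,
                 substrate_mw = 0.18016, charge_per_atp = 3.0)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(params))
    if (length(bad))
      stop("unknown override key(s): ", paste(bad, collapse = ", "))
    params[names(overrides)] <- overrides
  }
  model <- model_spec(default_reactions(params$gam, params$charge_per_atp),
                      default_enzymes(), params)
  model
}

# Keep the stoichiometric entries that depend on global parameters in sync
# after a parameter change.
sync_param_stoichiometry <- function(model) {
  model$reactions[["ATPS4rpp"]]$stoichiometry["chg"] <-
    -model$params$charge_per_atp
  model$reactions[["BIOMASS"]]$stoichiometry["atp"] <- -model$params$gam
  model
}

#' Construct a strain genotype
#'
#' A genotype is a set of gene-level perturbations (a fold change on the
#' catalytic efficiency and an additive offset on the folding stability of
#' the enzyme the gene belongs to) plus a set of knocked-out enzymes.
#'
#' @param strain_id identifier.
#' @param mutations data frame with columns `gene_id`, `keff_factor`,
#'   `dG_offset`. Empty by default.
#' @param knockouts character vector of enzyme ids whose flux capacity is
#'   set to zero.
#' @param keff_fold_range two-element range to which composed per-enzyme
#'   fold changes are clipped.
#' @param seed_path identifier of the RNG substream that produced the
#'   genotype (bookkeeping only).
#' @return a list of class `aero_genotype`.
#' @export
strain_genotype <- function(strain_id = "strain",
                            mutations = data.frame(
                              gene_id = character(),
                              keff_factor = numeric(),
                              dG_offset = numeric()),
                            knockouts = character(),
                            keff_fold_range = c(0.5, 2),
                            seed_path = NA_integer_) {
  stopifnot(all(c("gene_id", "keff_factor", "dG_offset") %in%
                  names(mutations)),
            length(keff_fold_range) == 2, keff_fold_range[1] < 1,
            keff_fold_range[2] > 1)
  structure(list(strain_id = strain_id, mutations = mutations,
                 knockouts = as.character(knockouts),
                 keff_fold_range = as.numeric(keff_fold_range),
                 seed_path = seed_path),
            class = "aero_genotype")
}

#' Apply a genotype to a model
#'
#' Gene-level perturbations are composed per enzyme (fold changes multiply,
#' stability offsets add; the composed fold change is clipped to the
#' genotype's configured range) and applied as `k_eff <- k_eff * factor`,
#' `dG_ref <- dG_ref + offset`. Knocked-out enzymes have their reactions'
#' flux capacity set to zero. Catalog genes that do not map to any model
#' enzyme are phenotypically silent.
#'
#' @param model an `aero_model`.
#' @param genotype an `aero_genotype`.
#' @return the perturbed model.
#' @export
apply_genotype <- function(model, genotype) {
  stopifnot(inherits(model, "aero_model"), inherits(genotype, "aero_genotype"))
  bad <- setdiff(genotype$knockouts, names(model$enzymes))
  if (length(bad))
    stop("knockout of unknown enzyme(s): ", paste(bad, collapse = ", "))
  mut <- genotype$mutations
  if (nrow(mut)) {
    gene2enz <- gene_to_enzyme_map(model)
    hit <- gene2enz[mut$gene_id]
    for (eid in unique(stats::na.omit(hit))) {
      rows <- which(!is.na(hit) & hit == eid)
      factor <- prod(mut$keff_factor[rows])
      factor <- min(max(factor, genotype$keff_fold_range[1]),
                    genotype$keff_fold_range[2])
      offset <- sum(mut$dG_offset[rows])
      model$enzymes[[eid]]$k_eff <- model$enzymes[[eid]]$k_eff * factor
      model$enzymes[[eid]]$dG_ref <- model$enzymes[[eid]]$dG_ref + offset
    }
  }
  if (length(genotype$knockouts)) {
    ko <- unique(c(attr(model, "knockouts"), genotype$knockouts))
    attr(model, "knockouts") <- ko
  }
  model
}

# named vector: gene id -> enzyme id
gene_to_enzyme_map <- function(model) {
  genes <- lapply(model$enzymes, `[[`, "genes")
  stats::setNames(rep(names(genes), lengths(genes)), unlist(genes))
}

#' Map gene names to model enzymes
#'
#' Resolves gene-level knockout names (e.g. `"cyoB"`, `"ndh"`) to the
#' enzyme complexes they belong to; removing any subunit gene disables the
#' whole complex.
#'
#' @param model an `aero_model`.
#' @param genes character vector of gene names.
#' @return character vector of enzyme ids.
#' @export
genes_to_enzymes <- function(model, genes) {
  map <- gene_to_enzyme_map(model)
  hit <- map[genes]
  if (anyNA(hit))
    stop("unknown gene(s): ", paste(genes[is.na(hit)], collapse = ", "),
         "; valid names: ", paste(sort(names(map)), collapse = ", "))
  unique(unname(hit))
}
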