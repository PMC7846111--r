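# ATP-production accounting over the eight-reaction registry, the
# constrained-fraction coupling, and the phenotype vector on the rate-yield
# plane.

#' ATP-production fractions over the eight-reaction registry
#'
#' For each registry reaction the ATP production is its ATP stoichiometric
#' weight times the flux in the producing direction (`max(0, v)`; reversible
#' reactions running backwards consume ATP and contribute nothing).
#' Fractions are production over total production. When total production is
#' zero all fractions are zero and the result carries `degenerate = TRUE`.
#'
#' @param solution an `aero_solution` (feasible).
#' @param model the `aero_model` it was solved on.
#' @return a list of class `atp_fractions` with elements `f_ATPS`, `f_PGK`,
#'   `f_PYK`, `f_ACKr`, `f_PPKr`, `f_PPK2r`, `f_SUCOAS`, `f_PRPPS`, the
#'   `total` production (mmol/gDW/h) and the `degenerate` flag.
#' @export
compute_fractions <- function(solution, model) {
  stopifnot(inherits(solution, "aero_solution"),
            inherits(model, "aero_model"))
  reg <- model$atp_registry
  missing <- setdiff(reg, names(solution$fluxes))
  if (length(missing))
    stop("registry reaction(s) missing from the solution: ",
         paste(missing, collapse = ", "))
  w <- vapply(model$reactions[reg], `[[`, 0, "atp_produced")
  prod <- w * pmax(0, solution$fluxes[reg])
  total <- sum(prod)
  degenerate <- total <= 0
  f <- if (degenerate) stats::setNames(numeric(8), reg) else prod / total
  out <- as.list(stats::setNames(unname(f), paste0("f_", sub("4rpp", "", reg))))
  names(out) <- c("f_ATPS", "f_PGK", "f_PYK", "f_ACKr", "f_PPKr",
                  "f_PPK2r", "f_SUCOAS", "f_PRPPS")
  out$total <- total
  out$degenerate <- degenerate
  structure(out, class = "atp_fractions")
}

#' Linear constraint fixing the ATP-synthase production fraction
#'
#' Encodes `(1 - p) w_ATPS V_ATPS4rpp = p sum_(r != ATPS) w_r V_r` over the
#' producing-direction fluxes of the registry reactions (w = ATP
#' stoichiometric weights; all 1 in the default model). Attaching the
#' descriptor to a solve forces the realised fraction of ATP produced by
#' ATP synthase to equal `p` whenever total production is positive.
#'
#' @param p target fraction in `[0, 1]`.
#' @return a list of class `fatps_constraint` with element `p`.
#' @export
build_fatps_constraint <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]")
  structure(list(p = p), class = "fatps_constraint")
}

#' Biomass yield
#'
#' `Y = mu / (q_glc * m)` in gDW per g substrate, with `m` the substrate
#' molecular mass in g/mmol.
#'
#' @param mu growth rate (1/h).
#' @param q_glc glucose uptake rate (mmol/gDW/h), must be positive.
#' @param m substrate molecular mass (g/mmol), default glucose.
#' @return yield (gDW/g).
#' @export
compute_yield <- function(mu, q_glc, m = 0.18016) {
  if (any(q_glc <= 0))
    stop("yield undefined: q_glc must be positive")
  mu / (q_glc * m)
}

#' Extract the rate-yield phenotype of a solution
#'
#' @param solution an `aero_solution`.
#' @param model the model it was solved on (for the substrate mass).
#' @return named numeric vector `q_glc`, `q_ac`, `mu`, `Y`, `q_o2`
#'   (mmol/gDW/h except `mu` in 1/h and `Y` in gDW/g).
#' @export
phenotype_vector <- function(solution, model) {
  fl <- solution$fluxes
  q_glc <- unname(fl["GLCpts"])
  q_ac <- unname(pmax(0, fl["ACKr"]))
  q_o2 <- if ("O2t" %in% names(fl)) unname(fl["O2t"]) else 0
  mu <- solution$mu
  Y <- if (q_glc > 0) compute_yield(mu, q_glc, model$params$substrate_mw)
       else 0
  c(q_glc = q_glc, q_ac = q_ac, mu = mu, Y = Y, q_o2 = q_o2)
}

#' Phenotypic distance on the rate-yield plane
#'
#' Euclidean distance between the four-element phenotype vectors
#' `(q_glc, q_ac, mu, Y)` after component-wise division by the reference
#' (wild-type) phenotype, so that quantities with different units are
#' compared on a common relative scale. The auxiliary `q_o2` component is
#' ignored.
#'
#' @param x named phenotype vector (as from [phenotype_vector()]).
#' @param ref reference phenotype vector with all-positive entries on the
#'   four used components.
#' @return non-negative scalar.
#' @export
phenotype_distance <- function(x, ref) {
  comp <- c("q_glc", "q_ac", "mu", "Y")
  stopifnot(all(comp %in% names(x)), all(comp %in% names(ref)))
  if (any(ref[comp] <= 0))
    stop("reference phenotype must be positive on q_glc, q_ac, mu, Y")
  sqrt(sum(((x[comp] - ref[comp]) / ref[comp])^2))
}

#' P/O ratio of a solution
#'
#' ATP synthase flux per atom of oxygen reduced: `V_ATPS / (2 q_O2)`. A
#' local descriptor of oxidative-phosphorylation stoichiometry, in contrast
#' to the global aero-type.
#'
#' @param solution an `aero_solution` with positive oxygen uptake.
#' @return the P/O ratio.
#' @export
compute_po_ratio <- function(solution) {
  fl <- solution$fluxes
  q_o2 <- if ("O2t" %in% names(fl)) unname(fl["O2t"]) else 0
  if (q_o2 <= 0)
    stop("P/O ratio undefined: oxygen uptake is zero")
  unname(fl["ATPS4rpp"]) / (2 * q_o2)
}
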