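# Growth maximisation by bisection over a linear feasibility program.
#
# At a trial growth rate mu the model is a linear program in the reaction
# fluxes: steady-state mass balance on internal metabolites (with the
# biomass and maintenance drains entering as fixed fluxes), and a proteome
# coupling constraint  sum_i v_i MW_i / (k_eff_i 3600 f_fold_i) +
# mu / kappa_t <= phi_max.  Growth is maximised by bisection on mu; at the
# optimum the linear program is re-solved minimising total enzyme mass so
# that alternate optima are resolved deterministically.

#' Construct a growth condition
#'
#' @param temperature degC, supported range 25-46.
#' @param electron_acceptor `"oxygen"`, `"nitrate"` or `"none"`.
#' @param substrate only `"glucose"` is supported.
#' @param fixed_growth_rate optional growth rate (1/h) to impose instead of
#'   maximising.
#' @param fatps optional fraction in `[0, 1]`: constrain the fraction of
#'   ATP produced by ATP synthase to this value (see
#'   [build_fatps_constraint()]).
#' @return a list of class `aero_condition`.
#' @export
growth_condition <- function(temperature = 37,
                             electron_acceptor = c("oxygen", "nitrate",
                                                   "none"),
                             substrate = "glucose",
                             fixed_growth_rate = NULL, fatps = NULL) {
  electron_acceptor <- match.arg(electron_acceptor)
  if (temperature < 25 || temperature > 46)
    stop("temperature outside the supported 25-46 degC range")
  if (!identical(substrate, "glucose"))
    stop("only glucose is supported as substrate")
  if (!is.null(fatps) && (fatps < 0 || fatps > 1))
    stop("fatps constraint must lie in [0, 1]")
  structure(list(temperature = temperature,
                 electron_acceptor = electron_acceptor,
                 substrate = substrate,
                 fixed_growth_rate = fixed_growth_rate,
                 fatps = fatps),
            class = "aero_condition")
}

# Internal: precompute the LP skeleton for a (model, condition) pair.
# Reversible reactions are split into forward/backward columns; BIOMASS and
# the NGAM part of ATPM are fixed fluxes folded into the right-hand side.
build_lp_skeleton <- function(model, condition, proteome = TRUE) {
  p <- model$params
  ko <- attr(model, "knockouts")
  active <- Filter(function(r) {
    if (r$id == "BIOMASS") return(FALSE)
    if (!is.na(r$enzyme) && r$enzyme %in% ko) return(FALSE)
    if (r$id == "O2t" && condition$electron_acceptor != "oxygen")
      return(FALSE)
    if (r$id %in% c("NO3t", "NO2t") &&
        condition$electron_acceptor != "nitrate") return(FALSE)
    # pyruvate formate-lyase is irreversibly inactivated by oxygen
    if (r$id == "PFL" && condition$electron_acceptor == "oxygen")
      return(FALSE)
    TRUE
  }, model$reactions)

  mets <- model$metabolites
  nr <- length(active)
  ids <- names(active)
  rev <- vapply(active, `[[`, FALSE, "reversible")
  ncol_f <- nr + sum(rev)
  col_rxn <- c(seq_len(nr), which(rev))       # reaction index per column
  col_sign <- c(rep(1, nr), rep(-1, sum(rev)))

  S <- matrix(0, length(mets), nr, dimnames = list(mets, ids))
  for (j in seq_len(nr)) {
    st <- active[[j]]$stoichiometry
    st <- st[!grepl("_e$", names(st))]
    S[names(st), j] <- st
  }
  A_mass <- S[, col_rxn, drop = FALSE] *
    rep(col_sign, each = length(mets))

  # proteome cost per unit flux (both directions cost enzyme)
  ffold <- vapply(model$enzymes, function(e)
    folded_fraction(e$dG_ref, condition$temperature), 0)
  cost_r <- vapply(active, function(r) {
    if (is.na(r$enzyme)) return(0)
    e <- model$enzymes[[r$enzyme]]
    e$mw / (e$k_eff * 3600 * ffold[[r$enzyme]])
  }, 0)
  cost <- cost_r[col_rxn]

  # fixed fluxes: biomass at mu (filled in later), maintenance at ngam
  S_bio <- numeric(length(mets))
  st <- model$reactions[["BIOMASS"]]$stoichiometry
  st <- st[!grepl("_e$", names(st))]
  S_bio[match(names(st), mets)] <- st

  b_ngam <- numeric(length(mets))
  b_ngam[match("atp", mets)] <- -p$ngam  # ATPM base flux of ngam

  list(active = active, ids = ids, rev = rev, mets = mets,
       col_rxn = col_rxn, col_sign = col_sign, A_mass = A_mass,
       cost = cost, S_bio = S_bio, b_ngam = b_ngam, params = p,
       proteome = proteome, fatps = condition$fatps)
}

# Internal: assemble and solve the LP at growth rate mu.
solve_lp_at_mu <- function(sk, mu) {
  p <- sk$params
  b_mass <- -(sk$S_bio * mu) - sk$b_ngam
  A <- sk$A_mass
  b <- b_mass
  dir <- rep("==", length(b))
  if (sk$proteome) {
    A <- rbind(A, sk$cost)
    b <- c(b, p$phi_max - mu / p$kappa_t)
    dir <- c(dir, "<=")
  }
  if (!is.null(sk$fatps)) {
    fc <- build_fatps_constraint(sk$fatps)
    row <- numeric(ncol(A))
    w <- vapply(sk$active, `[[`, 0, "atp_produced")
    for (k in seq_along(sk$ids)) {
      if (w[k] <= 0) next
      # net producing flux: forward minus backward column, so that futile
      # forward/backward cycles cannot fake ATP production. No registry
      # reaction can run net-negative in this network, which makes the
      # coupling coincide exactly with the realized fraction.
      coef <- if (sk$ids[k] == "ATPS4rpp") (1 - fc$p) * w[k] else
        -fc$p * w[k]
      row[sk$col_rxn == k] <- coef * sk$col_sign[sk$col_rxn == k]
    }
    A <- rbind(A, row)
    b <- c(b, 0)
    dir <- c(dir, "==")
  }
  if (p$phi_max - mu / p$kappa_t < -1e-12 && sk$proteome)
    return(list(status = "infeasible"))
  obj <- sk$cost + 1e-9  # tiny uniform term: deterministic, loop-free optima
  res <- lp_solve(obj, A, b, dir)
  res
}

# Internal: package an LP solution as a flux solution object.
as_solution <- function(sk, res, mu, condition, feasible) {
  ids <- sk$ids
  fluxes <- stats::setNames(numeric(length(ids)), ids)
  enz_ids <- unique(stats::na.omit(vapply(sk$active, `[[`, "", "enzyme")))
  enzyme_phi <- stats::setNames(numeric(length(enz_ids)), enz_ids)
  if (feasible && res$status == "optimal") {
    x <- res$x
    for (j in seq_along(x)) {
      k <- sk$col_rxn[j]
      fluxes[k] <- fluxes[k] + sk$col_sign[j] * x[j]
      r <- sk$active[[k]]
      if (!is.na(r$enzyme))
        enzyme_phi[r$enzyme] <- enzyme_phi[r$enzyme] + sk$cost[j] * x[j]
    }
    # mass-balance invariant: every accepted solution must balance
    resid <- sk$A_mass %*% x - (-(sk$S_bio * mu) - sk$b_ngam)
    scale <- max(1, sum(abs(sk$A_mass %*% x)))
    if (max(abs(resid)) > 1e-8 * scale)
      stop("mass-balance residual above tolerance: ", max(abs(resid)))
  }
  fluxes <- c(fluxes, BIOMASS = unname(mu))
  if ("ATPM" %in% names(fluxes))
    fluxes[["ATPM"]] <- fluxes[["ATPM"]] + sk$params$ngam
  structure(list(mu = if (feasible) mu else 0,
                 fluxes = fluxes,
                 enzyme_phi = enzyme_phi,
                 ribosome_phi = if (feasible) mu / sk$params$kappa_t else 0,
                 feasible = feasible,
                 condition = condition),
            class = "aero_solution")
}

#' @export
print.aero_solution <- function(x, ...) {
  cat(sprintf("Flux solution: mu = %.4f 1/h (%s), T = %g degC, %s\n",
              x$mu, if (x$feasible) "feasible" else "infeasible",
              x$condition$temperature, x$condition$electron_acceptor))
  invisible(x)
}

#' Maximise growth rate under the proteome budget
#'
#' Maximises the growth rate of a (possibly perturbed) model under a given
#' condition by bisection on mu with a linear feasibility program at each
#' trial value: steady-state mass balance, the enzyme-capacity coupling
#' constraint, ATP balance including growth-associated and maintenance
#' costs, an optional fixed growth rate, and an optional constraint on the
#' fraction of ATP produced by ATP synthase. Among alternate optima the
#' solution minimising total enzyme mass is returned, which makes the
#' solver deterministic.
#'
#' @param model an `aero_model`.
#' @param condition an `aero_condition`.
#' @param tol bisection tolerance on mu (1/h).
#' @param max_iter maximum bisection iterations.
#' @return an `aero_solution` with fields `mu`, `fluxes` (net, mmol/gDW/h;
#'   `BIOMASS` equals `mu`), `enzyme_phi` (proteome mass fractions),
#'   `ribosome_phi`, `feasible`, `condition`. Infeasible problems return
#'   `feasible = FALSE` and `mu = 0`.
#' @examples
#' \donttest{
#' m <- calibrate_wildtype(build_default_model())
#' sol <- solve_growth(m, growth_condition(37))
#' sol$mu
#' }
#' @export
solve_growth <- function(model, condition = growth_condition(),
                         tol = 1e-6, max_iter = 60) {
  stopifnot(inherits(model, "aero_model"), inherits(condition,
                                                    "aero_condition"))
  sk <- build_lp_skeleton(model, condition)

  if (!is.null(condition$fixed_growth_rate)) {
    mu <- condition$fixed_growth_rate
    res <- solve_lp_at_mu(sk, mu)
    return(as_solution(sk, res, mu, condition,
                       feasible = identical(res$status, "optimal")))
  }

  feas <- function(mu) identical(solve_lp_at_mu(sk, mu)$status, "optimal")

  if (!feas(0)) {
    return(as_solution(sk, list(status = "infeasible"), 0, condition,
                       feasible = FALSE))
  }
  lo <- 0
  hi <- sk$params$phi_max * sk$params$kappa_t  # ribosome-only upper bound
  if (feas(hi)) {
    lo <- hi
  } else {
    it <- 0
    while (hi - lo > tol) {
      if ((it <- it + 1) > max_iter)
        stop("growth bisection did not converge after ", max_iter,
             " iterations (interval [", lo, ", ", hi, "])")
      mid <- (lo + hi) / 2
      if (feas(mid)) lo <- mid else hi <- mid
    }
  }
  res <- solve_lp_at_mu(sk, lo)
  as_solution(sk, res, lo, condition, feasible = TRUE)
}

#' Maximal stoichiometric f_ATPS over the flux polytope
#'
#' The largest fraction of total ATP production that ATP synthase can carry
#' over the steady-state flux polytope alone (no proteome constraint, no
#' growth), found by bisection on the constrained-fraction feasibility
#' problem with a fixed ATP drain providing scale.
#'
#' @param model an `aero_model`.
#' @param tol bisection tolerance on the fraction.
#' @return the maximal fraction in `[0, 1]`.
#' @export
max_fatps <- function(model, tol = 1e-5) {
  cond0 <- growth_condition(37, "oxygen")
  feas_at <- function(p) {
    cond <- cond0
    cond$fatps <- p
    sk <- build_lp_skeleton(model, cond, proteome = FALSE)
    # fixed ATP drain of 10 mmol/gDW/h (scale only): raise ngam
    sk$b_ngam[match("atp", sk$mets)] <- -10
    identical(solve_lp_at_mu(sk, 0)$status, "optimal")
  }
  if (!feas_at(0)) stop("model cannot produce ATP at all")
  lo <- 0; hi <- 1
  if (feas_at(1)) return(1)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feas_at(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Calibrate the wild-type model
#'
#' Deterministically fixes the free coarse-model constant: the
#' charge-per-ATP stoichiometry of ATP synthase is chosen (by monotone
#' root finding over a fixed bracket) so that the maximal stoichiometric
#' f_ATPS over the flux polytope equals the target, and the calibration is
#' then verified by solving the wild-type optimum at 37 degC, which must
#' lie in the highest-f_ATPS regime. Because the root find always starts
#' from the same bracket, calibrating twice yields identical parameters.
#'
#' @param model an `aero_model` (default model).
#' @param target_max_fatps target for the maximal stoichiometric fraction.
#' @param wt_min_fatps minimal acceptable wild-type f_ATPS at 37 degC.
#' @return the calibrated model.
#' @export
calibrate_wildtype <- function(model = build_default_model(),
                               target_max_fatps = 0.83,
                               wt_min_fatps = 0.60) {
  f_of <- function(delta) {
    m <- model
    m$params$charge_per_atp <- delta
    m <- sync_param_stoichiometry(m)
    max_fatps(m) - target_max_fatps
  }
  root <- stats::uniroot(f_of, c(1.5, 8), tol = 1e-6)
  model$params$charge_per_atp <- root$root
  model <- sync_param_stoichiometry(model)

  sol <- solve_growth(model, growth_condition(37, "oxygen"))
  if (!sol$feasible)
    stop("calibration failed: wild-type infeasible at 37 degC")
  f <- compute_fractions(sol, model)
  if (f$f_ATPS < wt_min_fatps)
    stop(sprintf(paste0("calibration failed: wild-type f_ATPS at 37 degC ",
                        "is %.3f < %.2f"), f$f_ATPS, wt_min_fatps))
  model
}
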