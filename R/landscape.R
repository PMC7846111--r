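# Landscape statistics: Gaussian-mixture fitting of the multimodal f_ATPS
# distribution (a point mass at zero for the fully fermentative phenotype
# plus Gaussian components), aero-type assignment, stepwise variance
# decomposition, proteome-complexity metrics, flux PCA and the feasibility
# envelope on the rate-yield plane.

#' Fit the zero-peak + Gaussian mixture of f_ATPS
#'
#' Values below the zero-peak threshold are assigned to a point mass at 0
#' (the fully fermentative phenotype); the remaining values are fitted with
#' `k` Gaussian components by EM. Restarts are deterministic: initial
#' component means are data quantiles on shifted probability grids, refined
#' by k-means with explicit starting centres, which also makes the fit
#' invariant to duplication of the input. The best log-likelihood over all
#' restarts is retained and components are reported sorted by mean.
#'
#' @param values f_ATPS values in `[0, 1]`.
#' @param k number of Gaussian components (4 for the aerobic landscape, 3
#'   for the nitrate experiment).
#' @param zero_threshold values below this count as the fermentative point
#'   mass (default 0.02).
#' @param restarts deterministic restarts.
#' @param max_iter,tol EM convergence controls (log-likelihood change).
#' @return a list of class `fatps_mixture`: `zero_peak_weight`, `means`,
#'   `sds`, `weights` (component weights, summing with the zero peak to 1),
#'   `loglik`, `converged`, `n_used` (values entering the component fit),
#'   `k`, `zero_threshold`.
#' @export
fit_fatps_mixture <- function(values, k = 4, zero_threshold = 0.02,
                              restarts = 50, max_iter = 1000, tol = 1e-10) {
  values <- values[!is.na(values)]
  if (any(values < 0 | values > 1))
    stop("f_ATPS values must lie in [0, 1]")
  nz <- values[values >= zero_threshold]
  w0 <- 1 - length(nz) / length(values)
  if (length(nz) == 0) {
    return(structure(list(zero_peak_weight = 1, means = numeric(0),
                          sds = numeric(0), weights = numeric(0),
                          loglik = 0, converged = TRUE, n_used = 0L,
                          k = 0L, zero_threshold = zero_threshold),
                     class = "fatps_mixture"))
  }
  if (length(nz) < 50)
    stop("too few non-zero-peak values (", length(nz),
         ") for a ", k, "-component fit; need at least 50")

  best <- NULL
  for (r in seq_len(restarts)) {
    # quantile grid shifted by the restart index; deterministic and
    # unchanged under duplication of the data
    u <- (r - 1) / restarts
    probs <- (seq_len(k) - u) / k
    probs <- pmin(pmax(probs, 1e-3), 1 - 1e-3)
    centres <- as.numeric(stats::quantile(nz, probs, names = FALSE))
    centres <- centres + seq_len(k) * 1e-9  # break exact ties
    km <- tryCatch(stats::kmeans(nz, centers = matrix(centres, ncol = 1),
                                 iter.max = 25),
                   error = function(e) NULL)
    init <- if (!is.null(km)) {
      list(mu = as.numeric(km$centers),
           sd = vapply(seq_len(k), function(j) {
             x <- nz[km$cluster == j]
             max(stats::sd(x), 1e-3, na.rm = TRUE)
           }, 0),
           w = as.numeric(table(factor(km$cluster, levels = seq_len(k)))) /
             length(nz))
    } else {
      list(mu = centres, sd = rep(max(stats::sd(nz), 1e-3), k),
           w = rep(1 / k, k))
    }
    fit <- em_gaussian(nz, init$mu, init$sd, init$w, max_iter, tol)
    if (is.null(best) || (fit$converged && !best$converged) ||
        (fit$converged == best$converged && fit$loglik > best$loglik + 1e-12))
      best <- fit
  }
  if (!best$converged)
    stop("EM did not converge in any restart")

  ord <- order(best$mu)
  structure(list(zero_peak_weight = w0,
                 means = best$mu[ord],
                 sds = best$sd[ord],
                 weights = best$w[ord] * (1 - w0),
                 loglik = best$loglik,
                 converged = best$converged,
                 n_used = length(nz),
                 k = as.integer(k),
                 zero_threshold = zero_threshold),
            class = "fatps_mixture")
}

# Plain univariate Gaussian-mixture EM. sds floored to keep the likelihood
# bounded on near-degenerate clusters.
em_gaussian <- function(x, mu, sd, w, max_iter, tol) {
  n <- length(x)
  k <- length(mu)
  sd <- pmax(sd, 1e-4)
  w <- pmax(w, 1e-8); w <- w / sum(w)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sd[j]), numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < 1e-300] <- 1e-300
    ll <- sum(log(rowsum_d))
    if (is.finite(ll) && abs(ll - ll_old) < tol * max(1, abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- vapply(seq_len(k), function(j)
      sqrt(sum(resp[, j] * (x - mu[j])^2) / nk[j]), 0)
    sd <- pmax(sd, 1e-4)
  }
  list(mu = mu, sd = sd, w = w, loglik = ll_old, converged = converged)
}

#' @export
print.fatps_mixture <- function(x, ...) {
  cat(sprintf("f_ATPS mixture: zero peak %.3f + %d Gaussians (n_used = %d)\n",
              x$zero_peak_weight, x$k, x$n_used))
  if (x$k > 0)
    print(data.frame(mean = round(x$means, 4), sd = round(x$sds, 4),
                     weight = round(x$weights, 4)))
  invisible(x)
}

#' BIC scan over the number of mixture components
#'
#' Fits the non-zero-peak values with 1..max components and reports the
#' Bayesian information criterion for each, to check how many discrete
#' f_ATPS modes the data support.
#'
#' @param values f_ATPS values.
#' @param ks candidate component counts.
#' @param zero_threshold passed to [fit_fatps_mixture()].
#' @return data frame with columns `k`, `loglik`, `bic`; the preferred
#'   (minimum-BIC) k is in attribute `"best_k"`.
#' @export
mixture_bic_scan <- function(values, ks = 1:5, zero_threshold = 0.02) {
  rows <- lapply(ks, function(k) {
    fit <- fit_fatps_mixture(values, k = k, zero_threshold = zero_threshold)
    npar <- 3 * k - 1
    data.frame(k = k, loglik = fit$loglik,
               bic = -2 * fit$loglik + npar * log(fit$n_used))
  })
  out <- do.call(rbind, rows)
  attr(out, "best_k") <- out$k[which.min(out$bic)]
  out
}

#' Reference mixture built from stated peak values
#'
#' Constructs a `fatps_mixture` object directly from given component means
#' (without fitting), for use as a fixed classifier, e.g. when predicting
#' the aero-type of knockout strains. Defaults to the four non-zero peak
#' positions of the aerobic landscape with a small zero-peak mass.
#'
#' @param means component means.
#' @param sds component standard deviations (recycled).
#' @param weights component weights (default equal).
#' @param zero_peak_weight mass of the point mass at 0.
#' @return a `fatps_mixture`.
#' @export
reference_aerotype_fit <- function(means = c(0.37, 0.53, 0.64, 0.71),
                                   sds = 0.02, weights = NULL,
                                   zero_peak_weight = 0.1) {
  k <- length(means)
  sds <- rep_len(sds, k)
  if (is.null(weights)) weights <- rep((1 - zero_peak_weight) / k, k)
  stopifnot(abs(sum(weights) + zero_peak_weight - 1) < 1e-8)
  structure(list(zero_peak_weight = zero_peak_weight, means = means,
                 sds = sds, weights = weights, loglik = NA_real_,
                 converged = TRUE, n_used = 0L, k = as.integer(k),
                 zero_threshold = 0.02),
            class = "fatps_mixture")
}

#' Assign aero-types from a fitted mixture
#'
#' Values in the zero peak are labelled with the first (fully fermentative)
#' class; all others get the class of the maximum-posterior Gaussian
#' component, with components taken in ascending order of their means and
#' posterior ties broken toward the lower label.
#'
#' @param f f_ATPS value(s) in `[0, 1]`.
#' @param fit a `fatps_mixture`.
#' @param labels class labels: first entry for the zero peak, then one per
#'   component in mean order. Default the aero-types i..v.
#' @return character vector of labels.
#' @export
assign_aerotype <- function(f, fit,
                            labels = c("i", "ii", "iii", "iv", "v")) {
  stopifnot(inherits(fit, "fatps_mixture"))
  if (length(labels) != fit$k + 1)
    stop("need ", fit$k + 1, " labels (zero peak + components)")
  out <- rep(NA_character_, length(f))
  ok <- !is.na(f)
  if (any(f[ok] < 0 | f[ok] > 1))
    stop("f_ATPS values must lie in [0, 1]")
  zero <- ok & f < fit$zero_threshold
  out[zero] <- labels[1]
  rest <- ok & !zero
  if (any(rest)) {
    post <- vapply(seq_len(fit$k), function(j)
      fit$weights[j] * stats::dnorm(f[rest], fit$means[j], fit$sds[j]),
      numeric(sum(rest)))
    post <- matrix(post, nrow = sum(rest))
    out[rest] <- labels[apply(post, 1, which.max) + 1]
  }
  out
}

#' Nitro-type labels for the anaerobic (nitrate) landscape
#'
#' Same rule as [assign_aerotype()] with three components; the zero peak is
#' merged with the lowest class.
#'
#' @inheritParams assign_aerotype
#' @export
assign_nitrotype <- function(f, fit) {
  assign_aerotype(f, fit, labels = c("i", "i", "ii", "iii")[seq_len(fit$k + 1)])
}

#' Forward stepwise regression of phenotypic distance on ATP fractions
#'
#' Forward selection over the eight ATP-production fractions: at each step
#' the predictor with the smallest partial-F p-value below `alpha` is
#' added; selection stops when none qualifies. Cumulative R-squared is
#' reported after each addition.
#'
#' @param predictors data frame of explanatory variables (the eight
#'   fractions).
#' @param response numeric response (phenotypic distance).
#' @param alpha entry threshold on the partial-F p-value.
#' @return a list of class `stepwise_report`: `steps` (data frame
#'   `predictor`, `p_value`, `cum_r2`), `final_r2`, `skipped` (predictors
#'   dropped for rank deficiency).
#' @export
stepwise_regression <- function(predictors, response, alpha = 0.05) {
  stopifnot(is.data.frame(predictors), nrow(predictors) >= 30)
  dat <- cbind(predictors, .y = response)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  remaining <- names(predictors)
  selected <- character(0)
  steps <- list()
  skipped <- character(0)
  repeat {
    if (!length(remaining)) break
    fml <- stats::as.formula(paste(".y ~",
      if (length(selected)) paste(selected, collapse = " + ") else "1"))
    fit <- stats::lm(fml, data = dat)
    add <- stats::add1(fit, scope = stats::as.formula(
      paste("~ . +", paste(remaining, collapse = " + "))), test = "F")
    cand <- add[remaining, , drop = FALSE]
    pvals <- cand[["Pr(>F)"]]
    names(pvals) <- rownames(cand)
    pvals <- pvals[!is.na(pvals)]
    degenerate <- setdiff(remaining, names(pvals))
    if (length(degenerate)) {
      skipped <- c(skipped, degenerate)
      remaining <- setdiff(remaining, degenerate)
      if (!length(pvals)) break
    }
    if (!length(pvals) || min(pvals) >= alpha) break
    pick <- names(pvals)[which.min(pvals)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    fit2 <- stats::lm(stats::as.formula(paste(".y ~",
      paste(selected, collapse = " + "))), data = dat)
    steps[[length(steps) + 1L]] <- data.frame(
      predictor = pick, p_value = min(pvals),
      cum_r2 = summary(fit2)$r.squared)
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(predictor = character(), p_value = numeric(),
               cum_r2 = numeric())
  structure(list(steps = steps,
                 final_r2 = if (nrow(steps)) steps$cum_r2[nrow(steps)] else 0,
                 skipped = skipped),
            class = "stepwise_report")
}

#' @export
print.stepwise_report <- function(x, ...) {
  cat("Forward stepwise regression:\n")
  print(x$steps)
  cat(sprintf("final R-squared: %.4f\n", x$final_r2))
  invisible(x)
}

#' Proteome complexity of a solution
#'
#' An enzyme is expressed when its proteome mass fraction exceeds the
#' threshold. `n_genes_expressed` is the size of the union of the gene
#' sets of expressed enzymes; `avg_subunits` is the unweighted mean number
#' of polypeptide chains per expressed enzyme (0 when nothing is
#' expressed).
#'
#' @param solution an `aero_solution`.
#' @param model the model it was solved on.
#' @param threshold expression threshold on the mass fraction.
#' @return list with `n_genes_expressed` and `avg_subunits`.
#' @export
proteome_complexity <- function(solution, model, threshold = 1e-6) {
  expressed <- names(solution$enzyme_phi)[solution$enzyme_phi > threshold]
  if (!length(expressed))
    return(list(n_genes_expressed = 0L, avg_subunits = 0))
  enz <- model$enzymes[expressed]
  list(n_genes_expressed =
         length(unique(unlist(lapply(enz, `[[`, "genes")))),
       avg_subunits = mean(vapply(enz, `[[`, 0L, "n_subunits")))
}

#' Principal component analysis of central-metabolism fluxes
#'
#' PCA on the column-standardised fluxes of the named reactions across a
#' sample table. Zero-variance columns are dropped with a warning.
#'
#' @param table an `aero_sample_table` (with `v_<reaction>` flux columns).
#' @param reactions reaction ids to include; default every flux column
#'   except exchanges and biomass bookkeeping.
#' @return a list of class `flux_pca`: `loadings`, `scores`,
#'   `variance_fraction` (summing to 1), `reactions`.
#' @export
flux_pca <- function(table, reactions = NULL) {
  tab <- table[table$feasible, , drop = FALSE]
  if (nrow(tab) < 3) stop("need at least 3 feasible samples")
  vcols <- grep("^v_", names(tab), value = TRUE)
  if (is.null(reactions)) {
    drop <- paste0("v_", c("O2t", "NO3t", "NO2t", "FORt", "ATPM",
                           "BIOMASS"))
    vcols <- setdiff(vcols, drop)
  } else {
    vcols <- paste0("v_", reactions)
    missing <- setdiff(vcols, names(tab))
    if (length(missing))
      stop("flux column(s) absent: ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(tab[, vcols, drop = FALSE])
  vars <- apply(X, 2, stats::var)
  if (any(vars < 1e-12)) {
    warning("dropping zero-variance flux column(s): ",
            paste(vcols[vars < 1e-12], collapse = ", "))
    X <- X[, vars >= 1e-12, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  structure(list(loadings = pc$rotation, scores = pc$x,
                 variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
                 reactions = sub("^v_", "", colnames(X))),
            class = "flux_pca")
}

#' Feasibility envelope of the rate-yield plane from fixed-rate samples
#'
#' Along each growth-rate isocline, yield and glucose uptake are linear in
#' f_ATPS (positive and negative slope, respectively). Evaluating the
#' fitted lines at the minimal and maximal attainable fractions (0 and
#' `f_max`) gives four corner points per growth rate that trace the
#' boundary of the accessible region.
#'
#' @param table sample table from [run_fixed_growth_sampling()] (must carry
#'   a `mu_target` column), or a list of such tables.
#' @param f_max maximal stoichiometric fraction (default 0.83, the
#'   calibration anchor).
#' @param min_points isoclines with fewer feasible points are skipped with
#'   a warning.
#' @return data frame with one row per isocline: `mu_target`, `n`,
#'   `slope_Y`, `slope_q`, `Y_at_0`, `Y_at_fmax`, `q_at_0`, `q_at_fmax`.
#' @export
feasibility_envelope <- function(table, f_max = 0.83, min_points = 5) {
  if (is.list(table) && !is.data.frame(table))
    table <- do.call(rbind, table)
  if (!"mu_target" %in% names(table))
    stop("table must carry a mu_target column (fixed-rate samples)")
  rows <- lapply(split(table, table$mu_target), function(d) {
    d <- d[d$feasible & !is.na(d$f_ATPS), , drop = FALSE]
    if (nrow(d) < min_points) {
      warning("isocline mu = ", d$mu_target[1] %||% NA,
              " skipped: fewer than ", min_points, " feasible points")
      return(NULL)
    }
    fy <- stats::lm(Y ~ f_ATPS, data = d)
    fq <- stats::lm(q_glc ~ f_ATPS, data = d)
    py <- function(f) unname(stats::predict(fy, data.frame(f_ATPS = f)))
    pq <- function(f) unname(stats::predict(fq, data.frame(f_ATPS = f)))
    data.frame(mu_target = d$mu_target[1], n = nrow(d),
               slope_Y = unname(stats::coef(fy)[2]),
               slope_q = unname(stats::coef(fq)[2]),
               Y_at_0 = py(0), Y_at_fmax = py(f_max),
               q_at_0 = pq(0), q_at_fmax = pq(f_max))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
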