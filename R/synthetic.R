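# Synthetic-data generators. They emulate the statistical structure the
# analysis assumes -- a heavy-tailed per-gene mutation-frequency table over
# the 1,566-gene catalog, multimodal f_ATPS samples, and an expression
# counts matrix with aero-type structure and duplicate replicates -- so that
# every pipeline stage is testable without external downloads. All
# generators are pure functions of (config, seed).

#' Synthetic-data configuration
#'
#' @param n_genes catalog size (default 1566 protein-coding model genes).
#' @param total_mutations total coding-region mutations the frequency table
#'   is built from (default 266,940).
#' @param categories named mutation-category counts (non-synonymous SNPs,
#'   deletions, insertions); must sum to `total_mutations`.
#' @param n_strains size of the strain panel the counts were accumulated
#'   over (default 1765); per-strain mutation probabilities are
#'   `min(1, count / n_strains)`.
#' @param dispersion negative-binomial size parameter of the per-gene count
#'   law; smaller = heavier tail (default 0.5).
#' @param expression list of expression-fixture design parameters:
#'   `n_genes`, `n_strains`, `n_signal` (phenotype-correlated genes),
#'   `effect` (log2 effect size), `replicate_sd` (log2 replicate noise),
#'   `depth` (reads per sample), `oxphos_size`, `tca_size` (annotation set
#'   sizes).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1566, total_mutations = 266940,
                             categories = c(snp = 245635,
                                            deletion = 16591,
                                            insertion = 4714),
                             n_strains = 1765,
                             dispersion = 0.5,
                             expression = list(n_genes = 2000,
                                               n_strains = 16,
                                               n_signal = 50,
                                               effect = 1.2,
                                               replicate_sd = 0.05,
                                               depth = 5e6,
                                               oxphos_size = 94,
                                               tca_size = 27)) {
  if (any(categories < 0) || sum(categories) != total_mutations)
    stop("category counts must be non-negative and sum to total_mutations")
  structure(list(n_genes = as.integer(n_genes),
                 total_mutations = as.integer(total_mutations),
                 categories = categories,
                 n_strains = as.integer(n_strains),
                 dispersion = dispersion,
                 expression = expression),
            class = "synthetic_config")
}

#' The gene catalog
#'
#' Gene identifiers for the catalog: the genes of the coarse model's
#' enzymes first (by their *E. coli* names), padded with synthetic locus
#' tags to the requested size.
#'
#' @param n_genes catalog size.
#' @return character vector of gene ids.
#' @export
aero_gene_catalog <- function(n_genes = 1566) {
  model_genes <- unique(unlist(lapply(default_enzymes(), `[[`, "genes")))
  if (n_genes < length(model_genes))
    stop("catalog smaller than the model gene set (",
         length(model_genes), ")")
  c(model_genes,
    sprintf("y%04d", seq_len(n_genes - length(model_genes))))
}

#' Generate a synthetic mutation-frequency table
#'
#' Per-gene mutation counts are drawn from a negative-binomial law (many
#' genes with few fixed mutations, a heavy tail of highly mutated genes)
#' and rescaled to sum exactly to the configured total. The probability
#' that a sampled strain harbors a mutation in a gene is the per-strain
#' frequency of that gene's mutations across the panel,
#' `min(1, count / n_strains)`.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return data frame of class `mutation_frequency_table` with columns
#'   `gene_id`, `count`, `prob` (summing to 1); mutation-category totals in
#'   attribute `"categories"`.
#' @export
make_mutation_frequency_table <- function(config = synthetic_config(),
                                          seed = 1) {
  set.seed(seed)
  n <- config$n_genes
  total <- config$total_mutations
  raw <- stats::rnbinom(n, size = config$dispersion, mu = total / n)
  raw <- raw + 1e-9  # guard against an all-zero draw
  counts <- floor(raw / sum(raw) * total)
  deficit <- total - sum(counts)
  if (deficit > 0) {
    # hand the remainder to the largest genes, deterministically
    ord <- order(raw, decreasing = TRUE)
    counts[ord[seq_len(deficit)]] <- counts[ord[seq_len(deficit)]] + 1
  }
  out <- data.frame(gene_id = aero_gene_catalog(n),
                    count = as.integer(counts),
                    prob = pmin(counts / config$n_strains, 1),
                    stringsAsFactors = FALSE)
  attr(out, "categories") <- config$categories
  class(out) <- c("mutation_frequency_table", "data.frame")
  out
}

#' Draw synthetic f_ATPS samples from a stated mixture
#'
#' A point mass at 0 (the fully fermentative phenotype) with probability
#' `zero_weight`, otherwise a draw from the Gaussian component mixture,
#' truncated to `(0, 0.9]` by rejection.
#'
#' @param means component means in (0, 1).
#' @param sds component standard deviations (recycled).
#' @param weights component weights; together with `zero_weight` they must
#'   sum to 1.
#' @param zero_weight probability of the point mass at 0.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector in `[0, 0.9]`.
#' @export
make_fatps_samples <- function(means = c(0.37, 0.53, 0.64, 0.71),
                               sds = 0.02, weights = NULL,
                               zero_weight = 0.1, n = 2000, seed = 1) {
  k <- length(means)
  sds <- rep_len(sds, k)
  if (is.null(weights)) weights <- rep((1 - zero_weight) / k, k)
  if (length(weights) != k || any(weights < 0) || zero_weight < 0 ||
      abs(sum(weights) + zero_weight - 1) > 1e-8)
    stop("weights plus zero_weight must be non-negative and sum to 1")
  if (any(means <= 0 | means >= 1))
    stop("component means must lie in (0, 1)")
  set.seed(seed)
  comp <- sample.int(k + 1, n, replace = TRUE,
                     prob = c(zero_weight, weights))
  x <- numeric(n)
  todo <- which(comp > 1)
  while (length(todo)) {
    x[todo] <- stats::rnorm(length(todo), means[comp[todo] - 1],
                            sds[comp[todo] - 1])
    todo <- todo[x[todo] <= 0 | x[todo] > 0.9]
  }
  x
}

#' Generate a synthetic expression fixture with known ground truth
#'
#' Emulates the structure the expression pipeline assumes: strains fall
#' into two aero-type groups with bimodal biomass yield; acetate production
#' is anti-correlated with yield while growth rate varies independently;
#' a planted set of signal genes tracks yield (half up-regulated, half
#' down-regulated) while the remaining genes are noise; every strain is
#' measured in duplicate with small replicate noise; counts are generated
#' by inverting the TPM definition at the configured depth.
#'
#' @param config a [synthetic_config()] (the `expression` element is
#'   used).
#' @param seed integer seed.
#' @return list with `counts` (genes x samples), `lengths`, `annotations`
#'   (per sample: `sample`, `strain`, `mu`, `Y`, `q_glc`, `q_o2`, `q_ac`,
#'   `group`), `replicate_pairs`, `signal_genes`, `signal_direction`,
#'   `gene_sets` (planted oxidative-phosphorylation and TCA annotations),
#'   `group` (per strain).
#' @export
make_expression_fixture <- function(config = synthetic_config(), seed = 1) {
  set.seed(seed)
  ex <- config$expression
  ng <- ex$n_genes
  ns <- ex$n_strains

  genes <- sprintf("g%04d", seq_len(ng))
  lengths <- stats::setNames(sample(200:4000, ng, replace = TRUE), genes)

  # two aero-type groups with bimodal yield
  group <- rep(c("low", "high"), length.out = ns)
  Y <- ifelse(group == "high", stats::rnorm(ns, 0.52, 0.02),
              stats::rnorm(ns, 0.35, 0.02))
  q_ac <- pmax(0.1, 12 - 18 * Y + stats::rnorm(ns, 0, 0.3))
  mu <- stats::runif(ns, 0.4, 0.9)
  q_glc <- mu / (Y * 0.18016)
  q_o2 <- pmax(0.5, 25 * Y - 4 + stats::rnorm(ns, 0, 0.5))

  n_sig <- ex$n_signal
  signal <- sample(genes, n_sig)
  direction <- stats::setNames(rep(c(1, -1), length.out = n_sig), signal)

  # baseline log2 intensities: spread kept moderate so that sequencing
  # noise at the configured depth stays within the replicate-QC target
  base <- stats::rnorm(ng, 6, 1)
  names(base) <- genes
  z <- as.numeric(scale(Y))

  strains <- sprintf("strain%02d", seq_len(ns))
  samples <- as.vector(t(outer(strains, c("_r1", "_r2"), paste0)))
  logint <- matrix(0, ng, 2 * ns, dimnames = list(genes, samples))
  for (s in seq_len(ns)) {
    prof <- base + stats::rnorm(ng, 0, 0.25)
    prof[signal] <- prof[signal] + ex$effect * z[s] * direction[signal]
    for (r in 1:2) {
      col <- (s - 1) * 2 + r
      logint[, col] <- prof + stats::rnorm(ng, 0, ex$replicate_sd)
    }
  }

  # counts such that TPM recovers the intensities: count ~ TPM * length
  counts <- matrix(0L, ng, 2 * ns, dimnames = list(genes, samples))
  for (j in seq_len(2 * ns)) {
    tpm_share <- 2^logint[, j]
    pr <- tpm_share * lengths
    counts[, j] <- as.integer(stats::rmultinom(1, ex$depth, pr / sum(pr)))
  }

  # planted pathway annotations: signal genes seeded into the sets
  up <- signal[direction[signal] > 0]
  dn <- signal[direction[signal] < 0]
  noise_pool <- setdiff(genes, signal)
  oxphos <- c(up, sample(noise_pool, ex$oxphos_size - length(up)))
  noise_pool <- setdiff(noise_pool, oxphos)
  tca <- c(dn[seq_len(min(7, length(dn)))],
           sample(noise_pool, ex$tca_size - min(7, length(dn))))

  annotations <- data.frame(sample = samples,
                            strain = rep(strains, each = 2),
                            mu = rep(mu, each = 2), Y = rep(Y, each = 2),
                            q_glc = rep(q_glc, each = 2),
                            q_o2 = rep(q_o2, each = 2),
                            q_ac = rep(q_ac, each = 2),
                            group = rep(group, each = 2),
                            stringsAsFactors = FALSE)
  list(counts = counts, lengths = lengths, annotations = annotations,
       replicate_pairs = data.frame(a = paste0(strains, "_r1"),
                                    b = paste0(strains, "_r2"),
                                    stringsAsFactors = FALSE),
       signal_genes = signal, signal_direction = direction,
       gene_sets = list(oxidative_phosphorylation = oxphos, TCA = tca),
       group = stats::setNames(group, strains))
}
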