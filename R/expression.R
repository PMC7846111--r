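# Downstream expression statistics, starting from a counts matrix:
# TPM normalisation, replicate quality control, phenotype-correlated gene
# selection, exact binomial gene-set enrichment, and hierarchical
# clustering on correlation distance.

#' TPM normalisation
#'
#' `TPM_g = 1e6 (count_g / length_g) / sum_g' (count_g' / length_g')`,
#' per sample.
#'
#' @param counts genes x samples matrix of non-negative counts (rownames =
#'   gene ids).
#' @param lengths per-gene effective length (bp), named or in row order.
#' @return TPM matrix of the same shape; columns sum to 1e6.
#' @export
counts_to_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts) || any(is.na(lengths)) ||
      any(lengths <= 0))
    stop("need one positive length per gene")
  rate <- counts / lengths
  tot <- colSums(rate)
  zero <- tot <= 0
  if (any(zero))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(rate, 2, tot, "/") * 1e6
}

#' Log-transformed TPM
#'
#' `log2(TPM + 1)`, the scale used for all downstream statistics.
#'
#' @inheritParams counts_to_tpm
#' @return log-TPM matrix.
#' @export
counts_to_logtpm <- function(counts, lengths) {
  log2(counts_to_tpm(counts, lengths) + 1)
}

#' Replicate quality control
#'
#' Squared Pearson correlation of log-TPM profiles for each pair of
#' biological replicates.
#'
#' @param logtpm log-TPM matrix (genes x samples).
#' @param pairs two-column data frame (or matrix) of sample-name pairs.
#' @return named numeric vector of per-pair R-squared values.
#' @export
replicate_qc <- function(logtpm, pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(ncol(pairs) >= 2)
  vapply(seq_len(nrow(pairs)), function(i) {
    a <- as.character(pairs[i, 1]); b <- as.character(pairs[i, 2])
    if (!a %in% colnames(logtpm) || !b %in% colnames(logtpm))
      stop("unknown sample in replicate pair: ", a, " / ", b)
    x <- logtpm[, a]; y <- logtpm[, b]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("constant expression profile in pair ", a, " / ", b)
    stats::cor(x, y)^2
  }, 0, USE.NAMES = FALSE) -> r2
  stats::setNames(r2, paste(pairs[[1]], pairs[[2]], sep = "/"))
}

#' Select genes correlated with the fermentative phenotype but not growth
#'
#' A gene is selected when its log-TPM profile correlates with both the
#' acetate production rate and the biomass yield (Pearson p < `alpha`) but
#' not with the growth rate (p >= `alpha`). These are the phenotype
#' parameters that track the aero-type rather than the growth rate.
#'
#' @param logtpm log-TPM matrix (genes x samples).
#' @param annotations data frame with one row per sample (matched by a
#'   `sample` column or by order) carrying `q_ac`, `Y` and `mu`.
#' @param alpha significance threshold (default 0.01).
#' @return list with `genes` (selected ids) and `report` (per-gene
#'   correlations, p-values and the selection flag).
#' @export
select_phenotype_genes <- function(logtpm, annotations, alpha = 0.01) {
  ann <- as.data.frame(annotations)
  if ("sample" %in% names(ann)) {
    miss <- setdiff(colnames(logtpm), ann$sample)
    if (length(miss))
      stop("annotation missing for sample(s): ",
           paste(miss, collapse = ", "))
    ann <- ann[match(colnames(logtpm), ann$sample), ]
  } else if (nrow(ann) != ncol(logtpm)) {
    stop("annotations must match the samples")
  }
  if (ncol(logtpm) < 4)
    stop("need at least 4 annotated samples for correlation tests")
  ctest <- function(x, y) {
    if (stats::sd(x) == 0) return(c(r = 0, p = 1))
    ct <- stats::cor.test(x, y)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  rep_g <- t(apply(logtpm, 1, function(x) {
    a <- ctest(x, ann$q_ac); b <- ctest(x, ann$Y); m <- ctest(x, ann$mu)
    c(r_qac = a["r"], p_qac = a["p"], r_Y = b["r"], p_Y = b["p"],
      r_mu = m["r"], p_mu = m["p"])
  }))
  report <- as.data.frame(rep_g)
  names(report) <- c("r_qac", "p_qac", "r_Y", "p_Y", "r_mu", "p_mu")
  report$gene <- rownames(logtpm)
  report$selected <- report$p_qac < alpha & report$p_Y < alpha &
    report$p_mu >= alpha
  list(genes = report$gene[report$selected],
       report = report[, c("gene", "r_qac", "p_qac", "r_Y", "p_Y",
                           "r_mu", "p_mu", "selected")])
}

#' One-sided binomial gene-set enrichment
#'
#' Exact upper-tail probability `P(X >= k)` with
#' `X ~ Binomial(n, K / N)`: the chance of seeing at least `k` selected
#' genes in a set of size `n` when `K` of the `N` genes in the universe are
#' selected.
#'
#' @param k selected genes inside the set.
#' @param n set size.
#' @param K selected genes in the universe.
#' @param N universe size.
#' @return one-sided p-value.
#' @export
binomial_enrichment <- function(k, n, K, N) {
  if (k < 0 || k > n) stop("require 0 <= k <= n")
  if (K <= 0 || K > N) stop("require 0 < K <= N")
  stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)
}

#' Hierarchical clustering of expression profiles
#'
#' Average-linkage clustering of samples on the correlation distance
#' `1 - Pearson` computed over a gene subset. Samples are taken in
#' column-name order, which fixes the leaf order on ties.
#'
#' @param logtpm log-TPM matrix (genes x samples).
#' @param genes gene subset (default all genes).
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust` (the dendrogram) and `clusters` (named
#'   integer vector when `k` is given, else `NULL`).
#' @export
hierarchical_cluster <- function(logtpm, genes = NULL, k = NULL) {
  X <- logtpm
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(X))
    if (length(miss))
      stop("unknown gene(s): ", paste(utils::head(miss, 5), collapse = ", "))
    X <- X[genes, , drop = FALSE]
  }
  X <- X[, order(colnames(X)), drop = FALSE]
  if (ncol(X) == 1) {
    return(list(hclust = NULL,
                clusters = stats::setNames(1L, colnames(X))))
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant expression profile: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(X))
  hc <- stats::hclust(d, method = "average")
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, clusters = clusters)
}
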