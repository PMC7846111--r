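test_that("TPM normalization matches its definition", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- counts_to_tpm(counts, c(a = 100, b = 200))
  # hand arithmetic: rates 0.1 and 0.05 -> 2/3 and 1/3 of a million
  expect_equal(unname(tpm[, 1]), c(2, 1) / 3 * 1e6, tolerance = 1e-9)

  single <- matrix(5, 1, 1, dimnames = list("g", "s"))
  expect_equal(unname(counts_to_tpm(single, c(g = 500))[1, 1]), 1e6)
  expect_equal(unname(counts_to_logtpm(single, c(g = 500))[1, 1]),
               log2(1e6 + 1))

  fx <- expr_fixture()
  tpm2 <- counts_to_tpm(fx$counts, fx$lengths)
  expect_equal(unname(colSums(tpm2)), rep(1e6, ncol(tpm2)),
               tolerance = 1e-6)
  # scale invariance: multiplying one sample's counts changes nothing
  scaled <- fx$counts
  scaled[, 3] <- scaled[, 3] * 7
  tpm3 <- counts_to_tpm(scaled, fx$lengths)
  expect_equal(tpm3[, 3], tpm2[, 3], tolerance = 1e-9)

  zero <- fx$counts
  zero[, 2] <- 0
  expect_error(counts_to_tpm(zero, fx$lengths), colnames(fx$counts)[2])
})

test_that("replicate QC computes squared correlations", {
  lt <- expr_logtpm()
  fx <- expr_fixture()
  r2 <- replicate_qc(lt, fx$replicate_pairs)
  expect_true(all(r2 > 0.97))  # generator property
  # identical replicates have R^2 = 1
  dup <- cbind(lt[, 1, drop = FALSE], lt[, 1, drop = FALSE])
  colnames(dup) <- c("x", "y")
  expect_equal(unname(replicate_qc(dup, data.frame(a = "x", b = "y"))), 1)
  # independent noise profiles decorrelate (simulation oracle)
  set.seed(31)
  noise <- matrix(rnorm(8000), 4000, 2, dimnames = list(NULL, c("n1", "n2")))
  expect_lt(unname(replicate_qc(noise, data.frame(a = "n1", b = "n2"))),
            0.01)
  const <- noise
  const[, 2] <- 1
  expect_error(replicate_qc(const, data.frame(a = "n1", b = "n2")),
               "constant")
})

test_that("phenotype-correlated gene selection follows the three criteria", {
  set.seed(8)
  ns <- 24
  ann <- data.frame(sample = sprintf("s%02d", 1:ns),
                    q_ac = runif(ns, 1, 10), mu = runif(ns, 0.3, 0.9))
  ann$Y <- 0.6 - 0.04 * ann$q_ac + rnorm(ns, 0, 0.01)
  # construct: gene tracking q_ac and Y; gene tracking mu only; pure noise
  sig <- 5 + 2 * scale(ann$q_ac)[, 1]
  mu_g <- 5 + 2 * scale(ann$mu)[, 1]
  X <- rbind(sig = sig + rnorm(ns, 0, 0.1),
             mug = mu_g + rnorm(ns, 0, 0.1),
             noise = rnorm(ns, 5, 1))
  colnames(X) <- ann$sample
  sel <- select_phenotype_genes(X, ann)
  expect_true("sig" %in% sel$genes)
  expect_false("mug" %in% sel$genes)
  expect_error(select_phenotype_genes(X[, 1:3], ann[1:3, ]), "4")
})

test_that("binomial enrichment is the exact upper tail", {
  # brute-force point-mass oracle for n <= 100
  set.seed(12)
  for (i in 1:50) {
    n <- sample(1:100, 1)
    k <- sample(0:n, 1)
    K <- sample(1:300, 1); N <- K + sample(0:4000, 1)
    p <- K / N
    brute <- sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
    expect_equal(binomial_enrichment(k, n, K, N), brute,
                 tolerance = 1e-12)
  }
  expect_equal(binomial_enrichment(0, 10, 5, 100), 1)
  expect_error(binomial_enrichment(11, 10, 5, 100), "k <= n")
  expect_error(binomial_enrichment(2, 10, 0, 100), "0 < K")
})

test_that("hierarchical clustering uses correlation distance", {
  lt <- expr_logtpm()
  # two identical samples merge at height zero
  dup <- cbind(lt[, 1:3], lt[, 1, drop = FALSE])
  colnames(dup) <- c(colnames(lt)[1:3], "copy")
  hc <- hierarchical_cluster(dup)
  expect_lt(min(hc$hclust$height), 1e-12)
  # a single sample is a singleton
  single <- hierarchical_cluster(lt[, 1, drop = FALSE])
  expect_null(single$hclust)
  expect_equal(unname(single$clusters), 1L)
  expect_error(hierarchical_cluster(matrix(1, 5, 2,
                                           dimnames = list(NULL,
                                                           c("a", "b")))),
               "constant")
})
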