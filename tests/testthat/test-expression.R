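test_that("log2 transform and row standardisation behave as defined", {
  m <- matrix(c(0, 1, 7, 3), 2, 2)
  expect_equal(log2_transform(m), log2(m + 1))
  expect_equal(log2_transform(matrix(7)), matrix(3))
  expect_error(log2_transform(matrix(-1)), "nonnegative")

  r <- matrix(c(1, 2, 3), 1, 3)
  z <- standardize_rows(r)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  m2 <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_warning(z2 <- standardize_rows(m2), "zero-variance")
  expect_equal(rownames(z2), "b")
  set.seed(81)
  big <- matrix(rnorm(300), 30)
  zb <- standardize_rows(big)
  expect_lt(max(abs(rowMeans(zb))), 1e-12)
  expect_lt(max(abs(apply(zb, 1, sd) - 1)), 1e-12)
})

test_that("DEG selection recovers planted responders and controls type I error", {
  ex <- generate_expression(n_genes = 1000, k_clusters = 3,
                            n_responders = 100, seed = 82)
  degs <- select_degs(ex$fpkm, ex$samples)
  truth <- ex$truth$responder
  for (cond in c("cold", "heat")) {
    d <- degs[[cond]]$table
    recall <- sum(d$deg & truth) / sum(truth)
    precision <- sum(d$deg & truth) / sum(d$deg)
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.9)
  }
  # a gene with identical stress and control profiles is never a DEG
  fpkm_flat <- matrix(5, 1, nrow(ex$samples),
                      dimnames = list("flat", ex$samples$sample))
  d_flat <- select_degs(fpkm_flat, ex$samples)$cold$table
  expect_false(d_flat$deg)
  expect_equal(d_flat$max_abs_log2fc, 0)

  # null data: empirical type-I proportion stays near alpha
  ex0 <- generate_expression(n_genes = 5000, n_responders = 0, seed = 83)
  d0 <- select_degs(ex0$fpkm, ex0$samples)$cold$table
  expect_lte(mean(d0$p_value <= 0.05), 1.5 * 0.05)
  expect_error(select_degs(ex$fpkm, transform(ex$samples,
                                              condition = "cold")),
               "control")
})

test_that("noise-free responders with 4-fold induction all pass", {
  ex <- generate_expression(n_genes = 200, k_clusters = 2, n_responders = 40,
                            noise_sd = 0, seed = 84)
  d <- select_degs(ex$fpkm, ex$samples)$salt$table
  expect_true(all(d$deg[ex$truth$responder]))
  expect_false(any(d$deg[!ex$truth$responder]))
})

test_that("elbow-based k selection finds planted cluster counts", {
  set.seed(85)
  blobs <- rbind(matrix(rnorm(50 * 4, 0), ncol = 4),
                 matrix(rnorm(50 * 4, 6), ncol = 4),
                 matrix(rnorm(50 * 4, 12), ncol = 4))
  expect_equal(choose_k(blobs, seed = 85), 3)
  expect_equal(choose_k(blobs, seed = 85), choose_k(blobs, seed = 85))
  noise <- matrix(rnorm(120 * 4), ncol = 4)
  expect_equal(choose_k(noise, seed = 85), 2)
})

test_that("fuzzy c-means is row-stochastic with a monotone objective", {
  set.seed(86)
  clouds <- rbind(matrix(rnorm(40 * 3, 0), ncol = 3),
                  matrix(rnorm(40 * 3, 20), ncol = 3))
  rownames(clouds) <- sprintf("g%02d", 1:80)
  fc <- fuzzy_cmeans(clouds, 2, seed = 86)
  expect_lt(max(abs(rowSums(fc$membership) - 1)), 1e-9)
  expect_true(all(diff(fc$objective) <= 1e-8))
  expect_true(all(apply(fc$membership, 1, max) > 0.99))
  part <- fc$cluster
  expect_equal(length(unique(part[1:40])), 1)
  expect_equal(length(unique(part[41:80])), 1)
  expect_true(part[1] != part[41])
  expect_error(fuzzy_cmeans(clouds, 100, seed = 1), "more clusters")
  expect_error(fuzzy_cmeans(clouds, 1, seed = 1))
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(87)
  clouds <- rbind(matrix(rnorm(30 * 3, 0), ncol = 3),
                  matrix(rnorm(30 * 3, 8), ncol = 3))
  fc <- fuzzy_cmeans(clouds, 2, fuzzifier = 1.25, seed = 87)
  ref <- e1071::cmeans(clouds, 2, m = 1.25)
  # match cluster labels by nearest centers, then compare
  ord <- apply(ref$centers, 1, function(cc)
    which.min(colSums((t(fc$centers) - cc)^2)))
  expect_equal(unname(fc$centers[ord, ]), unname(ref$centers),
               tolerance = 1e-3)
  expect_equal(unname(fc$membership[, ord]), unname(ref$membership),
               tolerance = 1e-3)
})

test_that("BH correction reproduces the step-up formula", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(88)
  p <- runif(50)
  fdr <- benjamini_hochberg(p)
  # hand-computed step-up: fdr_(i) = min_{j >= i} m p_(j) / j
  m <- length(p)
  ord <- order(p)
  manual <- rev(cummin(rev(pmin(1, m * p[ord] / seq_len(m)))))
  expect_equal(fdr[ord], manual)
  # monotone: fdr order respects p order
  expect_true(all(diff(fdr[ord]) >= 0))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher enrichment equals the hypergeometric tail sum", {
  genes <- sprintf("g%03d", 1:100)
  go <- setNames(vector("list", 100), genes)
  for (g in genes[1:10]) go[[g]] <- "GO:0000100"   # annotates 10 genes
  cluster <- genes[c(1:5, 50:54)]                  # 5 of them in the cluster
  res <- fisher_enrichment(cluster, genes, go)
  row <- res[res$term == "GO:0000100", ]
  expect_equal(row$k, 5)
  expect_equal(row$p_value, oracle_hyper_tail(5, 10, 10, 100))

  # a term annotating every gene has p = 1
  for (g in genes) go[[g]] <- c(go[[g]], "GO:0000200")
  res2 <- fisher_enrichment(cluster, genes, go)
  expect_equal(res2$p_value[res2$term == "GO:0000200"], 1)
  expect_error(fisher_enrichment(character(), genes, go), "empty")
})

test_that("random 2x2 configurations match the exact tail to 1e-10", {
  set.seed(89)
  for (i in 1:200) {
    N <- sample(20:500, 1)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    p <- phyper(k - 1, n, N - n, K, lower.tail = FALSE)
    expect_equal(p, oracle_hyper_tail(k, K, n, N), tolerance = 1e-10)
  }
})

test_that("a planted enriched term is detected at FDR 0.01", {
  genes <- sprintf("g%04d", 1:500)
  target <- genes[1:40]
  go <- generate_go(genes, n_terms = 30,
                    enriched_spec = list(list(genes = target,
                                              rate_in = 0.8)), seed = 90)
  res <- fisher_enrichment(target, genes, go$go_map)
  expect_equal(res$term[1], go$truth$enriched_terms)
  expect_true(res$enriched[1])
  expect_lte(res$fdr[1], 0.01)
})
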