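test_that("pseudobulk sums match hand arithmetic; missing is not zero", {
  counts <- matrix(c(1, 2, 3, 4,   # cell1 (cl A, s1)
                     5, 6, 7, 8,   # cell2 (cl A, s1)
                     1, 0, 0, 1,   # cell3 (cl A, s2)
                     2, 2, 2, 2),  # cell4 (cl B, s1)  -- B absent in s2
                   nrow = 4, dimnames = list(paste0("g", 1:4), NULL))
  clusters <- c("A", "A", "A", "B")
  samples <- c("s1", "s1", "s2", "s1")
  expect_warning(pb <- make_pseudobulk(counts, clusters, samples,
                                       target_size = 36),
                 "< 2 samples")
  # A/s1 raw sums: 6,8,10,12 (total 36) -> unchanged at target 36
  expect_equal(unname(pb$values$A[, "s1"]), c(6, 8, 10, 12))
  # A/s2 raw sums: 1,0,0,1 scaled to total 36
  expect_equal(unname(pb$values$A[, "s2"]), c(18, 0, 0, 18))
  expect_true(all(is.na(pb$values$B[, "s2"])))
  expect_true(pb$missing["B", "s2"])
  expect_equal(pb$usable_clusters, "A")
  # every non-missing profile sums to the common size
  expect_equal(colSums(pb$values$A), c(s1 = 36, s2 = 36))
})

test_that("LOESS HVG selection finds variance-spiked genes and skips constants", {
  set.seed(3)
  n_genes <- 300L; n_samples <- 8L
  mu <- stats::rlnorm(n_genes, 3, 1)
  sd_trend <- function(m) 0.1 * m + 1
  mat <- t(vapply(seq_len(n_genes), function(i)
    stats::rnorm(n_samples, mu[i], sd_trend(mu[i])), numeric(n_samples)))
  spiked <- sample.int(n_genes, 15L)
  mat[spiked, ] <- t(vapply(spiked, function(i)
    stats::rnorm(n_samples, mu[i], 6 * sd_trend(mu[i])), numeric(n_samples)))
  rownames(mat) <- paste0("g", seq_len(n_genes))
  mat <- rbind(mat, const1 = rep(5, n_samples))  # SD = 0, never selected
  hvg <- select_hvg_loess(mat)
  expect_false("const1" %in% hvg)
  expect_gte(mean(paste0("g", spiked) %in% hvg), 0.9)
  # fallback with too few informative genes
  tiny <- matrix(stats::rnorm(5 * 4), 5, 4,
                 dimnames = list(paste0("g", 1:5), NULL)) - 10
  expect_warning(select_hvg_loess(pmin(tiny, 0)), "falling back")
})

test_that("concatenated PCA standardizes features and separates planted groups", {
  set.seed(5)
  sim <- simulate_sc(n_cells = 1200L, n_genes = 200L, n_clusters = 3L,
                     n_samples = 6L, de_lfc = 2, seed = 8L)
  pb <- make_pseudobulk(sim$ds)
  emb <- concat_pca(pb)
  expect_lt(max(abs(colMeans(emb$x))), 1e-8)
  expect_lt(max(abs(apply(emb$x, 2L, stats::var) - 1)), 1e-6)
  expect_true(all(emb$features$cluster %in% pb$clusters))
  # PC1 separates MPR from nonMPR samples under a strong planted shift
  grp <- sim$ds$cell_meta$group[match(rownames(emb$embedding),
                                      sim$ds$cell_meta$sample)]
  pc1 <- emb$embedding[, 1L]
  expect_true(max(pc1[grp == "MPR"]) < min(pc1[grp == "nonMPR"]) ||
              min(pc1[grp == "MPR"]) > max(pc1[grp == "nonMPR"]))
  expect_error(concat_pca(make_pseudobulk(
    sim$ds$counts[, 1:10], rep("A", 10), rep(c("s1", "s2"), 5))), "3 samples")
})

test_that("duplicated samples embed at coincident points", {
  set.seed(9)
  x <- matrix(stats::rnorm(40), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("f", 1:10)))
  x <- rbind(x, s5 = x["s1", ])  # exact duplicate of s1
  pb <- list(values = list(A = t(x)), samples = rownames(x), clusters = "A",
             missing = matrix(FALSE, 1, 5, dimnames = list("A", rownames(x))),
             target_size = 1, usable_clusters = "A")
  class(pb) <- "PseudobulkProfile"
  emb <- concat_pca(pb, hvg_sets = list(A = paste0("f", 1:10)))
  expect_equal(emb$embedding["s1", ], emb$embedding["s5", ], tolerance = 1e-10)
})

test_that("CC permutation test: perfect association, determinism, ordering", {
  set.seed(2)
  emb <- matrix(stats::rnorm(24), 12, 2)
  res <- cc_permutation_test(emb, emb[, 1L], n_perm = 200L, seed = 5L)
  expect_equal(res$observed_cc, 1, tolerance = 1e-10)
  expect_equal(res$p_value, 1 / 201)
  # reproducible under a seed and invariant to sample reordering
  res2 <- cc_permutation_test(emb, emb[, 1L], n_perm = 200L, seed = 5L)
  expect_identical(res$null_ccs, res2$null_ccs)
  ord <- sample.int(12)
  res3 <- cc_permutation_test(emb[ord, ], emb[ord, 1L], n_perm = 200L, seed = 5L)
  expect_equal(res3$observed_cc, res$observed_cc, tolerance = 1e-10)
  expect_error(cc_permutation_test(emb, rep("a", 12)), "constant")
})

test_that("binary covariate with complete separation is called significant", {
  set.seed(4)
  grp <- rep(c(0, 1), each = 10)
  emb <- cbind(stats::rnorm(20, grp * 6), stats::rnorm(20))
  res <- cc_permutation_test(emb, grp, n_perm = 10000L, seed = 1L)
  expect_lte(res$p_value, 0.001)
})

test_that("enrichment ratio arithmetic and threshold semantics", {
  sizes <- c(a = 100, b = 300, c = 600)
  mana <- c(a = 10, b = 4, c = 6)
  enr <- mana_enriched_clusters(sizes, mana, fold = 2)
  ratio <- attr(enr, "ratio")
  expect_equal(unname(ratio["a"]), (10 / 20) / (100 / 1000))  # = 5
  expect_equal(enr, "a", ignore_attr = TRUE)
  # uniform labels -> ratio 1 everywhere, nothing enriched at fold 2
  uni <- mana_enriched_clusters(sizes, sizes / 10, fold = 2)
  expect_length(uni, 0L)
  expect_equal(unname(attr(uni, "ratio")), rep(1, 3))
  # fold = 1 admits every cluster at ratio >= 1
  expect_equal(sort(mana_enriched_clusters(sizes, sizes / 10, fold = 1)),
               c("a", "b", "c"), ignore_attr = TRUE)
  expect_error(mana_enriched_clusters(sizes, c(a = 0, b = 0, c = 0)),
               "no labelled")
})

test_that("per-batch standardization hook runs and preserves shape", {
  sim <- simulate_sc(n_cells = 600L, n_genes = 100L, n_clusters = 2L,
                     n_samples = 4L, seed = 13L)
  pb <- make_pseudobulk(sim$ds)
  batch <- c("b1", "b1", "b2", "b2")
  cor1 <- correct_batch(pb, batch)
  expect_equal(dim(cor1$values[[1L]]), dim(pb$values[[1L]]))
  # external hook takes precedence
  cor2 <- correct_batch(pb, batch, fun = function(mat, batch) mat * 0)
  expect_true(all(cor2$values[[1L]] == 0, na.rm = TRUE))
})
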