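test_that("module score is near zero for a self-control set and shift-invariant", {
  expr <- toy_expr(n_genes = 120L, n_cells = 300L, seed = 2L)
  s_all <- module_score(expr, gene_set(rownames(expr), "all"), seed = 3L)
  expect_lt(abs(mean(s_all)), 0.02)
  # adding a constant to every gene in every cell cancels in the score
  set <- gene_set(rownames(expr)[1:10], "s")
  s1 <- module_score(expr, set, seed = 3L)
  s2 <- module_score(expr + 3.7, set, seed = 3L)
  expect_lt(max(abs(s1 - s2)), 1e-6)
  # seeded reproducibility, bit-identical
  expect_identical(s1, module_score(expr, set, seed = 3L))
  # absent genes dropped with warning; fully absent set errors
  expect_warning(module_score(expr, gene_set(c("g1", "NOPE"), "m")), "absent")
  expect_error(suppressWarnings(module_score(expr, gene_set("NOPE"))),
               "no set genes")
})

test_that("a planted subpopulation shift moves the score by about the shift", {
  expr <- toy_expr(n_genes = 1000L, n_cells = 400L, seed = 5L)
  set <- gene_set(sample(rownames(expr), 20L), "planted")
  sub <- 1:100
  expr2 <- expr
  expr2[set$genes, sub] <- expr2[set$genes, sub] + 1
  s <- module_score(expr2, set, seed = 1L)
  expect_equal(mean(s[sub]) - mean(s[-sub]), 1, tolerance = 0.1)
})

test_that("checkpoint score is monotone in the six genes and warns when absent", {
  expr <- toy_expr(n_genes = 100L, n_cells = 200L, seed = 7L)
  rownames(expr)[1:6] <- c("CTLA4", "PDCD1", "LAG3", "HAVCR2", "TIGIT", "ENTPD1")
  lo <- 1:100; hi <- 101:200
  expr[1:6, lo] <- 0
  expr[1:6, hi] <- expr[1:6, hi] + 2
  s <- checkpoint_score(expr, seed = 2L)
  expect_gt(mean(s[hi]), mean(s[lo]))
  # two-sided rank-sum on the scores flags the planted group difference
  expect_lt(stats::wilcox.test(s[hi], s[lo])$p.value, 1e-6)
  # permuting cell order permutes scores identically
  ord <- sample(ncol(expr))
  expect_identical(as.numeric(checkpoint_score(expr[, ord], seed = 2L)),
                   as.numeric(s[ord]))
  # a partially missing set warns and lists the members
  partial <- expr
  rownames(partial)[1L] <- "NOTCTLA4"
  # both the checkpoint wrapper and the generic score warn about the gap
  expect_warning(expect_warning(checkpoint_score(partial, seed = 1L), "CTLA4"))
})

test_that("exhaustion score uses the packaged synthetic list by default", {
  expr <- toy_expr(n_genes = 100L, n_cells = 150L, seed = 8L)
  rownames(expr)[1:4] <- c("TOX", "PDCD1", "LAG3", "BATF")
  s <- suppressWarnings(exhaustion_score(expr, seed = 1L))
  expect_length(s, 150L)
  s2 <- exhaustion_score(expr, genes = c("TOX", "PDCD1"), seed = 1L)
  expect_false(identical(s, s2))
})

test_that("score-correlated genes: exclusion, ranking, group difference", {
  expr <- toy_expr(n_genes = 150L, n_cells = 300L, seed = 9L)
  score <- as.numeric(expr["g1", ])           # g1 equals the score
  expr <- rbind(expr, FLAT = rep(1, ncol(expr)))
  groups <- rep(c("MPR", "nonMPR"), each = 150L)
  # planted: correlates with the score only in MPR cells
  planted <- rep(0, ncol(expr))
  planted[groups == "MPR"] <- score[groups == "MPR"] +
    stats::rnorm(150L, 0, 0.3 * stats::sd(score))
  expr <- rbind(expr, PLANTED = planted)
  out <- score_correlated_genes(expr, score, exclude = gene_set("g1", "ex"),
                                top_k = 200L, groups = groups)
  expect_false("g1" %in% out$gene)
  expect_true(out$constant[out$gene == "FLAT"])
  expect_equal(out$cor[out$gene == "FLAT"], 0)
  # the planted gene sits in the positive tail of the correlation difference
  expect_gte(out$cor_diff[out$gene == "PLANTED"],
             stats::quantile(out$cor_diff, 0.95))
  # deterministic given input ordering
  out2 <- score_correlated_genes(expr, score, exclude = gene_set("g1", "ex"),
                                 top_k = 200L, groups = groups)
  expect_identical(out, out2)
  # a gene equal to the score ranks first with coefficient 1
  out3 <- score_correlated_genes(expr, as.numeric(expr["g2", ]), top_k = 5L)
  expect_equal(out3$gene[1L], "g2")
  expect_equal(out3$cor[1L], 1, tolerance = 1e-12)
})

test_that("rank-sum marker p-values match exact enumeration for small groups", {
  set.seed(11)
  for (sizes in list(c(4L, 5L), c(6L, 6L), c(8L, 7L))) {
    x <- stats::rnorm(sizes[1L]); y <- stats::rnorm(sizes[2L], 1)
    expr <- rbind(gA = c(x, y), other = stats::rnorm(sum(sizes)))
    groups <- rep(c("a", "b"), sizes)
    mk <- marker_genes(expr, groups, min_pct = 0, only_pos = FALSE)
    got <- mk$p[mk$gene == "gA" & mk$group == "a"]
    expect_equal(got, oracle_ranksum_two_sided(x, y), tolerance = 1e-12)
  }
})

test_that("marker calling recovers planted 2-fold genes, excludes 1.1-fold ones", {
  set.seed(13)
  n <- 120L
  # counts on the expm1 scale: planted log2FC = 1 via (5+1)/(2+1) = 2
  strong <- log1p(c(stats::rpois(n, 5), stats::rpois(n, 2)))
  weak <- log1p(c(stats::rpois(n, 2.35), stats::rpois(n, 2)))  # (3.35/3) ~ 0.16
  flat <- log1p(stats::rpois(2L * n, 3))
  expr <- rbind(STRONG = strong, WEAK = weak, FLAT = flat)
  groups <- rep(c("hi", "rest"), each = n)
  mk <- marker_genes(expr, groups)
  srow <- mk[mk$gene == "STRONG" & mk$group == "hi", ]
  expect_true(srow$significant)
  expect_equal(srow$log2fc, 1, tolerance = 0.25)
  wrow <- mk[mk$gene == "WEAK" & mk$group == "hi", ]
  expect_false(wrow$significant)   # excluded by the fold-change floor
  expect_lt(wrow$log2fc, 0.25)
  # identical groups produce no markers
  same <- rbind(g1 = rep(flat, 2L))[, 1:(2 * n), drop = FALSE]
  mk0 <- marker_genes(same, groups)
  expect_false(any(mk0$significant))
  # Bonferroni equals the direct formula
  expect_equal(mk$p_bonferroni, pmin(1, mk$p * 3L))
  expect_error(marker_genes(expr, rep("one", 2L * n)), "2 groups")
  small_grp <- c(rep("a", 2L), rep("b", n - 1L), rep("c", n - 1L))
  expect_warning(marker_genes(expr, small_grp), "skipped")
})

test_that("dose-response summaries aggregate correctly and detect a trend", {
  set.seed(17)
  dose <- rep(c(0.1, 1, 10, 100), each = 40L)
  grp <- rep(rep(c("MANA", "flu"), each = 20L), times = 4L)
  score <- ifelse(grp == "MANA", 0.5 * log(dose), 0) + stats::rnorm(160L, 0, 0.3)
  out <- dose_response_summary(score, dose, grp)
  expect_equal(nrow(out$summary), 8L)
  expect_equal(out$summary$n, rep(20L, 8L))
  tr <- out$trend
  expect_lt(tr$p[tr$group == "MANA"], 1e-4)
  expect_gt(tr$spearman_rho[tr$group == "MANA"], 0.5)
  expect_lt(abs(tr$spearman_rho[tr$group == "flu"]), 0.35)
  # all scores equal -> SEM 0 everywhere
  out0 <- dose_response_summary(rep(1, 160L), dose, grp)
  expect_true(all(out0$summary$sem == 0))
  # weighted group means reconstruct the overall mean
  w <- out$summary
  expect_equal(sum(w$mean * w$n) / sum(w$n), mean(score), tolerance = 1e-12)
  # single (group, dose) cell with < 2 cells is flagged
  idx <- c(1, 21, 41, 61, 81)
  out1 <- dose_response_summary(score[idx], dose[idx], grp[idx])
  expect_true(any(out1$summary$sem_undefined))
  expect_error(dose_response_summary(score, rep(1, 160L), grp), "2 doses")
})
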