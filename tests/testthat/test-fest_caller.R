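test_that("one-sided Fisher p matches the enumeration oracle and fisher.test", {
  cases <- expand.grid(a = c(0L, 1L, 5L, 10L), b = c(0L, 2L, 5L),
                       n1 = c(20L, 100L), n2 = c(20L, 150L))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      got <- fisher_expansion_test(a, n1, b, n2)
      expect_equal(got$p, oracle_fisher_greater(a, n1, b, n2), tolerance = 1e-12)
      expect_equal(got$p,
                   stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2,
                                             byrow = TRUE),
                                      alternative = "greater")$p.value,
                   tolerance = 1e-9)
    })
  }
})

test_that("Fisher edge cases: empty clone, symmetry, odds-ratio correction", {
  expect_equal(fisher_expansion_test(0, 100, 0, 100)$p, 1.0)
  expect_gte(fisher_expansion_test(5, 1000, 5, 1000)$p, 0.5)
  # Haldane-Anscombe +0.5 on all cells when any cell is zero
  got <- fisher_expansion_test(10, 100, 0, 100)
  expect_equal(got$odds_ratio, (10.5 * 100.5) / (90.5 * 0.5))
  # no correction when all cells positive
  expect_equal(fisher_expansion_test(10, 100, 5, 100)$odds_ratio,
               (10 * 95) / (90 * 5))
  expect_error(fisher_expansion_test(1, 0, 0, 10), "positive")
})

test_that("one-sided p is monotone decreasing in a at fixed margins", {
  n1 <- 200L; n2 <- 300L; K <- 40L
  a <- max(0L, K - n2):min(n1, K)
  p <- fisher_expansion_test(a, n1, K - a, n2)$p
  expect_true(all(diff(p) <= 1e-12))
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("well presence fraction counts wells with >= 1 read", {
  rec <- data.frame(well_id = paste0("w", 1:10), cdr3_aa = "CASSLGDEQYF",
                    v_gene = NA, reads = c(3L, rep(0L, 9)), productive = TRUE)
  tab <- clonotype_table("pep1", rec, well_ids = paste0("w", 1:10))
  expect_equal(well_presence_fraction("CASSLGDEQYF", tab), 0.10)
  expect_equal(well_presence_fraction("CASSABSENTF", tab), 0.0)
  single <- toy_clonotype_table()
  expect_equal(well_presence_fraction("CASSLGDEQYF", single), 1.0)
})

test_that("caller recovers a spiked clone and only that clone", {
  sim <- simulate_repertoire(n_clones = 300L, n_conditions = 2L, depth = 5e4,
                             n_wells = 10L,
                             spiked = data.frame(clone = 1L,
                                                 condition = "peptide1",
                                                 fold = 50),
                             seed = 42L)
  tabs <- lapply(sim$tables, preprocess_cdr3)
  ctrl <- preprocess_cdr3(sim$control)
  calls <- call_antigen_specific(tabs, ctrl, fest_config(read_floor = 30L))
  hit <- calls[calls$verdict, ]
  expect_equal(hit$cdr3_aa, sim$truth$spiked$cdr3_aa)
  expect_equal(hit$condition_id, "peptide1")
})

test_that("each criterion gates the verdict (strict OR > 5; conjunction)", {
  # hand-built counts: same clone in condition and control
  mk <- function(id, reads_named, wells = "w1") {
    clonotype_table(id, data.frame(
      well_id = rep(wells, each = length(reads_named)),
      cdr3_aa = names(reads_named), v_gene = NA,
      reads = as.integer(reads_named), productive = TRUE))
  }
  # OR exactly 5: (500 x 10000) / (10000 x 100); strict ">5" must fail
  cond <- mk("pep", c(CASSAAAAEQYF = 500L, CASSBBBBEQYF = 10000L))
  ctrl <- mk("ctrl", c(CASSAAAAEQYF = 100L, CASSBBBBEQYF = 10000L))
  calls <- call_antigen_specific(list(pep = cond), ctrl,
                                 fest_config(read_floor = 300L))
  row <- calls[calls$cdr3_aa == "CASSAAAAEQYF", ]
  expect_equal(row$odds_ratio, 5, tolerance = 1e-12)
  expect_true(row$crit_expanded_vs_control)
  expect_false(row$crit_odds_ratio)
  expect_false(row$verdict)
  # one more read tips the ratio above 5 and the verdict flips
  cond2 <- mk("pep", c(CASSAAAAEQYF = 501L, CASSBBBBEQYF = 10000L))
  calls2 <- call_antigen_specific(list(pep = cond2), ctrl,
                                  fest_config(read_floor = 300L))
  expect_true(calls2[calls2$cdr3_aa == "CASSAAAAEQYF", "verdict"])
})

test_that("criterion 2 is a conjunction over other conditions; mutation groups exempt", {
  mk <- function(id, a, rest = 20000L) clonotype_table(id, data.frame(
    well_id = "w1", cdr3_aa = c("CASSAAAAEQYF", "CASSBBBBEQYF"),
    v_gene = NA, reads = as.integer(c(a, rest)), productive = TRUE))
  cond1 <- mk("pep1", 800L)   # expanded vs control
  cond2 <- mk("pep2", 800L)   # clone equally expanded here too
  ctrl <- mk("ctrl", 20L)
  cfg <- fest_config(read_floor = 300L)
  calls <- call_antigen_specific(list(pep1 = cond1, pep2 = cond2), ctrl, cfg)
  r1 <- calls[calls$condition_id == "pep1" & calls$cdr3_aa == "CASSAAAAEQYF", ]
  expect_true(r1$crit_expanded_vs_control)
  expect_false(r1$crit_expanded_vs_others)  # not expanded vs pep2
  expect_false(r1$verdict)
  # same mutation group: pep2 exempt, verdict can pass
  cfg_mg <- fest_config(read_floor = 300L,
                        mutation_groups = c(pep1 = "mutA", pep2 = "mutA"))
  calls_mg <- call_antigen_specific(list(pep1 = cond1, pep2 = cond2), ctrl, cfg_mg)
  r1mg <- calls_mg[calls_mg$condition_id == "pep1" &
                   calls_mg$cdr3_aa == "CASSAAAAEQYF", ]
  expect_true(r1mg$crit_expanded_vs_others)
  expect_true(r1mg$verdict)
})

test_that("verdicts are invariant to condition-table order; control required", {
  sim <- simulate_repertoire(n_clones = 200L, n_conditions = 3L, depth = 3e4,
                             n_wells = 5L,
                             spiked = data.frame(clone = 1:2,
                                                 condition = c("peptide1", "peptide2"),
                                                 fold = c(30, 30)),
                             seed = 9L)
  tabs <- lapply(sim$tables, preprocess_cdr3)
  ctrl <- preprocess_cdr3(sim$control)
  cfg <- fest_config(read_floor = 30L)
  c1 <- call_antigen_specific(tabs, ctrl, cfg)
  c2 <- call_antigen_specific(rev(tabs), ctrl, cfg)
  expect_equal(c1[order(c1$cdr3_aa, c1$condition_id), ],
               c2[order(c2$cdr3_aa, c2$condition_id), ],
               ignore_attr = TRUE)
  expect_error(call_antigen_specific(tabs, NULL, cfg), "control")
})

test_that("triplicate mode: 2-of-3 rule with exclusivity across conditions", {
  sim <- simulate_repertoire(n_clones = 200L, n_conditions = 2L, depth = 3e4,
                             n_wells = 1L, n_replicates = 3L,
                             spiked = data.frame(clone = 1L,
                                                 condition = "peptide1",
                                                 fold = 40),
                             seed = 3L)
  tabs <- lapply(sim$tables, function(reps) lapply(reps, preprocess_cdr3))
  ctrl <- preprocess_cdr3(sim$control)
  cfg <- fest_config(read_floor = 30L, triplicate_mode = TRUE)
  calls <- call_triplicate_mode(tabs, ctrl, cfg)
  hit <- calls[calls$verdict, ]
  expect_equal(unique(hit$cdr3_aa), sim$truth$spiked$cdr3_aa)
  expect_true(all(hit$n_significant >= 2L))
  # a clone expanded in both conditions fails both by exclusivity
  sim2 <- simulate_repertoire(n_clones = 200L, n_conditions = 2L, depth = 3e4,
                              n_wells = 1L, n_replicates = 3L,
                              spiked = data.frame(clone = c(1L, 1L),
                                                  condition = c("peptide1", "peptide2"),
                                                  fold = c(40, 40)),
                              seed = 4L)
  tabs2 <- lapply(sim2$tables, function(reps) lapply(reps, preprocess_cdr3))
  calls2 <- call_triplicate_mode(tabs2, preprocess_cdr3(sim2$control), cfg)
  both <- calls2[calls2$cdr3_aa == sim2$truth$spiked$cdr3_aa[1L], ]
  expect_true(all(!both$verdict))
  expect_true(any(both$n_significant >= 2L))
  # replicate-count enforcement
  bad <- tabs
  bad$peptide1 <- bad$peptide1[1:2]
  expect_error(call_triplicate_mode(bad, ctrl, cfg), "3 replicate")
})
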