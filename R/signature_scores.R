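#' Gene-set module scores, correlated-gene ranking, marker calling and
#' dose-response summaries
#'
#' The module score is the binned-control composite score widely used for
#' single-cell gene programs: genes are binned by average expression, each
#' set gene contributes control genes sampled from its bin, and a cell's
#' score is the mean expression of the set genes minus the mean of the
#' control genes. Checkpoint and exhaustion scores are module scores over
#' fixed sets.
#'
#' @name signature_scores
NULL

#' Read a gene set from a plain-text file (one symbol per line)
#'
#' @param path File path.
#' @param name Set name (default: file name).
#' @return A `GeneSet` list with `name` and unique, nonempty `genes`.
#' @export
read_gene_set <- function(path, name = NULL) {
  genes <- unique(trimws(readLines(path)))
  genes <- genes[nzchar(genes)]
  gene_set(genes, name %||% sub("\\.[^.]+$", "", basename(path)))
}

#' Construct a gene set
#' @param genes Character vector of symbols.
#' @param name Set name.
#' @return A `GeneSet`.
#' @export
gene_set <- function(genes, name = "set") {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("empty gene set", call. = FALSE)
  structure(list(name = name, genes = genes), class = "GeneSet")
}

#' Binned-control module score
#'
#' Genes are ranked by average expression over cells and split into `bins`
#' equal-size bins; for every set gene, `n_controls` control genes are
#' sampled (with replacement) from the non-set genes of the same bin (the
#' whole bin if the set fills it). The per-cell score is
#' `mean(expr of set genes) - mean(expr of the pooled control genes)`.
#' Adding a constant to every gene in every cell leaves the score
#' unchanged.
#'
#' @param expr genes x cells matrix of normalized log expression.
#' @param set A `GeneSet` (or character vector of symbols). Symbols absent
#'   from `expr` are dropped with a warning.
#' @param bins Number of expression bins (default 24).
#' @param n_controls Control genes sampled per set gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return Named numeric vector of per-cell scores; attributes record the
#'   control parameters.
#' @export
module_score <- function(expr, set, bins = 24L, n_controls = 100L, seed = 1L) {
  if (!inherits(set, "GeneSet")) set <- gene_set(set)
  expr <- as.matrix(expr)
  if (nrow(expr) < bins)
    stop("fewer genes than bins", call. = FALSE)
  genes <- intersect(set$genes, rownames(expr))
  if (length(genes) < length(set$genes))
    warning(sprintf("module_score('%s'): %d set gene(s) absent from the data: %s",
                    set$name, length(set$genes) - length(genes),
                    paste(setdiff(set$genes, genes), collapse = ", ")),
            call. = FALSE)
  if (!length(genes))
    stop("no set genes present in the expression matrix", call. = FALSE)
  avg <- rowMeans(expr)
  # equal-size bins by average-expression rank
  bin <- ceiling(rank(avg, ties.method = "first") * bins / length(avg))
  by_bin <- split(rownames(expr), bin)
  set.seed(seed)
  controls <- unlist(lapply(genes, function(g) {
    pool <- by_bin[[as.character(bin[g])]]
    pool_ns <- setdiff(pool, genes)  # controls must not come from the set itself
    if (length(pool_ns)) pool <- pool_ns
    pool[sample.int(length(pool), n_controls, replace = TRUE)]
  }), use.names = FALSE)
  score <- colMeans(expr[genes, , drop = FALSE]) -
    colMeans(expr[controls, , drop = FALSE])
  attr(score, "control_bins") <- as.integer(bins)
  attr(score, "controls_per_bin") <- as.integer(n_controls)
  attr(score, "seed") <- as.integer(seed)
  score
}

#' Checkpoint score over the six clinically targeted checkpoints
#'
#' Module score over CTLA4, PDCD1, LAG3, HAVCR2, TIGIT and ENTPD1.
#'
#' @inheritParams module_score
#' @return Per-cell score vector.
#' @export
checkpoint_score <- function(expr, bins = 24L, n_controls = 100L, seed = 1L) {
  set <- gene_set(c("CTLA4", "PDCD1", "LAG3", "HAVCR2", "TIGIT", "ENTPD1"),
                  "checkpoint")
  missing <- setdiff(set$genes, rownames(as.matrix(expr)))
  if (length(missing))
    warning("checkpoint genes absent from the data: ",
            paste(missing, collapse = ", "), call. = FALSE)
  module_score(expr, set, bins = bins, n_controls = n_controls, seed = seed)
}

#' Exhaustion score over a published exhausted-T-cell gene list
#'
#' Module score over a user-replaceable exhaustion gene list. The packaged
#' default (`exhaustion_genes.synthetic.txt`) is a synthetic stand-in of
#' canonical exhaustion-program genes, not the original published list;
#' supply your own list for real analyses.
#'
#' @inheritParams module_score
#' @param genes Optional character vector or `GeneSet` overriding the
#'   packaged list.
#' @return Per-cell score vector.
#' @export
exhaustion_score <- function(expr, genes = NULL, bins = 24L,
                             n_controls = 100L, seed = 1L) {
  if (is.null(genes)) {
    path <- system.file("extdata", "exhaustion_genes.synthetic.txt",
                        package = "festsc", mustWork = TRUE)
    genes <- read_gene_set(path, "exhaustion")
  }
  if (!inherits(genes, "GeneSet")) genes <- gene_set(genes, "exhaustion")
  module_score(expr, genes, bins = bins, n_controls = n_controls, seed = seed)
}

#' Genes maximally correlated with a per-cell score
#'
#' Pearson correlation of each candidate gene with the score; candidates
#' are typically highly variable genes minus the score's own members
#' (`exclude`). When `groups` is supplied, per-group coefficients and
#' their difference (first level minus second) are reported for waterfall
#' comparisons.
#'
#' @param expr genes x cells normalized log expression.
#' @param score Per-cell score vector.
#' @param candidates Candidate gene symbols (default: all genes in `expr`).
#' @param exclude `GeneSet` or symbols never reported (e.g. the six
#'   checkpoint genes).
#' @param top_k Number of top genes returned (default 30).
#' @param groups Optional per-cell two-level factor (e.g. MPR vs non-MPR).
#' @return Data frame ranked by correlation: `gene`, `cor`, `constant`
#'   flag, and per-group columns plus `cor_diff` when `groups` is given.
#' @export
score_correlated_genes <- function(expr, score, candidates = NULL,
                                   exclude = NULL, top_k = 30L,
                                   groups = NULL) {
  expr <- as.matrix(expr)
  stopifnot(length(score) == ncol(expr), all(is.finite(score)))
  if (is.null(candidates)) candidates <- rownames(expr)
  if (!is.null(exclude)) {
    ex <- if (inherits(exclude, "GeneSet")) exclude$genes else exclude
    candidates <- setdiff(candidates, ex)
  }
  candidates <- intersect(candidates, rownames(expr))
  safe_cor <- function(mat, v) {
    sds <- apply(mat, 1L, stats::sd)
    out <- rep(0, nrow(mat))
    ok <- sds > 0
    if (any(ok)) out[ok] <- as.numeric(stats::cor(t(mat[ok, , drop = FALSE]), v))
    list(cor = out, constant = !ok)
  }
  cc <- safe_cor(expr[candidates, , drop = FALSE], score)
  out <- data.frame(gene = candidates, cor = cc$cor, constant = cc$constant,
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    groups <- factor(groups)
    if (nlevels(groups) != 2L)
      stop("groups must have exactly two levels", call. = FALSE)
    for (lv in levels(groups)) {
      j <- groups == lv
      out[[paste0("cor_", lv)]] <-
        safe_cor(expr[candidates, j, drop = FALSE], score[j])$cor
    }
    out$cor_diff <- out[[paste0("cor_", levels(groups)[1L])]] -
      out[[paste0("cor_", levels(groups)[2L])]]
  }
  out <- out[order(-out$cor), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Wilcoxon rank-sum marker genes with fold-change and detection filters
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per gene and group on
#' normalized log expression. Significant markers must pass all of:
#' log2 fold change > `lfc_min`, detection in at least `min_pct` of cells
#' of either compared population, and Bonferroni-adjusted p < `alpha`
#' (adjustment over the genes tested per group). The fold change
#' convention is `log2((mean(expm1(x)) + 1) / (mean(expm1(y)) + 1))`.
#'
#' @param expr genes x cells normalized log expression (natural-log scale
#'   assumed by the `expm1` convention; any monotone log works for the
#'   test itself).
#' @param groups Per-cell group labels; groups with fewer than 3 cells are
#'   skipped with a warning.
#' @param lfc_min Fold-change threshold (default 0.25, strict `>`).
#' @param min_pct Detection-fraction threshold (default 0.25).
#' @param alpha Bonferroni-adjusted significance level (default 0.05).
#' @param only_pos Keep only up-regulated markers (default TRUE).
#' @return Data frame: `gene`, `group`, `p`, `p_bonferroni`, `log2fc`,
#'   `pct_in`, `pct_out`, `significant`. Only rows passing the detection
#'   pre-filter are tested; `significant` applies all three thresholds.
#' @export
marker_genes <- function(expr, groups, lfc_min = 0.25, min_pct = 0.25,
                         alpha = 0.05, only_pos = TRUE) {
  expr <- as.matrix(expr)
  groups <- factor(groups)
  stopifnot(length(groups) == ncol(expr))
  sizes <- table(groups)
  use_groups <- names(sizes)[sizes >= 3L]
  if (length(use_groups) < length(sizes))
    warning("group(s) with < 3 cells skipped: ",
            paste(setdiff(names(sizes), use_groups), collapse = ", "),
            call. = FALSE)
  if (length(use_groups) < 2L)
    stop("need at least 2 groups with >= 3 cells", call. = FALSE)
  res <- list()
  for (g in use_groups) {
    j_in <- groups == g
    j_out <- !j_in & groups %in% use_groups
    pct_in <- rowMeans(expr[, j_in, drop = FALSE] > 0)
    pct_out <- rowMeans(expr[, j_out, drop = FALSE] > 0)
    test_genes <- rownames(expr)[pmax(pct_in, pct_out) >= min_pct]
    if (!length(test_genes)) next
    lfc <- log2((rowMeans(expm1(expr[test_genes, j_in, drop = FALSE])) + 1) /
                (rowMeans(expm1(expr[test_genes, j_out, drop = FALSE])) + 1))
    p <- vapply(test_genes, function(gene)
      suppressWarnings(stats::wilcox.test(expr[gene, j_in], expr[gene, j_out],
                                          alternative = "two.sided")$p.value),
      numeric(1))
    p_bonf <- pmin(1, p * length(test_genes))
    keep_dir <- if (only_pos) lfc > lfc_min else abs(lfc) > lfc_min
    res[[g]] <- data.frame(
      gene = test_genes, group = g, p = unname(p),
      p_bonferroni = unname(p_bonf), log2fc = unname(lfc),
      pct_in = unname(pct_in[test_genes]), pct_out = unname(pct_out[test_genes]),
      significant = unname(keep_dir & p_bonf < alpha),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Dose-response summary of per-cell scores
#'
#' Mean and standard error of the score per (group, dose), plus a
#' per-group monotone-trend statistic (Spearman correlation of score with
#' log dose).
#'
#' @param scores Per-cell score vector.
#' @param dose Per-cell dose/concentration (> 0 for the log-dose trend).
#' @param group Per-cell group labels (e.g. antigen class).
#' @return List with `summary` (group, dose, n, mean, sem; cells with
#'   fewer than 2 observations have NA `sem` and are flagged) and `trend`
#'   (group, spearman_rho, p).
#' @export
dose_response_summary <- function(scores, dose, group) {
  stopifnot(length(scores) == length(dose), length(dose) == length(group))
  if (length(unique(dose)) < 2L) stop("need >= 2 doses", call. = FALSE)
  key <- interaction(group, dose, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_along(scores), key), function(j) {
    data.frame(group = as.character(group[j][1L]), dose = dose[j][1L],
               n = length(j), mean = mean(scores[j]),
               sem = if (length(j) >= 2L) stats::sd(scores[j]) / sqrt(length(j))
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  agg$sem_undefined <- is.na(agg$sem)
  agg <- agg[order(agg$group, agg$dose), ]
  rownames(agg) <- NULL
  trend <- do.call(rbind, lapply(split(seq_along(scores), group), function(j) {
    ct <- tryCatch(
      suppressWarnings(stats::cor.test(scores[j], log(dose[j]),
                                       method = "spearman")),
      error = function(e) NULL)  # too few cells / constant dose in the group
    data.frame(group = as.character(group[j][1L]),
               spearman_rho = if (is.null(ct)) NA_real_ else unname(ct$estimate),
               p = if (is.null(ct)) NA_real_ else ct$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(trend) <- NULL
  list(summary = agg, trend = trend)
}
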