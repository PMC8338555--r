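#' Pseudobulk construction, HVG selection, concatenated PCA and the
#' canonical-correlation permutation test
#'
#' Cells are aggregated per (cluster, sample) into pseudobulk profiles,
#' library-size normalized, highly variable genes are selected per cluster
#' by positive LOESS residuals of SD against mean, per-cluster HVG blocks
#' are concatenated into one standardized sample x feature table, samples
#' are embedded by PCA, and the association of the first two PCs with a
#' covariate of interest (tissue, response status, ...) is tested by a
#' canonical-correlation permutation test.
#'
#' @name pseudobulk_pca
NULL

#' Aggregate cells into per-(cluster, sample) pseudobulk profiles
#'
#' Gene counts are summed over the cells of each (cluster, sample) pair and
#' each profile is scaled to a common library size. Combinations with no
#' cells are recorded as missing (not zero). Clusters observed in fewer
#' than two samples are flagged and excluded from PCA features downstream.
#'
#' @param ds A `CellDataset`, or a genes x cells count matrix.
#' @param clusters Per-cell cluster labels (default: `cell_meta$cluster`).
#' @param samples Per-cell sample labels (default: `cell_meta$sample`).
#' @param target_size Common library size each profile is scaled to
#'   (default 1e6).
#' @return A `PseudobulkProfile`: list with `values` (list per cluster of
#'   genes x samples matrices, missing entries NA), `samples`, `clusters`,
#'   `missing` (cluster x sample logical) and `target_size`.
#' @export
make_pseudobulk <- function(ds, clusters = NULL, samples = NULL,
                            target_size = 1e6) {
  m <- if (inherits(ds, "CellDataset")) ds$counts else ds
  if (inherits(ds, "CellDataset")) {
    if (is.null(clusters)) clusters <- ds$cell_meta$cluster
    if (is.null(samples)) samples <- ds$cell_meta$sample
  }
  if (is.null(clusters) || is.null(samples) ||
      anyNA(clusters) || anyNA(samples))
    stop("every cell needs a cluster and a sample label", call. = FALSE)
  clusters <- as.character(clusters); samples <- as.character(samples)
  stopifnot(length(clusters) == ncol(m), length(samples) == ncol(m))
  cl_levels <- sort(unique(clusters)); s_levels <- sort(unique(samples))

  values <- list()
  missing <- matrix(FALSE, length(cl_levels), length(s_levels),
                    dimnames = list(cl_levels, s_levels))
  for (cl in cl_levels) {
    prof <- matrix(NA_real_, nrow(m), length(s_levels),
                   dimnames = list(rownames(m), s_levels))
    for (s in s_levels) {
      idx <- clusters == cl & samples == s
      if (!any(idx)) { missing[cl, s] <- TRUE; next }
      v <- Matrix::rowSums(m[, idx, drop = FALSE])
      tot <- sum(v)
      prof[, s] <- if (tot > 0) v * (target_size / tot) else v
    }
    values[[cl]] <- prof
  }
  sparse_cl <- rowSums(!missing) < 2L
  if (any(sparse_cl))
    warning("cluster(s) present in < 2 samples excluded from PCA features: ",
            paste(cl_levels[sparse_cl], collapse = ", "), call. = FALSE)
  structure(list(values = values, samples = s_levels, clusters = cl_levels,
                 missing = missing, target_size = target_size,
                 usable_clusters = cl_levels[!sparse_cl]),
            class = "PseudobulkProfile")
}

#' Center and scale pseudobulk profiles within batch
#'
#' A light per-batch standardization of each gene (center to the batch
#' mean, scale to unit batch SD where defined) applied to every cluster's
#' profile. A hook (`fun`) lets callers substitute any external
#' batch-correction method operating on a genes x samples matrix.
#'
#' @param profile A `PseudobulkProfile`.
#' @param batch Per-sample batch labels, aligned with `profile$samples`.
#' @param fun Optional function(mat, batch) -> mat replacing the built-in
#'   per-batch standardization.
#' @return The corrected `PseudobulkProfile`.
#' @export
correct_batch <- function(profile, batch, fun = NULL) {
  stopifnot(inherits(profile, "PseudobulkProfile"),
            length(batch) == length(profile$samples))
  batch <- as.character(batch)
  std <- function(mat, batch) {
    for (b in unique(batch)) {
      j <- which(batch == b & !apply(is.na(mat), 2, all))
      if (length(j) < 2L) next
      mu <- rowMeans(mat[, j, drop = FALSE])
      sd <- apply(mat[, j, drop = FALSE], 1L, stats::sd)
      sd[!is.finite(sd) | sd == 0] <- 1
      mat[, j] <- (mat[, j, drop = FALSE] - mu) / sd
    }
    mat
  }
  f <- if (is.null(fun)) std else fun
  profile$values <- lapply(profile$values, f, batch = batch)
  profile
}

#' Select highly variable genes by positive LOESS residual
#'
#' Fits a LOESS regression of per-gene SD against per-gene mean (span 0.3,
#' on log1p-transformed means) across samples and returns the genes whose
#' SD lies above the fitted trend (positive residual). With fewer than 10
#' genes of nonzero mean the LOESS fit is skipped and the top half of genes
#' by SD is returned with a warning.
#'
#' @param mat genes x samples matrix (one cluster's pseudobulk profile);
#'   columns that are entirely NA (missing profiles) are ignored.
#' @param span LOESS span (default 0.3).
#' @return Character vector of selected gene names.
#' @export
select_hvg_loess <- function(mat, span = 0.3) {
  use <- !apply(is.na(mat), 2L, any)
  mat <- mat[, use, drop = FALSE]
  if (ncol(mat) < 2L) stop("need >= 2 non-missing samples", call. = FALSE)
  mu <- rowMeans(mat)
  sd <- apply(mat, 1L, stats::sd)
  nz <- mu > 0
  if (sum(nz) < 10L) {
    warning("too few genes with nonzero mean for LOESS; falling back to top-50% by SD",
            call. = FALSE)
    ord <- order(sd, decreasing = TRUE)
    return(rownames(mat)[ord[seq_len(ceiling(length(ord) / 2))]])
  }
  df <- data.frame(lmu = log1p(mu[nz]), sd = sd[nz])
  fit <- stats::loess(sd ~ lmu, data = df, span = span, degree = 2,
                      family = "gaussian")
  resid <- df$sd - stats::predict(fit, df)
  sel <- rownames(mat)[nz][resid > 0 & df$sd > 0]
  sel
}

#' Concatenated-profile PCA embedding of samples
#'
#' Builds the sample x feature table whose features are the union over
#' clusters of (cluster, HVG) pseudobulk values, standardizes every feature
#' to mean 0 / variance 1 across samples, and embeds the samples with PCA.
#' Clusters with a missing profile in any sample are dropped
#' (complete-case features).
#'
#' @param profile A `PseudobulkProfile`.
#' @param hvg_sets Named list (per cluster) of gene vectors, e.g. from
#'   [select_hvg_loess()]; defaults to computing them per usable cluster.
#' @param n_pcs Number of PCs to return (default 2).
#' @return List with `embedding` (samples x n_pcs), `var_explained`,
#'   `features` (data frame cluster/gene), and `x` the standardized
#'   feature matrix.
#' @export
concat_pca <- function(profile, hvg_sets = NULL, n_pcs = 2L) {
  stopifnot(inherits(profile, "PseudobulkProfile"))
  if (length(profile$samples) < 3L)
    stop("need at least 3 samples for PCA", call. = FALSE)
  usable <- profile$usable_clusters
  usable <- usable[vapply(usable, function(cl) !any(profile$missing[cl, ]),
                          logical(1))]
  if (!length(usable))
    stop("no cluster has a complete profile across samples", call. = FALSE)
  if (is.null(hvg_sets))
    hvg_sets <- lapply(stats::setNames(usable, usable), function(cl)
      select_hvg_loess(profile$values[[cl]]))
  blocks <- list(); feat <- list()
  for (cl in usable) {
    genes <- intersect(hvg_sets[[cl]], rownames(profile$values[[cl]]))
    if (!length(genes)) next
    blocks[[cl]] <- t(profile$values[[cl]][genes, profile$samples, drop = FALSE])
    feat[[cl]] <- data.frame(cluster = cl, gene = genes,
                             stringsAsFactors = FALSE)
  }
  x <- do.call(cbind, blocks)
  features <- do.call(rbind, feat)
  sds <- apply(x, 2L, stats::sd)
  keep <- is.finite(sds) & sds > 0
  x <- scale(x[, keep, drop = FALSE])
  features <- features[keep, , drop = FALSE]
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  list(embedding = pc$x[, seq_len(n_pcs), drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pcs)],
       features = features, x = x)
}

first_canonical_correlation <- function(pcs, covariate) {
  y <- if (is.numeric(covariate)) matrix(covariate, ncol = 1L)
       else stats::model.matrix(~ f - 1, data.frame(f = factor(covariate)))
  # drop one dummy column to avoid collinearity with the implicit mean
  if (ncol(y) > 1L) y <- y[, -1L, drop = FALSE]
  cc <- tryCatch(stats::cancor(pcs, y), error = function(e) NULL)
  if (is.null(cc) || !length(cc$cor)) return(0)
  cc$cor[1L]
}

#' Canonical-correlation permutation test of a sample covariate
#'
#' Computes the first canonical correlation between the sample embedding
#' (PC1, PC2) and a covariate of interest, and assesses significance by
#' randomly permuting the sample labels (`n_perm` times, 10,000 by
#' default). The p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_perm)` and is one-sided (large
#' correlation = association). Categorical covariates are dummy-coded, so
#' factors with more than two levels are handled by the same canonical
#' formulation.
#'
#' @param embedding samples x 2 PC coordinate matrix.
#' @param covariate Per-sample label or numeric value; must take at least
#'   two distinct values.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param strata Optional per-sample strata; permutations shuffle labels
#'   within strata only.
#' @return A `PermutationResult` list: `observed_cc`, `null_ccs`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
cc_permutation_test <- function(embedding, covariate, n_perm = 10000L,
                                seed = 1L, strata = NULL) {
  embedding <- as.matrix(embedding)
  stopifnot(nrow(embedding) == length(covariate))
  if (length(unique(covariate)) < 2L)
    stop("covariate is constant", call. = FALSE)
  observed <- first_canonical_correlation(embedding, covariate)
  n <- length(covariate)
  set.seed(seed)
  perm_idx <- function() {
    if (is.null(strata)) return(sample.int(n))
    idx <- seq_len(n)
    for (s in unique(strata)) {
      j <- which(strata == s)
      idx[j] <- j[sample.int(length(j))]
    }
    idx
  }
  null_ccs <- vapply(seq_len(n_perm), function(i)
    first_canonical_correlation(embedding, covariate[perm_idx()]),
    numeric(1))
  p <- (1 + sum(null_ccs >= observed)) / (1 + n_perm)
  structure(list(observed_cc = observed, null_ccs = null_ccs, p_value = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("CC permutation test: observed = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$observed_cc, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Clusters enriched for a labelled cell subset
#'
#' A cluster is enriched when the labelled-cell frequency is at least
#' `fold` times higher than randomly expected, i.e.
#' `(labelled_c / labelled_total) / (cells_c / cells_total) >= fold`.
#' Enriched clusters are intended to be merged into one combined
#' pseudo-cluster for downstream pseudobulk PCA.
#'
#' @param cluster_sizes Named vector of cells per cluster.
#' @param mana_counts Named vector of labelled (e.g. MANA-specific) cells
#'   per cluster; names must be a subset of `names(cluster_sizes)`.
#' @param fold Enrichment fold threshold, inclusive (default 2).
#' @return Character vector of enriched cluster names; attribute `ratio`
#'   carries every cluster's enrichment ratio.
#' @export
mana_enriched_clusters <- function(cluster_sizes, mana_counts, fold = 2) {
  stopifnot(all(names(mana_counts) %in% names(cluster_sizes)),
            sum(cluster_sizes) > 0)
  full <- stats::setNames(numeric(length(cluster_sizes)), names(cluster_sizes))
  full[names(mana_counts)] <- mana_counts
  if (sum(full) == 0) stop("no labelled cells", call. = FALSE)
  ratio <- (full / sum(full)) / (cluster_sizes / sum(cluster_sizes))
  out <- names(cluster_sizes)[ratio >= fold]
  attr(out, "ratio") <- ratio
  out
}
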