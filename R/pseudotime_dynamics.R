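#' Pseudotime differential-expression likelihood-ratio permutation test
#'
#' Per gene, expression along pseudotime is modelled in each sample by a
#' least-squares cubic B-spline regression `f_gs(t)` and compared to a
#' constant (intercept-only) null via a Gaussian likelihood-ratio
#' statistic summed over samples. The null distribution of the statistic
#' is built by permuting pseudotime within each sample and refitting.
#' P-values across genes are converted to FDR by Benjamini-Hochberg;
#' genes with FDR < 0.05 are called dynamic, and dynamic genes' mean
#' temporal curves are grouped into patterns by k-means.
#'
#' @name pseudotime_dynamics
NULL

#' Retain genes by minimum expression prevalence
#'
#' Keeps genes with normalized expression at or above `min_expr` in at
#' least a `min_frac` fraction of cells.
#'
#' @param expr genes x cells normalized expression matrix.
#' @param min_expr Expression threshold (default 0.01).
#' @param min_frac Cell-fraction threshold (default 0.01).
#' @return Character vector of retained gene names.
#' @export
retain_genes <- function(expr, min_expr = 0.01, min_frac = 0.01) {
  expr <- as.matrix(expr)
  frac <- rowMeans(expr >= min_expr)
  out <- rownames(expr)[frac >= min_frac]
  attr(out, "thresholds") <- c(min_expr = min_expr, min_frac = min_frac)
  out
}

# cubic B-spline design matrix with intercept; df counts all columns.
# Interior knots at pseudotime quantiles.
spline_basis <- function(t, df = 7L) {
  if (df < 5L) stop("df must be >= 5 (cubic basis + intercept)", call. = FALSE)
  inner_df <- df - 1L
  knots <- stats::quantile(t, probs = seq_len(inner_df - 3L) / (inner_df - 2L))
  cbind(1, splines::bs(t, knots = knots, degree = 3L,
                       Boundary.knots = range(t)))
}

#' Fit a temporal B-spline and its constant null to one gene in one sample
#'
#' Least-squares cubic B-spline with `df - 1` basis columns plus
#' intercept, interior knots at pseudotime quantiles; Gaussian
#' log-likelihood with the MLE error variance, and the matching
#' intercept-only null fit. `LR = n * log(RSS0 / RSS1)` (twice the
#' log-likelihood difference), non-negative by nesting.
#'
#' @param t Pseudotimes (finite; any monotone ordering rescaled or not).
#' @param y Expression values, same length.
#' @param df Total spline degrees of freedom including the intercept
#'   (default 7: cubic basis with 3 interior knots).
#' @return List with `coef`, `fitted`, `rss`, `rss0`, `loglik`, `loglik0`,
#'   `lr`, `df`, and `predict(t_new)`.
#' @export
fit_spline <- function(t, y, df = 7L) {
  n <- length(t)
  stopifnot(length(y) == n, all(is.finite(t)), all(is.finite(y)))
  if (n < df + 2L)
    stop("need at least df + 2 cells to fit the spline", call. = FALSE)
  X <- spline_basis(t, df)
  fit <- stats::lm.fit(X, y)
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  # guard exact fits: likelihoods with zero variance are degenerate
  eps <- 1e-12 * max(rss0, 1)
  ll <- function(rss) -n / 2 * (log(2 * pi) + log(max(rss, eps) / n) + 1)
  lr <- max(0, n * (log(max(rss0, eps)) - log(max(rss1, eps))))
  knots <- attr(X, "knots")
  list(coef = fit$coefficients, fitted = fit$fitted.values,
       rss = rss1, rss0 = rss0, loglik = ll(rss1), loglik0 = ll(rss0),
       lr = lr, df = df,
       predict = function(t_new) {
         Xn <- spline_basis_like(t, t_new, df)
         co <- fit$coefficients
         co[is.na(co)] <- 0
         as.numeric(Xn %*% co)
       })
}

# basis for new points using the knot layout derived from the training t
spline_basis_like <- function(t_train, t_new, df) {
  inner_df <- df - 1L
  knots <- stats::quantile(t_train, probs = seq_len(inner_df - 3L) / (inner_df - 2L))
  cbind(1, splines::bs(t_new, knots = knots, degree = 3L,
                       Boundary.knots = range(t_train)))
}

# Per-sample projection machinery: Q factors allow the spline RSS of many
# genes (columns of Y) to be computed as colSums(Y^2) - colSums((Q'Y)^2).
sample_projectors <- function(t, samples, df) {
  lapply(split(seq_along(t), samples), function(j) {
    X <- spline_basis(t[j], df)
    qr_ <- qr(X)
    list(idx = j, Q = qr.Q(qr_), n = length(j))
  })
}

lr_from_projector <- function(proj, Y) {
  # Y: cells-of-sample x genes matrix
  tot <- colSums(Y^2)
  rss0 <- tot - colSums(Y)^2 / proj$n
  qy <- crossprod(proj$Q, Y)
  rss1 <- pmax(tot - colSums(qy^2), 0)
  eps <- 1e-12 * pmax(rss0, 1)
  pmax(0, proj$n * (log(pmax(rss0, eps)) - log(pmax(rss1, eps))))
}

#' Likelihood-ratio permutation test for pseudotime-dynamic genes
#'
#' For each gene the LR statistic (spline vs constant, summed over
#' samples) is compared with a permutation null built by shuffling
#' pseudotime within each sample and refitting both models. P-values use
#' the add-one estimator over permutations exceeding the observed LR, are
#' BH-adjusted across genes, and genes with FDR below `fdr_alpha` are
#' flagged dynamic.
#'
#' @param expr genes x cells normalized expression matrix.
#' @param t Per-cell pseudotime.
#' @param samples Per-cell sample ids (a single sample is allowed).
#' @param df Spline degrees of freedom (default 7; see [fit_spline()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param fdr_alpha Dynamic-gene FDR threshold (default 0.05).
#' @return A `PseudotimeFit`: data frame `results` (gene, lr, p, fdr,
#'   dynamic) plus `curves` (genes x 100-point grid of the mean temporal
#'   curve across samples), `grid`, `df`, `n_perm`, `seed`.
#' @export
lr_permutation_test <- function(expr, t, samples = NULL, df = 7L,
                                n_perm = 1000L, seed = 1L,
                                fdr_alpha = 0.05) {
  expr <- as.matrix(expr)
  n <- length(t)
  stopifnot(ncol(expr) == n, all(is.finite(t)))
  if (is.null(samples)) samples <- rep("s1", n)
  samples <- as.character(samples)
  empty <- setdiff(unique(samples), samples[!is.na(t)])
  keepable <- vapply(split(seq_len(n), samples), length, integer(1)) >= df + 2L
  if (any(!keepable))
    warning("sample(s) with too few cells skipped: ",
            paste(names(keepable)[!keepable], collapse = ", "), call. = FALSE)
  use <- samples %in% names(keepable)[keepable]
  expr <- expr[, use, drop = FALSE]; t <- t[use]; samples <- samples[use]

  projs <- sample_projectors(t, samples, df)
  Yt <- t(expr)
  obs <- Reduce(`+`, lapply(projs, function(pr)
    lr_from_projector(pr, Yt[pr$idx, , drop = FALSE])))

  set.seed(seed)
  exceed <- numeric(ncol(Yt))
  for (b in seq_len(n_perm)) {
    lr_b <- Reduce(`+`, lapply(projs, function(pr) {
      Yp <- Yt[pr$idx[sample.int(pr$n)], , drop = FALSE]
      lr_from_projector(pr, Yp)
    }))
    exceed <- exceed + (lr_b > obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  fdr <- bh_adjust(p)

  grid <- seq(min(t), max(t), length.out = 100L)
  curves <- matrix(0, nrow(expr), length(grid),
                   dimnames = list(rownames(expr), NULL))
  for (pr_name in names(split(seq_along(t), samples))) {
    j <- which(samples == pr_name)
    X <- spline_basis(t[j], df)
    co <- qr.coef(qr(X), t(expr[, j, drop = FALSE]))
    co[is.na(co)] <- 0
    Xg <- spline_basis_like(t[j], pmin(pmax(grid, min(t[j])), max(t[j])), df)
    curves <- curves + t(Xg %*% co)
  }
  curves <- curves / length(unique(samples))

  structure(list(
    results = data.frame(gene = rownames(expr), lr = obs, p = p, fdr = fdr,
                         dynamic = fdr < fdr_alpha, stringsAsFactors = FALSE),
    curves = curves, grid = grid, df = as.integer(df),
    n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "PseudotimeFit")
}

#' @export
print.PseudotimeFit <- function(x, ...) {
  cat(sprintf("Pseudotime LR test: %d genes, %d dynamic at FDR < 0.05 (%d permutations)\n",
              nrow(x$results), sum(x$results$dynamic), x$n_perm))
  invisible(x)
}

#' Cluster dynamic genes by temporal pattern
#'
#' K-means on the standardized mean temporal curves (each curve scaled to
#' mean 0, SD 1, making clustering invariant to per-gene amplitude).
#'
#' @param curves genes x grid matrix of mean temporal curves (e.g.
#'   `fit$curves[fit$results$dynamic, ]`).
#' @param k Number of pattern clusters (>= 2).
#' @param seed RNG seed for k-means initialisation.
#' @param nstart Random restarts (default 10).
#' @return List with `cluster` (named assignments) and `centers`.
#' @export
cluster_patterns <- function(curves, k, seed = 1L, nstart = 10L) {
  curves <- as.matrix(curves)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (nrow(curves) < k) stop("fewer curves than clusters", call. = FALSE)
  z <- t(apply(curves, 1L, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 50L)
  list(cluster = stats::setNames(km$cluster, rownames(curves)),
       centers = km$centers)
}
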