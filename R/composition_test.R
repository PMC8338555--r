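#' Cell-type composition change test for a labelled cell subset
#'
#' Tests whether the distribution of a labelled cell subset (e.g.
#' MANA-specific T cells) across cell types changes between two timepoints,
#' adjusting for background cell-type abundance. With `m_ct` the subset
#' proportion of type `c` at time `t` and `p_ct` the background proportion,
#' the relative-abundance ratio is `R_ct = m_ct / p_ct` and the statistic is
#' `S = sum_c (R_c,T1 - R_c,T2)^2`, calibrated against a multinomial
#' Monte-Carlo null that holds subset totals fixed per timepoint. A plain
#' Fisher 2xC homogeneity test on the subset counts is computed as a
#' companion.
#'
#' @name composition_test
NULL

#' Assemble composition counts
#'
#' @param background_counts cell types x 2 matrix of all-cell counts per
#'   timepoint.
#' @param subset_counts cell types x 2 matrix of labelled-cell counts, same
#'   row/column layout.
#' @param cell_types Optional type labels (default: rownames).
#' @param timepoints Optional timepoint labels (default: colnames or
#'   `c("T1", "T2")`).
#' @return A `CompositionCounts` list with derived proportions `p`, `m`
#'   and ratios `R`.
#' @export
composition_counts <- function(background_counts, subset_counts,
                               cell_types = NULL, timepoints = NULL) {
  bg <- as.matrix(background_counts); sub <- as.matrix(subset_counts)
  if (!all(dim(bg) == dim(sub)) || ncol(bg) != 2L)
    stop("background and subset must be types x 2 matrices of equal shape",
         call. = FALSE)
  if (any(bg < 0) || any(sub < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(cell_types))
    cell_types <- rownames(bg) %||% paste0("type", seq_len(nrow(bg)))
  if (is.null(timepoints))
    timepoints <- colnames(bg) %||% c("T1", "T2")
  dimnames(bg) <- dimnames(sub) <- list(cell_types, timepoints)
  if (any(sub > 0 & bg == 0))
    stop("subset cells present in a type with zero background cells",
         call. = FALSE)
  p <- sweep(bg, 2L, colSums(bg), "/")
  m <- sweep(sub, 2L, pmax(colSums(sub), 1), "/")
  R <- ifelse(p > 0, m / p, NA_real_)
  structure(list(cell_types = cell_types, timepoints = timepoints,
                 background_counts = bg, subset_counts = sub,
                 p = p, m = m, R = R),
            class = "CompositionCounts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Composition-change statistic S
#'
#' `S = sum_c (R_c,T1 - R_c,T2)^2` over cell types with nonzero background
#' at both timepoints; types with zero background at either timepoint are
#' excluded and reported via the `excluded_types` attribute.
#'
#' @param counts A `CompositionCounts`.
#' @return The statistic (non-negative scalar).
#' @examples
#' bg <- matrix(c(50, 50, 50, 50), 2)
#' sub <- matrix(c(8, 2, 5, 5), 2)
#' compute_S(composition_counts(bg, sub))  # 0.72
#' @export
compute_S <- function(counts) {
  stopifnot(inherits(counts, "CompositionCounts"))
  ok <- rowSums(counts$p > 0) == 2L
  S <- sum((counts$R[ok, 1L] - counts$R[ok, 2L])^2)
  attr(S, "excluded_types") <- counts$cell_types[!ok]
  S
}

#' Fisher exact homogeneity test on a types x 2 subset table
#'
#' Exact conditional test for total counts up to `exact_limit`; beyond
#' that, a seeded Monte-Carlo p-value with fixed margins is used. All-zero
#' rows are dropped.
#'
#' @param subset_counts types x 2 non-negative integer matrix.
#' @param exact_limit Largest total for the exact computation (default
#'   200).
#' @param B Monte-Carlo replicates for large tables (default 1e5).
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return p-value; attribute `method` records which branch ran.
#' @export
fisher_2xC <- function(subset_counts, exact_limit = 200L, B = 1e5L, seed = 1L) {
  tab <- as.matrix(subset_counts)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (!nrow(tab) || sum(tab) == 0) stop("all counts are zero", call. = FALSE)
  if (nrow(tab) == 1L) {
    p <- 1
    attr(p, "method") <- "degenerate_single_type"
    return(p)
  }
  if (sum(tab) <= exact_limit) {
    p <- stats::fisher.test(tab)$p.value
    attr(p, "method") <- "exact"
  } else {
    set.seed(seed)
    p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value
    attr(p, "method") <- sprintf("monte_carlo_B%d", as.integer(B))
  }
  p
}

#' Monte-Carlo null distribution and p-value for the S statistic
#'
#' Pools the two timepoints to estimate the common relative-abundance
#' ratio `R_c`, then repeatedly redistributes each timepoint's labelled
#' cells over cell types from `Multinomial(n_t, p_ct * R_c / sum)` (the
#' null expectation), keeping the observed subset total `n_t` per
#' timepoint, and recomputes S. The p-value uses the add-one estimator.
#'
#' @param counts A `CompositionCounts` with at least two types and at
#'   least one labelled cell per timepoint.
#' @param n_sim Number of Monte-Carlo replicates (default 10000).
#' @param seed RNG seed.
#' @return A `CompositionTestResult`: `S_observed`, `null_S`, `p_value`,
#'   `n_sim`, `seed`, `fisher_p`, `common_R`.
#' @export
monte_carlo_null <- function(counts, n_sim = 10000L, seed = 1L) {
  stopifnot(inherits(counts, "CompositionCounts"))
  sub <- counts$subset_counts; bg <- counts$background_counts
  if (nrow(sub) < 2L) stop("need at least two cell types", call. = FALSE)
  n_t <- colSums(sub)
  if (any(n_t < 1)) stop("need >= 1 labelled cell per timepoint", call. = FALSE)
  ok <- rowSums(counts$p > 0) == 2L
  pooled_sub <- rowSums(sub[ok, , drop = FALSE])
  pooled_bg <- rowSums(bg[ok, , drop = FALSE])
  common_R <- (pooled_sub / sum(pooled_sub)) / (pooled_bg / sum(pooled_bg))
  if (!any(is.finite(common_R) & common_R > 0))
    stop("degenerate pooled ratio: no type carries labelled cells", call. = FALSE)
  p_ok <- counts$p[ok, , drop = FALSE]
  ex <- sweep(p_ok * common_R, 2L, colSums(p_ok * common_R), "/")

  S_obs <- as.numeric(compute_S(counts))
  set.seed(seed)
  draws1 <- stats::rmultinom(n_sim, n_t[1L], ex[, 1L])
  draws2 <- stats::rmultinom(n_sim, n_t[2L], ex[, 2L])
  stopifnot(all(colSums(draws1) == n_t[1L]), all(colSums(draws2) == n_t[2L]))
  R1 <- (draws1 / n_t[1L]) / p_ok[, 1L]
  R2 <- (draws2 / n_t[2L]) / p_ok[, 2L]
  null_S <- colSums((R1 - R2)^2)
  p <- (1 + sum(null_S >= S_obs)) / (1 + n_sim)
  structure(list(S_observed = S_obs, null_S = null_S, p_value = p,
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 fisher_p = as.numeric(fisher_2xC(sub, seed = seed)),
                 common_R = common_R),
            class = "CompositionTestResult")
}

#' @export
print.CompositionTestResult <- function(x, ...) {
  cat(sprintf("Composition ratio test: S = %.4f, Monte-Carlo p = %.4g (%d sims), Fisher p = %.4g\n",
              x$S_observed, x$p_value, x$n_sim, x$fisher_p))
  invisible(x)
}
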