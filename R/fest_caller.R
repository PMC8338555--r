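#' FEST antigen-specific clonotype calling
#'
#' Calls antigen-specific (expanded) T cell clonotypes from peptide-stimulated
#' culture TCR-seq versus a no-peptide control. A clonotype is called in a
#' condition when all four criteria hold:
#' (1) significant expansion versus the no-peptide control
#'     (one-sided Fisher exact test, Benjamini-Hochberg FDR < `fdr_alpha`);
#' (2) significant expansion versus every other peptide condition
#'     (FDR < `fdr_alpha`), except conditions in the same mutation group;
#' (3) odds ratio > `or_threshold` versus the control;
#' (4) present in at least `min_well_fraction` of the condition's wells.
#' Only clonotypes with at least `read_floor` reads in the condition are
#' tested.
#'
#' @name fest_caller
NULL

#' FEST caller configuration
#'
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param or_threshold Odds-ratio threshold, strict `>` (default 5).
#' @param min_well_fraction Minimum fraction of wells containing the clone,
#'   inclusive `>=` (default 0.10).
#' @param read_floor Minimum condition reads for a clonotype to be tested
#'   (300 for short-read core assays, 30 for survey-level Adaptive assays).
#' @param triplicate_mode Use the triplicate decision rule (assays testing
#'   fewer than 10 peptides are typically run in triplicate).
#' @param mutation_groups Named character vector mapping condition ids to a
#'   mutation identifier; conditions sharing an identifier are exempt from
#'   the cross-condition criterion in both directions.
#' @return A `FestConfig` list.
#' @export
fest_config <- function(fdr_alpha = 0.05, or_threshold = 5,
                        min_well_fraction = 0.10, read_floor = 300L,
                        triplicate_mode = FALSE,
                        mutation_groups = NULL) {
  stopifnot(fdr_alpha > 0, fdr_alpha < 1, or_threshold > 0,
            min_well_fraction >= 0, min_well_fraction <= 1, read_floor >= 0)
  structure(list(fdr_alpha = fdr_alpha, or_threshold = or_threshold,
                 min_well_fraction = min_well_fraction,
                 read_floor = as.integer(read_floor),
                 triplicate_mode = isTRUE(triplicate_mode),
                 mutation_groups = mutation_groups,
                 odds_ratio_convention = "haldane_anscombe_0.5_on_zero_cell"),
            class = "FestConfig")
}

#' One-sided Fisher expansion test for a 2x2 clonotype table
#'
#' Tests whether a clonotype's read proportion is greater in the condition
#' than in the reference, conditioning on the margins of the table
#' `[[a, n1 - a], [b, n2 - b]]`. The p-value is the upper hypergeometric
#' tail; the odds ratio is the cross-product ratio, with a Haldane-Anscombe
#' +0.5 applied to every cell when any cell is zero.
#'
#' @param a Clone reads in the condition.
#' @param n1 Total reads in the condition.
#' @param b Clone reads in the reference.
#' @param n2 Total reads in the reference.
#' @return List with `p` and `odds_ratio`. Vectorised over `a`, `b` (and
#'   `n1`, `n2`).
#' @examples
#' fisher_expansion_test(10, 100, 0, 100)
#' @export
fisher_expansion_test <- function(a, n1, b, n2) {
  if (any(n1 <= 0) || any(n2 <= 0))
    stop("n1 and n2 must be positive", call. = FALSE)
  if (any(a < 0) || any(b < 0) || any(a > n1) || any(b > n2))
    stop("need 0 <= a <= n1 and 0 <= b <= n2", call. = FALSE)
  # P(X >= a) for X ~ Hypergeom(white = a + b, black = n1 + n2 - a - b, drawn = n1)
  p <- stats::phyper(a - 1, a + b, n1 + n2 - a - b, n1, lower.tail = FALSE)
  x11 <- a; x12 <- n1 - a; x21 <- b; x22 <- n2 - b
  zero <- x11 == 0 | x12 == 0 | x21 == 0 | x22 == 0
  h <- ifelse(zero, 0.5, 0)
  odds_ratio <- ((x11 + h) * (x22 + h)) / ((x12 + h) * (x21 + h))
  list(p = p, odds_ratio = odds_ratio)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, order-aligned with the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Fraction of wells containing a clonotype
#'
#' @param cdr3 CDR3 amino-acid string.
#' @param table A `ClonotypeTable` with at least one declared well.
#' @return Fraction of the condition's wells in which the clone has >= 1
#'   read.
#' @export
well_presence_fraction <- function(cdr3, table) {
  stopifnot(inherits(table, "ClonotypeTable"))
  if (length(table$well_ids) == 0L)
    stop("table declares zero wells", call. = FALSE)
  rec <- table$records
  hit <- rec$cdr3_aa == cdr3 & rec$reads >= 1L
  length(unique(rec$well_id[hit])) / length(table$well_ids)
}

# p-values of all eligible clones of `cond` versus reference counts.
# counts are named integer vectors (cdr3 -> reads).
pairwise_expansion <- function(clones, cond_counts, ref_counts) {
  n1 <- sum(cond_counts); n2 <- sum(ref_counts)
  a <- ifelse(clones %in% names(cond_counts), cond_counts[clones], 0L)
  b <- ifelse(clones %in% names(ref_counts), ref_counts[clones], 0L)
  ft <- fisher_expansion_test(as.integer(a), n1, as.integer(b), n2)
  data.frame(cdr3_aa = clones, reads_condition = as.integer(a),
             reads_reference = as.integer(b), p = ft$p,
             odds_ratio = ft$odds_ratio, stringsAsFactors = FALSE)
}

#' Call antigen-specific clonotypes
#'
#' Applies the four calling criteria to every eligible (clonotype,
#' condition) pair. FDR adjustment is applied within each comparison family
#' (condition versus control, condition versus each other condition) across
#' all clonotypes eligible in that condition.
#'
#' @param tables Named list of condition `ClonotypeTable`s (preprocessed and
#'   depth-filtered).
#' @param control The no-peptide control `ClonotypeTable`.
#' @param config A [fest_config()].
#' @return Data frame of FEST calls, one row per eligible (clonotype,
#'   condition): reads, p and FDR versus control, worst FDR versus other
#'   conditions, odds ratio, well fraction, the four criterion flags and the
#'   conjunctive `verdict`. Per-condition p-values versus each other
#'   condition are attached as attribute `cross_fdr` (a list of matrices).
#' @export
call_antigen_specific <- function(tables, control, config = fest_config()) {
  if (missing(control) || is.null(control))
    stop("a no-peptide control table is required", call. = FALSE)
  stopifnot(is.list(tables), length(tables) >= 1L,
            inherits(control, "ClonotypeTable"), inherits(config, "FestConfig"))
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, function(t) t$condition_id, character(1))
  # stable alphabetical order: verdicts invariant to input ordering
  tables <- tables[order(names(tables))]

  counts <- lapply(tables, condition_counts)
  ctrl_counts <- condition_counts(control)
  mg <- config$mutation_groups

  calls <- vector("list", length(tables))
  cross_fdr_all <- list()
  for (ci in seq_along(tables)) {
    cond <- names(tables)[ci]
    cc <- counts[[cond]]
    eligible <- sort(names(cc)[cc >= config$read_floor])
    if (!length(eligible)) next
    vs_ctrl <- pairwise_expansion(eligible, cc, ctrl_counts)
    vs_ctrl$fdr <- bh_adjust(vs_ctrl$p)

    others <- setdiff(names(tables), cond)
    if (!is.null(mg) && cond %in% names(mg))
      others <- others[is.na(mg[others]) | mg[others] != mg[[cond]]]
    cross_fdr <- matrix(numeric(0), nrow = length(eligible), ncol = 0,
                        dimnames = list(eligible, NULL))
    for (oth in others) {
      po <- pairwise_expansion(eligible, cc, counts[[oth]])
      cross_fdr <- cbind(cross_fdr, bh_adjust(po$p))
      colnames(cross_fdr)[ncol(cross_fdr)] <- oth
    }
    cross_fdr_all[[cond]] <- cross_fdr

    wf <- vapply(eligible, well_presence_fraction, numeric(1),
                 table = tables[[cond]])
    crit1 <- vs_ctrl$fdr < config$fdr_alpha
    crit2 <- if (ncol(cross_fdr)) apply(cross_fdr < config$fdr_alpha, 1L, all)
             else rep(TRUE, length(eligible))
    crit3 <- vs_ctrl$odds_ratio > config$or_threshold
    crit4 <- wf >= config$min_well_fraction
    calls[[ci]] <- data.frame(
      cdr3_aa = eligible, condition_id = cond,
      reads_condition = vs_ctrl$reads_condition,
      reads_control = vs_ctrl$reads_reference,
      p_vs_control = vs_ctrl$p, fdr_vs_control = vs_ctrl$fdr,
      max_fdr_vs_others = if (ncol(cross_fdr)) apply(cross_fdr, 1L, max) else NA_real_,
      odds_ratio = vs_ctrl$odds_ratio, well_fraction = unname(wf),
      crit_expanded_vs_control = crit1, crit_expanded_vs_others = crit2,
      crit_odds_ratio = crit3, crit_well_distribution = crit4,
      verdict = crit1 & crit2 & crit3 & crit4,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(cdr3_aa = character(0), condition_id = character(0),
                      reads_condition = integer(0), reads_control = integer(0),
                      p_vs_control = numeric(0), fdr_vs_control = numeric(0),
                      max_fdr_vs_others = numeric(0), odds_ratio = numeric(0),
                      well_fraction = numeric(0),
                      crit_expanded_vs_control = logical(0),
                      crit_expanded_vs_others = logical(0),
                      crit_odds_ratio = logical(0),
                      crit_well_distribution = logical(0),
                      verdict = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cross_fdr") <- cross_fdr_all
  attr(out, "config") <- config
  out
}

#' Call reactive clonotypes in triplicate mode
#'
#' For assays run in triplicate (typically those testing fewer than 10
#' peptides), a clonotype is reactive in a condition when it is
#' significantly expanded versus the no-peptide control (FDR < `fdr_alpha`)
#' in at least 2 of the 3 triplicate cultures, and not significantly
#' expanded in any culture of any other condition.
#'
#' @param tables Named list of conditions, each a list of 3 replicate
#'   `ClonotypeTable`s.
#' @param control The no-peptide control `ClonotypeTable`.
#' @param config A [fest_config()] with `triplicate_mode = TRUE`.
#' @param allow_unbalanced Permit conditions with a replicate count other
#'   than 3 (the 2-of-3 rule becomes majority-of-replicates).
#' @return Data frame with one row per (clonotype, condition):
#'   `n_significant`, `n_replicates`, `significant_elsewhere`, `verdict`.
#' @export
call_triplicate_mode <- function(tables, control, config = fest_config(triplicate_mode = TRUE),
                                 allow_unbalanced = FALSE) {
  if (missing(control) || is.null(control))
    stop("a no-peptide control table is required", call. = FALSE)
  if (!isTRUE(config$triplicate_mode))
    stop("config$triplicate_mode must be TRUE", call. = FALSE)
  stopifnot(is.list(tables), length(tables) >= 1L)
  nrep <- vapply(tables, length, integer(1))
  if (any(nrep != 3L) && !allow_unbalanced)
    stop("each condition needs exactly 3 replicate tables ",
         "(set allow_unbalanced = TRUE to override)", call. = FALSE)
  tables <- tables[order(names(tables))]
  ctrl_counts <- condition_counts(control)

  # significance of every eligible clone in every replicate culture
  rep_sig <- list()  # condition -> clone x replicate logical matrix
  for (cond in names(tables)) {
    reps <- tables[[cond]]
    clones <- sort(unique(unlist(lapply(reps, function(t) {
      cc <- condition_counts(t); names(cc)[cc >= config$read_floor]
    }))))
    sig <- matrix(FALSE, length(clones), length(reps),
                  dimnames = list(clones, NULL))
    if (length(clones)) {
      for (ri in seq_along(reps)) {
        cc <- condition_counts(reps[[ri]])
        pe <- pairwise_expansion(clones, cc, ctrl_counts)
        sig[, ri] <- bh_adjust(pe$p) < config$fdr_alpha
      }
    }
    rep_sig[[cond]] <- sig
  }

  out <- list()
  for (cond in names(tables)) {
    sig <- rep_sig[[cond]]
    if (!nrow(sig)) next
    n_sig <- rowSums(sig)
    need <- if (ncol(sig) == 3L) 2L else floor(ncol(sig) / 2) + 1L
    elsewhere <- vapply(rownames(sig), function(cl) {
      any(vapply(setdiff(names(tables), cond), function(oth) {
        s <- rep_sig[[oth]]
        cl %in% rownames(s) && any(s[cl, ])
      }, logical(1)))
    }, logical(1))
    out[[cond]] <- data.frame(
      cdr3_aa = rownames(sig), condition_id = cond,
      n_significant = as.integer(n_sig), n_replicates = ncol(sig),
      significant_elsewhere = unname(elsewhere),
      verdict = n_sig >= need & !elsewhere,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(cdr3_aa = character(0), condition_id = character(0),
                      n_significant = integer(0), n_replicates = integer(0),
                      significant_elsewhere = logical(0), verdict = logical(0))
  rownames(out) <- NULL
  out
}
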