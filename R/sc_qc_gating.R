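#' Single-cell QC, CD8 density gating, and clonotype linking
#'
#' Cell- and gene-level quality filters matching standard tumour TIL
#' processing, a density-trough gate for calling CD8+ cells from CD8A
#' expression, and exact CDR3-barcode linking of FEST-called clonotypes
#' into the single-cell data.
#'
#' @name sc_qc_gating
NULL

#' QC configuration
#'
#' @param min_genes Minimum detected genes per cell (default 250; a
#'   detected gene has count > 0).
#' @param mad_multiplier Upper cut at `median + mad_multiplier * MAD` of
#'   detected genes (raw MAD, no normal-consistency scaling; default 3).
#' @param max_mito_frac Cells with mitochondrial count fraction strictly
#'   above this are removed (default 0.10).
#' @param min_ribo_frac Cells with ribosomal count fraction strictly below
#'   this are removed (default 0.10). Ribosomal genes are symbols with
#'   prefix RPL or RPS.
#' @param min_cells_per_gene Genes detected in fewer than this many cells
#'   are removed (default 5).
#' @param exclusion_gene_lists Named list of character vectors of symbols to
#'   remove outright (e.g. dissociation/stress genes, high-abundance
#'   lincRNA). Prefix rules for MT-, RP- and TR segment genes are applied
#'   independently of these lists.
#' @param drop_rp_prefix Remove genes with prefix "RP-" style poorly
#'   supported models (here: symbols matching `^RP[0-9]` or `^RP-`);
#'   default TRUE.
#' @return A `QcConfig` list.
#' @export
qc_config <- function(min_genes = 250L, mad_multiplier = 3,
                      max_mito_frac = 0.10, min_ribo_frac = 0.10,
                      min_cells_per_gene = 5L,
                      exclusion_gene_lists = list(),
                      drop_rp_prefix = TRUE) {
  stopifnot(min_genes > 0, mad_multiplier > 0,
            max_mito_frac >= 0, max_mito_frac <= 1,
            min_ribo_frac >= 0, min_ribo_frac <= 1, min_cells_per_gene >= 0)
  structure(list(min_genes = as.integer(min_genes),
                 mad_multiplier = mad_multiplier,
                 max_mito_frac = max_mito_frac, min_ribo_frac = min_ribo_frac,
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 exclusion_gene_lists = exclusion_gene_lists,
                 drop_rp_prefix = isTRUE(drop_rp_prefix),
                 mad_convention = "raw (constant = 1)"),
            class = "QcConfig")
}

is_mito_gene <- function(symbols) startsWith(symbols, "MT-")
is_ribo_gene <- function(symbols) grepl("^RP[LS]", symbols)
is_tr_gene <- function(symbols)
  grepl("^TR[ABDG][VDJC]", symbols)

#' Filter low-quality cells
#'
#' Removes cells whose detected gene number is below `min_genes` or above
#' `median + mad_multiplier * MAD` of all cells, whose mitochondrial count
#' fraction exceeds `max_mito_frac`, or whose ribosomal count fraction is
#' below `min_ribo_frac`. Comparisons at the thresholds are kept (the mito
#' and ribo rules are strict inequalities).
#'
#' @param ds A `CellDataset` of raw counts.
#' @param cfg A [qc_config()].
#' @return The filtered `CellDataset`; attribute `qc_report` gives per-rule
#'   removal counts.
#' @export
filter_cells <- function(ds, cfg = qc_config()) {
  stopifnot(inherits(ds, "CellDataset"), inherits(cfg, "QcConfig"))
  m <- ds$counts
  detected <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  total[total == 0] <- 1
  mito <- Matrix::colSums(m[is_mito_gene(rownames(m)), , drop = FALSE]) / total
  ribo <- Matrix::colSums(m[is_ribo_gene(rownames(m)), , drop = FALSE]) / total
  upper <- stats::median(detected) +
    cfg$mad_multiplier * stats::mad(detected, constant = 1)
  low_genes <- detected < cfg$min_genes
  high_genes <- detected > upper
  high_mito <- mito > cfg$max_mito_frac
  low_ribo <- ribo < cfg$min_ribo_frac
  drop <- low_genes | high_genes | high_mito | low_ribo
  if (all(drop))
    stop(sprintf(paste0("all %d cells removed by QC (low genes %d, high genes %d, ",
                        "high mito %d, low ribo %d); check thresholds"),
                 length(drop), sum(low_genes), sum(high_genes),
                 sum(high_mito), sum(low_ribo)), call. = FALSE)
  out <- subset_cells(ds, cells = !drop)
  attr(out, "qc_report") <- list(
    n_input = length(drop), n_kept = sum(!drop),
    removed_low_genes = sum(low_genes), removed_high_genes = sum(high_genes),
    removed_high_mito = sum(high_mito), removed_low_ribo = sum(low_ribo),
    upper_gene_cut = upper, mad_convention = cfg$mad_convention)
  out
}

#' Filter genes
#'
#' Removes mitochondrial (prefix `MT-`), poorly supported `RP-`-style
#' models, TCR segment genes (TRA/TRB/TRD/TRG V/D/J/C symbols, to avoid
#' clonotype bias), any symbols on the configured exclusion lists, and
#' genes detected in fewer than `min_cells_per_gene` cells.
#'
#' @param ds A cell-filtered `CellDataset`.
#' @param cfg A [qc_config()].
#' @return The gene-filtered `CellDataset`; attribute `gene_report` gives
#'   per-rule removal counts.
#' @export
filter_genes <- function(ds, cfg = qc_config()) {
  stopifnot(inherits(ds, "CellDataset"), inherits(cfg, "QcConfig"))
  g <- rownames(ds$counts)
  listed <- g %in% unlist(cfg$exclusion_gene_lists, use.names = FALSE)
  mito <- is_mito_gene(g)
  rp <- if (cfg$drop_rp_prefix) grepl("^RP-|^RP[0-9]", g) else rep(FALSE, length(g))
  tr <- is_tr_gene(g)
  ncells <- Matrix::rowSums(ds$counts > 0)
  rare <- ncells < cfg$min_cells_per_gene
  drop <- listed | mito | rp | tr | rare
  out <- subset_cells(ds, genes = !drop)
  attr(out, "gene_report") <- list(
    n_input = length(g), n_kept = sum(!drop),
    removed_listed = sum(listed), removed_mito = sum(mito),
    removed_rp = sum(rp), removed_tr = sum(tr), removed_rare = sum(rare))
  out
}

#' CD8 gate from the trough of a bimodal expression density
#'
#' Fits a Gaussian-kernel density (Silverman bandwidth, 512-point grid
#' spanning the data range +/- 3 bandwidths) to per-cell log2 CD8A
#' expression and places the cut-off at the trough of the bimodal curve:
#' the first grid location where the first derivative crosses from
#' negative to positive. Cells above the cut-off are called CD8+.
#'
#' @param expr Numeric vector of per-cell log2 (imputed and/or normalized)
#'   CD8A expression.
#' @param min_cells Minimum number of cells required (default 100).
#' @return List with `cutoff`, logical `mask` (`expr > cutoff`), and the
#'   density object.
#' @export
gate_cd8 <- function(expr, min_cells = 100L) {
  if (length(expr) < min_cells)
    stop("need at least ", min_cells, " cells to fit the gate", call. = FALSE)
  if (any(!is.finite(expr)))
    stop("expression values must be finite", call. = FALSE)
  bw <- stats::bw.nrd0(expr)
  if (bw <= 0)
    stop("unimodal: no trough found (degenerate expression values)", call. = FALSE)
  d <- stats::density(expr, bw = bw, n = 512L,
                      from = min(expr) - 3 * bw, to = max(expr) + 3 * bw)
  dy <- diff(d$y)
  # trough = first sign change of the first derivative from negative to
  # positive strictly inside the grid
  trough <- which(dy[-length(dy)] < 0 & dy[-1L] > 0)
  trough <- trough[trough > 1L & trough < length(d$y) - 1L]
  if (!length(trough))
    stop("unimodal: no trough found in the fitted density", call. = FALSE)
  cutoff <- d$x[trough[1L] + 1L]
  list(cutoff = cutoff, mask = expr > cutoff, density = d)
}

#' Link FEST-called clonotypes into single-cell data by TRB CDR3 barcode
#'
#' Exact amino-acid string matching of each cell's TRB CDR3 against the
#' verdict-true clonotypes of a FEST call set. Cells whose CDR3 matches
#' clonotypes of two different antigen classes are flagged ambiguous.
#'
#' @param ds A `CellDataset` whose `cell_meta` has a `trb_cdr3` column
#'   (NA for cells without a VDJ assembly).
#' @param calls FEST call data frame (see [call_antigen_specific()]); only
#'   `verdict == TRUE` rows are used.
#' @param specificity_labels Named character vector mapping condition ids
#'   (or CDR3s, see `by`) to an antigen class such as "MANA", "EBV",
#'   "InfluenzaA".
#' @param by Either `"condition"` (default; `specificity_labels` keyed by
#'   condition id) or `"cdr3"` (keyed directly by CDR3).
#' @return Character vector per cell: the antigen class, `"ambiguous"`, or
#'   NA for unmatched/unlabelled cells.
#' @export
link_clonotypes <- function(ds, calls, specificity_labels, by = c("condition", "cdr3")) {
  stopifnot(inherits(ds, "CellDataset"))
  by <- match.arg(by)
  if (!"trb_cdr3" %in% names(ds$cell_meta))
    stop("cell_meta lacks a trb_cdr3 column", call. = FALSE)
  hits <- calls[calls$verdict %in% TRUE, , drop = FALSE]
  cls <- if (by == "condition") unname(specificity_labels[hits$condition_id])
         else unname(specificity_labels[hits$cdr3_aa])
  ok <- !is.na(cls)
  map <- split(cls[ok], hits$cdr3_aa[ok])
  map <- lapply(map, unique)
  cell_cdr3 <- as.character(ds$cell_meta$trb_cdr3)
  out <- rep(NA_character_, length(cell_cdr3))
  idx <- !is.na(cell_cdr3) & cell_cdr3 %in% names(map)
  out[idx] <- vapply(map[cell_cdr3[idx]], function(classes) {
    if (length(classes) > 1L) "ambiguous" else classes
  }, character(1))
  out
}
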