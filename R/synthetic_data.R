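#' Synthetic data generators with known ground truth
#'
#' Seed-deterministic generators for (1) peptide-stimulation repertoire
#' experiments with spiked antigen-driven clonal expansions and replicate
#' wells, (2) single-cell count data with cluster structure, clonotype
#' labels, binary covariates and batch effects, and (3) pseudotime
#' expression with genes of known dynamic pattern. Every generator returns
#' a `truth` record sufficient to score the downstream modules.
#'
#' @name synthetic_data
NULL

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# grammar-valid CDR3s: start C, end F/W, length >= 7 — survive preprocessing
random_cdr3 <- function(n, min_len = 10L, max_len = 16L) {
  len <- sample(seq.int(min_len, max_len), n, replace = TRUE)
  vapply(len, function(l)
    paste0("C", paste(sample(AA, l - 2L, replace = TRUE), collapse = ""),
           sample(c("F", "W"), 1L)),
    character(1))
}

#' Simulate a peptide-stimulation repertoire experiment
#'
#' Baseline clone frequencies are drawn once from a symmetric Dirichlet;
#' in each spiked condition the designated clones' frequencies are
#' multiplied by their fold expansion and renormalized; reads are then
#' drawn multinomially per replicate well (total depth split equally
#' across wells). The no-peptide control uses the baseline frequencies.
#'
#' @param n_clones Number of clonotypes in the repertoire (default 1000).
#' @param n_conditions Number of peptide conditions (default 2).
#' @param depth Total reads per condition (default 1e5).
#' @param n_wells Replicate wells per condition (default 10).
#' @param spiked Data frame with columns `clone` (index), `condition`
#'   (condition name, e.g. "peptide1") and `fold` (> 1); NULL for a null
#'   experiment.
#' @param concentration Symmetric Dirichlet concentration for baseline
#'   frequencies (default 0.5, giving a skewed repertoire).
#' @param n_replicates Tables per condition (default 1; 3 for triplicate
#'   designs — each replicate redraws reads at `depth`).
#' @param seed RNG seed.
#' @return List with `tables` (named list of condition `ClonotypeTable`s),
#'   `control`, and `truth` (spiked set, baseline frequencies, CDR3s).
#' @export
simulate_repertoire <- function(n_clones = 1000L, n_conditions = 2L,
                                depth = 1e5, n_wells = 10L, spiked = NULL,
                                concentration = 0.5, n_replicates = 1L,
                                seed = 1L) {
  stopifnot(n_clones >= 2L, n_conditions >= 1L, depth > 0, n_wells >= 1L)
  if (!is.null(spiked)) {
    stopifnot(all(c("clone", "condition", "fold") %in% names(spiked)),
              all(spiked$fold > 1), all(spiked$clone <= n_clones))
  }
  set.seed(seed)
  cdr3 <- random_cdr3(n_clones)
  while (anyDuplicated(cdr3))
    cdr3[duplicated(cdr3)] <- random_cdr3(sum(duplicated(cdr3)))
  v_gene <- paste0("TRBV", sample(1:30, n_clones, replace = TRUE))
  base_freq <- stats::rgamma(n_clones, shape = concentration)
  base_freq <- base_freq / sum(base_freq)
  if (depth * min(base_freq) < 0.01)
    message("simulate_repertoire: smallest baseline clone expected < 0.01 reads at this depth")

  conditions <- paste0("peptide", seq_len(n_conditions))
  draw_table <- function(freq, id) {
    per_well <- diff(round(seq(0, depth, length.out = n_wells + 1L)))
    recs <- lapply(seq_len(n_wells), function(w) {
      reads <- as.integer(stats::rmultinom(1L, per_well[w], freq))
      keep <- reads > 0L
      data.frame(well_id = sprintf("well%02d", w), cdr3_aa = cdr3[keep],
                 v_gene = v_gene[keep], reads = reads[keep],
                 productive = TRUE, stringsAsFactors = FALSE)
    })
    new_clonotype_table(id, do.call(rbind, recs),
                        sprintf("well%02d", seq_len(n_wells)))
  }
  cond_freq <- lapply(stats::setNames(conditions, conditions), function(cond) {
    f <- base_freq
    if (!is.null(spiked)) {
      sp <- spiked[spiked$condition == cond, , drop = FALSE]
      f[sp$clone] <- f[sp$clone] * sp$fold
      f <- f / sum(f)
    }
    f
  })
  tables <- lapply(stats::setNames(conditions, conditions), function(cond) {
    if (n_replicates == 1L) draw_table(cond_freq[[cond]], cond)
    else lapply(stats::setNames(seq_len(n_replicates),
                                paste0(cond, "_rep", seq_len(n_replicates))),
                function(r) draw_table(cond_freq[[cond]],
                                       paste0(cond, "_rep", r)))
  })
  control <- draw_table(base_freq, "no_peptide")
  truth <- list(
    spiked = if (is.null(spiked)) spiked else
      cbind(spiked, cdr3_aa = cdr3[spiked$clone], stringsAsFactors = FALSE),
    base_freq = base_freq, cdr3 = cdr3, seed = seed)
  list(tables = tables, control = control, truth = truth)
}

#' Simulate a single-cell dataset with clusters, covariates and clonotypes
#'
#' Counts follow a Poisson-lognormal model around cluster-, covariate- and
#' batch-shifted gene means. A designated gene subset is shifted in one
#' covariate group (ground-truth DE genes); `CD8A` is simulated bimodally
#' across a CD8+ and a CD8- population; clonotype labels follow a
#' truncated power-law clone-size distribution with grammar-valid CDR3s,
#' and labelled (antigen-specific) cells are placed in designated clusters
#' at a designated enrichment.
#'
#' @param n_cells,n_genes,n_clusters Dataset dimensions (defaults 2000,
#'   500, 4).
#' @param n_samples Samples, split evenly over two covariate groups
#'   (default 6).
#' @param n_batches Batches (default 2).
#' @param de_frac Fraction of genes shifted in group "MPR" (default 0.1).
#' @param de_lfc Log2 shift of DE genes (default 1).
#' @param n_clonotypes Clonotypes to assign (default 50).
#' @param labelled_clusters Clusters that concentrate the labelled
#'   (antigen-specific) clonotype cells (default cluster 1).
#' @param labelled_frac Fraction of cells carrying a labelled clonotype
#'   (default 0.05).
#' @param enrichment Fold by which labelled cells prefer
#'   `labelled_clusters` (default 5).
#' @param dropout Extra Bernoulli dropout applied to counts (default 0).
#' @param mean_log,sd_log Baseline lognormal parameters of gene means
#'   (defaults -1, 1).
#' @param seed RNG seed.
#' @return List with `ds` (a `CellDataset` whose metadata carries sample,
#'   group, batch, cluster, trb_cdr3) and `truth` (cluster labels, DE
#'   genes, clonotype map, labelled clusters, CD8 status).
#' @export
simulate_sc <- function(n_cells = 2000L, n_genes = 500L, n_clusters = 4L,
                        n_samples = 6L, n_batches = 2L, de_frac = 0.10,
                        de_lfc = 1, n_clonotypes = 50L,
                        labelled_clusters = 1L, labelled_frac = 0.05,
                        enrichment = 5, dropout = 0,
                        mean_log = -1, sd_log = 1, seed = 1L) {
  set.seed(seed)
  genes <- c("CD8A", "CTLA4", "PDCD1", "LAG3", "HAVCR2", "TIGIT", "ENTPD1",
             paste0("gene", seq_len(n_genes - 7L)))
  base_mu <- stats::rlnorm(n_genes, mean_log, sd_log)
  names(base_mu) <- genes

  cluster <- sample.int(n_clusters, n_cells, replace = TRUE)
  sample_id <- paste0("s", sample.int(n_samples, n_cells, replace = TRUE))
  group <- ifelse(as.integer(sub("s", "", sample_id)) <= n_samples / 2,
                  "MPR", "nonMPR")
  batch <- paste0("b", ((as.integer(sub("s", "", sample_id)) - 1L) %% n_batches) + 1L)

  # per-cluster multiplicative signatures on a random 20% of genes
  cl_shift <- matrix(1, n_genes, n_clusters)
  for (k in seq_len(n_clusters)) {
    idx <- sample.int(n_genes, ceiling(0.2 * n_genes))
    cl_shift[idx, k] <- 2^stats::runif(length(idx), -1.5, 1.5)
  }
  de_genes <- sample(setdiff(genes, "CD8A"), ceiling(de_frac * n_genes))
  de_shift <- stats::setNames(rep(1, n_genes), genes)
  de_shift[de_genes] <- 2^de_lfc
  batch_shift <- matrix(2^stats::runif(n_genes * n_batches, -0.3, 0.3),
                        n_genes, n_batches)

  mu <- base_mu * cl_shift[, cluster]
  grp_mult <- outer(de_shift, group == "MPR")
  grp_mult[, !(group == "MPR")] <- 1
  mu <- mu * grp_mult * batch_shift[, as.integer(sub("b", "", batch))]

  # bimodal CD8A: CD8+ cells high, CD8- near-zero ambient
  cd8_pos <- stats::runif(n_cells) < 0.7
  mu["CD8A", ] <- ifelse(cd8_pos, 16, 0.05)

  noise <- matrix(stats::rlnorm(n_genes * n_cells, 0, 0.3), n_genes, n_cells)
  counts <- matrix(stats::rpois(n_genes * n_cells, mu * noise),
                   n_genes, n_cells, dimnames = list(genes, NULL))
  if (dropout > 0)
    counts <- counts * matrix(stats::rbinom(n_genes * n_cells, 1L, 1 - dropout),
                              n_genes, n_cells)

  # clonotypes: truncated power-law clone sizes; labelled clones enriched
  # in the designated clusters
  cdr3 <- random_cdr3(n_clonotypes)
  clone_w <- (seq_len(n_clonotypes))^-1.5
  n_lab <- max(1L, ceiling(labelled_frac * n_cells))
  lab_clones <- seq_len(max(1L, ceiling(n_clonotypes * 0.2)))
  in_lab_cl <- cluster %in% labelled_clusters
  w_cell <- ifelse(in_lab_cl, enrichment, 1)
  lab_cells <- sample.int(n_cells, n_lab, prob = w_cell)
  trb <- rep(NA_character_, n_cells)
  trb[lab_cells] <- cdr3[sample(lab_clones, n_lab, replace = TRUE,
                                prob = clone_w[lab_clones])]
  unlab_cells <- sample(setdiff(seq_len(n_cells), lab_cells),
                        min(n_lab, n_cells - n_lab))
  other_clones <- setdiff(seq_len(n_clonotypes), lab_clones)
  if (length(other_clones))
    trb[unlab_cells] <- cdr3[sample(other_clones, length(unlab_cells),
                                    replace = TRUE,
                                    prob = clone_w[other_clones])]

  meta <- data.frame(sample = sample_id, group = group, batch = batch,
                     cluster = paste0("c", cluster), trb_cdr3 = trb,
                     stringsAsFactors = FALSE)
  ds <- cell_dataset(counts, meta)
  truth <- list(cluster = paste0("c", cluster), de_genes = de_genes,
                clonotype_map = stats::setNames(
                  rep(c("MANA", "other"), c(length(lab_clones),
                                            n_clonotypes - length(lab_clones))),
                  cdr3),
                labelled_cdr3 = cdr3[lab_clones],
                labelled_clusters = paste0("c", labelled_clusters),
                cd8_pos = cd8_pos, seed = seed)
  list(ds = ds, truth = truth)
}

#' Pseudotime pattern templates
#'
#' Rising, falling and transient shapes on the unit interval, used as
#' ground-truth dynamic patterns.
#'
#' @return Named list of functions of `t` in \[0, 1\].
#' @export
pseudotime_templates <- function() {
  list(rising = function(t) t,
       falling = function(t) 1 - t,
       transient = function(t) sin(pi * t))
}

#' Simulate expression along pseudotime
#'
#' Per-sample pseudotimes are uniform on \[0, 1\]; dynamic genes follow a
#' template shape (scaled by `amplitude`) plus Gaussian noise, flat genes
#' are constant plus noise.
#'
#' @param n_cells Cells per sample (default 300).
#' @param n_samples Samples (default 3).
#' @param n_dynamic,n_flat Number of dynamic / flat genes (defaults 30,
#'   120).
#' @param templates Named list of template functions on \[0, 1\] (default
#'   [pseudotime_templates()]), recycled over dynamic genes.
#' @param amplitude Template amplitude (default 1).
#' @param noise_sd Gaussian noise SD (default 0.3).
#' @param seed RNG seed.
#' @return List with `expr` (genes x cells), `t`, `samples`, and `truth`
#'   (dynamic gene set and template assignment).
#' @export
simulate_pseudotime <- function(n_cells = 300L, n_samples = 3L,
                                n_dynamic = 30L, n_flat = 120L,
                                templates = pseudotime_templates(),
                                amplitude = 1, noise_sd = 0.3, seed = 1L) {
  set.seed(seed)
  total <- n_cells * n_samples
  samples <- rep(paste0("s", seq_len(n_samples)), each = n_cells)
  t <- stats::runif(total)
  tmpl_names <- rep(names(templates), length.out = n_dynamic)
  dyn_names <- sprintf("dyn%03d_%s", seq_len(n_dynamic), tmpl_names)
  flat_names <- sprintf("flat%03d", seq_len(n_flat))
  expr <- matrix(0, n_dynamic + n_flat, total,
                 dimnames = list(c(dyn_names, flat_names), NULL))
  for (i in seq_len(n_dynamic))
    expr[i, ] <- amplitude * templates[[tmpl_names[i]]](t) +
      stats::rnorm(total, 0, noise_sd)
  base <- stats::runif(n_flat, 0.2, 1)
  for (i in seq_len(n_flat))
    expr[n_dynamic + i, ] <- base[i] + stats::rnorm(total, 0, noise_sd)
  list(expr = expr, t = t, samples = samples,
       truth = list(dynamic = dyn_names,
                    template = stats::setNames(tmpl_names, dyn_names),
                    seed = seed))
}
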