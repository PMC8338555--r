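#' End-to-end pipeline over synthetic or user data
#'
#' Runs the stages in dependency order from a single configuration (a YAML
#' file or an equivalent nested list): synthetic-data generation, FEST
#' calling, single-cell QC + CD8 gating + clonotype linking, pseudobulk
#' PCA + covariate permutation test, composition test, signature scoring,
#' and the pseudotime LR test. Every output table is written as TSV with a
#' JSON sidecar recording the stage configuration hash and seed, and a
#' manifest lists all artifacts. Outputs carry no timestamps, so reruns
#' with the same config and seed are byte-identical.
#'
#' @param config Path to a YAML file or a nested list. Recognised blocks
#'   (all optional, each with stage-specific fields): `sim_repertoire`,
#'   `fest`, `sim_sc`, `qc`, `pseudobulk`, `composition`,
#'   `sim_pseudotime`, `pseudotime`. Top level: `seed` (default 1),
#'   `out_dir` (required).
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML path or a list", call. = FALSE)
  if (is.null(config$out_dir))
    stop("config$out_dir is required", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(config)
  manifest <- list(config_hash = cfg_hash, seed = seed, stages = list())

  emit <- function(stage, name, df) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    sidecar <- list(stage = stage, config_hash = cfg_hash, seed = seed,
                    package_version = as.character(utils::packageVersion("festsc")))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
    manifest$stages[[stage]] <<- union(manifest$stages[[stage]] %||% character(0),
                                       basename(path))
    path
  }

  defaults <- function(block, d) utils::modifyList(d, config[[block]] %||% list())

  # -- repertoire simulation + FEST calling ------------------------------
  if (!is.null(config$sim_repertoire) || !is.null(config$fest)) {
    sim_cfg <- defaults("sim_repertoire",
                        list(n_clones = 1000L, n_conditions = 2L, depth = 1e5,
                             n_wells = 10L, spiked = NULL))
    spiked <- if (!is.null(sim_cfg$spiked)) as.data.frame(sim_cfg$spiked) else NULL
    rep_sim <- simulate_repertoire(
      n_clones = sim_cfg$n_clones, n_conditions = sim_cfg$n_conditions,
      depth = sim_cfg$depth, n_wells = sim_cfg$n_wells, spiked = spiked,
      seed = seed)
    fest_cfg_l <- defaults("fest", list(fdr_alpha = 0.05, or_threshold = 5,
                                        min_well_fraction = 0.10,
                                        read_floor = 300L))
    tabs <- lapply(rep_sim$tables, preprocess_cdr3)
    ctrl <- preprocess_cdr3(rep_sim$control)
    kept <- exclude_low_depth(c(tabs, list(no_peptide = ctrl)))$kept
    ctrl <- kept$no_peptide
    if (is.null(ctrl))
      stop("pipeline: the no-peptide control was excluded at depth filtering; ",
           "cannot run the FEST stage", call. = FALSE)
    tabs <- kept[setdiff(names(kept), "no_peptide")]
    calls <- call_antigen_specific(
      tabs, ctrl,
      fest_config(fdr_alpha = fest_cfg_l$fdr_alpha,
                  or_threshold = fest_cfg_l$or_threshold,
                  min_well_fraction = fest_cfg_l$min_well_fraction,
                  read_floor = fest_cfg_l$read_floor))
    emit("fest", "fest_calls", calls)
    summary <- list(n_tested = nrow(calls), n_called = sum(calls$verdict),
                    conditions = names(tabs), seed = seed)
    jsonlite::write_json(summary, file.path(out_dir, "fest_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest$stages$fest <- union(manifest$stages$fest, "fest_summary.json")
  } else calls <- NULL

  # -- single-cell simulation, QC, gating, linking -----------------------
  if (!is.null(config$sim_sc) || !is.null(config$qc)) {
    sc_cfg <- defaults("sim_sc", list(n_cells = 2000L, n_genes = 500L,
                                      n_clusters = 4L))
    sc <- simulate_sc(n_cells = sc_cfg$n_cells, n_genes = sc_cfg$n_genes,
                      n_clusters = sc_cfg$n_clusters, seed = seed + 1L)
    qc_cfg_l <- defaults("qc", list(min_genes = 50L, mad_multiplier = 3,
                                    max_mito_frac = 0.10, min_ribo_frac = 0,
                                    min_cells_per_gene = 5L))
    cfg <- qc_config(min_genes = qc_cfg_l$min_genes,
                     mad_multiplier = qc_cfg_l$mad_multiplier,
                     max_mito_frac = qc_cfg_l$max_mito_frac,
                     min_ribo_frac = qc_cfg_l$min_ribo_frac,
                     min_cells_per_gene = qc_cfg_l$min_cells_per_gene)
    ds <- filter_genes(filter_cells(sc$ds, cfg), cfg)
    logx <- lognorm_counts(ds)
    gate <- gate_cd8(logx["CD8A", ])
    ds$cell_meta$cd8_pos <- gate$mask
    if (!is.null(calls) && any(calls$verdict)) {
      labels <- stats::setNames(rep("MANA", length(unique(calls$condition_id))),
                                unique(calls$condition_id))
      ds$cell_meta$antigen <- link_clonotypes(ds, calls, labels)
    }
    emit("sc_qc", "cell_metadata",
         cbind(barcode = colnames(ds$counts), ds$cell_meta))

    pb_cfg <- defaults("pseudobulk", list(n_perm = 1000L))
    pb <- make_pseudobulk(ds)
    emb <- concat_pca(pb)
    emit("pseudobulk", "pca_embedding",
         data.frame(sample = rownames(emb$embedding), emb$embedding))
    cov <- ds$cell_meta$group[match(rownames(emb$embedding), ds$cell_meta$sample)]
    cc <- cc_permutation_test(emb$embedding, cov, n_perm = pb_cfg$n_perm,
                              seed = seed + 2L)
    jsonlite::write_json(list(observed_cc = cc$observed_cc, p = cc$p_value,
                              n_perm = cc$n_perm, seed = cc$seed),
                         file.path(out_dir, "pseudobulk_cc_test.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$stages$pseudobulk <- union(manifest$stages$pseudobulk,
                                        "pseudobulk_cc_test.json")
  }

  # -- composition test ---------------------------------------------------
  if (!is.null(config$composition)) {
    co <- config$composition
    cc <- composition_counts(do.call(cbind, co$background_counts),
                             do.call(cbind, co$subset_counts))
    res <- monte_carlo_null(cc, n_sim = co$n_sim %||% 10000L, seed = seed + 3L)
    jsonlite::write_json(list(S = res$S_observed, p = res$p_value,
                              fisher_p = res$fisher_p, n_sim = res$n_sim,
                              seed = res$seed),
                         file.path(out_dir, "composition_test.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$stages$composition <- "composition_test.json"
  }

  # -- pseudotime ---------------------------------------------------------
  if (!is.null(config$sim_pseudotime) || !is.null(config$pseudotime)) {
    pt_sim <- defaults("sim_pseudotime", list(n_cells = 200L, n_samples = 2L,
                                              n_dynamic = 10L, n_flat = 40L))
    pt_cfg <- defaults("pseudotime", list(n_perm = 200L, k = 3L))
    sim <- simulate_pseudotime(n_cells = pt_sim$n_cells,
                               n_samples = pt_sim$n_samples,
                               n_dynamic = pt_sim$n_dynamic,
                               n_flat = pt_sim$n_flat, seed = seed + 4L)
    fit <- lr_permutation_test(sim$expr, sim$t, sim$samples,
                               n_perm = pt_cfg$n_perm, seed = seed + 5L)
    res <- fit$results
    if (sum(res$dynamic) >= pt_cfg$k) {
      cl <- cluster_patterns(fit$curves[res$dynamic, , drop = FALSE],
                             k = pt_cfg$k, seed = seed + 6L)
      res$pattern_cluster <- NA_integer_
      res$pattern_cluster[match(names(cl$cluster), res$gene)] <- cl$cluster
    }
    emit("pseudotime", "pseudotime_genes", res)
    emit("pseudotime", "pseudotime_curves",
         data.frame(gene = rownames(fit$curves), fit$curves))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# order-stable hash of the analysis configuration (md5 of its canonical
# serialization); out_dir is excluded so runs into different directories
# compare equal
config_hash <- function(config) {
  config$out_dir <- NULL
  canon <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                            null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}
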