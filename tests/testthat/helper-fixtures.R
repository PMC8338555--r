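# Small fixture builders used across test files.

toy_clonotype_table <- function(condition_id = "pep1",
                                cdr3 = c("CASSIRSSYEQYF", "CASSLGDEQYF", "CASSQETQYF"),
                                reads = c(100L, 50L, 10L),
                                well = "well1", productive = TRUE) {
  clonotype_table(condition_id, data.frame(
    well_id = well, cdr3_aa = cdr3, v_gene = "TRBV19", reads = reads,
    productive = productive, stringsAsFactors = FALSE))
}

# genes x cells log-normalized-style matrix with named genes
toy_expr <- function(n_genes = 60L, n_cells = 40L, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_genes * n_cells, 2), n_genes, n_cells,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("c", seq_len(n_cells))))
  m
}
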