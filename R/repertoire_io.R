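#' Clonotype table input, validation and preprocessing
#'
#' A `ClonotypeTable` holds the productive TCR-beta clonotype read counts of
#' one peptide-stimulated culture condition (or the no-peptide control),
#' organised by replicate well. It is the unit object of FEST expansion
#' testing: see [call_antigen_specific()].
#'
#' @name repertoire_io
NULL

#' Built-in column dialects for clonotype files
#'
#' Maps the canonical record fields (`cdr3_aa`, `v_gene`, `reads`,
#' `productive`, optional `well_id`) onto the header names a sequencing
#' provider uses. Two dialects ship with the package:
#' `"airr"` (AIRR-style rearrangement TSV: `junction_aa`, `v_call`,
#' `duplicate_count`, `productive`) and `"adaptive"` (Adaptive-style:
#' `aminoAcid`, `vGeneName`, `count (templates/reads)`, `sequenceStatus`
#' where productive rows carry the value `"In"`).
#'
#' @param dialect Either the name of a built-in dialect, or a named list /
#'   named character vector mapping canonical field names to file column
#'   names. Unmapped optional fields are looked up under their canonical
#'   name.
#' @return A named list with entries `cdr3_aa`, `v_gene`, `reads`,
#'   `productive`, `well_id` and `productive_true` (the value that marks a
#'   productive row; `NULL` means the column is logical / "true"-like).
#' @examples
#' clonotype_dialect("airr")
#' clonotype_dialect(list(cdr3_aa = "aminoAcid", reads = "templates"))
#' @export
clonotype_dialect <- function(dialect = "airr") {
  builtin <- list(
    airr = list(cdr3_aa = "junction_aa", v_gene = "v_call",
                reads = "duplicate_count", productive = "productive",
                well_id = "well_id", productive_true = NULL),
    adaptive = list(cdr3_aa = "aminoAcid", v_gene = "vGeneName",
                    reads = "count (templates/reads)",
                    productive = "sequenceStatus", well_id = "well_id",
                    productive_true = "In")
  )
  if (is.character(dialect) && length(dialect) == 1L && dialect %in% names(builtin))
    return(builtin[[dialect]])
  if (is.character(dialect))
    dialect <- as.list(dialect)
  if (!is.list(dialect))
    stop("`dialect` must be a built-in name or a named mapping", call. = FALSE)
  out <- builtin$airr
  out[] <- list(cdr3_aa = "cdr3_aa", v_gene = "v_gene", reads = "reads",
                productive = "productive", well_id = "well_id",
                productive_true = NULL)
  out[names(dialect)] <- dialect
  out
}

new_clonotype_table <- function(condition_id, records, well_ids = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("well_id", "cdr3_aa", "v_gene", "reads", "productive")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("records missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  records <- records[, needed]
  records$reads <- as.integer(records$reads)
  if (any(records$reads < 0, na.rm = TRUE))
    stop("negative read counts", call. = FALSE)
  if (is.null(well_ids)) well_ids <- unique(records$well_id)
  if (!all(records$well_id %in% well_ids))
    stop("record well_id outside declared well set", call. = FALSE)
  structure(
    list(condition_id = as.character(condition_id),
         well_ids = as.character(well_ids),
         records = records,
         total_productive_reads = sum(records$reads[records$productive %in% TRUE])),
    class = "ClonotypeTable")
}

#' Construct a clonotype table
#'
#' @param condition_id Condition label (peptide, peptide pool, or the
#'   no-peptide control).
#' @param records Data frame with columns `well_id`, `cdr3_aa`, `v_gene`,
#'   `reads`, `productive`.
#' @param well_ids Optional full set of replicate wells (a well may have no
#'   records); defaults to the wells seen in `records`.
#' @return A `ClonotypeTable`.
#' @export
clonotype_table <- function(condition_id, records, well_ids = NULL)
  new_clonotype_table(condition_id, records, well_ids)

#' @export
print.ClonotypeTable <- function(x, ...) {
  cat(sprintf("ClonotypeTable '%s': %d records, %d well(s), %d productive reads\n",
              x$condition_id, nrow(x$records), length(x$well_ids),
              x$total_productive_reads))
  invisible(x)
}

#' Read a tab-separated clonotype file
#'
#' Parses one condition's TCR-seq clonotype counts. Rows whose read count or
#' CDR3 fail to parse are dropped and counted in the `n_dropped` attribute.
#' When the file has no well column the whole condition is treated as a
#' single well `"well1"`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Column mapping; see [clonotype_dialect()].
#' @param condition_id Condition label; defaults to the file name without
#'   extension.
#' @return A `ClonotypeTable`; attribute `n_dropped` counts unparseable rows.
#' @export
read_clonotype_table <- function(path, dialect = "airr", condition_id = NULL) {
  map <- clonotype_dialect(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L && ncol(raw) == 0L)
    stop("empty clonotype file: ", path, call. = FALSE)
  need <- c("cdr3_aa", "reads")
  for (f in need)
    if (!map[[f]] %in% names(raw))
      stop(sprintf("required column '%s' (field %s) absent in %s",
                   map[[f]], f, path), call. = FALSE)
  get_col <- function(field, default) {
    col <- map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else default
  }
  cdr3 <- as.character(raw[[map$cdr3_aa]])
  reads <- suppressWarnings(as.integer(raw[[map$reads]]))
  vg <- as.character(get_col("v_gene", NA_character_))
  prod_raw <- get_col("productive", TRUE)
  productive <- if (!is.null(map$productive_true))
    prod_raw == map$productive_true
  else if (is.logical(prod_raw)) prod_raw
  else toupper(as.character(prod_raw)) %in% c("T", "TRUE", "1", "YES")
  well <- as.character(get_col("well_id", "well1"))

  ok <- !is.na(reads) & reads >= 0 & !is.na(cdr3) & nzchar(cdr3)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("read_clonotype_table: dropped %d unparseable row(s) from %s",
                    n_dropped, basename(path)))
  rec <- data.frame(well_id = well[ok], cdr3_aa = cdr3[ok], v_gene = vg[ok],
                    reads = reads[ok], productive = productive[ok],
                    stringsAsFactors = FALSE)
  if (is.null(condition_id))
    condition_id <- sub("\\.[^.]+$", "", basename(path))
  tab <- new_clonotype_table(condition_id, rec)
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Write a clonotype table to a tab-separated file
#'
#' Inverse of [read_clonotype_table()]; round trips bit-exactly under the
#' same dialect.
#'
#' @param table A `ClonotypeTable`.
#' @param path Output path.
#' @param dialect Column mapping; see [clonotype_dialect()].
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(table, path, dialect = "airr") {
  stopifnot(inherits(table, "ClonotypeTable"))
  map <- clonotype_dialect(dialect)
  rec <- table$records
  prod <- if (!is.null(map$productive_true))
    ifelse(rec$productive, map$productive_true, "Out") else rec$productive
  out <- data.frame(rec$cdr3_aa, rec$v_gene, rec$reads, prod, rec$well_id,
                    stringsAsFactors = FALSE)
  names(out) <- c(map$cdr3_aa, map$v_gene, map$reads, map$productive, map$well_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Preprocess CDR3 records
#'
#' Applies the standard FEST preprocessing rules: keep only productive
#' records whose (uppercased) CDR3 amino-acid sequence begins with C, ends
#' with F or W, and is at least 7 residues long; then aggregate duplicate
#' CDR3s within each well by summing reads. Idempotent.
#'
#' @param table A `ClonotypeTable`.
#' @return The filtered, aggregated `ClonotypeTable`.
#' @examples
#' rec <- data.frame(well_id = "w1", cdr3_aa = c("CASSLG", "CASSLGDEQYF"),
#'                   v_gene = NA, reads = c(5L, 10L), productive = TRUE)
#' preprocess_cdr3(clonotype_table("pep1", rec))
#' @export
preprocess_cdr3 <- function(table) {
  stopifnot(inherits(table, "ClonotypeTable"))
  rec <- table$records
  cdr3 <- toupper(rec$cdr3_aa)
  keep <- rec$productive %in% TRUE &
    nchar(cdr3) >= 7L &
    substr(cdr3, 1L, 1L) == "C" &
    substr(cdr3, nchar(cdr3), nchar(cdr3)) %in% c("F", "W")
  rec <- rec[keep, , drop = FALSE]
  rec$cdr3_aa <- cdr3[keep]
  if (nrow(rec)) {
    key <- paste(rec$well_id, rec$cdr3_aa, sep = "\r")
    agg_reads <- rowsum(rec$reads, key)
    first <- rec[!duplicated(key), , drop = FALSE]
    first <- first[match(rownames(agg_reads), paste(first$well_id, first$cdr3_aa, sep = "\r")), ]
    first$reads <- as.integer(agg_reads[, 1L])
    rec <- first[order(first$well_id, first$cdr3_aa), , drop = FALSE]
    rownames(rec) <- NULL
  }
  new_clonotype_table(table$condition_id, rec, table$well_ids)
}

#' Exclude low-depth clonotype tables
#'
#' Tables with fewer than `min_reads` total productive reads are moved to
#' the excluded set (the standard exclusion depth is 1,000 productive
#' reads); each exclusion is reported by condition.
#'
#' @param tables List of preprocessed `ClonotypeTable`s.
#' @param min_reads Minimum productive-read depth; exclusion is strict
#'   (`< min_reads`).
#' @return List with elements `kept` and `excluded`.
#' @export
exclude_low_depth <- function(tables, min_reads = 1000L) {
  stopifnot(is.list(tables))
  depths <- vapply(tables, function(t) t$total_productive_reads, numeric(1))
  low <- depths < min_reads
  for (t in tables[low])
    message(sprintf("exclude_low_depth: condition '%s' excluded (%d < %d productive reads)",
                    t$condition_id, t$total_productive_reads, as.integer(min_reads)))
  list(kept = tables[!low], excluded = tables[low])
}

# condition-level read counts: named vector cdr3 -> reads summed over wells
condition_counts <- function(table) {
  rec <- table$records[table$records$productive %in% TRUE, , drop = FALSE]
  if (!nrow(rec)) return(integer(0))
  s <- rowsum(rec$reads, rec$cdr3_aa)
  stats::setNames(as.integer(s[, 1L]), rownames(s))
}
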