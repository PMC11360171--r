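#' Construct a signature matrix
#'
#' A `signature_matrix` holds the differential-expression z-score profiles of
#' a set of chemical treatments in one cell line, together with the
#' transcriptional activity score (TAS) of each profile and the tier of each
#' gene. Genes belong to one of three tiers mirroring the L1000 design:
#' `"landmark"` (directly measured), `"best_inferred"` (imputed with
#' gene-level recall > 0.95) and `"inferred"` (imputed with lower recall).
#'
#' @param values numeric matrix, one row per profile, one column per gene.
#'   Column names must match `genes$gene_id`.
#' @param chemical_id character vector, one id per row of `values`. A chemical
#'   may own several profiles (duplicates) until deduplication.
#' @param cell_line single string naming the cell line (e.g. `"MCF7"`).
#' @param tas numeric vector of transcriptional activity scores per profile;
#'   `NA` allowed until deduplication is attempted.
#' @param genes data.frame with columns `gene_id`, `tier`.
#'
#' @return An object of class `signature_matrix`.
#' @seealso [filter_gene_tier()], [dedupe_profiles_by_tas()]
#' @export
signature_matrix <- function(values, chemical_id, cell_line, tas, genes) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values))
  if (length(chemical_id) != nrow(values))
    stop("one chemical_id per profile row is required", call. = FALSE)
  if (length(tas) != nrow(values))
    stop("one TAS per profile row is required", call. = FALSE)
  if (!is.character(cell_line) || length(cell_line) != 1L)
    stop("cell_line must be a single string", call. = FALSE)
  genes <- as.data.frame(genes)
  if (!all(c("gene_id", "tier") %in% names(genes)))
    stop("genes must have columns gene_id and tier", call. = FALSE)
  bad <- setdiff(unique(genes$tier), c("landmark", "best_inferred", "inferred"))
  if (length(bad))
    stop("unknown gene tier(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (ncol(values) != nrow(genes) ||
      !identical(colnames(values), as.character(genes$gene_id)))
    stop("columns of values must match genes$gene_id in order", call. = FALSE)
  if (any(!is.finite(values)))
    stop("z-scores must be finite", call. = FALSE)
  structure(
    list(values = values,
         chemical_id = as.character(chemical_id),
         cell_line = cell_line,
         tas = as.numeric(tas),
         genes = genes),
    class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  tiers <- table(x$genes$tier)
  cat(sprintf(
    "<signature_matrix> %s: %d profiles (%d chemicals) x %d genes [%s]\n",
    x$cell_line, nrow(x$values), length(unique(x$chemical_id)),
    ncol(x$values),
    paste(sprintf("%s:%d", names(tiers), tiers), collapse = ", ")))
  invisible(x)
}

#' @export
dim.signature_matrix <- function(x) dim(x$values)

#' Number of distinct chemicals in a signature matrix
#' @param x a `signature_matrix`.
#' @return integer count of distinct chemical ids.
#' @export
n_chemicals <- function(x) length(unique(x$chemical_id))

# Subset profiles (rows) of a signature matrix, keeping metadata aligned.
subset_profiles <- function(x, idx) {
  signature_matrix(x$values[idx, , drop = FALSE], x$chemical_id[idx],
                   x$cell_line, x$tas[idx], x$genes)
}

# Tier prefix used in the on-disk column naming: L:/B:/I:
tier_prefix <- c(landmark = "L", best_inferred = "B", inferred = "I")

#' Write a signature matrix as TSV
#'
#' One row per profile: `chemical_id`, `cell_line`, `tas`, then one column per
#' gene named `<tier prefix>:<gene_id>` with prefixes `L` (landmark),
#' `B` (best inferred) and `I` (inferred).
#'
#' @param x a `signature_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(x, path) {
  cols <- paste0(tier_prefix[x$genes$tier], ":", x$genes$gene_id)
  dt <- data.table::data.table(
    chemical_id = x$chemical_id, cell_line = x$cell_line, tas = x$tas)
  vals <- data.table::as.data.table(x$values)
  data.table::setnames(vals, cols)
  data.table::fwrite(cbind(dt, vals), path, sep = "\t")
  invisible(path)
}

#' Read a signature matrix written by [write_signature_matrix()]
#'
#' @param path TSV file path.
#' @return A `signature_matrix`.
#' @export
read_signature_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  meta <- c("chemical_id", "cell_line", "tas")
  if (!all(meta %in% names(dt)))
    stop("not a signature matrix file: ", path, call. = FALSE)
  gene_cols <- setdiff(names(dt), meta)
  pref <- substr(gene_cols, 1, 1)
  tier <- names(tier_prefix)[match(pref, tier_prefix)]
  if (anyNA(tier))
    stop("gene columns must be prefixed L:, B: or I:", call. = FALSE)
  ids <- substring(gene_cols, 3)
  values <- as.matrix(dt[, gene_cols, with = FALSE])
  colnames(values) <- ids
  signature_matrix(values, dt$chemical_id, unique(dt$cell_line)[1], dt$tas,
                   data.frame(gene_id = ids, tier = tier))
}

#' Write / read an activity table as TSV
#'
#' Columns: `chemical_id`, `endpoint`, `label`, `n_sources`.
#'
#' @param x data.frame with those columns.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_activity_table <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t")
  invisible(path)
}

#' @rdname write_activity_table
#' @export
read_activity_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
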