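#' Resolve duplicate activity records
#'
#' Collapses raw activity records to exactly one record per
#' (chemical, endpoint). When duplicate records contradict each other, the
#' chemical is considered active — activity reported by any source wins over
#' inactivity. `n_sources` counts the raw records behind each resolved
#' record, the literature-evidence count used for confidence filtering.
#'
#' @param raw_records data.frame with columns `chemical_id`, `endpoint`,
#'   `label` (`"active"` / `"inactive"`); extra columns are ignored.
#' @return data.frame `chemical_id`, `endpoint`, `label`, `n_sources`, one
#'   row per (chemical, endpoint), in first-appearance order.
#' @examples
#' raw <- data.frame(chemical_id = c("c1", "c1"), endpoint = "ER",
#'                   label = c("active", "inactive"))
#' resolve_activity_conflicts(raw)  # c1 resolves to active, n_sources = 2
#' @export
resolve_activity_conflicts <- function(raw_records) {
  raw <- as.data.frame(raw_records)
  need <- c("chemical_id", "endpoint", "label")
  if (!all(need %in% names(raw)))
    stop("activity records need columns chemical_id, endpoint, label",
         call. = FALSE)
  bad <- setdiff(unique(raw$label), c("active", "inactive"))
  if (length(bad))
    stop("invalid activity label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  # records that are themselves resolved carry an n_sources count; summing it
  # makes resolution idempotent
  raw$n_raw_sources <- if ("n_sources" %in% names(raw)) raw$n_sources else 1L
  dt <- data.table::as.data.table(raw[, c(need, "n_raw_sources")])
  res <- dt[, list(
    label = if (any(label == "active")) "active" else "inactive",
    n_sources = sum(n_raw_sources)), by = c("chemical_id", "endpoint")]
  as.data.frame(res)
}

#' Keep one profile per chemical by maximal TAS
#'
#' When a chemical owns several expression profiles, the profile with the
#' highest transcriptional activity score (TAS) is retained. Ties are broken
#' by input order (first profile wins), making the rule deterministic.
#'
#' @param matrix a [signature_matrix()], possibly with several profiles per
#'   chemical.
#' @return A `signature_matrix` with exactly one profile per chemical, in
#'   first-appearance chemical order.
#' @export
dedupe_profiles_by_tas <- function(matrix) {
  x <- matrix
  dup_chems <- unique(x$chemical_id[duplicated(x$chemical_id)])
  if (length(dup_chems) &&
      anyNA(x$tas[x$chemical_id %in% dup_chems]))
    stop("missing TAS on a duplicated chemical", call. = FALSE)
  keep <- vapply(unique(x$chemical_id), function(id) {
    idx <- which(x$chemical_id == id)
    idx[which.max(x$tas[idx])]  # which.max takes the first maximum: tie rule
  }, integer(1))
  subset_profiles(x, unname(keep))
}

#' Restrict a signature matrix to gene tiers
#'
#' The L1000-style catalog carries directly measured landmark genes and two
#' tiers of statistically imputed genes; lower-recall inferred genes are
#' typically removed before modelling. Column order is preserved.
#'
#' @param matrix a [signature_matrix()].
#' @param keep non-empty subset of
#'   `c("landmark", "best_inferred", "inferred")`.
#' @return A `signature_matrix` restricted to the requested tiers.
#' @export
filter_gene_tier <- function(matrix, keep) {
  if (length(keep) == 0)
    stop("configuration error: keep must name at least one tier",
         call. = FALSE)
  bad <- setdiff(keep, c("landmark", "best_inferred", "inferred"))
  if (length(bad))
    stop("unknown tier(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cols <- which(matrix$genes$tier %in% keep)
  signature_matrix(matrix$values[, cols, drop = FALSE], matrix$chemical_id,
                   matrix$cell_line, matrix$tas,
                   matrix$genes[cols, , drop = FALSE])
}

#' Split chemicals into per-cell-line training sets and a shared validation set
#'
#' The validation set is a simple random sample of the chemicals present in
#' every cell line, so the same held-out chemicals score each cell-line model
#' and the consensus. Each cell line's training set is its remaining
#' chemicals; chemicals lacking a profile in a cell line are simply absent
#' from that cell line's sets.
#'
#' @param matrices named list of deduplicated [signature_matrix()] objects,
#'   one per cell line.
#' @param activity resolved activity table (one record per chemical).
#' @param n_validation number of validation chemicals to draw from the
#'   cell-line intersection.
#' @param seed integer seed for the random draw.
#' @return A `split_assignment` list: `validation` (chemical ids),
#'   `training` (named list of chemical-id vectors per cell line), `seed`.
#' @examples
#' # an ER-like pair of cohorts with 1552- and 1262-chemical cell lines and
#' # 1259 common chemicals yields training sizes 1261 and 971 at
#' # n_validation = 291
#' @export
make_split <- function(matrices, activity, n_validation, seed = 1L) {
  chem_sets <- lapply(matrices, function(m) unique(m$chemical_id))
  common <- Reduce(intersect, chem_sets)
  if (n_validation > length(common))
    stop("n_validation exceeds the ", length(common),
         " chemicals common to all cell lines", call. = FALSE)
  validation <- if (n_validation > 0)
    with_seed(seed, sort(sample(common, n_validation))) else character()
  training <- lapply(chem_sets, function(ids) setdiff(ids, validation))
  structure(list(validation = validation, training = training,
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> validation: %d chemicals; training: %s\n",
              length(x$validation),
              paste(sprintf("%s=%d", names(x$training),
                            lengths(x$training)), collapse = ", ")))
  invisible(x)
}

#' Write a split assignment as TSV
#'
#' Columns: `chemical_id`, `cell_line` (`"*"` for the shared validation
#' rows), `role` (`train` / `validation`).
#'
#' @param split a `split_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  rows <- rbind(
    data.frame(chemical_id = split$validation, cell_line = "*",
               role = "validation"),
    do.call(rbind, lapply(names(split$training), function(cl)
      if (length(split$training[[cl]]))
        data.frame(chemical_id = split$training[[cl]], cell_line = cl,
                   role = "train"))))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}

#' Assemble a modelling dataset for one cell line
#'
#' Joins a deduplicated signature matrix with resolved activity labels and a
#' split, returning ready-to-model feature matrices and 0/1 label vectors
#' (1 = active).
#'
#' @param matrix deduplicated [signature_matrix()].
#' @param activity resolved activity table for one endpoint.
#' @param split a `split_assignment` from [make_split()].
#' @return list with `x_train`, `y_train`, `x_valid`, `y_valid`,
#'   `chemical_train`, `chemical_valid`, `cell_line`, `genes`.
#' @export
assemble_dataset <- function(matrix, activity, split) {
  lab <- setNames(as.integer(activity$label == "active"),
                  activity$chemical_id)
  take <- function(ids) {
    ids <- ids[ids %in% matrix$chemical_id & ids %in% names(lab)]
    idx <- match(ids, matrix$chemical_id)
    list(x = matrix$values[idx, , drop = FALSE], y = unname(lab[ids]),
         ids = ids)
  }
  tr <- take(split$training[[matrix$cell_line]])
  va <- take(split$validation)
  list(x_train = tr$x, y_train = tr$y, chemical_train = tr$ids,
       x_valid = va$x, y_valid = va$y, chemical_valid = va$ids,
       cell_line = matrix$cell_line, genes = matrix$genes)
}
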