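# Run code with a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic signature generator
#'
#' Defines the conditions a generated cohort emulates: an L1000-like gene
#' catalog (landmark / best-inferred / inferred tiers), z-score-distributed
#' expression features, a subset of informative genes whose expression is
#' shifted in active chemicals, cell-line-specific expression offsets, class
#' imbalance, and optional duplicate profiles / conflicting activity records.
#'
#' Defaults: the active prevalence 484/1552 matches the ER-binding MCF7
#' cohort composition; the effect shift (2 z-score units), the cell-line
#' offset spread (0.5) and the number of informative genes (20) are the
#' package's chosen study conditions, since no effect-size statistics of real
#' L1000 signatures are published (see the methods vignette).
#'
#' @param n_chemicals number of chemicals in the cohort.
#' @param n_landmark,n_best_inferred,n_inferred genes per tier. The full
#'   L1000-like catalog would be 978 / 9196 / 2154; defaults are a
#'   landmark-only catalog.
#' @param n_informative number of informative (label-associated) genes,
#'   planted in the landmark tier first, then the best-inferred tier.
#' @param effect_shift mean z-score shift of informative genes in active
#'   chemicals.
#' @param prevalence fraction of active chemicals, in (0, 1).
#' @param cell_line_offset_sd SD (z-score units) of the additive
#'   per-(gene, cell line) offset modelling cell-line divergence.
#' @param inferred_noise_factor multiplier on the noise SD of inferred-tier
#'   genes (> 1 makes landmark-only models outperform all-gene models).
#' @param duplicate_profile_rate fraction of chemicals given a second,
#'   perturbed profile with a different TAS.
#' @param conflict_label_rate fraction of chemicals given a second activity
#'   record with the opposite label.
#' @param cell_lines character vector of cell-line names (the protocol uses
#'   two).
#' @param endpoint endpoint name attached to activity records
#'   (`"ER"`, `"AR"` or `"TR"`).
#' @param seed integer seed; the whole cohort is reproducible from it.
#'
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_chemicals = 300,
                         n_landmark = 978,
                         n_best_inferred = 0,
                         n_inferred = 0,
                         n_informative = 20,
                         effect_shift = 2,
                         prevalence = 484 / 1552,
                         cell_line_offset_sd = 0.5,
                         inferred_noise_factor = 2,
                         duplicate_profile_rate = 0,
                         conflict_label_rate = 0,
                         cell_lines = c("MCF7", "A549"),
                         endpoint = "ER",
                         seed = 1L) {
  cfg <- list(n_chemicals = n_chemicals, n_landmark = n_landmark,
              n_best_inferred = n_best_inferred, n_inferred = n_inferred,
              n_informative = n_informative, effect_shift = effect_shift,
              prevalence = prevalence,
              cell_line_offset_sd = cell_line_offset_sd,
              inferred_noise_factor = inferred_noise_factor,
              duplicate_profile_rate = duplicate_profile_rate,
              conflict_label_rate = conflict_label_rate,
              cell_lines = cell_lines, endpoint = endpoint,
              seed = as.integer(seed))
  counts <- c("n_chemicals", "n_landmark", "n_best_inferred", "n_inferred",
              "n_informative")
  for (f in counts)
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop("configuration error: ", f, " must be a non-negative count",
           call. = FALSE)
  if (cfg$n_informative > cfg$n_landmark + cfg$n_best_inferred)
    stop("configuration error: n_informative exceeds landmark + ",
         "best-inferred catalog", call. = FALSE)
  if (!is.finite(cfg$prevalence) || cfg$prevalence <= 0 || cfg$prevalence >= 1)
    stop("configuration error: prevalence must lie in (0, 1)", call. = FALSE)
  for (f in c("duplicate_profile_rate", "conflict_label_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: ", f, " must lie in [0, 1]", call. = FALSE)
  if (cfg$cell_line_offset_sd < 0 || cfg$effect_shift < 0)
    stop("configuration error: effect_shift and cell_line_offset_sd must be ",
         ">= 0", call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

# Gene catalog in column order: landmark, best_inferred, inferred.
make_gene_catalog <- function(cfg) {
  total <- cfg$n_landmark + cfg$n_best_inferred + cfg$n_inferred
  ids <- sprintf("G%0*d", max(4L, nchar(total)), seq_len(total))
  data.frame(
    gene_id = ids,
    tier = rep(c("landmark", "best_inferred", "inferred"),
               c(cfg$n_landmark, cfg$n_best_inferred, cfg$n_inferred)))
}

#' Generate a synthetic two-cell-line cohort
#'
#' Draws a cohort of chemicals with binary activity labels at the configured
#' prevalence and, for each cell line, a signature matrix of z-score features:
#' background features are standard normal, inferred-tier features get
#' `inferred_noise_factor` times the noise SD, every (gene, cell line) pair
#' receives a fixed offset drawn `Normal(0, cell_line_offset_sd)` (cell-line
#' divergence), and the informative genes of active chemicals are shifted by
#' `effect_shift`. Labels and chemical ids are shared across cell lines.
#' The returned ground truth enables parameter-recovery tests downstream.
#'
#' @param config a [synth_config()].
#' @return A list with elements
#'   `signatures` (named list of [signature_matrix()] per cell line),
#'   `activity` (raw activity records: `chemical_id`, `endpoint`, `label`,
#'   `provenance`), and
#'   `truth` (list: `informative_gene_ids`, `true_labels` named 0/1 vector,
#'   `offsets` per cell line, `config`).
#' @examples
#' cohort <- generate_cohort(synth_config(n_chemicals = 50, n_landmark = 30,
#'                                        n_informative = 5, seed = 1))
#' cohort$signatures$MCF7
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  cfg <- config
  genes <- make_gene_catalog(cfg)
  n <- cfg$n_chemicals
  chem_ids <- sprintf("C%0*d", max(4L, nchar(n)), seq_len(n))
  with_seed(cfg$seed, {
    labels <- rbinom(n, 1L, cfg$prevalence)
    pool <- genes$gene_id[genes$tier %in% c("landmark", "best_inferred")]
    # landmark-first ordering of the pool makes informative genes landmark
    # unless the landmark tier is exhausted
    informative <- if (cfg$n_informative > 0)
      sort(sample(pool[seq_len(min(length(pool), max(cfg$n_landmark,
                                                     cfg$n_informative)))],
                  cfg$n_informative)) else character()
    noise_sd <- ifelse(genes$tier == "inferred", cfg$inferred_noise_factor, 1)
    signatures <- list()
    offsets <- list()
    for (cl in cfg$cell_lines) {
      off <- rnorm(nrow(genes), 0, cfg$cell_line_offset_sd)
      names(off) <- genes$gene_id
      vals <- matrix(rnorm(n * nrow(genes)), nrow = n) *
        rep(noise_sd, each = n)
      vals <- sweep(vals, 2L, off, "+")
      colnames(vals) <- genes$gene_id
      if (length(informative) && any(labels == 1L))
        vals[labels == 1L, informative] <-
          vals[labels == 1L, informative] + cfg$effect_shift
      tas <- runif(n)
      signatures[[cl]] <- signature_matrix(vals, chem_ids, cl, tas, genes)
      offsets[[cl]] <- off
    }
    activity <- data.frame(
      chemical_id = chem_ids,
      endpoint = cfg$endpoint,
      label = ifelse(labels == 1L, "active", "inactive"),
      provenance = "simulated")
    truth <- list(informative_gene_ids = informative,
                  true_labels = setNames(labels, chem_ids),
                  offsets = offsets, config = cfg)
    list(signatures = signatures, activity = activity, truth = truth)
  })
}

#' Inject duplicate profiles and conflicting activity records
#'
#' Creates the situations the assembly stage has to resolve: a fraction of
#' chemicals gains a second signature profile (z-scores perturbed, distinct
#' TAS) and a fraction gains a second activity record carrying the opposite
#' label, flagged `provenance = "conflict"`. With both rates zero the inputs
#' are returned unchanged.
#'
#' @param matrix a [signature_matrix()].
#' @param activity raw activity records (as from [generate_cohort()]).
#' @param config the [synth_config()] holding `duplicate_profile_rate`,
#'   `conflict_label_rate` and `seed`.
#' @return `list(matrix =, activity =)` with duplicates injected.
#' @export
inject_duplicates <- function(matrix, activity, config) {
  cfg <- config
  for (f in c("duplicate_profile_rate", "conflict_label_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: ", f, " must lie in [0, 1]", call. = FALSE)
  if (cfg$duplicate_profile_rate == 0 && cfg$conflict_label_rate == 0)
    return(list(matrix = matrix, activity = activity))
  with_seed(cfg$seed + 104729L, {
    chems <- unique(matrix$chemical_id)
    n_dup <- round(cfg$duplicate_profile_rate * length(chems))
    if (n_dup > 0) {
      dup_ids <- sample(chems, n_dup)
      idx <- match(dup_ids, matrix$chemical_id)
      vals <- matrix$values[idx, , drop = FALSE] +
        rnorm(length(idx) * ncol(matrix$values), 0, 0.1)
      tas <- runif(length(idx))
      same <- tas == matrix$tas[idx]
      tas[same] <- 1 - tas[same]  # TAS of a duplicate must differ
      matrix <- signature_matrix(
        rbind(matrix$values, vals),
        c(matrix$chemical_id, dup_ids),
        matrix$cell_line, c(matrix$tas, tas), matrix$genes)
    }
    n_conf <- round(cfg$conflict_label_rate * length(chems))
    if (n_conf > 0) {
      conf_ids <- sample(chems, n_conf)
      orig <- activity[match(conf_ids, activity$chemical_id), , drop = FALSE]
      flipped <- orig
      flipped$label <- ifelse(orig$label == "active", "inactive", "active")
      flipped$provenance <- "conflict"
      activity <- rbind(activity, flipped)
      rownames(activity) <- NULL
    }
    list(matrix = matrix, activity = activity)
  })
}

#' Write a generated cohort to a directory
#'
#' Writes `signatures_<cell line>.tsv` per cell line (see
#' [write_signature_matrix()]), `activity.tsv` and
#' `informative_genes.txt`.
#'
#' @param cohort as returned by [generate_cohort()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(cohort$signatures))
    write_signature_matrix(cohort$signatures[[cl]],
                           file.path(dir, paste0("signatures_", cl, ".tsv")))
  data.table::fwrite(cohort$activity, file.path(dir, "activity.tsv"),
                     sep = "\t")
  writeLines(cohort$truth$informative_gene_ids,
             file.path(dir, "informative_genes.txt"))
  invisible(dir)
}
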