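test_that("generated cohorts honour the configured shape and label prevalence", {
  cfg <- synth_config(n_chemicals = 200, n_landmark = 100, n_informative = 10,
                      effect_shift = 2, prevalence = 0.3, seed = 7)
  co <- generate_cohort(cfg)
  expect_named(co$signatures, c("MCF7", "A549"))
  for (sm in co$signatures) {
    expect_s3_class(sm, "signature_matrix")
    expect_equal(dim(sm), c(200L, 100L))
  }
  expect_identical(co$signatures$MCF7$chemical_id,
                   co$signatures$A549$chemical_id)
  n_active <- sum(co$activity$label == "active")
  expect_lt(abs(n_active - 200 * 0.3), 3 * sqrt(200 * 0.3 * 0.7))
  expect_length(co$truth$informative_gene_ids, 10)
  expect_true(all(co$truth$informative_gene_ids %in%
                    co$signatures$MCF7$genes$gene_id))
})

test_that("the default prevalence reproduces the ER-cohort class balance", {
  # 484 actives of 1552 chemicals ~ 0.312
  cfg <- synth_config(n_chemicals = 1552, n_landmark = 20, n_informative = 0,
                      seed = 11)
  co <- generate_cohort(cfg)
  n_active <- sum(co$activity$label == "active")
  p <- 484 / 1552
  expect_lt(abs(n_active - 1552 * p), 3 * sqrt(1552 * p * (1 - p)))
})

test_that("cohorts are bit-identical under one seed and differ across seeds", {
  cfg <- synth_config(n_chemicals = 40, n_landmark = 15, n_informative = 3,
                      seed = 5)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- synth_config(n_chemicals = 40, n_landmark = 15, n_informative = 3,
                       seed = 6)
  expect_false(identical(generate_cohort(cfg)$signatures$MCF7$values,
                         generate_cohort(cfg2)$signatures$MCF7$values))
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(n_chemicals = -1), "non-negative")
  expect_error(synth_config(prevalence = 0), "prevalence")
  expect_error(synth_config(prevalence = 1.2), "prevalence")
  expect_error(synth_config(n_landmark = 5, n_best_inferred = 0,
                            n_informative = 10), "exceeds")
  expect_error(synth_config(duplicate_profile_rate = 1.5), "\\[0, 1\\]")
})

test_that("informative genes land in the landmark tier and carry the shift", {
  cfg <- synth_config(n_chemicals = 400, n_landmark = 30, n_best_inferred = 10,
                      n_inferred = 10, n_informative = 5, effect_shift = 2,
                      cell_line_offset_sd = 0, seed = 9)
  co <- generate_cohort(cfg)
  genes <- co$signatures$MCF7$genes
  tiers <- genes$tier[match(co$truth$informative_gene_ids, genes$gene_id)]
  expect_true(all(tiers == "landmark"))
  act <- co$truth$true_labels == 1
  vals <- co$signatures$MCF7$values
  gap <- mean(vals[act, co$truth$informative_gene_ids]) -
    mean(vals[!act, co$truth$informative_gene_ids])
  expect_lt(abs(gap - 2), 0.3)
  # inferred-tier genes carry inflated noise
  inf_ids <- genes$gene_id[genes$tier == "inferred"]
  lm_ids <- setdiff(genes$gene_id[genes$tier == "landmark"],
                    co$truth$informative_gene_ids)
  expect_gt(mean(apply(vals[, inf_ids], 2, sd)),
            1.5 * mean(apply(vals[, lm_ids], 2, sd)))
})

test_that("duplicate injection adds second profiles and conflicting labels", {
  cfg <- synth_config(n_chemicals = 200, n_landmark = 10,
                      n_informative = 0, duplicate_profile_rate = 0.1,
                      conflict_label_rate = 0.05, seed = 21)
  co <- generate_cohort(cfg)
  inj <- inject_duplicates(co$signatures$MCF7, co$activity, cfg)
  dup <- table(inj$matrix$chemical_id)
  expect_equal(sum(dup == 2), 20)
  for (id in names(dup[dup == 2])) {
    tas <- inj$matrix$tas[inj$matrix$chemical_id == id]
    expect_false(tas[1] == tas[2])
  }
  conflicted <- inj$activity$chemical_id[inj$activity$provenance == "conflict"]
  expect_length(conflicted, 10)
  # after assembly every conflicted chemical is labelled active
  resolved <- resolve_activity_conflicts(inj$activity)
  expect_true(all(resolved$label[resolved$chemical_id %in% conflicted] ==
                    "active"))
})

test_that("zero injection rates leave the cohort untouched", {
  cfg <- synth_config(n_chemicals = 30, n_landmark = 8, n_informative = 0,
                      seed = 2)
  co <- generate_cohort(cfg)
  inj <- inject_duplicates(co$signatures$MCF7, co$activity, cfg)
  expect_identical(inj$matrix, co$signatures$MCF7)
  expect_identical(inj$activity, co$activity)
})

test_that("signature matrices and cohorts round-trip through TSV", {
  cfg <- synth_config(n_chemicals = 12, n_landmark = 4, n_best_inferred = 3,
                      n_inferred = 2, n_informative = 2, seed = 4)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_signature_matrix(file.path(dir, "signatures_MCF7.tsv"))
  orig <- co$signatures$MCF7
  expect_equal(back$values, orig$values, tolerance = 1e-12)
  expect_identical(back$chemical_id, orig$chemical_id)
  expect_identical(back$genes$tier, orig$genes$tier)
  act <- read_activity_table(file.path(dir, "activity.tsv"))
  expect_identical(act$label, co$activity$label)
})
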