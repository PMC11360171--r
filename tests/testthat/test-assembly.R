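toy_matrix <- function(ids, tas, cell_line = "MCF7", p = 3) {
  genes <- data.frame(gene_id = sprintf("G%04d", 1:p), tier = "landmark")
  vals <- matrix(seq_along(ids) + rep(seq_len(p), each = length(ids)),
                 nrow = length(ids), dimnames = list(NULL, genes$gene_id))
  signature_matrix(vals, ids, cell_line, tas, genes)
}

test_that("contradicting activity records resolve to active", {
  raw <- data.frame(
    chemical_id = c("c1", "c1", "c2", "c3", "c3"),
    endpoint = c("ER", "ER", "AR", "TR", "TR"),
    label = c("active", "inactive", "inactive", "inactive", "inactive"))
  res <- resolve_activity_conflicts(raw)
  expect_equal(nrow(res), 3)
  expect_equal(res$label[res$chemical_id == "c1"], "active")
  expect_equal(res$label[res$chemical_id == "c2"], "inactive")
  expect_equal(res$label[res$chemical_id == "c3"], "inactive")
  expect_equal(res$n_sources[res$chemical_id == "c3"], 2L)
  expect_error(resolve_activity_conflicts(
    data.frame(chemical_id = "x", endpoint = "ER", label = "maybe")),
    "invalid activity label")
})

test_that("profile deduplication keeps the highest-TAS profile, first on ties", {
  m <- toy_matrix(c("c1", "c2", "c1"), tas = c(0.2, 0.5, 0.9))
  d <- dedupe_profiles_by_tas(m)
  expect_equal(d$chemical_id, c("c1", "c2"))
  expect_equal(d$tas, c(0.9, 0.5))
  expect_equal(d$values["c1" == d$chemical_id, ],
               m$values[3, ])
  # tie: first input profile retained
  tie <- toy_matrix(c("c1", "c1"), tas = c(0.5, 0.5))
  dt <- dedupe_profiles_by_tas(tie)
  expect_equal(dt$values[1, ], tie$values[1, ])
  # no duplicates: identity
  single <- toy_matrix(c("a", "b"), tas = c(0.1, 0.2))
  expect_identical(dedupe_profiles_by_tas(single)$values, single$values)
  # missing TAS on a duplicated chemical
  bad <- toy_matrix(c("c1", "c1"), tas = c(NA, 0.3))
  expect_error(dedupe_profiles_by_tas(bad), "missing TAS")
})

test_that("deduplication and conflict resolution are idempotent", {
  cfg <- synth_config(n_chemicals = 50, n_landmark = 6, n_informative = 0,
                      duplicate_profile_rate = 0.2, conflict_label_rate = 0.1,
                      seed = 13)
  co <- generate_cohort(cfg)
  inj <- inject_duplicates(co$signatures$MCF7, co$activity, cfg)
  once <- dedupe_profiles_by_tas(inj$matrix)
  expect_identical(dedupe_profiles_by_tas(once), once)
  res <- resolve_activity_conflicts(inj$activity)
  expect_identical(resolve_activity_conflicts(res), res)
})

test_that("gene-tier filtering restricts columns and preserves order", {
  genes <- data.frame(
    gene_id = sprintf("G%04d", 1:10),
    tier = rep(c("landmark", "best_inferred", "inferred"), c(4, 3, 3)))
  vals <- matrix(rnorm(20), 2, 10, dimnames = list(NULL, genes$gene_id))
  m <- signature_matrix(vals, c("a", "b"), "MCF7", c(0.1, 0.2), genes)
  lm <- filter_gene_tier(m, "landmark")
  expect_equal(ncol(lm$values), 4)
  both <- filter_gene_tier(m, c("landmark", "best_inferred"))
  expect_equal(ncol(both$values), 7)
  expect_identical(both$genes$gene_id, genes$gene_id[1:7])
  all3 <- filter_gene_tier(m, c("landmark", "best_inferred", "inferred"))
  expect_identical(all3$values, m$values)
  expect_error(filter_gene_tier(m, character()), "at least one tier")
  expect_error(filter_gene_tier(m, "bogus"), "unknown tier")
})

test_that("the shared validation split reproduces the published ER training sizes", {
  # cell lines of 1552 and 1262 chemicals sharing 1259; 291 validation
  # chemicals leave training sets of 1261 and 971
  ids1 <- sprintf("c%04d", 1:1552)
  ids2 <- sprintf("c%04d", c(1:1259, 2001:2003))
  m1 <- toy_matrix(ids1, tas = runif(1552), cell_line = "MCF7", p = 1)
  m2 <- toy_matrix(ids2, tas = runif(1262), cell_line = "A549", p = 1)
  act <- data.frame(chemical_id = union(ids1, ids2), endpoint = "ER",
                    label = "inactive", n_sources = 1L)
  sp <- make_split(list(MCF7 = m1, A549 = m2), act, 291, seed = 3)
  expect_length(sp$validation, 291)
  expect_true(all(sp$validation %in% intersect(ids1, ids2)))
  expect_length(sp$training$MCF7, 1261)
  expect_length(sp$training$A549, 971)
  # disjointness and round-trip counts per cell line
  expect_length(intersect(sp$validation, sp$training$MCF7), 0)
  expect_length(intersect(sp$validation, sp$training$A549), 0)
  expect_equal(length(sp$training$MCF7) + length(sp$validation), 1552)
  expect_equal(length(sp$training$A549) + length(sp$validation), 1262)
  expect_error(make_split(list(MCF7 = m1, A549 = m2), act, 1300), "exceeds")
  empty <- make_split(list(MCF7 = m1, A549 = m2), act, 0)
  expect_length(empty$validation, 0)
  expect_length(empty$training$MCF7, 1552)
})

test_that("assembled datasets align features and labels per split role", {
  fx <- assembled_cohort(n = 60, p = 10, n_validation = 15, seed = 19)
  for (ds in fx$datasets) {
    expect_equal(nrow(ds$x_train), length(ds$y_train))
    expect_equal(nrow(ds$x_valid), 15)
    expect_length(intersect(ds$chemical_train, ds$chemical_valid), 0)
    truth <- fx$truth$true_labels[ds$chemical_train]
    expect_equal(unname(truth), ds$y_train)
  }
  # the shared validation chemicals are identical across cell lines
  expect_identical(fx$datasets$MCF7$chemical_valid,
                   fx$datasets$A549$chemical_valid)
})
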