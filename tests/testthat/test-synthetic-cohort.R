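test_that("variance components control intra/inter-subject correlations", {
  # no within-subject noise: each subject's profiles identical over time
  d0 <- cohort_design(n_subjects = 6,
                      group_sizes = c(probiotic = 3, placebo = 3),
                      n_taxa = 40,
                      variance_components = list(
                        microbiota = c(shared = 0.5, subject = 0.5,
                                       noise = 0),
                        lipidome = c(shared = 0.9, subject = 0.02,
                                     noise = 0.08)),
                      planted_associations = list(), planted_effect = NULL,
                      seed = 11)
  prof <- generate_profiles(d0, "microbiota")
  intra <- intra_subject_similarity(prof$values, prof$metadata, c(1, 2))
  expect_equal(intra$per_subject$r, rep(1, 6), tolerance = 1e-12)

  # fully independent profiles: inter-subject r near zero
  d1 <- cohort_design(n_subjects = 12,
                      group_sizes = c(probiotic = 6, placebo = 6),
                      n_taxa = 400,
                      variance_components = list(
                        microbiota = c(shared = 0, subject = 0, noise = 1),
                        lipidome = c(shared = 0.9, subject = 0.02,
                                     noise = 0.08)),
                      planted_associations = list(), planted_effect = NULL,
                      seed = 12)
  prof1 <- generate_profiles(d1, "microbiota")
  inter <- inter_subject_similarity(prof1$values, prof1$metadata, tp = 1)
  expect_lt(max(abs(inter$mean_r)), 0.05)
})

test_that("default calibration hits the target stability correlations", {
  intra <- inter <- numeric(5)
  for (i in seq_len(5)) {
    d <- cohort_design(planted_associations = list(), planted_effect = NULL,
                       seed = 100 + i)
    prof <- generate_profiles(d, "microbiota")
    intra[i] <- mean(intra_subject_similarity(prof$values, prof$metadata,
                                              c(1, 2))$per_subject$r)
    inter[i] <- mean(inter_subject_similarity(prof$values, prof$metadata,
                                              tp = 1)$mean_r)
  }
  expect_lt(abs(mean(intra) - 0.94), 0.02)
  expect_lt(abs(mean(inter) - 0.77), 0.03)
})

test_that("generation is deterministic given the seed", {
  c1 <- generate_cohort(cohort_design(seed = 42))
  c2 <- generate_cohort(cohort_design(seed = 42))
  expect_identical(c1$abundance, c2$abundance)
  expect_identical(c1$lipids, c2$lipids)
  expect_identical(c1$panel, c2$panel)
  c3 <- generate_cohort(cohort_design(seed = 43))
  expect_false(identical(c1$abundance, c3$abundance))
})

test_that("planted associations realise their target correlation", {
  # iid observations: sample bicor of the planted pair concentrates on the
  # target; unbiasedness checked over replicate seeds
  n <- 44
  vals <- vapply(seq_len(60), function(s) {
    set.seed(s)
    x <- matrix(rnorm(n, 0, sqrt(0.23)), ncol = 1,
                dimnames = list(sprintf("s%02d", 1:n), "tax"))
    y <- matrix(rnorm(n, 0, sqrt(0.10)), ncol = 1,
                dimnames = list(sprintf("s%02d", 1:n), "lip"))
    res <- plant_association(x, y, planted_association("tax", "lip", 0.6),
                             seed = 1000 + s)
    bicor(res$abundance[, 1], res$lipids[, 1])
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.6), 0.05)
  expect_gt(mean(abs(vals - 0.6) < 0.25), 0.9)
})

test_that("a zero-loading association is a no-op and disjoint associations
           stay independent", {
  set.seed(9)
  x <- matrix(rnorm(40), ncol = 2,
              dimnames = list(sprintf("s%02d", 1:20), c("t1", "t2")))
  y <- matrix(rnorm(40), ncol = 2,
              dimnames = list(sprintf("s%02d", 1:20), c("l1", "l2")))
  res0 <- plant_association(x, y, planted_association("t1", "l1", 0),
                            seed = 1)
  expect_identical(res0$abundance, x)
  expect_identical(res0$lipids, y)

  # two disjoint associations leave cross-association lipids uncorrelated
  big_n <- 4000
  xx <- matrix(rnorm(2 * big_n), ncol = 2,
               dimnames = list(sprintf("s%04d", 1:big_n), c("t1", "t2")))
  yy <- matrix(rnorm(2 * big_n), ncol = 2,
               dimnames = list(sprintf("s%04d", 1:big_n), c("l1", "l2")))
  r1 <- plant_association(xx, yy, planted_association("t1", "l1", 0.6),
                          seed = 21)
  r2 <- plant_association(r1$abundance, r1$lipids,
                          planted_association("t2", "l2", 0.6),
                          seed = 22)
  expect_lt(abs(cor(r2$lipids[, "l1"], r2$lipids[, "l2"])), 0.06)
})

test_that("planted effects shift exactly the stated cell", {
  d <- cohort_design(planted_associations = list(), planted_effect = NULL,
                     seed = 5)
  prof <- generate_profiles(d, "microbiota")
  eff <- planted_effect(taxon = colnames(prof$values)[1],
                        group = "probiotic", timepoint = 2,
                        log10_fold_change = log10(2))
  shifted <- plant_effect(prof$values, prof$metadata, eff)
  md <- prof$metadata
  target <- md$sample_id[md$group == "probiotic" & md$timepoint == 2]
  others <- setdiff(rownames(prof$values), target)
  expect_equal(shifted[target, 1] - prof$values[target, 1],
               rep(log10(2), length(target)), ignore_attr = TRUE)
  expect_identical(shifted[others, ], prof$values[others, ])
  expect_identical(shifted[, -1], prof$values[, -1])
  # identity at zero fold change
  null_eff <- planted_effect(1, "probiotic", 2, 0)
  expect_identical(plant_effect(prof$values, prof$metadata, null_eff),
                   prof$values)
  expect_error(plant_effect(prof$values, prof$metadata,
                            planted_effect(1, "nogroup", 2, 1)),
               "unknown group")
})

test_that("the cohort's ledger matches the planted items and lipid names
           parse", {
  co <- generate_cohort(cohort_design(seed = 3))
  expect_equal(ncol(co$lipids), 407L)
  anno <- parse_lipid_names(colnames(co$lipids))
  expect_equal(length(unique(anno$class)), 11L)
  expect_false(any(duplicated(colnames(co$lipids))))
  expect_equal(length(co$ledger$associations),
               length(co$design$planted_associations))
  for (i in seq_along(co$ledger$associations)) {
    truth <- co$ledger$associations[[i]]
    spec <- co$design$planted_associations[[i]]
    expect_equal(truth$target_r, spec$target_r)
    expect_true(all(truth$lipids %in% colnames(co$lipids)))
  }
  expect_identical(co$ledger$effect, co$design$planted_effect)
  # invalid designs rejected
  expect_error(cohort_design(variance_components = list(
    microbiota = c(-0.1, 0.2, 0.2),
    lipidome = c(0.9, 0.02, 0.08))), "variance components")
  expect_error(plant_association(co$abundance, co$lipids,
                                 list(taxon = 1, lipids = 1, target_r = 1),
                                 seed = 1),
               "target_r")
})
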