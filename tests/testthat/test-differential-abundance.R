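test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 6)), rep(1, 6))
  set.seed(12)
  p <- runif(50)
  expect_equal(bh_adjust(p), hand_bh(p), tolerance = 1e-12)
  expect_warning(bh_adjust(c(0.1, NA)), "NA")
})

test_that("moderated t collapses to ordinary t when variances are equal
           and interpolates otherwise", {
  set.seed(20)
  md <- make_two_group_metadata(6)
  p <- 40
  x <- matrix(rnorm(12 * p), 12, p,
              dimnames = list(md$sample_id, paste0("tax", 1:p)))
  res <- suppressWarnings(
    fit_moderated_contrast(x, md, type = "two_group", timepoints = 1,
                           groups = c("A", "B")))
  d0 <- attr(res, "df_prior")
  s0 <- attr(res, "s2_prior")
  d <- attr(res, "df")
  # moderated |t| lies between the ordinary t and the s0-based t, with
  # preserved sign
  v <- 1 / 6 + 1 / 6
  t_s0 <- res$effect / sqrt(s0 * v)
  lo <- pmin(abs(res$t), abs(t_s0))
  hi <- pmax(abs(res$t), abs(t_s0))
  expect_true(all(abs(res$moderated_t) >= lo - 1e-12))
  expect_true(all(abs(res$moderated_t) <= hi + 1e-12))
  expect_true(all(sign(res$moderated_t) == sign(res$t)))
  # shrinkage fixed point: forcing every s2 to s0 makes both t equal
  s2 <- rep(2.5, p)
  fake <- suppressWarnings(lipitax:::moderate_fit(rnorm(p), s2, d, v))
  expect_equal(fake$moderated_t, fake$t, tolerance = 1e-8)
})

test_that("the moments prior estimation is consistent with limma", {
  skip_if_not_installed("limma")
  set.seed(33)
  p <- 300
  d <- 12
  s0_true <- 0.3
  s2 <- s0_true * rf(p, d, 20) * 1  # heterogeneous variances, d0 = 20
  prior <- lipitax:::estimate_prior(s2, d)
  sq <- limma::squeezeVar(s2, df = d)
  expect_equal(log(prior$s0_2), log(sq$var.prior), tolerance = 0.15)
  expect_equal(1 / prior$d0, 1 / sq$df.prior, tolerance = 0.1)
  # and moderated p-values agree closely on a heterogeneous-variance
  # contrast (finite d0 on both routes)
  md <- make_two_group_metadata(7)
  sig2 <- 0.5 * 10 / rchisq(100, 10)
  x <- matrix(rnorm(14 * 100), 14, 100,
              dimnames = list(md$sample_id, paste0("t", 1:100)))
  x <- sweep(x, 2, sqrt(sig2), "*")
  res <- fit_moderated_contrast(x, md, type = "two_group", timepoints = 1,
                                groups = c("A", "B"))
  design <- cbind(1, md$group == "A")
  fit <- limma::eBayes(limma::lmFit(t(x), design))
  expect_equal(res$p, fit$p.value[, 2], tolerance = 0.02,
               ignore_attr = TRUE)
  expect_gt(cor(res$moderated_t, fit$t[, 2]), 0.999)
})

test_that("a paired contrast recovers a planted effect and controls the
           null", {
  co <- generate_cohort(cohort_design(seed = 29))
  res <- suppressWarnings(
    fit_moderated_contrast(co$abundance, co$metadata, type = "paired",
                           timepoints = c(1, 2), group = "probiotic"))
  eff <- co$ledger$effect
  idx <- match(eff$taxon, res$taxon)
  expect_lt(res$adj_p[idx], 0.05)
  expect_lt(abs(res$effect[idx] - eff$log10_fold_change), 0.3)
  # null taxa essentially unflagged
  expect_lte(sum(res$adj_p[-idx] < 0.05), 2)
  expect_error(fit_moderated_contrast(co$abundance, co$metadata[1:2, ],
                                      type = "paired"),
               "fewer than 2 subjects")
})

test_that("null type-I error of the moderated detection rule stays at or
           below nominal", {
  null_design <- cohort_design(planted_associations = list(),
                               planted_effect = NULL, seed = 1)
  rates <- vapply(1:40, function(s) {
    d <- null_design; d$seed <- 500 + s
    co <- generate_cohort(d)
    # homogeneous true variances make d0 = Inf a legitimate outcome here
    res <- suppressWarnings(
      fit_moderated_contrast(co$abundance, co$metadata,
                             type = "two_group", timepoints = 2,
                             groups = c("probiotic", "placebo")))
    mean(res$adj_p < 0.05)
  }, numeric(1))
  # binomial tolerance: mean false-flag fraction must not exceed nominal
  expect_lte(mean(rates), 0.05 + 2 * sd(rates) / sqrt(length(rates)))
})

test_that("empirical power is null-calibrated, monotone, and saturates for
           huge effects", {
  co <- generate_cohort(cohort_design(seed = 37))
  # fold change 1 = null insertion: detection near the nominal rate
  p0 <- empirical_power(co$abundance, fold_change = 1, n = 8, reps = 100,
                        seed = 2)
  expect_lte(p0$detection_rate, 0.08)
  # separation: giant effect at low noise always detected
  p1 <- empirical_power(co$abundance, fold_change = 1e6, n = 8, reps = 50,
                        seed = 3, noise_sd = 0.05)
  expect_equal(p1$detection_rate, 1)
  # monotone in fold change at fixed noise
  rates <- vapply(c(2, 8, 32), function(fc) {
    empirical_power(co$abundance, fc, n = 8, reps = 60, seed = 4,
                    noise_sd = 0.3)$detection_rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  # power -> 1 for a 2-fold change at low noise (few taxa, small variance)
  set.seed(40)
  lown <- matrix(rnorm(30 * 30, 0, 0.05), 30, 30,
                 dimnames = list(sprintf("s%02d", 1:30),
                                 sprintf("t%02d", 1:30)))
  p2 <- empirical_power(lown, fold_change = 2, n = 8, reps = 100, seed = 5,
                        noise_sd = 0.05)
  expect_gte(p2$detection_rate, 0.99)
  expect_error(empirical_power(co$abundance, fold_change = -2, n = 8),
               "fold_change")
})

test_that("power is monotone in sample size on calibrated data", {
  set.seed(50)
  x <- matrix(rnorm(40 * 40, 0, 0.25), 40, 40,
              dimnames = list(sprintf("s%02d", 1:40),
                              sprintf("t%02d", 1:40)))
  curve <- power_curve(x, fold_change = 2, sample_sizes = c(4, 10, 18),
                       reps = 80, seed = 6, noise_sd = 0.2)
  expect_true(all(diff(curve$detection_rate) >= -0.05))
  expect_gt(curve$detection_rate[3], curve$detection_rate[1])
})
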