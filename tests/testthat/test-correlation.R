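test_that("bicor matches a brute-force transcription of the formula", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.3 * x
    expect_equal(bicor(x, y), brute_force_bicor(x, y), tolerance = 1e-12)
  }
  # and on a frozen 10-point pair
  x0 <- c(0.62, -1.37, 0.48, 1.95, -0.22, 0.73, -0.06, -1.11, 0.29, 2.40)
  y0 <- c(0.51, -0.93, 0.81, 1.42, 0.13, 0.55, -0.42, -1.30, -0.02, 1.10)
  expect_equal(bicor(x0, y0), brute_force_bicor(x0, y0), tolerance = 1e-12)
})

test_that("bicor is normalised, antisymmetric, and close to Pearson on
           clean Gaussian data", {
  set.seed(7)
  x <- rnorm(30)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
  z <- rnorm(1000)
  w <- 0.5 * z + sqrt(1 - 0.25) * rnorm(1000)
  expect_lt(abs(bicor(z, w) - cor(z, w)), 0.05)
})

test_that("bicor resists a gross outlier better than Pearson", {
  set.seed(11)
  moved_less <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(50)
    y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(50)
    r_b0 <- bicor(x, y); r_p0 <- cor(x, y)
    y[1] <- y[1] + 10   # a 10-SD outlier
    abs(bicor(x, y) - r_b0) < abs(cor(x, y) - r_p0)
  }, logical(1))
  expect_gte(mean(moved_less), 0.95)
})

test_that("zero-MAD columns fall back to Pearson with a warning", {
  x <- c(rep(0, 6), 1, 2, 3, 4)   # median run => mad 0, but not constant
  y <- seq_len(10)
  expect_warning(r <- bicor(x, y), "Pearson fallback")
  expect_equal(r, suppressWarnings(bicor(y, x)), tolerance = 1e-12)
  expect_warning(bicor(rep(1, 10), y), "constant")
})

test_that("bicor_matrix agrees with pairwise bicor", {
  set.seed(3)
  x <- matrix(rnorm(60), 12, 5)
  y <- matrix(rnorm(48), 12, 4)
  m <- bicor_matrix(x, y)
  for (i in 1:5) for (j in 1:4) {
    expect_equal(m[i, j], bicor(x[, i], y[, j]), tolerance = 1e-12)
  }
})

test_that("analytic p-values match the t transform and the permutation
           null", {
  expect_equal(bicor_pvalue(0, 20), 1)
  expect_equal(bicor_pvalue(1, 20), 0)
  expect_equal(bicor_pvalue(-1, 20), 0)
  # monotone decreasing in |r|
  rs <- seq(0, 0.95, 0.05)
  expect_true(all(diff(bicor_pvalue(rs, 30)) < 0))
  expect_equal(bicor_pvalue(0.6, 44),
               2 * pt(-0.6 * sqrt(42 / (1 - 0.36)), df = 42))
  # permutation cross-check at r ~ 0.45, n = 44
  set.seed(21)
  x <- rnorm(44)
  y <- 0.45 * x + sqrt(1 - 0.45^2) * rnorm(44)
  r <- bicor(x, y)
  p_t <- bicor_pvalue(r, 44)
  perm <- bicor_perm_pvalue(x, y, B = 20000, seed = 4)
  mc_sd <- sqrt(p_t * (1 - p_t) / 20000)
  expect_lt(abs(perm$p - p_t), 3 * mc_sd + 1 / 20000)
})

test_that("q-values reduce to BH at pi0 = 1 and are monotone in p", {
  set.seed(31)
  p <- c(runif(300)^2, runif(200))
  q <- qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), hand_bh(p), tolerance = 1e-12)
  expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)
  q_est <- qvalues(p)
  o <- order(p)
  expect_true(all(diff(q_est[o]) >= -1e-12))
  expect_true(all(q_est >= 0 & q_est <= 1))
  expect_equal(as.numeric(qvalues(rep(1, 5))), rep(1, 5))
})

test_that("pi0 is estimated near 1 on uniform null p-values", {
  set.seed(41)
  for (s in 1:3) {
    p <- runif(10000)
    pi0 <- attr(qvalues(p), "pi0")
    expect_gte(pi0, 0.9)
    expect_lte(pi0, 1.0)
  }
})

test_that("the screen selects planted pairs and respects ordering
           invariance", {
  co <- generate_cohort(cohort_design(seed = 19))
  sc <- correlation_screen(co$abundance, co$lipids)
  expect_true(all(abs(sc$r) <= 1))
  expect_equal(dim(sc$r), c(131L, 407L))
  expect_equal(sc$n, 44L)
  # the strongest planted (positive) association is found
  a <- co$ledger$associations[[1]]
  expect_gt(sum(sc$mask[a$taxon, a$lipids]), 0)
  # permuting features leaves the selection invariant
  set.seed(5)
  perm_t <- sample(ncol(co$abundance))
  perm_l <- sample(ncol(co$lipids))
  sc2 <- correlation_screen(co$abundance[, perm_t], co$lipids[, perm_l])
  expect_equal(sc2$summary$n_selected, sc$summary$n_selected)
  expect_equal(sort(significant_pairs(sc2)$lipid),
               sort(significant_pairs(sc)$lipid))
  expect_error(correlation_screen(co$abundance[1:3, ], co$lipids),
               "shared samples")
})

test_that("two-way clustering merges identical rows first and is
           permutation invariant", {
  set.seed(8)
  m <- matrix(rnorm(80), 8, 10,
              dimnames = list(paste0("r", 1:8), paste0("c", 1:10)))
  m[2, ] <- m[1, ]   # identical pair
  cl <- two_way_cluster(m)
  h <- cl$row_hclust
  first <- sort(abs(h$merge[1, ]))
  expect_equal(first, c(1, 2))
  expect_equal(h$height[1], 0, tolerance = 1e-12)
  # permuting input rows gives the same topology (same cophenetic dists)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  cl2 <- two_way_cluster(m[perm, ])
  d1 <- as.matrix(cophenetic(cl$row_hclust))
  d2 <- as.matrix(cophenetic(cl2$row_hclust))
  expect_equal(d1[rownames(d2), colnames(d2)], d2, tolerance = 1e-12)
})

test_that("block-structured correlation matrices cluster into contiguous
           blocks", {
  base <- matrix(0, 12, 14, dimnames = list(sprintf("t%02d", 1:12),
                                            sprintf("l%02d", 1:14)))
  blockA_r <- 1:5; blockA_c <- 1:6
  blockB_r <- 8:12; blockB_c <- 9:14
  base[blockA_r, blockA_c] <- 0.6
  base[blockB_r, blockB_c] <- -0.6
  set.seed(13)
  noisy <- base + matrix(rnorm(length(base), 0, 0.05), nrow(base))
  cl <- two_way_cluster(noisy)
  pos <- match(rownames(base)[blockA_r], cl$row_order)
  expect_equal(max(pos) - min(pos) + 1L, length(blockA_r))
  posB <- match(rownames(base)[blockB_r], cl$row_order)
  expect_equal(max(posB) - min(posB) + 1L, length(blockB_r))
})
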