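# planted-block generator shared with the acceptance suite
make_planted_block <- function(seed, nr = 60, nc = 100, rows = 1:8,
                               cols = 1:10, effect = 1, noise_sd = 0.1) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc, 0, noise_sd), nr, nc,
              dimnames = list(sprintf("r%03d", 1:nr), sprintf("c%03d", 1:nc)))
  m[rows, cols] <- m[rows, cols] + effect
  m
}

jaccard_cells <- function(layer, rows, cols, nr, nc) {
  truth <- matrix(FALSE, nr, nc)
  truth[rows, cols] <- TRUE
  found <- outer(layer$rows, layer$cols, "&")
  sum(truth & found) / sum(truth | found)
}

test_that("a constant matrix yields the background layer only", {
  m <- matrix(5, 10, 12, dimnames = list(paste0("r", 1:10),
                                         paste0("c", 1:12)))
  fit <- fit_plaid(m, plaid_params(seed = 1))
  expect_equal(length(fit$layers), 0L)
  expect_equal(fit$background, 5)
  expect_equal(max(abs(fit$residual)), 0)
  expect_error(fit_plaid(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("a planted block is recovered with high cell Jaccard", {
  hits <- vapply(1:20, function(s) {
    m <- make_planted_block(s)
    fit <- fit_plaid(m, plaid_params(seed = 1000 + s))
    if (!length(fit$layers)) return(0)
    jaccard_cells(fit$layers[[1]], 1:8, 1:10, 60, 100)
  }, numeric(1))
  expect_gte(mean(hits >= 0.9), 0.95)
})

test_that("two disjoint blocks of opposite sign give two matching layers", {
  found <- vapply(1:10, function(s) {
    set.seed(s)
    m <- matrix(rnorm(60 * 100, 0, 0.1), 60, 100,
                dimnames = list(sprintf("r%03d", 1:60),
                                sprintf("c%03d", 1:100)))
    m[1:8, 1:10] <- m[1:8, 1:10] + 1
    m[30:40, 50:62] <- m[30:40, 50:62] - 1
    fit <- fit_plaid(m, plaid_params(seed = 2000 + s))
    if (length(fit$layers) < 2) return(FALSE)
    j1 <- vapply(fit$layers, jaccard_cells, numeric(1), rows = 1:8,
                 cols = 1:10, nr = 60, nc = 100)
    j2 <- vapply(fit$layers, jaccard_cells, numeric(1), rows = 30:40,
                 cols = 50:62, nr = 60, nc = 100)
    max(j1) >= 0.9 && max(j2) >= 0.9
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("residual sum of squares never increases over accepted layers", {
  m <- make_planted_block(77)
  m[20:30, 40:60] <- m[20:30, 40:60] + 0.8
  p <- plaid_params(seed = 9)
  fit <- fit_plaid(m, p)
  z <- m - fit$background
  rss <- sum(z^2)
  for (l in fit$layers) {
    z[l$rows, l$cols] <- z[l$rows, l$cols] - l$mu
    expect_lte(sum(z^2), rss + 1e-9)
    rss <- sum(z^2)
  }
  expect_equal(sum(fit$residual^2), rss, tolerance = 1e-9)
})

test_that("pure noise rarely yields an accepted layer", {
  n_layers <- vapply(1:40, function(s) {
    set.seed(s)
    m <- matrix(rnorm(40 * 60), 40, 60)
    dimnames(m) <- list(sprintf("r%02d", 1:40), sprintf("c%02d", 1:60))
    length(fit_plaid(m, plaid_params(seed = 3000 + s))$layers)
  }, numeric(1))
  expect_gte(mean(n_layers == 0), 0.9)
})

test_that("the fit is invariant (up to relabeling) to input permutation", {
  m <- make_planted_block(5)
  fit1 <- fit_plaid(m, plaid_params(seed = 11))
  set.seed(6)
  pr <- sample(nrow(m)); pc <- sample(ncol(m))
  fit2 <- fit_plaid(m[pr, pc], plaid_params(seed = 11))
  expect_equal(length(fit1$layers), length(fit2$layers))
  if (length(fit1$layers)) {
    expect_setequal(fit2$layers[[1]]$row_names, fit1$layers[[1]]$row_names)
    expect_setequal(fit2$layers[[1]]$col_names, fit1$layers[[1]]$col_names)
    expect_equal(fit2$layers[[1]]$mu, fit1$layers[[1]]$mu, tolerance = 0.05)
  }
})

test_that("bicluster summaries list the planted members with the right
           sign", {
  m <- make_planted_block(8, effect = -1)
  fit <- fit_plaid(m, plaid_params(seed = 21))
  expect_equal(length(fit$layers), 1L)
  summ <- bicluster_summary(fit)
  expect_equal(summ$n_taxa, 8L)
  expect_equal(summ$n_lipids, 10L)
  expect_lt(summ$effect, 0)
  expect_setequal(strsplit(summ$taxa, ",")[[1]], sprintf("r%03d", 1:8))
  # empty set reported, not dropped
  empty <- bicluster_summary(list(layers = list()))
  expect_equal(nrow(empty), 0L)
})
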