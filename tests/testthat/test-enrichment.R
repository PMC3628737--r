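test_that("Fisher p agrees with exhaustive enumeration on small tables", {
  # exhaustive over all 2x2 tables with N <= 24 (the full N <= 40 sweep
  # runs in the acceptance suite)
  for (N in c(6, 12, 24)) {
    parts <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    parts <- parts[rowSums(parts) <= N, ]
    parts$d <- N - parts$a - parts$b - parts$c
    for (i in seq_len(nrow(parts))) {
      tb <- unlist(parts[i, c("a", "b", "c", "d")])
      got <- fisher_exact_2x2(tb)$p
      want <- enumerate_fisher_p(tb[1], tb[2], tb[3], tb[4])
      if (abs(got - want) > 1e-9) {
        fail(sprintf("mismatch at table (%s): %g vs %g",
                     paste(tb, collapse = ","), got, want))
      }
    }
  }
  succeed()
})

test_that("Fisher test matches stats::fisher.test and is symmetric", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  set.seed(17)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 6), 2)
    got <- fisher_exact_2x2(tb)
    ref <- fisher.test(tb)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
    # swapping rows and columns leaves p unchanged
    expect_equal(fisher_exact_2x2(tb[2:1, ])$p, got$p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tb[, 2:1])$p, got$p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t(tb))$p, got$p, tolerance = 1e-12)
  }
  # zero margin convention
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$p, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 3, 4), 2)), "non-negative")
})

test_that("category enrichment flags a constructed odd-carbon selection", {
  universe <- c(sprintf("TG(%d:2)", seq(45, 63, 2)),   # 10 odd
                sprintf("TG(%d:2)", seq(44, 62, 2)),   # 10 even
                sprintf("PC(%d:1)", seq(30, 44, 2)),   # 8 even
                sprintf("PC(%d:0)", seq(31, 43, 2)))   # 7 odd... total 35
  selected <- sprintf("TG(%d:2)", seq(45, 63, 2))      # all 10 odd TGs
  res <- category_enrichment(selected, universe)
  odd <- res[res$category == "odd", ]
  expect_equal(unname(unlist(odd[c("a", "b", "c", "d")])),
               c(10, 0, 7, 18))
  expect_equal(odd$p, enumerate_fisher_p(10, 0, 7, 18), tolerance = 1e-9)
  expect_lt(odd$p, 0.001)
  # selection = universe gives p = 1 everywhere
  all_sel <- category_enrichment(universe, universe)
  expect_true(all(all_sel$p == 1))
  # empty selection gives p = 1 everywhere
  none <- category_enrichment(character(0), universe)
  expect_true(all(none$p == 1))
  expect_error(category_enrichment("Cer(34:1)", universe), "subset")
})

test_that("random selections give calibrated (uniformish) enrichment p", {
  set.seed(23)
  universe <- c(sprintf("TG(%d:%d)", sample(44:62, 60, TRUE),
                        sample(0:8, 60, TRUE)))
  universe <- unique(universe)
  ps <- vapply(1:200, function(i) {
    sel <- sample(universe, 12)
    res <- category_enrichment(sel, universe)
    res$p[res$category == "PUFA"]
  }, numeric(1))
  # discrete conservative p: no excess of small values
  expect_lte(mean(ps < 0.05), 0.07)
  expect_gt(mean(ps), 0.3)
})

test_that("taxon enrichment ranks a pure-phylum bicluster first", {
  groups <- data.frame(taxon = sprintf("t%02d", 1:30),
                       group = rep(c("Proteobacteria", "Firmicutes",
                                     "Bacteroidetes"), each = 10),
                       stringsAsFactors = FALSE)
  res <- taxon_enrichment(sprintf("t%02d", 1:10), groups$taxon, groups)
  expect_equal(res$category[which.min(res$p)], "Proteobacteria")
  expect_lt(min(res$p), 0.001)
  # single-taxon bicluster is computable
  one <- taxon_enrichment("t01", groups$taxon, groups)
  expect_true(all(one$p > 0 & one$p <= 1))
  # unlabeled taxa are skipped with a warning
  expect_warning(taxon_enrichment("t01", c(groups$taxon, "tX"), groups),
                 "skipped")
})

test_that("bicluster enrichment covers both axes over screened features", {
  co <- generate_cohort(cohort_design(seed = 31))
  sc <- correlation_screen(co$abundance, co$lipids)
  cl <- two_way_cluster(sc)
  fake_set <- list(layers = list(list(
    rows = rep(TRUE, nrow(cl$matrix)), cols = rep(TRUE, ncol(cl$matrix)),
    mu = 0.5, ss = 1, row_names = rownames(cl$matrix),
    col_names = colnames(cl$matrix))))
  en <- bicluster_enrichment(fake_set, sc, co$taxa)
  expect_true(all(c("lipid", "taxon") %in% en$axis))
  # layer = universe on the lipid axis: all lipid p-values 1
  expect_true(all(en$p[en$axis == "lipid"] == 1))
})
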