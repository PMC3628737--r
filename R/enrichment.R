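# Fisher exact over-representation tests of taxa and of lipid structural
# categories within biclusters / significant sets.

#' Fisher's exact test for a 2 x 2 table
#'
#' Exact hypergeometric test with fixed margins.  The two-sided p-value is
#' the total probability of all tables whose hypergeometric probability is
#' at most that of the observed table (the "probability mass <= observed"
#' rule, with the customary 1e-7 relative tolerance for ties).  The odds
#' ratio is the unconditional `ad / bc` (0 and infinity allowed at zero
#' cells).
#'
#' @param table 2 x 2 matrix (or length-4 vector, row-major `a, b, c, d`) of
#'   non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"` for
#'   one-sided enrichment / depletion of cell `a`.
#' @return List with `odds_ratio`, `p` and the table.  A zero row or column
#'   margin gives `p = 1` by convention.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  check_that(all(dim(table) == 2), "'table' must be 2 x 2")
  check_that(all(is.finite(table)) && all(table >= 0) &&
               all(table == round(table)),
             "cells must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  or <- (a * d) / (b * c_)
  m <- a + b          # row-1 margin
  n2 <- c_ + d        # row-2 margin
  k <- a + c_         # column-1 margin
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) {
    return(list(odds_ratio = or, p = 1, table = table))
  }
  lo <- max(0, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- switch(alternative,
              two.sided = sum(dens[dens <= p_obs * (1 + 1e-7)]),
              greater = sum(dens[support >= a]),
              less = sum(dens[support <= a]))
  list(odds_ratio = or, p = min(p, 1), table = table)
}

# shared 2x2 enrichment driver: selected / universe membership vs a logical
# category indicator over the universe
enrich_2x2 <- function(in_set, in_category, label,
                       alternative = "two.sided") {
  a <- sum(in_set & in_category)
  b <- sum(in_set & !in_category)
  c_ <- sum(!in_set & in_category)
  d <- sum(!in_set & !in_category)
  ft <- fisher_exact_2x2(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                         alternative = alternative)
  data.frame(category = label, a = a, b = b, c = c_, d = d,
             odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
}

#' Structural-category enrichment of a lipid selection
#'
#' Tests over-representation, within a selected lipid set against a
#' universe, of each structural category level: carbon-count parity
#' (odd/even), saturation class (SAFA / MUFA / PUFA), long-chain and ether
#' linkage.
#'
#' @param selected character vector of selected species names (subset of
#'   `universe`).
#' @param universe character vector of universe species names.
#' @param long_chain_threshold carbons threshold passed to
#'   [lipid_categories()].
#' @param alternative passed to [fisher_exact_2x2()].
#' @return Data frame with one row per category level: `category`, the 2x2
#'   cells `a`-`d`, `odds_ratio`, `p`.  An empty selection yields all
#'   `p = 1`.
#' @export
category_enrichment <- function(selected, universe,
                                long_chain_threshold = 54,
                                alternative = "two.sided") {
  check_that(all(selected %in% universe),
             "'selected' must be a subset of 'universe'")
  anno <- lipid_categories(parse_lipid_names(universe),
                           long_chain_threshold = long_chain_threshold)
  in_set <- universe %in% selected
  cats <- list(odd = anno$parity == "odd", even = anno$parity == "even",
               SAFA = anno$saturation == "SAFA",
               MUFA = anno$saturation == "MUFA",
               PUFA = anno$saturation == "PUFA",
               long_chain = anno$long_chain, ether = anno$ether)
  out <- do.call(rbind, lapply(names(cats), function(nm) {
    enrich_2x2(in_set, cats[[nm]], nm, alternative)
  }))
  rownames(out) <- NULL
  out
}

#' Taxon-group enrichment of a bicluster
#'
#' Tests over-representation of each phylum / Clostridium-cluster label
#' among a bicluster's taxa, against the universe of screened taxa.
#'
#' @param taxa character vector of the bicluster's taxon names.
#' @param universe character vector of all screened taxon names.
#' @param taxon_groups data frame with columns `taxon` and `group` (phylum
#'   or cluster label) covering the universe; taxa with no label are
#'   skipped with a warning.
#' @param alternative passed to [fisher_exact_2x2()].
#' @return Data frame as in [category_enrichment()], one row per group
#'   label present in the universe.
#' @export
taxon_enrichment <- function(taxa, universe, taxon_groups,
                             alternative = "two.sided") {
  check_that(all(taxa %in% universe),
             "'taxa' must be a subset of 'universe'")
  grp <- taxon_groups$group[match(universe, taxon_groups$taxon)]
  if (anyNA(grp)) {
    warning(sprintf("%d taxa without group label skipped", sum(is.na(grp))),
            call. = FALSE)
    keep <- !is.na(grp)
    universe <- universe[keep]
    grp <- grp[keep]
    taxa <- intersect(taxa, universe)
  }
  in_set <- universe %in% taxa
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    enrich_2x2(in_set, grp == g, g, alternative)
  }))
  rownames(out) <- NULL
  out
}

#' Enrichment of all bicluster layers
#'
#' Runs lipid-category and taxon-group enrichment for every layer of a
#' bicluster set, with the enrichment universe defaulting to the features
#' carrying at least one significant correlation (the features the plaid
#' model saw).
#'
#' @param set a `bicluster_set` fitted on the screen's clustered submatrix.
#' @param screen the `correlation_screen`.
#' @param taxon_groups taxon annotation data frame (`taxon`, `group`).
#' @param lipid_universe `"screened"` (features with a significant
#'   correlation; default) or `"all"` (every profiled lipid).
#' @param long_chain_threshold passed to [category_enrichment()].
#' @return Data frame with columns `layer`, `axis`, `category`, `a`-`d`,
#'   `odds_ratio`, `p`.
#' @export
bicluster_enrichment <- function(set, screen, taxon_groups,
                                 lipid_universe = c("screened", "all"),
                                 long_chain_threshold = 54) {
  lipid_universe <- match.arg(lipid_universe)
  uni_lip <- if (lipid_universe == "screened") {
    colnames(screen$r)[colSums(screen$mask) > 0]
  } else colnames(screen$r)
  uni_tax <- if (lipid_universe == "screened") {
    rownames(screen$r)[rowSums(screen$mask) > 0]
  } else rownames(screen$r)
  rows <- list()
  for (i in seq_along(set$layers)) {
    l <- set$layers[[i]]
    lips <- intersect(l$col_names, uni_lip)
    taxs <- intersect(l$row_names, uni_tax)
    ce <- category_enrichment(lips, uni_lip,
                              long_chain_threshold = long_chain_threshold)
    ce$layer <- i; ce$axis <- "lipid"
    te <- taxon_enrichment(taxs, uni_tax, taxon_groups)
    te$layer <- i; te$axis <- "taxon"
    rows[[i]] <- rbind(ce, te)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(0), a = integer(0), b = integer(0),
               c = integer(0), d = integer(0), odds_ratio = numeric(0),
               p = numeric(0), layer = integer(0), axis = character(0))
  out <- out[, c("layer", "axis", "category", "a", "b", "c", "d",
                 "odds_ratio", "p")]
  rownames(out) <- NULL
  out
}
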