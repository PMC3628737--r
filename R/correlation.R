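# Robust taxon x lipid correlation screen: biweight midcorrelation,
# analytic / permutation significance, Storey q-values, selection of
# significant pairs, and two-way average-linkage clustering of the
# correlation matrix.

# Biweight transform of one vector: median-centred values downweighted by
# Tukey's biweight with tuning constant `c` applied to the unscaled median
# absolute deviation, normalised to unit sum of squares.  Falls back to the
# Pearson transform (mean-centring) when the MAD is zero.
bicor_transform <- function(x, tuning = 9, warn = TRUE) {
  check_that(is.numeric(x) && all(is.finite(x)),
             "input vectors must be finite and numeric")
  med <- stats::median(x)
  mad_u <- stats::median(abs(x - med))
  if (mad_u == 0) {
    if (stats::sd(x) == 0) {
      if (warn) warning("constant vector: correlation undefined",
                        call. = FALSE)
      return(rep(NA_real_, length(x)))
    }
    if (warn) warning("zero median absolute deviation: Pearson fallback",
                      call. = FALSE)
    cx <- x - mean(x)
    return(cx / sqrt(sum(cx^2)))
  }
  u <- (x - med) / (tuning * mad_u)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  num <- (x - med) * w
  den <- sqrt(sum((x - med)^2 * w^2))
  num / den
}

#' Biweight midcorrelation
#'
#' Robust correlation based on Tukey biweight weights centred on the median
#' and scaled by the (unscaled) median absolute deviation.  With
#' `u_i = (x_i - med(x)) / (tuning * mad(x))` and weight
#' `w_i = (1 - u_i^2)^2 * 1[|u_i| < 1]` (likewise for `y`),
#' the correlation is the normalised cross-product of the weighted
#' median-centred vectors.  Less sensitive to outliers than Pearson
#' correlation while agreeing with it closely on well-behaved data.
#'
#' @param x,y numeric vectors of equal length (at least 5).
#' @param tuning biweight tuning constant; 9 is the standard choice.
#' @return Correlation in \[-1, 1\].  Vectors with zero median absolute
#'   deviation fall back to Pearson weighting with a warning; constant
#'   vectors give `NA`.
#' @examples
#' x <- rnorm(50); y <- x + rnorm(50)
#' bicor(x, y)
#' @export
bicor <- function(x, y, tuning = 9) {
  check_that(length(x) == length(y), "'x' and 'y' must have equal length")
  check_that(length(x) >= 5, "need at least 5 observations")
  tx <- bicor_transform(x, tuning)
  ty <- bicor_transform(y, tuning)
  r <- sum(tx * ty)
  # guard against rounding outside [-1, 1]
  max(-1, min(1, r))
}

#' Biweight midcorrelation between all column pairs of two matrices
#'
#' @param x,y matrices with observations in rows (equal row counts).
#' @param tuning biweight tuning constant.
#' @return `ncol(x)` x `ncol(y)` correlation matrix.
#' @export
bicor_matrix <- function(x, y, tuning = 9) {
  check_that(nrow(x) == nrow(y), "'x' and 'y' must have equal row counts")
  check_that(nrow(x) >= 5, "need at least 5 observations")
  warned <- FALSE
  tf <- function(m) {
    apply(m, 2, function(col) {
      res <- withCallingHandlers(
        bicor_transform(col, tuning, warn = TRUE),
        warning = function(w) {
          warned <<- TRUE
          invokeRestart("muffleWarning")
        })
      res
    })
  }
  tx <- tf(x)
  ty <- tf(y)
  if (warned) warning("some columns had zero MAD or were constant",
                      call. = FALSE)
  r <- crossprod(tx, ty)
  r[r > 1] <- 1
  r[r < -1] <- -1
  dimnames(r) <- list(colnames(x), colnames(y))
  r
}

#' Analytic p-value for a correlation
#'
#' Student-t approximation: `t = r * sqrt((n - 2) / (1 - r^2))` against a t
#' distribution with `n - 2` degrees of freedom, two-sided.
#'
#' @param r correlation value(s).
#' @param n number of observations.
#' @return Two-sided p-value(s); `|r| = 1` gives 0, `NA` propagates.
#' @export
bicor_pvalue <- function(r, n) {
  check_that(all(n >= 5), "need at least 5 observations")
  p <- rep(NA_real_, length(r))
  edge <- !is.na(r) & abs(r) >= 1
  p[edge] <- 0
  ok <- !is.na(r) & abs(r) < 1
  tt <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

#' Permutation p-value for a biweight midcorrelation
#'
#' Two-sided permutation test: `y` is permuted `B` times and the fraction of
#' permuted |bicor| values at or above the observed one is reported (with
#' the +1 correction so p is never 0).
#'
#' @param x,y numeric vectors.
#' @param B number of permutations.
#' @param seed integer seed.
#' @param tuning biweight tuning constant.
#' @return List with `r` (observed) and `p`.
#' @export
bicor_perm_pvalue <- function(x, y, B = 1000, seed = 1, tuning = 9) {
  r_obs <- bicor(x, y, tuning)
  tx <- bicor_transform(x, tuning, warn = FALSE)
  perm <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      yy <- y[sample.int(length(y))]
      sum(tx * bicor_transform(yy, tuning, warn = FALSE))
    }, numeric(1))
  })
  list(r = r_obs, p = (1 + sum(abs(perm) >= abs(r_obs))) / (B + 1))
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the proportion of true nulls `pi0`
#' estimated by the smoother method on a lambda grid; `q_i` is the minimum,
#' over all tests with `p_j >= p_i`, of `pi0 * m * p_j / rank(p_j)`.  With
#' `pi0 = 1` this reduces exactly to Benjamini-Hochberg adjusted p-values.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param pi0 optionally force the null proportion; `NULL` (default)
#'   estimates it.  The estimate falls back to 1 when there are fewer than
#'   100 tests or the smoother is unstable.
#' @param lambda grid for the pi0 smoother.
#' @return Vector of q-values in \[0, 1\], monotone in p, with attribute
#'   `"pi0"`.
#' @examples
#' qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)  # equals p.adjust BH
#' @export
qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05)) {
  check_that(is.numeric(p) && length(p) >= 1, "'p' must be non-empty numeric")
  ok <- !is.na(p)
  check_that(all(p[ok] >= 0 & p[ok] <= 1), "p-values must lie in [0, 1]")
  m <- sum(ok)
  if (is.null(pi0)) {
    pi0 <- estimate_pi0(p[ok], lambda)
  } else {
    check_that(pi0 > 0 && pi0 <= 1, "'pi0' must be in (0, 1]")
  }
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  rk <- rank(pv, ties.method = "max")
  raw <- pi0 * m * pv / rk
  o <- order(pv, decreasing = TRUE)
  raw[o] <- cummin(raw[o])
  q[ok] <- pmin(raw, 1)
  attr(q, "pi0") <- pi0
  q
}

# pi0 estimation by the smoother method; conservative fallback to 1.
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(p)
  if (m < 100 || length(unique(p)) == 1L) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- tryCatch({
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }, error = function(e) NA_real_)
  if (is.na(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- min(max(pi0_l, 0), 1)
  if (is.na(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- 1
  pi0
}

#' Taxon x lipid robust correlation screen
#'
#' Computes the full biweight-midcorrelation matrix between taxa and lipid
#' species across shared samples (observations pooled over time points),
#' analytic p-values, Storey q-values over all pairs, and the significant
#' pair selection at `q < q_max` and `|r| >= r_min`.
#'
#' @param abundance samples x taxa matrix (sample IDs as row names).
#' @param lipids samples x lipid species matrix.
#' @param r_min minimum absolute correlation for selection (default 0.5).
#' @param q_max maximum q-value for selection (default 0.05).
#' @param tuning biweight tuning constant.
#' @return Object of class `correlation_screen`: list with matrices `r`,
#'   `p`, `q`, logical `mask`, `n` (observations per pair), the thresholds,
#'   and a `summary` list (selected pair count, distinct taxa, per-class
#'   share of the significant correlations).
#' @export
correlation_screen <- function(abundance, lipids, r_min = 0.5,
                               q_max = 0.05, tuning = 9) {
  shared <- intersect(rownames(abundance), rownames(lipids))
  check_that(length(shared) >= 10,
             sprintf("need >= 10 shared samples, found %d", length(shared)))
  x <- abundance[shared, , drop = FALSE]
  y <- lipids[shared, , drop = FALSE]
  r <- suppressWarnings(bicor_matrix(x, y, tuning))
  n <- length(shared)
  p <- matrix(bicor_pvalue(as.vector(r), n), nrow = nrow(r),
              dimnames = dimnames(r))
  qv <- qvalues(as.vector(p))
  pi0 <- attr(qv, "pi0")
  q <- matrix(qv, nrow = nrow(r), dimnames = dimnames(r))
  mask <- !is.na(r) & !is.na(q) & q < q_max & abs(r) >= r_min
  sel <- which(mask, arr.ind = TRUE)
  cls <- tryCatch(parse_lipid_names(colnames(lipids))$class,
                  error = function(e) rep(NA_character_, ncol(lipids)))
  class_share <- if (nrow(sel)) {
    tab <- table(cls[sel[, 2]])
    sort(as.numeric(tab) / nrow(sel), decreasing = TRUE) |>
      stats::setNames(names(sort(tab, decreasing = TRUE)))
  } else numeric(0)
  structure(list(r = r, p = p, q = q, mask = mask, n = n,
                 r_min = r_min, q_max = q_max,
                 pi0 = pi0,
                 summary = list(
                   n_tests = length(r),
                   n_selected = sum(mask),
                   n_taxa_selected = length(unique(rownames(r)[sel[, 1]])),
                   n_lipids_selected = length(unique(colnames(r)[sel[, 2]])),
                   class_share = class_share)),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Correlation screen: %d taxa x %d lipids (n = %d samples)\n",
              nrow(x$r), ncol(x$r), x$n))
  cat(sprintf("  selected pairs (|r| >= %.2f, q < %.2g): %d, spanning %d taxa and %d lipids\n",
              x$r_min, x$q_max, s$n_selected, s$n_taxa_selected,
              s$n_lipids_selected))
  if (length(s$class_share)) {
    cat("  class share of significant correlations:\n")
    cat(sprintf("    %s: %.0f%%\n", names(s$class_share),
                100 * s$class_share), sep = "")
  }
  invisible(x)
}

#' Significant pairs of a correlation screen
#'
#' @param screen a `correlation_screen`.
#' @return Data frame with `taxon`, `lipid`, `r`, `p`, `q`, sorted by
#'   decreasing |r|.
#' @export
significant_pairs <- function(screen) {
  sel <- which(screen$mask, arr.ind = TRUE)
  out <- data.frame(taxon = rownames(screen$r)[sel[, 1]],
                    lipid = colnames(screen$r)[sel[, 2]],
                    r = screen$r[sel], p = screen$p[sel], q = screen$q[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-way average-linkage clustering of a correlation matrix
#'
#' Restricts the matrix to rows and columns with at least one selected cell
#' (when given a screen), then clusters rows and columns by average-linkage
#' (UPGMA) hierarchical clustering of the distance `1 - Pearson correlation`
#' between the correlation profiles.  Ties are broken by input order
#' (deterministic).
#'
#' @param x a `correlation_screen` or a numeric matrix.
#' @param require_significant when `x` is a screen: keep only features with
#'   at least one selected correlation (default `TRUE`).
#' @return List with `matrix` (the clustered submatrix), `row_order`,
#'   `col_order` (leaf orders) and `row_hclust` / `col_hclust` dendrograms.
#' @export
two_way_cluster <- function(x, require_significant = TRUE) {
  if (inherits(x, "correlation_screen")) {
    r <- x$r
    if (require_significant) {
      keep_r <- rowSums(x$mask) > 0
      keep_c <- colSums(x$mask) > 0
      check_that(sum(keep_r) >= 2 && sum(keep_c) >= 2,
                 "need >= 2 rows and columns with a significant cell")
      r <- r[keep_r, keep_c, drop = FALSE]
    }
  } else {
    r <- as.matrix(x)
  }
  check_that(nrow(r) >= 2 && ncol(r) >= 2, "matrix must be at least 2 x 2")
  dcor <- function(m) {
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[!is.finite(cc)] <- 0
    d <- 1 - cc
    diag(d) <- 0
    stats::as.dist(d)
  }
  hr <- stats::hclust(dcor(r), method = "average")
  hc <- stats::hclust(dcor(t(r)), method = "average")
  list(matrix = r[hr$order, hc$order, drop = FALSE],
       row_order = rownames(r)[hr$order], col_order = colnames(r)[hc$order],
       row_hclust = hr, col_hclust = hc)
}

#' Heatmap of the clustered correlation matrix
#'
#' Draws (or writes to PNG) the two-way clustered taxon x lipid correlation
#' heatmap, red for positive and blue for negative correlations.
#'
#' @param screen a `correlation_screen`.
#' @param path optional PNG output path; `NULL` draws to the active device.
#' @param ... passed to [two_way_cluster()].
#' @return The clustering, invisibly.
#' @export
plot_screen_heatmap <- function(screen, path = NULL, ...) {
  cl <- two_way_cluster(screen, ...)
  m <- cl$matrix
  if (!is.null(path)) {
    grDevices::png(path, width = 1200, height = 900)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  old <- graphics::par(mar = c(8, 10, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  col = pal, zlim = c(-1, 1), axes = FALSE,
                  main = "taxon x lipid biweight midcorrelation")
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                 labels = colnames(m), las = 2, cex.axis = 0.5)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                 labels = rev(rownames(m)), las = 2, cex.axis = 0.5)
  invisible(cl)
}

#' Write screen matrices and the significant pair list as TSV
#'
#' @param screen a `correlation_screen`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (what in c("r", "p", "q")) {
    write_feature_table(screen[[what]],
                        file.path(dir, sprintf("screen_%s.tsv", what)),
                        id_column = "taxon")
  }
  utils::write.table(significant_pairs(screen),
                     file.path(dir, "significant_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
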