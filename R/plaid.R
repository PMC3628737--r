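# Constant plaid-model biclustering of the taxon x lipid correlation
# matrix.  The model expresses the matrix as
#
#   Y_ij ~ mu0 + sum_k mu_k rho_ik kappa_jk
#
# with binary row memberships rho and column memberships kappa and a single
# scalar effect mu_k per layer.  Layers are fitted greedily on residuals and
# accepted only when their explained sum of squares exceeds that of layers
# fitted, with identical effort, to permuted reference matrices.

#' Parameters of the constant plaid fit
#'
#' @param max_layers maximum number of layers to attempt.
#' @param row_release,col_release release thresholds in (0, 1]: a row
#'   (column) is kept in a layer when its squared-error reduction is at
#'   least `(1 - release)` times the best row's (column's).  Higher values
#'   keep more members.
#' @param n_shuffles number of permuted reference matrices per layer
#'   acceptance test.  A candidate layer is accepted only when its explained
#'   sum of squares exceeds all `n_shuffles` references; under a pure-noise
#'   input the acceptance probability is therefore about
#'   `1 / (n_shuffles + 1)`, so the default of 30 keeps the false-layer
#'   rate near 3%.
#' @param background subtract a background effect (the grand mean) before
#'   fitting layers.
#' @param max_iterations membership-update iterations per layer.
#' @param n_starts random restarts per layer fit (best kept); shuffle
#'   references use the same number, keeping the acceptance test
#'   exchangeable.
#' @param seed integer seed.
#' @return An object of class `plaid_params`.
#' @export
plaid_params <- function(max_layers = 5, row_release = 0.7,
                         col_release = 0.7, n_shuffles = 30,
                         background = TRUE, max_iterations = 20,
                         n_starts = 5, seed = 1) {
  check_that(is_count(max_layers, 1), "'max_layers' must be >= 1")
  check_that(row_release > 0 && row_release <= 1 &&
               col_release > 0 && col_release <= 1,
             "release thresholds must lie in (0, 1]")
  check_that(is_count(n_shuffles, 0), "'n_shuffles' must be >= 0")
  check_that(is_count(max_iterations, 1), "'max_iterations' must be >= 1")
  check_that(is_count(n_starts, 1), "'n_starts' must be >= 1")
  structure(list(max_layers = max_layers, row_release = row_release,
                 col_release = col_release, n_shuffles = n_shuffles,
                 background = background, max_iterations = max_iterations,
                 n_starts = n_starts, seed = as.integer(seed)),
            class = "plaid_params")
}

# Fit a single constant layer to a residual matrix from one randomized
# start.  Initialisation is a seed cell drawn with probability
# proportional to the squared residual (a randomized rank-1-style seeding
# that lands inside strong blocks with high probability), grown from a
# 1 x 1 block.  Membership updates use the squared-error reduction of
# including row i over the current columns J at effect mu:
#   benefit_i = 2 * mu * sum_{j in J} Z_ij - |J| * mu^2
# rows with benefit >= (1 - release) * best are kept (likewise columns).
fit_one_layer <- function(z, row_release, col_release, max_iterations) {
  nr <- nrow(z); nc <- ncol(z)
  w <- as.vector(z)^2
  seed_cell <- if (sum(w) > 0) {
    sample.int(length(w), 1, prob = w)
  } else {
    sample.int(length(w), 1)
  }
  rows <- seq_len(nr) == ((seed_cell - 1) %% nr) + 1
  cols <- seq_len(nc) == ((seed_cell - 1) %/% nr) + 1
  empty <- list(rows = logical(nr), cols = logical(nc), mu = 0, ss = 0)
  for (it in seq_len(max_iterations)) {
    mu <- mean(z[rows, cols, drop = FALSE])
    if (!is.finite(mu) || mu == 0) return(empty)
    s_row <- rowSums(z[, cols, drop = FALSE])
    b_row <- 2 * mu * s_row - sum(cols) * mu^2
    best <- max(b_row)
    if (best <= 0) return(empty)
    rows_new <- b_row >= (1 - row_release) * best & b_row > 0
    mu <- mean(z[rows_new, cols, drop = FALSE])
    if (!is.finite(mu) || mu == 0) return(empty)
    s_col <- colSums(z[rows_new, , drop = FALSE])
    b_col <- 2 * mu * s_col - sum(rows_new) * mu^2
    best_c <- max(b_col)
    if (best_c <= 0) return(empty)
    cols_new <- b_col >= (1 - col_release) * best_c & b_col > 0
    if (identical(rows_new, rows) && identical(cols_new, cols)) {
      rows <- rows_new; cols <- cols_new
      break
    }
    rows <- rows_new; cols <- cols_new
  }
  mu <- mean(z[rows, cols, drop = FALSE])
  list(rows = rows, cols = cols, mu = mu,
       ss = sum(rows) * sum(cols) * mu^2)
}

fit_layer_multistart <- function(z, params) {
  best <- list(ss = -Inf)
  for (s in seq_len(params$n_starts)) {
    cand <- fit_one_layer(z, params$row_release, params$col_release,
                          params$max_iterations)
    if (cand$ss > best$ss) best <- cand
  }
  best
}

# permuted reference: all entries shuffled, destroying row/column structure
shuffle_matrix <- function(z) {
  matrix(z[sample.int(length(z))], nrow = nrow(z))
}

#' Fit a constant plaid model
#'
#' Iteratively fits constant layers to the residual matrix.  Each candidate
#' layer alternates effect and membership updates from a random start (best
#' of `n_starts` restarts); it is accepted only if its explained sum of
#' squares exceeds that of layers fitted with identical effort to
#' `n_shuffles` entry-permuted copies of the residual matrix.  Accepted
#' layers are subtracted and fitting continues; the first rejection (or
#' `max_layers`) stops the fit.  Deterministic given `params$seed`.
#'
#' @param values numeric matrix (finite entries), at least 2 x 2.
#' @param params a [plaid_params()].
#' @return Object of class `bicluster_set`: list with `layers` (each with
#'   logical `rows`, `cols`, effect `mu` and explained sum of squares
#'   `ss`), `background` (mu0), `residual` matrix and `params`.
#' @examples
#' m <- matrix(rnorm(600, sd = 0.1), 20, 30)
#' m[1:5, 1:6] <- m[1:5, 1:6] + 1
#' fit_plaid(m, plaid_params(seed = 1))
#' @export
fit_plaid <- function(values, params = plaid_params()) {
  check_that(is.matrix(values) && all(is.finite(values)),
             "'values' must be a finite numeric matrix")
  check_that(nrow(values) >= 2 && ncol(values) >= 2,
             "'values' must be at least 2 x 2")
  mu0 <- if (params$background) mean(values) else 0
  z <- values - mu0
  layers <- list()
  with_seed(params$seed, {
    for (k in seq_len(params$max_layers)) {
      cand <- fit_layer_multistart(z, params)
      if (cand$ss <= 0) break
      ref_ss <- vapply(seq_len(params$n_shuffles), function(s) {
        fit_layer_multistart(shuffle_matrix(z), params)$ss
      }, numeric(1))
      if (length(ref_ss) && cand$ss <= max(ref_ss)) break
      z[cand$rows, cand$cols] <- z[cand$rows, cand$cols] - cand$mu
      cand$row_names <- rownames(values)[cand$rows]
      cand$col_names <- colnames(values)[cand$cols]
      layers[[length(layers) + 1L]] <- cand
    }
  })
  structure(list(layers = layers, background = mu0, residual = z,
                 params = params,
                 dim_names = dimnames(values)),
            class = "bicluster_set")
}

#' @export
print.bicluster_set <- function(x, ...) {
  cat(sprintf("Constant plaid fit: %d accepted layer(s), background %.3f\n",
              length(x$layers), x$background))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  layer %d: %d rows x %d cols, effect %+.3f\n",
                i, sum(l$rows), sum(l$cols), l$mu))
  }
  invisible(x)
}

#' Summarise biclusters against a correlation screen
#'
#' Maps each layer's members back to taxon and lipid labels and reports the
#' mean correlation of the layer's cells.
#'
#' @param set a `bicluster_set` fitted on (a submatrix of) the screen's
#'   correlation matrix.
#' @param screen the `correlation_screen` the matrix came from (optional;
#'   used for the mean r of the layer's cells).
#' @return Data frame with one row per layer: `layer`, `n_taxa`,
#'   `n_lipids`, `effect`, `mean_r`, `taxa`, `lipids` (comma-separated).
#'   Empty layers are reported, not dropped.
#' @export
bicluster_summary <- function(set, screen = NULL) {
  if (!length(set$layers)) {
    return(data.frame(layer = integer(0), n_taxa = integer(0),
                      n_lipids = integer(0), effect = numeric(0),
                      mean_r = numeric(0), taxa = character(0),
                      lipids = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(set$layers), function(i) {
    l <- set$layers[[i]]
    mean_r <- if (!is.null(screen) && length(l$row_names) &&
                  length(l$col_names)) {
      mean(screen$r[l$row_names, l$col_names])
    } else NA_real_
    data.frame(layer = i, n_taxa = sum(l$rows), n_lipids = sum(l$cols),
               effect = l$mu, mean_r = mean_r,
               taxa = paste(l$row_names, collapse = ","),
               lipids = paste(l$col_names, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write bicluster layers as TSV
#'
#' One row per (layer, axis, member) with the layer effect.
#'
#' @param set a `bicluster_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_biclusters <- function(set, path) {
  rows <- list()
  for (i in seq_along(set$layers)) {
    l <- set$layers[[i]]
    if (length(l$row_names)) {
      rows[[length(rows) + 1L]] <- data.frame(
        layer = i, axis = "taxon", member = l$row_names, effect = l$mu,
        stringsAsFactors = FALSE)
    }
    if (length(l$col_names)) {
      rows[[length(rows) + 1L]] <- data.frame(
        layer = i, axis = "lipid", member = l$col_names, effect = l$mu,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(layer = integer(0), axis = character(0),
               member = character(0), effect = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
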