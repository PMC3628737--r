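# Correlation of taxa against a small enzymatically determined serum lipid
# panel (total cholesterol, LDL, HDL, triglycerides), using the identical
# robust-correlation + q-value machinery as the full lipidomics screen.

#' Taxon x enzymatic-panel correlation screen
#'
#' Biweight midcorrelation of every taxon against each panel analyte across
#' shared samples, with Storey q-values over all taxon x analyte tests and
#' the significant-pair selection reported in a wide table (one row per
#' taxon with at least one significant correlation, the correlation shown
#' where `q < q_max` and `|r| >= r_min`).
#'
#' @param abundance samples x taxa matrix (sample IDs as row names).
#' @param panel samples x analyte matrix (e.g. columns TC, LDL, HDL, TG in
#'   mmol/L).  Constant analytes are excluded with a warning.
#' @param r_min minimum absolute correlation for the significant table
#'   (default 0.45, tuned to a small panel where q-control does most of the
#'   work; the full-screen default of 0.5 applies to the lipidome screen).
#' @param q_max maximum q-value for selection.
#' @param tuning biweight tuning constant.
#' @return Object of class `panel_screen`: list with `r`, `p`, `q` (taxa x
#'   analytes), `mask`, `significant` (wide data frame of significant
#'   correlations), `n`, thresholds.
#' @export
panel_screen <- function(abundance, panel, r_min = 0.45, q_max = 0.05,
                         tuning = 9) {
  shared <- intersect(rownames(abundance), rownames(panel))
  check_that(length(shared) >= 10,
             sprintf("need >= 10 shared samples, found %d", length(shared)))
  x <- abundance[shared, , drop = FALSE]
  y <- as.matrix(panel[shared, , drop = FALSE])
  const <- apply(y, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning(sprintf("constant analyte(s) excluded: %s",
                    paste(colnames(y)[const], collapse = ", ")),
            call. = FALSE)
    y <- y[, !const, drop = FALSE]
  }
  check_that(ncol(y) >= 1, "no non-constant analytes")
  r <- suppressWarnings(bicor_matrix(x, y, tuning))
  n <- length(shared)
  p <- matrix(bicor_pvalue(as.vector(r), n), nrow = nrow(r),
              dimnames = dimnames(r))
  qv <- qvalues(as.vector(p))
  q <- matrix(qv, nrow = nrow(r), dimnames = dimnames(r))
  mask <- !is.na(r) & q < q_max & abs(r) >= r_min
  sig <- r
  sig[!mask] <- NA_real_
  keep <- rowSums(mask) > 0
  significant <- data.frame(taxon = rownames(r)[keep],
                            as.data.frame(round(sig[keep, , drop = FALSE],
                                                2)),
                            stringsAsFactors = FALSE, check.names = FALSE)
  rownames(significant) <- NULL
  structure(list(r = r, p = p, q = q, mask = mask,
                 significant = significant, n = n, r_min = r_min,
                 q_max = q_max, pi0 = attr(qv, "pi0")),
            class = "panel_screen")
}

#' @export
print.panel_screen <- function(x, ...) {
  cat(sprintf(
    "Enzymatic panel screen: %d taxa x %d analytes (n = %d samples)\n",
    nrow(x$r), ncol(x$r), x$n))
  cat(sprintf("  significant correlations (|r| >= %.2f, q < %.2g): %d\n",
              x$r_min, x$q_max, sum(x$mask)))
  if (nrow(x$significant)) print(x$significant, row.names = FALSE)
  invisible(x)
}

#' Write the panel screen's significant-correlation table as TSV
#'
#' Wide table: one row per implicated taxon, one column per analyte, the
#' correlation shown only where significant.
#'
#' @param screen a `panel_screen`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_screen <- function(screen, path) {
  utils::write.table(screen$significant, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "-")
  invisible(path)
}
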