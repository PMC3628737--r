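# Temporal (intra-individual) and population (inter-individual) profile
# similarity, group comparisons, and PCA ordination.

# Pearson correlation between two profile vectors with pairwise-complete
# handling; requires at least `min_overlap` shared finite features.
profile_cor <- function(x, y, min_overlap = 10) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_overlap) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Intra-individual profile similarity
#'
#' For every subject with samples at both time points, the Pearson
#' correlation between the subject's two feature profiles (on the log10
#' scale), summarised per group.
#'
#' @param values samples x features matrix, sample IDs as row names.
#' @param metadata data frame with `sample_id`, `subject`, `timepoint`,
#'   `group`.
#' @param tp_pair integer vector of length 2: the two time points compared.
#' @param min_overlap minimum shared finite features per subject.
#' @return List with `per_subject` (data frame: subject, group, r) and
#'   `by_group` (data frame: group, n, mean_r, sd_r).  Subjects missing a
#'   time point are excluded with a warning.
#' @export
intra_subject_similarity <- function(values, metadata, tp_pair = c(1, 2),
                                     min_overlap = 10) {
  check_that(length(tp_pair) == 2L, "'tp_pair' must have length 2")
  md <- metadata[metadata$sample_id %in% rownames(values), , drop = FALSE]
  subjects <- unique(md$subject)
  rows <- list()
  for (s in subjects) {
    id1 <- md$sample_id[md$subject == s & md$timepoint == tp_pair[1]]
    id2 <- md$sample_id[md$subject == s & md$timepoint == tp_pair[2]]
    if (length(id1) != 1L || length(id2) != 1L) {
      warning(sprintf("subject %s missing a time point; excluded", s),
              call. = FALSE)
      next
    }
    rows[[s]] <- data.frame(subject = s,
                            group = md$group[md$subject == s][1],
                            r = profile_cor(values[id1, ], values[id2, ],
                                            min_overlap),
                            stringsAsFactors = FALSE)
  }
  check_that(length(rows) > 0, "no subject has both time points")
  per_subject <- do.call(rbind, rows)
  rownames(per_subject) <- NULL
  by_group <- do.call(rbind, lapply(split(per_subject, per_subject$group),
                                    function(d) data.frame(
                                      group = d$group[1], n = nrow(d),
                                      mean_r = mean(d$r, na.rm = TRUE),
                                      sd_r = stats::sd(d$r, na.rm = TRUE),
                                      stringsAsFactors = FALSE)))
  rownames(by_group) <- NULL
  list(per_subject = per_subject, by_group = by_group, tp_pair = tp_pair)
}

#' Inter-individual profile similarity
#'
#' Mean Pearson correlation over all unordered subject pairs within each
#' group at one time point.
#'
#' @inheritParams intra_subject_similarity
#' @param tp time point index.
#' @return Data frame with `group`, `n_subjects`, `mean_r`, `sd_r` (mean and
#'   SD over subject pairs).  Groups with a single subject are reported with
#'   `NA` and a warning.
#' @export
inter_subject_similarity <- function(values, metadata, tp = 1,
                                     min_overlap = 10) {
  md <- metadata[metadata$sample_id %in% rownames(values) &
                   metadata$timepoint == tp, , drop = FALSE]
  check_that(nrow(md) > 0, sprintf("no samples at time point %s", tp))
  out <- lapply(split(md, md$group), function(d) {
    if (nrow(d) < 2L) {
      warning(sprintf("group %s has a single subject at tp %s; undefined",
                      d$group[1], tp), call. = FALSE)
      return(data.frame(group = d$group[1], n_subjects = nrow(d),
                        mean_r = NA_real_, sd_r = NA_real_,
                        stringsAsFactors = FALSE))
    }
    prof <- values[d$sample_id, , drop = FALSE]
    pr <- stats::cor(t(prof), use = "pairwise.complete.obs")
    rs <- pr[upper.tri(pr)]
    data.frame(group = d$group[1], n_subjects = nrow(d),
               mean_r = mean(rs, na.rm = TRUE),
               sd_r = stats::sd(rs, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare per-subject stability between two groups
#'
#' Two-sided Wilcoxon rank-sum test on per-subject intra-individual
#' correlations.
#'
#' @param report an `intra_subject_similarity()` result (or its
#'   `per_subject` data frame) covering both groups.
#' @param groups character vector of length 2 naming the groups compared.
#' @return List with `p_value`, `groups` and per-group medians.  Degenerate
#'   all-tied input yields `p = 1` with a warning.
#' @export
compare_group_stability <- function(report, groups = NULL) {
  per <- if (is.data.frame(report)) report else report$per_subject
  if (is.null(groups)) groups <- unique(per$group)
  check_that(length(groups) == 2L, "exactly two groups required")
  a <- per$r[per$group == groups[1]]
  b <- per$r[per$group == groups[2]]
  check_that(length(a) >= 1 && length(b) >= 1,
             "each group needs at least one subject")
  if (length(a) < 2 && length(b) < 2) {
    stop("insufficient data: both groups have a single subject",
         call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) {
    warning("all stability values tied; p = 1", call. = FALSE)
    p <- 1
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }
  list(p_value = p, groups = groups,
       medians = c(stats::median(a), stats::median(b)))
}

#' Full stability report for one omic
#'
#' Computes inter-individual similarity at every time point and
#' intra-individual similarity for consecutive time-point pairs, per group,
#' mirroring the layout groups x (between TP1..TPk, within TP-pairs).
#'
#' @inheritParams intra_subject_similarity
#' @return Object of class `stability_report`: list with `between` (per
#'   time point), `within` (per time-point pair), `per_subject`, and the
#'   group-difference p-value on the first within-pair.
#' @export
stability_report <- function(values, metadata, min_overlap = 10) {
  tps <- sort(unique(metadata$timepoint[metadata$sample_id %in%
                                          rownames(values)]))
  between <- do.call(rbind, lapply(tps, function(tp) {
    d <- inter_subject_similarity(values, metadata, tp, min_overlap)
    d$timepoint <- tp
    d
  }))
  pairs <- if (length(tps) > 1) {
    lapply(seq_len(length(tps) - 1), function(i) tps[c(i, i + 1)])
  } else list()
  within <- list()
  per_subject <- list()
  for (pp in pairs) {
    res <- intra_subject_similarity(values, metadata, pp, min_overlap)
    lab <- sprintf("TP%d vs TP%d", pp[1], pp[2])
    res$by_group$pair <- lab
    res$per_subject$pair <- lab
    within[[lab]] <- res$by_group
    per_subject[[lab]] <- res$per_subject
  }
  within <- do.call(rbind, within)
  per_subject <- do.call(rbind, per_subject)
  rownames(within) <- rownames(per_subject) <- NULL
  p <- if (!is.null(per_subject) &&
           length(unique(per_subject$group)) == 2) {
    first <- per_subject[per_subject$pair == per_subject$pair[1], ,
                         drop = FALSE]
    compare_group_stability(first)$p_value
  } else NA_real_
  structure(list(between = between, within = within,
                 per_subject = per_subject, group_diff_p = p),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Profile stability (Pearson r)\n\nBetween subjects:\n")
  print(x$between, row.names = FALSE)
  cat("\nWithin subjects:\n")
  print(x$within, row.names = FALSE)
  cat(sprintf("\nGroup difference (Wilcoxon, first pair): p = %.3g\n",
              x$group_diff_p))
  invisible(x)
}

#' Write a stability report as TSV
#'
#' @param report a `stability_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  between <- report$between
  between$pair <- sprintf("between TP%d", between$timepoint)
  between$timepoint <- NULL
  within <- report$within
  within$n_subjects <- within$n
  within$n <- NULL
  within$pair <- paste("within", within$pair)
  cols <- c("group", "pair", "n_subjects", "mean_r", "sd_r")
  utils::write.table(rbind(between[, cols], within[, cols]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Principal component scores of sample profiles
#'
#' Centred (not scaled) PCA of the samples x features matrix, for
#' visualising sample relationships.
#'
#' @param values samples x features matrix.
#' @param n_components number of components to return.
#' @return List with `scores` (samples x components), `explained` (fraction
#'   of variance per returned component, non-increasing) and `total_variance`.
#' @export
pca_scores <- function(values, n_components = 2) {
  check_that(nrow(values) >= 2, "need at least two samples")
  n_components <- min(n_components, nrow(values) - 1L, ncol(values))
  pc <- stats::prcomp(values, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  expl <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  k <- seq_len(min(n_components, ncol(pc$x)))
  list(scores = pc$x[, k, drop = FALSE], explained = expl[k],
       total_variance = tot)
}
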