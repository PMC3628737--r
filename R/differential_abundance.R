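# Moderated testing of per-taxon intervention effects and the empirical
# permutation-based power calculation.
#
# The linear model is fitted with subject-level blocking: with one sample
# per subject per time point, subject- and sample-level random effects are
# confounded, so the identifiable reading of the design is the paired
# within-subject contrast.  Per-taxon residual variances are shrunk towards
# a common prior by empirical Bayes, with the prior degrees of freedom d0
# and prior variance s0^2 estimated by the method of moments on the log
# residual variances (scaled-F working distribution).

# Newton inversion of the trigamma function (for the moments estimator).
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Method-of-moments estimation of (d0, s0^2) from per-feature sample
# variances s2 on d residual degrees of freedom.  Returns d0 = Inf
# (complete shrinkage towards the geometric-mean variance) when the moment
# system is inconsistent, with a warning.
estimate_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  check_that(sum(ok) >= 2, "need at least two positive residual variances")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  e_mean <- mean(e)
  e_var <- stats::var(e) * (sum(ok) - 1) / sum(ok) - trigamma(d / 2)
  if (is.na(e_var) || e_var <= 0) {
    warning("moment system inconsistent; using d0 = Inf (complete shrinkage)",
            call. = FALSE)
    d0 <- Inf
    # degenerate case: no excess dispersion of log variances.  Shrink to
    # the geometric mean of the observed s2 (no sampling-bias correction),
    # so that identical variances are a fixed point of the moderation.
    s0_2 <- exp(mean(z))
  } else {
    d0 <- 2 * trigamma_inverse(e_var)
    s0_2 <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

# Internal moderated testing given per-feature effects, variances, df and
# the unscaled variance multiplier v (Var(effect) = sigma^2 * v).
moderate_fit <- function(effect, s2, d, v) {
  prior <- estimate_prior(s2, d)
  d0 <- prior$d0
  s0_2 <- prior$s0_2
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d * s2) / (d0 + d)
  t_ord <- effect / sqrt(s2 * v)
  t_mod <- effect / sqrt(s2_post * v)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  list(effect = effect, s2 = s2, t = t_ord, moderated_t = t_mod,
       df = d, df_prior = d0, s2_prior = s0_2, df_total = df_total, p = p)
}

#' Moderated per-taxon contrast
#'
#' Fits per-taxon linear contrasts with empirical-Bayes variance shrinkage.
#' Two contrast types are supported:
#'
#' * `type = "paired"`: the within-subject difference between two time
#'   points (`timepoints[2]` minus `timepoints[1]`), optionally restricted
#'   to one group.  Subject blocking is handled exactly by differencing.
#' * `type = "two_group"`: an unpaired comparison of `groups[1]` minus
#'   `groups[2]` at one time point, with a pooled per-taxon variance.
#'
#' The per-taxon residual variance is shrunk as
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)` with `(d0, s0^2)` estimated
#' by the method of moments on log variances; the moderated t statistic
#' `effect / sqrt(s2_post * v)` is referred to a t distribution with
#' `d0 + d` degrees of freedom.
#'
#' @param values samples x taxa matrix (log10 scale).
#' @param metadata sample metadata (`sample_id`, `subject`, `timepoint`,
#'   `group`).
#' @param type `"paired"` or `"two_group"`.
#' @param timepoints length-2 vector for `"paired"`; single time point for
#'   `"two_group"`.
#' @param group group label restricting a paired contrast (`NULL` = all).
#' @param groups length-2 group labels for `"two_group"`.
#' @return Object of class `contrast_result`: data frame with per-taxon
#'   `effect` (log10 difference), `t`, `moderated_t`, `p`, `adj_p`
#'   (Benjamini-Hochberg) and `q` (Storey), plus attributes `df`,
#'   `df_prior` and `s2_prior`.
#' @export
fit_moderated_contrast <- function(values, metadata,
                                   type = c("paired", "two_group"),
                                   timepoints = c(1, 2), group = NULL,
                                   groups = NULL) {
  type <- match.arg(type)
  md <- metadata[metadata$sample_id %in% rownames(values), , drop = FALSE]
  if (type == "paired") {
    check_that(length(timepoints) == 2L, "'timepoints' must have length 2")
    if (!is.null(group)) md <- md[md$group %in% group, , drop = FALSE]
    s1 <- md[md$timepoint == timepoints[1], , drop = FALSE]
    s2m <- md[md$timepoint == timepoints[2], , drop = FALSE]
    subj <- intersect(s1$subject, s2m$subject)
    check_that(length(subj) >= 2,
               "fewer than 2 subjects with both time points")
    id1 <- s1$sample_id[match(subj, s1$subject)]
    id2 <- s2m$sample_id[match(subj, s2m$subject)]
    diffs <- values[id2, , drop = FALSE] - values[id1, , drop = FALSE]
    n <- length(subj)
    check_that(n - 1 >= 1, "zero residual degrees of freedom")
    effect <- colMeans(diffs)
    s2 <- apply(diffs, 2, stats::var)
    d <- n - 1
    v <- 1 / n
  } else {
    check_that(length(groups) == 2L, "'groups' must have length 2")
    tp <- timepoints[1]
    ga <- md[md$group == groups[1] & md$timepoint == tp, , drop = FALSE]
    gb <- md[md$group == groups[2] & md$timepoint == tp, , drop = FALSE]
    na <- nrow(ga); nb <- nrow(gb)
    check_that(na >= 2 && nb >= 2, "fewer than 2 subjects per cell")
    a <- values[ga$sample_id, , drop = FALSE]
    b <- values[gb$sample_id, , drop = FALSE]
    effect <- colMeans(a) - colMeans(b)
    s2 <- ((na - 1) * apply(a, 2, stats::var) +
             (nb - 1) * apply(b, 2, stats::var)) / (na + nb - 2)
    d <- na + nb - 2
    v <- 1 / na + 1 / nb
  }
  fit <- moderate_fit(effect, s2, d, v)
  out <- data.frame(taxon = colnames(values), effect = fit$effect,
                    t = fit$t, moderated_t = fit$moderated_t,
                    p = fit$p, adj_p = bh_adjust(fit$p),
                    q = as.numeric(qvalues(fit$p)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("contrast_result", "data.frame"),
            df = fit$df, df_prior = fit$df_prior, s2_prior = fit$s2_prior,
            df_total = fit$df_total, type = type)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment, monotone in rank and capped at 1 (a thin wrapper
#' around [stats::p.adjust()]).
#'
#' @param p vector of p-values; `NA` is propagated with a warning.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  check_that(is.numeric(p), "'p' must be numeric")
  if (anyNA(p)) warning("NA p-values propagated", call. = FALSE)
  check_that(all(p >= 0 & p <= 1, na.rm = TRUE),
             "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Default detection rule for the power calculation
#'
#' Flags a taxon when its Benjamini-Hochberg adjusted moderated p-value is
#' below `alpha` and (optionally) its absolute effect exceeds
#' `min_log2_effect` on the log2 scale.
#'
#' @param alpha adjusted-p threshold.
#' @param min_log2_effect minimum |effect| in log2 units; 0 disables the
#'   effect-size filter.
#' @return A function `(contrast_result, taxon_index) -> logical`.
#' @export
detection_rule <- function(alpha = 0.05, min_log2_effect = 0) {
  function(result, taxon) {
    idx <- if (is.character(taxon)) match(taxon, result$taxon) else taxon
    log2_eff <- result$effect[idx] / log10(2)
    isTRUE(result$adj_p[idx] < alpha &&
             abs(log2_eff) >= min_log2_effect)
  }
}

#' Empirical power calculation by permutation
#'
#' For each replicate: the sample rows of the data are randomly permuted
#' (destroying any real structure), `2 * n` samples are split into a
#' control and a treatment arm, a fold-change alteration is inserted into
#' one randomly chosen taxon in the treatment arm, Gaussian noise with the
#' original data's average per-taxon standard deviation is added, and the
#' detection rule (default: the moderated two-group contrast at
#' Benjamini-Hochberg adjusted p < 0.05) is applied to the altered taxon.
#' The detection fraction over replicates estimates the study's power.
#'
#' @param values samples x taxa matrix (log10 scale).
#' @param fold_change linear-scale fold change inserted (> 0; 2 means a
#'   doubling, i.e. +log10(2) on the log10 scale).  Set
#'   `log_scale = TRUE` to interpret `fold_change` directly as a log10
#'   shift.
#' @param n samples per arm (must satisfy `2 * n <= nrow(values)`).
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param noise_sd standard deviation of the added Gaussian noise; default
#'   is the average per-taxon SD of `values`.
#' @param detect detection function `(contrast_result, taxon) -> logical`;
#'   see [detection_rule()].
#' @param log_scale interpret `fold_change` as a log10 shift instead of a
#'   linear fold change.
#' @return Object of class `power_result`: list with `detection_rate`,
#'   `fold_change`, `n`, `reps`, `noise_sd`, `seed`.
#' @export
empirical_power <- function(values, fold_change, n, reps = 1000, seed = 1,
                            noise_sd = NULL, detect = detection_rule(),
                            log_scale = FALSE) {
  check_that(is.numeric(fold_change) && fold_change > 0 || log_scale,
             "'fold_change' must be > 0")
  check_that(is_count(n, 2), "'n' must be an integer >= 2")
  check_that(is_count(reps, 1), "'reps' must be >= 1")
  check_that(2 * n <= nrow(values),
             "2 * n exceeds the available samples")
  delta <- if (log_scale) fold_change else log10(fold_change)
  if (is.null(noise_sd)) noise_sd <- mean(apply(values, 2, stats::sd))
  p_tax <- ncol(values)
  md <- data.frame(sample_id = sprintf("perm%03d", seq_len(2 * n)),
                   subject = sprintf("perm%03d", seq_len(2 * n)),
                   timepoint = 1,
                   group = rep(c("control", "treatment"), each = n),
                   stringsAsFactors = FALSE)
  hits <- with_seed(seed, {
    vapply(seq_len(reps), function(b) {
      rows <- sample.int(nrow(values), 2 * n)
      x <- values[rows, , drop = FALSE]
      rownames(x) <- md$sample_id
      taxon <- sample.int(p_tax, 1)
      x[md$group == "treatment", taxon] <-
        x[md$group == "treatment", taxon] + delta
      x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow = nrow(x))
      # permuted + noised data has near-homogeneous variances, for which
      # complete shrinkage (d0 = Inf) is the expected moments outcome
      res <- suppressWarnings(
        fit_moderated_contrast(x, md, type = "two_group", timepoints = 1,
                               groups = c("treatment", "control")))
      detect(res, taxon)
    }, logical(1))
  })
  structure(list(detection_rate = mean(hits), fold_change = fold_change,
                 n = n, reps = reps, noise_sd = noise_sd, seed = seed),
            class = "power_result")
}

#' Power curve over sample sizes
#'
#' Runs [empirical_power()] for each sample size and returns the detection
#' rates as a data frame (TSV-ready).
#'
#' @inheritParams empirical_power
#' @param sample_sizes integer vector of per-arm sample sizes.
#' @return Data frame with `n` and `detection_rate`.
#' @export
power_curve <- function(values, fold_change, sample_sizes, reps = 200,
                        seed = 1, noise_sd = NULL,
                        detect = detection_rule()) {
  rates <- vapply(seq_along(sample_sizes), function(i) {
    empirical_power(values, fold_change, sample_sizes[i], reps,
                    seed = split_seed(seed, i), noise_sd = noise_sd,
                    detect = detect)$detection_rate
  }, numeric(1))
  data.frame(n = sample_sizes, detection_rate = rates)
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Empirical power: %.1f%% detection of %g-fold change (n = %d/arm, %d reps, noise SD %.3f)\n",
    100 * x$detection_rate, x$fold_change, x$n, x$reps, x$noise_sd))
  invisible(x)
}

#' Write a contrast result as TSV
#'
#' @param result a `contrast_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contrast_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
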