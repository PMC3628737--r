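# Independent oracles used across the test files.  These re-derive the
# statistics from their definitions by direct transcription / enumeration
# and are kept independent of the package implementation paths.

# Biweight midcorrelation by literal transcription of the defining formula.
brute_force_bicor <- function(x, y, tuning = 9) {
  mx <- median(x); my <- median(y)
  madx <- median(abs(x - mx)); mady <- median(abs(y - my))
  ux <- (x - mx) / (tuning * madx)
  uy <- (y - my) / (tuning * mady)
  wx <- (1 - ux^2)^2 * (abs(ux) < 1)
  wy <- (1 - uy^2)^2 * (abs(uy) < 1)
  num <- sum((x - mx) * wx * (y - my) * wy)
  den <- sqrt(sum((x - mx)^2 * wx^2) * sum((y - my)^2 * wy^2))
  num / den
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, computing each table's probability from binomial
# coefficients (no dhyper).
enumerate_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - n2); hi <- min(k, m)
  supp <- lo:hi
  logp <- lchoose(m, supp) + lchoose(n2, k - supp) - lchoose(m + n2, k)
  probs <- exp(logp)
  p_obs <- probs[supp == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by hand.
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# small balanced metadata for contrast tests
make_two_group_metadata <- function(n_per_group, groups = c("A", "B"),
                                    timepoint = 1) {
  n <- n_per_group * 2
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             subject = sprintf("s%02d", seq_len(n)),
             timepoint = timepoint,
             group = rep(groups, each = n_per_group),
             stringsAsFactors = FALSE)
}

make_paired_metadata <- function(n_subjects, group = "A") {
  md <- expand.grid(subject = sprintf("p%02d", seq_len(n_subjects)),
                    timepoint = 1:2, stringsAsFactors = FALSE)
  md$group <- group
  md$sample_id <- sprintf("%s.T%d", md$subject, md$timepoint)
  md
}
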