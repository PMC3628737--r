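# Synthetic paired microbiota/lipidomics cohort generator.
#
# Profiles are generated directly on the log10 scale from a three-component
# Gaussian variance model per feature:
#
#   x[s, t, f] = mu + m[f] + a[s, f] + e[s, t, f]
#
# with m ~ N(0, sigma2_shared) a feature effect shared by all subjects,
# a ~ N(0, sigma2_subject) a subject-specific feature effect stable over
# time, and e ~ N(0, sigma2_noise) per-sample noise.  Across features this
# yields expected inter-individual profile correlation
# sigma2_shared / total and intra-individual correlation
# (sigma2_shared + sigma2_subject) / total, which is how the defaults are
# calibrated to the observed stability of gut microbiota (0.94 within /
# 0.77 between subjects) and serum lipidome (0.92 / 0.90) profiles.

#' Specify a planted taxon-lipid association
#'
#' A shared latent variable embedded into one taxon column and a set of
#' lipid columns with loadings solved analytically so that the population
#' correlation between the taxon and each listed lipid equals `target_r`,
#' while each column's total variance is preserved.
#'
#' @param taxon taxon name (or column index into the abundance matrix).
#' @param lipids character vector of lipid species names (or indices), or
#'   `NULL` to select `n_lipids` species of `lipid_class` at cohort
#'   generation time.
#' @param target_r target population correlation, in (-1, 1).
#' @param lipid_class,n_lipids,ether used only when `lipids` is `NULL`:
#'   select `n_lipids` species of the class (optionally restricted to ether
#'   or non-ether species) when the cohort is generated.
#' @param min_carbons,max_carbons,min_double_bonds,max_double_bonds
#'   optional structural filters applied to the class-level selection, used
#'   to emulate motifs such as long-chain or highly unsaturated
#'   triglyceride blocks.
#' @return An object of class `planted_association`.
#' @export
planted_association <- function(taxon, lipids = NULL, target_r,
                                lipid_class = NULL, n_lipids = NULL,
                                ether = NA, min_carbons = NULL,
                                max_carbons = NULL, min_double_bonds = NULL,
                                max_double_bonds = NULL) {
  check_that(is.numeric(target_r) && length(target_r) == 1L &&
               abs(target_r) < 1,
             "'target_r' must be a single number with |target_r| < 1")
  check_that(!is.null(lipids) || (!is.null(lipid_class) &&
                                    is_count(n_lipids)),
             "give either 'lipids' or 'lipid_class' + 'n_lipids'")
  if (!is.null(lipids)) check_that(length(lipids) >= 1L,
                                   "'lipids' must be non-empty")
  structure(list(taxon = taxon, lipids = lipids, target_r = target_r,
                 lipid_class = lipid_class, n_lipids = n_lipids,
                 ether = ether, min_carbons = min_carbons,
                 max_carbons = max_carbons,
                 min_double_bonds = min_double_bonds,
                 max_double_bonds = max_double_bonds),
            class = "planted_association")
}

#' Specify a planted intervention effect
#'
#' A log10 fold change added to one taxon for all samples of one group at
#' one time point, emulating a transient probiotic-intake spike.
#'
#' @param taxon taxon name (or column index).
#' @param group group label, e.g. `"probiotic"`.
#' @param timepoint time point index.
#' @param log10_fold_change shift on the log10 abundance scale
#'   (`log10(2)` for a 2-fold change).
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(taxon, group, timepoint, log10_fold_change) {
  check_that(is.numeric(log10_fold_change) && length(log10_fold_change) == 1L
             && is.finite(log10_fold_change),
             "'log10_fold_change' must be a single finite number")
  structure(list(taxon = taxon, group = group, timepoint = timepoint,
                 log10_fold_change = log10_fold_change),
            class = "planted_effect")
}

#' Design of a synthetic paired cohort
#'
#' Defaults emulate a probiotic-intervention study in healthy adults:
#' 25 subjects (11 probiotic, 14 placebo), three faecal microbiota time
#' points with 131 genus-level taxa, serum lipidomes for 22 of the subjects
#' (8 probiotic / 14 placebo) at the first two time points with 407 lipid
#' species across 11 classes, variance components calibrated so intra- /
#' inter-individual profile correlations are 0.94 / 0.77 (microbiota) and
#' 0.92 / 0.90 (lipids), one planted probiotic-taxon spike, and three
#' planted taxon-lipid associations of magnitude 0.5-0.6.
#'
#' @param n_subjects number of subjects.
#' @param group_sizes named integer vector of per-group subject counts; must
#'   sum to `n_subjects`.
#' @param n_timepoints number of microbiota time points.
#' @param n_taxa number of genus-level taxa.
#' @param lipid_class_counts named integer vector, species per lipid class.
#' @param lipid_timepoints time points at which the lipidome is measured.
#' @param lipid_group_sizes per-group subject counts with lipidome data
#'   (first subjects of each group); defaults to all subjects.
#' @param variance_components list with elements `microbiota` and
#'   `lipidome`, each a numeric vector `c(shared=, subject=, noise=)` of
#'   non-negative variances (log10 scale), not all zero.
#' @param mean_level named numeric vector: baseline log10 level per omic.
#' @param planted_associations list of [planted_association()] objects.
#' @param planted_effect a [planted_effect()] object or `NULL`.
#' @param seed integer master seed; all randomness in
#'   [generate_cohort()] derives from it.
#' @return An object of class `cohort_design`.
#' @examples
#' d <- cohort_design(seed = 1)
#' d$n_taxa
#' @export
cohort_design <- function(n_subjects = 25,
                          group_sizes = c(probiotic = 11, placebo = 14),
                          n_timepoints = 3,
                          n_taxa = 131,
                          lipid_class_counts = c(TG = 150, PC = 100, PE = 55,
                                                 SM = 25, ChoE = 18,
                                                 lysoPC = 15, PA = 12,
                                                 PG = 10, PS = 10, Cer = 7,
                                                 lysoPE = 5),
                          lipid_timepoints = c(1, 2),
                          lipid_group_sizes = c(probiotic = 8, placebo = 14),
                          variance_components = list(
                            microbiota = c(shared = 0.77, subject = 0.17,
                                           noise = 0.06),
                            lipidome = c(shared = 0.90, subject = 0.02,
                                         noise = 0.08)),
                          mean_level = c(microbiota = 3, lipidome = 6),
                          planted_associations = default_associations(),
                          planted_effect = default_effect(),
                          seed = 1L) {
  check_that(is_count(n_subjects, min = 2), "'n_subjects' must be >= 2")
  check_that(is_count(n_timepoints, min = 2), "'n_timepoints' must be >= 2")
  check_that(is_count(n_taxa, min = 2), "'n_taxa' must be >= 2")
  check_that(!is.null(names(group_sizes)) &&
               sum(group_sizes) == n_subjects,
             "'group_sizes' must be named and sum to n_subjects")
  # clamp the lipidome subset to the available subjects; groups absent from
  # lipid_group_sizes get full coverage
  lgs <- group_sizes
  for (g in names(group_sizes)) {
    if (g %in% names(lipid_group_sizes)) {
      lgs[g] <- min(lipid_group_sizes[[g]], group_sizes[[g]])
    }
  }
  lipid_group_sizes <- lgs
  check_that(all(lipid_timepoints %in% seq_len(n_timepoints)),
             "'lipid_timepoints' must be within 1..n_timepoints")
  check_that(!is.null(names(lipid_class_counts)) &&
               all(names(lipid_class_counts) %in% LIPID_CLASSES),
             "'lipid_class_counts' names must be known lipid classes")
  for (om in c("microbiota", "lipidome")) {
    vc <- variance_components[[om]]
    check_that(is.numeric(vc) && length(vc) == 3L && all(is.finite(vc)) &&
                 all(vc >= 0) && sum(vc) > 0,
               sprintf("variance components for %s must be finite, >= 0 and not all zero", om))
    names(variance_components[[om]]) <- c("shared", "subject", "noise")
  }
  check_that(is_count(abs(seed), min = 0), "'seed' must be an integer")
  structure(list(n_subjects = n_subjects, group_sizes = group_sizes,
                 n_timepoints = n_timepoints, n_taxa = n_taxa,
                 lipid_class_counts = lipid_class_counts,
                 lipid_timepoints = lipid_timepoints,
                 lipid_group_sizes = lipid_group_sizes,
                 variance_components = variance_components,
                 mean_level = mean_level,
                 planted_associations = planted_associations,
                 planted_effect = planted_effect,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Default planted taxon-lipid associations
#'
#' Ten associations reproducing the three association motifs the pipeline
#' is meant to detect in a probiotic-cohort integration: a dominant
#' positive block between a Clostridium-cluster-XIVa taxon and long-chain
#' triglycerides (plus a smaller saturated-TG partner), a positive
#' cholesteryl-ester association of an Actinobacteria genus, a negative
#' block between highly unsaturated high-carbon triglycerides and two
#' further taxa, and a negative ether-phosphatidylcholine block spanning
#' several Proteobacteria and Firmicutes.  Magnitudes are 0.5-0.61.
#'
#' @return List of [planted_association()] objects.
#' @export
default_associations <- function() {
  list(
    # positive TG block, long acyl chains
    planted_association(taxon = "Ruminococcus gnavus et rel.",
                        lipid_class = "TG", n_lipids = 31, target_r = 0.61,
                        min_carbons = 50),
    planted_association(taxon = "Dorea formicigenerans et rel.",
                        lipid_class = "TG", n_lipids = 4, target_r = 0.58,
                        max_carbons = 50, max_double_bonds = 1),
    # positive cholesteryl-ester association
    planted_association(taxon = "Collinsella",
                        lipid_class = "ChoE", n_lipids = 3,
                        target_r = 0.59),
    # negative block of highly unsaturated, high-carbon TGs
    planted_association(taxon = "Megamonas hypermegale et rel.",
                        lipid_class = "TG", n_lipids = 6, target_r = -0.55,
                        min_carbons = 56, min_double_bonds = 6),
    planted_association(taxon = "Actinomycetaceae",
                        lipid_class = "TG", n_lipids = 5, target_r = -0.55,
                        min_carbons = 56, min_double_bonds = 6),
    # negative ether-PC block
    planted_association(taxon = "Helicobacter pylori et rel.",
                        lipid_class = "PC", n_lipids = 5, ether = TRUE,
                        target_r = -0.55),
    planted_association(taxon = "Campylobacter",
                        lipid_class = "PC", n_lipids = 4, ether = TRUE,
                        target_r = -0.55),
    planted_association(taxon = "Moraxellaceae",
                        lipid_class = "PC", n_lipids = 4, ether = TRUE,
                        target_r = -0.55),
    planted_association(taxon = "Eubacterium cylindroides et rel.",
                        lipid_class = "PC", n_lipids = 4, ether = TRUE,
                        target_r = -0.5),
    planted_association(taxon = "Lactobacillus rhamnosus et rel.",
                        lipid_class = "PC", n_lipids = 3, ether = FALSE,
                        target_r = -0.5))
}

#' Default planted intervention effect
#'
#' A transient ~3-fold (0.5 log10 unit) spike of the ingested probiotic
#' taxon in the probiotic group at the during-intervention time point.
#'
#' @return A [planted_effect()] object.
#' @export
default_effect <- function() {
  planted_effect(taxon = "Lactobacillus rhamnosus et rel.",
                 group = "probiotic", timepoint = 2,
                 log10_fold_change = 0.5)
}

# ---------------------------------------------------------------------------
# feature naming

# A handful of recognisable genus-level taxon names at fixed positions; the
# remainder are generic uncultured phylotype groups.  The second column is
# the phylum (or Firmicutes order / Clostridium cluster) label used for
# taxon enrichment.
named_taxa <- function() {
  data.frame(
    taxon = c("Lactobacillus rhamnosus et rel.",
              "Ruminococcus gnavus et rel.",
              "Ruminococcus obeum et rel.",
              "Dorea formicigenerans et rel.",
              "Collinsella",
              "Eubacterium biforme et rel.",
              "Eubacterium cylindroides et rel.",
              "Helicobacter pylori et rel.",
              "Campylobacter",
              "Moraxellaceae",
              "Megamonas hypermegale et rel.",
              "Actinomycetaceae",
              "Bacteroides vulgatus et rel.",
              "Bacteroides plebeius et rel.",
              "Tannerella et rel.",
              "Aneurinibacillus",
              "Anaerofustis"),
    group = c("Bacilli", "Clostridium cluster XIVa",
              "Clostridium cluster XIVa", "Clostridium cluster XIVa",
              "Actinobacteria", "Clostridium cluster XVI",
              "Clostridium cluster XVI", "Proteobacteria", "Proteobacteria",
              "Proteobacteria", "Clostridium cluster IX", "Actinobacteria",
              "Bacteroidetes", "Bacteroidetes", "Bacteroidetes", "Bacilli",
              "Clostridium cluster XV"),
    stringsAsFactors = FALSE)
}

make_taxa <- function(n_taxa, seed) {
  base <- named_taxa()
  check_that(n_taxa >= nrow(base),
             sprintf("'n_taxa' must be at least %d", nrow(base)))
  n_fill <- n_taxa - nrow(base)
  pool <- c("Clostridium cluster XIVa", "Clostridium cluster IV",
            "Bacteroidetes", "Clostridium cluster IX", "Bacilli",
            "Proteobacteria", "Actinobacteria", "Uncultured Clostridiales")
  wts <- c(0.28, 0.22, 0.18, 0.08, 0.08, 0.07, 0.05, 0.04)
  fill_groups <- with_seed(seed, sample(pool, n_fill, replace = TRUE,
                                        prob = wts))
  fill <- data.frame(taxon = sprintf("Uncultured phylotype %03d et rel.",
                                     seq_len(n_fill)),
                     group = fill_groups, stringsAsFactors = FALSE)
  rbind(base, fill)
}

# Realistic total-carbon / double-bond ranges per class; combinations are
# sampled without replacement so names are unique.  A fraction of PC and PE
# species carry an ether linkage.
lipid_name_pool <- function(class, ether_frac = c(PC = 0.2, PE = 0.15)) {
  ranges <- list(
    TG     = list(c = 44:62, d = 0:10),
    PC     = list(c = 30:44, d = 0:8),
    PE     = list(c = 32:44, d = 0:8),
    SM     = list(c = 32:42, d = 0:3),
    ChoE   = list(c = 14:22, d = 0:6),
    lysoPC = list(c = 16:22, d = 0:4),
    lysoPE = list(c = 16:22, d = 0:4),
    PA     = list(c = 32:40, d = 0:6),
    PG     = list(c = 32:40, d = 0:6),
    PS     = list(c = 34:42, d = 0:6),
    Cer    = list(c = 34:42, d = 0:2))
  rg <- ranges[[class]]
  grid <- expand.grid(carbons = rg$c, double_bonds = rg$d)
  grid <- grid[grid$carbons > 2 * grid$double_bonds, , drop = FALSE]
  grid$class <- class
  grid$ether <- FALSE
  if (class %in% names(ether_frac)) {
    eth <- grid
    eth$ether <- TRUE
    grid <- rbind(grid, eth)
  }
  grid
}

make_lipid_names <- function(class_counts, seed) {
  out <- character(0)
  for (i in seq_along(class_counts)) {
    cls <- names(class_counts)[i]
    n <- class_counts[[i]]
    pool <- lipid_name_pool(cls)
    check_that(n <= nrow(pool),
               sprintf("requested %d %s species but only %d combinations available",
                       n, cls, nrow(pool)))
    # prefer non-ether combinations, then fill with ether variants
    ord <- with_seed(split_seed(seed, i), {
      idx_plain <- sample(which(!pool$ether))
      idx_eth <- if (any(pool$ether)) sample(which(pool$ether)) else integer(0)
      n_eth <- min(length(idx_eth), round(0.2 * n))
      c(idx_plain[seq_len(n - n_eth)], idx_eth[seq_len(n_eth)])
    })
    out <- c(out, format_lipid_name(pool[ord, , drop = FALSE]))
  }
  out
}

# ---------------------------------------------------------------------------
# profile generation

sample_ids <- function(subjects, timepoints) {
  as.vector(outer(subjects, timepoints,
                  function(s, t) sprintf("%s.T%d", s, t)))
}

cohort_metadata <- function(design) {
  subj <- sprintf("S%02d", seq_len(design$n_subjects))
  grp <- rep(names(design$group_sizes), design$group_sizes)
  md <- expand.grid(subject = subj, timepoint = seq_len(design$n_timepoints),
                    stringsAsFactors = FALSE)
  md$group <- grp[match(md$subject, subj)]
  md$sample_id <- sprintf("%s.T%d", md$subject, md$timepoint)
  # lipidome availability: the first lipid_group_sizes subjects per group at
  # the lipid time points
  lip_subj <- unlist(lapply(names(design$group_sizes), function(g) {
    in_g <- subj[grp == g]
    k <- design$lipid_group_sizes[g]
    if (is.na(k)) character(0) else in_g[seq_len(k)]
  }))
  md$has_lipids <- md$subject %in% lip_subj &
    md$timepoint %in% design$lipid_timepoints
  md[, c("sample_id", "subject", "timepoint", "group", "has_lipids")]
}

#' Generate one omic's profiles for a cohort design
#'
#' Draws the three-component Gaussian model described in the package
#' vignette: a feature effect shared across subjects, a subject-specific
#' feature effect stable over time points, and per-sample noise.  Expected
#' inter-individual profile correlation is `shared / total` and expected
#' intra-individual correlation `(shared + subject) / total`.
#'
#' @param design a [cohort_design()].
#' @param omic `"microbiota"` or `"lipidome"`.
#' @param feature_names optional feature names (defaults to generated taxa
#'   or lipid species names).
#' @param seed integer seed; defaults to a stream split from `design$seed`.
#' @return List with `values` (samples x features matrix, sample IDs as row
#'   names) and `metadata` (one row per sample).
#' @export
generate_profiles <- function(design, omic = c("microbiota", "lipidome"),
                              feature_names = NULL, seed = NULL) {
  omic <- match.arg(omic)
  vc <- design$variance_components[[omic]]
  check_that(all(is.finite(vc)) && all(vc >= 0),
             "non-finite or negative variance components")
  md <- cohort_metadata(design)
  if (omic == "lipidome") md <- md[md$has_lipids, , drop = FALSE]
  if (is.null(feature_names)) {
    feature_names <- if (omic == "microbiota") {
      make_taxa(design$n_taxa, split_seed(design$seed, 101))$taxon
    } else {
      make_lipid_names(design$lipid_class_counts, split_seed(design$seed, 102))
    }
  }
  p <- length(feature_names)
  subj <- unique(md$subject)
  if (is.null(seed)) {
    seed <- split_seed(design$seed, if (omic == "microbiota") 11 else 12)
  }
  vals <- with_seed(seed, {
    m <- rnorm(p, 0, sqrt(vc[["shared"]]))
    a <- matrix(rnorm(length(subj) * p, 0, sqrt(vc[["subject"]])),
                nrow = length(subj),
                dimnames = list(subj, NULL))
    e <- matrix(rnorm(nrow(md) * p, 0, sqrt(vc[["noise"]])), nrow = nrow(md))
    sweep(a[md$subject, , drop = FALSE] + e, 2,
          -(design$mean_level[[omic]] + m))
  })
  dimnames(vals) <- list(md$sample_id, feature_names)
  list(values = vals, metadata = md)
}

# ---------------------------------------------------------------------------
# planting

#' Plant a taxon-lipid association into generated matrices
#'
#' Embeds a shared standard-normal latent variable into the taxon column
#' and each listed lipid column.  Each column devotes the fraction
#' `f = |target_r|` of its (mean-centred) variance to the latent and keeps
#' the fraction `1 - f` of its original signal, so the population
#' correlation between the taxon and each lipid is
#' `sign(target_r) * sqrt(f * f) = target_r` exactly while every column's
#' total variance — and hence the cohort's calibrated stability structure —
#' is preserved.  The latent is partly subject-stable
#' (`subject_fraction` of its variance is shared by a subject's samples),
#' reflecting that taxon-lipid covariation is a property of subjects more
#' than of single samples.
#'
#' @param abundance samples x taxa matrix (sample IDs as row names).
#' @param lipids samples x lipid species matrix (sample IDs as row names;
#'   may cover a subset of the abundance samples).
#' @param assoc a [planted_association()] with explicit `taxon` and
#'   `lipids` columns.
#' @param seed integer seed for the latent draw.
#' @param subjects optional named vector mapping sample IDs to subject IDs
#'   (enables the subject-stable latent component); `NULL` draws a fully
#'   independent latent per sample.
#' @param subject_fraction fraction of the latent's variance shared within
#'   subject (used only with `subjects`).
#' @return List with modified `abundance` and `lipids` matrices and the
#'   variance fraction `loading` devoted to the latent.
#' @export
plant_association <- function(abundance, lipids, assoc, seed,
                              subjects = NULL, subject_fraction = 0.7) {
  check_that(abs(assoc$target_r) < 1, "|target_r| must be < 1")
  tx <- assoc$taxon
  if (is.character(tx)) {
    check_that(tx %in% colnames(abundance),
               sprintf("taxon '%s' not found in abundance matrix", tx))
  } else {
    check_that(tx >= 1 && tx <= ncol(abundance), "taxon index out of range")
  }
  lip <- assoc$lipids
  if (is.character(lip)) {
    check_that(all(lip %in% colnames(lipids)),
               "some lipid names not found in lipid matrix")
  } else {
    check_that(all(lip >= 1 & lip <= ncol(lipids)),
               "lipid index out of range")
  }
  if (assoc$target_r == 0) {
    return(list(abundance = abundance, lipids = lipids, loading = 0))
  }
  f <- abs(assoc$target_r)
  ids <- union(rownames(abundance), rownames(lipids))
  z <- with_seed(seed, {
    z_obs <- stats::setNames(rnorm(length(ids)), ids)
    if (is.null(subjects)) {
      z_obs
    } else {
      subj <- subjects[ids]
      check_that(!anyNA(subj), "every sample needs a subject mapping")
      z_subj <- stats::setNames(rnorm(length(unique(subj))), unique(subj))
      stats::setNames(sqrt(subject_fraction) * z_subj[subj] +
                        sqrt(1 - subject_fraction) * z_obs, ids)
    }
  })
  embed <- function(col, ids_here, sign = 1) {
    mu <- mean(col)
    s <- stats::sd(col)
    check_that(s > 0, "cannot plant an association into a constant column")
    mu + sqrt(1 - f) * (col - mu) + sign * sqrt(f) * s * z[ids_here]
  }
  abundance[, tx] <- embed(abundance[, tx], rownames(abundance),
                           sign(assoc$target_r))
  for (l in lip) {
    lipids[, l] <- embed(lipids[, l], rownames(lipids))
  }
  list(abundance = abundance, lipids = lipids, loading = f)
}

#' Plant an intervention effect into an abundance matrix
#'
#' Adds `log10_fold_change` to the named taxon for all samples of the named
#' group at the named time point; all other cells are untouched.
#'
#' @param abundance samples x taxa matrix.
#' @param metadata sample metadata with `sample_id`, `group`, `timepoint`.
#' @param effect a [planted_effect()].
#' @return Modified abundance matrix.
#' @export
plant_effect <- function(abundance, metadata, effect) {
  check_that(effect$group %in% metadata$group,
             sprintf("unknown group '%s'", effect$group))
  check_that(effect$timepoint %in% metadata$timepoint,
             sprintf("unknown timepoint '%s'", effect$timepoint))
  tx <- effect$taxon
  if (is.character(tx)) {
    check_that(tx %in% colnames(abundance),
               sprintf("taxon '%s' not found", tx))
  }
  sel <- metadata$sample_id[metadata$group == effect$group &
                              metadata$timepoint == effect$timepoint]
  sel <- intersect(sel, rownames(abundance))
  abundance[sel, tx] <- abundance[sel, tx] + effect$log10_fold_change
  abundance
}

# species matching an association's class/structure selector
association_pool <- function(assoc, lipid_annotation,
                             exclude = character(0)) {
  keep <- lipid_annotation$class == assoc$lipid_class &
    (is.na(assoc$ether) | lipid_annotation$ether == assoc$ether) &
    !(lipid_annotation$name %in% exclude)
  if (!is.null(assoc$min_carbons)) {
    keep <- keep & lipid_annotation$carbons >= assoc$min_carbons
  }
  if (!is.null(assoc$max_carbons)) {
    keep <- keep & lipid_annotation$carbons <= assoc$max_carbons
  }
  if (!is.null(assoc$min_double_bonds)) {
    keep <- keep & lipid_annotation$double_bonds >= assoc$min_double_bonds
  }
  if (!is.null(assoc$max_double_bonds)) {
    keep <- keep & lipid_annotation$double_bonds <= assoc$max_double_bonds
  }
  lipid_annotation$name[keep]
}

# resolve class-level lipid selectors into concrete species names,
# avoiding lipids already claimed by earlier associations
resolve_association <- function(assoc, lipid_annotation, seed,
                                exclude = character(0)) {
  if (!is.null(assoc$lipids)) return(assoc)
  pool <- association_pool(assoc, lipid_annotation, exclude)
  check_that(length(pool) >= assoc$n_lipids,
             sprintf("not enough %s species to plant association",
                     assoc$lipid_class))
  assoc$lipids <- with_seed(seed, sample(pool, assoc$n_lipids))
  assoc
}

# ---------------------------------------------------------------------------
# enzymatic panel

# Enzymatic serum lipid panel derived from the lipidome: analyte values are
# mixtures of a lipid-class signal and independent noise, scaled to
# population means (SD): TC 5.10 (1.02), LDL 3.00 (1.21), HDL 1.50 (0.33),
# TG 1.20 (0.71) mmol/L.
generate_panel <- function(lipids, lipid_annotation, associations, seed) {
  n <- nrow(lipids)
  std <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  driver <- function(class) {
    hit <- NULL
    for (a in associations) {
      cls <- unique(lipid_annotation$class[match(a$lipids,
                                                 lipid_annotation$name)])
      if (class %in% cls) { hit <- a; break }
    }
    if (is.null(hit)) return(rep(0, n))
    std(rowMeans(lipids[, hit$lipids, drop = FALSE]))
  }
  mix <- function(base, f, noise) {
    if (all(base == 0)) f <- 0
    sqrt(f) * base + sqrt(1 - f) * noise
  }
  with_seed(seed, {
    tg_base <- driver("TG")
    choe_base <- driver("ChoE")
    eps <- matrix(rnorm(4 * n), ncol = 4)
    tg <- 1.20 + 0.71 * mix(tg_base, 0.75, eps[, 1])
    hdl <- 1.50 + 0.33 * mix(-tg_base, 0.43, eps[, 2])
    ldl <- 3.00 + 1.21 * mix(choe_base, 0.73, eps[, 3])
    tc <- 5.10 + 1.02 * mix(choe_base, 0.70, eps[, 4])
    panel <- cbind(TC = pmax(tc, 0.05), LDL = pmax(ldl, 0.05),
                   HDL = pmax(hdl, 0.05), TG = pmax(tg, 0.05))
    rownames(panel) <- rownames(lipids)
    panel
  })
}

# ---------------------------------------------------------------------------
# full cohort

#' Generate a full synthetic paired cohort
#'
#' Composes profile generation, association planting, effect planting and
#' the enzymatic panel, and records every planted item in a ground-truth
#' ledger for parameter-recovery testing.  Deterministic given
#' `design$seed`.
#'
#' @param design a [cohort_design()].
#' @return An object of class `lipitax_cohort`: a list with elements
#'   `abundance` (samples x taxa log10 matrix), `lipids` (samples x species
#'   log10 matrix), `panel` (samples x 4 analyte matrix, mmol/L),
#'   `metadata`, `taxa` (taxon annotation with phylum/cluster labels),
#'   `lipid_annotation`, `ledger` (planted truths) and `design`.
#' @examples
#' cohort <- generate_cohort(cohort_design(seed = 7))
#' dim(cohort$abundance)
#' @export
generate_cohort <- function(design = cohort_design()) {
  check_that(inherits(design, "cohort_design"),
             "'design' must be a cohort_design object")
  taxa <- make_taxa(design$n_taxa, split_seed(design$seed, 101))
  lipid_names <- make_lipid_names(design$lipid_class_counts,
                                  split_seed(design$seed, 102))
  anno <- lipid_categories(parse_lipid_names(lipid_names))

  mic <- generate_profiles(design, "microbiota", feature_names = taxa$taxon)
  lip <- generate_profiles(design, "lipidome", feature_names = lipid_names)
  abundance <- mic$values
  lipids <- lip$values

  subjects <- stats::setNames(mic$metadata$subject, mic$metadata$sample_id)

  assoc_truth <- list()
  assocs <- design$planted_associations
  if (length(assocs)) {
    # resolve the most constrained selectors first so broad selections do
    # not exhaust a narrow structural pool (selections are disjoint)
    pool_size <- vapply(assocs, function(a) {
      if (!is.null(a$lipids)) return(0L)
      length(association_pool(a, anno))
    }, integer(1))
    used <- character(0)
    for (i in order(pool_size)) {
      a <- resolve_association(assocs[[i]], anno,
                               split_seed(design$seed, 200 + i),
                               exclude = used)
      used <- c(used, a$lipids)
      res <- plant_association(abundance, lipids, a,
                               seed = split_seed(design$seed, 300 + i),
                               subjects = subjects)
      abundance <- res$abundance
      lipids <- res$lipids
      assoc_truth[[i]] <- list(taxon = a$taxon, lipids = a$lipids,
                               target_r = a$target_r, loading = res$loading)
    }
  }
  if (!is.null(design$planted_effect)) {
    abundance <- plant_effect(abundance, mic$metadata, design$planted_effect)
  }
  panel <- generate_panel(lipids, anno,
                          lapply(assoc_truth, function(a)
                            planted_association(a$taxon, a$lipids,
                                                a$target_r)),
                          seed = split_seed(design$seed, 400))

  ledger <- list(associations = assoc_truth,
                 effect = design$planted_effect,
                 variance_components = design$variance_components,
                 expected_similarity = lapply(design$variance_components,
                                              function(vc) {
                                                tot <- sum(vc)
                                                c(intra = (vc[["shared"]] +
                                                             vc[["subject"]]) / tot,
                                                  inter = vc[["shared"]] / tot)
                                              }),
                 seed = design$seed)
  structure(list(abundance = abundance, lipids = lipids, panel = panel,
                 metadata = mic$metadata, taxa = taxa,
                 lipid_annotation = anno, ledger = ledger, design = design),
            class = "lipitax_cohort")
}

#' @export
print.lipitax_cohort <- function(x, ...) {
  cat("Synthetic paired cohort\n")
  cat(sprintf("  microbiota: %d samples x %d taxa\n",
              nrow(x$abundance), ncol(x$abundance)))
  cat(sprintf("  lipidome:   %d samples x %d species (%d classes)\n",
              nrow(x$lipids), ncol(x$lipids),
              length(unique(x$lipid_annotation$class))))
  cat(sprintf("  planted: %d association(s), %s effect\n",
              length(x$ledger$associations),
              if (is.null(x$ledger$effect)) "no" else "1"))
  invisible(x)
}

#' Write a cohort to TSV files
#'
#' Writes the abundance, lipid, panel and metadata tables (samples as rows,
#' first column the sample ID) plus the ground-truth ledger as a structured
#' key-value text file.
#'
#' @param cohort a `lipitax_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(cohort$abundance, file.path(dir, "abundance.tsv"))
  write_feature_table(cohort$lipids, file.path(dir, "lipids.tsv"))
  write_feature_table(cohort$panel, file.path(dir, "panel.tsv"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$taxa, file.path(dir, "taxa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  led <- cohort$ledger
  lines <- c(sprintf("seed\t%d", led$seed))
  for (om in names(led$variance_components)) {
    vc <- led$variance_components[[om]]
    lines <- c(lines, sprintf("variance_components.%s\t%s", om,
                              paste(sprintf("%s=%g", names(vc), vc),
                                    collapse = ",")))
  }
  if (!is.null(led$effect)) {
    e <- led$effect
    lines <- c(lines, sprintf("effect\ttaxon=%s;group=%s;timepoint=%d;log10_fc=%g",
                              e$taxon, e$group, e$timepoint,
                              e$log10_fold_change))
  }
  for (a in led$associations) {
    lines <- c(lines,
               sprintf("association\ttaxon=%s;target_r=%g;loading=%g;lipids=%s",
                       a$taxon, a$target_r, a$loading,
                       paste(a$lipids, collapse = ",")))
  }
  writeLines(lines, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
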