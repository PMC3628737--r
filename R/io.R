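# TSV readers/writers, flat key-value configuration, and the end-to-end
# pipeline driver.

#' Read a samples x features TSV table
#'
#' Expects a header row of feature names, a first column of sample IDs and
#' a numeric body.  Values are read with a fixed decimal point regardless of
#' locale.
#'
#' @param path input file path.
#' @param transpose set `TRUE` when the file stores features as rows.
#' @return Numeric matrix with sample IDs as row names and feature names as
#'   column names, in file order.
#' @export
read_feature_table <- function(path, transpose = FALSE) {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 path, bad, nf[bad], nf[1]), call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  check_that(ncol(df) >= 2, sprintf("%s: need an ID column plus data", path))
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("%s: duplicated sample ID '%s' (line %d)", path, dup[1],
                 which(ids == dup[1])[2] + 1L), call. = FALSE)
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num) && !all(is.na(num) == (body %in% c("NA", "")))) {
    bad <- which(is.na(num) & !(body %in% c("NA", "")), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: non-numeric value '%s' at line %d, column %d",
                 path, body[bad[1], bad[2]], bad[1] + 1L, bad[2] + 1L),
         call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(df)[-1])
  if (transpose) num <- t(num)
  num
}

#' Write a samples x features matrix as TSV
#'
#' Canonical format: header of feature names, first column the sample ID.
#' Reading the result with [read_feature_table()] and writing it again
#' reproduces the file byte-identically.
#'
#' @param values numeric matrix with row and column names.
#' @param path output file path.
#' @param id_column header of the first (ID) column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(values, path, id_column = "sample_id") {
  check_that(!is.null(rownames(values)) && !is.null(colnames(values)),
             "'values' must have row and column names")
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `subject`, `timepoint`, `group` (extra
#' columns are kept).  `(subject, timepoint)` pairs must be unique.
#'
#' @param path input file path.
#' @return Data frame.
#' @export
read_sample_metadata <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject", "timepoint", "group")
  missing_cols <- setdiff(need, colnames(md))
  check_that(length(missing_cols) == 0,
             sprintf("%s: missing column(s): %s", path,
                     paste(missing_cols, collapse = ", ")))
  key <- paste(md$subject, md$timepoint)
  check_that(!any(duplicated(key)),
             sprintf("%s: duplicated (subject, timepoint): %s", path,
                     key[duplicated(key)][1]))
  md
}

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value` (or `key<TAB>value`); `#` starts a
#' comment.  Values are converted to numbers where possible.
#'
#' @param path input file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=\t]", perl = TRUE)[[1]]
    check_that(length(kv) >= 2, sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full integrated analysis pipeline
#'
#' Executes stability analysis, the moderated intervention contrast, the
#' power calculation, the taxon x lipid correlation screen, two-way
#' clustering, plaid biclustering, enrichment and the enzymatic-panel
#' screen, writing every result table (TSV) plus a run log to `out_dir`.
#'
#' Inputs are given either as file paths (`abundance`, `lipids`,
#' `metadata`, optional `panel`, optional `taxa`) or, when all paths are
#' `NULL`, a synthetic cohort is generated with `seed`.
#'
#' @param abundance,lipids,metadata,panel,taxa input TSV paths (or `NULL`
#'   to simulate).
#' @param out_dir output directory.
#' @param r_min,q_max selection thresholds of the correlation screen.
#' @param long_chain_threshold lipid carbons threshold for enrichment.
#' @param power_fold_change,power_n,power_reps empirical power settings
#'   (`power_n = NULL` skips the power calculation).
#' @param plaid a [plaid_params()].
#' @param seed master seed (simulation, plaid, power).
#' @return List with all stage results, invisibly.
#' @export
run_pipeline <- function(abundance = NULL, lipids = NULL, metadata = NULL,
                         panel = NULL, taxa = NULL, out_dir = "lipitax_out",
                         r_min = 0.5, q_max = 0.05,
                         long_chain_threshold = 54,
                         power_fold_change = 2, power_n = 8,
                         power_reps = 200,
                         plaid = NULL, seed = 1) {
  t0 <- Sys.time()
  if (is.null(plaid)) plaid <- plaid_params(seed = split_seed(seed, 31))
  if (is.null(abundance)) {
    cohort <- generate_cohort(cohort_design(seed = seed))
    abundance_m <- cohort$abundance
    lipids_m <- cohort$lipids
    panel_m <- cohort$panel
    md <- cohort$metadata
    taxa_df <- cohort$taxa
  } else {
    check_that(!is.null(metadata), "metadata file is required")
    md <- read_sample_metadata(metadata)
    abundance_m <- read_feature_table(abundance)
    lipids_m <- if (!is.null(lipids)) read_feature_table(lipids) else NULL
    panel_m <- if (!is.null(panel)) read_feature_table(panel) else NULL
    taxa_df <- if (!is.null(taxa)) utils::read.delim(taxa,
                                                     stringsAsFactors = FALSE)
    else NULL
    cohort <- NULL
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logline <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat(sprintf("lipitax %s run %s\nseed\t%d\nr_min\t%g\nq_max\t%g\n",
              as.character(utils::packageVersion("lipitax")),
              format(t0, "%Y-%m-%d %H:%M:%S"), seed, r_min, q_max),
      file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  results <- list()
  results$stability_microbiota <- stage("stability", {
    rep <- stability_report(abundance_m, md)
    write_stability_report(rep, file.path(out_dir,
                                          "stability_microbiota.tsv"))
    rep
  })
  if (!is.null(lipids_m)) {
    results$stability_lipids <- stage("stability", {
      rep <- stability_report(lipids_m, md)
      write_stability_report(rep, file.path(out_dir, "stability_lipids.tsv"))
      rep
    })
  }
  logline("stability: done")

  results$contrast <- stage("differential abundance", {
    grp <- unique(md$group)[1]
    ct <- fit_moderated_contrast(abundance_m, md, type = "paired",
                                 timepoints = c(1, 2), group = grp)
    write_contrast_result(ct, file.path(out_dir, "contrast.tsv"))
    ct
  })
  logline("differential abundance: done")

  if (!is.null(power_n)) {
    results$power <- stage("power", {
      pw <- empirical_power(abundance_m, power_fold_change, power_n,
                            reps = power_reps, seed = split_seed(seed, 41))
      utils::write.table(
        data.frame(n = pw$n, fold_change = pw$fold_change,
                   detection_rate = pw$detection_rate, reps = pw$reps,
                   noise_sd = pw$noise_sd),
        file.path(out_dir, "power.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      pw
    })
    logline("power: done (rate %.3f)", results$power$detection_rate)
  }

  if (!is.null(lipids_m)) {
    results$screen <- stage("correlation screen", {
      sc <- correlation_screen(abundance_m, lipids_m, r_min = r_min,
                               q_max = q_max)
      write_screen(sc, out_dir)
      sc
    })
    logline("screen: %d significant pairs",
            results$screen$summary$n_selected)

    results$composition <- stage("lipid composition", {
      comp <- class_composition(lipids_m)
      utils::write.table(comp, file.path(out_dir, "lipid_classes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      comp
    })

    if (results$screen$summary$n_selected >= 4) {
      results$clustering <- stage("clustering", {
        plot_screen_heatmap(results$screen,
                            path = file.path(out_dir, "heatmap.png"))
      })
      results$biclusters <- stage("biclustering", {
        bc <- fit_plaid(results$clustering$matrix, plaid)
        write_biclusters(bc, file.path(out_dir, "biclusters.tsv"))
        bc
      })
      logline("biclustering: %d layer(s)", length(results$biclusters$layers))
      if (!is.null(taxa_df)) {
        results$enrichment <- stage("enrichment", {
          en <- bicluster_enrichment(results$biclusters, results$screen,
                                     taxa_df,
                                     long_chain_threshold =
                                       long_chain_threshold)
          utils::write.table(en, file.path(out_dir, "enrichment.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          en
        })
        logline("enrichment: done")
      }
    }
  }

  if (!is.null(panel_m)) {
    results$panel <- stage("panel", {
      ps <- panel_screen(abundance_m, panel_m, q_max = q_max)
      write_panel_screen(ps, file.path(out_dir, "panel_significant.tsv"))
      ps
    })
    logline("panel: %d significant correlations", sum(results$panel$mask))
  }
  results$cohort <- cohort
  logline("completed in %.1f s",
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(results)
}
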