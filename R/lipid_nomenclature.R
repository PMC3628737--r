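# Parsing of shorthand lipid species names and derivation of the structural
# categories used in enrichment analyses.

# The eleven lipid classes handled by the default grammar.
LIPID_CLASSES <- c("Cer", "ChoE", "lysoPC", "lysoPE", "PA", "PG", "PC",
                   "PE", "PS", "SM", "TG")

#' Parse shorthand lipid species names
#'
#' Lipid species are named `CLASS(C:D)` where `CLASS` is one of the eleven
#' supported abbreviations (Cer: ceramide; ChoE: cholesteryl ester; lysoPC:
#' lysophosphatidylcholine; lysoPE: lysophosphatidylethanolamine; PA:
#' phosphatidic acid; PG: phosphatidylglycerol; PC: phosphatidylcholine; PE:
#' phosphatidylethanolamine; PS: phosphatidylserine; SM: sphingomyelin; TG:
#' triglyceride), `C` is the total number of carbon atoms in the fatty acyl
#' chains and `D` the total number of double bonds.  A lowercase `e` after
#' the double-bond count (e.g. `"PC(38:4e)"`) marks an ether linkage.
#'
#' Names giving an explicit per-chain fatty acid composition (slash-separated
#' chains such as `"TG(16:0/18:1/18:2)"`) are outside the default grammar;
#' with `strict = FALSE` their carbons and double bonds are summed over the
#' chains instead of raising an error.
#'
#' @param names character vector of species names.
#' @param ether_regex regular expression (with two capture groups for carbons
#'   and double bonds) used to recognise the ether dialect inside the
#'   parentheses.  The default matches a trailing `"e"` on the double-bond
#'   count.
#' @param strict logical; if `TRUE` (default) slash-separated per-chain names
#'   are rejected, if `FALSE` their chains are summed.
#' @return A data frame with one row per name and columns `name`, `class`,
#'   `carbons`, `double_bonds`, `ether`.
#' @examples
#' parse_lipid_names(c("TG(54:5)", "ChoE(20:5)", "PC(38:4e)"))
#' @export
parse_lipid_names <- function(names,
                              ether_regex = "^([0-9]+):([0-9]+)e$",
                              strict = TRUE) {
  check_that(is.character(names) && length(names) >= 1L,
             "'names' must be a non-empty character vector")
  class_alt <- paste(LIPID_CLASSES, collapse = "|")
  outer_re <- paste0("^(", class_alt, ")\\((.+)\\)$")
  m <- regmatches(names, regexec(outer_re, names))
  out <- data.frame(name = names, class = NA_character_,
                    carbons = NA_integer_, double_bonds = NA_integer_,
                    ether = NA, stringsAsFactors = FALSE)
  for (i in seq_along(names)) {
    hit <- m[[i]]
    if (length(hit) == 0L) {
      # distinguish an unknown class token from a malformed name
      cls <- sub("\\(.*$", "", names[i])
      if (grepl("^[A-Za-z]+\\(.+\\)$", names[i]) &&
          !(cls %in% LIPID_CLASSES)) {
        stop(sprintf("unknown lipid class '%s' in name '%s'", cls, names[i]),
             call. = FALSE)
      }
      stop(sprintf("malformed lipid name '%s'", names[i]), call. = FALSE)
    }
    cls <- hit[2L]
    body <- hit[3L]
    if (grepl("/", body, fixed = TRUE)) {
      if (strict) {
        stop(sprintf(paste0("per-chain composition '%s' in '%s' is outside ",
                            "the default grammar (use strict = FALSE to sum ",
                            "chains)"), body, names[i]), call. = FALSE)
      }
      chains <- strsplit(body, "/", fixed = TRUE)[[1L]]
      cm <- regmatches(chains, regexec("^([0-9]+):([0-9]+)(e?)$", chains))
      if (any(lengths(cm) == 0L)) {
        stop(sprintf("malformed chain token in '%s'", names[i]),
             call. = FALSE)
      }
      carb <- sum(vapply(cm, function(h) as.integer(h[2L]), integer(1)))
      db <- sum(vapply(cm, function(h) as.integer(h[3L]), integer(1)))
      eth <- any(vapply(cm, function(h) h[4L] == "e", logical(1)))
    } else {
      em <- regmatches(body, regexec(ether_regex, body))[[1L]]
      if (length(em) >= 3L) {
        carb <- as.integer(em[2L]); db <- as.integer(em[3L]); eth <- TRUE
      } else {
        pm <- regmatches(body, regexec("^([0-9]+):([0-9]+)$", body))[[1L]]
        if (length(pm) == 0L) {
          stop(sprintf("malformed carbon:double-bond token '%s' in '%s'",
                       body, names[i]), call. = FALSE)
        }
        carb <- as.integer(pm[2L]); db <- as.integer(pm[3L]); eth <- FALSE
      }
    }
    if (carb < db) {
      warning(sprintf("'%s': double bonds (%d) exceed carbons (%d)",
                      names[i], db, carb), call. = FALSE)
    }
    out$class[i] <- cls
    out$carbons[i] <- carb
    out$double_bonds[i] <- db
    out$ether[i] <- eth
  }
  out
}

#' Reconstruct a species name from parsed fields
#'
#' Inverse of [parse_lipid_names()] on the default grammar.
#'
#' @param species data frame with columns `class`, `carbons`, `double_bonds`,
#'   `ether` (as returned by [parse_lipid_names()]).
#' @return Character vector of names.
#' @export
format_lipid_name <- function(species) {
  check_that(all(c("class", "carbons", "double_bonds", "ether") %in%
                   names(species)),
             "'species' must have class/carbons/double_bonds/ether columns")
  paste0(species$class, "(", species$carbons, ":", species$double_bonds,
         ifelse(species$ether, "e", ""), ")")
}

#' Structural category flags for lipid species
#'
#' Categories used in the enrichment analyses: carbon-count parity (odd-chain
#' fatty acids are not synthesised by humans and point to a dietary,
#' bacterial or marine origin), saturation class (SAFA: saturated, 0 double
#' bonds; MUFA: monounsaturated, 1; PUFA: polyunsaturated, 2 or more), a
#' long-chain flag, and ether linkage.
#'
#' @param species parsed species data frame from [parse_lipid_names()].
#' @param long_chain_threshold total acyl carbons at or above which a species
#'   counts as long-chain.  Default 54, aimed at triglyceride-class
#'   comparisons.
#' @return The input data frame with added columns `parity` (`"odd"`/
#'   `"even"`), `saturation` (`"SAFA"`/`"MUFA"`/`"PUFA"`) and `long_chain`
#'   (logical).
#' @examples
#' sp <- parse_lipid_names(c("TG(54:5)", "TG(51:2)", "PC(32:0)"))
#' lipid_categories(sp)
#' @export
lipid_categories <- function(species, long_chain_threshold = 54) {
  check_that(is_count(long_chain_threshold, min = 1),
             "'long_chain_threshold' must be a positive integer")
  species$parity <- ifelse(species$carbons %% 2L == 1L, "odd", "even")
  species$saturation <- ifelse(species$double_bonds == 0L, "SAFA",
                               ifelse(species$double_bonds == 1L, "MUFA",
                                      "PUFA"))
  species$long_chain <- species$carbons >= long_chain_threshold
  species
}

#' Lipid class composition of an intensity table
#'
#' Counts species per class and the share of the total (linear-scale) signal
#' contributed by each class.
#'
#' @param lipids samples x species numeric matrix of intensities.  Column
#'   names must be parseable species names.
#' @param log10_scale logical; if `TRUE` (default) values are log10
#'   intensities and are exponentiated before summing.
#' @return Data frame with columns `class`, `n_species`, `intensity_share`,
#'   sorted by decreasing share.  Shares sum to 1.
#' @export
class_composition <- function(lipids, log10_scale = TRUE) {
  check_that(is.matrix(lipids) && !is.null(colnames(lipids)),
             "'lipids' must be a matrix with species names as column names")
  anno <- tryCatch(parse_lipid_names(colnames(lipids)),
                   error = function(e) {
                     bad <- which(is.na(suppressWarnings(
                       vapply(colnames(lipids), function(nm) {
                         tryCatch({parse_lipid_names(nm); 1},
                                  error = function(e2) NA_real_)
                       }, numeric(1)))))
                     stop(sprintf("unparseable lipid names at columns: %s",
                                  paste(bad, collapse = ", ")),
                          call. = FALSE)
                   })
  vals <- if (log10_scale) 10^lipids else lipids
  per_species <- colSums(vals)
  tot <- sum(per_species)
  agg <- tapply(per_species, anno$class, sum)
  cnt <- table(anno$class)
  out <- data.frame(class = names(agg),
                    n_species = as.integer(cnt[names(agg)]),
                    intensity_share = as.numeric(agg) / tot,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$intensity_share), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a lipid annotation table
#'
#' Writes name, class, carbons, double bonds, ether flag, parity and
#' saturation class for each species as TSV.
#'
#' @param species annotated species data frame from [lipid_categories()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lipid_annotation <- function(species, path) {
  utils::write.table(species, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
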