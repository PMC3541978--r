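## Cohort-wide completion-pattern classification
##
## Across a reference cohort a module's completion-ratio profile falls into
## one of four patterns: universal (A; completed by most of the cohort, or
## nearly completed by most of it), restricted (B; completed by few),
## diversified (C; everything in between) and non-prokaryotic (D; completed
## by no organism).  Universal modules split into A-1 (completers dominate)
## and A-2 (high ratios dominate but full completion is scarce).  Modules
## completed by under 10% of the cohort are additionally flagged "rare".

#' Classifier thresholds
#'
#' Defaults follow the pattern definitions: "universal" means more than 70%
#' of the cohort, "restricted" less than 30%, "high ratio" means strictly
#' above 80%, and "rare" means completed by fewer than 10% of organisms.
#' All comparisons are strict.
#'
#' @param universal_threshold cohort fraction above which a module is
#'   universal.
#' @param restricted_threshold cohort fraction below which a module is
#'   restricted.
#' @param high_ratio_cutoff percent ratio above which an organism counts as
#'   a near-completer (A-2).
#' @param rare_threshold completer fraction below which a module is rare.
#' @return a `classifier_config`.
#' @export
classifier_config <- function(universal_threshold = 0.70,
                              restricted_threshold = 0.30,
                              high_ratio_cutoff = 80,
                              rare_threshold = 0.10) {
  if (!(restricted_threshold > 0 && restricted_threshold <= universal_threshold &&
        universal_threshold < 1)) {
    mc_stop("need 0 < restricted_threshold <= universal_threshold < 1")
  }
  if (!(high_ratio_cutoff > 0 && high_ratio_cutoff < 100)) {
    mc_stop("high_ratio_cutoff must be in (0, 100)")
  }
  structure(list(universal_threshold = universal_threshold,
                 restricted_threshold = restricted_threshold,
                 high_ratio_cutoff = high_ratio_cutoff,
                 rare_threshold = rare_threshold),
            class = "classifier_config")
}

#' Taxonomic-pattern labelling thresholds
#'
#' @param specificity_fraction fraction of completers that must share a
#'   taxon for a "-specific" (or joint) label.
#' @param max_joint_phyla maximum number of phyla allowed in a joint label.
#' @return a `taxonomic_pattern_config`.
#' @export
taxonomic_pattern_config <- function(specificity_fraction = 0.90,
                                     max_joint_phyla = 3L) {
  if (!(specificity_fraction > 0.5 && specificity_fraction <= 1)) {
    mc_stop("specificity_fraction must be in (0.5, 1]")
  }
  structure(list(specificity_fraction = specificity_fraction,
                 max_joint_phyla = as.integer(max_joint_phyla)),
            class = "taxonomic_pattern_config")
}

#' Classify a module's cohort completion profile
#'
#' Precedence: D if no organism completes; else A1 if the completer fraction
#' exceeds the universal threshold; else A2 if the fraction of organisms
#' above the high-ratio cutoff exceeds it; else B if the completer fraction
#' is below the restricted threshold; else C.  The rare flag is set
#' independently when the completer fraction is positive but below the rare
#' threshold.
#'
#' @param ratios numeric vector of per-organism completion ratios (percent).
#' @param config a [classifier_config()].
#' @param module_id optional id recorded on the result.
#' @return a `pattern_call` list: `module_id`, `pattern` (one of
#'   `"A1" "A2" "B" "C" "D"`), `rare`, `completer_fraction`, `high_fraction`.
#' @export
#' @examples
#' classify_pattern(c(rep(100, 80), rep(50, 20)))$pattern  # "A1"
classify_pattern <- function(ratios, config = classifier_config(),
                             module_id = NA_character_) {
  if (length(ratios) == 0L) mc_stop("empty cohort")
  if (anyNA(ratios) || any(ratios < 0 | ratios > 100)) {
    mc_stop("ratios must lie in [0, 100]")
  }
  cf <- mean(ratios == 100)
  hf <- mean(ratios > config$high_ratio_cutoff)
  pattern <-
    if (cf == 0) "D"
    else if (cf > config$universal_threshold) "A1"
    else if (hf > config$universal_threshold) "A2"
    else if (cf < config$restricted_threshold) "B"
    else "C"
  structure(list(module_id = module_id, pattern = pattern,
                 rare = cf > 0 && cf < config$rare_threshold,
                 completer_fraction = cf, high_fraction = hf),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat("<pattern_call> ",
      if (!is.na(x$module_id)) paste0(x$module_id, ": "),
      x$pattern, if (x$rare) " (rare)",
      sprintf("  completers %.4f, high %.4f", x$completer_fraction,
              x$high_fraction), "\n", sep = "")
  invisible(x)
}

lineage_at <- function(profile, rank) {
  lin <- profile$lineage
  if (rank %in% names(lin)) unname(lin[[rank]]) else NA_character_
}

#' Taxonomic pattern of a module's completers
#'
#' Labels which clades complete a module.  Rules, in order: no completers ->
#' `"Non-prokaryote"`; a single taxon covering at least
#' `specificity_fraction` of the completers at the most specific sub-domain
#' level wins (`"*Cyanobacteria*-specific"`, `"*Gammaproteobacteria*-specific"`);
#' else at most `max_joint_phyla` phyla jointly reaching the fraction give a
#' joint label (`"*Proteobacteria/Firmicutes*"`); else a dominant domain
#' gives a plain `"Bacteria-specific"` / `"Archaea-specific"`; else
#' `"Prokaryote"`.
#'
#' @param completers list of `genome_profile`s that complete the module.
#' @param cohort full cohort (completers must be a subset); used only for
#'   validation.
#' @param config a [taxonomic_pattern_config()].
#' @return a single label string.
#' @export
taxonomic_pattern <- function(completers, cohort = NULL,
                              config = taxonomic_pattern_config()) {
  if (length(completers) == 0L) return("Non-prokaryote")
  if (!is.null(cohort)) {
    cids <- vapply(cohort, `[[`, "", "organism_id")
    ids <- vapply(completers, `[[`, "", "organism_id")
    if (!all(ids %in% cids)) mc_stop("completers must be a subset of cohort")
  }
  n <- length(completers)
  ranks <- names(completers[[1L]]$lineage)
  dominant_at <- function(rank) {
    taxa <- vapply(completers, lineage_at, "", rank = rank)
    taxa <- taxa[!is.na(taxa) & nzchar(taxa)]
    if (!length(taxa)) return(NULL)
    tab <- sort(table(taxa), decreasing = TRUE)
    if (tab[1L] / n >= config$specificity_fraction) names(tab)[1L] else NULL
  }
  # single dominant taxon at the most specific sub-domain level
  for (rank in rev(setdiff(ranks, "domain"))) {
    top <- dominant_at(rank)
    if (!is.null(top)) return(paste0("*", top, "*-specific"))
  }
  # a few phyla jointly dominant (preferred over a domain-wide label)
  phyla <- vapply(completers, lineage_at, "", rank = "phylum")
  phyla <- phyla[!is.na(phyla) & nzchar(phyla)]
  if (length(phyla)) {
    tab <- sort(table(phyla), decreasing = TRUE)
    k_max <- min(config$max_joint_phyla, length(tab))
    cum <- cumsum(tab) / n
    for (k in seq_len(k_max)) {
      if (k >= 2L && cum[k] >= config$specificity_fraction) {
        return(paste0("*", paste(names(tab)[seq_len(k)], collapse = "/"), "*"))
      }
    }
  }
  # a single dominant domain
  top <- dominant_at("domain")
  if (!is.null(top)) return(paste0(top, "-specific"))
  "Prokaryote"
}

#' Classify every module of a completion matrix
#'
#' @param cmatrix a [completion_matrix()].
#' @param config a [classifier_config()].
#' @param tax_config a [taxonomic_pattern_config()]; taxonomic labels are
#'   computed from the cohort attached to the matrix.
#' @return a `pattern_calls` data.frame: one row per module with columns
#'   `module_id`, `pattern`, `rare`, `completer_fraction`, `high_fraction`,
#'   `taxonomic_pattern`.
#' @export
classify_matrix <- function(cmatrix, config = classifier_config(),
                            tax_config = taxonomic_pattern_config()) {
  stopifnot(inherits(cmatrix, "completion_matrix"))
  cohort <- attr(cmatrix, "cohort")
  calls <- lapply(rownames(cmatrix), function(mid) {
    pc <- classify_pattern(cmatrix[mid, ], config, module_id = mid)
    label <- if (is.null(cohort)) NA_character_ else {
      taxonomic_pattern(cohort[cmatrix[mid, ] == 100], cohort, tax_config)
    }
    data.frame(module_id = mid, pattern = pc$pattern, rare = pc$rare,
               completer_fraction = pc$completer_fraction,
               high_fraction = pc$high_fraction,
               taxonomic_pattern = label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  class(out) <- c("pattern_calls", "data.frame")
  out
}

#' @export
print.pattern_calls <- function(x, ...) {
  cat("<pattern_calls> ", nrow(x), " modules: ",
      paste(sprintf("%s=%d", names(table(x$pattern)), table(x$pattern)),
            collapse = " "),
      "; rare=", sum(x$rare), "\n", sep = "")
  NextMethod()
  invisible(x)
}
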