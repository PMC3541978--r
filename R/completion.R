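## Module completion ratio (MCR)
##
## The MCR of a module against a KO inventory is the percentage of its
## counting blocks whose Boolean expression is satisfied by the inventory:
## complexes and sequential steps are "and", alternatives are "or", optional
## items are always satisfied.  A module is "completed" only at exactly 100%.

#' Construct a genome/sample profile
#'
#' @param organism_id unique organism or sample identifier.
#' @param lineage ordered character vector of taxon labels, most inclusive
#'   first (domain, phylum, class, ...).  May be named by rank; unnamed
#'   vectors are given the default rank names.
#' @param kos character vector of KO identifiers present in the genome.
#' @return a `genome_profile`.
#' @export
#' @examples
#' genome_profile("eco", c("Bacteria", "Proteobacteria"), c("K00134", "K01652"))
genome_profile <- function(organism_id, lineage, kos = character()) {
  if (!is_string(organism_id)) mc_stop("organism_id must be a single string")
  lineage <- as.character(lineage)
  if (length(lineage) < 1L) mc_stop("lineage needs at least a domain")
  if (is.null(names(lineage))) {
    names(lineage) <- TAXON_RANKS[seq_along(lineage)]
  }
  kos <- unique(as.character(kos))
  bad <- kos[!is_ko_id(kos)]
  if (length(bad)) {
    mc_stop("invalid KO identifiers: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(organism_id = organism_id, lineage = lineage, kos = kos),
            class = "genome_profile")
}

#' @export
print.genome_profile <- function(x, ...) {
  cat("<genome_profile> ", x$organism_id, " [",
      paste(x$lineage, collapse = ";"), "] ",
      length(x$kos), " KOs\n", sep = "")
  invisible(x)
}

TAXON_RANKS <- c("domain", "phylum", "class", "order", "family",
                 "genus", "species")

#' Is a single block satisfied by a KO inventory?
#'
#' Recursive Boolean evaluation: a KO leaf is satisfied by membership,
#' complexes and step sequences need all children, alternatives need any
#' child, and optional items are always satisfied.
#'
#' @param block a `module_expr`.
#' @param kos character vector (or `genome_profile`) of available KOs.
#' @return logical scalar.
#' @export
#' @examples
#' block_satisfied(parse_definition("(K00134,K00150)"), "K00150")
block_satisfied <- function(block, kos) {
  if (inherits(kos, "genome_profile")) kos <- kos$kos
  stopifnot(inherits(block, "module_expr"))
  eval_node <- function(e) {
    switch(e$kind,
      ko = e$ko %in% kos,
      optional = TRUE,
      alt = {
        for (ch in e$children) if (eval_node(ch)) return(TRUE)
        FALSE
      },
      # complex and seq are both conjunctions
      {
        for (ch in e$children) if (!eval_node(ch)) return(FALSE)
        TRUE
      })
  }
  eval_node(block)
}

#' Module completion ratio against a KO inventory
#'
#' @param module a `module_definition`.
#' @param kos character vector of KO ids, or a `genome_profile`.
#' @param organism_id optional label recorded in the result.
#' @return a `completion_record` with fields `module_id`, `organism_id`,
#'   `blocks_total`, `blocks_satisfied` and `ratio` (percent, full
#'   precision; printed half-up at 1 decimal).
#' @export
#' @examples
#' mods <- paper_modules()$modules
#' m <- mods[["M00019_1"]]
#' kos <- setdiff(collection_kos(mods["M00019_1"]), "K11258")
#' completion_ratio(m, kos)
completion_ratio <- function(module, kos, organism_id = NA_character_) {
  stopifnot(inherits(module, "module_definition"))
  if (inherits(kos, "genome_profile")) {
    organism_id <- kos$organism_id
    kos <- kos$kos
  }
  blocks <- top_level_blocks(module)
  sat <- sum(vapply(blocks, block_satisfied, TRUE, kos = kos))
  structure(
    list(module_id = module$module_id,
         organism_id = organism_id,
         blocks_total = length(blocks),
         blocks_satisfied = as.integer(sat),
         ratio = 100 * sat / length(blocks)),
    class = "completion_record")
}

#' @export
print.completion_record <- function(x, ...) {
  cat("<completion_record> ", x$module_id,
      if (!is.na(x$organism_id)) paste0(" / ", x$organism_id),
      ": ", x$blocks_satisfied, "/", x$blocks_total, " blocks = ",
      sprintf("%.1f", round_half_up(x$ratio, 1)), "%\n", sep = "")
  invisible(x)
}

#' Completion matrix over a module collection and a cohort
#'
#' Computes the full module x organism matrix of completion ratios,
#' deterministically ordered by module id then organism id.
#'
#' @param modules a `module_collection`.
#' @param cohort list of `genome_profile` objects.
#' @return a `completion_matrix`: numeric matrix (percent) with module rows
#'   and organism columns; the cohort is attached as attribute `"cohort"`.
#' @export
completion_matrix <- function(modules, cohort) {
  stopifnot(inherits(modules, "module_collection"))
  if (length(modules) == 0L || length(cohort) == 0L) {
    mc_stop("modules and cohort must be non-empty")
  }
  ok <- vapply(cohort, inherits, TRUE, what = "genome_profile")
  if (!all(ok)) mc_stop("cohort must be a list of genome_profile objects")
  org_ids <- vapply(cohort, `[[`, "", "organism_id")
  if (anyDuplicated(org_ids)) {
    mc_stop("duplicate organism ids: ",
            paste(unique(org_ids[duplicated(org_ids)]), collapse = ", "))
  }
  mod_ids <- sort(names(modules))
  ord <- order(org_ids)
  cohort <- cohort[ord]
  org_ids <- org_ids[ord]
  block_sets <- lapply(modules[mod_ids], top_level_blocks)
  mat <- matrix(NA_real_, nrow = length(mod_ids), ncol = length(org_ids),
                dimnames = list(module_id = mod_ids, organism_id = org_ids))
  for (j in seq_along(cohort)) {
    kos <- cohort[[j]]$kos
    for (i in seq_along(mod_ids)) {
      blocks <- block_sets[[i]]
      sat <- 0L
      for (b in blocks) if (block_satisfied(b, kos)) sat <- sat + 1L
      mat[i, j] <- 100 * sat / length(blocks)
    }
  }
  structure(mat, class = c("completion_matrix", "matrix"),
            cohort = cohort)
}

#' @export
print.completion_matrix <- function(x, ...) {
  cat("<completion_matrix> ", nrow(x), " modules x ", ncol(x),
      " organisms\n", sep = "")
  y <- unclass(x)
  attr(y, "cohort") <- NULL
  print(round_half_up(y[seq_len(min(10L, nrow(y))),
                        seq_len(min(8L, ncol(y))), drop = FALSE], 1))
  if (nrow(x) > 10L || ncol(x) > 8L) cat("...\n")
  invisible(x)
}

#' @export
summary.completion_matrix <- function(object, ...) {
  data.frame(
    module_id = rownames(object),
    mean_ratio = round_half_up(rowMeans(object), 1),
    completer_fraction = rowMeans(object == 100),
    row.names = NULL)
}

#' Heatmap of a completion matrix
#'
#' @param x a `completion_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.completion_matrix <- function(x, ...) {
  y <- unclass(x)
  attr(y, "cohort") <- NULL
  graphics::image(seq_len(ncol(y)), seq_len(nrow(y)), t(y),
                  zlim = c(0, 100), xlab = "organism", ylab = "module",
                  axes = FALSE, col = grDevices::hcl.colors(25, "YlGnBu",
                                                            rev = TRUE), ...)
  graphics::axis(1, at = seq_len(ncol(y)), labels = colnames(y),
                 las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(y)), labels = rownames(y),
                 las = 1, cex.axis = 0.6)
  invisible(x)
}

#' Summary of how many genes map into modules
#'
#' Counts, for an annotation table, how many genes carry a KO assignment and
#' how many of those KOs occur as leaves of at least one module.
#'
#' @param annotations data.frame with columns `gene_id`, `ko_id` (NA for
#'   unassigned genes) and optionally `taxon`.
#' @param modules a `module_collection`.
#' @return a `mapping_summary` list: `n_genes`, `n_ko_assigned`, `n_mapped`,
#'   `frac_ko_assigned` (of all genes), `frac_mapped` (of KO-assigned genes).
#' @export
mapping_summary <- function(annotations, modules) {
  stopifnot(is.data.frame(annotations), inherits(modules, "module_collection"))
  n_genes <- nrow(annotations)
  assigned <- !is.na(annotations$ko_id) & nzchar(annotations$ko_id)
  module_kos <- collection_kos(modules)
  mapped <- assigned & annotations$ko_id %in% module_kos
  structure(
    list(n_genes = n_genes,
         n_ko_assigned = sum(assigned),
         n_mapped = sum(mapped),
         frac_ko_assigned = if (n_genes) sum(assigned) / n_genes else 0,
         frac_mapped = if (sum(assigned)) sum(mapped) / sum(assigned) else 0),
    class = "mapping_summary")
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat("<mapping_summary> ", x$n_genes, " genes; ",
      x$n_ko_assigned, " KO-assigned (",
      sprintf("%.1f", 100 * x$frac_ko_assigned), "%); ",
      x$n_mapped, " mapped to modules (",
      sprintf("%.1f", 100 * x$frac_mapped), "% of assigned)\n", sep = "")
  invisible(x)
}
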