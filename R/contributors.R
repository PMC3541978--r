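## Taxonomic contributor breakdown
##
## For a module of interest in a metagenome, decompose each counting block
## and each KO leaf within it into per-taxon gene counts — the computation
## behind per-step pie charts of which phyla drive each reaction.  A gene
## contributes to every block whose leaf set contains its KO (KOs are shared
## across blocks and modules, so the same gene may appear in several
## contexts).

#' Taxon label at a rank from a lineage string
#'
#' @param lineage semicolon-separated lineage strings, most inclusive rank
#'   first (`"Bacteria;Firmicutes;Bacilli"`).
#' @param rank one of `r paste(TAXON_RANKS, collapse = ", ")`.
#' @return character vector of labels (`NA` where the rank is absent).
#' @export
taxon_at_rank <- function(lineage, rank) {
  i <- match(rank, TAXON_RANKS)
  if (is.na(i)) {
    mc_stop("unknown taxonomic rank '", rank, "'; expected one of ",
            paste(TAXON_RANKS, collapse = ", "))
  }
  vapply(strsplit(as.character(lineage), ";", fixed = TRUE),
         function(l) if (length(l) >= i) trimws(l[[i]]) else NA_character_,
         NA_character_)
}

#' Per-taxon gene counts for every block and KO of a module
#'
#' @param module a `module_definition`.
#' @param annotations data.frame with `gene_id`, `ko_id` and `taxon`
#'   (semicolon-separated lineage, or a bare label when `rank` is
#'   `"domain"`).
#' @param rank taxonomy rank at which to aggregate (default `"phylum"`).
#' @return a `contributor_table` data.frame with columns `module_id`,
#'   `block_index`, `ko_id`, `taxon_label`, `gene_count`.  KOs with no
#'   assigned genes appear once with `taxon_label` NA and count 0.
#' @export
#' @examples
#' mods <- paper_modules()$modules
#' ann <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                   ko_id = c("K00134", "K00134", "K00150"),
#'                   taxon = c("Bacteria;Firmicutes", "Bacteria;Firmicutes",
#'                             "Bacteria;Bacteroidetes"))
#' contributor_breakdown(mods[["M00002_1"]], ann, rank = "phylum")
contributor_breakdown <- function(module, annotations, rank = "phylum") {
  stopifnot(inherits(module, "module_definition"), is.data.frame(annotations))
  if (!all(c("gene_id", "ko_id", "taxon") %in% names(annotations))) {
    mc_stop("annotations need columns gene_id, ko_id, taxon")
  }
  labels <- taxon_at_rank(annotations$taxon, rank)
  blocks <- top_level_blocks(module)
  rows <- list()
  for (b in seq_along(blocks)) {
    for (ko in expression_kos(blocks[[b]])) {
      hit <- !is.na(annotations$ko_id) & annotations$ko_id == ko
      if (!any(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          module_id = module$module_id, block_index = b, ko_id = ko,
          taxon_label = NA_character_, gene_count = 0L,
          stringsAsFactors = FALSE)
        next
      }
      tab <- table(labels[hit], useNA = "ifany")
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = module$module_id, block_index = b, ko_id = ko,
        taxon_label = names(tab) %||% NA_character_,
        gene_count = as.integer(tab), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$block_index, out$ko_id, -out$gene_count,
                   out$taxon_label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contributor_table", "data.frame")
  out
}

#' @export
print.contributor_table <- function(x, ...) {
  cat("<contributor_table> ", x$module_id[1L], ": ",
      max(x$block_index), " blocks, ",
      sum(x$gene_count), " gene assignments\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Pie charts of taxonomic contributors per block
#'
#' One pie per counting block, pooled over the block's KOs; the gene totals
#' appear in the panel titles.
#'
#' @param x a `contributor_table`.
#' @param ... passed to [graphics::pie()].
#' @export
plot.contributor_table <- function(x, ...) {
  blocks <- sort(unique(x$block_index))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(blocks)),
                       mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (b in blocks) {
    d <- x[x$block_index == b & x$gene_count > 0, , drop = FALSE]
    counts <- tapply(d$gene_count, d$taxon_label, sum)
    if (is.null(counts) || !length(counts)) {
      graphics::plot.new()
      graphics::title(sprintf("step %d (0)", b))
      next
    }
    graphics::pie(counts, main = sprintf("step %d (%d)", b, sum(counts)), ...)
  }
  invisible(x)
}
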