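## Readers and writers for the tool's tabular dialects
##
## All tables are TSV with a single header row; writers prepend
## "#"-prefixed metadata lines (tool and version) so outputs are
## self-describing, and readers skip any "#" line.  Hit tables are the
## headerless 12-column BLAST tabular format (-outfmt 6).  Ratios are
## serialised at 1 decimal, fractions at 4.

meta_lines <- function() {
  paste0("# modcomp ",
         as.character(utils::packageVersion("modcomp")))
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) mc_stop(what, " file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    mc_stop(what, " file ", path, " is missing columns: ",
            paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path, fmt = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_lines(), con)
  if (!is.null(fmt)) for (col in names(fmt)) {
    df[[col]] <- sprintf(fmt[[col]], df[[col]])
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

## ---- modules ---------------------------------------------------------------

#' Read a module flat file
#'
#' TSV with columns `module_id`, `module_type`, `category`, `name`,
#' `definition`; `#` lines are comments.
#'
#' @param path file path.
#' @return a `module_collection`.
#' @export
read_modules <- function(path) {
  df <- read_tsv_checked(path, c("module_id", "module_type", "category",
                                 "name", "definition"), "module")
  defs <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      module_definition(df$module_id[i], df$definition[i],
                        module_type = df$module_type[i],
                        name = df$name[i], category = df$category[i]),
      error = function(e) {
        mc_stop("module file ", path, ", row ", i, " (", df$module_id[i],
                "): ", conditionMessage(e))
      })
  })
  module_collection(defs)
}

#' Write a module collection to a flat file
#'
#' @param modules a `module_collection`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  stopifnot(inherits(modules, "module_collection"))
  df <- data.frame(
    module_id = vapply(modules, `[[`, "", "module_id"),
    module_type = vapply(modules, `[[`, "", "module_type"),
    category = vapply(modules, `[[`, "", "category"),
    name = vapply(modules, `[[`, "", "name"),
    definition = vapply(modules, function(m) serialize_expression(m$expression), ""),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

## ---- annotations & taxonomy ------------------------------------------------

#' Read a KO annotation table
#'
#' TSV with columns `gene_id`, `ko_id` (empty for unassigned genes) and an
#' optional `taxon` column (semicolon-separated lineage).
#'
#' @param path file path.
#' @return data.frame with `gene_id`, `ko_id` (NA when unassigned) and
#'   `taxon` when present.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "ko_id"), "annotation")
  if (anyDuplicated(df$gene_id)) {
    mc_stop("annotation file ", path, " has duplicate gene ids: ",
            paste(utils::head(unique(df$gene_id[duplicated(df$gene_id)]), 5),
                  collapse = ", "))
  }
  df$ko_id[!nzchar(df$ko_id) | is.na(df$ko_id)] <- NA_character_
  bad <- df$ko_id[!is.na(df$ko_id) & !is_ko_id(df$ko_id)]
  if (length(bad)) {
    mc_stop("annotation file ", path, " has malformed KO ids: ",
            paste(utils::head(unique(bad), 5), collapse = ", "))
  }
  df
}

#' Write a KO annotation table
#'
#' @param annotations data.frame with `gene_id`, `ko_id` and optionally
#'   `taxon`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write_tsv(annotations, path)
}

#' Read an organism taxonomy table
#'
#' TSV with `organism_id` followed by rank columns (`domain`, `phylum`,
#' `class`, ...).
#'
#' @param path file path.
#' @return data.frame keyed by `organism_id`.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_checked(path, c("organism_id", "domain"), "taxonomy")
  if (anyDuplicated(df$organism_id)) {
    mc_stop("taxonomy file ", path, " has duplicate organism ids")
  }
  df
}

#' Assemble genome profiles from annotation files and a taxonomy table
#'
#' @param annotation_paths named character vector of per-organism annotation
#'   files; names are organism ids.
#' @param taxonomy data.frame from [read_taxonomy()].
#' @return list of `genome_profile`s.
#' @export
read_cohort <- function(annotation_paths, taxonomy) {
  ids <- names(annotation_paths)
  if (is.null(ids)) mc_stop("annotation_paths must be named by organism id")
  lapply(ids, function(org) {
    ann <- read_annotations(annotation_paths[[org]])
    row <- taxonomy[taxonomy$organism_id == org, , drop = FALSE]
    if (nrow(row) == 0L) mc_stop("organism ", org, " absent from taxonomy")
    ranks <- intersect(TAXON_RANKS, names(taxonomy))
    lin <- unlist(row[1, ranks])
    lin <- lin[!is.na(lin) & nzchar(lin)]
    genome_profile(org, lin, ann$ko_id[!is.na(ann$ko_id)])
  })
}

## ---- hits ------------------------------------------------------------------

#' Read a BLAST tabular (-outfmt 6) hit file
#'
#' Headerless 12 columns: query, subject, percent identity, alignment
#' length, mismatches, gap opens, query start/end, subject start/end,
#' e-value, bit score.
#'
#' @param path file path.
#' @return data.frame with columns [HIT_COLUMNS].
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) mc_stop("hit file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE,
                      colClasses = c("character", "character",
                                     rep("numeric", 10))),
    error = function(e) mc_stop("hit file ", path, ": ", conditionMessage(e)))
  if (ncol(df) != 12L) {
    mc_stop("hit file ", path, " has ", ncol(df),
            " columns; expected 12 (BLAST -outfmt 6)")
  }
  names(df) <- HIT_COLUMNS
  df
}

#' Write a hit table in BLAST tabular format
#'
#' @param hits data.frame with columns [HIT_COLUMNS].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  validate_hits(hits)
  utils::write.table(hits[, HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- results ---------------------------------------------------------------

#' Write a completion matrix
#'
#' Module rows, organism columns; ratios at 1 decimal (half-up).
#'
#' @param cmatrix a `completion_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_completion_matrix <- function(cmatrix, path) {
  stopifnot(inherits(cmatrix, "completion_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_lines(), con)
  writeLines(paste(c("module_id", colnames(cmatrix)), collapse = "\t"), con)
  for (i in seq_len(nrow(cmatrix))) {
    writeLines(paste(c(rownames(cmatrix)[i],
                       sprintf("%.1f", round_half_up(cmatrix[i, ], 1))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a completion matrix written by [write_completion_matrix()]
#'
#' @param path file path.
#' @return a `completion_matrix` (no cohort attribute).
#' @export
read_completion_matrix <- function(path) {
  df <- read_tsv_checked(path, "module_id", "completion matrix")
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  dimnames(mat) <- list(module_id = df$module_id,
                        organism_id = colnames(df)[-1])
  structure(mat, class = c("completion_matrix", "matrix"))
}

#' Write pattern calls
#'
#' @param calls a `pattern_calls` data.frame from [classify_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pattern_calls <- function(calls, path) {
  write_tsv(as.data.frame(calls), path,
            fmt = list(completer_fraction = "%.4f", high_fraction = "%.4f"))
}

#' Write a contributor table
#'
#' @param contributors a `contributor_table` from [contributor_breakdown()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_contributors <- function(contributors, path) {
  write_tsv(as.data.frame(contributors), path)
}

#' Write KO assignments
#'
#' @param assignments a `ko_assignments` data.frame from [assign_ko()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  write_tsv(as.data.frame(assignments), path)
}

#' Read a branch-specification table
#'
#' TSV with columns `base_module_id`, `shared_definition`, `branch_label`,
#' `branch_definition`, one row per branch; rows of one module must be
#' contiguous and share the `shared_definition`.
#'
#' @param path file path.
#' @return list of `branch_spec`s keyed by base module id.
#' @export
read_branch_specs <- function(path) {
  df <- read_tsv_checked(path, c("base_module_id", "shared_definition",
                                 "branch_label", "branch_definition"),
                         "branch spec")
  specs <- lapply(split(df, df$base_module_id), function(d) {
    shared <- unique(d$shared_definition)
    if (length(shared) != 1L) {
      mc_stop("branch spec for ", d$base_module_id[1L],
              " has inconsistent shared definitions")
    }
    branch_spec(d$base_module_id[1L],
                shared = if (nzchar(shared)) shared else NULL,
                branches = stats::setNames(as.list(d$branch_definition),
                                           d$branch_label))
  })
  specs[order(names(specs))]
}

#' Write branch specifications
#'
#' @param specs a `branch_spec` or list of them.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_branch_specs <- function(specs, path) {
  if (inherits(specs, "branch_spec")) specs <- list(specs)
  rows <- lapply(specs, function(sp) {
    data.frame(
      base_module_id = sp$base_module_id,
      shared_definition = if (is.null(sp$shared_expression)) ""
                          else serialize_expression(sp$shared_expression),
      branch_label = names(sp$branches),
      branch_definition = vapply(sp$branches, serialize_expression, ""),
      stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
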