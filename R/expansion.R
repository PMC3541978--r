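## Submodule expansion for branching modules
##
## Some pathway modules branch at an intermediate compound into alternative
## products (e.g. heme biosynthesis splitting into protoheme and siroheme).
## For accurate completion ratios such a module is redefined as submodules:
## "_1" keeps the original scope (shared steps, branch region satisfiable by
## either branch), and "_k" (k >= 2) covers the shared steps plus one branch.
## The branch structure is supplied explicitly: the flat definition string
## carries no compound information, so branching cannot be inferred from it.

#' Construct a branch specification
#'
#' @param base_module_id base module id, e.g. `"M00121"` (no submodule
#'   suffix).
#' @param shared definition string or `module_expr` for the steps shared by
#'   all branches (up to the branching compound); may be `NULL` when the
#'   branches share nothing.
#' @param branches named list of definition strings or `module_expr`s, one
#'   per branch product, in declaration order.  Names are the branch labels.
#' @param name,category free text carried into the expanded definitions.
#' @return a `branch_spec`.
#' @export
#' @examples
#' branch_spec("M00121",
#'   shared = "K90601 K90602",
#'   branches = list(protoheme = "K90605 K90606", siroheme = "K90608"))
branch_spec <- function(base_module_id, shared = NULL, branches,
                        name = "", category = "") {
  if (!is_string(base_module_id) || !grepl("^M[0-9]{5}$", base_module_id)) {
    mc_stop("invalid base module id '", base_module_id, "'")
  }
  if (length(branches) < 2L) mc_stop("a branch spec needs >= 2 branches")
  labels <- names(branches)
  if (is.null(labels) || any(!nzchar(labels))) {
    mc_stop("every branch needs a label")
  }
  if (anyDuplicated(labels)) {
    mc_stop("duplicate branch labels: ",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  as_expr <- function(x, what) {
    if (is.null(x)) return(NULL)
    e <- if (inherits(x, "module_expr")) x else parse_definition(x)
    validate_expression(e)
    e
  }
  branch_exprs <- lapply(branches, as_expr)
  if (any(vapply(branch_exprs, is.null, TRUE))) {
    mc_stop("empty branch expression")
  }
  structure(
    list(base_module_id = base_module_id,
         shared_expression = as_expr(shared),
         branches = stats::setNames(branch_exprs, labels),
         name = name, category = category),
    class = "branch_spec")
}

#' @export
print.branch_spec <- function(x, ...) {
  cat("<branch_spec> ", x$base_module_id, ": ",
      length(x$branches), " branches (",
      paste(names(x$branches), collapse = ", "), ")\n", sep = "")
  if (!is.null(x$shared_expression)) {
    cat("  shared: ", serialize_expression(x$shared_expression), "\n", sep = "")
  }
  for (lab in names(x$branches)) {
    cat("  ", lab, ": ", serialize_expression(x$branches[[lab]]),
        "\n", sep = "")
  }
  invisible(x)
}

## sequence items of an expression (a non-seq expression is one item)
seq_items <- function(e) {
  if (is.null(e)) list() else if (e$kind == "seq") e$children else list(e)
}

make_seq <- function(items) {
  if (length(items) == 1L) items[[1L]] else expr_node("seq", items)
}

#' Expand a branching module into submodules
#'
#' Returns `1 + n_branches` definitions: `<base>_1` is the original scope
#' (shared steps followed by one block in which the branches are
#' alternatives), and `<base>_k` for `k >= 2` is the shared steps followed by
#' branch `k - 1` alone.
#'
#' @param spec a `branch_spec`.
#' @param module_type module type recorded on the outputs.
#' @return a `module_collection` of `1 + length(spec$branches)` submodules.
#' @export
#' @examples
#' sp <- paper_modules()$branch_spec
#' names(expand_branches(sp))
expand_branches <- function(spec, module_type = "pathway") {
  stopifnot(inherits(spec, "branch_spec"))
  shared_items <- seq_items(spec$shared_expression)
  labels <- names(spec$branches)

  branch_alt <- expr_node("alt", unname(spec$branches))
  original <- make_seq(c(shared_items, list(branch_alt)))

  defs <- list(module_definition(
    paste0(spec$base_module_id, "_1"), original,
    module_type = module_type,
    name = if (nzchar(spec$name)) paste0(spec$name, " (original)") else "",
    category = spec$category))

  for (k in seq_along(labels)) {
    sub <- make_seq(c(shared_items, seq_items(spec$branches[[k]])))
    defs <- c(defs, list(module_definition(
      paste0(spec$base_module_id, "_", k + 1L), sub,
      module_type = module_type,
      name = if (nzchar(spec$name)) paste0(spec$name, " (", labels[k], ")")
             else labels[k],
      category = spec$category)))
  }
  module_collection(defs)
}
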