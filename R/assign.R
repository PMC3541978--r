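## KO assignment from similarity hit tables
##
## KAAS-style orthology assignment: take precomputed similarity searches
## (BLAST 12-column tabular), reduce them to best hits per reference
## organism, keep bidirectional best hits (BBH), then assign each query the
## KO of its supporting BBH subjects, using a variable bit-score threshold
## and, when several candidate KOs remain, the taxonomy of the supporting
## subjects.  The search itself is external; this module only consumes its
## output.

HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end",
                 "e_value", "bit_score")

#' Bit-score threshold policy for KO assignment
#'
#' The fixed 60-bit floor is the classic KAAS cutoff.  When at least
#' `relax_min_hits` BBH subjects agree on a single KO, the floor is relaxed
#' to `relax_factor` times the query's top bit score (never above the fixed
#' floor), so well-supported assignments are not lost to a hard cutoff.
#'
#' @param fixed_floor minimum bit score (bits).
#' @param relax_min_hits number of agreeing BBH subjects that triggers
#'   relaxation.
#' @param relax_factor fraction of the top bit score used as the relaxed
#'   threshold, in (0, 1].
#' @return a `threshold_policy`.
#' @export
threshold_policy <- function(fixed_floor = 60, relax_min_hits = 5L,
                             relax_factor = 0.8) {
  if (fixed_floor < 0) mc_stop("fixed_floor must be >= 0")
  if (!(relax_factor > 0 && relax_factor <= 1)) {
    mc_stop("relax_factor must be in (0, 1]")
  }
  structure(list(fixed_floor = fixed_floor,
                 relax_min_hits = as.integer(relax_min_hits),
                 relax_factor = relax_factor),
            class = "threshold_policy")
}

validate_hits <- function(hits) {
  if (!is.data.frame(hits) || !all(HIT_COLUMNS %in% names(hits))) {
    mc_stop("hit table must contain the 12 BLAST tabular columns")
  }
  hits
}

validate_refs <- function(refs) {
  if (!is.data.frame(refs) ||
      !all(c("gene_id", "organism_id") %in% names(refs))) {
    mc_stop("reference table needs columns gene_id, organism_id",
            " (plus ko_id, lineage)")
  }
  if (anyDuplicated(refs$gene_id)) {
    mc_stop("duplicate reference gene ids: ",
            paste(utils::head(unique(refs$gene_id[duplicated(refs$gene_id)]), 5),
                  collapse = ", "))
  }
  refs
}

#' Best hit per (query, reference organism)
#'
#' Keeps, for every query and every reference organism it hits, the single
#' highest-scoring hit.  Ties break by lower e-value, then lexicographically
#' smaller subject id, so the reduction is a total order.
#'
#' @param hits data.frame of [HIT_COLUMNS] rows (see [read_hits()]).
#' @param refs reference gene table with `gene_id`, `organism_id` (and
#'   usually `ko_id`, `lineage`).
#' @return the winning hit rows with an added `organism_id` column.
#' @export
best_hits_per_organism <- function(hits, refs) {
  validate_hits(hits)
  validate_refs(refs)
  if (nrow(hits) == 0L) {
    out <- hits
    out$organism_id <- character(0)
    return(out)
  }
  idx <- match(hits$subject_id, refs$gene_id)
  if (anyNA(idx)) {
    missing <- unique(hits$subject_id[is.na(idx)])
    mc_stop("subject ids not in reference table: ",
            paste(utils::head(missing, 10), collapse = ", "))
  }
  hits$organism_id <- refs$organism_id[idx]
  ord <- order(hits$query_id, hits$organism_id,
               -hits$bit_score, hits$e_value, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  keep <- !duplicated(paste(hits$query_id, hits$organism_id, sep = "\r"))
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bidirectional best hits
#'
#' A (query, subject) pair survives iff the subject is the query's best hit
#' within the subject's organism (forward table) and the query is the
#' subject's best hit within the query's organism (reverse table).
#'
#' @param forward best-hit table from queries to the reference
#'   ([best_hits_per_organism()] output).
#' @param reverse best-hit table from reference genes back to the query set.
#' @return the forward rows forming BBH pairs.
#' @export
bidirectional_best <- function(forward, reverse) {
  fkey <- paste(forward$query_id, forward$subject_id, sep = "\r")
  rkey <- paste(reverse$subject_id, reverse$query_id, sep = "\r")
  out <- forward[fkey %in% rkey, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign KO identifiers to queries from BBH pairs
#'
#' Candidate KOs are those of BBH subjects scoring at or above the effective
#' threshold (see [threshold_policy()]).  Among multiple candidates the
#' preference order is: KO whose supporting subjects' lineages contain
#' `query_taxon` (when given), more supporting BBH pairs, higher summed bit
#' score, lexicographically smaller KO id.  Queries with no candidate stay
#' unassigned (`ko_id` NA).
#'
#' @param bbh_pairs output of [bidirectional_best()].
#' @param refs reference gene table (`gene_id`, `organism_id`, `ko_id`,
#'   `lineage` as semicolon-separated taxa).
#' @param policy a [threshold_policy()].
#' @param query_taxon optional taxon label of the query organism/sample used
#'   for disambiguation.
#' @param query_ids optional full set of query ids so queries without any
#'   BBH are reported as unassigned.
#' @return a `ko_assignments` data.frame: `query_id`, `ko_id`,
#'   `best_bit_score`, `n_supporting_bbh`, `method_note`.
#' @export
assign_ko <- function(bbh_pairs, refs, policy = threshold_policy(),
                      query_taxon = NULL, query_ids = NULL) {
  validate_refs(refs)
  idx <- match(bbh_pairs$subject_id, refs$gene_id)
  if (anyNA(idx)) {
    mc_stop("BBH subjects missing from reference table: ",
            paste(utils::head(unique(bbh_pairs$subject_id[is.na(idx)]), 10),
                  collapse = ", "))
  }
  bbh_pairs$ko_id <- refs$ko_id[idx]
  bbh_pairs$lineage <- if ("lineage" %in% names(refs)) refs$lineage[idx]
                       else NA_character_
  queries <- unique(c(bbh_pairs$query_id, query_ids))
  rows <- lapply(queries, function(q) {
    sub <- bbh_pairs[bbh_pairs$query_id == q & !is.na(bbh_pairs$ko_id), ,
                     drop = FALSE]
    unassigned <- data.frame(query_id = q, ko_id = NA_character_,
                             best_bit_score = NA_real_,
                             n_supporting_bbh = 0L,
                             method_note = "no_bbh_support",
                             stringsAsFactors = FALSE)
    if (nrow(sub) == 0L) return(unassigned)
    top <- max(sub$bit_score)
    support <- table(sub$ko_id)
    relaxed <- max(support) >= policy$relax_min_hits
    eff <- if (relaxed) min(policy$fixed_floor, policy$relax_factor * top)
           else policy$fixed_floor
    sub <- sub[sub$bit_score >= eff, , drop = FALSE]
    if (nrow(sub) == 0L) {
      unassigned$method_note <- "below_threshold"
      return(unassigned)
    }
    stats <- do.call(rbind, lapply(split(sub, sub$ko_id), function(d) {
      taxon_match <- if (is.null(query_taxon)) FALSE else {
        any(vapply(strsplit(d$lineage, ";", fixed = TRUE),
                   function(l) query_taxon %in% l, TRUE), na.rm = TRUE)
      }
      data.frame(ko_id = d$ko_id[1L], n = nrow(d),
                 sum_bits = sum(d$bit_score), max_bits = max(d$bit_score),
                 taxon_match = isTRUE(taxon_match), stringsAsFactors = FALSE)
    }))
    ord <- order(-stats$taxon_match, -stats$n, -stats$sum_bits, stats$ko_id)
    win <- stats[ord[1L], ]
    note <- paste0(if (relaxed) "relaxed_threshold" else "fixed_floor",
                   if (nrow(stats) > 1L && win$taxon_match) "+taxonomy" else "")
    data.frame(query_id = q, ko_id = win$ko_id,
               best_bit_score = win$max_bits,
               n_supporting_bbh = win$n, method_note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ko_assignments", "data.frame")
  out
}

#' Reassignment sensitivity TP / (TP + FN)
#'
#' Evaluates assignments against a truth table.  Every gene with a true KO
#' counts: a true positive when the assignment matches the truth, a false
#' negative when the gene is unassigned or assigned a different KO.
#'
#' @param truth data.frame with `gene_id`, `ko_id` (true assignments; genes
#'   with NA ko are ignored).
#' @param assigned a `ko_assignments` data.frame.
#' @return sensitivity in `[0, 1]`.
#' @export
reassignment_sensitivity <- function(truth, assigned) {
  stopifnot(is.data.frame(truth), is.data.frame(assigned))
  eval_set <- truth[!is.na(truth$ko_id) & nzchar(truth$ko_id), , drop = FALSE]
  if (nrow(eval_set) == 0L) mc_stop("empty evaluation set: no genes with a true KO")
  got <- assigned$ko_id[match(eval_set$gene_id, assigned$query_id)]
  tp <- sum(!is.na(got) & got == eval_set$ko_id)
  tp / nrow(eval_set)
}
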