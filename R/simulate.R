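## Fixture modules and synthetic-data generators
##
## paper_modules() encodes the worked-example module structures used
## throughout the documentation and tests: the 8-reaction TCA-cycle core
## module, the 6-step glycolysis core module, the 5-reaction glyoxylate
## cycle, the 7-step leucine biosynthesis module whose first reaction is the
## 3-subunit acetolactate synthase complex, the 14-component (plant) and
## 12-component (cyanobacteria) photosystem-I complexes, and the branching
## heme biosynthesis module (protoheme / siroheme).  KO identifiers with a
## documented role keep their real ids (K01652, K01653, K11258, K00134,
## K00150, K01637, K01638); all other leaves are placeholders from the
## reserved K90000-K99999 range so they cannot collide with real ids.
##
## The simulators generate cohorts with known ground-truth completion
## patterns and leave-clade-out similarity-hit tables with known KO truth;
## both are deterministic under a fixed seed.

#' In-document fixture modules and branch specification
#'
#' @return list with `modules` (a `module_collection` of M00009_1,
#'   M00002_1, M00012_1, M00019_1, M00163_1, M00163_2) and `branch_spec`
#'   (the branching heme-biosynthesis module M00121).
#' @export
#' @examples
#' vapply(paper_modules()$modules, n_blocks, 0L)
paper_modules <- function() {
  ph <- function(i) sprintf("K9%04d", i) # placeholder KO
  psa <- vapply(501:514, ph, "")
  mods <- module_collection(list(
    module_definition(
      "M00009_1",
      paste("(K90101+K90102,K90103) K90104 (K90105,K90106) K90107",
            "(K90108+K90109) K90110 K90111 (K90112,K90113)"),
      module_type = "pathway",
      name = "Citrate cycle, core module (synthetic KO structure)",
      category = "Central carbohydrate metabolism"),
    module_definition(
      "M00002_1",
      "K90201 (K00134,K00150) K90202 K90203 K90204 (K90205,K90206)",
      module_type = "pathway",
      name = "Glycolysis, core module involving three-carbon compounds (synthetic KO structure)",
      category = "Central carbohydrate metabolism"),
    module_definition(
      "M00012_1",
      "(K90301,K90302) K90303 K01637 K01638 (K90304,K90305)",
      module_type = "pathway",
      name = "Glyoxylate cycle (synthetic KO structure)",
      category = "Central carbohydrate metabolism"),
    module_definition(
      "M00019_1",
      paste("(K01652+K01653+K11258) K90401 K90402 K90403 K90404 K90405",
            "K90406"),
      module_type = "pathway",
      name = "Leucine biosynthesis (synthetic KO structure)",
      category = "Branched-chain amino acid metabolism"),
    module_definition(
      "M00163_1", paste(psa, collapse = "+"),
      module_type = "complex",
      name = "Photosystem I, plant (synthetic KO structure)",
      category = "Photosynthesis"),
    module_definition(
      "M00163_2", paste(psa[1:12], collapse = "+"),
      module_type = "complex",
      name = "Photosystem I, cyanobacteria (synthetic KO structure)",
      category = "Photosynthesis")))
  spec <- branch_spec(
    "M00121",
    shared = "K90601 K90602 K90603 K90604",
    branches = list(protoheme = "K90605 K90606 K90607",
                    siroheme = "K90608 K90609"),
    name = "Heme biosynthesis (synthetic KO structure)",
    category = "Cofactor and vitamin biosynthesis")
  list(modules = mods, branch_spec = spec)
}

PATTERNS <- c("A1", "A2", "B", "C", "D")

default_completer_fraction <- function(pattern) {
  switch(pattern, A1 = 0.85, A2 = 0.05, B = 0.15, C = 0.50, D = 0)
}

default_taxon_composition <- function() {
  data.frame(
    domain = c(rep("Bacteria", 6), rep("Archaea", 2)),
    phylum = c("Proteobacteria", "Firmicutes", "Actinobacteria",
               "Bacteroidetes", "Cyanobacteria", "Chloroflexi",
               "Euryarchaeota", "Crenarchaeota"),
    prob = c(0.30, 0.25, 0.15, 0.10, 0.05, 0.03, 0.08, 0.04),
    stringsAsFactors = FALSE)
}

#' Specification for a synthetic reference cohort
#'
#' @param n_organisms cohort size (default 768, the size of a full
#'   complete-genome reference set).
#' @param patterns character vector of target completion patterns, one per
#'   module to generate (`"A1" "A2" "B" "C" "D"`).
#' @param completer_fractions target fraction of organisms completing each
#'   module; NA entries take pattern defaults (A1 0.85, A2 0.05, B 0.15,
#'   C 0.50, D 0).
#' @param n_blocks blocks per generated module (>= 6 so ratios strictly
#'   between 80 and 100 exist).
#' @param taxon_composition data.frame `domain`, `phylum`, `prob`.
#' @param seed mandatory integer random seed.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_organisms = 768L, patterns,
                        completer_fractions = NULL, n_blocks = 10L,
                        taxon_composition = default_taxon_composition(),
                        seed) {
  if (missing(seed)) mc_stop("cohort_spec requires an explicit seed")
  patterns <- match.arg(patterns, PATTERNS, several.ok = TRUE)
  if (is.null(completer_fractions)) {
    completer_fractions <- rep(NA_real_, length(patterns))
  }
  stopifnot(length(completer_fractions) == length(patterns), n_blocks >= 6L)
  cf <- ifelse(is.na(completer_fractions),
               vapply(patterns, default_completer_fraction, 0),
               completer_fractions)
  for (i in seq_along(patterns)) {
    p <- patterns[i]
    feasible <- switch(p,
      A1 = cf[i] > 0.70,
      A2 = cf[i] > 0 && cf[i] <= 0.70,
      B = cf[i] > 0 && cf[i] < 0.30,
      C = cf[i] >= 0.30 && cf[i] <= 0.70,
      D = cf[i] == 0)
    if (!feasible) {
      mc_stop("infeasible target: pattern ", p, " with completer fraction ",
              cf[i], class = "modcomp_infeasible_spec")
    }
  }
  if (abs(sum(taxon_composition$prob) - 1) > 1e-8) {
    mc_stop("taxon composition probabilities must sum to 1")
  }
  structure(list(n_organisms = as.integer(n_organisms), patterns = patterns,
                 completer_fractions = cf, n_blocks = as.integer(n_blocks),
                 taxon_composition = taxon_composition,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## number of satisfied blocks drawn for one organism under a target pattern
draw_satisfied <- function(pattern, cf, B) {
  u <- stats::runif(1)
  switch(pattern,
    A1 = if (u < cf) B else sample(0:(B - 1L), 1L),
    # non-completers mostly sit just under completion (ratio > 80)
    A2 = if (u < cf) B else if (u < cf + 0.80) B - 1L
         else sample(0:(B - 2L), 1L),
    B = if (u < cf) B else sample(0:(B %/% 2L), 1L),
    C = if (u < cf) B else sample(0:(B - 2L), 1L),
    D = sample(0:(B - 1L), 1L))
}

#' Simulate a reference cohort with known completion patterns
#'
#' Generates one simple pathway module per requested pattern (one placeholder
#' KO per block, module-disjoint KO ranges so completion profiles are
#' independent), then samples each organism's KO inventory so the realised
#' cohort profile matches the target pattern.
#'
#' @param spec a [cohort_spec()].
#' @return list with `modules` (a `module_collection`), `profiles` (list of
#'   `genome_profile`), and `truth` (data.frame `module_id`, `pattern`,
#'   `completer_fraction` of generating targets).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_organisms = 50,
#'                                    patterns = c("A1", "D"), seed = 1))
#' classify_pattern(completion_matrix(sim$modules, sim$profiles)[1, ])$pattern
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_mod <- length(spec$patterns)
  B <- spec$n_blocks
  # module m, block b -> K9[5000 + (m-1)B + b - 1]; disjoint across modules
  # and clear of the fixed fixture placeholders (K90101-K90609)
  mod_kos <- lapply(seq_len(n_mod), function(m) {
    sprintf("K9%04d", 5000L + (m - 1L) * B + seq_len(B) - 1L)
  })
  modules <- module_collection(lapply(seq_len(n_mod), function(m) {
    module_definition(sprintf("M9%04d_1", m), paste(mod_kos[[m]], collapse = " "),
                      name = sprintf("synthetic %s-pattern module",
                                     spec$patterns[m]))
  }))
  comp <- spec$taxon_composition
  n <- spec$n_organisms
  taxon_idx <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$prob)
  profiles <- vector("list", n)
  for (j in seq_len(n)) {
    kos <- character(0)
    for (m in seq_len(n_mod)) {
      s <- draw_satisfied(spec$patterns[m], spec$completer_fractions[m], B)
      if (s > 0L) kos <- c(kos, mod_kos[[m]][sample.int(B, s)])
    }
    profiles[[j]] <- genome_profile(
      sprintf("org%04d", j),
      c(domain = comp$domain[taxon_idx[j]], phylum = comp$phylum[taxon_idx[j]]),
      kos)
  }
  truth <- data.frame(module_id = names(modules), pattern = spec$patterns,
                      completer_fraction = spec$completer_fractions,
                      stringsAsFactors = FALSE)
  list(modules = modules, profiles = profiles, truth = truth)
}

## reference tiers by clade distance from the query organism; same-KO bit
## scores fall in non-overlapping bands that decrease with distance, and
## off-KO scores sit below every band, which makes leave-clade-out
## sensitivity provably non-increasing
HIT_TIERS <- data.frame(
  tier = c("genus", "order", "class", "phylum", "outgroup"),
  organism_id = c("ref_esc", "ref_ent", "ref_gam", "ref_pro", "ref_out"),
  lineage = c(
    "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Erwiniaceae;Erwinia",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Vibrionales;Vibrionaceae;Vibrio",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Rhizobiaceae;Rhizobium",
    "Bacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus"),
  lo = c(280, 220, 160, 100, 45),
  hi = c(320, 260, 200, 140, 75),
  stringsAsFactors = FALSE)

#' Simulate leave-clade-out similarity hit tables
#'
#' Builds a synthetic reference database with one gene per truth KO in each
#' of five reference organisms at increasing clade distance from the query
#' (same genus, order, class, phylum, and an outgroup phylum), plus off-KO
#' decoy hits.  Same-KO bit scores decrease with clade distance; the
#' outgroup band straddles the 60-bit floor.  `leave_out` removes every
#' reference organism whose lineage contains the label, emulating
#' progressively larger database gaps.
#'
#' @param truth data.frame `gene_id`, `ko_id` of the query genes.
#' @param leave_out clade label to remove (`NULL` removes nothing), e.g.
#'   `"Escherichia"`, `"Enterobacterales"`, `"Gammaproteobacteria"`,
#'   `"Proteobacteria"`.
#' @param seed integer random seed.
#' @return list with `forward` and `reverse` hit tables (12-column BLAST
#'   tabular data.frames) and `refs` (reference-gene table that also lists
#'   the query genes under organism `"query_sample"`).
#' @export
simulate_hit_tables <- function(truth, leave_out = NULL, seed) {
  stopifnot(is.data.frame(truth), nrow(truth) > 0L,
            all(c("gene_id", "ko_id") %in% names(truth)))
  if (missing(seed)) mc_stop("simulate_hit_tables requires an explicit seed")
  set.seed(as.integer(seed))
  tiers <- HIT_TIERS
  if (!is.null(leave_out)) {
    keep <- !vapply(strsplit(tiers$lineage, ";", fixed = TRUE),
                    function(l) leave_out %in% l, TRUE)
    tiers <- tiers[keep, , drop = FALSE]
  }
  query_lineage <- "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia"
  refs <- data.frame(gene_id = character(), organism_id = character(),
                     ko_id = character(), lineage = character(),
                     stringsAsFactors = FALSE)
  fwd <- list()
  rev <- list()
  kos <- unique(truth$ko_id)
  mk_hit <- function(q, s, bits) {
    n <- length(q)
    data.frame(query_id = q, subject_id = s,
               percent_identity = round(stats::runif(n, 40, 99), 1),
               alignment_length = sample(120:400, n, replace = TRUE),
               mismatches = sample(0:80, n, replace = TRUE),
               gap_opens = sample(0:5, n, replace = TRUE),
               q_start = rep(1, n), q_end = rep(100, n),
               s_start = rep(1, n), s_end = rep(100, n),
               e_value = signif(10^(-bits / 3), 3),
               bit_score = round(bits, 1),
               stringsAsFactors = FALSE)
  }
  for (t in seq_len(nrow(tiers))) {
    for (ko in kos) {
      refs <- rbind(refs, data.frame(
        gene_id = paste0(tiers$organism_id[t], "_", ko),
        organism_id = tiers$organism_id[t], ko_id = ko,
        lineage = tiers$lineage[t], stringsAsFactors = FALSE))
    }
  }
  # one decoy gene (different KO universe) per remaining tier
  for (t in seq_len(nrow(tiers))) {
    refs <- rbind(refs, data.frame(
      gene_id = paste0(tiers$organism_id[t], "_decoy"),
      organism_id = tiers$organism_id[t], ko_id = "K99999",
      lineage = tiers$lineage[t], stringsAsFactors = FALSE))
  }
  for (g in seq_len(nrow(truth))) {
    q <- truth$gene_id[g]
    ko <- truth$ko_id[g]
    for (t in seq_len(nrow(tiers))) {
      bits <- stats::runif(1, tiers$lo[t], tiers$hi[t])
      same <- mk_hit(q, paste0(tiers$organism_id[t], "_", ko), bits)
      off <- mk_hit(q, paste0(tiers$organism_id[t], "_decoy"),
                    stats::runif(1, 20, 40))
      fwd <- c(fwd, list(same, off))
      # mirror scores so same-KO pairs are mutual best
      rs <- same
      rs$query_id <- same$subject_id
      rs$subject_id <- q
      ro <- off
      ro$query_id <- off$subject_id
      ro$subject_id <- q
      ro$bit_score <- round(stats::runif(1, 10, 19), 1)
      rev <- c(rev, list(rs, ro))
    }
  }
  # query genes appear in the reference table so the reverse search can be
  # reduced per organism
  refs <- rbind(refs, data.frame(
    gene_id = truth$gene_id, organism_id = "query_sample",
    ko_id = NA_character_, lineage = query_lineage, stringsAsFactors = FALSE))
  empty <- mk_hit(character(0), character(0), numeric(0))
  list(forward = if (length(fwd)) do.call(rbind, fwd) else empty,
       reverse = if (length(rev)) do.call(rbind, rev) else empty,
       refs = refs)
}
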