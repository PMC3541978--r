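mk_hits <- function(query, subject, bits, evalue = 10^(-bits / 3)) {
  n <- max(length(query), length(subject))
  data.frame(query_id = rep_len(query, n), subject_id = rep_len(subject, n),
             percent_identity = rep_len(90, n),
             alignment_length = rep_len(200, n), mismatches = rep_len(10, n),
             gap_opens = rep_len(0, n), q_start = rep_len(1, n),
             q_end = rep_len(200, n), s_start = rep_len(1, n),
             s_end = rep_len(200, n), e_value = rep_len(evalue, n),
             bit_score = rep_len(bits, n), stringsAsFactors = FALSE)
}

mk_refs <- function(gene_id, organism_id, ko_id = NA_character_,
                    lineage = "Bacteria;Proteobacteria") {
  data.frame(gene_id = gene_id, organism_id = organism_id, ko_id = ko_id,
             lineage = lineage, stringsAsFactors = FALSE)
}

test_that("best hit per organism uses bits, then e-value, then subject id", {
  refs <- mk_refs(c("r1", "r2", "r3"), c("orgA", "orgA", "orgB"))
  hits <- mk_hits("q1", c("r1", "r2", "r3"), c(120, 80, 100))
  best <- best_hits_per_organism(hits, refs)
  expect_equal(best$subject_id[best$organism_id == "orgA"], "r1")
  expect_equal(nrow(best), 2L)

  # equal bits -> lower e-value wins
  hits <- mk_hits("q1", c("r1", "r2"), c(100, 100), evalue = c(1e-20, 1e-30))
  expect_equal(best_hits_per_organism(hits, refs)$subject_id, "r2")

  # equal bits and e-value -> lexicographically smaller subject
  hits <- mk_hits("q1", c("r2", "r1"), c(100, 100), evalue = 1e-30)
  expect_equal(best_hits_per_organism(hits, refs)$subject_id, "r1")

  expect_equal(nrow(best_hits_per_organism(mk_hits(character(), character(),
                                                   numeric()), refs)), 0L)
  expect_error(best_hits_per_organism(mk_hits("q1", "ghost", 100), refs),
               "ghost")
})

test_that("bidirectional best keeps only mutual best pairs", {
  refs <- rbind(mk_refs("r1", "ref_org", "K00001"),
                mk_refs(c("q1", "q2"), "query_org"))
  fwd <- best_hits_per_organism(mk_hits(c("q1", "q2"), "r1", c(120, 90)),
                                refs)
  rev_mutual <- best_hits_per_organism(mk_hits("r1", c("q1", "q2"),
                                               c(118, 80)), refs)
  bbh <- bidirectional_best(fwd, rev_mutual)
  expect_equal(bbh$query_id, "q1")
  expect_equal(bbh$subject_id, "r1")

  # r1's best is q2 while q1's best is r1 -> no pair for q1
  rev_other <- best_hits_per_organism(mk_hits("r1", c("q1", "q2"),
                                              c(80, 118)), refs)
  bbh <- bidirectional_best(fwd, rev_other)
  expect_false("q1" %in% bbh$query_id)
})

test_that("bidirectional best is symmetric on a brute-force 5x5 table", {
  set.seed(55)
  refs <- rbind(mk_refs(sprintf("r%d", 1:5), "ref_org"),
                mk_refs(sprintf("q%d", 1:5), "query_org"))
  grid <- expand.grid(q = sprintf("q%d", 1:5), r = sprintf("r%d", 1:5),
                      stringsAsFactors = FALSE)
  bits <- sample(50:150, nrow(grid))
  fwd_all <- mk_hits(grid$q, grid$r, bits)
  rev_all <- mk_hits(grid$r, grid$q, bits + stats::runif(nrow(grid), -5, 5))
  pairs <- bidirectional_best(best_hits_per_organism(fwd_all, refs),
                              best_hits_per_organism(rev_all, refs))
  # brute force: q's argmax row and r's argmax column must coincide
  expected <- character()
  for (q in sprintf("q%d", 1:5)) {
    fq <- fwd_all[fwd_all$query_id == q, ]
    best_r <- fq$subject_id[which.max(fq$bit_score)]
    rr <- rev_all[rev_all$query_id == best_r, ]
    if (rr$subject_id[which.max(rr$bit_score)] == q) {
      expected <- c(expected, paste(q, best_r))
    }
  }
  expect_setequal(paste(pairs$query_id, pairs$subject_id), expected)

  # swapping roles yields the same pair set with members swapped
  swapped <- bidirectional_best(best_hits_per_organism(rev_all, refs),
                                best_hits_per_organism(fwd_all, refs))
  expect_setequal(paste(swapped$subject_id, swapped$query_id),
                  paste(pairs$query_id, pairs$subject_id))
})

test_that("KO assignment applies the threshold policy and tie-breaks", {
  refs <- rbind(
    mk_refs("r1", "orgA", "K00001", "Bacteria;Proteobacteria"),
    mk_refs("r2", "orgB", "K00002", "Bacteria;Firmicutes"),
    mk_refs("r3", "orgC", "K00002", "Bacteria;Firmicutes"))

  # single BBH above the floor -> assigned
  bbh <- mk_hits("q1", "r1", 120)
  a <- assign_ko(bbh, refs)
  expect_equal(a$ko_id, "K00001")
  expect_equal(a$n_supporting_bbh, 1L)

  # below the 60-bit floor with no relaxation trigger -> unassigned
  a <- assign_ko(mk_hits("q1", "r1", 40), refs)
  expect_true(is.na(a$ko_id))
  expect_equal(a$method_note, "below_threshold")

  # five agreeing subjects relax the floor to 0.8 x top score
  refs5 <- mk_refs(sprintf("r%d", 1:5), sprintf("org%d", 1:5), "K00005")
  bbh5 <- mk_hits("q1", sprintf("r%d", 1:5), c(55, 54, 53, 52, 50))
  a <- assign_ko(bbh5, refs5)
  expect_equal(a$ko_id, "K00005")
  expect_match(a$method_note, "relaxed")
  # but four agreeing subjects do not
  expect_true(is.na(assign_ko(bbh5[1:4, ], refs5[1:4, ])$ko_id))

  # tie on count and score: the query taxon decides
  bbh_tie <- mk_hits("q1", c("r1", "r2"), c(100, 100))
  a <- assign_ko(bbh_tie, refs, query_taxon = "Firmicutes")
  expect_equal(a$ko_id, "K00002")
  a <- assign_ko(bbh_tie, refs, query_taxon = "Proteobacteria")
  expect_equal(a$ko_id, "K00001")
  # without a taxon, support count then summed bits then KO id decide
  a <- assign_ko(mk_hits("q1", c("r1", "r2", "r3"), c(100, 100, 100)), refs)
  expect_equal(a$ko_id, "K00002") # two supporters beat one
  a <- assign_ko(bbh_tie, refs)
  expect_equal(a$ko_id, "K00001") # full tie -> lexicographic

  # queries listed but without BBH come back unassigned
  a <- assign_ko(mk_hits("q1", "r1", 120), refs, query_ids = c("q1", "q2"))
  expect_equal(a$query_id, c("q1", "q2"))
  expect_true(is.na(a$ko_id[2]))
})

test_that("assignment is deterministic and monotone in the fixed floor", {
  set.seed(66)
  truth <- data.frame(gene_id = sprintf("g%02d", 1:15),
                      ko_id = sprintf("K%05d", 101:115),
                      stringsAsFactors = FALSE)
  sim <- simulate_hit_tables(truth, seed = 123)
  fwd <- best_hits_per_organism(sim$forward, sim$refs)
  rev <- best_hits_per_organism(sim$reverse, sim$refs)
  bbh <- bidirectional_best(fwd, rev)

  a1 <- assign_ko(bbh, sim$refs, query_ids = truth$gene_id)
  a2 <- assign_ko(bbh, sim$refs, query_ids = truth$gene_id)
  expect_identical(a1, a2)

  floors <- c(0, 30, 60, 120, 200, 300, 1000)
  n_assigned <- vapply(floors, function(f) {
    sum(!is.na(assign_ko(bbh, sim$refs, threshold_policy(fixed_floor = f),
                         query_ids = truth$gene_id)$ko_id))
  }, 0)
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("sensitivity is TP over genes with a true KO", {
  truth <- data.frame(gene_id = sprintf("g%d", 1:10),
                      ko_id = sprintf("K%05d", 1:10))
  assigned <- data.frame(query_id = sprintf("g%d", 1:10),
                         ko_id = c(sprintf("K%05d", 1:8), "K99999", NA))
  expect_equal(reassignment_sensitivity(truth, assigned), 0.8)
  assigned$ko_id <- truth$ko_id
  expect_equal(reassignment_sensitivity(truth, assigned), 1.0)
  expect_error(
    reassignment_sensitivity(data.frame(gene_id = "g", ko_id = NA), assigned),
    "empty evaluation set")

  # hand count on a small leave-taxon-out run
  sim <- simulate_hit_tables(truth, leave_out = "Proteobacteria", seed = 9)
  bbh <- bidirectional_best(best_hits_per_organism(sim$forward, sim$refs),
                            best_hits_per_organism(sim$reverse, sim$refs))
  got <- assign_ko(bbh, sim$refs, query_ids = truth$gene_id)
  manual_tp <- sum(got$ko_id[match(truth$gene_id, got$query_id)] ==
                     truth$ko_id, na.rm = TRUE)
  expect_equal(reassignment_sensitivity(truth, got), manual_tp / 10)
})
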