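test_that("pattern classification follows the threshold precedence", {
  # all completers -> A1
  expect_equal(classify_pattern(rep(100, 50))$pattern, "A1")
  # most organisms near-complete, few completers -> A2
  pc <- classify_pattern(c(rep(85, 75), rep(100, 10), rep(20, 15)))
  expect_equal(pc$pattern, "A2")
  expect_false(pc$rare)
  # a fifth of the cohort completes -> B, not rare; one in twenty -> rare
  expect_equal(classify_pattern(c(rep(100, 20), rep(0, 80)))$pattern, "B")
  expect_false(classify_pattern(c(rep(100, 20), rep(0, 80)))$rare)
  b_rare <- classify_pattern(c(rep(100, 5), rep(0, 95)))
  expect_equal(b_rare$pattern, "B")
  expect_true(b_rare$rare)
  # no completer at all -> D
  expect_equal(classify_pattern(rep(0, 100))$pattern, "D")
  expect_equal(classify_pattern(rep(99, 100))$pattern, "D")
  # mid completer fraction without dominating high ratios -> C
  pc <- classify_pattern(c(rep(100, 50), rep(85, 5), rep(10, 45)))
  expect_equal(pc$pattern, "C")
  expect_equal(pc$completer_fraction, 0.5)
  expect_equal(pc$high_fraction, 0.55)

  expect_error(classify_pattern(numeric()), "empty cohort")
  expect_error(classify_pattern(c(50, 101)), "\\[0, 100\\]")
})

test_that("classification is exhaustive, exclusive and permutation invariant", {
  set.seed(77)
  for (rep in 1:300) {
    n <- sample(2:200, 1L)
    ratios <- sample(c(0, 25, 50, 80, 85, 99, 100), n, replace = TRUE)
    pc <- classify_pattern(ratios)
    expect_true(pc$pattern %in% c("A1", "A2", "B", "C", "D"))
    pc2 <- classify_pattern(sample(ratios))
    expect_identical(pc2[c("pattern", "rare", "completer_fraction",
                           "high_fraction")],
                     pc[c("pattern", "rare", "completer_fraction",
                          "high_fraction")])
    # D excludes completers; rare implies a small positive fraction
    if (pc$pattern == "D") expect_equal(pc$completer_fraction, 0)
    if (pc$rare) {
      expect_gt(pc$completer_fraction, 0)
      expect_lt(pc$completer_fraction, 0.10)
    }
  }
})

test_that("boundary fractions use strict comparisons", {
  # exactly 70% completers is not A1 (needs > 70%)
  expect_equal(classify_pattern(c(rep(100, 70), rep(0, 30)))$pattern, "C")
  # ratio exactly 80 does not count toward the high fraction
  expect_equal(classify_pattern(c(rep(80, 90), rep(100, 10)))$pattern, "B")
  # exactly 30% completers is not restricted (needs < 30%)
  expect_equal(classify_pattern(c(rep(100, 30), rep(0, 70)))$pattern, "C")
  # exactly 10% completers is not rare (needs < 10%)
  expect_false(classify_pattern(c(rep(100, 10), rep(0, 90)))$rare)
})

make_cohort <- function(spec_rows, prefix = "o") {
  # spec_rows: data.frame(domain, phylum, class, n)
  out <- list()
  for (i in seq_len(nrow(spec_rows))) {
    for (j in seq_len(spec_rows$n[i])) {
      lin <- c(domain = spec_rows$domain[i], phylum = spec_rows$phylum[i])
      if (!is.na(spec_rows$class[i])) lin <- c(lin, class = spec_rows$class[i])
      out[[length(out) + 1L]] <- genome_profile(
        sprintf("%s%d_%d", prefix, i, j), lin, character())
    }
  }
  out
}

test_that("taxonomic patterns label completer clades", {
  cyano <- make_cohort(data.frame(domain = "Bacteria",
                                  phylum = "Cyanobacteria",
                                  class = NA, n = 10))
  expect_equal(taxonomic_pattern(cyano), "*Cyanobacteria*-specific")
  expect_equal(taxonomic_pattern(list()), "Non-prokaryote")

  # class-level specificity wins over phylum when available
  gamma <- make_cohort(data.frame(domain = "Bacteria",
                                  phylum = "Proteobacteria",
                                  class = "Gammaproteobacteria", n = 10),
                       prefix = "g")
  expect_equal(taxonomic_pattern(gamma), "*Gammaproteobacteria*-specific")

  # one domain, many phyla, none dominant -> domain-specific
  bact <- make_cohort(data.frame(
    domain = "Bacteria",
    phylum = c("Proteobacteria", "Firmicutes", "Actinobacteria",
               "Bacteroidetes", "Cyanobacteria"),
    class = NA, n = c(3, 3, 2, 2, 2)))
  expect_equal(taxonomic_pattern(bact), "Bacteria-specific")

  # two phyla jointly dominant across domains -> joint label
  joint <- make_cohort(data.frame(
    domain = c("Bacteria", "Bacteria", "Archaea"),
    phylum = c("Proteobacteria", "Firmicutes", "Euryarchaeota"),
    class = NA, n = c(10, 9, 1)))
  expect_equal(taxonomic_pattern(joint), "*Proteobacteria/Firmicutes*")

  # both domains, eight phyla, nothing dominant -> Prokaryote
  spread <- make_cohort(data.frame(
    domain = c(rep("Bacteria", 6), rep("Archaea", 2)),
    phylum = c("Proteobacteria", "Firmicutes", "Actinobacteria",
               "Bacteroidetes", "Cyanobacteria", "Chloroflexi",
               "Euryarchaeota", "Crenarchaeota"),
    class = NA, n = rep(2, 8)))
  expect_equal(taxonomic_pattern(spread), "Prokaryote")

  # completers must come from the cohort when one is supplied
  expect_error(taxonomic_pattern(cyano, cohort = gamma), "subset")
})

test_that("classify_matrix classifies rows and labels completer taxa", {
  mods <- module_collection(
    module_definition("M00001_1", "K00001 K00002"),
    module_definition("M00002_1", "K00003"))
  cohort <- list(
    genome_profile("a", c(domain = "Bacteria", phylum = "Cyanobacteria"),
                   c("K00001", "K00002")),
    genome_profile("b", c(domain = "Bacteria", phylum = "Cyanobacteria"),
                   c("K00001", "K00002")),
    genome_profile("c", c(domain = "Archaea", phylum = "Euryarchaeota"),
                   c("K00001")))
  cm <- completion_matrix(mods, cohort)
  calls <- classify_matrix(cm)
  expect_equal(calls$pattern[calls$module_id == "M00001_1"], "C")
  expect_equal(calls$taxonomic_pattern[calls$module_id == "M00001_1"],
               "*Cyanobacteria*-specific")
  expect_equal(calls$pattern[calls$module_id == "M00002_1"], "D")
  expect_equal(calls$taxonomic_pattern[calls$module_id == "M00002_1"],
               "Non-prokaryote")
})
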