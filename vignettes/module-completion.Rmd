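---
title: "Evaluating functionomes with module completion ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating functionomes with module completion ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modcomp)
```

## The problem

Functional annotation of a genome or metagenome usually stops at a list of
genes with ortholog identifiers. That list does not directly answer the
question practitioners care about: *which biological capabilities — pathways,
transporters, molecular machines — can this organism or community actually
run?* A pathway is only usable when every reaction step has an enzyme;
a transporter only assembles when all of its subunits are present.

`modcomp` evaluates this "potential functionome" through functional
modules in the KEGG style: small functional units (pathway segments,
structural complexes, functional sets, signature gene sets) defined as a
Boolean algebra-like equation over KO (KEGG Orthology) identifiers. The
package computes, for each module and each KO inventory, the **module
completion ratio (MCR)** — the percentage of the module's counting units
that the inventory satisfies — and builds comparative analyses on top of it.

## The definition grammar and its evaluation

A definition string combines KO identifiers with four operators, from
tightest to loosest binding: parentheses, `-` (optional item), `+`
(complex/subunit, "and"), `,` (alternatives, "or"), and space (consecutive
pathway elements, "and").

```{r}
e <- parse_definition("(K01652+K01653+K11258) K90401 -K90402 (K90403,K90404)")
e
```

The MCR denominator is the number of **blocks**: the top-level
space-delimited items plus, for bare top-level `+` chains, each subunit
individually; optional items are excluded from both numerator and
denominator. Two consequences deserve emphasis:

* A parenthesised complex inside a pathway step, such as the three-subunit
  acetolactate synthase `(K01652+K01653+K11258)`, is **one** block: the step
  either has a complete enzyme complex or it does not.
* A structural-complex module written as a bare plus-chain
  (`K1+K2+...+K14`) counts each component as its own block, so a
  photosystem missing 2 of 14 components scores 85.7%, not 0%.

This reconciles how pathway modules count reactions with how structural
complexes count components, and it is why the parser records whether a
complex was parenthesised. Satisfaction is the obvious recursion:
membership at leaves, "all children" for sequences and complexes, "any
child" for alternatives, always-true for optional items.

```{r}
m <- module_definition("M00019_1",
  "(K01652+K01653+K11258) K90401 K90402 K90403 K90404 K90405 K90406")
completion_ratio(m, setdiff(expression_kos(m$expression), "K11258"))
```

Design choices made where the notation itself is silent:

* `-` consumes exactly the next item (leaf or parenthesised group), and an
  optional member may also be attached directly inside a complex
  (`K1+K2-K3`), matching how module definitions are written in the wild.
* A top-level comma group counts as one block satisfiable by either
  alternative, even when an alternative is itself a multi-step sequence.
  No worked example disambiguates this; one block is the simplest reading.
* A module whose items are all optional has an empty denominator and is
  rejected rather than silently scored 100%.
* "Completed" means exactly 100%, with no tolerance; displayed ratios are
  rounded half-up to one decimal (85.714… prints as 85.7) while full
  precision is kept internally.
* The MCR depends only on the KO *set*; gene multiplicity matters only for
  contributor breakdowns.

## Branching modules and submodules

Some pathway modules branch at an intermediate compound into different
products (heme biosynthesis splits into protoheme and siroheme). A single
MCR over the whole module would conflate "can make either product" with
"can make both", so branching modules are redefined as submodules: `_1` for
the original scope and `_k` for each branch appended to the shared prefix.
Branch structure is supplied explicitly via `branch_spec()` — the flat
definition string does not encode compounds, so branching cannot be
inferred from it.

```{r}
expand_branches(paper_modules()$branch_spec)
```

In the `_1` original the branch region is one alternatives block: the
original is completed when the shared steps plus at least one full branch
are present.

## Completion patterns across a cohort

Computed over a reference cohort, each module's profile of ratios is
classified (`classify_pattern()`):

| pattern | meaning | rule (defaults) |
|---|---|---|
| A-1 | universal | >70% of organisms complete the module |
| A-2 | universal, completion scarce | >70% of organisms above 80% MCR |
| B | restricted | <30% complete it |
| C | diversified | everything else |
| D | non-prokaryotic (in a prokaryote cohort) | nobody completes it |

All comparisons are strict, matching the verbal definitions ">70%", ">80%",
"<30%"; A-1 is checked before A-2 because every A-1 module also satisfies
the A-2 condition. A module completed by fewer than 10% of the cohort is
additionally flagged **rare**, independently of its pattern. The
completers' taxonomy is then summarised (`taxonomic_pattern()`): a single
taxon covering ≥90% of completers at the most specific sub-domain level
gives `*X*-specific`; otherwise up to three phyla jointly covering ≥90%
give a joint label; otherwise a dominant domain gives `Bacteria-specific` /
`Archaea-specific`; otherwise `Prokaryote`. The 0.90 fraction and the
3-phylum cap are configurable: reference tables of such labels exist but no
published algorithm does, so the rule is an explicit, tunable convention of
this package.

## KO assignment from similarity searches

For raw query genes, KO identifiers are assigned from precomputed
similarity searches (BLAST tabular, 12 columns) in the KAAS manner: reduce
hits to the best hit per (query, reference organism) — ties broken by
e-value then subject id so the reduction is deterministic — keep
bidirectional best hits, and read the KO from the supporting subjects.
Two refinements:

* **Variable bit-score threshold.** The classic fixed 60-bit floor loses
  assignments that are supported by many concordant BBHs. When at least
  `relax_min_hits` (default 5) subjects agree on one KO, the floor relaxes
  to `relax_factor` (default 0.8) times the query's top bit score. The
  published description names the idea but not the formula; this
  parameterisation is our configurable interpretation, not a claim about
  the original server.
* **Taxonomic disambiguation.** With several candidate KOs, a KO whose
  supporting subjects' lineages contain the query's taxon wins; remaining
  ties fall to support count, summed bit score, then KO id, so assignment
  is a total order and identical inputs always give identical output.

Assignment quality is scored as sensitivity TP/(TP+FN) over genes with a
known KO (`reassignment_sensitivity()`).

## What the simulators emulate — and what they do not

`simulate_cohort()` emulates a reference cohort (default 768 organisms,
mirroring a complete-prokaryote reference set) with one simple pathway
module per requested pattern: 10 single-KO blocks, module-disjoint
placeholder KOs (K95000 upward), so a target pattern can be realised by
drawing, per organism, how many blocks are satisfied. Generating targets
default to completer fractions 0.85 (A-1), 0.05 with 80% of non-completers
at MCR 90 (A-2), 0.15 (B), 0.50 (C) and 0 (D) — values chosen to sit well
inside each pattern's definition for a cohort of hundreds, since a fraction
near a strict threshold would make the generating label itself ambiguous.
Infeasible targets (an A-1 module completed by 20% of organisms) are
rejected when the spec is built.

`simulate_hit_tables()` emulates the leave-clade-out database-dependency
design: five reference organisms at increasing clade distance from an
*Escherichia*-like query (same genus, order, class, phylum, and an outgroup
phylum), one reference gene per truth KO each, plus off-KO decoys.
Same-KO bit scores are drawn from non-overlapping bands that decrease with
distance (genus 280–320 down to outgroup 45–75) and decoys score below
every band (20–40). Because the bands are ordered, removing a larger clade
can only lower the best remaining same-KO score — never promote a decoy —
so sensitivity is monotonically non-increasing by construction, and the
outgroup band straddling the 60-bit floor makes removal of the query's own
phylum visibly costly. These generators reproduce the *structure* of real
data, not its messiness: no paralog confusion, no fragmented proteins, no
KO shared across generated modules, and bit scores that cleanly separate
orthologs from noise. Green tests therefore validate the algorithms'
logic, tie-breaking and bookkeeping — they do not certify recovery rates on
real genomes, which depend on the reference database of the day.

The in-document fixture modules returned by `paper_modules()` are
structurally faithful (8-reaction TCA core, 6-step glycolysis core,
5-reaction glyoxylate cycle, 7-step leucine biosynthesis with its 3-subunit
first step, 14/12-component photosystem I, branching heme module) and keep
the KO identifiers that have a documented role (K01652/K01653/K11258,
K00134/K00150, K01637/K01638); all other leaves are placeholders from the
reserved K90000–K99999 range, and the definitions are labelled synthetic in
their names.

## Numerical and testing choices

Ratios are exact rationals evaluated in double precision; completion is
tested as `== 100`, which is safe because `100 * s/b` with `s == b` is
exactly 100. Serialised tables round ratios half-up at one decimal and
fractions at four; files re-read from disk therefore carry the serialised
precision, and a write–read–write cycle is byte-identical. Property tests
run the Boolean evaluator against an independently written truth-table
oracle on 1,000 random expressions (≤6 KOs, depth ≤3, all 2^k subsets),
check monotonicity of the MCR in the KO set on 500 random pairs, and check
classifier exhaustiveness on random ratio vectors. The cohort-scale test
uses 768 organisms × 50 modules; cohort simulation, completion and
classification run in seconds at that size, and all randomised tests fix
their seeds.

## Limitations

* Branch structure must be curated by hand; there is no reaction-graph
  inference.
* Completion is presence-based: read counts or coverage never weight the
  ratio, so a metagenome's MCR reflects the community's united gene pool,
  not any single member's.
* The taxonomic-pattern labeller and the variable-threshold policy are
  conventions with defaults, not reconstructions of unpublished code.
* The KEGG FTP MODULE dialect is not parsed byte-for-byte (reaction and
  compound fields are out of scope); module flat files use the TSV layout
  described in `read_modules()`.
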