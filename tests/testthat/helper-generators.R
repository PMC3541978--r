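# Random well-formed definition strings for property-style tests.
# gen_definition() returns a definition text drawing from a small KO pool
# (<= max_kos distinct identifiers) with nesting depth <= depth.

gen_ko_pool <- function(max_kos = 6L) {
  sprintf("K%05d", sample.int(99999L, max_kos))
}

gen_definition <- function(depth = 3L, pool = gen_ko_pool(),
                           allow_optional = TRUE) {
  gen <- function(d) {
    if (d == 0L || stats::runif(1) < 0.35) {
      return(list(text = sample(pool, 1L), compound = FALSE))
    }
    kind <- sample(c("seq", "alt", "complex",
                     if (allow_optional) "optional"), 1L)
    wrap <- function(ch) if (ch$compound) paste0("(", ch$text, ")") else ch$text
    if (kind == "optional") {
      repeat { # "-" applies to a single item; no "--" chains
        ch <- gen(d - 1L)
        if (!startsWith(ch$text, "-")) break
      }
      return(list(text = paste0("-", wrap(ch)), compound = FALSE))
    }
    n <- sample(2:3, 1L)
    kids <- vapply(seq_len(n), function(k) wrap(gen(d - 1L)), "")
    sep <- switch(kind, seq = " ", alt = ",", complex = "+")
    list(text = paste(kids, collapse = sep), compound = TRUE)
  }
  repeat {
    out <- gen(depth)$text
    # an all-optional definition has no counting block; regenerate
    if (!grepl("^-", out)) return(out)
  }
}

# a genome profile with an arbitrary id and KO set
quick_profile <- function(id, kos, lineage = c(domain = "Bacteria",
                                               phylum = "Firmicutes")) {
  genome_profile(id, lineage, kos)
}
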