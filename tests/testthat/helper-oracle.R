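# Independent oracle for Boolean block evaluation: a one-pass recursive
# evaluator over the raw token stream that computes the truth value directly,
# without building or serializing an AST.  Kept deliberately separate from
# the package's parser so the two can disagree.

oracle_satisfied <- function(text, kos) {
  toks <- regmatches(text, gregexpr("K[0-9]{5}|[(),+-]| +", text))[[1]]
  toks <- sub("^ +$", " ", toks)
  i <- 0L
  peek <- function() if (i < length(toks)) toks[i + 1L] else ""
  take <- function() {
    i <<- i + 1L
    toks[i]
  }
  ev_primary <- function() {
    t <- take()
    if (t == "(") {
      v <- ev_seq()
      stopifnot(take() == ")")
      return(v)
    }
    t %in% kos
  }
  ev_opt <- function() {
    if (peek() == "-") {
      take()
      ev_primary()
      return(TRUE)
    }
    ev_primary()
  }
  ev_cplx <- function() {
    v <- ev_opt()
    while (peek() %in% c("+", "-")) {
      op <- take()
      if (op == "+") {
        w <- ev_opt()
        v <- v && w
      } else {
        ev_primary() # "-x" member is optional: consume and ignore
      }
    }
    v
  }
  ev_alt <- function() {
    v <- ev_cplx()
    while (peek() == ",") {
      take()
      v <- ev_cplx() || v
    }
    v
  }
  ev_seq <- function() {
    v <- ev_alt()
    while (peek() == " ") {
      take()
      v <- ev_alt() && v
    }
    v
  }
  out <- ev_seq()
  stopifnot(i == length(toks))
  out
}

# brute-force completion ratio: independent per-cell loop used as the
# completion_matrix oracle
oracle_matrix <- function(modules, cohort) {
  mod_ids <- sort(names(modules))
  org_ids <- sort(vapply(cohort, `[[`, "", "organism_id"))
  m <- matrix(NA_real_, length(mod_ids), length(org_ids),
              dimnames = list(mod_ids, org_ids))
  for (mid in mod_ids) {
    for (p in cohort) {
      m[mid, p$organism_id] <- completion_ratio(modules[[mid]], p$kos)$ratio
    }
  }
  m
}
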