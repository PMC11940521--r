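# Shared helpers: cached grammar, an exhaustive derivation enumerator used
# as the independent parser oracle, and a brute-force regulatory counter.

test_grammar <- function() {
  if (is.null(.test_env$grammar)) .test_env$grammar <- load_grammar()
  .test_env$grammar
}
.test_env <- new.env()

# Exhaustive enumeration of leftmost derivations of `tokens`, bounded by
# `max_rules` applications. Independent of the chart parser: plain DFS over
# sentential forms with prefix and minimum-length pruning. Returns a list of
# rule-index vectors (at most `limit` derivations).
enumerate_derivations <- function(tokens, grammar = test_grammar(),
                                  max_rules = 40L, limit = 5L) {
  minsz <- gramdta:::.min_expansion(grammar)
  n <- length(tokens)
  found <- list()
  recurse <- function(syms, is_nt, rules) {
    if (length(found) >= limit) return(invisible(NULL))
    k <- which(is_nt)[1]
    pre_len <- if (is.na(k)) length(syms) else k - 1L
    if (pre_len > n) return(invisible(NULL))
    if (pre_len > 0 && !identical(syms[seq_len(pre_len)], tokens[seq_len(pre_len)]))
      return(invisible(NULL))
    unit_min <- ifelse(is_nt, minsz[syms], 1)
    rest <- if (pre_len > 0L) unit_min[-seq_len(pre_len)] else unit_min
    min_total <- pre_len + sum(rest)
    if (min_total > n) return(invisible(NULL))
    if (is.na(k)) {
      if (length(syms) == n) found[[length(found) + 1L]] <<- rules
      return(invisible(NULL))
    }
    if (length(rules) >= max_rules) return(invisible(NULL))
    for (ri in grammar$rules_by_lhs[[syms[k]]]) {
      r <- grammar$rules[[ri]]
      recurse(append(syms[-k], r$rhs, after = k - 1L),
              append(is_nt[-k], r$rhs_is_nt, after = k - 1L),
              c(rules, ri))
    }
  }
  recurse(grammar$start, TRUE, integer(0))
  found
}

# Independent nested-loop regulatory counter over (perturbagen, gene,
# replicate), mirroring the definition directly.
brute_regulatory <- function(replicates, landmarks) {
  ids <- sort(unique(replicates$perturbagen_id))
  arr <- array(0, dim = c(length(ids), length(landmarks), 2),
               dimnames = list(ids, as.character(landmarks), c("up", "down")))
  for (i in seq_along(ids)) {
    rows <- which(replicates$perturbagen_id == ids[i])
    for (gi in seq_along(landmarks)) {
      g <- landmarks[gi]
      for (rr in rows) {
        if (g %in% replicates$up_genes[[rr]]) arr[i, gi, 1] <- arr[i, gi, 1] + 1
        if (g %in% replicates$down_genes[[rr]]) arr[i, gi, 2] <- arr[i, gi, 2] + 1
      }
    }
    arr[i, , ] <- arr[i, , ] / length(rows)
  }
  arr
}

# Small deterministic drug/protein pools shared across network tests, cached
# so SMILES generation (Open Babel round trips) runs once.
test_drugs <- function(n = 6) {
  if (is.null(.test_env$drugs)) .test_env$drugs <- gen_smiles(8, seed = 404)
  .test_env$drugs[seq_len(n)]
}
test_proteins <- function(n = 4) {
  if (is.null(.test_env$prots)) .test_env$prots <- gen_proteins(6, c(40, 90), seed = 405)
  .test_env$prots[seq_len(n)]
}
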