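# Earley chart parser over tokenized SMILES, with extraction of the leftmost
# derivation. The grammar is small (76 rules) and nearly deterministic; the
# chart parser is used so that ambiguity is detected rather than silently
# resolved. When the same constituent (symbol, span) completes through two
# different rule/split routes, the route with the lower rule index (then the
# smaller first split point) is kept and a warning is emitted.

#' Parse a token sequence into its production-rule index sequence
#'
#' Runs an Earley chart parser over the tokens and returns the rule indices
#' of the leftmost derivation of the unique parse tree rooted at the
#' grammar's start symbol whose left-to-right leaves equal the token
#' sequence. Replaying the returned indices as a leftmost rewrite (see
#' [replay_productions()]) regenerates the tokens exactly.
#'
#' @param tokens Character vector of grammar terminals, e.g. from
#'   [tokenize_smiles()].
#' @param grammar A `smiles_grammar`.
#' @param max_rules Capacity cap on the derivation length `q`
#'   (default 277, the row count of the one-hot encoding).
#' @return Integer vector of 1-based rule indices (class
#'   `production_sequence`), each in `1 .. padding_rule - 1`.
#' @examples
#' g <- load_grammar()
#' parse_to_productions(tokenize_smiles("CCO", g), g)
#' @export
parse_to_productions <- function(tokens, grammar = default_grammar(),
                                 max_rules = RULE_MAX) {
  tokens <- as.character(tokens)
  n <- length(tokens)
  if (n == 0L) stop("empty token sequence")
  bad <- setdiff(unique(tokens), grammar$terminals)
  if (length(bad)) {
    stop("token(s) not in the grammar's terminal alphabet: ",
         paste(bad, collapse = ", "))
  }
  rules <- grammar$rules
  by_lhs <- grammar$rules_by_lhs

  # State: list(rule, dot, origin, ends) where ends[k] is the input position
  # after consuming rhs symbol k. Chart[[i + 1]] holds states ending at i.
  # 'passive' maps "sym.i.j" -> list(rule, ends) for a completed constituent.
  chart_keys <- vector("list", n + 1L)    # environments for state dedup
  agenda <- vector("list", 4096L); a_head <- 0L; a_tail <- 0L
  chart_states <- vector("list", n + 1L)  # lists of states per position
  for (i in seq_len(n + 1L)) {
    chart_keys[[i]] <- new.env(parent = emptyenv())
    chart_states[[i]] <- list()
  }
  passive <- new.env(parent = emptyenv())
  ambiguous <- FALSE

  push <- function(state, pos) {
    key <- paste0(state$rule, ".", state$dot, ".", state$origin, ".",
                  paste(state$ends, collapse = ","))
    env <- chart_keys[[pos + 1L]]
    if (!is.null(env[[key]])) return(invisible(NULL))
    env[[key]] <- TRUE
    a_tail <<- a_tail + 1L
    if (a_tail > length(agenda)) length(agenda) <<- 2L * a_tail
    agenda[[a_tail]] <<- list(state = state, pos = pos)
    invisible(NULL)
  }

  complete_item <- function(sym, i, j, rule, ends) {
    key <- paste0(sym, ".", i, ".", j)
    old <- passive[[key]]
    if (is.null(old)) {
      passive[[key]] <- list(rule = rule, ends = ends)
      return(TRUE)
    }
    if (old$rule != rule || !identical(old$ends, ends)) {
      ambiguous <<- TRUE
      better <- rule < old$rule ||
        (rule == old$rule && ends[1] < old$ends[1])
      if (better) passive[[key]] <- list(rule = rule, ends = ends)
    }
    FALSE
  }

  for (r in by_lhs[[grammar$start]]) {
    push(list(rule = r, dot = 0L, origin = 0L, ends = integer(0)), 0L)
  }

  while (a_head < a_tail) {
    a_head <- a_head + 1L
    item <- agenda[[a_head]]
    st <- item$state; pos <- item$pos
    chart_states[[pos + 1L]][[length(chart_states[[pos + 1L]]) + 1L]] <- st
    r <- rules[[st$rule]]
    if (st$dot == length(r$rhs)) {
      # completion: new passive item lhs over [origin, pos]
      fresh <- complete_item(r$lhs, st$origin, pos, st$rule, st$ends)
      if (fresh) {
        # advance every state in chart[origin] expecting this lhs
        for (w in chart_states[[st$origin + 1L]]) {
          wr <- rules[[w$rule]]
          if (w$dot < length(wr$rhs) && wr$rhs_is_nt[w$dot + 1L] &&
              wr$rhs[w$dot + 1L] == r$lhs) {
            push(list(rule = w$rule, dot = w$dot + 1L, origin = w$origin,
                      ends = c(w$ends, pos)), pos)
          }
        }
      }
    } else {
      nxt_is_nt <- r$rhs_is_nt[st$dot + 1L]
      nxt <- r$rhs[st$dot + 1L]
      if (nxt_is_nt) {
        for (pr in by_lhs[[nxt]]) {
          push(list(rule = pr, dot = 0L, origin = pos, ends = integer(0)), pos)
        }
        # re-completion against already-completed constituents at pos
        for (j in pos:n) {
          p <- passive[[paste0(nxt, ".", pos, ".", j)]]
          if (!is.null(p)) {
            push(list(rule = st$rule, dot = st$dot + 1L, origin = st$origin,
                      ends = c(st$ends, j)), j)
          }
        }
      } else if (pos < n && tokens[pos + 1L] == nxt) {
        push(list(rule = st$rule, dot = st$dot + 1L, origin = st$origin,
                  ends = c(st$ends, pos + 1L)), pos + 1L)
      }
    }
  }

  root <- passive[[paste0(grammar$start, ".0.", n)]]
  if (is.null(root)) {
    stop("parse error: token sequence '",
         paste(tokens, collapse = ""), "' is not in the grammar's language")
  }
  if (ambiguous) {
    warning("ambiguous parse for '", paste(tokens, collapse = ""),
            "'; using the lowest-rule-index derivation")
  }

  # Pre-order (leftmost-derivation) walk of the chosen parse tree.
  out <- integer(0)
  walk <- function(sym, i, j) {
    p <- passive[[paste0(sym, ".", i, ".", j)]]
    if (is.null(p)) stop("internal parser error at ", sym, "[", i, ",", j, "]")
    out[[length(out) + 1L]] <<- p$rule
    r <- rules[[p$rule]]
    start <- i
    for (k in seq_along(r$rhs)) {
      if (r$rhs_is_nt[k]) walk(r$rhs[k], start, p$ends[k])
      start <- p$ends[k]
    }
  }
  walk(grammar$start, 0L, n)
  if (length(out) > max_rules) {
    stop("capacity error: derivation of '", paste(tokens, collapse = ""),
         "' needs ", length(out), " rules (maximum ", max_rules, ")")
  }
  structure(out, class = "production_sequence")
}

#' Replay a production sequence as a leftmost derivation
#'
#' Starting from the grammar's start symbol, applies each rule in turn to the
#' leftmost non-terminal of the sentential form. The result is the terminal
#' (token) sequence the derivation generates; this is the inverse check for
#' [parse_to_productions()].
#'
#' @param indices Integer vector of 1-based rule indices.
#' @param grammar A `smiles_grammar`.
#' @return Character vector of terminal tokens.
#' @export
replay_productions <- function(indices, grammar = default_grammar()) {
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("empty production sequence")
  rules <- grammar$rules
  # sentential form as a list of (symbol, is_nt)
  syms <- grammar$start
  is_nt <- TRUE
  for (idx in indices) {
    if (idx < 1L || idx > length(rules)) stop("rule index out of range: ", idx)
    r <- rules[[idx]]
    k <- which(is_nt)[1]
    if (is.na(k)) stop("replay error: no non-terminal left for rule ", idx)
    if (syms[k] != r$lhs) {
      stop("replay error: leftmost non-terminal '", syms[k],
           "' does not match rule ", idx, " (lhs '", r$lhs, "')")
    }
    syms <- append(syms[-k], r$rhs, after = k - 1L)
    is_nt <- append(is_nt[-k], r$rhs_is_nt, after = k - 1L)
  }
  if (any(is_nt)) {
    stop("replay error: derivation incomplete (non-terminals remain: ",
         paste(unique(syms[is_nt]), collapse = ", "), ")")
  }
  syms
}
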