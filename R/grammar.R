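# Fixed encoding dimensions: a parse is truncated/padded to RULE_MAX rows over
# RULE_COUNT production-rule columns, the last column being the padding rule.
RULE_MAX <- 277L
RULE_COUNT <- 76L

.gramdta_env <- new.env(parent = emptyenv())

#' Load a SMILES context-free grammar from a plain-text rule file
#'
#' Reads a grammar definition with one production per line in the form
#' `LHS -> sym sym ...`. Quoted symbols are terminals, unquoted symbols are
#' non-terminals, `#` starts a comment. The left-hand side of the first rule
#' is the start symbol; the final rule is the end-of-sequence padding rule
#' used to fill unused rows of the one-hot drug encoding.
#'
#' The shipped default (`system.file("extdata", "zinc_grammar.txt",
#' package = "gramdta")`) is the 76-production SMILES grammar of the grammar
#' variational autoencoder line of work.
#'
#' @param path Path to the grammar file. `NULL` loads the shipped default.
#' @param n_rules Expected number of productions (default 76). Loading fails
#'   if the file disagrees, unless `check_count = FALSE`.
#' @param check_count Set `FALSE` to permit experimental grammars of a
#'   different size.
#' @return An object of class `smiles_grammar`: a list with `rules`
#'   (list of `list(lhs, rhs, rhs_is_nt)`), `nonterminals`, `terminals`,
#'   `start`, and `padding_rule` (index of the padding production).
#' @examples
#' g <- load_grammar()
#' length(g$rules)
#' @export
load_grammar <- function(path = NULL, n_rules = RULE_COUNT, check_count = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "zinc_grammar.txt", package = "gramdta")
  }
  if (!file.exists(path)) stop("grammar file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # '#' starts a comment only at line start or after whitespace, so the
  # quoted '#' bond terminal survives
  lines <- sub("^#.*$", "", lines)
  lines <- sub("[[:space:]]#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("grammar file is empty: ", path)
  if (anyDuplicated(lines)) {
    stop("duplicate production rule(s) in grammar file: ",
         paste(unique(lines[duplicated(lines)]), collapse = "; "))
  }
  rules <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed production: '", ln, "'")
    lhs <- trimws(parts[1])
    if (!nzchar(lhs) || grepl("^'", lhs)) stop("malformed LHS in: '", ln, "'")
    rhs_syms <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(rhs_syms) == 0L || !all(nzchar(rhs_syms)))
      stop("empty RHS in: '", ln, "'")
    quoted <- grepl("^'.*'$", rhs_syms)
    rhs <- ifelse(quoted, substr(rhs_syms, 2L, nchar(rhs_syms) - 1L), rhs_syms)
    list(lhs = lhs, rhs = rhs, rhs_quoted = quoted)
  })
  if (check_count && length(rules) != n_rules) {
    stop("grammar has ", length(rules), " rules; expected ", n_rules,
         " (use check_count = FALSE to override)")
  }
  nonterminals <- unique(vapply(rules, `[[`, "", "lhs"))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    is_nt <- !r$rhs_quoted & r$rhs %in% nonterminals
    if (any(!r$rhs_quoted & !is_nt)) {
      stop("unquoted symbol(s) with no production in rule ", i, ": ",
           paste(r$rhs[!r$rhs_quoted & !is_nt], collapse = ", "))
    }
    rules[[i]] <- list(lhs = r$lhs, rhs = r$rhs, rhs_is_nt = is_nt)
  }
  terminals <- unique(unlist(lapply(rules, function(r) r$rhs[!r$rhs_is_nt])))
  g <- structure(
    list(rules = rules,
         nonterminals = nonterminals,
         terminals = terminals,
         start = rules[[1]]$lhs,
         padding_rule = length(rules)),
    class = "smiles_grammar")
  g$rules_by_lhs <- split(seq_along(rules),
                          factor(vapply(rules, `[[`, "", "lhs"),
                                 levels = nonterminals))
  # terminals sorted longest-first for maximal-munch tokenization
  g$munch_order <- g$terminals[order(-nchar(g$terminals), g$terminals)]
  g
}

#' @export
print.smiles_grammar <- function(x, ...) {
  cat("SMILES context-free grammar\n")
  cat("  start symbol :", x$start, "\n")
  cat("  productions  :", length(x$rules),
      "(padding rule:", x$padding_rule, ")\n")
  cat("  non-terminals:", length(x$nonterminals), "\n")
  cat("  terminals    :", length(x$terminals), "\n")
  invisible(x)
}

#' The default SMILES grammar (cached)
#'
#' @return The shipped `smiles_grammar`, loaded once per session.
#' @export
default_grammar <- function() {
  if (is.null(.gramdta_env$grammar)) .gramdta_env$grammar <- load_grammar()
  .gramdta_env$grammar
}

#' Canonicalize a SMILES string
#'
#' Converts a SMILES string to the canonical form assigned by the Open Babel
#' chemistry toolkit, so that the same molecule drawn from different sources
#' maps to one representation. Canonicalization is idempotent.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#' @examples
#' canonicalize_smiles("OCC")
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s))
    out <- trimws(out)
    if (!nzchar(out)) stop("SMILES parse failure: '", s, "'", call. = FALSE)
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Tokenize a SMILES string over a grammar's terminal alphabet
#'
#' Splits a SMILES string into grammar terminals by maximal munch: at each
#' position the longest matching terminal is taken, so multi-character
#' terminals such as `Cl`, `Br` and `@@` become single tokens. Concatenating
#' the returned tokens reproduces the input exactly.
#'
#' @param smiles A single SMILES string.
#' @param grammar A `smiles_grammar`; default [default_grammar()].
#' @return Character vector of terminal tokens, with the input attached as
#'   attribute `"source"`.
#' @examples
#' tokenize_smiles("CCl")
#' @export
tokenize_smiles <- function(smiles, grammar = default_grammar()) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  terms <- grammar$munch_order
  tokens <- character(0)
  pos <- 1L
  n <- nchar(smiles)
  while (pos <= n) {
    hit <- NULL
    for (t in terms) {
      if (substr(smiles, pos, pos + nchar(t) - 1L) == t) { hit <- t; break }
    }
    if (is.null(hit)) {
      stop("tokenization error: character '", substr(smiles, pos, pos),
           "' at position ", pos, " of '", smiles,
           "' matches no grammar terminal")
    }
    tokens <- c(tokens, hit)
    pos <- pos + nchar(hit)
  }
  attr(tokens, "source") <- smiles
  tokens
}
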