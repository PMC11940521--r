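# One-hot encoding of production-rule sequences: a fixed 277 x 76 binary
# matrix per drug. Row j carries the j-th rule of the leftmost derivation;
# rows beyond the derivation length q carry the end-of-sequence padding rule
# in the final column.

#' Encode a production sequence as a fixed-shape one-hot matrix
#'
#' @param productions Integer vector of 1-based rule indices (a
#'   `production_sequence`), none of which may be the padding rule.
#' @param grammar A `smiles_grammar`.
#' @param max_rules Number of rows `M` of the encoding (default 277).
#' @return A `max_rules` x `n_rules` binary matrix of class `drug_onehot`
#'   with attribute `rule_count = q`. Every row sums to 1; rows `q+1 .. M`
#'   have their 1 in the padding column.
#' @examples
#' g <- load_grammar()
#' o <- encode_one_hot(parse_to_productions(tokenize_smiles("CCO", g), g), g)
#' dim(o)
#' @export
encode_one_hot <- function(productions, grammar = default_grammar(),
                           max_rules = RULE_MAX) {
  idx <- as.integer(productions)
  q <- length(idx)
  n_rules <- length(grammar$rules)
  pad <- grammar$padding_rule
  if (q < 1L) stop("empty production sequence")
  if (q > max_rules) {
    stop("capacity error: ", q, " productions exceed the ", max_rules,
         "-row encoding")
  }
  if (any(idx < 1L | idx >= pad)) {
    stop("invalid rule index in parse: indices must lie in 1..", pad - 1L)
  }
  m <- matrix(0, nrow = max_rules, ncol = n_rules)
  m[cbind(seq_len(q), idx)] <- 1
  if (q < max_rules) m[(q + 1L):max_rules, pad] <- 1
  structure(m, class = c("drug_onehot", class(m)), rule_count = q)
}

#' Decode a one-hot drug matrix back to its production sequence
#'
#' Inverse of [encode_one_hot()] on its image: recovers the rule indices of
#' rows `1..q` and strips the trailing padding rows.
#'
#' @param onehot A binary matrix satisfying the `drug_onehot` invariants
#'   (each row has exactly one 1; trailing rows are padding).
#' @param grammar A `smiles_grammar`.
#' @return Integer `production_sequence`.
#' @export
decode_one_hot <- function(onehot, grammar = default_grammar()) {
  m <- unclass(onehot)
  if (!is.matrix(m) || ncol(m) != length(grammar$rules)) {
    stop("malformed matrix: expected ", length(grammar$rules), " columns")
  }
  if (!all(m %in% c(0, 1)) || any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("malformed matrix: every row must contain exactly one 1")
  }
  idx <- max.col(m, ties.method = "first")
  pad <- grammar$padding_rule
  is_pad <- idx == pad
  if (is_pad[1]) stop("malformed matrix: first row is padding (q must be >= 1)")
  q <- if (any(is_pad)) which(is_pad)[1] - 1L else length(idx)
  if (any(!is_pad[seq_along(idx) > q])) {
    stop("malformed matrix: non-padding row after the first padding row")
  }
  structure(idx[seq_len(q)], class = "production_sequence")
}

#' Encode SMILES strings as a stacked one-hot drug tensor
#'
#' Canonicalizes (optionally), tokenizes, parses and one-hot encodes each
#' unique SMILES. Strings that fail canonicalization or fall outside the
#' grammar's language are skipped with a warning and reported in the
#' `skipped` attribute rather than silently dropped.
#'
#' @param smiles Character vector of SMILES strings.
#' @param grammar A `smiles_grammar`.
#' @param canonicalize Canonicalize before parsing (default `TRUE`).
#' @return A 3-d array `n_ok x 277 x 76` with `dimnames[[1]]` the encodable
#'   canonical SMILES, attributes `rule_counts` (named integer) and `skipped`
#'   (character vector of unencodable inputs).
#' @export
encode_drug_batch <- function(smiles, grammar = default_grammar(),
                              canonicalize = TRUE) {
  smiles <- unique(as.character(smiles))
  ok <- character(0); mats <- list(); q_all <- integer(0); skipped <- character(0)
  for (s in smiles) {
    enc <- tryCatch({
      cs <- if (canonicalize) canonicalize_smiles(s) else s
      p <- parse_to_productions(tokenize_smiles(cs, grammar), grammar)
      list(cs = cs, onehot = encode_one_hot(p, grammar))
    }, error = function(e) e)
    if (inherits(enc, "error")) {
      skipped <- c(skipped, s)
    } else if (enc$cs %in% ok) {
      # two inputs canonicalizing to the same molecule
      next
    } else {
      ok <- c(ok, enc$cs)
      mats[[length(mats) + 1L]] <- enc$onehot
      q_all <- c(q_all, attr(enc$onehot, "rule_count"))
    }
  }
  if (length(skipped)) {
    warning(length(skipped), " SMILES could not be grammar-encoded and were skipped")
  }
  arr <- array(0, dim = c(length(ok), RULE_MAX, length(grammar$rules)),
               dimnames = list(ok, NULL, NULL))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  names(q_all) <- ok
  attr(arr, "rule_counts") <- q_all
  attr(arr, "skipped") <- skipped
  arr
}
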