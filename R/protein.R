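# One-hot protein encoding: a fixed 26 x 1000 binary matrix per amino-acid
# sequence. The dictionary is the 26 uppercase letters A-Z, covering the 20
# canonical residues plus the ambiguity codes (B, J, O, U, X, Z).

PROT_DICT <- LETTERS
PROT_MAX <- 1000L

#' The amino-acid dictionary used for protein one-hot encoding
#'
#' @return Character vector of the 26 uppercase symbols, in encoding order.
#' @export
aa_dictionary <- function() PROT_DICT

#' One-hot encode an amino-acid sequence
#'
#' Produces a 26 x 1000 binary matrix: column `c` has a single 1 in the row
#' of residue `c`. Sequences longer than 1000 residues are truncated to the
#' N-terminal 1000; shorter sequences leave trailing all-zero columns.
#' Lowercase input is uppercased with a warning.
#'
#' @param sequence A single amino-acid string.
#' @return A 26 x 1000 binary matrix of class `protein_onehot`, with
#'   attribute `true_length` (the original sequence length).
#' @examples
#' o <- encode_protein("MKV")
#' sum(o)
#' @export
encode_protein <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty protein sequence")
  if (grepl("[a-z]", sequence)) {
    warning("lowercase residues uppercased in protein sequence")
    sequence <- toupper(sequence)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, PROT_DICT)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop("encoding error: residue '", chars[p], "' at position ", p,
         " is not in the amino-acid dictionary")
  }
  len <- length(chars)
  keep <- min(len, PROT_MAX)
  m <- matrix(0, nrow = length(PROT_DICT), ncol = PROT_MAX)
  m[cbind(idx[seq_len(keep)], seq_len(keep))] <- 1
  structure(m, class = c("protein_onehot", class(m)), true_length = len)
}

#' Decode a protein one-hot matrix back to its sequence
#'
#' @param onehot A `protein_onehot` matrix.
#' @return The amino-acid string (truncated to 1000 residues if the original
#'   was longer).
#' @export
decode_protein <- function(onehot) {
  m <- unclass(onehot)
  stopifnot(is.matrix(m), nrow(m) == length(PROT_DICT))
  cs <- colSums(m)
  if (any(cs > 1)) stop("malformed matrix: a column has more than one 1")
  keep <- which(cs == 1)
  if (length(keep) && !identical(keep, seq_along(keep))) {
    stop("malformed matrix: populated columns are not a prefix")
  }
  paste(PROT_DICT[max.col(t(m[, keep, drop = FALSE]), ties.method = "first")],
        collapse = "")
}

#' One-hot encode a batch of protein sequences
#'
#' Deduplicates the input, encodes each unique sequence, and stacks the
#' results into a `p x 26 x 1000` tensor. A back-map from the original
#' positions to the deduplicated first axis is attached.
#'
#' @param sequences Character vector of amino-acid strings (or a named
#'   vector, e.g. from [read_fasta()]).
#' @return A 3-d array `p x 26 x 1000` with `dimnames[[1]]` the unique
#'   sequences, attributes `back_map` (integer vector, one entry per input)
#'   and `true_lengths`.
#' @export
batch_encode_proteins <- function(sequences) {
  sequences <- as.character(sequences)
  uniq <- unique(sequences)
  arr <- array(0, dim = c(length(uniq), length(PROT_DICT), PROT_MAX),
               dimnames = list(uniq, NULL, NULL))
  lens <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    o <- encode_protein(uniq[i])
    arr[i, , ] <- o
    lens[i] <- attr(o, "true_length")
  }
  attr(arr, "back_map") <- match(sequences, uniq)
  attr(arr, "true_lengths") <- lens
  arr
}

#' Read a FASTA file of protein sequences
#'
#' Minimal multi-record FASTA reader: returns a named character vector of
#' sequences, names taken from the record headers.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) paste(trimws(x), collapse = ""), character(1))
  names(seqs) <- sub("^>\\s*", "", lines[hdr])[as.integer(names(seqs))]
  seqs
}
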