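# Ingestion of drug-target affinity benchmark tables: cleaning, label
# transformation (Kd -> pKd), intersection with the perturbation-derived
# regulatory matrix, and deterministic splitting.

#' Transform a raw affinity label
#'
#' Dissociation constants (`kind = "kd"`, in nM) are converted to
#' pKd = -log10(Kd * 1e-9), the standard regression label for Kd-based
#' affinity datasets; unified `kiba` scores are already on a log-like scale
#' and pass through unchanged.
#'
#' @param value Numeric vector of raw labels.
#' @param kind `"kd"` (nM) or `"kiba"`.
#' @return Numeric vector of transformed labels.
#' @examples
#' transform_label(1, "kd")     # 9
#' transform_label(11.2, "kiba")
#' @export
transform_label <- function(value, kind = c("kd", "kiba")) {
  kind <- match.arg(kind)
  value <- as.numeric(value)
  if (kind == "kd") {
    if (any(value <= 0, na.rm = TRUE)) {
      stop("domain error: Kd values must be strictly positive")
    }
    -log10(value * 1e-9)
  } else {
    value
  }
}

#' Load a drug-target affinity table
#'
#' Reads a delimited interaction table (SMILES, protein sequence, affinity
#' label), drops rows with missing or unparseable required fields,
#' canonicalizes the SMILES, transforms the labels, and deduplicates
#' (drug, protein) pairs keeping the first occurrence. Every dropped row is
#' accounted for in the provenance tallies.
#'
#' @param path Path to a TSV/CSV file.
#' @param schema Named character vector mapping the required fields to column
#'   names, e.g. `c(smiles = "compound_smiles", protein = "target_sequence",
#'   label = "kd_nm")`.
#' @param label_kind `"kd"` or `"kiba"`.
#' @param sep Field separator (default tab).
#' @param canonicalize Canonicalize SMILES on load (default `TRUE`).
#' @return An object of class `dta_dataset`: list with `records` (data.frame
#'   `smiles`, `protein`, `label_raw`, `label`), `label_kind`, `splits`
#'   (NULL until [split_dataset()]), and `provenance` (source + tallies).
#' @export
load_dta_table <- function(path,
                           schema = c(smiles = "smiles", protein = "protein",
                                      label = "label"),
                           label_kind = c("kd", "kiba"), sep = "\t",
                           canonicalize = TRUE) {
  label_kind <- match.arg(label_kind)
  stopifnot(all(c("smiles", "protein", "label") %in% names(schema)))
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character")
  miss <- setdiff(unname(schema), names(df))
  if (length(miss)) {
    stop("schema error: column(s) not in table: ", paste(miss, collapse = ", "))
  }
  n_raw <- nrow(df)
  tallies <- c(missing_field = 0L, bad_label = 0L, bad_smiles = 0L,
               duplicate_pair = 0L)
  if (n_raw == 0L) {
    rec <- data.frame(smiles = character(0), protein = character(0),
                      label_raw = numeric(0), label = numeric(0))
    return(structure(list(records = rec, label_kind = label_kind,
                          splits = NULL,
                          provenance = list(source = path, n_raw = 0L,
                                            tallies = tallies)),
                     class = "dta_dataset"))
  }
  sm <- trimws(df[[schema[["smiles"]]]])
  pr <- trimws(df[[schema[["protein"]]]])
  lb <- trimws(df[[schema[["label"]]]])
  ok <- nzchar(sm) & nzchar(pr) & nzchar(lb) & !is.na(sm) & !is.na(pr) & !is.na(lb)
  tallies["missing_field"] <- sum(!ok)
  sm <- sm[ok]; pr <- pr[ok]; lb <- lb[ok]
  raw <- suppressWarnings(as.numeric(lb))
  bad <- is.na(raw) | !is.finite(raw) | (label_kind == "kd" & raw <= 0)
  tallies["bad_label"] <- sum(bad)
  sm <- sm[!bad]; pr <- pr[!bad]; raw <- raw[!bad]
  if (canonicalize) {
    can <- vapply(sm, function(s) {
      tryCatch(canonicalize_smiles(s), error = function(e) NA_character_)
    }, character(1), USE.NAMES = FALSE)
    bad_sm <- is.na(can)
    tallies["bad_smiles"] <- sum(bad_sm)
    sm <- can[!bad_sm]; pr <- pr[!bad_sm]; raw <- raw[!bad_sm]
  }
  dup <- duplicated(paste(sm, pr, sep = "\r"))
  tallies["duplicate_pair"] <- sum(dup)
  rec <- data.frame(smiles = sm[!dup], protein = pr[!dup],
                    label_raw = raw[!dup],
                    label = transform_label(raw[!dup], label_kind),
                    stringsAsFactors = FALSE)
  structure(list(records = rec, label_kind = label_kind, splits = NULL,
                 provenance = list(source = path, n_raw = n_raw,
                                   tallies = tallies)),
            class = "dta_dataset")
}

#' Construct a `dta_dataset` from in-memory records
#'
#' @param records Data.frame with columns `smiles`, `protein`, `label` (already
#'   transformed) and optionally `label_raw`.
#' @param label_kind `"kd"` or `"kiba"`.
#' @return A `dta_dataset`.
#' @export
dta_dataset <- function(records, label_kind = "kd") {
  stopifnot(all(c("smiles", "protein", "label") %in% names(records)))
  if (is.null(records$label_raw)) records$label_raw <- NA_real_
  structure(list(records = records[, c("smiles", "protein", "label_raw", "label")],
                 label_kind = label_kind, splits = NULL,
                 provenance = list(source = "<in-memory>",
                                   n_raw = nrow(records),
                                   tallies = c(missing_field = 0L, bad_label = 0L,
                                               bad_smiles = 0L, duplicate_pair = 0L))),
            class = "dta_dataset")
}

#' @export
print.dta_dataset <- function(x, ...) {
  cat("DTA dataset:", nrow(x$records), "interactions,",
      length(unique(x$records$smiles)), "compounds,",
      length(unique(x$records$protein)), "proteins",
      paste0("(labels: ", x$label_kind, ")\n"))
  t <- x$provenance$tallies
  cat("  source:", x$provenance$source, " raw rows:", x$provenance$n_raw, "\n")
  cat("  tallies:", paste(names(t), t, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$splits)) {
    cat("  splits:", paste(names(x$splits), lengths(x$splits),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Keep only interactions whose drug has a regulatory vector
#'
#' Mirrors the benchmark-processing step where only drugs present in the
#' perturbation assay are retained. Matching is by canonical SMILES.
#'
#' @param dataset A `dta_dataset` (canonical SMILES).
#' @param matrix A `regulatory_matrix`, or an array from
#'   [regulatory_by_smiles()].
#' @return The filtered `dta_dataset`; the number of removed interactions is
#'   appended to the provenance tallies as `no_regvec`.
#' @export
intersect_with_l1000 <- function(dataset, matrix) {
  stopifnot(inherits(dataset, "dta_dataset"))
  covered <- if (inherits(matrix, "regulatory_matrix")) {
    unique(unname(attr(matrix, "smiles")))
  } else {
    dimnames(matrix)[[1]]
  }
  keep <- dataset$records$smiles %in% covered
  if (!any(keep)) warning("no interactions remain after regulatory intersection")
  dataset$records <- dataset$records[keep, , drop = FALSE]
  rownames(dataset$records) <- NULL
  dataset$provenance$tallies <- c(dataset$provenance$tallies,
                                  no_regvec = sum(!keep))
  dataset$splits <- NULL
  dataset
}

#' Split a dataset into train/validation/test index sets
#'
#' Deterministic seeded shuffle split by interaction. Sizes are
#' `floor(n * fraction)` for all but the first split, which absorbs the
#' remainder; the splits are disjoint and cover all records.
#'
#' @param dataset A `dta_dataset`.
#' @param fractions Named numeric vector summing to 1
#'   (default `c(train = .8, valid = .1, test = .1)`).
#' @param seed Integer seed for the shuffle.
#' @return The dataset with `$splits` set to a named list of integer index
#'   vectors.
#' @export
split_dataset <- function(dataset,
                          fractions = c(train = 0.8, valid = 0.1, test = 0.1),
                          seed = 1L) {
  stopifnot(inherits(dataset, "dta_dataset"))
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("config error: split fractions must sum to 1")
  }
  n <- nrow(dataset$records)
  perm <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    sample.int(n)
  })
  sizes <- floor(n * fractions)
  sizes[1] <- n - sum(sizes[-1])
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  splits <- lapply(seq_along(sizes), function(i) {
    if (sizes[i] == 0L) integer(0) else sort(perm[starts[i]:ends[i]])
  })
  names(splits) <- names(fractions)
  dataset$splits <- splits
  dataset
}
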