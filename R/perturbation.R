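# Replicate-level chemical-perturbation records -> per-perturbagen 978 x 2
# regulatory vectors. For perturbagen i and landmark gene j, the up (down)
# entry is the number of dose-filtered replicates listing j as up- (down-)
# regulated, divided by that perturbagen's replicate count.

N_LANDMARKS <- 978L

#' The default synthetic landmark-gene panel
#'
#' 978 synthetic identifiers `G0001 .. G0978`, standing in for the
#' 978-landmark panel of reduced-representation transcriptomic assays.
#'
#' @return An object of class `landmark_set`: character vector of 978 ids.
#' @export
default_landmarks <- function() {
  structure(sprintf("G%04d", seq_len(N_LANDMARKS)), class = "landmark_set")
}

#' Read a landmark-gene list (one identifier per line)
#'
#' @param path Text file with exactly 978 unique gene identifiers.
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  g <- trimws(readLines(path, warn = FALSE))
  g <- g[nzchar(g)]
  if (length(g) != N_LANDMARKS) {
    stop("landmark list must contain exactly ", N_LANDMARKS,
         " genes; found ", length(g))
  }
  if (anyDuplicated(g)) stop("duplicate gene identifiers in landmark list")
  structure(g, class = "landmark_set")
}

# dose string/unit -> micromolar
.dose_to_um <- function(value, unit) {
  unit <- tolower(trimws(unit))
  unit <- sub("µ", "u", unit)   # micro sign
  fac <- c(pm = 1e-6, nm = 1e-3, um = 1, mm = 1e3, m = 1e6)[unit]
  as.numeric(value) * unname(fac)
}

.parse_dose_string <- function(x) {
  m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*([a-zA-Zµ]+)\\s*$", x))[[1]]
  if (length(m) != 3L) stop("unparseable dose: '", x, "'")
  um <- .dose_to_um(m[2], m[3])
  if (is.na(um)) stop("unparseable dose: '", x, "'")
  um
}

#' Read a replicate-level perturbation export
#'
#' Tab-delimited text with one row per (perturbagen, replicate) and columns
#' `perturbagen_id`, `dose_value`, `dose_unit`, `up_genes`, `down_genes`;
#' the gene lists are `|`-separated. Within a replicate the up and down sets
#' must be disjoint.
#'
#' @param path Path to the export.
#' @return A data.frame with list-columns `up_genes` and `down_genes`.
#' @export
read_replicates <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("perturbagen_id", "dose_value", "dose_unit", "up_genes", "down_genes")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("replicate file missing column(s): ",
                         paste(miss, collapse = ", "))
  split_genes <- function(x) {
    lapply(strsplit(x, "|", fixed = TRUE),
           function(g) unique(g[nzchar(g)]))
  }
  out <- data.frame(perturbagen_id = df$perturbagen_id,
                    dose_value = suppressWarnings(as.numeric(df$dose_value)),
                    dose_unit = df$dose_unit,
                    stringsAsFactors = FALSE)
  out$up_genes <- split_genes(df$up_genes)
  out$down_genes <- split_genes(df$down_genes)
  both <- mapply(function(u, d) length(intersect(u, d)) > 0,
                 out$up_genes, out$down_genes)
  if (any(both)) {
    stop("replicate file violates up/down disjointness in row(s): ",
         paste(which(both), collapse = ", "))
  }
  out
}

#' Filter perturbation replicates to a single dose concentration
#'
#' Doses are normalized to micromolar before comparison (so `10000 nM`
#' matches a `10uM` target) and compared with a relative tolerance of 1e-6.
#' Replicates with unparseable doses are dropped with a warning. Input order
#' is preserved.
#'
#' @param replicates Data.frame from [read_replicates()].
#' @param target_dose Target concentration as a string with unit
#'   (default `"10uM"`, the standard single-dose selection).
#' @return The retained replicate rows, with attribute
#'   `dropped_dose` / `dropped_unparseable` tallies.
#' @export
filter_by_dose <- function(replicates, target_dose = "10uM") {
  target <- .parse_dose_string(target_dose)
  n <- nrow(replicates)
  if (n == 0L) {
    return(structure(replicates, dropped_dose = 0L, dropped_unparseable = 0L))
  }
  um <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    um[i] <- tryCatch(.dose_to_um(replicates$dose_value[i],
                                  replicates$dose_unit[i]),
                      error = function(e) NA_real_)
  }
  bad <- is.na(um)
  if (any(bad)) warning(sum(bad), " replicate(s) dropped: unparseable dose")
  keep <- !bad & abs(um - target) <= 1e-6 * max(abs(target), 1e-300)
  structure(replicates[keep, , drop = FALSE],
            dropped_dose = sum(!keep & !bad),
            dropped_unparseable = sum(bad))
}

#' Annotate replicates with canonical SMILES via a perturbagen mapping table
#'
#' @param replicates Data.frame of replicates.
#' @param mapping Data.frame with columns `perturbagen_id` and `smiles`, or a
#'   path to a tab-delimited file with those columns.
#' @param canonicalize Canonicalize the mapped SMILES (default `TRUE`).
#' @return Replicates with a `smiles` column; perturbagens absent from the
#'   mapping are dropped, their count in attribute `dropped_unmapped`.
#' @export
map_to_smiles <- function(replicates, mapping, canonicalize = TRUE) {
  if (is.character(mapping)) {
    if (!file.exists(mapping)) {
      stop("configuration error: mapping file not found: ", mapping)
    }
    mapping <- read.delim(mapping, stringsAsFactors = FALSE)
  }
  if (!all(c("perturbagen_id", "smiles") %in% names(mapping))) {
    stop("mapping must have columns 'perturbagen_id' and 'smiles'")
  }
  sm <- mapping$smiles[match(replicates$perturbagen_id, mapping$perturbagen_id)]
  keep <- !is.na(sm)
  if (any(!keep)) {
    warning(sum(!keep), " replicate(s) dropped: perturbagen not in mapping")
  }
  out <- replicates[keep, , drop = FALSE]
  out$smiles <- if (canonicalize && nrow(out)) canonicalize_smiles(sm[keep]) else sm[keep]
  structure(out, dropped_unmapped = sum(!keep))
}

#' Compute the regulatory vector of one perturbagen
#'
#' For gene `j`, the up entry is the fraction of this perturbagen's
#' replicates listing `j` as up-regulated, and likewise for down. Genes
#' outside the landmark panel are dropped (tallied in attribute
#' `dropped_genes`); duplicate mentions within one replicate count once.
#'
#' @param replicates Data.frame of replicates, all of one perturbagen.
#' @param landmarks A `landmark_set`.
#' @return A 978 x 2 matrix (columns `up`, `down`, rows named by gene) of
#'   class `regulatory_vector`, with attribute `replicate_count`.
#' @export
compute_regulatory_vector <- function(replicates, landmarks = default_landmarks()) {
  n_rep <- nrow(replicates)
  if (is.null(n_rep) || n_rep < 1L) {
    stop("contract violation: at least one replicate is required")
  }
  if (length(unique(replicates$perturbagen_id)) > 1L) {
    stop("replicates belong to more than one perturbagen")
  }
  v <- matrix(0, nrow = N_LANDMARKS, ncol = 2,
              dimnames = list(as.character(landmarks), c("up", "down")))
  dropped <- 0L
  for (i in seq_len(n_rep)) {
    for (col in 1:2) {
      genes <- unique(replicates[[c("up_genes", "down_genes")[col]]][[i]])
      pos <- match(genes, landmarks)
      dropped <- dropped + sum(is.na(pos))
      pos <- pos[!is.na(pos)]
      v[pos, col] <- v[pos, col] + 1
    }
  }
  structure(v / n_rep, class = c("regulatory_vector", "matrix", "array"),
            replicate_count = n_rep, dropped_genes = dropped)
}

#' Build the stacked regulatory matrix for a perturbation export
#'
#' Full pipeline: dose filtering, SMILES mapping, per-perturbagen counting
#' and replicate normalization, and stacking into a `k x 978 x 2` array with
#' one slice per unique retained perturbagen, ordered by perturbagen id.
#'
#' @param replicates Data.frame from [read_replicates()] (or a path).
#' @param mapping Perturbagen-to-SMILES table or path (see [map_to_smiles()]).
#' @param landmarks A `landmark_set`.
#' @param target_dose Dose retained by the filter (default `"10uM"`).
#' @return An object of class `regulatory_matrix`: array `k x 978 x 2` with
#'   perturbagen ids on the first axis, plus attributes `smiles` (named
#'   character), `replicate_counts`, and `tallies` (drop counts per stage).
#' @export
build_regulatory_matrix <- function(replicates, mapping,
                                    landmarks = default_landmarks(),
                                    target_dose = "10uM") {
  if (is.character(replicates)) replicates <- read_replicates(replicates)
  dosed <- filter_by_dose(replicates, target_dose)
  mapped <- map_to_smiles(dosed, mapping)
  ids <- sort(unique(mapped$perturbagen_id))
  arr <- array(0, dim = c(length(ids), N_LANDMARKS, 2L),
               dimnames = list(ids, as.character(landmarks), c("up", "down")))
  smiles <- character(length(ids)); names(smiles) <- ids
  counts <- integer(length(ids)); names(counts) <- ids
  dropped_genes <- 0L
  for (i in seq_along(ids)) {
    rows <- mapped[mapped$perturbagen_id == ids[i], , drop = FALSE]
    v <- compute_regulatory_vector(rows, landmarks)
    arr[i, , ] <- v
    smiles[i] <- rows$smiles[1]
    counts[i] <- attr(v, "replicate_count")
    dropped_genes <- dropped_genes + attr(v, "dropped_genes")
  }
  structure(arr,
            class = c("regulatory_matrix", "array"),
            smiles = smiles,
            replicate_counts = counts,
            tallies = c(dropped_dose = attr(dosed, "dropped_dose"),
                        dropped_unparseable = attr(dosed, "dropped_unparseable"),
                        dropped_unmapped = attr(mapped, "dropped_unmapped"),
                        dropped_genes = dropped_genes))
}

#' @export
print.regulatory_matrix <- function(x, ...) {
  cat("Regulatory matrix:", dim(x)[1], "perturbagen(s) x", dim(x)[2],
      "landmark genes x 2 channels\n")
  t <- attr(x, "tallies")
  cat("  drop tallies:", paste(names(t), t, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Pool a regulatory matrix by canonical SMILES
#'
#' Two perturbagen ids can map to the same molecule; downstream the feature
#' is per drug. Pooling merges such slices by replicate-weighted averaging of
#' the frequencies (equivalent to recounting over the union of replicates).
#'
#' @param mat A `regulatory_matrix`.
#' @return A `k' x 978 x 2` array with canonical SMILES on the first axis and
#'   attribute `replicate_counts`.
#' @export
regulatory_by_smiles <- function(mat) {
  sm <- attr(mat, "smiles")
  counts <- attr(mat, "replicate_counts")
  uniq <- sort(unique(unname(sm)))
  out <- array(0, dim = c(length(uniq), dim(mat)[2], dim(mat)[3]),
               dimnames = list(uniq, dimnames(mat)[[2]], dimnames(mat)[[3]]))
  n_out <- integer(length(uniq)); names(n_out) <- uniq
  for (i in seq_along(uniq)) {
    idx <- which(sm == uniq[i])
    w <- counts[idx]
    acc <- 0
    for (j in seq_along(idx)) acc <- acc + mat[idx[j], , ] * w[j]
    out[i, , ] <- acc / sum(w)
    n_out[i] <- sum(w)
  }
  attr(out, "replicate_counts") <- n_out
  out
}
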