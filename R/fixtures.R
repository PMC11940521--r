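# Deterministic synthetic-data generators. Every pipeline stage can be
# exercised end-to-end, file-based, with no downloads: grammar-sampled
# SMILES, replicate-level perturbation exports with closed-form ground-truth
# regulatory vectors, random protein sequences, and interaction tables with
# known (planted) label structure.

# Minimum number of sentential-form symbols each non-terminal can terminate
# into, used to force termination once the size budget is reached.
.min_expansion <- function(grammar) {
  n_nt <- length(grammar$nonterminals)
  sz <- stats::setNames(rep(Inf, n_nt), grammar$nonterminals)
  repeat {
    changed <- FALSE
    for (r in grammar$rules) {
      cost <- sum(ifelse(r$rhs_is_nt, sz[r$rhs], 1))
      if (cost < sz[r$lhs]) { sz[r$lhs] <- cost; changed <- TRUE }
    }
    if (!changed) break
  }
  sz
}

# Default sampling weight per production, biased towards small acyclic
# molecules so that most draws are chemically meaningful.
.rule_weights <- function(grammar) {
  w <- rep(1, length(grammar$rules))
  for (i in seq_along(grammar$rules)) {
    r <- grammar$rules[[i]]
    rhs <- paste(r$rhs, collapse = " ")
    w[i] <- switch(r$lhs,
      chain = c("branched_atom" = 2.5, "chain branched_atom" = 2,
                "chain bond branched_atom" = 0.6)[rhs],
      branched_atom = c("atom" = 6, "atom RB" = 0.15, "atom BB" = 1,
                        "atom RB BB" = 0.05)[rhs],
      atom = c("bracket_atom" = 0.4, "aliphatic_organic" = 8,
               "aromatic_organic" = 0.5)[rhs],
      aliphatic_organic = if (rhs %in% c("'C'", "C")) 6 else
        if (rhs %in% c("N", "O")) 2 else 0.4,
      BB = c("BB branch" = 0.3, "branch" = 1)[rhs],
      branch = c("( chain )" = 1, "( bond chain )" = 0.2)[rhs],
      BAI = c("symbol" = 2, "symbol BAC" = 1, "isotope symbol" = 0.1,
              "isotope symbol BAC" = 0.05)[rhs],
      1)
    if (is.na(w[i])) w[i] <- 1
  }
  w[grammar$padding_rule] <- 0
  w
}

#' Sample syntactically valid SMILES from the grammar
#'
#' Draws random depth-bounded leftmost derivations from the start symbol, so
#' every string tokenizes and parses by construction, then keeps only draws
#' whose canonical form (Open Babel) also parses with at most 277 rules.
#' Draws failing canonicalization are regenerated within a bounded retry
#' budget.
#'
#' @param n Number of SMILES to generate.
#' @param seed Integer seed.
#' @param grammar A `smiles_grammar`.
#' @param max_symbols Size budget on the sentential form; once exceeded,
#'   every non-terminal is closed with its smallest expansion.
#' @param unique Require distinct canonical SMILES (default `TRUE`).
#' @param max_tries Total retry budget (default `50 * n`).
#' @return Character vector of `n` canonical SMILES, each of which
#'   tokenizes, parses, and re-canonicalizes to itself.
#' @export
gen_smiles <- function(n, seed = 1L, grammar = default_grammar(),
                       max_symbols = 40L, unique = TRUE,
                       max_tries = 50L * max(n, 1L)) {
  set.seed(seed)
  if (n == 0L) return(character(0))
  minsz <- .min_expansion(grammar)
  weights <- .rule_weights(grammar)
  by_lhs <- grammar$rules_by_lhs
  draw_one <- function() {
    syms <- grammar$start; is_nt <- TRUE
    q <- 0L
    while (any(is_nt)) {
      k <- which(is_nt)[1]
      cand <- by_lhs[[syms[k]]]
      if (q >= RULE_MAX - 1L || length(syms) > max_symbols) {
        # force termination: smallest expansion
        cost <- vapply(cand, function(ri) {
          r <- grammar$rules[[ri]]
          sum(ifelse(r$rhs_is_nt, minsz[r$rhs], 1))
        }, numeric(1))
        pick <- cand[which.min(cost)]
      } else {
        w <- weights[cand]
        if (sum(w) <= 0) w <- rep(1, length(cand))
        pick <- if (length(cand) == 1L) cand else
          sample(cand, 1L, prob = w)
      }
      r <- grammar$rules[[pick]]
      syms <- append(syms[-k], r$rhs, after = k - 1L)
      is_nt <- append(is_nt[-k], r$rhs_is_nt, after = k - 1L)
      q <- q + 1L
      if (q > 4L * RULE_MAX) return(NULL)   # runaway derivation
    }
    paste(syms, collapse = "")
  }
  out <- character(0)
  tries <- 0L
  while (length(out) < n && tries < max_tries) {
    tries <- tries + 1L
    s <- draw_one()
    if (is.null(s)) next
    cs <- tryCatch(canonicalize_smiles(s), error = function(e) NULL)
    if (is.null(cs)) next
    ok <- tryCatch({
      parse_to_productions(tokenize_smiles(cs, grammar), grammar)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) next
    if (unique && cs %in% out) next
    out <- c(out, cs)
  }
  if (length(out) < n) {
    stop("generation error: retry budget exhausted after ", tries,
         " draws (", length(out), "/", n, " SMILES)")
  }
  out
}

#' Sample random protein sequences
#'
#' Uniform sequences over the 20 canonical amino acids, lengths uniform in
#' `length_range`.
#'
#' @param n Number of sequences.
#' @param length_range Integer range of sequence lengths (default 80-160).
#' @param seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
gen_proteins <- function(n, length_range = c(80L, 160L), seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    len <- sample(length_range[1]:length_range[2], 1L)
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Write a synthetic replicate-level perturbation export
#'
#' Emulates an L1000-style chemical-perturbation file: each drug becomes a
#' perturbagen with `replicates_per_drug` replicates at the 10 uM target
#' dose plus `off_dose_replicates` replicates at an off-target dose (which
#' the dose filter must discard). Up and down gene sets are drawn disjointly
#' per replicate. A third of the on-target doses are spelled `10000 nM` to
#' exercise unit normalization. The closed-form ground-truth regulatory
#' matrix (counting only on-target replicates) is returned and written as a
#' JSON sidecar.
#'
#' @param drugs Character vector of (canonical) SMILES; one perturbagen each.
#' @param dir Output directory (created if needed).
#' @param landmarks A `landmark_set`.
#' @param replicates_per_drug On-target replicates per perturbagen.
#' @param off_dose_replicates Off-target (1 uM) replicates per perturbagen.
#' @param genes_per_list Genes drawn for each of the up and down lists.
#' @param seed Integer seed.
#' @return List with `replicates` and `mapping` file paths, `truth` (the
#'   `k x 978 x 2` ground-truth array, perturbagen-id dimnames), and
#'   `truth_json` path.
#' @export
gen_perturbation_export <- function(drugs, dir,
                                    landmarks = default_landmarks(),
                                    replicates_per_drug = 3L,
                                    off_dose_replicates = 1L,
                                    genes_per_list = 50L, seed = 1L) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("PERT-%04d", seq_along(drugs))
  rows <- list()
  truth <- array(0, dim = c(length(ids), N_LANDMARKS, 2L),
                 dimnames = list(ids, as.character(landmarks), c("up", "down")))
  for (i in seq_along(ids)) {
    for (rep_i in seq_len(replicates_per_drug + off_dose_replicates)) {
      on_target <- rep_i <= replicates_per_drug
      genes <- sample(as.character(landmarks), 2L * genes_per_list)
      up <- genes[seq_len(genes_per_list)]
      down <- genes[genes_per_list + seq_len(genes_per_list)]
      if (on_target) {
        truth[i, match(up, landmarks), 1L] <-
          truth[i, match(up, landmarks), 1L] + 1
        truth[i, match(down, landmarks), 2L] <-
          truth[i, match(down, landmarks), 2L] + 1
      }
      alt_unit <- on_target && rep_i %% 3L == 0L
      rows[[length(rows) + 1L]] <- data.frame(
        perturbagen_id = ids[i],
        dose_value = if (!on_target) "1" else if (alt_unit) "10000" else "10",
        dose_unit = if (!on_target) "uM" else if (alt_unit) "nM" else "uM",
        up_genes = paste(up, collapse = "|"),
        down_genes = paste(down, collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  truth <- truth / replicates_per_drug
  rep_path <- file.path(dir, "replicates.tsv")
  map_path <- file.path(dir, "mapping.tsv")
  truth_path <- file.path(dir, "regulatory_truth.json")
  write.table(do.call(rbind, rows), rep_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(perturbagen_id = ids, smiles = drugs),
              map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(perturbagens = ids, smiles = drugs,
         replicate_count = replicates_per_drug,
         up = lapply(seq_along(ids), function(i) unname(truth[i, , 1L])),
         down = lapply(seq_along(ids), function(i) unname(truth[i, , 2L]))),
    truth_path, digits = NA)
  list(replicates = rep_path, mapping = map_path, truth = truth,
       truth_json = truth_path)
}

#' Write a synthetic drug-target interaction table
#'
#' Samples `n_interactions` distinct (drug, protein) pairs and labels them
#' under one of three models: `random` (i.i.d. Gaussian labels),
#' `planted_rnaseq` (label linear in the drug's flattened ground-truth
#' regulatory vector plus noise, so the RNA-Seq branch carries the signal),
#' or `planted_linear` (label a fixed linear function of simple drug and
#' protein descriptors, a learnable deterministic target for overfitting
#' checks). Labels are centred at a pKd-like 7 with unit-scale spread.
#'
#' @param drugs Character vector of canonical SMILES.
#' @param proteins Character vector of sequences.
#' @param n_interactions Number of (drug, protein) pairs.
#' @param path Output TSV path.
#' @param label_model `"random"`, `"planted_rnaseq"`, or `"planted_linear"`.
#' @param regulatory For `planted_rnaseq`: the ground-truth array from
#'   [gen_perturbation_export()] with `smiles` dimnames, or that generator's
#'   `truth` with drugs in the same order as `drugs`.
#' @param noise_sd Gaussian noise added to planted labels (default 0.1).
#' @param seed Integer seed.
#' @return List with `path`, the records data.frame, and `truth` (planted
#'   weights / descriptor coefficients, for oracle checks).
#' @export
gen_dta_table <- function(drugs, proteins, n_interactions, path,
                          label_model = c("random", "planted_rnaseq",
                                          "planted_linear"),
                          regulatory = NULL, noise_sd = 0.1, seed = 1L) {
  label_model <- match.arg(label_model)
  set.seed(seed)
  n_max <- length(drugs) * length(proteins)
  if (n_interactions > n_max) {
    stop("spec error: ", n_interactions, " interactions requested but only ",
         n_max, " pairs exist")
  }
  pair_idx <- sample.int(n_max, n_interactions)
  di <- ((pair_idx - 1L) %% length(drugs)) + 1L
  pi_ <- ((pair_idx - 1L) %/% length(drugs)) + 1L
  truth <- list(model = label_model, noise_sd = noise_sd)
  if (label_model == "random") {
    y <- rnorm(n_interactions, mean = 7, sd = 1)
  } else if (label_model == "planted_rnaseq") {
    if (is.null(regulatory)) stop("planted_rnaseq requires the regulatory truth")
    v <- matrix(0, length(drugs), 2L * N_LANDMARKS)
    for (i in seq_along(drugs)) v[i, ] <- as.numeric(regulatory[i, , ])
    w <- rnorm(2L * N_LANDMARKS)
    z <- as.numeric(v %*% w)
    z <- (z - mean(z)) / max(sd(z), 1e-12)
    y <- 7 + z[di] + rnorm(n_interactions, sd = noise_sd)
    truth$weights <- w
  } else {
    qd <- vapply(drugs, function(s) {
      length(parse_to_productions(tokenize_smiles(s), max_rules = RULE_MAX))
    }, numeric(1))
    pl <- nchar(proteins)
    pa <- vapply(proteins, function(s) {
      mean(strsplit(s, "")[[1]] %in% c("A", "L", "V", "I"))
    }, numeric(1))
    z1 <- (qd - mean(qd)) / max(sd(qd), 1e-12)
    z2 <- (pl - mean(pl)) / max(sd(pl), 1e-12)
    z3 <- (pa - mean(pa)) / max(sd(pa), 1e-12)
    y <- 7 + 0.8 * z1[di] + 0.6 * z2[pi_] + 0.4 * z3[pi_] +
      rnorm(n_interactions, sd = noise_sd)
    truth$coef <- c(intercept = 7, drug_rules = 0.8, prot_len = 0.6,
                    prot_hydrophobic = 0.4)
  }
  rec <- data.frame(smiles = drugs[di], protein = proteins[pi_],
                    label = round(y, 6), stringsAsFactors = FALSE)
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(path = path, records = rec, truth = truth)
}

#' Generate a complete synthetic fixture set
#'
#' Orchestrates the individual generators into one directory: a landmark
#' list, a perturbation export with SMILES mapping, and an interaction
#' table, with the fixture specification serialized alongside as YAML.
#'
#' @param out_dir Output directory.
#' @param n_drugs,n_proteins,n_interactions Pool and table sizes.
#' @param replicates_per_drug On-target replicates per perturbagen.
#' @param protein_length_range Protein length range (default 80-160).
#' @param label_model Label model for the interaction table.
#' @param noise_sd Label noise for planted models.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return List of file paths plus the generator ground truths.
#' @export
gen_fixture_set <- function(out_dir, n_drugs = 20L, n_proteins = 10L,
                            n_interactions = 100L, replicates_per_drug = 3L,
                            protein_length_range = c(80L, 160L),
                            label_model = "random", noise_sd = 0.1,
                            seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- list(n_drugs = n_drugs, n_proteins = n_proteins,
               n_interactions = n_interactions,
               replicates_per_drug = replicates_per_drug,
               protein_length_range = as.integer(protein_length_range),
               label_model = label_model, noise_sd = noise_sd, seed = seed)
  yaml::write_yaml(spec, file.path(out_dir, "fixture_spec.yaml"))
  landmarks <- default_landmarks()
  writeLines(as.character(landmarks), file.path(out_dir, "landmarks.txt"))
  drugs <- gen_smiles(n_drugs, seed = seed)
  proteins <- gen_proteins(n_proteins, protein_length_range, seed = seed + 1L)
  pert <- gen_perturbation_export(drugs, out_dir, landmarks,
                                  replicates_per_drug = replicates_per_drug,
                                  seed = seed + 2L)
  reg_truth <- pert$truth
  dimnames(reg_truth)[[1]] <- drugs
  dta <- gen_dta_table(drugs, proteins, n_interactions,
                       file.path(out_dir, "interactions.tsv"),
                       label_model = label_model, regulatory = reg_truth,
                       noise_sd = noise_sd, seed = seed + 3L)
  list(dir = out_dir,
       landmarks = file.path(out_dir, "landmarks.txt"),
       replicates = pert$replicates, mapping = pert$mapping,
       interactions = dta$path,
       regulatory_truth = reg_truth, dta_truth = dta$truth,
       spec = spec)
}
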