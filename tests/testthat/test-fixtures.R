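test_that("grammar-sampled SMILES always tokenize and parse", {
  g <- test_grammar()
  sm <- gen_smiles(15, seed = 31)
  expect_length(sm, 15L)
  for (s in sm) {
    p <- parse_to_productions(tokenize_smiles(s, g), g)
    expect_lte(length(p), 277L)
    # canonical by construction: generator returns toolkit-canonical strings
    expect_identical(canonicalize_smiles(s), s)
  }
  expect_identical(gen_smiles(5, seed = 31), sm[1:5])  # seeded prefix property
  expect_identical(gen_smiles(0, seed = 1), character(0))
})

test_that("the perturbation export matches its closed-form ground truth", {
  dir <- tempfile("pert")
  drugs <- c("CCO", "CCN")
  out <- gen_perturbation_export(drugs, dir, replicates_per_drug = 3,
                                 off_dose_replicates = 1, seed = 17)
  reps <- read_replicates(out$replicates)
  # 4 replicate rows per drug, of which 3 survive the dose filter
  expect_identical(nrow(reps), 8L)
  mat <- build_regulatory_matrix(out$replicates, out$mapping)
  expect_identical(unname(attr(mat, "replicate_counts")), c(3L, 3L))
  expect_equal(unclass(mat)[, , ], out$truth[, , ])
  # up/down disjointness in every replicate row
  for (i in seq_len(nrow(reps))) {
    expect_length(intersect(reps$up_genes[[i]], reps$down_genes[[i]]), 0L)
  }
})

test_that("fixture files are byte-identical under a fixed seed", {
  d1 <- tempfile("fx1"); d2 <- tempfile("fx2")
  a <- gen_perturbation_export(c("CCO", "CC"), d1, seed = 5)
  b <- gen_perturbation_export(c("CCO", "CC"), d2, seed = 5)
  expect_identical(readLines(a$replicates), readLines(b$replicates))
  expect_identical(readLines(a$mapping), readLines(b$mapping))
  expect_identical(readLines(a$truth_json), readLines(b$truth_json))
  c2 <- gen_perturbation_export(c("CCO", "CC"), tempfile(), seed = 6)
  expect_false(identical(readLines(a$replicates), readLines(c2$replicates)))
})

test_that("planted-rnaseq labels are linear in the regulatory vectors", {
  dir <- tempfile("fx")
  drugs <- gen_smiles(8, seed = 23)
  pert <- gen_perturbation_export(drugs, dir, seed = 23)
  truth <- pert$truth
  dimnames(truth)[[1]] <- drugs
  dta <- gen_dta_table(drugs, gen_proteins(5, seed = 24), 40,
                       file.path(dir, "dta.tsv"),
                       label_model = "planted_rnaseq",
                       regulatory = truth, noise_sd = 0, seed = 25)
  # zero-noise oracle: a linear model on the flattened vectors is exact
  V <- t(vapply(dta$records$smiles, function(s) as.numeric(truth[s, , ]),
                numeric(2 * 978)))
  fitlm <- lm(dta$records$label ~ V[, colSums(abs(V)) > 0])
  expect_lt(mean(residuals(fitlm)^2), 1e-10)
  expect_true(all(is.finite(dta$records$label)))
})

test_that("interaction tables are seeded, bounded, and well-formed", {
  drugs <- c("CCO", "CC", "CCN")
  prots <- c("MKVLAW", "ACDEFG")
  f1 <- tempfile(); f2 <- tempfile()
  a <- gen_dta_table(drugs, prots, 6, f1, label_model = "planted_linear", seed = 3)
  b <- gen_dta_table(drugs, prots, 6, f2, label_model = "planted_linear", seed = 3)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(nrow(a$records), 6L)
  expect_false(any(duplicated(paste(a$records$smiles, a$records$protein))))
  expect_error(gen_dta_table(drugs, prots, 7, tempfile()), "spec error")
})

test_that("fixture sets round-trip through the package readers cleanly", {
  fx <- gen_fixture_set(tempfile("set"), n_drugs = 6, n_proteins = 4,
                        n_interactions = 12, seed = 41)
  expect_no_warning({
    lm_ <- read_landmarks(fx$landmarks)
    reps <- read_replicates(fx$replicates)
    ds <- load_dta_table(fx$interactions, label_kind = "kiba",
                         canonicalize = FALSE)
  })
  expect_identical(nrow(ds$records), 12L)
  expect_identical(sum(ds$provenance$tallies), 0L)
  mat <- build_regulatory_matrix(fx$replicates, fx$mapping, lm_)
  expect_identical(dim(mat)[1], 6L)
  spec <- yaml::read_yaml(file.path(fx$dir, "fixture_spec.yaml"))
  expect_equal(spec$seed, 41)
})
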