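# Small end-to-end fits: a handful of epochs on tiny fixtures, checking the
# modelling interface, determinism, and optimizer contracts rather than
# predictive quality (covered by the acceptance suite).

tiny_fit <- function(epochs = 2, lr = 0.001, seed = 1, use_rnaseq = TRUE) {
  fx <- .test_env$tiny_fx
  if (is.null(fx)) {
    fx <- gen_fixture_set(tempfile("tiny"), n_drugs = 6, n_proteins = 4,
                          n_interactions = 24, label_model = "random",
                          protein_length_range = c(40L, 80L), seed = 55)
    .test_env$tiny_fx <- fx
  }
  ds <- load_dta_table(fx$interactions, label_kind = "kiba", canonicalize = FALSE)
  ds$label_kind <- "transformed"
  reg <- build_regulatory_matrix(fx$replicates, fx$mapping,
                                 read_landmarks(fx$landmarks))
  gramdta(ds, regulatory = reg,
          config = gramdta_config(use_rnaseq = use_rnaseq),
          train = train_config(epochs = epochs, batch_size = 8, seed = seed,
                               learning_rate = lr, scheduler = "constant"),
          fractions = c(train = 0.7, valid = 0.15, test = 0.15),
          canonicalize = FALSE)
}

test_that("the fitted object exposes the standard modelling interface", {
  fit <- tiny_fit(epochs = 2)
  expect_s3_class(fit, "gramdta")
  expect_identical(nrow(fit$history), 2L)
  expect_true(all(c("epoch", "train_mse", "valid_mse", "valid_ci") %in%
                    names(fit$history)))
  expect_length(fitted(fit), length(fit$splits$train))
  expect_length(residuals(fit), length(fit$splits$train))
  expect_type(coef(fit), "list")
  expect_output(print(fit), "drug-target affinity")
  ev <- evaluate(fit, split = "test")
  expect_s3_class(ev, "gramdta_metrics")
  expect_gte(ev$ci, 0); expect_lte(ev$ci, 1); expect_gte(ev$mse, 0)
  expect_lte(ev$usable_pairs, ev$n * (ev$n - 1) / 2)
  # evaluating twice gives an identical report
  expect_identical(unclass(ev), unclass(evaluate(fit, split = "test")))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("predict scores new pairs and NA-flags unencodable drugs", {
  fit <- tiny_fit(epochs = 2)
  rec <- fit$tensors$records
  nd <- data.frame(smiles = c(rec$smiles[1], "C%99CC%99"),
                   protein = c(rec$protein[1], rec$protein[1]))
  p <- suppressWarnings(predict(fit, nd, canonicalize = FALSE))
  expect_length(p, 2L)
  expect_true(is.finite(p[1]))
  expect_true(is.na(p[2]))
  # stored-pair prediction agrees with the training-split fitted values
  idx <- fit$splits$train[1]
  pair <- fit$tensors$records[idx, ]
  p2 <- predict(fit, pair[, c("smiles", "protein")], canonicalize = FALSE)
  expect_equal(unname(p2), fitted(fit)[1], tolerance = 1e-10)
})

test_that("fixed seeds reproduce the epoch-1 loss bit-for-bit", {
  f1 <- tiny_fit(epochs = 1, seed = 9)
  f2 <- tiny_fit(epochs = 1, seed = 9)
  expect_identical(f1$history$train_mse[1], f2$history$train_mse[1])
  expect_identical(f1$model$params, f2$model$params)
  f3 <- tiny_fit(epochs = 1, seed = 10)
  expect_false(identical(f1$history$train_mse[1], f3$history$train_mse[1]))
})

test_that("a zero learning rate leaves the loss unchanged across epochs", {
  fit <- tiny_fit(epochs = 3, lr = 0)
  expect_identical(fit$history$train_mse[1], fit$history$train_mse[2])
  expect_identical(fit$history$train_mse[2], fit$history$train_mse[3])
})

test_that("ablation changes only the head input width, not the interface", {
  fit <- tiny_fit(epochs = 1, use_rnaseq = FALSE)
  expect_false(fit$config$use_rnaseq)
  expect_identical(ncol(fit$model$params[["head.dense1.W"]]), 56L + 128L)
  expect_s3_class(evaluate(fit, "test"), "gramdta_metrics")
})

test_that("empty training splits are rejected", {
  expect_error(gramdta(
    dta_dataset(data.frame(smiles = c("CCO", "CC"),
                           protein = c("MKV", "MKV"), label = c(7, 8))),
    config = gramdta_config(use_rnaseq = FALSE),
    train = train_config(epochs = 1),
    fractions = c(train = 0, valid = 0.5, test = 0.5),
    canonicalize = FALSE), "empty training split")
})
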