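test_that("branch latents have the configured shapes", {
  m <- gramdta_model(gramdta_config(), seed = 1)
  drugs <- encode_drug_batch(test_drugs(4), canonicalize = FALSE)
  lat <- drug_encoder_forward(m, drugs)
  expect_identical(dim(lat), c(4L, 56L))
  expect_true(all(is.finite(lat)))

  vecs <- array(runif(2 * 978 * 2), c(2, 978, 2))
  rl <- rnaseq_encoder_forward(m, vecs)
  expect_identical(dim(rl), c(2L, 128L))
  # all-zero regulation still yields finite output
  expect_true(all(is.finite(rnaseq_encoder_forward(m, array(0, c(1, 978, 2))))))
  # two different perturbagen vectors map to different latents at random init
  expect_false(isTRUE(all.equal(rl[1, ], rl[2, ])))

  prots <- batch_encode_proteins(test_proteins(2))
  pl <- protein_cnn_forward(m, prots)
  expect_identical(dim(pl), c(2L, 128L))
})

test_that("identical inputs give identical latents and batches are equivariant", {
  m <- gramdta_model(gramdta_config(), seed = 2)
  drugs <- encode_drug_batch(test_drugs(3), canonicalize = FALSE)
  l1 <- drug_encoder_forward(m, drugs)
  l2 <- drug_encoder_forward(m, drugs)
  expect_identical(l1, l2)
  perm <- c(3L, 1L, 2L)
  lp <- drug_encoder_forward(m, drugs[perm, , , drop = FALSE])
  expect_equal(lp, l1[perm, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("global max pooling ignores motif position within zero padding", {
  m <- gramdta_model(gramdta_config(), seed = 3)
  motif <- unclass(encode_protein("MKVLAWHH"))[, 1:8]
  mk <- function(at) {
    x <- array(0, c(1, 26, 1000))
    x[1, , at:(at + 7)] <- motif
    x
  }
  # both placements keep full zero flanks, so every window type (all-zero,
  # partial-overlap, interior) occurs in both maps and the pooled max agrees
  a <- protein_cnn_forward(m, mk(51))
  b <- protein_cnn_forward(m, mk(301))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("cropped protein convolution equals the full-width computation", {
  ns <- asNamespace("gramdta")
  m <- gramdta_model(gramdta_config(), seed = 4)
  oh <- batch_encode_proteins(test_proteins(3))
  cropped <- protein_cnn_forward(m, oh)       # uses the trailing-zero shortcut
  full <- t(ns$.prot_cnn_fwd(m$params, m$config, aperm(oh, c(2, 3, 1)))$latent)
  expect_identical(cropped, full)
})

test_that("the LSTM branch is order-sensitive and finite on padding", {
  cfg <- gramdta_config(protein_branch = "rnn")
  m <- gramdta_model(cfg, seed = 5)
  s <- "MKVLAWHHGGACDEFIKLMN"
  fwd <- protein_rnn_forward(m, encode_protein(s))
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  bwd <- protein_rnn_forward(m, encode_protein(rev_s))
  expect_identical(dim(fwd), c(1L, 128L))
  expect_false(isTRUE(all.equal(fwd, bwd)))
  # all-padding input (no residues) still yields a finite latent
  allpad <- array(0, c(1, 26, 1000))
  expect_true(all(is.finite(protein_rnn_forward(m, allpad))))
})

test_that("the head fuses latents and shrinks without the RNA-Seq branch", {
  m_on <- gramdta_model(gramdta_config(use_rnaseq = TRUE), seed = 6)
  m_off <- gramdta_model(gramdta_config(use_rnaseq = FALSE), seed = 6)
  w_on <- ncol(m_on$params[["head.dense1.W"]])
  w_off <- ncol(m_off$params[["head.dense1.W"]])
  expect_identical(w_on - w_off, 128L)   # exactly the rnaseq latent width
  dl <- matrix(rnorm(2 * 56), 2, 56)
  pl <- matrix(rnorm(2 * 128), 2, 128)
  rl <- matrix(rnorm(2 * 128), 2, 128)
  pred <- regression_head(m_on, dl, pl, rl)
  expect_length(pred, 2L)
  expect_true(all(is.finite(pred)))
  expect_length(regression_head(m_off, dl, pl), 2L)
  expect_error(regression_head(m_on, dl, pl), "rnaseq latent")
  expect_error(regression_head(m_on, dl[, 1:10], pl, rl), "width mismatch")
})

test_that("parameter count is a pure function of the configuration", {
  n1 <- n_parameters(gramdta_model(gramdta_config(), seed = 1))
  n2 <- n_parameters(gramdta_model(gramdta_config(), seed = 99))
  expect_identical(n1, n2)
  n3 <- n_parameters(gramdta_model(gramdta_config(rnaseq_latent = 64), seed = 1))
  expect_false(n1 == n3)
})

test_that("configs round-trip through YAML", {
  cfg <- gramdta_config(protein_branch = "rnn", use_rnaseq = FALSE,
                        head_hidden = c(32, 16))
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  expect_identical(read_config(f), cfg)
})

test_that("one optimization step moves parameters in every branch", {
  ns <- asNamespace("gramdta")
  set.seed(8)
  cfg <- gramdta_config()
  m <- gramdta_model(cfg, seed = 8)
  B <- 4L
  batch <- list(drug = array(rbinom(76 * 277 * B, 1, 0.05), c(76, 277, B)),
                rnaseq = matrix(runif(1956 * B), 1956, B),
                protein = array(rbinom(26 * 80 * B, 1, 0.15), c(26, 80, B)),
                prot_lens = rep(60L, B))
  y <- rnorm(B, 7)
  fw <- ns$.model_fwd(m, batch)
  gr <- ns$.model_bwd(m, fw$cache, 2 * (fw$pred - y) / B)
  upd <- ns$adam_step(m$params, gr, ns$adam_init(m$params), lr = 1e-3)
  moved <- function(prefix) {
    any(vapply(grep(prefix, names(m$params), value = TRUE), function(nm) {
      !identical(upd$params[[nm]], m$params[[nm]])
    }, logical(1)))
  }
  expect_true(moved("^drug\\.conv"))
  expect_true(moved("^rna\\."))
  expect_true(moved("^prot\\."))
  expect_true(moved("^head\\."))
})
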