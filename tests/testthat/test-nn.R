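# Backward passes are validated against central finite differences. Bias
# vectors are jittered away from zero first: with zero biases and sparse
# one-hot inputs, many pre-activations sit exactly on the ReLU kink where
# the two-sided difference quotient is not the subgradient the code uses.

num_grad <- function(f, x, j, eps = 1e-6) {
  x2 <- x; x2[j] <- x[j] + eps
  x3 <- x; x3[j] <- x[j] - eps
  (f(x2) - f(x3)) / (2 * eps)
}

test_that("conv1d forward/backward match finite differences", {
  ns <- asNamespace("gramdta")
  set.seed(1)
  C <- 3L; L <- 12L; B <- 2L; k <- 4L; Fo <- 5L
  x <- array(rnorm(C * L * B), c(C, L, B))
  W <- matrix(rnorm(Fo * C * k), Fo, C * k)
  b <- rnorm(Fo)
  tgt <- array(rnorm(Fo * (L - k + 1) * B), c(Fo, L - k + 1, B))
  fw <- ns$conv1d_fwd(x, W, b, k)
  expect_identical(dim(fw$y), c(Fo, L - k + 1L, B))
  # brute-force forward: loop over filters and windows
  for (f in 1:Fo) for (j in 1:(L - k + 1)) for (bb in 1:B) {
    win <- as.vector(x[, j:(j + k - 1), bb])
    expect_equal(fw$y[f, j, bb], sum(W[f, ] * win) + b[f], tolerance = 1e-12)
  }
  bw <- ns$conv1d_bwd(fw$y - tgt, fw, W, need_dx = TRUE)
  loss_x <- function(x) sum((ns$conv1d_fwd(x, W, b, k)$y - tgt)^2) / 2
  loss_W <- function(W) sum((ns$conv1d_fwd(x, W, b, k)$y - tgt)^2) / 2
  loss_b <- function(b) sum((ns$conv1d_fwd(x, W, b, k)$y - tgt)^2) / 2
  for (j in sample(length(x), 8)) {
    expect_equal(bw$dx[j], num_grad(loss_x, x, j), tolerance = 1e-5)
  }
  for (j in sample(length(W), 8)) {
    expect_equal(bw$dW[j], num_grad(loss_W, W, j), tolerance = 1e-5)
  }
  for (j in seq_along(b)) {
    expect_equal(bw$db[j], num_grad(loss_b, b, j), tolerance = 1e-5)
  }
})

test_that("lstm forward/backward match finite differences", {
  ns <- asNamespace("gramdta")
  set.seed(2)
  H <- 4L; In <- 3L; L <- 6L; B <- 2L
  Wx <- matrix(rnorm(4 * H * In), 4 * H, In)
  Wh <- matrix(rnorm(4 * H * H) * 0.3, 4 * H, H)
  b <- rnorm(4 * H)
  x <- array(rnorm(In * L * B), c(In, L, B))
  tgt <- array(rnorm(H * L * B), c(H, L, B))
  fw <- ns$lstm_fwd(x, Wx, Wh, b)
  bw <- ns$lstm_bwd(fw$h - tgt, fw, Wx, Wh, need_dx = TRUE)
  loss <- function(Wx, Wh, b, x) sum((ns$lstm_fwd(x, Wx, Wh, b)$h - tgt)^2) / 2
  for (j in sample(length(Wx), 6)) {
    expect_equal(bw$dWx[j],
                 num_grad(function(v) loss(v, Wh, b, x), Wx, j),
                 tolerance = 1e-5)
  }
  for (j in sample(length(Wh), 6)) {
    expect_equal(bw$dWh[j],
                 num_grad(function(v) loss(Wx, v, b, x), Wh, j),
                 tolerance = 1e-5)
  }
  for (j in sample(length(x), 6)) {
    expect_equal(bw$dx[j],
                 num_grad(function(v) loss(Wx, Wh, b, v), x, j),
                 tolerance = 1e-5)
  }
})

test_that("whole-model gradients match finite differences for both variants", {
  ns <- asNamespace("gramdta")
  set.seed(7)
  B <- 3L
  batch <- list(drug = array(rbinom(76 * 277 * B, 1, 0.05), c(76, 277, B)),
                rnaseq = matrix(runif(1956 * B), 1956, B),
                protein = array(rbinom(26 * 60 * B, 1, 0.1), c(26, 60, B)),
                prot_lens = c(40L, 55L, 20L))
  y <- rnorm(B)
  for (branch in c("cnn", "rnn")) {
    cfg <- gramdta_config(protein_branch = branch,
                          drug_conv_filters = c(3, 4), drug_conv_kernels = c(5, 3),
                          drug_latent = 6, rnaseq_hidden = 8, rnaseq_latent = 5,
                          protein_cnn_filters = c(4, 5), protein_cnn_kernels = c(3, 4),
                          protein_latent = 7, rnn_hidden = 5, head_hidden = c(9, 8))
    m <- gramdta_model(cfg, seed = 3)
    for (nm in names(m$params)) {
      m$params[[nm]] <- m$params[[nm]] + rnorm(length(m$params[[nm]])) * 0.01
    }
    lossfun <- function(mm) {
      fw <- ns$.model_fwd(mm, batch)
      mean((fw$pred - y)^2)
    }
    fw <- ns$.model_fwd(m, batch)
    gr <- ns$.model_bwd(m, fw$cache, 2 * (fw$pred - y) / B)
    for (nm in names(m$params)) {
      if (grepl("logvar", nm)) next   # not part of the regression loss
      p <- m$params[[nm]]
      for (j in sample(length(p), min(3, length(p)))) {
        m2 <- m; m2$params[[nm]][j] <- p[j] + 1e-6
        m3 <- m; m3$params[[nm]][j] <- p[j] - 1e-6
        num <- (lossfun(m2) - lossfun(m3)) / 2e-6
        expect_equal(gr[[nm]][j], num, tolerance = 1e-3,
                     info = paste(branch, nm))
      }
    }
  }
})

test_that("adam preserves parameter shapes and reduces a quadratic", {
  ns <- asNamespace("gramdta")
  params <- list(W = matrix(c(3, -2, 1, 4), 2, 2), b = c(5, -5))
  st <- ns$adam_init(params)
  for (i in 1:400) {
    g <- list(W = 2 * params$W, b = 2 * params$b)   # d/dx of sum(x^2)
    upd <- ns$adam_step(params, g, st, lr = 0.05)
    params <- upd$params; st <- upd$state
  }
  expect_true(is.matrix(params$W))
  expect_null(dim(params$b))
  expect_lt(sum(params$W^2) + sum(params$b^2), 1e-3)
})
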