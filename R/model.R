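# The three-branch fusion model: a convolutional drug encoder over the
# 277 x 76 grammar one-hot (returning the variational posterior mean as a
# deterministic 56-d latent), a fully connected encoder over the flattened
# 978 x 2 regulatory vector, a convolutional or LSTM protein encoder over the
# 26 x 1000 one-hot, and a fully connected regression head over the
# concatenated latents.

#' Model architecture configuration
#'
#' Captures every architecture hyperparameter. The convolutional filter and
#' kernel sizes and the 56-d drug latent follow the reference grammar-VAE
#' drug encoder; dense widths, activations and pooling are not pinned down by
#' that lineage and default to conventional choices (256-wide hidden dense
#' layers, ReLU, global max pooling after the protein CNN, no dropout).
#'
#' @param protein_branch `"cnn"` (three 1-D convolutions + global max pool)
#'   or `"rnn"` (two stacked LSTM layers).
#' @param use_rnaseq Include the regulatory-vector branch (default `TRUE`);
#'   `FALSE` gives the structure-only ablation model.
#' @param drug_conv_filters,drug_conv_kernels Drug encoder convolution sizes
#'   (defaults 9, 9, 10 filters with kernels 9, 9, 11).
#' @param drug_latent Drug latent dimension (default 56).
#' @param rnaseq_hidden,rnaseq_latent Widths of the two dense layers of the
#'   RNA-Seq encoder (defaults 256 and 128).
#' @param protein_cnn_filters,protein_cnn_kernels Protein CNN sizes (defaults
#'   32, 64, 96 filters with kernels 4, 8, 12).
#' @param protein_latent Protein latent dimension (default 128).
#' @param rnn_hidden LSTM hidden size per layer (default 64).
#' @param rnn_layers Number of stacked LSTM layers (default 2).
#' @param head_hidden Widths of the hidden dense layers of the regression
#'   head (default `c(256, 256)`; with the final scalar layer the head has
#'   three dense layers).
#' @return An object of class `gramdta_config`.
#' @export
gramdta_config <- function(protein_branch = c("cnn", "rnn"),
                           use_rnaseq = TRUE,
                           drug_conv_filters = c(9L, 9L, 10L),
                           drug_conv_kernels = c(9L, 9L, 11L),
                           drug_latent = 56L,
                           rnaseq_hidden = 256L,
                           rnaseq_latent = 128L,
                           protein_cnn_filters = c(32L, 64L, 96L),
                           protein_cnn_kernels = c(4L, 8L, 12L),
                           protein_latent = 128L,
                           rnn_hidden = 64L,
                           rnn_layers = 2L,
                           head_hidden = c(256L, 256L)) {
  protein_branch <- match.arg(protein_branch)
  cfg <- list(protein_branch = protein_branch,
              use_rnaseq = isTRUE(use_rnaseq),
              drug_conv_filters = as.integer(drug_conv_filters),
              drug_conv_kernels = as.integer(drug_conv_kernels),
              drug_latent = as.integer(drug_latent),
              rnaseq_hidden = as.integer(rnaseq_hidden),
              rnaseq_latent = as.integer(rnaseq_latent),
              protein_cnn_filters = as.integer(protein_cnn_filters),
              protein_cnn_kernels = as.integer(protein_cnn_kernels),
              protein_latent = as.integer(protein_latent),
              rnn_hidden = as.integer(rnn_hidden),
              rnn_layers = as.integer(rnn_layers),
              head_hidden = as.integer(head_hidden))
  if (length(cfg$drug_conv_filters) != length(cfg$drug_conv_kernels)) {
    stop("drug filter and kernel lists must have equal length")
  }
  if (length(cfg$protein_cnn_filters) != length(cfg$protein_cnn_kernels)) {
    stop("protein filter and kernel lists must have equal length")
  }
  if (any(unlist(cfg[-(1:2)]) <= 0L)) stop("all size parameters must be positive")
  structure(cfg, class = "gramdta_config")
}

#' Write / read a model configuration as YAML
#'
#' @param config A `gramdta_config`.
#' @param path File path.
#' @return `read_config()` returns the `gramdta_config`; the writer returns
#'   `path` invisibly. Configurations round-trip unchanged.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "gramdta_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(gramdta_config, raw)
}

# width of the concatenated latent entering the head
.fusion_width <- function(cfg) {
  cfg$drug_latent + cfg$protein_latent +
    if (cfg$use_rnaseq) cfg$rnaseq_latent else 0L
}

#' Initialise an untrained model
#'
#' Glorot-uniform weights, zero biases, seeded for reproducibility.
#'
#' @param config A `gramdta_config`.
#' @param seed Integer seed for the weight draw.
#' @return An object of class `gramdta_model`: list with `params` (named
#'   flat list of weight arrays), `config`, and `seed`.
#' @export
gramdta_model <- function(config = gramdta_config(), seed = 1L) {
  stopifnot(inherits(config, "gramdta_config"))
  set.seed(seed)
  p <- list()
  # drug encoder: convs over the 277-step axis, 76 input channels
  Cin <- RULE_COUNT; L <- RULE_MAX
  for (i in seq_along(config$drug_conv_filters)) {
    Fo <- config$drug_conv_filters[i]; k <- config$drug_conv_kernels[i]
    p[[paste0("drug.conv", i, ".W")]] <- glorot(Fo, Cin * k)
    p[[paste0("drug.conv", i, ".b")]] <- numeric(Fo)
    Cin <- Fo; L <- L - k + 1L
  }
  flat <- Cin * L
  p[["drug.mean.W"]] <- glorot(config$drug_latent, flat)
  p[["drug.mean.b"]] <- numeric(config$drug_latent)
  p[["drug.logvar.W"]] <- glorot(config$drug_latent, flat)
  p[["drug.logvar.b"]] <- numeric(config$drug_latent)
  # RNA-Seq encoder: 978*2 flattened -> two dense layers
  p[["rna.dense1.W"]] <- glorot(config$rnaseq_hidden, 2L * N_LANDMARKS)
  p[["rna.dense1.b"]] <- numeric(config$rnaseq_hidden)
  p[["rna.dense2.W"]] <- glorot(config$rnaseq_latent, config$rnaseq_hidden)
  p[["rna.dense2.b"]] <- numeric(config$rnaseq_latent)
  # protein encoder
  if (config$protein_branch == "cnn") {
    Cin <- length(PROT_DICT)
    for (i in seq_along(config$protein_cnn_filters)) {
      Fo <- config$protein_cnn_filters[i]; k <- config$protein_cnn_kernels[i]
      p[[paste0("prot.conv", i, ".W")]] <- glorot(Fo, Cin * k)
      p[[paste0("prot.conv", i, ".b")]] <- numeric(Fo)
      Cin <- Fo
    }
    p[["prot.dense.W"]] <- glorot(config$protein_latent, Cin)
    p[["prot.dense.b"]] <- numeric(config$protein_latent)
  } else {
    Cin <- length(PROT_DICT)
    for (i in seq_len(config$rnn_layers)) {
      H <- config$rnn_hidden
      p[[paste0("prot.lstm", i, ".Wx")]] <- glorot(4L * H, Cin)
      p[[paste0("prot.lstm", i, ".Wh")]] <- glorot(4L * H, H)
      p[[paste0("prot.lstm", i, ".b")]] <- numeric(4L * H)
      Cin <- H
    }
    p[["prot.dense.W"]] <- glorot(config$protein_latent, Cin)
    p[["prot.dense.b"]] <- numeric(config$protein_latent)
  }
  # regression head
  widths <- c(.fusion_width(config), config$head_hidden, 1L)
  for (i in seq_len(length(widths) - 1L)) {
    p[[paste0("head.dense", i, ".W")]] <- glorot(widths[i + 1L], widths[i])
    p[[paste0("head.dense", i, ".b")]] <- numeric(widths[i + 1L])
  }
  structure(list(params = p, config = config, seed = seed),
            class = "gramdta_model")
}

#' Number of trainable parameters of a model
#' @param model A `gramdta_model` or fitted `gramdta` object.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  if (inherits(model, "gramdta")) model <- model$model
  sum(vapply(model$params, length, integer(1)))
}

# ---- internal branch forward/backward --------------------------------------
# Internal layouts are channels-first: drug (76, 277, B), rnaseq (1956, B),
# protein (26, L, B).

.drug_fwd <- function(p, cfg, x) {
  caches <- list()
  h <- x
  for (i in seq_along(cfg$drug_conv_filters)) {
    cv <- conv1d_fwd(h, p[[paste0("drug.conv", i, ".W")]],
                     p[[paste0("drug.conv", i, ".b")]],
                     cfg$drug_conv_kernels[i])
    rl <- relu_fwd(cv$y)
    caches[[i]] <- list(cv = cv, rl = rl)
    h <- rl$y
  }
  d <- dim(h); B <- d[3]
  flat <- h; dim(flat) <- c(d[1] * d[2], B)
  mn <- dense_fwd(flat, p[["drug.mean.W"]], p[["drug.mean.b"]])
  lv <- dense_fwd(flat, p[["drug.logvar.W"]], p[["drug.logvar.b"]])
  list(latent = mn$y, logvar = lv$y,
       cache = list(convs = caches, flat = mn, hdim = d))
}

.drug_bwd <- function(p, cfg, dlat, cache) {
  g <- list()
  dn <- dense_bwd(dlat, cache$flat, p[["drug.mean.W"]])
  g[["drug.mean.W"]] <- dn$dW; g[["drug.mean.b"]] <- dn$db
  dh <- dn$dx; dim(dh) <- cache$hdim
  for (i in rev(seq_along(cfg$drug_conv_filters))) {
    dh <- relu_bwd(dh, cache$convs[[i]]$rl)
    cb <- conv1d_bwd(dh, cache$convs[[i]]$cv,
                     p[[paste0("drug.conv", i, ".W")]], need_dx = i > 1L)
    g[[paste0("drug.conv", i, ".W")]] <- cb$dW
    g[[paste0("drug.conv", i, ".b")]] <- cb$db
    dh <- cb$dx
  }
  g
}

.rna_fwd <- function(p, cfg, x) {
  d1 <- dense_fwd(x, p[["rna.dense1.W"]], p[["rna.dense1.b"]])
  r1 <- relu_fwd(d1$y)
  d2 <- dense_fwd(r1$y, p[["rna.dense2.W"]], p[["rna.dense2.b"]])
  r2 <- relu_fwd(d2$y)
  list(latent = r2$y, cache = list(d1 = d1, r1 = r1, d2 = d2, r2 = r2))
}

.rna_bwd <- function(p, cfg, dlat, cache) {
  g <- list()
  dh <- relu_bwd(dlat, cache$r2)
  b2 <- dense_bwd(dh, cache$d2, p[["rna.dense2.W"]])
  g[["rna.dense2.W"]] <- b2$dW; g[["rna.dense2.b"]] <- b2$db
  dh <- relu_bwd(b2$dx, cache$r1)
  b1 <- dense_bwd(dh, cache$d1, p[["rna.dense1.W"]])
  g[["rna.dense1.W"]] <- b1$dW; g[["rna.dense1.b"]] <- b1$db
  g
}

.prot_cnn_fwd <- function(p, cfg, x) {
  caches <- list()
  h <- x
  for (i in seq_along(cfg$protein_cnn_filters)) {
    cv <- conv1d_fwd(h, p[[paste0("prot.conv", i, ".W")]],
                     p[[paste0("prot.conv", i, ".b")]],
                     cfg$protein_cnn_kernels[i])
    rl <- relu_fwd(cv$y)
    caches[[i]] <- list(cv = cv, rl = rl)
    h <- rl$y
  }
  mp <- maxpool_fwd(h)
  dn <- dense_fwd(mp$y, p[["prot.dense.W"]], p[["prot.dense.b"]])
  rl <- relu_fwd(dn$y)
  list(latent = rl$y,
       cache = list(convs = caches, mp = mp, dn = dn, rl = rl))
}

.prot_cnn_bwd <- function(p, cfg, dlat, cache) {
  g <- list()
  dh <- relu_bwd(dlat, cache$rl)
  bd <- dense_bwd(dh, cache$dn, p[["prot.dense.W"]])
  g[["prot.dense.W"]] <- bd$dW; g[["prot.dense.b"]] <- bd$db
  dh <- maxpool_bwd(bd$dx, cache$mp)
  for (i in rev(seq_along(cfg$protein_cnn_filters))) {
    dh <- relu_bwd(dh, cache$convs[[i]]$rl)
    cb <- conv1d_bwd(dh, cache$convs[[i]]$cv,
                     p[[paste0("prot.conv", i, ".W")]], need_dx = i > 1L)
    g[[paste0("prot.conv", i, ".W")]] <- cb$dW
    g[[paste0("prot.conv", i, ".b")]] <- cb$db
    dh <- cb$dx
  }
  g
}

.prot_rnn_fwd <- function(p, cfg, x, lens) {
  B <- dim(x)[3]
  caches <- list()
  h <- x
  for (i in seq_len(cfg$rnn_layers)) {
    lc <- lstm_fwd(h, p[[paste0("prot.lstm", i, ".Wx")]],
                   p[[paste0("prot.lstm", i, ".Wh")]],
                   p[[paste0("prot.lstm", i, ".b")]])
    caches[[i]] <- lc
    h <- lc$h
  }
  # final hidden state at each sequence's true end (zeros for empty input)
  H <- cfg$rnn_hidden
  hT <- matrix(0, H, B)
  for (b in seq_len(B)) if (lens[b] >= 1L) hT[, b] <- h[, lens[b], b]
  dn <- dense_fwd(hT, p[["prot.dense.W"]], p[["prot.dense.b"]])
  rl <- relu_fwd(dn$y)
  list(latent = rl$y,
       cache = list(lstms = caches, dn = dn, rl = rl, lens = lens,
                    L = dim(x)[2], B = B))
}

.prot_rnn_bwd <- function(p, cfg, dlat, cache) {
  g <- list()
  dh <- relu_bwd(dlat, cache$rl)
  bd <- dense_bwd(dh, cache$dn, p[["prot.dense.W"]])
  g[["prot.dense.W"]] <- bd$dW; g[["prot.dense.b"]] <- bd$db
  H <- cfg$rnn_hidden
  dhT <- array(0, dim = c(H, cache$L, cache$B))
  for (b in seq_len(cache$B)) {
    if (cache$lens[b] >= 1L) dhT[, cache$lens[b], b] <- bd$dx[, b]
  }
  dh <- dhT
  for (i in rev(seq_len(cfg$rnn_layers))) {
    lb <- lstm_bwd(dh, cache$lstms[[i]],
                   p[[paste0("prot.lstm", i, ".Wx")]],
                   p[[paste0("prot.lstm", i, ".Wh")]], need_dx = i > 1L)
    g[[paste0("prot.lstm", i, ".Wx")]] <- lb$dWx
    g[[paste0("prot.lstm", i, ".Wh")]] <- lb$dWh
    g[[paste0("prot.lstm", i, ".b")]] <- lb$db
    dh <- lb$dx
  }
  g
}

.head_fwd <- function(p, cfg, z) {
  n_layers <- length(cfg$head_hidden) + 1L
  caches <- list()
  h <- z
  for (i in seq_len(n_layers)) {
    dn <- dense_fwd(h, p[[paste0("head.dense", i, ".W")]],
                    p[[paste0("head.dense", i, ".b")]])
    if (i < n_layers) {
      rl <- relu_fwd(dn$y)
      caches[[i]] <- list(dn = dn, rl = rl)
      h <- rl$y
    } else {
      caches[[i]] <- list(dn = dn)
      h <- dn$y
    }
  }
  list(pred = as.numeric(h), cache = caches)
}

.head_bwd <- function(p, cfg, dpred, cache) {
  n_layers <- length(cfg$head_hidden) + 1L
  g <- list()
  dh <- matrix(dpred, nrow = 1L)
  for (i in rev(seq_len(n_layers))) {
    if (i < n_layers) dh <- relu_bwd(dh, cache[[i]]$rl)
    bd <- dense_bwd(dh, cache[[i]]$dn, p[[paste0("head.dense", i, ".W")]])
    g[[paste0("head.dense", i, ".W")]] <- bd$dW
    g[[paste0("head.dense", i, ".b")]] <- bd$db
    dh <- bd$dx
  }
  list(grads = g, dz = dh)
}

# Full forward pass. batch: list(drug = (76, 277, B), rnaseq = (1956, B) or
# NULL, protein = (26, Lc, B), prot_lens = integer(B)).
.model_fwd <- function(model, batch) {
  p <- model$params; cfg <- model$config
  dr <- .drug_fwd(p, cfg, batch$drug)
  pr <- if (cfg$protein_branch == "cnn") {
    .prot_cnn_fwd(p, cfg, batch$protein)
  } else {
    .prot_rnn_fwd(p, cfg, batch$protein, batch$prot_lens)
  }
  rn <- if (cfg$use_rnaseq) .rna_fwd(p, cfg, batch$rnaseq) else NULL
  z <- if (cfg$use_rnaseq) {
    rbind(dr$latent, rn$latent, pr$latent)
  } else {
    rbind(dr$latent, pr$latent)
  }
  hd <- .head_fwd(p, cfg, z)
  list(pred = hd$pred,
       latents = list(drug = dr$latent, rnaseq = rn$latent,
                      protein = pr$latent),
       cache = list(dr = dr, rn = rn, pr = pr, hd = hd))
}

.model_bwd <- function(model, cache, dpred) {
  p <- model$params; cfg <- model$config
  hb <- .head_bwd(p, cfg, dpred, cache$hd$cache)
  dz <- hb$dz
  i1 <- cfg$drug_latent
  d_dr <- dz[seq_len(i1), , drop = FALSE]
  if (cfg$use_rnaseq) {
    d_rn <- dz[i1 + seq_len(cfg$rnaseq_latent), , drop = FALSE]
    d_pr <- dz[i1 + cfg$rnaseq_latent + seq_len(cfg$protein_latent), ,
               drop = FALSE]
  } else {
    d_rn <- NULL
    d_pr <- dz[i1 + seq_len(cfg$protein_latent), , drop = FALSE]
  }
  g <- hb$grads
  g <- c(g, .drug_bwd(p, cfg, d_dr, cache$dr$cache))
  if (cfg$use_rnaseq) g <- c(g, .rna_bwd(p, cfg, d_rn, cache$rn$cache))
  g <- c(g, if (cfg$protein_branch == "cnn") {
    .prot_cnn_bwd(p, cfg, d_pr, cache$pr$cache)
  } else {
    .prot_rnn_bwd(p, cfg, d_pr, cache$pr$cache)
  })
  g
}

# ---- public branch forwards (batch-first layouts, as encoded) ---------------

#' Drug encoder forward pass
#'
#' Runs the convolutional drug encoder over a batch of 277 x 76 one-hot
#' matrices and returns the variational posterior mean as the deterministic
#' latent (no sampling, so identical inputs give identical latents).
#'
#' @param model A `gramdta_model` or fitted `gramdta` object.
#' @param onehot Array `B x 277 x 76` (e.g. from [encode_drug_batch()]), or a
#'   single `drug_onehot` matrix.
#' @return Matrix `B x drug_latent`.
#' @export
drug_encoder_forward <- function(model, onehot) {
  model <- .as_model(model)
  if (is.matrix(onehot)) {
    onehot <- array(unclass(onehot), dim = c(1L, nrow(onehot), ncol(onehot)))
  }
  d <- dim(onehot)
  if (length(d) != 3L || d[2] != RULE_MAX || d[3] != RULE_COUNT) {
    stop("contract error: expected a B x ", RULE_MAX, " x ", RULE_COUNT,
         " drug one-hot batch")
  }
  x <- aperm(onehot, c(3, 2, 1))   # -> (76, 277, B)
  t(.drug_fwd(model$params, model$config, x)$latent)
}

#' RNA-Seq encoder forward pass
#'
#' @param model A `gramdta_model` or fitted `gramdta` object.
#' @param vectors Array `B x 978 x 2` of regulatory vectors (values in
#'   `[0, 1]`), or a single `regulatory_vector` matrix.
#' @return Matrix `B x rnaseq_latent`.
#' @export
rnaseq_encoder_forward <- function(model, vectors) {
  model <- .as_model(model)
  if (is.matrix(vectors)) {
    vectors <- array(unclass(vectors), dim = c(1L, nrow(vectors), ncol(vectors)))
  }
  d <- dim(vectors)
  if (length(d) != 3L || d[2] != N_LANDMARKS || d[3] != 2L) {
    stop("contract error: expected a B x ", N_LANDMARKS, " x 2 batch")
  }
  if (anyNA(vectors) || any(!is.finite(vectors))) {
    stop("contract error: non-finite values in regulatory vectors")
  }
  x <- t(matrix(vectors, d[1], d[2] * d[3]))   # (1956, B)
  t(.rna_fwd(model$params, model$config, x)$latent)
}

#' Protein encoder forward pass
#'
#' `protein_cnn_forward()` applies the three 1-D convolutions and global max
#' pooling; `protein_rnn_forward()` runs the stacked LSTM and projects the
#' final hidden state. Both return one latent row per sequence. The function
#' matching `model$config$protein_branch` must be used.
#'
#' @param model A `gramdta_model` or fitted `gramdta` object.
#' @param onehots Array `B x 26 x 1000` (e.g. from
#'   [batch_encode_proteins()]), or a single `protein_onehot` matrix.
#' @return Matrix `B x protein_latent`.
#' @export
protein_cnn_forward <- function(model, onehots) {
  model <- .as_model(model)
  if (model$config$protein_branch != "cnn") {
    stop("model was configured with the RNN protein branch")
  }
  x <- .prot_batch(onehots)
  t(.prot_cnn_fwd(model$params, model$config, x$x)$latent)
}

#' @rdname protein_cnn_forward
#' @export
protein_rnn_forward <- function(model, onehots) {
  model <- .as_model(model)
  if (model$config$protein_branch != "rnn") {
    stop("model was configured with the CNN protein branch")
  }
  x <- .prot_batch(onehots, crop = FALSE)
  t(.prot_rnn_fwd(model$params, model$config, x$x, x$lens)$latent)
}

#' Regression head forward pass
#'
#' Concatenates the branch latents (omitting the RNA-Seq latent when
#' `use_rnaseq` is `FALSE`) and applies the dense regression head.
#'
#' @param model A `gramdta_model` or fitted `gramdta` object.
#' @param drug_latent Matrix `B x drug_latent`.
#' @param protein_latent Matrix `B x protein_latent`.
#' @param rnaseq_latent Matrix `B x rnaseq_latent`, required iff the model
#'   uses the RNA-Seq branch.
#' @return Numeric vector of `B` predicted affinities.
#' @export
regression_head <- function(model, drug_latent, protein_latent,
                            rnaseq_latent = NULL) {
  model <- .as_model(model)
  cfg <- model$config
  if (ncol(drug_latent) != cfg$drug_latent ||
      ncol(protein_latent) != cfg$protein_latent) {
    stop("contract error: latent width mismatch")
  }
  if (cfg$use_rnaseq) {
    if (is.null(rnaseq_latent) || ncol(rnaseq_latent) != cfg$rnaseq_latent) {
      stop("contract error: rnaseq latent of width ", cfg$rnaseq_latent,
           " required")
    }
    z <- rbind(t(drug_latent), t(rnaseq_latent), t(protein_latent))
  } else {
    z <- rbind(t(drug_latent), t(protein_latent))
  }
  .head_fwd(model$params, cfg, z)$pred
}

.as_model <- function(x) {
  if (inherits(x, "gramdta")) x$model else {
    stopifnot(inherits(x, "gramdta_model")); x
  }
}

# Convert a batch-first protein one-hot tensor to channels-first, optionally
# cropping trailing all-zero columns (exact under valid convolutions +
# global max pooling when a full receptive field of tail zeros is kept).
.prot_batch <- function(onehots, crop = TRUE, margin = 22L) {
  if (is.matrix(onehots)) {
    onehots <- array(unclass(onehots),
                     dim = c(1L, nrow(onehots), ncol(onehots)))
  }
  d <- dim(onehots)
  if (length(d) != 3L || d[2] != length(PROT_DICT) || d[3] != PROT_MAX) {
    stop("contract error: expected a B x ", length(PROT_DICT), " x ",
         PROT_MAX, " protein one-hot batch")
  }
  x <- aperm(onehots, c(2, 3, 1))   # (26, 1000, B)
  lens <- integer(d[1])
  for (b in seq_len(d[1])) {
    nz <- which(colSums(x[, , b, drop = FALSE][, , 1]) > 0)
    lens[b] <- if (length(nz)) max(nz) else 0L
  }
  if (crop) {
    keep <- min(max(lens) + margin, PROT_MAX)
    keep <- max(keep, margin)   # convolutions need at least the receptive field
    x <- x[, seq_len(keep), , drop = FALSE]
  }
  list(x = x, lens = lens)
}

#' @export
print.gramdta_model <- function(x, ...) {
  cfg <- x$config
  cat("gramdta model (untrained)\n")
  cat("  protein branch:", cfg$protein_branch,
      "| RNA-Seq branch:", if (cfg$use_rnaseq) "on" else "off", "\n")
  cat("  latents: drug", cfg$drug_latent, "/ rnaseq", cfg$rnaseq_latent,
      "/ protein", cfg$protein_latent, "\n")
  cat("  parameters:", format(n_parameters(x), big.mark = ","), "\n")
  invisible(x)
}
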