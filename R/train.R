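# End-to-end training: encodes a DTA dataset into tensors, minimises MSE
# with Adam, tracks per-epoch train/validation metrics, and keeps the
# best-validation checkpoint. Protein batches are assembled at the batch's
# maximum true length plus one receptive field of zero padding, which
# reproduces the fixed-width computation exactly under valid convolutions
# and global max pooling.

#' Training configuration
#'
#' @param epochs Number of passes over the training split (default 500).
#' @param learning_rate Initial Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 256).
#' @param seed Integer seed governing weight initialisation and shuffling.
#' @param scheduler `"plateau"` (halve the learning rate when the validation
#'   MSE has not improved for `patience` epochs) or `"constant"`.
#' @param patience,factor Plateau scheduler parameters (defaults 20 and 0.5).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 500L, learning_rate = 0.001,
                         batch_size = 256L, seed = 1L,
                         scheduler = c("plateau", "constant"),
                         patience = 20L, factor = 0.5) {
  scheduler <- match.arg(scheduler)
  stopifnot(epochs >= 1L, learning_rate >= 0, batch_size >= 1L,
            patience >= 1L, factor > 0, factor <= 1)
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 scheduler = scheduler,
                 patience = as.integer(patience), factor = factor),
            class = "train_config")
}

# Encode a dta_dataset (+ regulatory features) into training tensors.
# Records whose drug cannot be grammar-encoded (or, when use_rnaseq, has no
# regulatory vector) are dropped with a tally. Returns NULL-split indices
# untouched; splits must be assigned on the returned record subset.
.prepare_tensors <- function(dataset, regulatory, config,
                             grammar = default_grammar()) {
  rec <- dataset$records
  drug_arr <- encode_drug_batch(unique(rec$smiles), grammar,
                                canonicalize = FALSE)
  keep <- rec$smiles %in% dimnames(drug_arr)[[1]]
  rna <- NULL
  if (config$use_rnaseq) {
    if (is.null(regulatory)) {
      stop("use_rnaseq = TRUE requires a regulatory matrix")
    }
    by_sm <- if (inherits(regulatory, "regulatory_matrix")) {
      regulatory_by_smiles(regulatory)
    } else {
      regulatory
    }
    keep <- keep & rec$smiles %in% dimnames(by_sm)[[1]]
    rna <- by_sm
  }
  n_drop <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no encodable interactions remain")
  drugs <- dimnames(drug_arr)[[1]]
  prots <- unique(rec$protein)
  # channels-first per-entity tensors
  drug_cf <- aperm(drug_arr, c(3, 2, 1))                 # (76, 277, nd)
  prot_list <- vector("list", length(prots))
  prot_lens <- integer(length(prots))
  for (i in seq_along(prots)) {
    o <- encode_protein(prots[i])
    len <- min(attr(o, "true_length"), PROT_MAX)
    prot_list[[i]] <- unclass(o)[, seq_len(len), drop = FALSE]
    prot_lens[i] <- len
  }
  rna_mat <- NULL
  if (config$use_rnaseq) {
    rna_mat <- matrix(0, 2L * N_LANDMARKS, length(drugs))
    for (i in seq_along(drugs)) rna_mat[, i] <- as.numeric(rna[drugs[i], , ])
  }
  list(records = rec,
       drug_idx = match(rec$smiles, drugs),
       prot_idx = match(rec$protein, prots),
       y = rec$label,
       drug_cf = drug_cf,
       prot_list = prot_list, prot_lens = prot_lens,
       rna_mat = rna_mat,
       dropped_unencodable = n_drop)
}

# Assemble a channels-first batch for record indices `idx`.
.make_batch <- function(tens, idx, margin = 22L) {
  B <- length(idx)
  di <- tens$drug_idx[idx]; pi_ <- tens$prot_idx[idx]
  drug <- tens$drug_cf[, , di, drop = FALSE]
  lens <- tens$prot_lens[pi_]
  Lc <- min(max(lens) + margin, PROT_MAX)
  prot <- array(0, dim = c(length(PROT_DICT), Lc, B))
  for (b in seq_len(B)) {
    L <- lens[b]
    if (L > 0L) prot[, seq_len(L), b] <- tens$prot_list[[pi_[b]]]
  }
  rnaseq <- if (!is.null(tens$rna_mat)) {
    tens$rna_mat[, di, drop = FALSE]
  }
  list(drug = drug, rnaseq = rnaseq, protein = prot, prot_lens = lens,
       y = tens$y[idx])
}

# Deterministic predictions for record indices, in chunks.
.predict_tensors <- function(model, tens, idx, chunk = 128L) {
  out <- numeric(length(idx))
  for (s in split(seq_along(idx), ceiling(seq_along(idx) / chunk))) {
    b <- .make_batch(tens, idx[s])
    out[s] <- .model_fwd(model, b)$pred
  }
  out
}

# Core loop. Returns list(model, history, best_params, best_epoch).
.train_loop <- function(model, tens, splits, tc, verbose = FALSE) {
  train_idx <- splits$train
  valid_idx <- splits$valid
  if (length(train_idx) == 0L) stop("config error: empty training split")
  has_valid <- length(valid_idx) > 0L
  opt <- adam_init(model$params)
  lr <- tc$learning_rate
  best_mse <- Inf; best_params <- model$params; best_epoch <- 0L
  since_improve <- 0L
  hist <- vector("list", tc$epochs)
  set.seed(tc$seed)
  for (ep in seq_len(tc$epochs)) {
    perm <- sample(train_idx)
    n_batches <- ceiling(length(perm) / tc$batch_size)
    tr_loss <- 0
    for (bi in seq_len(n_batches)) {
      take <- perm[(((bi - 1L) * tc$batch_size) + 1L):
                     min(bi * tc$batch_size, length(perm))]
      batch <- .make_batch(tens, take)
      fw <- .model_fwd(model, batch)
      err <- fw$pred - batch$y
      if (any(!is.finite(err))) {
        stop("non-finite loss at epoch ", ep, ", batch ", bi,
             "; try a lower learning rate")
      }
      tr_loss <- tr_loss + sum(err^2)
      grads <- .model_bwd(model, fw$cache, 2 * err / length(err))
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params; opt <- upd$state
    }
    train_mse <- tr_loss / length(perm)
    valid_mse <- NA_real_; valid_ci <- NA_real_
    if (has_valid) {
      vp <- .predict_tensors(model, tens, valid_idx)
      valid_mse <- mse(tens$y[valid_idx], vp)
      valid_ci <- tryCatch(as.numeric(concordance_index(tens$y[valid_idx], vp)),
                           error = function(e) NA_real_)
      if (valid_mse < best_mse - 1e-12) {
        best_mse <- valid_mse; best_params <- model$params; best_epoch <- ep
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (tc$scheduler == "plateau" && since_improve >= tc$patience) {
          lr <- lr * tc$factor
          since_improve <- 0L
        }
      }
    } else {
      best_params <- model$params; best_epoch <- ep
    }
    hist[[ep]] <- data.frame(epoch = ep, lr = lr, train_mse = train_mse,
                             valid_mse = valid_mse, valid_ci = valid_ci)
    if (verbose) {
      message(sprintf("epoch %3d  train MSE %.4f  valid MSE %s", ep, train_mse,
                      ifelse(is.na(valid_mse), "-", sprintf("%.4f", valid_mse))))
    }
  }
  list(model = model, history = do.call(rbind, hist),
       best_params = best_params, best_epoch = best_epoch)
}
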