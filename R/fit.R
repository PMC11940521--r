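#' Fit a grammar-based drug-target affinity model
#'
#' The main fitting interface. Takes an interaction table (drug SMILES,
#' protein sequence, affinity label), encodes the three views — grammar
#' one-hot drug matrices, per-drug regulatory vectors, protein one-hot
#' matrices — and trains the three-branch fusion network end-to-end with
#' Adam on mean squared error. Returns a fitted object with the usual
#' modelling methods ([predict.gramdta()], `print`, `summary`, `plot`,
#' `coef`, `fitted`, `residuals`) plus [evaluate()] for held-out metrics.
#'
#' Records whose SMILES fall outside the grammar's language, or (when the
#' RNA-Seq branch is on) lack a regulatory vector, are dropped with a
#' recorded tally before splitting.
#'
#' @param data A `dta_dataset` (see [load_dta_table()]) or a data.frame with
#'   columns `smiles`, `protein`, `label` (labels already transformed).
#' @param regulatory A `regulatory_matrix` from [build_regulatory_matrix()]
#'   (or a SMILES-keyed array from [regulatory_by_smiles()]); required when
#'   `config$use_rnaseq` is `TRUE`.
#' @param config A [gramdta_config()].
#' @param train A [train_config()]; its `seed` drives weight initialisation
#'   and shuffling.
#' @param fractions Train/validation/test fractions (must sum to 1).
#' @param grammar The SMILES grammar asset.
#' @param canonicalize Canonicalize SMILES first (set `FALSE` when `data`
#'   already holds canonical SMILES).
#' @param verbose Print per-epoch progress.
#' @return An object of class `gramdta`.
#' @export
gramdta <- function(data, regulatory = NULL,
                    config = gramdta_config(),
                    train = train_config(),
                    fractions = c(train = 0.8, valid = 0.1, test = 0.1),
                    grammar = default_grammar(),
                    canonicalize = TRUE, verbose = FALSE) {
  cl <- match.call()
  if (is.data.frame(data)) data <- dta_dataset(data)
  stopifnot(inherits(data, "dta_dataset"), inherits(config, "gramdta_config"),
            inherits(train, "train_config"))
  if (canonicalize) {
    data$records$smiles <- canonicalize_smiles(data$records$smiles)
  }
  tens <- .prepare_tensors(data, regulatory, config, grammar)
  ds <- dta_dataset(tens$records, data$label_kind)
  ds <- split_dataset(ds, fractions, seed = train$seed)
  model <- gramdta_model(config, seed = train$seed)
  res <- .train_loop(model, tens, ds$splits, train, verbose = verbose)
  final <- res$model
  final$params <- res$best_params
  fit <- structure(
    list(model = final, config = config, train = train,
         history = res$history, best_epoch = res$best_epoch,
         tensors = tens, splits = ds$splits, label_kind = data$label_kind,
         dropped_unencodable = tens$dropped_unencodable,
         call = cl),
    class = "gramdta")
  fit$fitted_train <- .predict_tensors(final, tens, ds$splits$train)
  fit
}

#' Evaluate a fitted model on a held-out split
#'
#' Deterministic forward pass over a stored split, reporting the two
#' affinity-regression metrics: MSE and concordance index.
#'
#' @param object A fitted `gramdta` object.
#' @param split One of `"train"`, `"valid"`, `"test"`.
#' @param ... Unused.
#' @return An object of class `gramdta_metrics`: list with `mse`, `ci`, `n`
#'   (pairs evaluated) and `usable_pairs` (concordance denominator).
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")

#' @rdname evaluate
#' @export
evaluate.gramdta <- function(object, split = "test", ...) {
  idx <- object$splits[[split]]
  if (is.null(idx) || length(idx) == 0L) {
    stop("contract error: split '", split, "' is empty")
  }
  y <- object$tensors$y[idx]
  p <- .predict_tensors(object$model, object$tensors, idx)
  ci <- concordance_index(y, p)
  structure(list(mse = mse(y, p), ci = as.numeric(ci), n = length(idx),
                 usable_pairs = attr(ci, "usable_pairs"), split = split),
            class = "gramdta_metrics")
}

#' @export
print.gramdta_metrics <- function(x, ...) {
  cat(sprintf("%s split: n = %d, MSE = %.4f, CI = %.4f (%d usable pairs)\n",
              x$split, x$n, x$mse, x$ci, x$usable_pairs))
  invisible(x)
}

#' Predict affinities for new drug-protein pairs
#'
#' @param object A fitted `gramdta` object.
#' @param newdata Data.frame with columns `smiles` and `protein`. Omitted for
#'   fitted values on the training split.
#' @param regulatory Regulatory features for the new drugs (a
#'   `regulatory_matrix` or SMILES-keyed array); defaults to the features
#'   stored at fit time, which cover the training drugs.
#' @param canonicalize Canonicalize `newdata$smiles` first.
#' @param ... Unused.
#' @return Numeric vector of predicted (transformed) affinities, `NA` for
#'   pairs whose drug cannot be encoded.
#' @export
predict.gramdta <- function(object, newdata = NULL, regulatory = NULL,
                            canonicalize = TRUE, ...) {
  if (is.null(newdata)) return(object$fitted_train)
  stopifnot(all(c("smiles", "protein") %in% names(newdata)))
  rec <- data.frame(smiles = as.character(newdata$smiles),
                    protein = as.character(newdata$protein),
                    label = 0, stringsAsFactors = FALSE)
  if (canonicalize) rec$smiles <- canonicalize_smiles(rec$smiles)
  reg <- regulatory
  if (object$config$use_rnaseq && is.null(reg)) {
    # reuse fit-time features: rebuild a SMILES-keyed array view
    drugs <- dimnames(object$tensors$drug_cf)[[3]]
    reg <- array(0, dim = c(length(drugs), N_LANDMARKS, 2L),
                 dimnames = list(drugs, NULL, NULL))
    for (i in seq_along(drugs)) {
      reg[i, , ] <- matrix(object$tensors$rna_mat[, i], N_LANDMARKS, 2L)
    }
  }
  out <- rep(NA_real_, nrow(rec))
  tens <- tryCatch(
    suppressWarnings(.prepare_tensors(dta_dataset(rec), reg, object$config)),
    error = function(e) NULL)
  if (is.null(tens)) return(out)
  ok <- paste(rec$smiles, rec$protein) %in%
    paste(tens$records$smiles, tens$records$protein)
  pred <- .predict_tensors(object$model, tens, seq_len(nrow(tens$records)))
  key <- paste(tens$records$smiles, tens$records$protein)
  out[ok] <- pred[match(paste(rec$smiles, rec$protein)[ok], key)]
  out
}

#' @export
fitted.gramdta <- function(object, ...) object$fitted_train

#' @export
residuals.gramdta <- function(object, ...) {
  object$tensors$y[object$splits$train] - object$fitted_train
}

#' @export
coef.gramdta <- function(object, ...) object$model$params

#' @export
print.gramdta <- function(x, ...) {
  cfg <- x$config
  cat("Grammar-based drug-target affinity model\n")
  cat("  branches: GVAE-style drug encoder (latent ", cfg$drug_latent, ") + ",
      if (cfg$use_rnaseq) "RNA-Seq FCNN + " else "",
      toupper(cfg$protein_branch), " protein encoder\n", sep = "")
  cat("  parameters:", format(n_parameters(x), big.mark = ","),
      "| label kind:", x$label_kind, "\n")
  cat("  records:", nrow(x$tensors$records),
      sprintf("(train %d / valid %d / test %d; %d dropped unencodable)\n",
              length(x$splits$train), length(x$splits$valid),
              length(x$splits$test), x$dropped_unencodable))
  h <- x$history
  last <- h[nrow(h), ]
  cat(sprintf("  trained %d epochs; final train MSE %.4f; best epoch %d\n",
              nrow(h), last$train_mse, x$best_epoch))
  invisible(x)
}

#' @export
summary.gramdta <- function(object, ...) {
  print(object)
  for (s in names(object$splits)) {
    if (length(object$splits[[s]]) >= 2L) {
      print(evaluate(object, split = s))
    }
  }
  invisible(object)
}

#' @export
plot.gramdta <- function(x, ...) {
  h <- x$history
  ylim <- range(c(h$train_mse, h$valid_mse), na.rm = TRUE)
  matplot(h$epoch, cbind(h$train_mse, h$valid_mse), type = "l", lty = 1,
          col = c("black", "firebrick"), xlab = "epoch", ylab = "MSE",
          ylim = ylim, main = "Training history", ...)
  if (x$best_epoch > 0) abline(v = x$best_epoch, lty = 3, col = "grey50")
  legend("topright", c("train", "validation"), lty = 1, bty = "n",
         col = c("black", "firebrick"))
  invisible(x)
}
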