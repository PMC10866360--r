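#' @title Surrogate good/bad molecule classifier
#' @description
#' A fully-connected network with two hidden layers (ReLU, dropout, sigmoid
#' output, binary cross-entropy) trained on binary 1024-bit Morgan
#' fingerprints to predict whether a molecule is "good" (STG below 0.6 and
#' OS above 0, strict inequalities) or "bad". Data are split 48/32/20 into
#' train/validation/holdout; hyperparameters (epochs, patience, learning
#' rate, neurons per layer, dropout) are tuned by random search scored on
#' validation accuracy, and the final accuracy is reported on the holdout
#' set. The trained model gates the genetic operators: only predicted-good
#' molecules reach property evaluation. Decision threshold 0.5.
#' @name surrogate-classifier
NULL

#' Good/bad label rule
#'
#' good iff stg < 0.6 (strict) and os > 0 (strict).
#'
#' @param stg,os numeric vectors
#' @return character vector of "good"/"bad"
#' @export
label_example <- function(stg, os) {
  ifelse(stg < 0.6 & os > 0, "good", "bad")
}

#' Fingerprint matrix
#'
#' Dense binary matrix of Morgan fingerprints, one row per molecule.
#'
#' @param smiles character vector
#' @param radius Morgan radius (default 2)
#' @param nbits bits (default 1024)
#' @return numeric matrix n x nbits with 0/1 entries
#' @export
fingerprint_matrix <- function(smiles, radius = 2L, nbits = 1024L) {
  bits <- chem_fingerprints(smiles, radius = radius, nbits = nbits)
  X <- matrix(0, nrow = length(smiles), ncol = nbits)
  for (i in seq_along(bits)) {
    if (!is.null(bits[[i]])) X[i, bits[[i]]] <- 1
  }
  rownames(X) <- smiles
  X
}

#' Tanimoto similarity against a reference fingerprint
#'
#' @param ref integer vector of on-bit positions
#' @param others list of integer vectors of on-bit positions
#' @return numeric vector in [0, 1]
#' @export
tanimoto <- function(ref, others) {
  vapply(others, function(b) {
    if (is.null(b)) return(NA_real_)
    inter <- length(intersect(ref, b))
    uni <- length(ref) + length(b) - inter
    if (uni == 0) return(1)
    inter / uni
  }, numeric(1))
}

#' Three-way split
#'
#' Random disjoint partition into train/validation/holdout with sizes
#' round(0.48 N) / round(0.32 N) / remainder, reproducible from
#' `split_seed`.
#'
#' @param n number of examples (>= 10)
#' @param labels character vector of labels (both classes must be present)
#' @param split_seed integer seed
#' @return list of integer index vectors `train`, `validation`, `holdout`
#' @export
split_dataset <- function(n, labels, split_seed = 1L) {
  stopifnot(n >= 10, length(labels) == n)
  if (length(unique(labels)) < 2) stop("degenerate dataset: single label")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(split_seed)
  perm <- sample.int(n)
  n_train <- round(0.48 * n)
  n_val <- round(0.32 * n)
  list(train = perm[seq_len(n_train)],
       validation = perm[n_train + seq_len(n_val)],
       holdout = perm[(n_train + n_val + 1L):n])
}

# ---- two-hidden-layer MLP in base R ---------------------------------------

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

mlp_init <- function(n_in, hidden) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  list(W1 = he(n_in, hidden[1]), b1 = rep(0, hidden[1]),
       W2 = he(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
       W3 = he(hidden[2], 1), b3 = 0)
}

mlp_forward <- function(par, X, dropout = 0, train = FALSE) {
  Z1 <- sweep(X %*% par$W1, 2, par$b1, `+`)
  A1 <- relu(Z1)
  M1 <- NULL
  if (train && dropout > 0) {
    M1 <- matrix(stats::rbinom(length(A1), 1, 1 - dropout), nrow(A1)) / (1 - dropout)
    A1 <- A1 * M1
  }
  Z2 <- sweep(A1 %*% par$W2, 2, par$b2, `+`)
  A2 <- relu(Z2)
  M2 <- NULL
  if (train && dropout > 0) {
    M2 <- matrix(stats::rbinom(length(A2), 1, 1 - dropout), nrow(A2)) / (1 - dropout)
    A2 <- A2 * M2
  }
  Z3 <- A2 %*% par$W3 + par$b3
  p <- sigmoid(Z3)
  list(p = p, A1 = A1, A2 = A2, Z1 = Z1, Z2 = Z2, M1 = M1, M2 = M2)
}

mlp_grad <- function(par, X, y, fw, w = NULL) {
  n <- nrow(X)
  # d loss / d Z3 for (weighted) BCE + sigmoid
  d3 <- if (is.null(w)) (fw$p - y) / n else w * (fw$p - y) / sum(w)
  gW3 <- t(fw$A2) %*% d3
  gb3 <- sum(d3)
  d2 <- (d3 %*% t(par$W3)) * (fw$Z2 > 0)
  if (!is.null(fw$M2)) d2 <- d2 * fw$M2
  gW2 <- t(fw$A1) %*% d2
  gb2 <- colSums(d2)
  d1 <- (d2 %*% t(par$W2)) * (fw$Z1 > 0)
  if (!is.null(fw$M1)) d1 <- d1 * fw$M1
  gW1 <- t(X) %*% d1
  gb1 <- colSums(d1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Train the two-hidden-layer network
#'
#' Adam optimizer, minibatches, early stopping on validation loss.
#'
#' @param X,y training matrix and 0/1 labels
#' @param Xval,yval validation data for early stopping
#' @param hidden two hidden-layer sizes
#' @param lr learning rate
#' @param epochs maximum epochs
#' @param patience epochs without validation-loss improvement before stopping
#' @param dropout dropout rate in [0, 0.5]
#' @param batch_size minibatch size
#' @param pos_weight loss weight on positive examples; good molecules are a
#'   small minority of campaign data (pre-gate success rates in realistic
#'   campaigns sit below 10 percent), and unweighted training collapses to the
#'   majority class. Default 1 (unweighted); [train_with_tuning()] sets the
#'   inverse class frequency.
#' @return list with weights `par`, `val_loss`, `val_accuracy`, `epochs_run`
#' @export
mlp_train <- function(X, y, Xval, yval, hidden = c(64L, 64L), lr = 1e-3,
                      epochs = 60L, patience = 10L, dropout = 0.1,
                      batch_size = 64L, pos_weight = 1) {
  par <- mlp_init(ncol(X), hidden)
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  t <- 0
  best <- list(loss = Inf, par = par, epoch = 0L)
  n <- nrow(X)
  wts <- ifelse(y == 1, pos_weight, 1)
  wval <- ifelse(yval == 1, pos_weight, 1)
  bce <- function(p, y, w) -sum(w * (y * log(pmax(p, 1e-12)) +
                                       (1 - y) * log(pmax(1 - p, 1e-12)))) / sum(w)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1, n)]
      Xb <- X[bi, , drop = FALSE]; yb <- y[bi]
      fw <- mlp_forward(par, Xb, dropout = dropout, train = TRUE)
      gr <- mlp_grad(par, Xb, yb, fw, w = wts[bi])
      t <- t + 1
      for (nm in names(par)) {
        m[[nm]] <- b1m * m[[nm]] + (1 - b1m) * gr[[nm]]
        v[[nm]] <- b2m * v[[nm]] + (1 - b2m) * gr[[nm]]^2
        mhat <- m[[nm]] / (1 - b1m^t)
        vhat <- v[[nm]] / (1 - b2m^t)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    pv <- mlp_forward(par, Xval)$p
    vloss <- bce(pv, yval, wval)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, par = par, epoch = ep)
    } else if (ep - best$epoch >= patience) {
      break
    }
  }
  pv <- mlp_forward(best$par, Xval)$p
  list(par = best$par, val_loss = best$loss,
       val_accuracy = mean((pv > 0.5) == (yval == 1)), epochs_run = ep,
       hidden = hidden)
}

#' Hyperparameter search space
#'
#' Bounded ranges for random search: epochs, early-stop patience, log-scale
#' learning rate, neurons per hidden layer, dropout.
#'
#' @param epochs,patience,neurons integer ranges c(lo, hi)
#' @param lr learning-rate range (sampled log-uniformly)
#' @param dropout dropout range
#' @return a `search_space`
#' @export
search_space <- function(epochs = c(10L, 200L), patience = c(5L, 30L),
                         lr = c(1e-4, 1e-2), neurons = c(32L, 512L),
                         dropout = c(0, 0.5)) {
  stopifnot(epochs[1] <= epochs[2], patience[1] <= patience[2],
            lr[1] > 0, lr[1] <= lr[2], neurons[1] <= neurons[2],
            dropout[1] >= 0, dropout[2] <= 1)
  structure(list(epochs = epochs, patience = patience, lr = lr,
                 neurons = neurons, dropout = dropout),
            class = "search_space")
}

sample_trial <- function(space) {
  runif_int <- function(r) sample(seq(r[1], r[2]), 1L)
  list(epochs = runif_int(space$epochs),
       patience = runif_int(space$patience),
       lr = exp(stats::runif(1, log(space$lr[1]), log(space$lr[2]))),
       hidden = c(runif_int(space$neurons), runif_int(space$neurons)),
       dropout = stats::runif(1, space$dropout[1], space$dropout[2]))
}

#' Train with hyperparameter tuning
#'
#' Runs `n_trials` random-search trials over the space, keeps the trial
#' with best validation accuracy, and reports holdout accuracy. A model
#' that fails to beat the majority-class baseline is still returned, with
#' a warning.
#'
#' @param data data.frame with columns `canonical` and `label` ("good" /
#'   "bad"); fingerprints are computed internally
#' @param space a [search_space()]
#' @param n_trials number of random-search trials (default 30)
#' @param split_seed seed for the 48/32/20 split
#' @param radius,nbits fingerprint parameters
#' @return an `invest_classifier`: weights, chosen hyperparameters, trial
#'   history, split indices, validation and holdout accuracy
#' @export
train_with_tuning <- function(data, space = search_space(), n_trials = 30L,
                              split_seed = 1L, radius = 2L, nbits = 1024L) {
  stopifnot(all(c("canonical", "label") %in% names(data)))
  X <- fingerprint_matrix(data$canonical, radius = radius, nbits = nbits)
  y <- as.numeric(data$label == "good")
  sp <- split_dataset(nrow(X), data$label, split_seed = split_seed)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  Xv <- X[sp$validation, , drop = FALSE]; yv <- y[sp$validation]
  Xh <- X[sp$holdout, , drop = FALSE]; yh <- y[sp$holdout]
  trials <- list()
  best <- NULL
  pos_weight <- min(sum(ytr == 0) / max(sum(ytr == 1), 1), 50)
  for (k in seq_len(n_trials)) {
    hp <- sample_trial(space)
    fit <- mlp_train(Xtr, ytr, Xv, yv, hidden = hp$hidden, lr = hp$lr,
                     epochs = hp$epochs, patience = hp$patience,
                     dropout = hp$dropout, pos_weight = pos_weight)
    trials[[k]] <- c(hp[c("epochs", "patience", "lr", "dropout")],
                     list(h1 = hp$hidden[1], h2 = hp$hidden[2],
                          val_accuracy = fit$val_accuracy))
    if (is.null(best) || fit$val_accuracy > best$fit$val_accuracy) {
      best <- list(fit = fit, hp = hp)
    }
  }
  majority <- max(mean(yh == 1), mean(yh == 0))
  ph <- mlp_forward(best$fit$par, Xh)$p
  holdout_acc <- mean((ph > 0.5) == (yh == 1))
  if (holdout_acc <= majority - 0.05) {
    warning("tuned model does not beat the majority-class baseline")
  }
  structure(list(par = best$fit$par, hyperparameters = best$hp,
                 trials = do.call(rbind, lapply(trials, as.data.frame)),
                 radius = radius, nbits = nbits,
                 val_accuracy = best$fit$val_accuracy,
                 holdout_accuracy = holdout_acc,
                 split = sp, n_train = length(sp$train)),
            class = "invest_classifier")
}

#' @export
print.invest_classifier <- function(x, ...) {
  cat("<invest_classifier> 2 hidden layers (",
      paste(x$hyperparameters$hidden, collapse = ", "),
      "), validation accuracy ", round(x$val_accuracy, 3),
      ", holdout accuracy ", round(x$holdout_accuracy, 3), "\n", sep = "")
  invisible(x)
}

#' Predict good-probability
#'
#' Accepts either a trained `invest_classifier` or a plain function
#' (character vector of SMILES -> probabilities), so toy classifiers can
#' stand in wherever a model is expected (gating, explanations).
#'
#' @param model an `invest_classifier` or a function
#' @param smiles character vector
#' @return numeric vector of probabilities
#' @export
predict_good <- function(model, smiles) {
  if (is.function(model)) return(as.numeric(model(smiles)))
  X <- fingerprint_matrix(smiles, radius = model$radius, nbits = model$nbits)
  as.numeric(mlp_forward(model$par, X)$p)
}

#' Classification accuracy
#' @param predicted character vector of predicted labels
#' @param truth character vector of true labels
#' @return fraction correct
#' @export
accuracy <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  mean(predicted == truth)
}

#' Classifier gate
#'
#' Returns TRUE for molecules the model scores strictly above 0.5
#' ("good"); used inside the genetic operators so only predicted-good
#' structures reach property evaluation.
#'
#' @param model an `invest_classifier`
#' @param smiles character vector
#' @return logical vector
#' @export
gate_candidates <- function(model, smiles) {
  if (length(smiles) == 0) return(logical())
  predict_good(model, smiles) > 0.5
}

#' Subset candidates through the gate
#' @param model an `invest_classifier`
#' @param smiles character vector
#' @return the subset predicted good, order preserved
#' @export
gate <- function(model, smiles) {
  smiles[gate_candidates(model, smiles)]
}
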