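## Single-hidden-layer feed-forward regressor for stability changes.
## Inputs and target are min-max scaled to [-1, 1] by training-split
## statistics and predictions mapped back to kcal/mol. Training is
## online (per-instance) gradient descent with momentum on squared error, with a
## validation split for early stopping: once the validation RMSE has not
## set a new minimum (beyond a 1e-6 tolerance) for `patience` consecutive
## epochs, training stops and the best-validation-epoch parameters are
## returned.

#' Train the stability regressor
#'
#' @param X numeric feature matrix (rows = mutations).
#' @param y experimental stability changes, kcal/mol (positive =
#'   destabilizing under the default sign convention).
#' @param hidden_units hidden-layer width, default 5.
#' @param val_fraction fraction of rows held out for early stopping,
#'   default 0.15 (the last 15% of a seeded shuffle).
#' @param patience consecutive non-improving epochs tolerated, default 5.
#' @param seed integer seed for the shuffle and weight initialisation.
#' @param max_epochs epoch cap, default 500.
#' @param learning_rate per-instance gradient step, default 0.1 (0.3, the
#'   classic online-backpropagation default, overshoots on descriptors of
#'   this width; see the methods vignette).
#' @param momentum momentum coefficient, default 0.2.
#' @param activation hidden activation, `"tanh"` (default) or
#'   `"identity"` (linear limit, useful for closed-form checks).
#' @return object of class `ddg_model`: weights, input/target scalers,
#'   per-epoch history and the manifest hash when `X` carries slot names.
#' @export
train_model <- function(X, y, hidden_units = 5, val_fraction = 0.15,
                        patience = 5, seed = 1L, max_epochs = 500,
                        learning_rate = 0.1, momentum = 0.2,
                        activation = c("tanh", "identity")) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  if (nrow(X) < 10) stop("too few rows to train: ", nrow(X))
  if (stats::var(y) == 0)
    warning("degenerate target (zero variance); model trains to a constant")

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- nrow(X)
  perm <- sample.int(n)
  n_val <- max(1L, floor(val_fraction * n))
  val_idx <- perm[(n - n_val + 1L):n]
  tr_idx <- perm[1:(n - n_val)]

  # min-max scale inputs and target to [-1, 1] on training-split statistics
  lo <- apply(X[tr_idx, , drop = FALSE], 2, min)
  hi <- apply(X[tr_idx, , drop = FALSE], 2, max)
  mu <- (lo + hi) / 2
  sdv <- (hi - lo) / 2
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  y_mu <- (min(y[tr_idx]) + max(y[tr_idx])) / 2
  y_sd <- (max(y[tr_idx]) - min(y[tr_idx])) / 2
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  t <- (y - y_mu) / y_sd
  Ztr <- Z[tr_idx, , drop = FALSE]; ttr <- t[tr_idx]
  Zva <- Z[val_idx, , drop = FALSE]; tva <- t[val_idx]

  d <- ncol(X); h <- hidden_units
  W1 <- matrix(stats::runif(d * h, -0.5, 0.5), d, h)
  b1 <- stats::runif(h, -0.5, 0.5)
  W2 <- matrix(stats::runif(h, -0.5, 0.5), h, 1)
  b2 <- stats::runif(1, -0.5, 0.5)
  vW1 <- matrix(0, d, h); vb1 <- numeric(h); vW2 <- matrix(0, h, 1); vb2 <- 0

  act <- if (activation == "tanh") tanh else identity
  dact <- if (activation == "tanh") function(a) 1 - a^2 else
    function(a) matrix(1, nrow(a), ncol(a))
  fwd <- function(Zm) {
    A <- act(sweep(Zm %*% W1, 2, b1, "+"))
    list(A = A, out = drop(A %*% W2) + b2)
  }
  rmse <- function(pred, target) sqrt(mean((pred - target)^2))

  best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
               val = Inf, epoch = 0L)
  history <- data.frame(epoch = integer(), train_rmse = numeric(),
                        val_rmse = numeric())
  stale <- 0L
  ntr <- length(tr_idx)
  for (epoch in seq_len(max_epochs)) {
    # online backpropagation: one momentum update per training instance,
    # instance order reshuffled every epoch
    for (r in sample.int(ntr)) {
      x <- Ztr[r, ]
      a <- act(drop(x %*% W1) + b1)
      out <- sum(a * W2) + b2
      err <- out - ttr[r]                    # d(SE/2)/d out
      delta1 <- drop(err * W2) * drop(dact(matrix(a, 1)))
      vW2 <- momentum * vW2 - learning_rate * err * a
      vb2 <- momentum * vb2 - learning_rate * err
      vW1 <- momentum * vW1 - learning_rate * outer(x, delta1)
      vb1 <- momentum * vb1 - learning_rate * delta1
      W1 <- W1 + vW1; b1 <- b1 + vb1; W2 <- W2 + vW2; b2 <- b2 + vb2
    }
    tr_rmse <- rmse(fwd(Ztr)$out, ttr)
    va_rmse <- rmse(fwd(Zva)$out, tva)
    history <- rbind(history, data.frame(epoch = epoch, train_rmse = tr_rmse,
                                         val_rmse = va_rmse))
    if (va_rmse < best$val - 1e-6) {
      best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, val = va_rmse,
                   epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }

  out <- list(
    input_dim = d, hidden_units = h, activation = activation,
    W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
    x_center = mu, x_scale = sdv, y_center = y_mu, y_scale = y_sd,
    slots = colnames(X),
    manifest_hash = if (!is.null(colnames(X)))
      digest::digest(paste(colnames(X), collapse = "|"), algo = "xxhash32")
      else NA_character_,
    history = history, best_epoch = best$epoch, seed = seed,
    sign_convention = "positive_destabilizing"
  )
  class(out) <- "ddg_model"
  out
}

#' @export
print.ddg_model <- function(x, ...) {
  cat(sprintf(
    "<ddg_model> %d inputs, %d hidden (%s); best epoch %d (val RMSE %.4f)\n",
    x$input_dim, x$hidden_units, x$activation, x$best_epoch,
    min(x$history$val_rmse)))
  invisible(x)
}

#' Predict stability changes
#'
#' @param object a `ddg_model`.
#' @param X feature matrix with `input_dim` columns.
#' @param ... unused.
#' @return numeric vector of predicted stability changes, kcal/mol.
#' @export
predict.ddg_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$input_dim)
    stop("dimension mismatch: model expects ", object$input_dim,
         " features, got ", ncol(X))
  Z <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  act <- if (object$activation == "tanh") tanh else identity
  A <- act(sweep(Z %*% object$W1, 2, object$b1, "+"))
  out_z <- drop(A %*% object$W2) + object$b2
  out_z * object$y_scale + object$y_center
}

#' k-fold cross-validation
#'
#' Seeded random partition into `k` folds; every row is predicted exactly
#' once by a model that never saw it. Fold seeds are derived from `seed`
#' so the whole procedure is reproducible.
#'
#' @param X feature matrix.
#' @param y target vector.
#' @param k number of folds, default 10.
#' @param seed integer seed.
#' @param ... passed to [train_model()].
#' @return list with `predictions` (length n), `folds` (fold id per row),
#'   `metrics` (pooled [metrics_report()]) and `per_fold` metrics.
#' @export
cross_validate <- function(X, y, k = 10, seed = 1L, ...) {
  n <- length(y)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k rows")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  pred <- rep(NA_real_, n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    m <- train_model(X[tr, , drop = FALSE], y[tr], seed = seed + f, ...)
    pred[te] <- predict(m, X[te, , drop = FALSE])
    per_fold[[f]] <- metrics_report(y[te], pred[te])
  }
  list(predictions = pred, folds = folds,
       metrics = metrics_report(y, pred),
       per_fold = do.call(rbind, per_fold))
}

#' Save / load a trained model
#'
#' Plain-text JSON serialization carrying dimensions, the manifest hash,
#' weights, scalers and training history. Loading refuses a file whose
#' manifest hash disagrees with `expected_hash`.
#'
#' @param model a `ddg_model`.
#' @param path output / input file.
#' @param expected_hash optional manifest hash to enforce on load.
#' @return the model (invisibly for save).
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$W1 <- as.vector(obj$W1); obj$W2 <- as.vector(obj$W2)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(model)
}

#' @rdname save_model
#' @export
load_model <- function(path, expected_hash = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W1 <- matrix(obj$W1, obj$input_dim, obj$hidden_units)
  obj$W2 <- matrix(obj$W2, obj$hidden_units, 1)
  obj$x_center <- stats::setNames(as.numeric(obj$x_center), obj$slots)
  obj$x_scale <- stats::setNames(as.numeric(obj$x_scale), obj$slots)
  class(obj) <- "ddg_model"
  if (!is.null(expected_hash) && !identical(obj$manifest_hash, expected_hash))
    stop("manifest hash mismatch: model was trained with a different ",
         "feature layout (", obj$manifest_hash, " vs ", expected_hash, ")")
  obj
}
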