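#' Build the lagged feature matrix
#'
#' The surrogate's input space: the six outdoor variables at time t plus
#' `T_a`, `G` and `A_G` at 3, 6, 12 and 24 hours prior — 18 features. Rows
#' exist only where the full 24-hour lag history is available. Column order
#' is the contract `T_a, T_d, v, p, G, A_G, T_a_lag3, G_lag3, A_G_lag3,
#' T_a_lag6, ..., A_G_lag24`.
#'
#' @param series a [meteo_series()] at a 1 h or 3 h step.
#' @return a `feature_matrix`: list with `X` (numeric matrix, 18 columns)
#'   and `timestamps` (POSIXct of each row).
#' @export
build_feature_matrix <- function(series) {
  stopifnot(inherits(series, "meteo_series"))
  step <- step_hours(series)
  lags_h <- c(3, 6, 12, 24)
  if (any(lags_h %% step != 0)) {
    stop("series step must divide the lag offsets (1 h or 3 h)")
  }
  n <- nrow(series)
  max_lag <- max(lags_h) / step
  if (n < max_lag) stop("series shorter than the 24 h lag history")
  rows <- if (n == max_lag) integer(0) else (max_lag + 1):n
  lag_vars <- c("T_a", "G", "A_G")
  cols <- vector("list", 18L)
  names(cols) <- c(METEO_VARS,
                   unlist(lapply(lags_h, function(h) paste0(lag_vars, "_lag", h))))
  for (vn in METEO_VARS) cols[[vn]] <- series[[vn]][rows]
  for (h in lags_h) {
    k <- h / step
    for (vn in lag_vars) {
      cols[[paste0(vn, "_lag", h)]] <- series[[vn]][rows - k]
    }
  }
  X <- do.call(cbind, cols)
  structure(list(X = X, timestamps = series$timestamp[rows]),
            class = "feature_matrix")
}

#' Random train/validation/test split
#'
#' Shuffles row indices reproducibly and assigns 80% / 10% / 10% (sizes by
#' rounding: `round(0.8 n)`, `round(0.1 n)`, remainder to test).
#'
#' @param n_rows number of rows (>= 10).
#' @param seed integer seed.
#' @return a `data_split`: list of disjoint integer index vectors `train`,
#'   `validation`, `test` covering `1:n_rows`.
#' @export
split_dataset <- function(n_rows, seed) {
  if (n_rows < 10) stop("n_rows must be >= 10")
  set.seed(seed)
  perm <- sample.int(n_rows)
  n_tr <- round(0.8 * n_rows)
  n_va <- round(0.1 * n_rows)
  structure(list(train = sort(perm[seq_len(n_tr)]),
                 validation = sort(perm[n_tr + seq_len(n_va)]),
                 test = sort(perm[(n_tr + n_va + 1):n_rows]),
                 seed = seed),
            class = "data_split")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(Xs, w) {
  H <- sigmoid(sweep(Xs %*% w$W1, 2, w$b1, "+"))
  drop(H %*% w$W2) + w$b2
}

#' Train a neural surrogate
#'
#' Fits the fixed 18-16-1 architecture (sigmoid hidden layer, linear
#' output) by mini-batch Adam on mean squared error: learning rate 1e-4,
#' batch size 8, early stopping on validation loss with patience 20 over at
#' most 500 epochs, restoring the best-validation weights. Features and
#' target are z-scored with training-split statistics (stored on the model
#' and inverted at prediction). Deterministic for a given seed, which drives
#' weight initialisation (Glorot uniform) and batch shuffling.
#'
#' @param features a [build_feature_matrix()] result.
#' @param y target vector (`T_i` or `PET_i`, degC), aligned to the feature
#'   rows.
#' @param split a [split_dataset()] over the feature rows.
#' @param hyper optional overrides: `learning_rate`, `batch_size`,
#'   `max_epochs`, `patience`.
#' @param seed integer seed.
#' @param workplace_id,target metadata strings recorded on the model.
#' @return a `surrogate_model` with weights, scalers, per-epoch loss
#'   history, early-stopping epoch and test MAE (K).
#' @export
train_surrogate <- function(features, y, split = NULL, hyper = list(),
                            seed = 1L, workplace_id = "synthetic",
                            target = "T_i") {
  stopifnot(inherits(features, "feature_matrix"))
  X <- features$X
  if (length(y) != nrow(X)) stop("features and target are not aligned")
  if (any(!is.finite(y))) stop("non-finite values in target")
  hp <- utils::modifyList(list(learning_rate = 1e-4, batch_size = 8L,
                               max_epochs = 500L, patience = 20L), hyper)
  if (is.null(split)) split <- split_dataset(nrow(X), seed)

  x_center <- colMeans(X[split$train, , drop = FALSE])
  x_scale <- apply(X[split$train, , drop = FALSE], 2, stats::sd)
  x_scale[x_scale < 1e-12] <- 1
  y_center <- mean(y[split$train])
  y_scale <- stats::sd(y[split$train])
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale

  set.seed(seed)
  n_in <- ncol(X); n_h <- 16L
  glorot <- function(n1, n2) {
    lim <- sqrt(6 / (n1 + n2))
    matrix(stats::runif(n1 * n2, -lim, lim), n1, n2)
  }
  w <- list(W1 = glorot(n_in, n_h), b1 = numeric(n_h),
            W2 = glorot(n_h, 1L), b2 = 0)
  adam <- list(m = lapply(w, function(x) x * 0),
               v = lapply(w, function(x) x * 0), t = 0L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  tr <- split$train; va <- split$validation
  Xtr <- Xs[tr, , drop = FALSE]; ytr <- ys[tr]
  Xva <- Xs[va, , drop = FALSE]; yva <- ys[va]
  n_tr <- length(tr)
  val_loss <- function(w) mean((mlp_forward(Xva, w) - yva)^2)

  best <- list(w = w, loss = val_loss(w), epoch = 0L)
  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())
  wait <- 0L
  for (epoch in seq_len(hp$max_epochs)) {
    idx <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = hp$batch_size)
    ep_loss <- 0
    for (s in starts) {
      b <- idx[s:min(s + hp$batch_size - 1L, n_tr)]
      Xb <- Xtr[b, , drop = FALSE]; yb <- ytr[b]
      nb <- length(b)
      # forward
      H <- sigmoid(sweep(Xb %*% w$W1, 2, w$b1, "+"))
      yhat <- drop(H %*% w$W2) + w$b2
      err <- yhat - yb
      ep_loss <- ep_loss + sum(err^2)
      # backward (MSE, mean over batch)
      d_out <- 2 * err / nb
      g <- list(W2 = crossprod(H, d_out), b2 = sum(d_out))
      dH <- tcrossprod(d_out, drop(w$W2)) * H * (1 - H)
      g$W1 <- crossprod(Xb, dH)
      g$b1 <- colSums(dH)
      g <- g[names(w)]
      adam$t <- adam$t + 1L
      corr1 <- 1 - b1^adam$t; corr2 <- 1 - b2^adam$t
      for (nm in names(w)) {
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g[[nm]]
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g[[nm]]^2
        w[[nm]] <- w[[nm]] - hp$learning_rate * (adam$m[[nm]] / corr1) /
          (sqrt(adam$v[[nm]] / corr2) + eps)
      }
    }
    vl <- val_loss(w)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_mse = ep_loss / n_tr,
                                         val_mse = vl))
    if (vl < best$loss - 1e-12) {
      best <- list(w = w, loss = vl, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp$patience) break
    }
    if (!is.finite(vl)) stop("divergent loss at epoch ", epoch)
  }

  model <- structure(list(
    weights = lapply(best$w, unname),
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    feature_names = colnames(features$X),
    hyper = hp,
    meta = list(workplace_id = workplace_id, target = target,
                optimizer = "adam", seed = seed,
                epochs_run = nrow(history), best_epoch = best$epoch),
    history = history
  ), class = "surrogate_model")
  model$test_mae <- evaluate_mae(model,
                                 X[split$test, , drop = FALSE],
                                 y[split$test])
  model
}

predict_scaled <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  mlp_forward(Xs, model$weights) * model$y_scale + model$y_center
}

#' Predict a target series from outdoor weather
#'
#' @param model a trained `surrogate_model`.
#' @param series a [meteo_series()] covering the required 24 h lag history.
#' @return data.frame with `timestamp` and the predicted target (one row
#'   per usable feature row).
#' @export
predict_series <- function(model, series) {
  fm <- build_feature_matrix(series)
  if (!identical(colnames(fm$X), model$feature_names)) {
    stop("feature/scaler mismatch between model and series")
  }
  out <- data.frame(timestamp = fm$timestamps,
                    pred = predict_scaled(model, fm$X))
  names(out)[2] <- model$meta$target
  attr(out, "step_hours") <- step_hours(series)
  attr(out, "calendar") <- series_calendar(series)
  out
}

#' Mean absolute error on a held-out set
#'
#' @param model a `surrogate_model`.
#' @param X_test feature matrix rows (18 columns, model column order).
#' @param y_test observed target values.
#' @return MAE (K).
#' @export
evaluate_mae <- function(model, X_test, y_test) {
  if (length(y_test) == 0L) stop("empty test set")
  mean(abs(predict_scaled(model, X_test) - y_test))
}

#' Serialize / restore a surrogate model as JSON
#'
#' Weights, scalers, hyperparameters and metadata in one documented JSON
#' file (the 18-16-1 weight matrices are small enough for plain text).
#'
#' @param model a `surrogate_model`.
#' @param path file path.
#' @return `write_surrogate` returns `path` invisibly; `read_surrogate`
#'   the restored model.
#' @export
write_surrogate <- function(model, path) {
  obj <- unclass(model)
  obj$weights <- lapply(obj$weights, function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else list(dim = length(x), data = as.numeric(x))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$weights <- lapply(obj$weights, function(wo) {
    if (length(wo$dim) == 2) matrix(wo$data, wo$dim[1], wo$dim[2])
    else as.numeric(wo$data)
  })
  obj$x_center <- unlist(obj$x_center)
  obj$x_scale <- unlist(obj$x_scale)
  structure(obj, class = "surrogate_model")
}
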