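# Feed-forward binding-affinity regressors on latent features.
#
# The regressor is a fully connected network with three hidden layers
# (default 512/1024/512 rectified units) trained with minibatch Adam on a
# mean-squared-error loss, following the architecture and schedule used for
# transporter-inhibition panels: 1000 epochs at learning rate 1e-4 for the
# first half and 1e-5 for the second, batch size 16. Features and labels
# are standardized internally and predictions returned on the original
# kcal/mol scale. No R package in this stack offers an arbitrary-depth MLP
# with Adam, so the forward/backward pass is implemented here directly.

#' Configuration of the affinity regressor
#'
#' @param hidden_sizes integer vector of hidden-layer widths. Default
#'   `c(512, 1024, 512)`.
#' @param epochs training epochs. Default 1000.
#' @param lr_schedule data.frame with columns `from_epoch` and `rate`: the
#'   learning rate used from each epoch onward. Default 1e-4 from epoch 1,
#'   1e-5 from epoch 501.
#' @param batch_size minibatch size. Default 16.
#' @param activation hidden nonlinearity, `"relu"` (default) or `"tanh"`.
#' @param standardize standardize features and labels internally (default
#'   TRUE; predictions are always on the original scale).
#' @param seed integer seed governing initialization and batch shuffling.
#' @return an object of class `predictor_config`.
#' @export
predictor_config <- function(hidden_sizes = c(512L, 1024L, 512L),
                             epochs = 1000L,
                             lr_schedule = data.frame(
                               from_epoch = c(1L, 501L),
                               rate = c(1e-4, 1e-5)),
                             batch_size = 16L,
                             activation = c("relu", "tanh"),
                             standardize = TRUE,
                             seed = 1L) {
  activation <- match.arg(activation)
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) < 1L || any(is.na(hidden_sizes) | hidden_sizes < 1L)) {
    stop_config("hidden_sizes must be positive integers")
  }
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop_config("epochs must be positive")
  if (!is.data.frame(lr_schedule) ||
      !all(c("from_epoch", "rate") %in% names(lr_schedule)) ||
      nrow(lr_schedule) < 1L || any(lr_schedule$rate <= 0)) {
    stop_config("lr_schedule needs columns from_epoch, rate (positive)")
  }
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L) stop_config("batch_size must be positive")
  structure(list(hidden_sizes = hidden_sizes, epochs = epochs,
                 lr_schedule = lr_schedule[order(lr_schedule$from_epoch), ],
                 batch_size = batch_size, activation = activation,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "predictor_config")
}

#' Scaled-down regressor configuration for small synthetic panels
#'
#' Same architecture family as [predictor_config()] but sized for datasets
#' of a few hundred molecules in low-dimensional latent spaces: 32/64/32
#' hidden units, 150 epochs at learning rate 1e-2 dropping to 1e-3 after
#' epoch 75. Used by the test fixtures and the pipeline defaults on
#' codebook-scale data.
#'
#' @param ... overrides passed on to [predictor_config()].
#' @export
desk_predictor_config <- function(...) {
  args <- list(hidden_sizes = c(32L, 64L, 32L), epochs = 150L,
               lr_schedule = data.frame(from_epoch = c(1L, 76L),
                                        rate = c(1e-2, 1e-3)))
  do.call(predictor_config, utils::modifyList(args, list(...)))
}

.lr_at <- function(schedule, epoch) {
  schedule$rate[max(which(schedule$from_epoch <= epoch))]
}

.act <- function(z, kind) if (kind == "relu") pmax(z, 0) else tanh(z)
.act_grad <- function(a, kind) if (kind == "relu") (a > 0) * 1 else 1 - a^2

# Forward pass keeping activations for backprop. X is b x d.
.forward <- function(X, W, b, kind) {
  L <- length(W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    acts[[l + 1L]] <- .act(acts[[l]] %*% W[[l]] +
                             rep(b[[l]], each = nrow(X)), kind)
  }
  acts[[L + 1L]] <- acts[[L]] %*% W[[L]] + rep(b[[L]], each = nrow(X))
  acts
}

#' Train a binding-affinity regressor
#'
#' Fits the feed-forward network of `config` to latent features `x` and
#' binding free energies `y` (kcal/mol) by minibatch Adam on mean squared
#' error. Deterministic given `config$seed`.
#'
#' @param x numeric matrix of latent features, one molecule per row.
#' @param y numeric vector of binding free energies in kcal/mol.
#' @param config a [predictor_config()].
#' @param target optional target name carried in the fit (e.g. `"DAT"`).
#' @return an object of class `affinity_net` with `predict`, `print`,
#'   `summary`, `coef` and `residuals` methods.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200 * 4), 200)
#' y <- x %*% c(1, -2, 0.5, 0) - 9
#' fit <- affinity_net(x, y, desk_predictor_config(epochs = 50))
#' sqrt(mean((predict(fit, x) - y)^2))  # small training RMSE
#' @export
affinity_net <- function(x, y, config = predictor_config(), target = NULL) {
  stopifnot(inherits(config, "predictor_config"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) {
    stop_data("feature rows (", nrow(x), ") and labels (", length(y),
              ") differ in length")
  }
  if (nrow(x) < config$batch_size) {
    stop_data("need at least batch_size (", config$batch_size, ") samples")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_data("non-finite features or labels")
  }

  if (config$standardize) {
    x_center <- colMeans(x)
    x_scale <- apply(x, 2L, stats::sd)
    x_scale[x_scale == 0 | !is.finite(x_scale)] <- 1
    y_center <- mean(y)
    y_scale <- stats::sd(y)
    if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  } else {
    x_center <- rep(0, ncol(x)); x_scale <- rep(1, ncol(x))
    y_center <- 0; y_scale <- 1
  }
  Xs <- sweep(sweep(x, 2L, x_center), 2L, x_scale, "/")
  ys <- (y - y_center) / y_scale

  sizes <- c(ncol(x), config$hidden_sizes, 1L)
  L <- length(sizes) - 1L
  kind <- config$activation
  n <- nrow(Xs)

  fit_env <- with_seed(config$seed, {
    W <- vector("list", L); b <- vector("list", L)
    mW <- vector("list", L); vW <- vector("list", L)
    mb <- vector("list", L); vb <- vector("list", L)
    for (l in seq_len(L)) {
      # He initialization for rectifier nets
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L]) * sqrt(2 / sizes[l]),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
      mW[[l]] <- W[[l]] * 0; vW[[l]] <- W[[l]] * 0
      mb[[l]] <- b[[l]]; vb[[l]] <- b[[l]]
    }
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_adam <- 0L
    for (epoch in seq_len(config$epochs)) {
      lr <- .lr_at(config$lr_schedule, epoch)
      ord <- sample.int(n)
      starts <- seq.int(1L, n, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]
        yb <- ys[idx]
        acts <- .forward(Xb, W, b, kind)
        pred <- acts[[L + 1L]][, 1L]
        delta <- matrix(2 * (pred - yb) / length(idx), ncol = 1L)
        t_adam <- t_adam + 1L
        for (l in rev(seq_len(L))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(W[[l]])) * .act_grad(acts[[l]], kind)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          corr1 <- 1 - beta1^t_adam; corr2 <- 1 - beta2^t_adam
          W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
    }
    list(W = W, b = b)
  })

  obj <- structure(
    list(weights = fit_env$W, biases = fit_env$b, config = config,
         target = target, dimension = ncol(x),
         scaling = list(x_center = x_center, x_scale = x_scale,
                        y_center = y_center, y_scale = y_scale),
         n_train = n),
    class = "affinity_net")
  fitted <- predict(obj, x)
  obj$fitted <- fitted
  obj$residuals_train <- y - fitted
  obj$train_rmse <- sqrt(mean(obj$residuals_train^2))
  obj
}

#' Predict binding free energies from latent features
#'
#' @param object a fitted [affinity_net()].
#' @param newdata numeric matrix of latent features (rows) or a single
#'   latent vector.
#' @param ... unused.
#' @return numeric vector of predicted binding free energies (kcal/mol).
#' @export
predict.affinity_net <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(as.numeric(newdata), nrow = 1L)
  if (ncol(newdata) != object$dimension) {
    stop_domain("feature dimension ", ncol(newdata),
                " does not match the fitted model (", object$dimension, ")")
  }
  sc <- object$scaling
  Xs <- sweep(sweep(newdata, 2L, sc$x_center), 2L, sc$x_scale, "/")
  acts <- .forward(Xs, object$weights, object$biases, object$config$activation)
  acts[[length(acts)]][, 1L] * sc$y_scale + sc$y_center
}

#' @export
print.affinity_net <- function(x, ...) {
  cat("Affinity regressor",
      if (!is.null(x$target)) paste0("(", x$target, ")"), "\n")
  cat("  architecture:", paste(c(x$dimension, x$config$hidden_sizes, 1L),
                               collapse = "-"),
      "(", x$config$activation, ")\n")
  cat("  trained on", x$n_train, "molecules,", x$config$epochs,
      "epochs; training RMSE", signif(x$train_rmse, 4), "kcal/mol\n")
  invisible(x)
}

#' @export
summary.affinity_net <- function(object, ...) {
  n_par <- sum(vapply(object$weights, length, 1L)) +
    sum(vapply(object$biases, length, 1L))
  out <- list(target = object$target,
              architecture = c(object$dimension, object$config$hidden_sizes, 1L),
              n_parameters = n_par, n_train = object$n_train,
              train_rmse = object$train_rmse,
              train_r = stats::cor(object$fitted,
                                   object$fitted - object$residuals_train))
  class(out) <- "summary.affinity_net"
  out
}

#' @export
print.summary.affinity_net <- function(x, ...) {
  cat("Affinity regressor summary\n")
  if (!is.null(x$target)) cat("  target:", x$target, "\n")
  cat("  architecture:", paste(x$architecture, collapse = "-"),
      "(", x$n_parameters, "parameters )\n")
  cat("  training RMSE:", signif(x$train_rmse, 4), "kcal/mol\n")
  invisible(x)
}

#' @export
coef.affinity_net <- function(object, ...) {
  list(weights = object$weights, biases = object$biases)
}

#' @export
residuals.affinity_net <- function(object, ...) object$residuals_train

#' Pearson correlation coefficient
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop_domain("length mismatch")
  stats::cor(observed, predicted)
}

#' Root-mean-square error
#'
#' @param observed,predicted equal-length numeric vectors (kcal/mol).
#' @return RMSE, >= 0.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop_domain("length mismatch")
  sqrt(mean((observed - predicted)^2))
}

#' k-fold cross-validation of the affinity regressor
#'
#' Shuffles the sample with the configuration seed, splits it into `k`
#' folds whose sizes differ by at most one, holds each fold out once, and
#' reports per-fold and pooled Pearson R and RMSE. "Pooled" metrics are
#' computed on the concatenated out-of-fold predictions; fold-averaged
#' metrics are also reported.
#'
#' @inheritParams affinity_net
#' @param k number of folds (default 10).
#' @return an object of class `affinity_cv` with elements `fold` (fold id
#'   per sample), `per_fold` (data.frame of fold metrics), `pooled_r`,
#'   `pooled_rmse`, `mean_r`, `mean_rmse`, `predictions` (out-of-fold, in
#'   input order) and `seed`.
#' @export
kfold_cv <- function(x, y, config = predictor_config(), k = 10L,
                     target = NULL) {
  stopifnot(inherits(config, "predictor_config"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  k <- as.integer(k)
  if (is.na(k) || k < 2L || n < k) stop_data("need n >= k >= 2")
  fold <- with_seed(derive_seed(config$seed, "cv-folds"), {
    rep_len(seq_len(k), n)[sample.int(n)]
  })
  oof <- rep(NA_real_, n)
  per_fold <- data.frame(fold = seq_len(k), n = NA_integer_,
                         r = NA_real_, rmse = NA_real_)
  for (f in seq_len(k)) {
    hold <- which(fold == f)
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, paste0("cv-fit-", f))
    fit <- affinity_net(x[-hold, , drop = FALSE], y[-hold], cfg_f,
                        target = target)
    oof[hold] <- predict(fit, x[hold, , drop = FALSE])
    per_fold$n[f] <- length(hold)
    per_fold$r[f] <- pearson_r(y[hold], oof[hold])
    per_fold$rmse[f] <- rmse(y[hold], oof[hold])
  }
  structure(list(fold = fold, per_fold = per_fold,
                 pooled_r = pearson_r(y, oof),
                 pooled_rmse = rmse(y, oof),
                 mean_r = mean(per_fold$r),
                 mean_rmse = mean(per_fold$rmse),
                 predictions = oof, k = k, n = n, target = target,
                 seed = config$seed),
            class = "affinity_cv")
}

#' @export
print.affinity_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation",
      if (!is.null(x$target)) paste0("(", x$target, ")"), "on", x$n,
      "molecules\n", sep = " ")
  cat("  pooled R =", signif(x$pooled_r, 4),
      ", pooled RMSE =", signif(x$pooled_rmse, 4), "kcal/mol\n")
  cat("  fold-averaged R =", signif(x$mean_r, 4),
      ", RMSE =", signif(x$mean_rmse, 4), "kcal/mol\n")
  invisible(x)
}

#' Predict a multi-target affinity panel
#'
#' Applies one fitted regressor per target to each molecule's latent
#' vector, returning one binding free energy per molecule per target.
#'
#' @param candidates data.frame of molecules carrying `id` and latent
#'   `z0..z{d-1}` columns (see [generate_candidates()]).
#' @param predictors named list of [affinity_net()] fits, one per target.
#' @param targets targets to predict; defaults to
#'   `c("DAT", "NET", "SERT", "hERG")`.
#' @return data.frame with `id` plus one kcal/mol column per target.
#' @export
predict_panel <- function(candidates, predictors,
                          targets = c("DAT", "NET", "SERT", "hERG")) {
  missing_t <- setdiff(targets, names(predictors))
  if (length(missing_t) > 0L) {
    stop_config("no predictor for target(s): ",
                paste(missing_t, collapse = ", "))
  }
  out <- data.frame(id = as.character(candidates$id),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    for (t in targets) out[[t]] <- numeric(0)
    return(out)
  }
  z <- latent_matrix(candidates)
  for (t in targets) out[[t]] <- predict(predictors[[t]], z)
  out
}
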