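# Linear stacked autoencoder for the scalp-mixing model. With linear
# activations the encoder composes to a single unmixing map H = W I, so a
# 32-64-12 encoder trained to reconstruct 32-channel EEG through a
# 12-dimensional bottleneck recovers the source subspace whenever the data
# is (close to) a rank-12 linear mixture. Validation is by adjusted R^2
# between held-out channel vectors and their reconstruction.

#' Closed-form trainable-parameter count of the stacked autoencoder
#'
#' Sums `in * out + out` over consecutive encoder layers and, when
#' `mirrored = TRUE`, over the mirrored decoder (widths reversed), every
#' layer carrying a bias. The default 32-64-12 encoder with mirrored decoder
#' has 5804 parameters.
#'
#' @param layer_widths Integer vector of encoder widths, input first
#'   (default `c(32, 64, 12)`).
#' @param mirrored Include the mirrored decoder (default TRUE).
#' @return Integer parameter count.
#' @examples
#' count_sae_params(c(32, 64, 12))        # 5804
#' count_sae_params(c(32, 64, 12), FALSE) # encoder only
#' @export
count_sae_params <- function(layer_widths = c(32, 64, 12), mirrored = TRUE) {
  if (length(layer_widths) < 2L) stop_arg("need at least two layer widths")
  layer_widths <- vapply(seq_along(layer_widths), function(i)
    check_count(layer_widths[i], "layer_widths"), integer(1))
  widths <- if (mirrored) c(layer_widths, rev(layer_widths)[-1]) else layer_widths
  n_in <- widths[-length(widths)]
  n_out <- widths[-1]
  sum(n_in * n_out + n_out)
}

#' Assemble a stacked-autoencoder model from explicit weights
#'
#' Weight matrix `W[[l]]` maps layer `l`'s input to its output
#' (`out x in` orientation); biases are vectors. Layers run encoder first,
#' then the mirrored decoder. `center`/`scale` hold the per-channel z-scoring
#' applied before encoding and inverted after decoding.
#'
#' @param W List of weight matrices.
#' @param b List of bias vectors (same length as `W`).
#' @param center,scale Per-input-channel location/scale (defaults 0/1).
#' @param trained Logical flag gating [decompose()].
#' @param log Optional training-log tibble.
#' @return An object of class `sae_model`.
#' @export
sae_model <- function(W, b, center = NULL, scale = NULL, trained = FALSE,
                      log = NULL) {
  if (length(W) != length(b)) stop_arg("`W` and `b` must have equal length")
  for (l in seq_along(W)) {
    if (nrow(W[[l]]) != length(b[[l]])) {
      stop_arg("bias ", l, " length must equal the rows of W[[", l, "]]")
    }
    if (l > 1 && ncol(W[[l]]) != nrow(W[[l - 1]])) {
      stop_arg("layer ", l, " input width does not match layer ", l - 1,
               " output width")
    }
    if (!all(is.finite(W[[l]])) || !all(is.finite(b[[l]]))) {
      stop_arg("non-finite parameter in layer ", l)
    }
  }
  d_in <- ncol(W[[1]])
  if (is.null(center)) center <- rep(0, d_in)
  if (is.null(scale)) scale <- rep(1, d_in)
  widths <- c(d_in, vapply(W, nrow, integer(1)))
  structure(list(W = W, b = b, center = center, scale = scale,
                 widths = widths, trained = trained, log = log),
            class = "sae_model")
}

# Fan-in-scaled symmetric uniform initialisation, zero biases.
sae_init <- function(layer_widths = c(32, 64, 12), seed = 1) {
  widths <- c(layer_widths, rev(layer_widths)[-1])
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(widths) - 1L)) {
      fan_in <- widths[l]
      W[[l]] <- matrix(runif(widths[l + 1] * fan_in, -1, 1) / sqrt(fan_in),
                       widths[l + 1], fan_in)
      b[[l]] <- rep(0, widths[l + 1])
    }
    sae_model(W, b)
  })
}

# number of encoder layers (the code sits after them)
sae_code_layer <- function(model) (length(model$W)) %/% 2

# Forward pass on raw rows; returns activations per layer. Rows of `x` are
# channel vectors. Scaling is applied here and inverted by reconstruct().
sae_activations <- function(model, x) {
  x_sc <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  acts <- vector("list", length(model$W) + 1L)
  acts[[1]] <- x_sc
  for (l in seq_along(model$W)) {
    acts[[l + 1]] <- acts[[l]] %*% t(model$W[[l]]) +
      rep(model$b[[l]], each = nrow(x))
  }
  acts
}

#' Run channel vectors through the autoencoder
#'
#' `decoder(encoder(x))` with the stored per-channel scaling applied before
#' the encoder and inverted after the decoder; with zero centers the whole
#' map is linear.
#'
#' @param model An `sae_model`.
#' @param x Matrix of channel vectors (rows) or a single vector.
#' @return Matrix of reconstructed vectors, same shape as `x`.
#' @export
reconstruct <- function(model, x) {
  if (!inherits(model, "sae_model")) stop_arg("`model` must be an sae_model")
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$widths[1]) {
    stop_arg("input width ", ncol(x), " does not match the input layer (",
             model$widths[1], ")")
  }
  acts <- sae_activations(model, x)
  out <- acts[[length(acts)]]
  out <- sweep(sweep(out, 2, model$scale, "*"), 2, model$center, "+")
  if (vec) out[1, ] else out
}

#' Adjusted R-squared between data and its reconstruction
#'
#' `R^2 = 1 - sum((x - xhat)^2) / sum((x - mean(x))^2)` pooled over all
#' entries, and `adj R^2 = 1 - (1 - R^2)(N - 1)/(N - p - 1)` with `N` sample
#' vectors and `p` predictors (the 32 input channels by default).
#'
#' @param x,x_hat Matrices of equal shape (rows = sample vectors).
#' @param p Number of predictors (default 32).
#' @param N Sample count (default `nrow(x)`).
#' @return A `reconstruction_metrics` list: `r2`, `adjusted_r2`, `mse`,
#'   `n_samples`, `n_predictors`.
#' @examples
#' x <- matrix(rnorm(200), 100)
#' adjusted_r2(x, x, p = 2)$adjusted_r2  # 1
#' @export
adjusted_r2 <- function(x, x_hat, p = 32, N = NULL) {
  x <- as.matrix(x); x_hat <- as.matrix(x_hat)
  if (!all(dim(x) == dim(x_hat))) stop_arg("`x` and `x_hat` shapes differ")
  p <- check_count(p, "p", min = 1L)
  if (is.null(N)) N <- nrow(x)
  N <- check_count(N, "N", min = 2L)
  if (N <= p + 1) stop_arg("need N > p + 1 for the adjusted R-squared")
  ss_tot <- sum((x - mean(x))^2)
  if (ss_tot == 0) {
    stop(errorCondition("adjusted R-squared undefined: `x` has zero variance",
                        class = c("eegemo_undefined_metric", "error")))
  }
  ss_res <- sum((x - x_hat)^2)
  r2 <- 1 - ss_res / ss_tot
  adj <- 1 - (1 - r2) * (N - 1) / (N - p - 1)
  structure(list(r2 = r2, adjusted_r2 = adj, mse = mean((x - x_hat)^2),
                 n_samples = N, n_predictors = p),
            class = "reconstruction_metrics")
}

#' Training control for the autoencoder
#'
#' Mini-batch gradient descent with step-decayed learning rate, MSE
#' reconstruction loss, L2 weight decay and an L1 sparsity penalty on the
#' code; training stops when the validation adjusted R-squared reaches
#' `target_adj_r2` or after `max_epochs`.
#'
#' @param max_epochs,batch_size,lr,lr_decay,decay_every Optimiser settings.
#' @param lambda_l2 Weight-decay coefficient.
#' @param lambda_l1 Code-sparsity coefficient.
#' @param val_fraction Fraction of pooled samples held out (last part of the
#'   shuffled pool).
#' @param target_adj_r2 Early-stopping criterion (default 0.9).
#' @param max_samples Cap on pooled channel vectors used for training.
#' @return List of class `sae_control`.
#' @export
sae_control <- function(max_epochs = 80, batch_size = 128, lr = 1e-2,
                        lr_decay = 0.5, decay_every = 25, lambda_l2 = 1e-5,
                        lambda_l1 = 1e-4, val_fraction = 0.1,
                        target_adj_r2 = 0.9, max_samples = 20000) {
  structure(list(max_epochs = check_count(max_epochs, "max_epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 lr = check_positive(lr, "lr"),
                 lr_decay = check_positive(lr_decay, "lr_decay"),
                 decay_every = check_count(decay_every, "decay_every"),
                 lambda_l2 = check_nonneg(lambda_l2, "lambda_l2"),
                 lambda_l1 = check_nonneg(lambda_l1, "lambda_l1"),
                 val_fraction = val_fraction,
                 target_adj_r2 = target_adj_r2,
                 max_samples = check_count(max_samples, "max_samples")),
            class = "sae_control")
}

# loss and gradients on a batch of scaled rows x (n x d)
sae_loss_grad <- function(model, x_sc, lambda_l2, lambda_l1) {
  nl <- length(model$W)
  n <- nrow(x_sc)
  acts <- vector("list", nl + 1L)
  acts[[1]] <- x_sc
  for (l in seq_len(nl)) {
    acts[[l + 1]] <- acts[[l]] %*% t(model$W[[l]]) + rep(model$b[[l]], each = n)
  }
  x_hat <- acts[[nl + 1L]]
  code <- acts[[sae_code_layer(model) + 1L]]
  d <- ncol(x_sc)
  loss <- mean((x_hat - x_sc)^2) +
    lambda_l2 * sum(vapply(model$W, function(w) sum(w^2), numeric(1))) +
    lambda_l1 * mean(abs(code))

  gW <- vector("list", nl); gb <- vector("list", nl)
  g <- 2 * (x_hat - x_sc) / (n * d)
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- t(g) %*% acts[[l]] + 2 * lambda_l2 * model$W[[l]]
    gb[[l]] <- colSums(g)
    if (l > 1) {
      g <- g %*% model$W[[l]]
      if (l - 1L == sae_code_layer(model)) {
        g <- g + lambda_l1 * sign(acts[[l]]) / (n * ncol(acts[[l]]))
      }
    }
  }
  list(loss = loss, gW = gW, gb = gb, x_hat = x_hat)
}

#' Train the stacked autoencoder on pooled channel vectors
#'
#' Pools every time sample of every trial into one set of 32-channel
#' vectors, z-scores per channel over the training split, and minimises the
#' penalised MSE by mini-batch gradient descent (see [sae_control()]).
#' Per-epoch validation MSE and adjusted R-squared are logged; training
#' stops early once the validation adjusted R-squared reaches the target.
#'
#' @param data A [trialset()] or a `samples x channels` matrix.
#' @param layer_widths Encoder widths, input first (default `c(32, 64, 12)`;
#'   the decoder mirrors them).
#' @param control An [sae_control()].
#' @param seed Seed for shuffling and weight initialisation.
#' @param p Predictor count for the adjusted R-squared (defaults to the
#'   input width).
#' @return A trained `sae_model`; `$log` holds the per-epoch training curve
#'   and `$val_metrics` the final validation [adjusted_r2()].
#' @export
train_sae <- function(data, layer_widths = c(32, 64, 12),
                      control = sae_control(), seed = 1, p = NULL) {
  x <- pool_channel_vectors(data)
  if (ncol(x) != layer_widths[1]) {
    stop_arg("data has ", ncol(x), " channels but the input layer expects ",
             layer_widths[1])
  }
  if (is.null(p)) p <- ncol(x)

  with_seed(seed, {
    n_all <- nrow(x)
    take <- min(n_all, control$max_samples)
    ord <- sample.int(n_all, take)
    x <- x[ord, , drop = FALSE]
    n_val <- max(1L, floor(control$val_fraction * take))
    n_tr <- take - n_val
    if (n_tr < 2L) stop_arg("too few samples to train (", take, ")")
    x_tr <- x[seq_len(n_tr), , drop = FALSE]
    x_val <- x[(n_tr + 1L):take, , drop = FALSE]

    center <- colMeans(x_tr)
    scale <- apply(x_tr, 2, sd)
    degenerate_input <- all(scale == 0)
    scale[scale == 0] <- 1

    model <- sae_init(layer_widths, seed = seed)
    model$center <- center
    model$scale <- scale
    xs_tr <- sweep(sweep(x_tr, 2, center), 2, scale, "/")

    lr <- control$lr
    log_rows <- list()
    val_metrics <- NULL
    for (epoch in seq_len(control$max_epochs)) {
      if (epoch > 1 && (epoch - 1) %% control$decay_every == 0) {
        lr <- lr * control$lr_decay
      }
      perm <- sample.int(n_tr)
      ep_loss <- 0; n_batch <- 0L
      for (start in seq(1L, n_tr, by = control$batch_size)) {
        idx <- perm[start:min(start + control$batch_size - 1L, n_tr)]
        lg <- sae_loss_grad(model, xs_tr[idx, , drop = FALSE],
                            control$lambda_l2, control$lambda_l1)
        if (!is.finite(lg$loss)) {
          stop(errorCondition(
            paste0("training diverged (non-finite loss) at epoch ", epoch,
                   ", lr ", lr),
            class = c("eegemo_training_error", "error")))
        }
        for (l in seq_along(model$W)) {
          model$W[[l]] <- model$W[[l]] - lr * lg$gW[[l]]
          model$b[[l]] <- model$b[[l]] - lr * lg$gb[[l]]
        }
        ep_loss <- ep_loss + lg$loss; n_batch <- n_batch + 1L
      }
      x_val_hat <- reconstruct(model, x_val)
      val_mse <- mean((x_val - x_val_hat)^2)
      val_adj <- if (degenerate_input) NA_real_ else
        tryCatch(adjusted_r2(x_val, x_val_hat, p = p)$adjusted_r2,
                 eegemo_undefined_metric = function(e) NA_real_)
      log_rows[[epoch]] <- tibble(epoch = epoch, lr = lr,
                                  train_loss = ep_loss / n_batch,
                                  val_mse = val_mse, val_adj_r2 = val_adj)
      if (is.finite(val_adj) && val_adj >= control$target_adj_r2) break
    }
    if (degenerate_input) {
      warning("input has zero variance; validation adjusted R-squared is undefined")
    }
    model$log <- do.call(rbind, log_rows)
    model$trained <- TRUE
    model$val_metrics <- if (degenerate_input) NULL else
      tryCatch(adjusted_r2(x_val, reconstruct(model, x_val), p = p),
               eegemo_undefined_metric = function(e) NULL)
    model$seed <- seed
    model
  })
}

pool_channel_vectors <- function(data) {
  if (inherits(data, "trialset")) {
    d <- dim(data$data)
    # trials x channels x samples -> (trials*samples) x channels
    x <- aperm(data$data, c(3, 1, 2))
    dim(x) <- c(d[3] * d[1], d[2])
    x
  } else if (is.matrix(data)) {
    data
  } else {
    stop_arg("`data` must be a trialset or a samples x channels matrix")
  }
}

#' Decompose trials into latent source signals
#'
#' Applies the trained encoder to every (z-scored) time sample of every
#' trial; the code dimension is the configured source count (12 by default).
#'
#' @param model A trained `sae_model`.
#' @param trials A [trialset()].
#' @return A `source_estimate`: list with `sources`
#'   (`trials x n_code x samples`) and `fs`.
#' @export
decompose <- function(model, trials) {
  if (!inherits(model, "sae_model")) stop_arg("`model` must be an sae_model")
  if (!isTRUE(model$trained)) {
    stop_state("model is untrained; call train_sae() first")
  }
  if (!inherits(trials, "trialset")) stop_arg("`trials` must be a trialset")
  d <- dim(trials$data)
  if (d[2] != model$widths[1]) {
    stop_arg("trialset has ", d[2], " channels but the model expects ",
             model$widths[1])
  }
  nc <- sae_code_layer(model)
  k <- model$widths[nc + 1L]
  out <- array(0, dim = c(d[1], k, d[3]))
  for (tr in seq_len(d[1])) {
    x <- t(trials$data[tr, , ])            # samples x channels
    acts <- sae_activations(model, x)
    out[tr, , ] <- t(acts[[nc + 1L]])
  }
  structure(list(sources = out, fs = trials$fs, n_sources = k),
            class = "source_estimate")
}

#' @export
print.sae_model <- function(x, ...) {
  cat(sprintf("<sae_model> widths %s, %d parameters, %s\n",
              paste(x$widths, collapse = "-"),
              sum(vapply(x$W, length, integer(1))) +
                sum(vapply(x$b, length, integer(1))),
              if (isTRUE(x$trained)) "trained" else "untrained"))
  if (!is.null(x$val_metrics)) {
    cat(sprintf("  validation: R2 %.4f, adjusted R2 %.4f (N=%d, p=%d)\n",
                x$val_metrics$r2, x$val_metrics$adjusted_r2,
                x$val_metrics$n_samples, x$val_metrics$n_predictors))
  }
  invisible(x)
}

#' Tidy the autoencoder training curve
#'
#' @param x A trained `sae_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `lr`, `train_loss`, `val_mse`, `val_adj_r2`.
#' @method tidy sae_model
#' @export
tidy.sae_model <- function(x, ...) {
  if (is.null(x$log)) stop_state("model has no training log")
  as_tibble(x$log)
}

#' One-row summary of a trained autoencoder
#'
#' @param x A trained `sae_model`.
#' @param ... Unused.
#' @return Tibble with parameter count, epochs run and validation metrics.
#' @method glance sae_model
#' @export
glance.sae_model <- function(x, ...) {
  tibble(
    n_params = sum(vapply(x$W, length, integer(1))) +
      sum(vapply(x$b, length, integer(1))),
    epochs = if (is.null(x$log)) NA_integer_ else max(x$log$epoch),
    val_mse = if (is.null(x$val_metrics)) NA_real_ else x$val_metrics$mse,
    val_r2 = if (is.null(x$val_metrics)) NA_real_ else x$val_metrics$r2,
    val_adj_r2 = if (is.null(x$val_metrics)) NA_real_ else
      x$val_metrics$adjusted_r2
  )
}

#' Plot the autoencoder training curve
#'
#' @param object A trained `sae_model`.
#' @param ... Unused.
#' @return A ggplot of validation MSE and adjusted R-squared per epoch.
#' @method autoplot sae_model
#' @export
autoplot.sae_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$val_adj_r2), colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0.9, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "validation adjusted R²",
                  title = "Autoencoder training") +
    ggplot2::theme_minimal()
}
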