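# The emotion timing model: an LSTM runs over the 125-frame feature
# sequence, every per-step hidden output is kept and flattened, a biased
# fully connected layer (tanh) integrates the whole sequence, and one
# sigmoid unit emits the High-emotion probability. Trained with MSE loss by
# mini-batch gradient descent under a two-stage learning rate, dropout on
# the LSTM outputs and FC activations, and L2 regularisation. The forward
# and backward passes are written out explicitly so the parameterisation
# (and its closed-form parameter count) is fully specified.

#' Classifier architecture specification
#'
#' @param input_dim Features per frame (default 48 = 12 sources x 4 bands).
#' @param seq_len Frames per sequence (default 125).
#' @param lstm_hidden LSTM hidden width (default 125).
#' @param fc_units Fully connected units (default 125).
#' @param output_units Output units (default 1, sigmoid).
#' @param dropout_lstm,dropout_fc Dropout rates in [0, 1) applied during
#'   training to the flattened LSTM outputs and the FC activations.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(input_dim = 48, seq_len = 125, lstm_hidden = 125,
                            fc_units = 125, output_units = 1,
                            dropout_lstm = 0.2, dropout_fc = 0.2) {
  spec <- list(input_dim = check_count(input_dim, "input_dim"),
               seq_len = check_count(seq_len, "seq_len"),
               lstm_hidden = check_count(lstm_hidden, "lstm_hidden"),
               fc_units = check_count(fc_units, "fc_units"),
               output_units = check_count(output_units, "output_units"),
               dropout_lstm = check_nonneg(dropout_lstm, "dropout_lstm"),
               dropout_fc = check_nonneg(dropout_fc, "dropout_fc"))
  if (spec$dropout_lstm >= 1 || spec$dropout_fc >= 1) {
    stop_arg("dropout rates must lie in [0, 1)")
  }
  structure(spec, class = "classifier_spec")
}

#' Closed-form trainable-parameter count of the classifier
#'
#' `4 ((D + H) H + H)` for the four biased LSTM gates, `(L H) F + F` for the
#' fully connected layer over the flattened per-step outputs, and `F K + K`
#' for the sigmoid output layer. The default 48/125/125/125/1 architecture
#' has 2,040,376 parameters.
#'
#' @param spec A [classifier_spec()].
#' @return Integer parameter count.
#' @examples
#' count_classifier_params(classifier_spec())  # 2040376
#' @export
count_classifier_params <- function(spec = classifier_spec()) {
  if (!inherits(spec, "classifier_spec")) {
    stop_arg("`spec` must be a classifier_spec")
  }
  d <- spec$input_dim; h <- spec$lstm_hidden; l <- spec$seq_len
  f <- spec$fc_units; k <- spec$output_units
  as.integer(4 * ((d + h) * h + h) + (l * h) * f + f + f * k + k)
}

# fan-in-scaled init; forget-gate bias starts at 1 (standard practice,
# keeps early memory open)
lstm_init <- function(spec, seed = 1) {
  d <- spec$input_dim; h <- spec$lstm_hidden
  l <- spec$seq_len; f <- spec$fc_units; k <- spec$output_units
  with_seed(seed, {
    u <- function(nr, nc) matrix(runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
    bg <- rep(0, 4 * h)
    bg[(h + 1):(2 * h)] <- 1
    structure(list(spec = spec,
                   Wg = u(d + h, 4 * h), bg = bg,
                   Wfc = u(l * h, f), bfc = rep(0, f),
                   Wout = u(f, k), bout = rep(0, k),
                   center = rep(0, d), scale = rep(1, d),
                   trained = FALSE, log = NULL, seed = seed),
              class = "lstm_classifier")
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass over a batch. `xt` is a list of seq_len matrices (B x D),
# already feature-scaled. Dropout masks (inverted dropout) are supplied by
# the caller during training, NULL at inference. Returns caches for BPTT.
lstm_forward_batch <- function(model, xt, mask_lstm = NULL, mask_fc = NULL) {
  sp <- model$spec
  h <- sp$lstm_hidden; l <- sp$seq_len
  b <- nrow(xt[[1]])
  i_ix <- seq_len(h); f_ix <- h + i_ix; g_ix <- 2 * h + i_ix; o_ix <- 3 * h + i_ix
  hs <- vector("list", l + 1L); cs <- vector("list", l + 1L)
  gates <- vector("list", l); tanhc <- vector("list", l)
  hs[[1]] <- matrix(0, b, h); cs[[1]] <- matrix(0, b, h)
  for (t in seq_len(l)) {
    zcat <- cbind(xt[[t]], hs[[t]])
    a <- zcat %*% model$Wg + rep(model$bg, each = b)
    gi <- sigmoid(a[, i_ix, drop = FALSE])
    gf <- sigmoid(a[, f_ix, drop = FALSE])
    gg <- tanh(a[, g_ix, drop = FALSE])
    go <- sigmoid(a[, o_ix, drop = FALSE])
    cs[[t + 1L]] <- gf * cs[[t]] + gi * gg
    tanhc[[t]] <- tanh(cs[[t + 1L]])
    hs[[t + 1L]] <- go * tanhc[[t]]
    gates[[t]] <- list(i = gi, f = gf, g = gg, o = go)
  }
  hall <- do.call(cbind, hs[-1L])           # B x (L*H), step-major blocks
  if (!is.null(mask_lstm)) hall <- hall * mask_lstm
  fc_pre <- hall %*% model$Wfc + rep(model$bfc, each = b)
  fc_act <- tanh(fc_pre)
  if (!is.null(mask_fc)) fc_act <- fc_act * mask_fc
  out <- sigmoid(fc_act %*% model$Wout + rep(model$bout, each = b))
  list(out = out, hall = hall, fc_act = fc_act, hs = hs, cs = cs,
       gates = gates, tanhc = tanhc, xt = xt,
       mask_lstm = mask_lstm, mask_fc = mask_fc)
}

# MSE loss gradient through the whole stack; returns per-parameter grads.
lstm_backward_batch <- function(model, cache, y, lambda_l2 = 0) {
  sp <- model$spec
  h <- sp$lstm_hidden; l <- sp$seq_len; d <- sp$input_dim
  b <- nrow(cache$out)
  p <- cache$out
  dout <- 2 * (p - y) / (b * sp$output_units)
  dpre_out <- dout * p * (1 - p)
  gWout <- t(cache$fc_act) %*% dpre_out + 2 * lambda_l2 * model$Wout
  gbout <- colSums(dpre_out)
  dfc_act <- dpre_out %*% t(model$Wout)
  if (!is.null(cache$mask_fc)) dfc_act <- dfc_act * cache$mask_fc
  dfc_pre <- dfc_act * (1 - tanh(cache$hall %*% model$Wfc +
                                   rep(model$bfc, each = b))^2)
  # fc_act in cache is post-dropout; recompute tanh' from pre-activation
  gWfc <- t(cache$hall) %*% dfc_pre + 2 * lambda_l2 * model$Wfc
  gbfc <- colSums(dfc_pre)
  dhall <- dfc_pre %*% t(model$Wfc)
  if (!is.null(cache$mask_lstm)) dhall <- dhall * cache$mask_lstm

  gWg <- matrix(0, d + h, 4 * h); gbg <- rep(0, 4 * h)
  dh_next <- matrix(0, b, h); dc_next <- matrix(0, b, h)
  i_ix <- seq_len(h)
  for (t in rev(seq_len(l))) {
    g <- cache$gates[[t]]
    dh <- dhall[, ((t - 1L) * h + 1L):(t * h), drop = FALSE] + dh_next
    do_ <- dh * cache$tanhc[[t]]
    dc <- dc_next + dh * g$o * (1 - cache$tanhc[[t]]^2)
    dpre <- cbind((dc * g$g) * g$i * (1 - g$i),
                  (dc * cache$cs[[t]]) * g$f * (1 - g$f),
                  (dc * g$i) * (1 - g$g^2),
                  do_ * g$o * (1 - g$o))
    zcat <- cbind(cache$xt[[t]], cache$hs[[t]])
    gWg <- gWg + t(zcat) %*% dpre
    gbg <- gbg + colSums(dpre)
    dzcat <- dpre %*% t(model$Wg)
    dh_next <- dzcat[, (d + 1L):(d + h), drop = FALSE]
    dc_next <- dc * g$f
  }
  gWg <- gWg + 2 * lambda_l2 * model$Wg
  loss <- mean((p - y)^2) +
    lambda_l2 * (sum(model$Wg^2) + sum(model$Wfc^2) + sum(model$Wout^2))
  list(loss = loss, gWg = gWg, gbg = gbg, gWfc = gWfc, gbfc = gbfc,
       gWout = gWout, gbout = gbout)
}

#' Forward pass of the emotion classifier
#'
#' Runs one feature sequence through the LSTM recurrence, flattens all
#' per-step hidden outputs, applies the fully connected layer (tanh) and the
#' sigmoid output unit. Dropout is disabled (inference mode).
#'
#' @param model An `lstm_classifier`.
#' @param sequence `seq_len x input_dim` matrix.
#' @return Probability in (0, 1) that the sequence belongs to the High class.
#' @export
classifier_forward <- function(model, sequence) {
  if (!inherits(model, "lstm_classifier")) {
    stop_arg("`model` must be an lstm_classifier")
  }
  sequence <- as.matrix(sequence)
  sp <- model$spec
  if (nrow(sequence) != sp$seq_len || ncol(sequence) != sp$input_dim) {
    stop_arg("sequence must be ", sp$seq_len, " x ", sp$input_dim, ", got ",
             nrow(sequence), " x ", ncol(sequence))
  }
  xs <- sweep(sweep(sequence, 2, model$center), 2, model$scale, "/")
  xt <- lapply(seq_len(sp$seq_len), function(t) xs[t, , drop = FALSE])
  as.numeric(lstm_forward_batch(model, xt)$out)
}

#' Training control for the classifier
#'
#' Mini-batch gradient descent on the MSE between the sigmoid output and the
#' 0/1 labels, with a two-stage learning rate (high first, low afterwards),
#' gradient-norm clipping, dropout in training only, and early stopping once
#' the training accuracy reaches `target_accuracy`.
#'
#' @param max_epochs Total epoch budget.
#' @param stage_epochs Epochs run at `lr1` before switching to `lr2`.
#' @param lr1,lr2 Stage learning rates.
#' @param batch_size Sequences per mini-batch.
#' @param lambda_l2 L2 regularisation on the weight matrices.
#' @param clip_norm Global gradient-norm clip (Inf disables).
#' @param target_accuracy Early-stop threshold on training accuracy.
#' @return List of class `lstm_control`.
#' @export
lstm_control <- function(max_epochs = 150, stage_epochs = 100, lr1 = 0.05,
                         lr2 = 0.01, batch_size = 16, lambda_l2 = 1e-5,
                         clip_norm = 5, target_accuracy = 0.99) {
  structure(list(max_epochs = check_count(max_epochs, "max_epochs"),
                 stage_epochs = check_count(stage_epochs, "stage_epochs"),
                 lr1 = check_positive(lr1, "lr1"),
                 lr2 = check_positive(lr2, "lr2"),
                 batch_size = check_count(batch_size, "batch_size"),
                 lambda_l2 = check_nonneg(lambda_l2, "lambda_l2"),
                 clip_norm = clip_norm,
                 target_accuracy = target_accuracy),
            class = "lstm_control")
}

#' Train the LSTM+FC emotion classifier
#'
#' Features are z-scored per column over the training set (stored in the
#' model). Labels may be 0/1, logical, or a factor/character with levels
#' Low/High.
#'
#' @param sequences A `feature_set` or list of `seq_len x input_dim`
#'   matrices.
#' @param labels Binary labels, one per sequence.
#' @param spec A [classifier_spec()]; defaults are inferred from the data
#'   when omitted.
#' @param control An [lstm_control()].
#' @param seed Seed for initialisation, shuffling and dropout.
#' @return A trained `lstm_classifier` with a `$log` training curve.
#' @export
train_classifier <- function(sequences, labels, spec = NULL,
                             control = lstm_control(), seed = 1) {
  seqs <- if (inherits(sequences, "feature_set")) sequences$sequences else sequences
  if (!is.list(seqs) || !length(seqs)) stop_arg("`sequences` must be a nonempty list")
  y <- encode_labels(labels)
  if (length(y) != length(seqs)) stop_arg("one label per sequence required")
  if (length(unique(y)) < 2L) {
    warning("training labels contain a single class; the fit will be degenerate")
  }
  l <- nrow(seqs[[1]]); d <- ncol(seqs[[1]])
  if (is.null(spec)) spec <- classifier_spec(input_dim = d, seq_len = l)
  if (l != spec$seq_len || d != spec$input_dim) {
    stop_arg("sequences are ", l, " x ", d, " but the spec expects ",
             spec$seq_len, " x ", spec$input_dim)
  }
  n <- length(seqs)

  # stack once: n x L x D
  arr <- array(0, dim = c(n, l, d))
  for (k in seq_len(n)) arr[k, , ] <- seqs[[k]]
  flat <- matrix(aperm(arr, c(2, 1, 3)), n * l, d)  # rows: all frames
  center <- colMeans(flat)
  scl <- apply(flat, 2, sd); scl[scl == 0] <- 1
  for (j in seq_len(d)) arr[, , j] <- (arr[, , j] - center[j]) / scl[j]

  model <- lstm_init(spec, seed = seed)
  model$center <- center
  model$scale <- scl

  with_seed(seed + 1L, {
    log_rows <- list()
    for (epoch in seq_len(control$max_epochs)) {
      lr <- if (epoch <= control$stage_epochs) control$lr1 else control$lr2
      perm <- sample.int(n)
      ep_loss <- 0; n_batch <- 0L; n_correct <- 0L
      for (start in seq(1L, n, by = control$batch_size)) {
        idx <- perm[start:min(start + control$batch_size - 1L, n)]
        b <- length(idx)
        xt <- lapply(seq_len(l), function(t)
          matrix(arr[idx, t, ], b, d))
        m_lstm <- if (spec$dropout_lstm > 0)
          matrix((runif(b * l * spec$lstm_hidden) >= spec$dropout_lstm) /
                   (1 - spec$dropout_lstm), b) else NULL
        m_fc <- if (spec$dropout_fc > 0)
          matrix((runif(b * spec$fc_units) >= spec$dropout_fc) /
                   (1 - spec$dropout_fc), b) else NULL
        cache <- lstm_forward_batch(model, xt, m_lstm, m_fc)
        gr <- lstm_backward_batch(model, cache, y[idx], control$lambda_l2)
        if (!is.finite(gr$loss)) {
          stop(errorCondition(
            paste0("classifier training diverged (non-finite loss) at epoch ",
                   epoch), class = c("eegemo_training_error", "error")))
        }
        # global gradient-norm clipping
        gn <- sqrt(sum(gr$gWg^2) + sum(gr$gbg^2) + sum(gr$gWfc^2) +
                     sum(gr$gbfc^2) + sum(gr$gWout^2) + sum(gr$gbout^2))
        sc <- if (is.finite(control$clip_norm) && gn > control$clip_norm)
          control$clip_norm / gn else 1
        model$Wg <- model$Wg - lr * sc * gr$gWg
        model$bg <- model$bg - lr * sc * gr$gbg
        model$Wfc <- model$Wfc - lr * sc * gr$gWfc
        model$bfc <- model$bfc - lr * sc * gr$gbfc
        model$Wout <- model$Wout - lr * sc * gr$gWout
        model$bout <- model$bout - lr * sc * gr$gbout
        ep_loss <- ep_loss + gr$loss; n_batch <- n_batch + 1L
        n_correct <- n_correct + sum((cache$out > 0.5) == (y[idx] == 1))
      }
      acc <- n_correct / n
      log_rows[[epoch]] <- tibble(epoch = epoch, lr = lr,
                                  train_loss = ep_loss / n_batch,
                                  train_accuracy = acc)
      if (acc >= control$target_accuracy) break
    }
    model$log <- do.call(rbind, log_rows)
  })
  model$trained <- TRUE
  model
}

encode_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("Low", "High"))) {
      stop_arg("character labels must be 'Low' or 'High'")
    }
    return(as.numeric(labels == "High"))
  }
  if (is.logical(labels)) return(as.numeric(labels))
  if (!all(labels %in% c(0, 1))) stop_arg("numeric labels must be 0 or 1")
  as.numeric(labels)
}

#' Predicted High-class probabilities
#'
#' @param model A trained `lstm_classifier`.
#' @param sequences A `feature_set` or list of sequence matrices.
#' @return Numeric vector of probabilities.
#' @export
predict_prob <- function(model, sequences) {
  seqs <- if (inherits(sequences, "feature_set")) sequences$sequences else sequences
  if (is.matrix(seqs)) seqs <- list(seqs)
  vapply(seqs, function(s) classifier_forward(model, s), numeric(1))
}

#' Threshold probabilities into Low/High labels
#'
#' High when the probability strictly exceeds `threshold`; an exact tie is
#' classified Low.
#'
#' @param model A trained `lstm_classifier`.
#' @param sequences A `feature_set` or list of sequence matrices.
#' @param threshold Decision threshold (default 0.5).
#' @return Factor with levels `Low`, `High`.
#' @export
predict_label <- function(model, sequences, threshold = 0.5) {
  p <- predict_prob(model, sequences)
  factor(ifelse(p > threshold, "High", "Low"), levels = c("Low", "High"))
}

#' @export
predict.lstm_classifier <- function(object, newdata,
                                    type = c("prob", "label"),
                                    threshold = 0.5, ...) {
  type <- match.arg(type)
  if (type == "prob") predict_prob(object, newdata)
  else predict_label(object, newdata, threshold)
}

#' @export
print.lstm_classifier <- function(x, ...) {
  sp <- x$spec
  cat(sprintf(paste0("<lstm_classifier> %d features x %d steps, LSTM %d, ",
                     "FC %d, %d output; %d parameters, %s\n"),
              sp$input_dim, sp$seq_len, sp$lstm_hidden, sp$fc_units,
              sp$output_units, count_classifier_params(sp),
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

#' Tidy the classifier training curve
#'
#' @param x A trained `lstm_classifier`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `lr`, `train_loss`, `train_accuracy`.
#' @method tidy lstm_classifier
#' @export
tidy.lstm_classifier <- function(x, ...) {
  if (is.null(x$log)) stop_state("model has no training log")
  as_tibble(x$log)
}

#' One-row summary of a trained classifier
#'
#' @param x A trained `lstm_classifier`.
#' @param ... Unused.
#' @return Tibble with parameter count, epochs and final training metrics.
#' @method glance lstm_classifier
#' @export
glance.lstm_classifier <- function(x, ...) {
  tibble(n_params = count_classifier_params(x$spec),
         epochs = if (is.null(x$log)) NA_integer_ else max(x$log$epoch),
         train_loss = if (is.null(x$log)) NA_real_ else
           x$log$train_loss[nrow(x$log)],
         train_accuracy = if (is.null(x$log)) NA_real_ else
           x$log$train_accuracy[nrow(x$log)])
}

#' Plot the classifier training curve
#'
#' @param object A trained `lstm_classifier`.
#' @param ... Unused.
#' @return A ggplot of training loss and accuracy per epoch.
#' @method autoplot lstm_classifier
#' @export
autoplot.lstm_classifier <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$train_accuracy),
                       colour = "#2166ac") +
    ggplot2::geom_line(ggplot2::aes(y = .data$train_loss), colour = "#b2182b",
                       linetype = "dotted") +
    ggplot2::labs(x = "epoch", y = "training accuracy (solid) / loss (dotted)",
                  title = "Classifier training") +
    ggplot2::theme_minimal()
}

#' Enumerate the trainable scalars of an instantiated model
#'
#' Walks every weight matrix and bias vector of the object and sums their
#' lengths — the independent cross-check for the closed-form counters
#' [count_sae_params()] and [count_classifier_params()].
#'
#' @param model An `sae_model` or `lstm_classifier`.
#' @return Integer parameter count.
#' @examples
#' enumerate_params(new_classifier(classifier_spec(2, 3, 2, 2, 1)))
#' @export
enumerate_params <- function(model) {
  if (inherits(model, "lstm_classifier")) {
    length(model$Wg) + length(model$bg) + length(model$Wfc) +
      length(model$bfc) + length(model$Wout) + length(model$bout)
  } else if (inherits(model, "sae_model")) {
    sum(vapply(model$W, length, integer(1))) +
      sum(vapply(model$b, length, integer(1)))
  } else {
    stop_arg("`model` must be an sae_model or lstm_classifier")
  }
}

#' Instantiate an untrained classifier
#'
#' Allocates all weight matrices and biases for a [classifier_spec()] with
#' fan-in-scaled random initialisation.
#'
#' @param spec A [classifier_spec()].
#' @param seed Initialisation seed.
#' @return An untrained `lstm_classifier`.
#' @export
new_classifier <- function(spec = classifier_spec(), seed = 1) {
  lstm_init(spec, seed = seed)
}

#' Instantiate an untrained stacked autoencoder
#'
#' Allocates encoder and mirrored-decoder layers for the given widths with
#' fan-in-scaled random initialisation and zero biases.
#'
#' @param layer_widths Encoder widths, input first (default `c(32, 64, 12)`).
#' @param seed Initialisation seed.
#' @return An untrained `sae_model`.
#' @export
new_sae <- function(layer_widths = c(32, 64, 12), seed = 1) {
  sae_init(layer_widths, seed = seed)
}
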