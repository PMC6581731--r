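# Experimental harness: High/Low labeling of the 1-9 ratings with a
# discarded middle band, class balancing by down-sampling, k-fold
# cross-validation with mean accuracy, and paired t-tests between pipeline
# arms.

#' Label trials High/Low from their ratings
#'
#' A trial is High when its rating on the chosen dimension strictly exceeds
#' `high` (default 5.5), Low when strictly below `low` (default 4.5), and
#' discarded otherwise (including values exactly at a threshold).
#'
#' @param ratings A [trialset()], a ratings matrix with `valence`/`arousal`
#'   columns, or a numeric vector of ratings.
#' @param dimension `"valence"` or `"arousal"` (ignored for a vector).
#' @param high,low Thresholds on the 1--9 scale.
#' @return Tibble with `trial`, `rating`, `label` (factor Low/High, `NA` for
#'   discarded) and `kept`.
#' @examples
#' label_trials(c(6, 5, 4))$label
#' @export
label_trials <- function(ratings, dimension = c("valence", "arousal"),
                         high = 5.5, low = 4.5) {
  dimension <- match.arg(dimension)
  if (inherits(ratings, "trialset")) ratings <- ratings$ratings
  r <- if (is.matrix(ratings)) ratings[, dimension] else as.numeric(ratings)
  if (any(!is.finite(r)) || any(r < 1 | r > 9)) {
    stop_arg("ratings must be finite values in [1, 9]")
  }
  if (low > high) stop_arg("`low` must not exceed `high`")
  lab <- rep(NA_character_, length(r))
  lab[r > high] <- "High"
  lab[r < low] <- "Low"
  tibble(trial = seq_along(r), rating = r,
         label = factor(lab, levels = c("Low", "High")),
         kept = !is.na(lab))
}

#' Balance classes by down-sampling the majority class
#'
#' @param labels Tibble from [label_trials()] (discarded rows are dropped
#'   first).
#' @param seed Seed for the random subsample.
#' @return The balanced tibble (equal Low/High counts), with a `balance`
#'   attribute recording the before/after counts.
#' @export
balance_downsample <- function(labels, seed = 1) {
  keep <- labels[labels$kept, , drop = FALSE]
  n_low <- sum(keep$label == "Low")
  n_high <- sum(keep$label == "High")
  if (n_low == 0L || n_high == 0L) {
    stop_arg("cannot balance: one class is empty (Low = ", n_low,
             ", High = ", n_high, ")")
  }
  n_min <- min(n_low, n_high)
  out <- with_seed(seed, {
    pick <- function(cls) {
      ix <- which(keep$label == cls)
      if (length(ix) > n_min) sort(sample(ix, n_min)) else ix
    }
    keep[sort(c(pick("Low"), pick("High"))), , drop = FALSE]
  })
  attr(out, "balance") <- c(low_before = n_low, high_before = n_high,
                            per_class_after = n_min)
  out
}

#' Random k-fold partition
#'
#' @param n_items Number of items to split.
#' @param k Number of folds (default 10).
#' @param seed Seed for the random assignment.
#' @return List of `k` disjoint index vectors whose union is
#'   `1:n_items`; sizes differ by at most one.
#' @export
kfold_split <- function(n_items, k = 10, seed = 1) {
  n_items <- check_count(n_items, "n_items")
  k <- check_count(k, "k", min = 2L)
  if (n_items < k) stop_arg("n_items (", n_items, ") must be >= k (", k, ")")
  with_seed(seed, {
    assign_ <- sample(rep(seq_len(k), length.out = n_items))
    lapply(seq_len(k), function(f) which(assign_ == f))
  })
}

#' Cross-validated mean accuracy
#'
#' The arithmetic mean over folds of the per-fold fraction correct.
#'
#' @param fold_correct_counts,fold_test_sizes Equal-length integer vectors.
#' @return Mean accuracy in [0, 1].
#' @examples
#' mean_accuracy(c(8, 9), c(10, 10))
#' @export
mean_accuracy <- function(fold_correct_counts, fold_test_sizes) {
  if (length(fold_correct_counts) != length(fold_test_sizes) ||
      !length(fold_test_sizes)) {
    stop_arg("fold vectors must be nonempty and of equal length")
  }
  if (any(fold_test_sizes <= 0)) stop_arg("every fold must contain test items")
  if (any(fold_correct_counts < 0 | fold_correct_counts > fold_test_sizes)) {
    stop_arg("correct counts must lie in [0, fold size]")
  }
  mean(fold_correct_counts / fold_test_sizes)
}

#' Paired t-test between two sets of fold accuracies
#'
#' Standard paired t statistic with `n - 1` degrees of freedom and two-sided
#' p-value. Identical inputs give `t = 0, p = 1`; constant nonzero
#' differences make the statistic undefined and raise a degenerate-test
#' condition.
#'
#' @param acc_a,acc_b Equal-length accuracy vectors (length >= 2).
#' @return Tibble with `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2L) {
    stop_arg("need two equal-length vectors of length >= 2")
  }
  d <- acc_a - acc_b
  tol <- sqrt(.Machine$double.eps) * (1 + abs(mean(d)))
  if (sd(d) < tol) {
    if (all(abs(d) < tol)) {
      return(tibble(t = 0, df = length(d) - 1L, p_value = 1, mean_diff = 0))
    }
    stop(errorCondition(
      "paired t-test degenerate: differences have zero variance",
      class = c("eegemo_degenerate_test", "error")))
  }
  tt <- t.test(acc_a, acc_b, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Run one experimental arm end-to-end under k-fold cross-validation
#'
#' Chains decomposition (stacked autoencoder or none), feature extraction
#' (band power or reference-channel Pearson correlations), labeling,
#' balancing, and a k-fold cross-validated classifier (LSTM or an SVM
#' baseline via e1071 on per-sequence summary features).
#'
#' @param trials A [trialset()]; simulated with [simulate_trialset()] when
#'   `NULL`.
#' @param dimension Emotion dimension to classify (`"valence"` or
#'   `"arousal"`).
#' @param decomposition `"sae"`, `"none"` or `"ica"` (the ICA arm requires
#'   the optional fastICA package and is not re-implemented here).
#' @param features `"fbp"` or `"pcc"`.
#' @param classifier `"lstm"` or `"svm"`.
#' @param k Folds (default 10).
#' @param sae_layers Encoder widths for the `"sae"` arm.
#' @param lstm_hidden,fc_units,dropout Classifier architecture for the
#'   `"lstm"` arm (defaults 125/125/0.2).
#' @param sae_ctrl,lstm_ctrl Training controls ([sae_control()],
#'   [lstm_control()]).
#' @param bands Band set for FBP features.
#' @param seed Master seed; balancing, folds and per-fold training derive
#'   their seeds from it.
#' @param high,low Labeling thresholds.
#' @return A `cv_report`.
#' @export
run_experiment <- function(trials = NULL, dimension = c("valence", "arousal"),
                           decomposition = c("sae", "none", "ica"),
                           features = c("fbp", "pcc"),
                           classifier = c("lstm", "svm"),
                           k = 10, sae_layers = c(32, 64, 12),
                           lstm_hidden = 125, fc_units = 125, dropout = 0.2,
                           sae_ctrl = sae_control(),
                           lstm_ctrl = lstm_control(), bands = eeg_bands(),
                           seed = 1, high = 5.5, low = 4.5) {
  dimension <- match.arg(dimension)
  decomposition <- match.arg(decomposition)
  features <- match.arg(features)
  classifier <- match.arg(classifier)
  if (is.null(trials)) trials <- simulate_trialset(seed = seed)
  if (!inherits(trials, "trialset")) stop_arg("`trials` must be a trialset")

  signal <- switch(decomposition,
    sae = {
      model <- train_sae(trials, layer_widths = sae_layers,
                         control = sae_ctrl, seed = seed)
      decompose(model, trials)
    },
    none = trials,
    ica = {
      if (!requireNamespace("fastICA", quietly = TRUE)) {
        stop_arg("the ICA comparison arm needs the optional fastICA package; ",
                 "use decomposition = 'sae' or 'none'")
      }
      ica_decompose(trials, n_sources = sae_layers[length(sae_layers)])
    })

  fset <- switch(features,
    fbp = extract_fbp_sequence(signal, bands = bands),
    pcc = extract_pcc_sequence(signal))

  labs <- label_trials(trials, dimension = dimension, high = high, low = low)
  n_total <- nrow(labs)
  balanced <- balance_downsample(labs, seed = seed + 1L)
  n_bal <- nrow(balanced)
  seqs <- fset$sequences[balanced$trial]
  y <- as.character(balanced$label)

  folds <- kfold_split(n_bal, k = k, seed = seed + 2L)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_ix <- folds[[f]]
    train_ix <- setdiff(seq_len(n_bal), test_ix)
    pred <- if (classifier == "lstm") {
      sp <- classifier_spec(input_dim = ncol(seqs[[1]]),
                            seq_len = nrow(seqs[[1]]),
                            lstm_hidden = lstm_hidden, fc_units = fc_units,
                            dropout_lstm = dropout, dropout_fc = dropout)
      fit <- train_classifier(seqs[train_ix], y[train_ix], spec = sp,
                              control = lstm_ctrl, seed = seed + 10L + f)
      as.character(predict_label(fit, seqs[test_ix]))
    } else {
      svm_baseline(seqs, y, train_ix, test_ix)
    }
    n_corr <- sum(pred == y[test_ix])
    fold_rows[[f]] <- tibble(fold = f, n_test = length(test_ix),
                             n_correct = n_corr,
                             accuracy = n_corr / length(test_ix))
  }
  fold_tbl <- do.call(rbind, fold_rows)

  structure(list(
    folds = fold_tbl,
    mean_accuracy = mean_accuracy(fold_tbl$n_correct, fold_tbl$n_test),
    arm = c(decomposition = decomposition, features = features,
            classifier = classifier),
    dimension = dimension, k = k, seed = seed,
    n_total = n_total, n_kept = sum(labs$kept), n_balanced = n_bal,
    balance = attr(balanced, "balance")
  ), class = "cv_report")
}

# summary-feature SVM adapter (baseline; internals live in e1071)
svm_baseline <- function(seqs, y, train_ix, test_ix) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop_arg("the SVM baseline needs the e1071 package")
  }
  summ <- t(vapply(seqs, function(m) c(colMeans(m), apply(m, 2, sd)),
                   numeric(2 * ncol(seqs[[1]]))))
  fit <- e1071::svm(x = summ[train_ix, , drop = FALSE],
                    y = factor(y[train_ix], levels = c("Low", "High")),
                    kernel = "radial", scale = TRUE)
  as.character(predict(fit, summ[test_ix, , drop = FALSE]))
}

# optional ICA adapter; only reachable when fastICA is installed
ica_decompose <- function(trials, n_sources) {
  d <- dim(trials$data)
  out <- array(0, dim = c(d[1], n_sources, d[3]))
  for (tr in seq_len(d[1])) {
    x <- t(trials$data[tr, , ])
    ic <- fastICA::fastICA(x, n.comp = n_sources)
    out[tr, , ] <- t(ic$S)
  }
  structure(list(sources = out, fs = trials$fs, n_sources = n_sources),
            class = "source_estimate")
}

#' Compare two cross-validation reports with a paired t-test
#'
#' @param report_a,report_b `cv_report`s with equal fold counts.
#' @return Tibble with both mean accuracies and the paired-test columns of
#'   [paired_ttest()].
#' @export
compare_reports <- function(report_a, report_b) {
  if (!inherits(report_a, "cv_report") || !inherits(report_b, "cv_report")) {
    stop_arg("both arguments must be cv_report objects")
  }
  tt <- paired_ttest(report_a$folds$accuracy, report_b$folds$accuracy)
  cbind(tibble(mean_a = report_a$mean_accuracy,
               mean_b = report_b$mean_accuracy), tt)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s | %s\n",
              paste(names(x$arm), x$arm, sep = "=", collapse = ", "),
              x$dimension))
  cat(sprintf("  trials: %d total, %d labeled, %d after balancing\n",
              x$n_total, x$n_kept, x$n_balanced))
  cat(sprintf("  %d-fold mean accuracy: %.4f (folds %s)\n", x$k,
              x$mean_accuracy,
              paste(sprintf("%.2f", x$folds$accuracy), collapse = " ")))
  invisible(x)
}

#' Per-fold accuracies of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with `fold`, `n_test`, `n_correct`, `accuracy`.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) as_tibble(x$folds)

#' One-row summary of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with the arm, fold count, mean and spread of accuracies.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(decomposition = x$arm[["decomposition"]],
         features = x$arm[["features"]],
         classifier = x$arm[["classifier"]],
         dimension = x$dimension, k = x$k,
         n_balanced = x$n_balanced,
         mean_accuracy = x$mean_accuracy,
         sd_accuracy = sd(x$folds$accuracy))
}

#' Plot per-fold accuracies
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot bar chart with the mean accuracy marked.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fold", y = "accuracy",
                  title = sprintf("%s / %s / %s on %s: mean %.3f",
                                  object$arm[["decomposition"]],
                                  object$arm[["features"]],
                                  object$arm[["classifier"]],
                                  object$dimension, object$mean_accuracy)) +
    ggplot2::theme_minimal()
}
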