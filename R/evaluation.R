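#' Stratified k-fold split
#'
#' Partitions `1..n_samples` into `k` disjoint folds of near-equal size
#' (sizes differ by at most one) such that every class's samples are spread
#' across folds as evenly as possible (per-class counts per fold differ by
#' at most one).
#'
#' @param n_samples Number of samples (>= k).
#' @param labels Integer class labels, length `n_samples`.
#' @param k Number of folds (>= 2, default 10).
#' @param seed Seed for the within-class shuffle.
#' @return List of `k` integer index vectors; disjoint, union `1..n`.
#' @export
kfold_split <- function(n_samples, labels, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  if (n_samples < k) stop("need at least k samples")
  stopifnot(length(labels) == n_samples)
  with_seed(seed, {
    ord <- unlist(lapply(split(seq_len(n_samples), labels),
                         function(ix) ix[sample.int(length(ix))]),
                  use.names = FALSE)
    fold <- rep_len(seq_len(k), n_samples)
    unname(split(ord, fold))
  })
}

#' Confusion matrix of multiclass predictions
#'
#' @param true,pred Integer labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return Object of class `confusion_matrix`: an integer
#'   `n_classes x n_classes` matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true, pred, n_classes) {
  stopifnot(length(true) == length(pred))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true)) cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Accuracy, true-positive rate and false-positive rate from a confusion matrix
#'
#' `ACC` is the overall fraction of correct classifications
#' (`(TP + TN) / (TP + FN + FP + TN)` with correct classifications counted
#' as positive).  `TPR = TP / (TP + FN)` and `FPR = FP / (FP + TN)` are
#' computed one-vs-rest per class and macro-averaged.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `acc`, `tpr`, `fpr`.
#' @export
cm_metrics <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  seen <- (tp + fn) > 0
  list(acc = sum(tp) / n,
       tpr = mean((tp / (tp + fn))[seen]),
       fpr = mean(fp / (fp + tn)))
}

#' Wolpaw information transfer rate
#'
#' `ITR = (60 / T) * (log2 Q + P log2 P + (1 - P) log2((1 - P) / (Q - 1)))`
#' in bits per minute, where `P` is the recognition accuracy, `Q` the number
#' of targets and `T` the average trial duration in seconds (time window
#' plus gaze-shift time; offline analyses conventionally add 0.55 s for the
#' gaze shift).  `0 * log2(0)` is taken as 0, so `P = 1` gives
#' `(60 / T) * log2 Q`.  Below-chance accuracies (`P < 1/Q`) do not
#' represent usable information transfer; they are reported as 0 with a
#' warning.
#'
#' @param p Accuracy in `(0, 1]`.
#' @param q Number of targets (>= 2).
#' @param t_trial_s Average trial duration in seconds (> 0).
#' @return ITR in bits/min.
#' @examples
#' itr(0.8999, 40, 1.0 + 0.55)  # about 167.36
#' @export
itr <- function(p, q, t_trial_s) {
  if (any(p <= 0) || any(p > 1)) stop("p must be in (0, 1]")
  if (any(q < 2)) stop("q must be at least 2")
  if (any(t_trial_s <= 0)) stop("t_trial_s must be positive")
  bits <- log2(q) +
    ifelse(p > 0, p * log2(p), 0) +
    ifelse(p < 1, (1 - p) * log2((1 - p) / (q - 1)), 0)
  out <- 60 / t_trial_s * bits
  below <- p < 1 / q
  if (any(below)) {
    warning("accuracy below chance (p < 1/q); reporting ITR = 0")
    out[below] <- 0
  }
  pmax(out, 0)
}

#' Cross-validated evaluation of the full pipeline on an epoch array
#'
#' Featurizes the epochs ([featurize_epochs()]), splits *trials* (not
#' windows) into stratified folds so that overlapping windows from one trial
#' never straddle the train/test boundary, trains one classifier per fold
#' and aggregates fold accuracies, a pooled confusion matrix, macro TPR/FPR
#' and the Wolpaw ITR at the mean accuracy.
#'
#' @param epochs An [epoch_array][simulate_epochs].
#' @param window_s Analysis window length in seconds.
#' @param variant Classifier/feature variant, see [featurize_epochs()].
#' @param n_bands Number of harmonic bands for spectral variants.
#' @param latency_s Visual latency applied when cutting windows.
#' @param step_s Sliding step in seconds.
#' @param k Number of folds (default 10).
#' @param tcfg A [train_config()].
#' @param gaze_shift_s Gaze-shift time added to the window length in the
#'   ITR trial duration (default 0.55).
#' @param seed Master seed for fold assignment and weight initialization.
#' @return Object of class `eval_report`: list with `fold_acc`, `mean_acc`,
#'   `se_acc`, `confusion`, `tpr`, `fpr`, `itr_bpm`, `window_s`,
#'   `gaze_shift_s`, `variant`, `n_bands`, `seed`.
#' @export
evaluate_pipeline <- function(epochs, window_s,
                              variant = c("zpfd", "fd", "raw", "separable"),
                              n_bands = 2L, latency_s = 0.13, step_s = 0.1,
                              k = 10L, tcfg = train_config(),
                              gaze_shift_s = 0.55, seed = 1L) {
  variant <- match.arg(variant)
  feats <- featurize_epochs(epochs, window_s, latency_s = latency_s,
                            step_s = step_s, variant = variant,
                            n_bands = n_bands)
  K <- n_targets(epochs$codebook)
  trials <- unique(feats$trial)
  trial_label <- feats$y[match(trials, feats$trial)]
  folds <- kfold_split(length(trials), trial_label, k = k, seed = seed)
  cfg <- model_config(feats$rows, feats$cols, K, variant = variant)
  fold_acc <- numeric(k)
  pooled <- matrix(0L, K, K)
  for (f in seq_len(k)) {
    test_trials <- trials[folds[[f]]]
    te <- feats$trial %in% test_trials
    model <- build_model(cfg, seed = seed + f)
    tc <- tcfg
    tc$seed <- tcfg$seed + f
    model <- train_cnn(model, feats$x[!te, , drop = FALSE], feats$y[!te], tc)
    pred <- predict(model, feats$x[te, , drop = FALSE])
    cm <- confusion_matrix(feats$y[te], pred, K)
    fold_acc[f] <- cm_metrics(cm)$acc
    pooled <- pooled + cm
  }
  pooled <- structure(pooled, class = c("confusion_matrix", "matrix"))
  m <- cm_metrics(pooled)
  mean_acc <- mean(fold_acc)
  structure(list(fold_acc = fold_acc, mean_acc = mean_acc,
                 se_acc = stats::sd(fold_acc) / sqrt(k),
                 confusion = pooled, tpr = m$tpr, fpr = m$fpr,
                 itr_bpm = if (mean_acc <= 1 / K) 0 else
                   itr(mean_acc, K, window_s + gaze_shift_s),
                 window_s = window_s, gaze_shift_s = gaze_shift_s,
                 variant = variant, n_bands = n_bands, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report '%s'> %d-fold CV\n", x$variant,
              length(x$fold_acc)))
  cat(sprintf("  accuracy: %.4f +/- %.4f (SE); TPR %.4f, FPR %.4f\n",
              x$mean_acc, x$se_acc, x$tpr, x$fpr))
  cat(sprintf("  ITR: %.2f bits/min at window %.2f s + gaze shift %.2f s\n",
              x$itr_bpm, x$window_s, x$gaze_shift_s))
  invisible(x)
}

#' Compare feature/classifier variants on matched synthetic data
#'
#' For each seed, one synthetic dataset is simulated and every requested
#' variant is evaluated on it with identical folds and training recipe.
#' Used to test the expected accuracy ordering (zero-padded features above
#' unpadded features above raw time-domain input; full 3x3 kernels above the
#' separable factorisation).
#'
#' @param codebook A [make_codebook()] object.
#' @param cfg A [sim_config()]; its `seed` is replaced by each study seed.
#' @param variants Character vector of variants to evaluate.
#' @param window_s,latency_s,step_s,n_bands,k,tcfg,seed As in
#'   [evaluate_pipeline()]; `seeds` gives the study seeds.
#' @param seeds Integer vector of study seeds (>= 1 entries).
#' @return Data frame with columns `variant`, `seed`, `mean_acc`.
#' @export
compare_variants <- function(codebook, cfg,
                             variants = c("zpfd", "fd", "raw", "separable"),
                             window_s = 1.0, latency_s = cfg$latency_mean_s,
                             step_s = 0.1, n_bands = 2L, k = 10L,
                             tcfg = train_config(), seeds = 1:5) {
  out <- expand.grid(variant = variants, seed = seeds,
                     stringsAsFactors = FALSE)
  out$mean_acc <- NA_real_
  for (s in seeds) {
    cfg_s <- cfg
    cfg_s$seed <- as.integer(s)
    epochs <- simulate_epochs(codebook, cfg_s)
    for (v in variants) {
      rep <- evaluate_pipeline(epochs, window_s, variant = v,
                               n_bands = n_bands, latency_s = latency_s,
                               step_s = step_s, k = k, tcfg = tcfg, seed = s)
      out$mean_acc[out$variant == v & out$seed == s] <- rep$mean_acc
    }
  }
  out
}

#' Accuracy as a function of the number of harmonic bands
#'
#' Evaluates the zero-padded-feature classifier with different numbers of
#' harmonic sub-bands on the same simulated data, to quantify how much the
#' harmonic rows contribute (a lot when the response carries a strong second
#' harmonic, next to nothing when it does not).
#'
#' @param codebook,cfg,window_s,latency_s,step_s,k,tcfg As in
#'   [compare_variants()].
#' @param n_bands_values Integer vector of band counts to evaluate.
#' @param seeds Study seeds.
#' @return Data frame with columns `n_bands`, `seed`, `mean_acc`.
#' @export
harmonic_band_sweep <- function(codebook, cfg, n_bands_values = 1:2,
                                window_s = 1.0,
                                latency_s = cfg$latency_mean_s,
                                step_s = 0.1, k = 10L,
                                tcfg = train_config(), seeds = 1:3) {
  out <- expand.grid(n_bands = n_bands_values, seed = seeds)
  out$mean_acc <- NA_real_
  for (s in seeds) {
    cfg_s <- cfg
    cfg_s$seed <- as.integer(s)
    epochs <- simulate_epochs(codebook, cfg_s)
    for (nb in n_bands_values) {
      rep <- evaluate_pipeline(epochs, window_s, variant = "zpfd",
                               n_bands = nb, latency_s = latency_s,
                               step_s = step_s, k = k, tcfg = tcfg, seed = s)
      out$mean_acc[out$n_bands == nb & out$seed == s] <- rep$mean_acc
    }
  }
  out
}
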