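# Decoder harness, cross-validation schemes, accuracy and information
# transfer rate.

DECODER_METHODS <- c("cca", "ecca", "trca", "etrca", "mfcca", "emfcca")

#' Classification accuracy
#' @param predictions,labels equal-length vectors of target indices.
#' @return fraction correct in \[0, 1\].
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("invalid argument: predictions and labels must have equal length")
  mean(predictions == labels)
}

#' Information transfer rate (Wolpaw)
#'
#' `B = log2(K) + P*log2(P) + (1-P)*log2((1-P)/(K-1))` bits per selection,
#' scaled to bits/min with a selection time of `tw + gaze_shift` seconds.
#' Accuracy at or below chance is floored to 0 bits; `P = 1` is handled as
#' the limit `B = log2(K)`.
#'
#' @param p accuracy fraction in \[0, 1\].
#' @param k number of targets (>= 2).
#' @param tw analysis window length in seconds.
#' @param gaze_shift gaze-shift time added to every selection (default 0.5 s).
#' @return bits per minute.
#' @export
itr <- function(p, k, tw, gaze_shift = 0.5) {
  if (k < 2) stop("invalid argument: itr needs at least 2 targets")
  if (p < 0 || p > 1) stop("invalid argument: p must be in [0, 1]")
  bits <- if (p <= 1 / k) {
    0
  } else if (p >= 1) {
    log2(k)
  } else {
    log2(k) + p * log2(p) + (1 - p) * log2((1 - p) / (k - 1))
  }
  bits * 60 / (tw + gaze_shift)
}

#' Fit a decoder on prepared training epochs
#'
#' Builds everything a method needs to score test epochs: sinusoidal
#' references, per-sub-band templates, and — depending on the method —
#' TRCA filters or the ensemble filter bank.
#'
#' @param prep_train a [prepare_epochs()] result (training trials).
#' @param method one of `"cca"` (standard CCA, training-free), `"ecca"`
#'   (extended CCA), `"trca"` / `"etrca"` (task-related component analysis,
#'   basic / ensemble), `"mfcca"` / `"emfcca"` (multi-feature CCA, basic /
#'   ensemble).
#' @param n_harmonics harmonics in the sinusoidal references (default 3).
#' @param alpha ensemble feature weights for `"emfcca"` (default uniform);
#'   an [optimize_weights()] object is accepted.
#' @param selected optional feature subset for `"mfcca"` (indices into the
#'   45-feature bank) replacing the frozen six-feature set.
#' @param q_mode TRCA variance normalization, see [trca_train()].
#' @return object of class `ssvep_decoder`.
#' @export
fit_decoder <- function(prep_train, method = DECODER_METHODS,
                        n_harmonics = 3, alpha = rep(1, 6), selected = NULL,
                        q_mode = "concatenated") {
  method <- match.arg(method)
  stopifnot(inherits(prep_train, "prepared_epochs"))
  if (inherits(alpha, "ensemble_weights")) alpha <- alpha$alpha
  layout <- prep_train$layout
  K <- layout$n_targets
  nt <- dim(prep_train$subbands[[1]])[3L]
  refs <- reference_bank(layout, prep_train$fs, nt, n_harmonics)
  model <- list(method = method, layout = layout, refs = refs,
                fb = prep_train$fb, tw = prep_train$tw, alpha = alpha,
                selected = selected, n_harmonics = n_harmonics)
  if (method != "cca") {
    model$templates <- lapply(prep_train$subbands, function(arr) {
      build_templates(arr, prep_train$labels, K)
    })
  }
  if (method %in% c("trca", "etrca")) {
    model$filters <- lapply(prep_train$subbands, function(arr) {
      lapply(seq_len(K), function(k) {
        idx <- which(prep_train$labels == k)
        trca_train(lapply(idx, function(i) trial_matrix(arr, i)),
                   q_mode = q_mode)
      })
    })
    if (method == "etrca") {
      model$W <- lapply(model$filters, function(fl) do.call(cbind, fl))
    }
  }
  if (method == "emfcca") {
    model$W_ens <- lapply(model$templates, function(tpl) {
      ensemble_filter_bank(tpl, refs)
    })
  }
  structure(model, class = "ssvep_decoder")
}

# per-sub-band score vector for one epoch
decoder_scores_one <- function(model, X, s) {
  switch(model$method,
    cca = standard_cca_classify(X, model$refs)$scores,
    ecca = extended_cca_classify(X, model$templates[[s]], model$refs)$scores,
    trca = trca_classify(X, model$templates[[s]], model$filters[[s]])$scores,
    etrca = ensemble_trca_classify(X, model$templates[[s]], model$W[[s]])$scores,
    mfcca = basic_classify(X, model$templates[[s]], model$refs,
                           selected = model$selected)$scores,
    emfcca = {
      tpl <- model$templates[[s]]
      W_ens <- model$W_ens[[s]]
      vapply(seq_along(tpl$templates), function(k) {
        sum(model$alpha * ensemble_features(X, tpl, model$refs, k, W_ens))
      }, numeric(1))
    }
  )
}

#' Predict targets for prepared test epochs
#'
#' Scores every trial against every target, fusing sub-band scores with the
#' filter-bank weights when a filter bank is in use.
#'
#' @param object a fitted [fit_decoder()] model.
#' @param prep_test a [prepare_epochs()] result (same preprocessing as the
#'   training set).
#' @param ... unused.
#' @return list: `predictions` (length n_trials), `scores`
#'   (`n_trials x K`, fused).
#' @export
predict.ssvep_decoder <- function(object, prep_test, ...) {
  stopifnot(inherits(prep_test, "prepared_epochs"))
  w <- prepared_weights(prep_test)
  n <- dim(prep_test$subbands[[1]])[1L]
  K <- object$layout$n_targets
  scores <- matrix(0, n, K)
  for (s in seq_along(prep_test$subbands)) {
    arr <- prep_test$subbands[[s]]
    for (i in seq_len(n)) {
      scores[i, ] <- scores[i, ] +
        w[s] * decoder_scores_one(object, trial_matrix(arr, i), s)
    }
  }
  pred <- vapply(seq_len(n), function(i) as.integer(argmax_tie(scores[i, ])),
                 integer(1))
  list(predictions = pred, scores = scores)
}

#' Leave-one-block-out cross-validation
#'
#' For each recording block: fit the decoder on the remaining blocks
#' (templates, spatial filters) and classify the held-out block's trials.
#' Fold accuracies are averaged with equal weights.
#'
#' @param es an [epoch_set()].
#' @param method decoder name, see [fit_decoder()].
#' @param pp a [preprocess_config()].
#' @param fb optional [filter_bank_config()].
#' @param gaze_shift seconds added per selection for the ITR (default 0.5).
#' @param ... further arguments passed to [fit_decoder()] (`n_harmonics`,
#'   `alpha`, `selected`, `q_mode`).
#' @return object of class `eval_result`: `method`, `tw`, `accuracy`,
#'   `itr`, `fold_accuracy`, `predictions`, `labels`, `blocks`.
#' @export
loo_block_cv <- function(es, method, pp, fb = NULL, gaze_shift = 0.5, ...) {
  stopifnot(inherits(es, "epoch_set"))
  prep <- prepare_epochs(es, pp, fb)
  block_ids <- sort(unique(prep$blocks))
  if (length(block_ids) < 2 && method != "cca")
    stop("invalid argument: training-based methods need >= 2 blocks")
  preds <- integer(length(prep$labels))
  fold_acc <- numeric(length(block_ids))
  for (bi in seq_along(block_ids)) {
    b <- block_ids[bi]
    test_idx <- which(prep$blocks == b)
    train_idx <- which(prep$blocks != b)
    tr <- subset_prepared(prep, train_idx)
    te <- subset_prepared(prep, test_idx)
    model <- fit_decoder(tr, method, ...)
    out <- predict(model, te)
    preds[test_idx] <- out$predictions
    fold_acc[bi] <- accuracy(out$predictions, prep$labels[test_idx])
  }
  acc <- mean(fold_acc)
  structure(
    list(method = method, tw = prep$tw, accuracy = acc,
         itr = itr(acc, es$layout$n_targets, prep$tw, gaze_shift),
         fold_accuracy = fold_acc, predictions = preds,
         labels = prep$labels, blocks = prep$blocks),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s @ Tw=%.2fs: accuracy %.3f, ITR %.1f bits/min (%d folds)\n",
              x$method, x$tw, x$accuracy, x$itr, length(x$fold_accuracy)))
  invisible(x)
}

# restrict a prepared_epochs object to a trial subset
subset_prepared <- function(prep, idx) {
  out <- prep
  out$subbands <- lapply(prep$subbands, function(arr) arr[idx, , , drop = FALSE])
  out$labels <- prep$labels[idx]
  out$blocks <- prep$blocks[idx]
  out
}

#' Partition subjects into cross-validation folds
#'
#' Contiguous-by-index groups of as-equal-as-possible size; optionally a
#' seeded shuffle first. Every subject is held out in exactly one fold.
#'
#' @param n_subjects number of subjects.
#' @param n_folds number of folds (default 7).
#' @param shuffle shuffle subjects before grouping?
#' @param seed seed for the shuffle.
#' @return integer vector: fold assignment per subject.
#' @export
make_subject_folds <- function(n_subjects, n_folds = 7, shuffle = FALSE,
                               seed = 0) {
  if (n_folds < 2 || n_folds > n_subjects)
    stop("invalid argument: need 2 <= n_folds <= n_subjects")
  subjects <- seq_len(n_subjects)
  if (shuffle) {
    subjects <- with_preserved_rng({
      set.seed(seed)
      sample(subjects)
    })
  }
  fold <- integer(n_subjects)
  sizes <- rep(n_subjects %/% n_folds, n_folds)
  extra <- n_subjects %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  fold[subjects] <- rep(seq_len(n_folds), times = sizes)
  fold
}

#' Per-subject feature banks for subject-independent training
#'
#' Computes, for every trial and candidate target, the correlation feature
#' vector the selection / weight-fitting stage consumes. Templates are
#' built leave-one-block-out within the subject (the trial's own block
#' never contributes to its templates). With a filter bank, per-sub-band
#' features are fused with the sub-band weights first, so selection runs on
#' the representation used at test time.
#'
#' @param es an [epoch_set()] (one subject).
#' @param pp a [preprocess_config()].
#' @param fb optional [filter_bank_config()].
#' @param type `"full"` for the 45-feature bank (forward selection) or
#'   `"ensemble"` for the 6 ensemble features (weight fitting).
#' @param n_harmonics harmonics in the references.
#' @return list: `features` (array `n_trials x K x F`), `labels`.
#' @export
banked_features <- function(es, pp, fb = NULL,
                            type = c("full", "ensemble"), n_harmonics = 3) {
  type <- match.arg(type)
  prep <- prepare_epochs(es, pp, fb)
  block_ids <- sort(unique(prep$blocks))
  if (length(block_ids) < 2)
    stop("invalid argument: banked features need >= 2 blocks for leave-one-block-out templates")
  K <- prep$layout$n_targets
  nf <- if (type == "full") 45L else 6L
  n <- length(prep$labels)
  nt <- dim(prep$subbands[[1]])[3L]
  refs <- reference_bank(prep$layout, prep$fs, nt, n_harmonics)
  w <- prepared_weights(prep)
  feats <- array(0, dim = c(n, K, nf))
  for (b in block_ids) {
    test_idx <- which(prep$blocks == b)
    train_idx <- which(prep$blocks != b)
    for (s in seq_along(prep$subbands)) {
      arr <- prep$subbands[[s]]
      tpl <- build_templates(arr[train_idx, , , drop = FALSE],
                             prep$labels[train_idx], K)
      W_ens <- if (type == "ensemble") ensemble_filter_bank(tpl, refs)
      for (i in test_idx) {
        X <- trial_matrix(arr, i)
        for (k in seq_len(K)) {
          f <- if (type == "full") {
            feature_bank(enumerate_cvs(X, tpl$templates[[k]], refs$refs[[k]]))
          } else {
            ensemble_features(X, tpl, refs, k, W_ens)
          }
          feats[i, k, ] <- feats[i, k, ] + w[s] * f
        }
      }
    }
  }
  list(features = feats, labels = prep$labels)
}

#' Subject-level k-fold hyperparameter fitting
#'
#' Splits subjects into folds; for each fold the *training* subjects' banked
#' features drive the hyperparameter fitter (forward selection of the
#' feature set, or GA fitting of the ensemble weights), and the result is
#' intended for the held-out subjects' subject-specific models.
#'
#' @param datasets list of per-subject [epoch_set()]s.
#' @param n_folds number of folds (default 7).
#' @param fitter `"features"` (forward selection over the 36 candidates) or
#'   `"weights"` (GA over the six ensemble-feature weights).
#' @param pp,fb,n_harmonics preprocessing passed to [banked_features()].
#' @param control [ga_control()] for the weight fitter.
#' @param shuffle,seed subject partition options, see
#'   [make_subject_folds()].
#' @return list of class `subject_kfold`: per fold, `held_out` (subject
#'   indices) and `hyperparams` (selected feature indices or an
#'   `ensemble_weights`); plus the fold assignment.
#' @export
subject_kfold_hyperparams <- function(datasets, n_folds = 7,
                                      fitter = c("features", "weights"),
                                      pp, fb = NULL, n_harmonics = 3,
                                      control = ga_control(),
                                      shuffle = FALSE, seed = 0) {
  fitter <- match.arg(fitter)
  fold <- make_subject_folds(length(datasets), n_folds, shuffle, seed)
  type <- if (fitter == "features") "full" else "ensemble"
  banks <- lapply(datasets, banked_features, pp = pp, fb = fb,
                  type = type, n_harmonics = n_harmonics)
  folds <- lapply(seq_len(n_folds), function(f) {
    train_banks <- banks[fold != f]
    hp <- if (fitter == "features") {
      forward_selection(train_banks)
    } else {
      optimize_weights(train_banks, control = control)
    }
    list(held_out = which(fold == f), hyperparams = hp)
  })
  structure(list(folds = folds, assignment = fold, fitter = fitter),
            class = "subject_kfold")
}

#' Compare decoders over a grid of window lengths
#'
#' Runs [loo_block_cv()] for every (method, window) combination, with and/or
#' without the filter bank, and returns a long-format results table.
#'
#' @param es an [epoch_set()].
#' @param methods character vector of decoder names.
#' @param tw_grid window lengths in seconds.
#' @param fb `NULL` (no filter bank), a [filter_bank_config()], or a list of
#'   both (e.g. `list(NULL, filter_bank_config())`) to toggle.
#' @param latency epoch-extraction latency in seconds.
#' @param gaze_shift seconds per selection for the ITR.
#' @param ... passed to [fit_decoder()].
#' @return data.frame: `method`, `tw`, `filter_bank`, `accuracy`, `itr`.
#' @export
compare_methods <- function(es, methods = DECODER_METHODS,
                            tw_grid = seq(0.2, 1, by = 0.1), fb = NULL,
                            latency = 0.14, gaze_shift = 0.5, ...) {
  fb_list <- if (inherits(fb, "filter_bank_config") || is.null(fb)) list(fb) else fb
  rows <- list()
  for (fb_i in seq_along(fb_list)) {
    for (tw in tw_grid) {
      pp <- preprocess_config(tw = tw, latency = latency)
      for (m in methods) {
        r <- loo_block_cv(es, m, pp, fb = fb_list[[fb_i]],
                          gaze_shift = gaze_shift, ...)
        rows[[length(rows) + 1]] <- data.frame(
          method = m, tw = tw,
          filter_bank = !is.null(fb_list[[fb_i]]),
          accuracy = r$accuracy, itr = r$itr)
      }
    }
  }
  do.call(rbind, rows)
}
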