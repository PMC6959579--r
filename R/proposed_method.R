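# The multi-feature CCA decoder: canonical-variable enumeration, the
# 45-feature correlation bank, the 36-candidate admissibility mask,
# subject-independent forward selection, the frozen six-feature basic
# classifier, and the weighted ensemble classifier.

#' Enumerate the ten canonical variables of a (test, template, reference) triple
#'
#' Three data matrices are in play for each candidate target: the test
#' epoch `X`, the trial-averaged template `Xhat`, and the sinusoidal
#' reference `Y`. CCA between each pair yields six spatial filters (one per
#' side of each CCA); projecting `X` and `Xhat` through the four
#' signal-space filters and `Y` through the two reference-side filters
#' gives ten canonical variables:
#'
#' | CV | projection           | CV | projection            |
#' |----|----------------------|----|-----------------------|
#' | 1  | X' W_X(X,Xhat)       | 6  | Xhat' W_X(X,Y)        |
#' | 2  | Xhat' W_X(X,Xhat)    | 7  | X' W_Xhat(Xhat,Y)     |
#' | 3  | X' W_Xhat(X,Xhat)    | 8  | Xhat' W_Xhat(Xhat,Y)  |
#' | 4  | Xhat' W_Xhat(X,Xhat) | 9  | Y' W_Y(X,Y)           |
#' | 5  | X' W_X(X,Y)          | 10 | Y' W_Y(Xhat,Y)        |
#'
#' Only the leading canonical pair of each CCA is used.
#'
#' @param X test epoch `M x Nt`.
#' @param Xhat template `M x Nt`.
#' @param Y reference `2*Nh x Nt`.
#' @return list of class `cv_set`: `cvs` (list of 10 numeric time series)
#'   and `filters` (the 6 weight vectors, named).
#' @export
enumerate_cvs <- function(X, Xhat, Y) {
  degenerate <- sum((Xhat - mean(Xhat))^2) <= 0
  cxt <- cca(X, Xhat)
  cxy <- cca(X, Y)
  cty <- cca(Xhat, Y)
  filters <- list(
    w_x_xt = cxt$wx,  # W_X(X, Xhat)
    w_t_xt = cxt$wy,  # W_Xhat(X, Xhat)
    w_x_xy = cxy$wx,  # W_X(X, Y)
    w_t_ty = cty$wx,  # W_Xhat(Xhat, Y)
    w_y_xy = cxy$wy,  # W_Y(X, Y)
    w_y_ty = cty$wy   # W_Y(Xhat, Y)
  )
  cvs <- list(
    proj(X, filters$w_x_xt),
    proj(Xhat, filters$w_x_xt),
    proj(X, filters$w_t_xt),
    proj(Xhat, filters$w_t_xt),
    proj(X, filters$w_x_xy),
    proj(Xhat, filters$w_x_xy),
    proj(X, filters$w_t_ty),
    proj(Xhat, filters$w_t_ty),
    proj(Y, filters$w_y_xy),
    proj(Y, filters$w_y_ty)
  )
  structure(list(cvs = cvs, filters = filters, degenerate = degenerate),
            class = "cv_set")
}

#' Canonical ordering of the 45 CV pairs
#'
#' @return integer matrix `45 x 2`, rows `(i, j)` with `i < j` in
#'   lexicographic order — the frozen index convention for the feature bank,
#'   so selected-feature indices are portable across analyses.
#' @export
cv_pairs <- function() {
  p <- t(utils::combn(10L, 2L))
  colnames(p) <- c("i", "j")
  p
}

#' The full correlation-feature bank
#'
#' Pearson correlation of every unordered pair of the ten canonical
#' variables: `choose(10, 2) = 45` features, ordered by [cv_pairs()].
#' Zero-variance canonical variables yield 0 for their pairs.
#'
#' @param cvset a [enumerate_cvs()] result (or a plain list of 10 series).
#' @return numeric length-45 vector.
#' @export
feature_bank <- function(cvset) {
  cvs <- if (inherits(cvset, "cv_set")) cvset$cvs else cvset
  stopifnot(length(cvs) == 10)
  p <- cv_pairs()
  vapply(seq_len(nrow(p)), function(r) {
    as.numeric(corr_safe(cvs[[p[r, 1]]], cvs[[p[r, 2]]]))
  }, numeric(1))
}

#' Admissible candidate features
#'
#' Of the 45 pairwise correlations, nine are structurally useless for
#' target identification: the eight pairs correlating a template projection
#' (CV 2, 4, 6, 8) with a reference projection (CV 9, 10) involve no test
#' data at all beyond the filters, and the pair (CV 9, CV 10) correlates
#' two reference projections. The remaining 36 features form the candidate
#' set for forward selection.
#'
#' @return sorted integer vector of 36 indices into the [cv_pairs()] order.
#' @export
candidate_mask <- function() {
  p <- cv_pairs()
  template_cvs <- c(2L, 4L, 6L, 8L)
  reference_cvs <- c(9L, 10L)
  excl <- (p[, 1] %in% template_cvs & p[, 2] %in% reference_cvs) |
    (p[, 1] == 9L & p[, 2] == 10L)
  which(!excl)
}

# index into the 45-vector for a given (i, j) CV pair
pair_index <- function(i, j) {
  p <- cv_pairs()
  which(p[, 1] == min(i, j) & p[, 2] == max(i, j))
}

# the frozen six-feature set as CV pairs: (5,9) (1,4) (1,2) (5,6) (7,8) (7,10)
basic_feature_pairs <- function() {
  rbind(c(5L, 9L), c(1L, 4L), c(1L, 2L), c(5L, 6L), c(7L, 8L), c(7L, 10L))
}

#' The six-feature vector of the basic multi-feature CCA classifier
#'
#' The frozen feature set found by subject-independent forward selection
#' over the 36 candidates (identical across folds in the original
#' derivation, hence shipped as the default):
#' correlations of CV pairs (5,9), (1,4), (1,2), (5,6), (7,8), (7,10).
#' Components 1, 3, 4 and 5 coincide with extended-CCA features; components
#' 2 and 6 are the novel ones.
#'
#' @inheritParams enumerate_cvs
#' @return numeric length-6 feature vector.
#' @export
basic_features <- function(X, Xhat, Y) {
  cvset <- enumerate_cvs(X, Xhat, Y)
  if (cvset$degenerate) return(structure(numeric(6), degenerate = TRUE))
  p <- basic_feature_pairs()
  vapply(seq_len(nrow(p)), function(r) {
    as.numeric(corr_safe(cvset$cvs[[p[r, 1]]], cvset$cvs[[p[r, 2]]]))
  }, numeric(1))
}

#' Basic multi-feature CCA target identification
#'
#' Scores each target by the unweighted sum of its six features (or of an
#' alternative selected feature set) and picks the argmax.
#'
#' @param X test epoch `M x Nt`.
#' @param templates a [build_templates()] bank.
#' @param refs a [reference_bank()].
#' @param selected optional integer indices into the 45-feature bank; when
#'   given, the score is the sum of those features instead of the frozen
#'   six (used to deploy a freshly forward-selected set).
#' @return list: `k`, `scores`, `tie`.
#' @export
basic_classify <- function(X, templates, refs, selected = NULL) {
  scores <- vapply(seq_along(templates$templates), function(k) {
    if (is.null(selected)) {
      sum(basic_features(X, templates$templates[[k]], refs$refs[[k]]))
    } else {
      fb <- feature_bank(enumerate_cvs(X, templates$templates[[k]],
                                       refs$refs[[k]]))
      sum(fb[selected])
    }
  }, numeric(1))
  k <- argmax_tie(scores)
  list(k = as.integer(k), scores = scores, tie = attr(k, "tie"))
}

#' Ensemble filter bank of template-side CCA filters
#'
#' For each target k, the template-side filter of CCA(template_k,
#' reference_k); stacked into `M x K`. This is the only filter family whose
#' ensemble can be applied to both the test epoch and any template — the
#' requirement for an ensemble correlation feature.
#'
#' @param templates a [build_templates()] bank.
#' @param refs a [reference_bank()].
#' @return numeric matrix `M x K`.
#' @export
ensemble_filter_bank <- function(templates, refs) {
  K <- length(templates$templates)
  vapply(seq_len(K), function(k) {
    cca(templates$templates[[k]], refs$refs[[k]])$wx
  }, numeric(nrow(templates$templates[[1]])))
}

#' Ensemble feature vector
#'
#' Identical to [basic_features()] except component 5, which is replaced by
#' the two-dimensional correlation between the test epoch and the k-th
#' template, both projected on the ensemble of template-side filters of all
#' K targets.
#'
#' @inheritParams basic_classify
#' @param k candidate target index.
#' @param W_ens precomputed [ensemble_filter_bank()] (computed on the fly if
#'   `NULL`).
#' @return numeric length-6 feature vector.
#' @export
ensemble_features <- function(X, templates, refs, k, W_ens = NULL) {
  if (length(templates$templates) < length(refs$refs))
    stop("invalid argument: ensemble features need a template for every target")
  W_ens <- W_ens %||% ensemble_filter_bank(templates, refs)
  r <- basic_features(X, templates$templates[[k]], refs$refs[[k]])
  r[5] <- as.numeric(corr2d(crossprod(X, W_ens),
                            crossprod(templates$templates[[k]], W_ens)))
  r
}

#' Ensemble multi-feature CCA target identification
#'
#' Scores each target by the weighted sum `sum(alpha * r_hat_k)` of its six
#' ensemble features and picks the argmax. With `alpha = rep(1, 6)` and a
#' single target class this reduces to the basic classifier's score with
#' the ensemble substitution.
#'
#' @inheritParams basic_classify
#' @param alpha length-6 non-negative weights in \[0, 1\] (default uniform),
#'   or an [optimize_weights()] result.
#' @return list: `k`, `scores`, `tie`.
#' @export
ensemble_classify <- function(X, templates, refs, alpha = rep(1, 6)) {
  if (inherits(alpha, "ensemble_weights")) alpha <- alpha$alpha
  stopifnot(length(alpha) == 6)
  W_ens <- ensemble_filter_bank(templates, refs)
  scores <- vapply(seq_along(templates$templates), function(k) {
    sum(alpha * ensemble_features(X, templates, refs, k, W_ens))
  }, numeric(1))
  k <- argmax_tie(scores)
  list(k = as.integer(k), scores = scores, tie = attr(k, "tie"))
}

# ---- feature-bank scoring utilities (selection / weight fitting) ----------

# scores matrix (trials x K) from a bank array (trials x K x F) and either
# a feature subset (unweighted sum) or a weight vector
bank_scores <- function(bank, sel = NULL, weights = NULL) {
  d <- dim(bank)
  if (!is.null(weights)) {
    flat <- matrix(bank, d[1] * d[2], d[3])
    return(matrix(flat %*% weights, d[1], d[2]))
  }
  if (length(sel) == 1) return(matrix(bank[, , sel], d[1], d[2]))
  apply(bank[, , sel, drop = FALSE], c(1, 2), sum)
}

# mean accuracy across subjects for a feature subset or weight vector
banks_accuracy <- function(banks, sel = NULL, weights = NULL) {
  mean(vapply(banks, function(bk) {
    sc <- bank_scores(bk$features, sel, weights)
    pred <- max.col(sc, ties.method = "first")
    mean(pred == bk$labels)
  }, numeric(1)))
}

#' Greedy forward selection of correlation features
#'
#' Subject-independent wrapper selection: starting from the empty set, each
#' round adds the candidate feature that maximizes the mean classification
#' accuracy across subjects (score = sum of selected features, argmax over
#' targets, lowest index on ties) and stops at the first round with no
#' strict improvement.
#'
#' @param banks a list of per-subject feature banks, each a list with
#'   `features` (array `n_trials x K x 45`, feature values of every trial
#'   against every candidate target) and `labels` (true target per trial).
#'   A single bank may be passed directly.
#' @param mask candidate feature indices (default [candidate_mask()]).
#' @param tol minimum accuracy improvement to continue (default 0: strictly
#'   positive improvement required).
#' @return integer vector of selected feature indices, in selection order,
#'   with attribute `accuracy` (the achieved mean accuracy after each step).
#' @export
forward_selection <- function(banks, mask = candidate_mask(), tol = 0) {
  if (!is.null(banks$features)) banks <- list(banks)
  if (length(mask) == 0) stop("invalid argument: empty candidate set")
  selected <- integer(0)
  acc_trace <- numeric(0)
  best_acc <- -Inf
  remaining <- sort(mask)
  repeat {
    accs <- vapply(remaining, function(f) {
      banks_accuracy(banks, sel = c(selected, f))
    }, numeric(1))
    round_best <- max(accs)
    if (round_best <= best_acc + tol) break
    pick <- remaining[which.max(accs)]   # which.max = lowest index on ties
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    best_acc <- round_best
    acc_trace <- c(acc_trace, round_best)
    if (length(remaining) == 0) break
  }
  structure(selected, accuracy = acc_trace)
}

#' Fit ensemble feature weights by a genetic algorithm
#'
#' Maximizes the mean classification accuracy across subjects over weight
#' vectors `alpha` in \[0, 1\]^6 applied to banked ensemble features. The
#' objective is piecewise constant in `alpha` (accuracy of an argmax rule),
#' so a bounded stochastic search is used rather than a gradient method.
#'
#' @param banks per-subject banks as in [forward_selection()], with
#'   `features` of dimension `n_trials x K x 6` (ensemble features).
#' @param control a [ga_control()]; the seed makes the fit reproducible.
#' @return object of class `ensemble_weights`: `alpha` (length 6),
#'   `objective` (achieved mean accuracy), `control`.
#' @export
optimize_weights <- function(banks, control = ga_control()) {
  if (!is.null(banks$features)) banks <- list(banks)
  for (bk in banks) {
    if (length(unique(bk$labels)) < 2)
      stop("invalid argument: degenerate labels (need >= 2 classes)")
  }
  fit <- ga_maximize(function(a) banks_accuracy(banks, weights = a),
                     n_par = 6, lower = 0, upper = 1, control = control)
  structure(list(alpha = fit$par, objective = fit$value, control = control),
            class = "ensemble_weights")
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat("<ensemble_weights> alpha =",
      paste(sprintf("%.3f", x$alpha), collapse = " "),
      sprintf("(objective %.3f)\n", x$objective))
  invisible(x)
}
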