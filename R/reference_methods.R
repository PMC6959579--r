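# Reference decoders: extended CCA and task-related component analysis
# (TRCA), basic and ensemble.

# projections used throughout: column vector time series t(X) %*% w
proj <- function(X, w) drop(crossprod(X, w))

#' Extended-CCA correlation features
#'
#' The five-feature vector combining the canonical correlation with
#' template-based correlations. Three CCAs are computed — test vs
#' reference, test vs template, template vs reference — and the five
#' correlations between specific projections form the feature vector; the
#' first is the canonical correlation itself (always >= 0), the rest may be
#' negative and carry sign information.
#'
#' @param X test epoch `M x Nt`.
#' @param Xhat template `M x Nt` for the candidate target.
#' @param Y sinusoidal reference `2*Nh x Nt` for the candidate target.
#' @return numeric length-5 feature vector; all zeros (flagged via
#'   attribute `degenerate`) when the template has no variance.
#' @export
extended_cca_features <- function(X, Xhat, Y) {
  if (sum((Xhat - mean(Xhat))^2) <= 0)
    return(structure(numeric(5), degenerate = TRUE))
  cxy <- cca(X, Y)
  cxt <- cca(X, Xhat)
  cty <- cca(Xhat, Y)
  c(
    corr_safe(proj(X, cxy$wx), proj(Y, cxy$wy)),
    corr_safe(proj(X, cxt$wx), proj(Xhat, cxt$wx)),
    corr_safe(proj(X, cxy$wx), proj(Xhat, cxy$wx)),
    corr_safe(proj(X, cty$wx), proj(Xhat, cty$wx)),
    corr_safe(proj(Xhat, cxt$wx), proj(Xhat, cxt$wy))
  )
}

#' Extended-CCA target identification
#'
#' Scores each target by the sum of its five extended-CCA features and
#' picks the argmax (lowest index on ties).
#'
#' @param X test epoch `M x Nt`.
#' @param templates a [build_templates()] bank.
#' @param refs a [reference_bank()].
#' @return list: `k`, `scores`, `tie`.
#' @export
extended_cca_classify <- function(X, templates, refs) {
  scores <- vapply(seq_along(templates$templates), function(k) {
    sum(extended_cca_features(X, templates$templates[[k]], refs$refs[[k]]))
  }, numeric(1))
  k <- argmax_tie(scores)
  list(k = as.integer(k), scores = scores, tie = attr(k, "tie"))
}

#' Train a TRCA spatial filter for one target
#'
#' Task-related component analysis: the filter `w` maximizes the
#' reproducibility of the projected signal across training trials, i.e. the
#' Rayleigh quotient `(w' S w) / (w' Q w)` where `S` sums the inter-trial
#' cross-covariances over all ordered pairs of distinct trials and `Q`
#' normalizes the projected variance. Solved as the leading eigenvector of
#' `solve(Q + ridge) %*% S`; the filter is unit-norm with its
#' largest-magnitude element positive.
#'
#' @param trials list of `H` training trials (`M x Nt` matrices) of one
#'   target, or an `H x M x Nt` array. At least two trials are required —
#'   with a single trial there are no inter-trial covariances to maximize.
#' @param q_mode variance normalization: `"concatenated"` (default) takes
#'   the covariance of the globally centered concatenation of the training
#'   trials; `"pooled"` sums per-trial centered covariances. The two differ
#'   only by between-trial mean cross-terms.
#' @param eps relative ridge.
#' @return unit-norm filter `w` (length M).
#' @export
trca_train <- function(trials, q_mode = c("concatenated", "pooled"),
                       eps = 1e-8) {
  q_mode <- match.arg(q_mode)
  if (is.array(trials) && length(dim(trials)) == 3)
    trials <- lapply(seq_len(dim(trials)[1L]), function(h) trial_matrix(trials, h))
  h <- length(trials)
  if (h < 2)
    stop("insufficient data: TRCA needs at least 2 training trials (blocks) per target")
  centered <- lapply(trials, function(x) x - rowMeans(x))
  z <- Reduce(`+`, centered)
  s_self <- Reduce(`+`, lapply(centered, tcrossprod))
  S <- tcrossprod(z) - s_self   # sum over ordered pairs h1 != h2
  S <- (S + t(S)) / 2
  if (q_mode == "concatenated") {
    cat_all <- do.call(cbind, trials)
    cat_all <- cat_all - rowMeans(cat_all)
    Q <- tcrossprod(cat_all)
  } else {
    Q <- s_self
  }
  Q <- (Q + t(Q)) / 2
  Qr <- Q + diag(ridge_of(Q, eps), nrow(Q))
  e <- eigen(solve(Qr, S))
  w <- Re(e$vectors[, which.max(Re(e$values))])
  w <- w / sqrt(sum(w^2))
  sgn <- sign(w[which.max(abs(w))])
  if (sgn == 0) sgn <- 1
  sgn * w
}

#' TRCA target identification (basic)
#'
#' Scores target k by the Pearson correlation between the test epoch and
#' the target's template, both projected through the target's own TRCA
#' filter.
#'
#' @param X test epoch `M x Nt`.
#' @param templates a [build_templates()] bank.
#' @param filters list (length K) of TRCA filters from [trca_train()].
#' @return list: `k`, `scores`, `tie`.
#' @export
trca_classify <- function(X, templates, filters) {
  scores <- vapply(seq_along(filters), function(k) {
    corr_safe(proj(X, filters[[k]]), proj(templates$templates[[k]], filters[[k]]))
  }, numeric(1))
  k <- argmax_tie(scores)
  list(k = as.integer(k), scores = scores, tie = attr(k, "tie"))
}

#' Ensemble-TRCA target identification
#'
#' Stacks all K target filters into `W = [w_1 ... w_K]` and scores target k
#' by the two-dimensional correlation [corr2d()] between the test epoch and
#' the k-th template, both projected on the full ensemble `W` — exploiting
#' that scalp mixing is nearly target-independent, so every target's filter
#' is informative for every other.
#'
#' @param X test epoch `M x Nt`.
#' @param templates a [build_templates()] bank.
#' @param W filter matrix `M x K` (columns = per-target TRCA filters).
#' @return list: `k`, `scores`, `tie`.
#' @export
ensemble_trca_classify <- function(X, templates, W) {
  XW <- crossprod(X, W)
  scores <- vapply(seq_along(templates$templates), function(k) {
    corr2d(XW, crossprod(templates$templates[[k]], W))
  }, numeric(1))
  k <- argmax_tie(scores)
  list(k = as.integer(k), scores = scores, tie = attr(k, "tie"))
}
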