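# Sinusoidal references, the canonical correlation solver, trial-averaged
# templates, and the standard CCA classifier.

#' Sinusoidal reference matrix for one stimulus frequency
#'
#' Builds the `2*Nh x Nt` reference whose rows alternate
#' `sin(2*pi*h*f*t)`, `cos(2*pi*h*f*t)` for harmonics h = 1..Nh, on the
#' 1-based time grid t = 1/fs, 2/fs, ..., Nt/fs. The sin/cos pair per
#' harmonic spans all stimulus phases, which is what makes the reference
#' usable without phase knowledge.
#'
#' @param f stimulus frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param nt number of samples.
#' @param nh number of harmonics (default 3).
#' @return numeric matrix `2*nh x nt`.
#' @export
build_reference <- function(f, fs, nt, nh = 3) {
  if (nh < 1) stop("invalid argument: nh must be >= 1")
  if (f * nh >= fs / 2)
    stop("invalid argument: harmonic above Nyquist frequency")
  t <- seq_len(nt) / fs
  y <- matrix(0, 2 * nh, nt)
  for (h in seq_len(nh)) {
    y[2 * h - 1, ] <- sin(2 * pi * h * f * t)
    y[2 * h, ] <- cos(2 * pi * h * f * t)
  }
  y
}

#' Reference bank for a whole stimulus layout
#'
#' @param layout a [make_jfpm_layout()].
#' @param fs sampling rate in Hz.
#' @param nt number of samples per epoch.
#' @param nh number of harmonics.
#' @return list of `K` reference matrices (class `reference_bank`).
#' @export
reference_bank <- function(layout, fs, nt, nh = 3) {
  structure(
    list(refs = lapply(layout$freqs, build_reference, fs = fs, nt = nt, nh = nh),
         nh = nh, fs = fs),
    class = "reference_bank"
  )
}

#' Canonical correlation analysis of two multichannel signals
#'
#' Finds weight vectors `wx`, `wy` maximizing the Pearson correlation of
#' the projections `t(X) %*% wx` and `t(Y) %*% wy`. Rows are mean-centered
#' over the window; auto-covariances are whitened through their symmetric
#' inverse square root with a Tikhonov ridge (`eps * trace / dim`), which
#' keeps the solver stable on short windows where covariances are
#' rank-deficient; the leading singular value of the whitened
#' cross-covariance is the canonical correlation.
#'
#' Sign convention: the returned pair always correlates positively, weights
#' are unit-norm, and the pair is jointly flipped so the largest-magnitude
#' element of `wx` is positive — correlations between projections from
#' *different* CCAs are therefore reproducible rather than sign-random.
#'
#' @param X numeric matrix `p x Nt`.
#' @param Y numeric matrix `q x Nt` (same Nt).
#' @param eps relative ridge (default 1e-8).
#' @param all_pairs if `TRUE`, also return all `min(p, q)` canonical pairs.
#' @return list of class `cca_result`: `wx`, `wy`, `rho`, `degenerate`;
#'   with `all_pairs`, matrices `Wx`, `Wy` (columns = pairs) and `rhos`.
#' @export
cca <- function(X, Y, eps = 1e-8, all_pairs = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  nt <- ncol(X)
  if (ncol(Y) != nt || nt < 2)
    stop("invalid argument: X and Y need the same Nt >= 2")
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  degenerate <- sum(Xc * Xc) <= 0 || sum(Yc * Yc) <= 0
  if (degenerate) {
    wx <- c(1, numeric(nrow(X) - 1))
    wy <- c(1, numeric(nrow(Y) - 1))
    return(structure(list(wx = wx, wy = wy, rho = 0, degenerate = TRUE),
                     class = "cca_result"))
  }
  Cx <- tcrossprod(Xc) / nt
  Cy <- tcrossprod(Yc) / nt
  Cxy <- tcrossprod(Xc, Yc) / nt
  Wxh <- inv_sqrt_sym(Cx, eps)
  Wyh <- inv_sqrt_sym(Cy, eps)
  s <- svd(Wxh %*% Cxy %*% Wyh)
  fix_pair <- function(u, v) {
    wx <- drop(Wxh %*% u)
    wy <- drop(Wyh %*% v)
    wx <- wx / sqrt(sum(wx^2))
    wy <- wy / sqrt(sum(wy^2))
    # projections of u, v already correlate positively (singular value >= 0);
    # joint flip pins the overall sign
    sgn <- sign(wx[which.max(abs(wx))])
    if (sgn == 0) sgn <- 1
    list(wx = sgn * wx, wy = sgn * wy)
  }
  lead <- fix_pair(s$u[, 1], s$v[, 1])
  out <- list(wx = lead$wx, wy = lead$wy, rho = min(s$d[1], 1),
              degenerate = FALSE)
  if (all_pairs) {
    npair <- min(nrow(X), nrow(Y))
    pairs <- lapply(seq_len(npair), function(i) fix_pair(s$u[, i], s$v[, i]))
    out$Wx <- vapply(pairs, `[[`, numeric(nrow(X)), "wx")
    out$Wy <- vapply(pairs, `[[`, numeric(nrow(Y)), "wy")
    out$rhos <- pmin(s$d[seq_len(npair)], 1)
  }
  structure(out, class = "cca_result")
}

#' Trial-averaged SSVEP templates
#'
#' Element-wise mean of the training trials of each target — the
#' subject-specific reference `X_hat_k` used by all training-based decoders.
#'
#' @param data numeric array `n_trials x M x Nt` (e.g. one sub-band of a
#'   [prepare_epochs()] result).
#' @param labels target index per trial.
#' @param n_targets number of targets K; every target must have at least one
#'   training trial.
#' @return list of class `template_bank`: `templates` (list of `M x Nt`
#'   matrices) and `n_trials_averaged` (per target).
#' @export
build_templates <- function(data, labels, n_targets) {
  stopifnot(length(dim(data)) == 3, length(labels) == dim(data)[1L])
  counts <- tabulate(labels, n_targets)
  if (any(counts == 0))
    stop(sprintf("invalid argument: no training trial for target(s) %s",
                 paste(which(counts == 0), collapse = ", ")))
  m <- dim(data)[2L]; nt <- dim(data)[3L]
  templates <- lapply(seq_len(n_targets), function(k) {
    idx <- which(labels == k)
    tpl <- matrix(0, m, nt)
    for (i in idx) tpl <- tpl + trial_matrix(data, i)
    tpl / length(idx)
  })
  structure(list(templates = templates, n_trials_averaged = counts),
            class = "template_bank")
}

#' Standard CCA target identification
#'
#' Scores each candidate target by the canonical correlation between the
#' test epoch and that target's sinusoidal reference, and picks the argmax
#' (ties broken toward the lowest index, flagged).
#'
#' @param X test epoch `M x Nt`.
#' @param refs a [reference_bank()] (or plain list of reference matrices).
#' @return list: `k` (predicted target), `scores` (length K), `tie`.
#' @export
standard_cca_classify <- function(X, refs) {
  ylist <- if (inherits(refs, "reference_bank")) refs$refs else refs
  scores <- vapply(ylist, function(Y) cca(X, Y)$rho, numeric(1))
  k <- argmax_tie(scores)
  list(k = as.integer(k), scores = scores, tie = attr(k, "tie"))
}
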