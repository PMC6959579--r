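# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation robust to zero-variance inputs
#'
#' Returns 0 (with a `degenerate` attribute) when either input has zero
#' variance, so downstream feature banks never propagate NaN.
#' @param a,b numeric vectors of equal length.
#' @return correlation in \[-1, 1\].
#' @keywords internal
corr_safe <- function(a, b) {
  a <- a - mean(a)
  b <- b - mean(b)
  va <- sum(a * a)
  vb <- sum(b * b)
  if (va <= 0 || vb <= 0) {
    return(structure(0, degenerate = TRUE))
  }
  sum(a * b) / sqrt(va * vb)
}

#' Two-dimensional (matrix) correlation coefficient
#'
#' Pearson correlation of two equally shaped matrices after removing each
#' matrix's grand mean — the similarity measure used by ensemble decoders
#' to compare multi-filter projections.
#'
#' @param A,B numeric matrices of identical dimension.
#' @return scalar in \[-1, 1\]; 0 if either matrix is constant.
#' @export
corr2d <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  corr_safe(as.numeric(A), as.numeric(B))
}

# argmax with deterministic lowest-index tie-break; attaches tie flag
argmax_tie <- function(scores, tol = 0) {
  best <- max(scores)
  hits <- which(scores >= best - tol)
  structure(hits[1L], tie = length(hits) > 1L)
}

# Tikhonov ridge scaled to the matrix: eps * trace / dim
ridge_of <- function(C, eps = 1e-8) {
  eps * sum(diag(C)) / nrow(C)
}

# symmetric inverse square root with ridge, for whitening covariances
inv_sqrt_sym <- function(C, eps = 1e-8) {
  C <- (C + t(C)) / 2
  r <- ridge_of(C, eps)
  e <- eigen(C + diag(r, nrow(C)), symmetric = TRUE)
  d <- pmax(e$values, r)
  e$vectors %*% (t(e$vectors) / sqrt(d))
}

# run code with the global RNG stream untouched afterwards
with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

# single trial as an M x Nt matrix from an epoch-set data array
trial_matrix <- function(data, i) {
  m <- dim(data)[2L]
  nt <- dim(data)[3L]
  matrix(data[i, , ], m, nt)
}
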