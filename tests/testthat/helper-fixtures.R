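# Shared fixtures: small layouts and datasets built in code at test time.

# widely spaced small layout -> easy discrimination at short windows
small_layout <- function(k = 5) make_jfpm_layout(k, f0 = 8, df = 1)

small_dataset <- function(k = 5, blocks = 3, snr_db = 0, seed = 11,
                          duration = 1.2, channels = 6) {
  simulate_dataset(small_layout(k),
                   sim_config(n_channels = channels, duration = duration,
                              n_blocks = blocks, snr_db = snr_db, seed = seed))
}

# matched noiseless (epoch, template, reference) triple for one target
matched_triple <- function(k = 2, tw = 0.6, nh = 3, seed = 5) {
  lay <- small_layout(4)
  cfg <- sim_config(n_channels = 5, duration = 1, snr_db = Inf, seed = seed)
  tr <- simulate_trial(lay, k, cfg)
  X <- extract_epoch(tr, cfg$fs, tw)
  Y <- build_reference(lay$freqs[k], cfg$fs, ncol(X), nh)
  list(X = X, Xhat = X, Y = Y, layout = lay, cfg = cfg)
}

# toy three-feature bank with exhaustively known greedy path:
# f1 alone 60%, f2 alone 55%, {f1,f2} 80%, f3 never strictly helps.
toy_selection_bank <- function() {
  margins <- rbind(
    matrix(rep(c(3, 3, -1.5), 5), ncol = 3, byrow = TRUE),
    c(1, -3, -1.5),
    matrix(rep(c(3, -1, -1.5), 6), ncol = 3, byrow = TRUE),
    matrix(rep(c(-1, 3, -1.5), 5), ncol = 3, byrow = TRUE),
    c(-3, 1, -1.5),
    matrix(rep(c(-3, -3, -1.5), 2), ncol = 3, byrow = TRUE)
  )
  n <- nrow(margins)
  labels <- rep(c(1L, 2L), length.out = n)
  feats <- array(0, dim = c(n, 2, 3))
  for (t in seq_len(n)) {
    for (f in 1:3) {
      feats[t, labels[t], f] <- margins[t, f] / 2
      feats[t, 3 - labels[t], f] <- -margins[t, f] / 2
    }
  }
  list(features = feats, labels = labels)
}

# accuracy of a feature subset on a toy bank (independent oracle for the
# greedy path: score = sum of selected features, argmax, lowest index ties)
bank_subset_accuracy <- function(bank, sel) {
  d <- dim(bank$features)
  sc <- apply(bank$features[, , sel, drop = FALSE], c(1, 2), sum)
  pred <- max.col(sc, ties.method = "first")
  mean(pred == bank$labels)
}

# independent re-evaluation of the weighted-feature accuracy objective
banks_accuracy_oracle <- function(bank, weights) {
  d <- dim(bank$features)
  sc <- matrix(0, d[1], d[2])
  for (f in seq_len(d[3])) sc <- sc + weights[f] * bank$features[, , f]
  pred <- max.col(sc, ties.method = "first")
  mean(pred == bank$labels)
}
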