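test_that("the canonical-variable enumeration yields 10 CVs from 6 filters", {
  tri <- matched_triple(k = 2)
  cvset <- enumerate_cvs(tri$X, tri$Xhat, tri$Y)
  expect_length(cvset$cvs, 10)
  expect_length(cvset$filters, 6)
  expect_true(all(lengths(cvset$cvs) == ncol(tri$X)))
})

test_that("identical test and template collapse the paired CVs", {
  set.seed(60)
  X <- matrix(rnorm(4 * 100), 4)
  Y <- build_reference(10, 250, 100, 2)
  cvset <- enumerate_cvs(X, X, Y)
  expect_equal(cvset$cvs[[1]], cvset$cvs[[2]])
  expect_equal(cvset$cvs[[3]], cvset$cvs[[4]])
  expect_equal(cvset$cvs[[5]], cvset$cvs[[6]])
})

test_that("reference-side CVs depend on the test data only through the filters", {
  set.seed(61)
  Xhat <- matrix(rnorm(4 * 100), 4)
  Y <- build_reference(10, 250, 100, 2)
  X1 <- matrix(rnorm(4 * 100), 4)
  X2 <- matrix(rnorm(4 * 100), 4)
  c1 <- enumerate_cvs(X1, Xhat, Y)
  c2 <- enumerate_cvs(X2, Xhat, Y)
  # CV10 = Y' W_Y(Xhat, Y): no dependence on X at all
  expect_identical(c1$cvs[[10]], c2$cvs[[10]])
  # CV9 = Y' W_Y(X, Y): changes with X (through the filter only)
  expect_false(isTRUE(all.equal(c1$cvs[[9]], c2$cvs[[9]])))
})

test_that("the feature bank enumerates all 45 ordered CV pairs", {
  p <- cv_pairs()
  expect_equal(dim(p), c(45, 2))
  expect_true(all(p[, 1] < p[, 2]))
  expect_false(any(duplicated(p)))

  tri <- matched_triple(k = 3)
  fbank <- feature_bank(enumerate_cvs(tri$X, tri$Xhat, tri$Y))
  expect_length(fbank, 45)
  expect_true(all(abs(fbank) <= 1 + 1e-12))
})

test_that("the candidate mask removes exactly the 9 uninformative pairs", {
  mask <- candidate_mask()
  expect_length(mask, 36)
  p <- cv_pairs()
  excluded <- setdiff(seq_len(45), mask)
  expect_length(excluded, 9)
  # 8 template x reference pairs ...
  tpl_ref <- excluded[p[excluded, 1] %in% c(2, 4, 6, 8) &
                        p[excluded, 2] %in% c(9, 10)]
  expect_length(tpl_ref, 8)
  # ... plus the (9, 10) reference-reference pair
  expect_true(any(p[excluded, 1] == 9 & p[excluded, 2] == 10))
  expect_length(intersect(mask, excluded), 0)
})

test_that("the six default features are admissible candidates", {
  p <- cv_pairs()
  six <- rbind(c(5, 9), c(1, 4), c(1, 2), c(5, 6), c(7, 8), c(7, 10))
  idx <- apply(six, 1, function(pr) which(p[, 1] == pr[1] & p[, 2] == pr[2]))
  expect_true(all(idx %in% candidate_mask()))
})

test_that("restricting the bank to the extended-CCA pairs reproduces it exactly", {
  set.seed(62)
  lay <- small_layout(3)
  cfg <- sim_config(n_channels = 5, duration = 1, snr_db = 0, seed = 62)
  X <- extract_epoch(simulate_trial(lay, 2, cfg), cfg$fs, 0.6)
  Xh <- extract_epoch(simulate_trial(lay, 2, cfg), cfg$fs, 0.6)
  Y <- build_reference(lay$freqs[2], cfg$fs, ncol(X), 3)

  fbank <- feature_bank(enumerate_cvs(X, Xh, Y))
  p <- cv_pairs()
  ext_pairs <- rbind(c(5, 9), c(1, 2), c(5, 6), c(7, 8), c(2, 4))
  idx <- apply(ext_pairs, 1, function(pr)
    which(p[, 1] == pr[1] & p[, 2] == pr[2]))
  expect_identical(unname(fbank[idx]),
                   as.numeric(extended_cca_features(X, Xh, Y)))
})

test_that("four of the six features equal their extended-CCA counterparts on any input", {
  set.seed(63)
  for (i in 1:5) {
    X <- matrix(rnorm(4 * 120), 4)
    Xh <- matrix(rnorm(4 * 120), 4)
    Y <- build_reference(8 + i, 250, 120, 3)
    b <- basic_features(X, Xh, Y)
    e <- extended_cca_features(X, Xh, Y)
    expect_identical(b[c(1, 3, 4, 5)], e[c(1, 2, 3, 4)])
    # the two novel components genuinely differ from their neighbours
    expect_false(isTRUE(all.equal(b[2], b[3])))
  }
})

test_that("all six features approach 1 on a matched noiseless trial", {
  tri <- matched_triple(k = 2)
  b <- basic_features(tri$X, tri$Xhat, tri$Y)
  expect_length(b, 6)
  expect_true(all(abs(b - 1) < 1e-6))
})

test_that("basic classification recovers noiseless targets and supports K=1", {
  es <- small_dataset(k = 4, blocks = 3, snr_db = Inf, duration = 0.8)
  expect_equal(loo_block_cv(es, "mfcca", preprocess_config(tw = 0.5))$accuracy, 1)

  tri <- matched_triple(k = 1)
  tpl <- structure(list(templates = list(tri$Xhat), n_trials_averaged = 1L),
                   class = "template_bank")
  refs <- structure(list(refs = list(tri$Y)), class = "reference_bank")
  expect_equal(basic_classify(tri$X, tpl, refs)$k, 1L)
})

test_that("ensemble features replace only component 5", {
  es <- small_dataset(k = 3, blocks = 2, snr_db = 0, duration = 1)
  prep <- prepare_epochs(es, preprocess_config(tw = 0.5))
  arr <- prep$subbands[[1]]
  tpl <- build_templates(arr[prep$blocks == 1, , , drop = FALSE],
                         prep$labels[prep$blocks == 1], 3)
  refs <- reference_bank(es$layout, es$fs, dim(arr)[3], 3)
  X <- trial_matrix(arr, which(prep$blocks == 2)[1])
  W_ens <- ensemble_filter_bank(tpl, refs)
  expect_equal(dim(W_ens), c(6, 3))
  for (k in 1:3) {
    b <- basic_features(X, tpl$templates[[k]], refs$refs[[k]])
    e <- ensemble_features(X, tpl, refs, k, W_ens)
    expect_identical(e[-5], b[-5])
    expect_false(isTRUE(all.equal(e[5], b[5])))
  }
})

test_that("K=1 ensemble features reduce to the basic features", {
  tri <- matched_triple(k = 1)
  tpl <- structure(list(templates = list(tri$Xhat), n_trials_averaged = 1L),
                   class = "template_bank")
  refs <- structure(list(refs = list(tri$Y)), class = "reference_bank")
  e <- ensemble_features(tri$X, tpl, refs, 1)
  # X == Xhat: the ensemble 2-D correlation is exactly 1
  expect_equal(as.numeric(e[5]), 1, tolerance = 1e-9)
  # and the uniform-weight ensemble score equals the basic score
  s_ens <- ensemble_classify(tri$X, tpl, refs)$scores
  s_bas <- basic_classify(tri$X, tpl, refs)$scores
  expect_equal(s_ens, s_bas, tolerance = 1e-9)
})

test_that("classifier scores are equivariant under target permutation", {
  es <- small_dataset(k = 4, blocks = 2, snr_db = 0, duration = 1)
  prep <- prepare_epochs(es, preprocess_config(tw = 0.5))
  arr <- prep$subbands[[1]]
  train <- which(prep$blocks == 1)
  tpl <- build_templates(arr[train, , , drop = FALSE], prep$labels[train], 4)
  refs <- reference_bank(es$layout, es$fs, dim(arr)[3], 3)
  X <- trial_matrix(arr, which(prep$blocks == 2)[2])

  perm <- c(3, 1, 4, 2)
  tpl_p <- structure(list(templates = tpl$templates[perm],
                          n_trials_averaged = tpl$n_trials_averaged[perm]),
                     class = "template_bank")
  refs_p <- structure(list(refs = refs$refs[perm]), class = "reference_bank")

  s <- basic_classify(X, tpl, refs)$scores
  sp <- basic_classify(X, tpl_p, refs_p)$scores
  expect_equal(sp, s[perm], tolerance = 1e-9)

  se <- ensemble_classify(X, tpl, refs)$scores
  sep <- ensemble_classify(X, tpl_p, refs_p)$scores
  expect_equal(sep, se[perm], tolerance = 1e-9)
})

test_that("forward selection follows the exhaustively verified greedy path", {
  bank <- toy_selection_bank()
  # oracle accuracies engineered into the bank
  expect_equal(bank_subset_accuracy(bank, 1), 0.60)
  expect_equal(bank_subset_accuracy(bank, 2), 0.55)
  expect_equal(bank_subset_accuracy(bank, c(1, 2)), 0.80)
  expect_equal(bank_subset_accuracy(bank, c(1, 2, 3)), 0.80)  # no gain
  expect_lt(bank_subset_accuracy(bank, c(1, 3)), 0.80)

  sel <- forward_selection(bank, mask = 1:3)
  expect_equal(as.integer(sel), c(1L, 2L))
  expect_equal(attr(sel, "accuracy"), c(0.60, 0.80))
})

test_that("forward selection saturates on a perfectly discriminative feature", {
  set.seed(64)
  n <- 30
  feats <- array(rnorm(n * 2 * 4, sd = 0.1), dim = c(n, 2, 4))
  labels <- rep(1:2, length.out = n)
  for (t in seq_len(n)) {
    feats[t, labels[t], 2] <- 1     # feature 2 is Bayes-separable
    feats[t, 3 - labels[t], 2] <- -1
  }
  sel <- forward_selection(list(features = feats, labels = labels), mask = 1:4)
  expect_equal(as.integer(sel)[1], 2L)
  expect_equal(attr(sel, "accuracy")[1], 1)
  expect_length(sel, 1)  # nothing can strictly improve 100%
})

test_that("forward selection rejects an empty candidate set", {
  bank <- toy_selection_bank()
  expect_error(forward_selection(bank, mask = integer(0)), "empty candidate")
})

test_that("GA weight fitting is seeded-deterministic and finds the informative feature", {
  set.seed(65)
  n <- 40
  feats <- array(rnorm(n * 3 * 6, sd = 0.5), dim = c(n, 3, 6))
  labels <- rep(1:3, length.out = n)
  for (t in seq_len(n)) feats[t, labels[t], 5] <- feats[t, labels[t], 5] + 2
  bank <- list(features = feats, labels = labels)

  ctrl <- ga_control(pop_size = 30, generations = 30, seed = 9)
  w1 <- optimize_weights(bank, control = ctrl)
  w2 <- optimize_weights(bank, control = ctrl)
  expect_identical(w1$alpha, w2$alpha)
  expect_true(all(w1$alpha >= 0 & w1$alpha <= 1))
  expect_equal(which.max(w1$alpha), 5L)
  expect_gte(w1$objective, banks_accuracy_oracle(bank, rep(1, 6)))
})

test_that("GA weight fitting tolerates a flat landscape and rejects degenerate labels", {
  feats <- array(0, dim = c(10, 2, 6))
  labels <- rep(1:2, 5)
  ctrl <- ga_control(pop_size = 10, generations = 3, seed = 1)
  w <- optimize_weights(list(features = feats, labels = labels), control = ctrl)
  # all-zero features: every trial ties to target 1 -> accuracy = 1/2 = chance
  expect_equal(w$objective, 0.5)

  expect_error(optimize_weights(list(features = feats, labels = rep(1L, 10)),
                                control = ctrl),
               "degenerate labels")
})
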