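test_that("accuracy is the fraction of matching predictions", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(accuracy(c(1, 1), c(2, 2)), 0)
  expect_equal(accuracy(c(1, 2, 3, 4), c(1, 2, 3, 1)), 0.75)
  expect_error(accuracy(1:3, 1:4), "equal length")
})

test_that("ITR matches its closed forms and boundary handling", {
  expect_equal(itr(1, 40, 0.7, 0.5), 60 * log2(40) / 1.2)  # ~266.2 bits/min
  expect_equal(itr(1 / 40, 40, 0.5), 0)     # chance floor
  expect_equal(itr(0.5, 2, 1), 0)           # binary chance
  expect_equal(itr(0, 10, 0.5), 0)
  expect_error(itr(0.9, 1, 0.5), "at least 2 targets")
  expect_error(itr(1.2, 10, 0.5), "invalid")

  # monotone non-decreasing in accuracy
  p_grid <- seq(0, 1, by = 0.05)
  bits <- sapply(p_grid, itr, k = 8, tw = 0.5)
  expect_true(all(diff(bits) >= 0))
})

test_that("leave-one-block-out holds each block out exactly once", {
  es <- small_dataset(k = 3, blocks = 3, snr_db = 0, duration = 1)
  r <- loo_block_cv(es, "cca", preprocess_config(tw = 0.5))
  expect_length(r$fold_accuracy, 3)
  expect_equal(r$accuracy, mean(r$fold_accuracy))
  expect_length(r$predictions, length(es$labels))

  es2 <- small_dataset(k = 3, blocks = 2, snr_db = 0, duration = 1)
  r2 <- loo_block_cv(es2, "ecca", preprocess_config(tw = 0.5))
  expect_length(r2$fold_accuracy, 2)
})

test_that("block relabeling does not change leave-one-block-out results", {
  es <- small_dataset(k = 3, blocks = 3, snr_db = -3, duration = 1)
  es_relab <- es
  es_relab$blocks <- c(3L, 1L, 2L)[es$blocks]  # permute block identities
  pp <- preprocess_config(tw = 0.6)
  r1 <- loo_block_cv(es, "ecca", pp)
  r2 <- loo_block_cv(es_relab, "ecca", pp)
  expect_equal(r2$accuracy, r1$accuracy)
  expect_equal(sort(r2$fold_accuracy), sort(r1$fold_accuracy))
})

test_that("all decoders are perfect on noiseless data at 0.5 s windows", {
  es <- small_dataset(k = 5, blocks = 3, snr_db = Inf, duration = 0.8)
  pp <- preprocess_config(tw = 0.5)
  for (m in c("cca", "ecca", "trca", "etrca", "mfcca", "emfcca")) {
    expect_equal(loo_block_cv(es, m, pp)$accuracy, 1, label = m)
  }
})

test_that("the ensemble decoder does not materially hurt the basic decoder", {
  es <- small_dataset(k = 6, blocks = 3, snr_db = -12, seed = 77, duration = 1)
  pp <- preprocess_config(tw = 0.5)
  acc_b <- loo_block_cv(es, "mfcca", pp)$accuracy
  acc_e <- loo_block_cv(es, "emfcca", pp)$accuracy
  expect_gte(acc_e, acc_b - 0.02)
})

test_that("subject folds partition subjects as equally as possible", {
  f35 <- make_subject_folds(35, 7)
  expect_equal(unname(table(f35)), rep(5L, 7), ignore_attr = TRUE)
  expect_length(f35, 35)

  f2 <- make_subject_folds(2, 2)  # leave-one-subject-out
  expect_equal(sort(unique(f2)), 1:2)

  fs <- make_subject_folds(10, 3, shuffle = TRUE, seed = 4)
  expect_equal(unname(sort(table(fs))), c(3L, 3L, 4L), ignore_attr = TRUE)
  expect_identical(fs, make_subject_folds(10, 3, shuffle = TRUE, seed = 4))
  expect_error(make_subject_folds(5, 6), "invalid")
})

test_that("identical subjects produce identical per-fold hyperparameters", {
  es <- small_dataset(k = 3, blocks = 2, snr_db = 0, duration = 1)
  datasets <- list(es, es, es)
  pp <- preprocess_config(tw = 0.5)
  hk <- subject_kfold_hyperparams(datasets, n_folds = 3, fitter = "features",
                                  pp = pp)
  sel <- lapply(hk$folds, function(f) as.integer(f$hyperparams))
  expect_equal(sel[[1]], sel[[2]])
  expect_equal(sel[[2]], sel[[3]])
  expect_true(all(sel[[1]] %in% candidate_mask()))
  held <- sort(unlist(lapply(hk$folds, `[[`, "held_out")))
  expect_equal(held, 1:3)
})

test_that("banked features have the documented shape and need >= 2 blocks", {
  es <- small_dataset(k = 3, blocks = 2, snr_db = 0, duration = 1)
  bk <- banked_features(es, preprocess_config(tw = 0.5), type = "full")
  expect_equal(dim(bk$features), c(6, 3, 45))
  bke <- banked_features(es, preprocess_config(tw = 0.5), type = "ensemble")
  expect_equal(dim(bke$features), c(6, 3, 6))

  es1 <- small_dataset(k = 3, blocks = 1, snr_db = 0, duration = 1)
  expect_error(banked_features(es1, preprocess_config(tw = 0.5)), ">= 2 blocks")
})

test_that("compare_methods produces the full long-format grid", {
  es <- small_dataset(k = 3, blocks = 2, snr_db = 0, duration = 1)
  tab <- compare_methods(es, methods = c("cca", "ecca"),
                         tw_grid = c(0.4, 0.6))
  expect_equal(nrow(tab), 4)
  expect_equal(sort(unique(tab$method)), c("cca", "ecca"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_true(all(tab$itr >= 0))

  # filter-bank toggle doubles the conditions
  tab2 <- compare_methods(es, methods = "cca", tw_grid = 0.5,
                          fb = list(NULL, filter_bank_config(2)))
  expect_equal(nrow(tab2), 2)
  expect_equal(sort(tab2$filter_bank), c(FALSE, TRUE))

  # the window grid of a standard comparison: 0.2 .. 1.0 s in 0.1 s steps
  expect_length(seq(0.2, 1, by = 0.1), 9)
})

test_that("fitted decoders round-trip through the model container", {
  es <- small_dataset(k = 3, blocks = 2, snr_db = 0, duration = 1)
  prep <- prepare_epochs(es, preprocess_config(tw = 0.5))
  model <- fit_decoder(prep, "mfcca")
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  save_decoder(model, path)
  back <- load_decoder(path)
  out1 <- predict(model, prep)
  out2 <- predict(back, prep)
  expect_identical(out1$predictions, out2$predictions)
})

test_that("the command-line interface simulates and evaluates end to end", {
  data_path <- tempfile(fileext = ".rds")
  out_path <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(data_path, out_path)))
  ssvep_decode_cli(c("simulate", "--targets", "3", "--blocks", "2",
                     "--duration", "1", "--snr", "0", "--seed", "3",
                     "-o", data_path))
  es <- read_epochs(data_path)
  expect_equal(dim(es$data)[1], 6)
  ssvep_decode_cli(c("evaluate", "--data", data_path, "--method", "cca",
                     "--tw", "0.5", "-o", out_path))
  lines <- readLines(out_path)
  expect_match(lines[1], "accuracy")
  expect_error(ssvep_decode_cli(c("bogus")), "unknown command")
})
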