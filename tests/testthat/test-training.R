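test_that("the optimiser learns a separable two-class problem", {
  ws <- easy_windows(n_per_class = 40, L = 300, animals = c("a", "b"))
  tr <- ws[ws$animal_id == "a"]
  va <- ws[ws$animal_id == "b"]
  spec <- architecture_spec(
    data.frame(out_channels = c(8, 16), kernel = c(8, 1), stride = c(2, 1)),
    dropout_p = 0.1)
  model <- build_model(spec, seed = 1)
  cfg <- train_config(max_epochs = 40, early_stop_patience = 39,
                      batch_size = 10, seed = 1)
  fit <- train_cnn(model, tr, va, cfg)
  # loss goes down early and the problem ends essentially solved
  expect_lt(mean(tail(fit$history$train_loss, 3)),
            fit$history$train_loss[1])
  pred <- predict(fit$model, va)
  expect_gt(mean(pred == va$labels), 0.95)
})

test_that("training is deterministic given the seed", {
  ws <- easy_windows(n_per_class = 10, L = 100)
  tr <- ws[ws$animal_id == "a"]
  va <- ws[ws$animal_id == "b"]
  spec <- tiny_spec(dropout_p = 0.2)
  cfg <- train_config(max_epochs = 3, early_stop_patience = 2,
                      batch_size = 10, seed = 9)
  f1 <- train_cnn(build_model(spec, 5), tr, va, cfg)
  f2 <- train_cnn(build_model(spec, 5), tr, va, cfg)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$history, f2$history)
})

test_that("early stopping fires after exactly patience non-improving epochs", {
  ws <- easy_windows(n_per_class = 10, L = 100)
  tr <- ws[ws$animal_id == "a"]
  va <- ws[ws$animal_id == "b"]
  # frozen optimisation: zero learning rate keeps validation loss constant,
  # so epoch 1 sets the baseline and the run stops patience epochs later
  cfg <- train_config(learning_rate = 0, max_epochs = 50,
                      early_stop_patience = 4, batch_size = 10, seed = 2,
                      lr_policy = "constant")
  fit <- train_cnn(build_model(tiny_spec(), 3), tr, va, cfg)
  expect_equal(nrow(fit$history), 5)  # patience + 1
  expect_equal(fit$best_epoch, 1)
})

test_that("leakage and empty-set guards reject invalid splits", {
  ws <- easy_windows(n_per_class = 6, L = 60)
  expect_error(train_cnn(build_model(tiny_spec(), 1), ws, ws,
                         train_config(max_epochs = 2,
                                      early_stop_patience = 1)),
               "leakage")
  tr <- ws[ws$animal_id == "a"]
  expect_error(train_cnn(build_model(tiny_spec(), 1), tr, tr[0],
                         train_config(max_epochs = 2,
                                      early_stop_patience = 1)),
               "empty")
})

test_that("cross-validation visits every animal exactly once as validation", {
  herd <- small_herd()
  ws <- balance_windows(small_windows(), seed = 2)
  plan <- make_folds(unique(ws$animal_id), 3, seed = 2)
  spec <- tiny_spec(dropout_p = 0.1)
  cfg <- train_config(max_epochs = 2, early_stop_patience = 1,
                      batch_size = 64, seed = 4)
  cv <- cross_validate(ws, plan, spec, cfg)
  expect_length(cv$fold_reports, 3)
  expect_setequal(unlist(plan$folds), unique(ws$animal_id))
  expect_equal(nrow(cv$summary), 3)
  expect_true(all(c("precision", "recall", "f1") %in% cv$summary$metric))
  expect_true(all(cv$summary$mean >= 0 & cv$summary$mean <= 1))

  bad_plan <- plan
  bad_plan$folds[[1]] <- c(bad_plan$folds[[1]], "phantom_animal")
  expect_error(cross_validate(ws, bad_plan, spec, cfg), "unknown animal")
})

test_that("metrics are invariant to animal-id relabelling", {
  ws <- easy_windows(n_per_class = 16, L = 100, animals = c("a", "b"))
  relabelled <- ws
  relabelled$animal_id <- chartr("ab", "xy", ws$animal_id)
  spec <- tiny_spec(dropout_p = 0)
  cfg <- train_config(max_epochs = 2, early_stop_patience = 1,
                      batch_size = 16, seed = 7)
  plan_a <- make_folds(c("a", "b"), 2, seed = 1)
  plan_x <- make_folds(c("x", "y"), 2, seed = 1)
  cv_a <- cross_validate(ws, plan_a, spec, cfg, balance = FALSE)
  cv_x <- cross_validate(relabelled, plan_x, spec, cfg, balance = FALSE)
  expect_equal(cv_a$summary$mean, cv_x$summary$mean, tolerance = 1e-10)
})

test_that("the search grid is enumerated fully and the best spec returned", {
  ws <- easy_windows(n_per_class = 12, L = 100)
  plan <- make_folds(c("a", "b"), 2, seed = 1)
  cfg <- train_config(max_epochs = 2, early_stop_patience = 1,
                      batch_size = 12, seed = 3)
  # single-point space returns that spec
  one <- hyperparameter_search(
    list(n_blocks = 2, kernel_sizes = 8, dropout_ps = 0.1, repeats = 1),
    ws, plan, cfg, filters = 6, expansion = 12, balance = FALSE)
  expect_equal(nrow(one$best_row), 1)
  expect_equal(one$best_spec$conv_blocks$kernel[1], 8)
  expect_equal(nrow(one$score_table), 1 * 1 * 2)  # grid x repeats x folds

  # two-point space: bookkeeping has |grid| * repeats * folds rows
  two <- hyperparameter_search(
    list(n_blocks = 2, kernel_sizes = c(4, 8), dropout_ps = 0.1,
         repeats = 2),
    ws, plan, cfg, filters = 6, expansion = 12, balance = FALSE)
  expect_equal(nrow(two$score_table), 2 * 2 * 2)
  expect_true(two$best_row$f1 >= mean(two$score_table$f1) - 1e-12)
})

test_that("an uninformative architecture loses the search", {
  # informative spec vs a kernel-1, single-block strawman on data whose
  # classes differ only in oscillation frequency: per-sample marginals are
  # identical, so kernel-1 layers (which never see the waveform) cannot
  # separate them while a kernel-8 block can
  ws <- freq_windows(n_per_class = 24, L = 120)
  plan <- make_folds(c("a", "b"), 2, seed = 1)
  cfg <- train_config(max_epochs = 20, early_stop_patience = 19,
                      batch_size = 12, seed = 5)
  out <- hyperparameter_search(
    list(n_blocks = c(1, 2), kernel_sizes = c(1, 8), dropout_ps = 0,
         repeats = 1),
    ws, plan, cfg, filters = 6, expansion = 12, balance = FALSE)
  # only the (2 blocks, kernel 8) candidate can see the waveform
  expect_equal(out$best_row$n_blocks, 2)
  expect_equal(out$best_row$kernel, 8)
})

test_that("window-length models evaluate across lengths via adaptive pooling", {
  herd <- generate_herd(synth_config(n_animals = 4, hours_per_animal = 2,
                                     seed = 12))
  plan <- make_folds(vapply(herd, `[[`, "", "animal_id"), 2, seed = 1)
  spec <- architecture_spec(
    data.frame(out_channels = c(6, 12), kernel = c(8, 1), stride = c(4, 1)),
    dropout_p = 0.1)
  cfg <- train_config(max_epochs = 2, early_stop_patience = 1,
                      batch_size = 64, seed = 6)
  study <- window_length_study(herd, plan, spec, cfg,
                               lengths = c(60, 90), resamples = 50,
                               balance = FALSE)
  expect_equal(dim(study$f1), c(2, 2))
  expect_false(anyNA(study$f1))
  expect_true(all(study$ci_low <= study$f1 + 1e-12))
  expect_true(all(study$ci_high >= study$f1 - 1e-12))
})
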