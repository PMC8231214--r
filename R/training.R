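#' Training configuration
#'
#' The default values are the package's standard training policy: AdamW at
#' base learning rate 1e-4 with decoupled weight decay 0.01, batch size
#' 256, a one-cycle learning-rate schedule with cosine annealing, at most
#' 50 epochs with early stopping when the validation loss fails to improve
#' by `early_stop_min_delta` for `early_stop_patience` consecutive epochs.
#' The model state returned is the one with the best validation loss.
#'
#' @param learning_rate base learning rate
#' @param batch_size minibatch size
#' @param max_epochs maximum training epochs
#' @param early_stop_patience epochs without improvement before stopping
#' @param early_stop_min_delta minimum validation-loss improvement
#' @param weight_decay decoupled weight-decay coefficient (lambda)
#' @param lr_policy `"one_cycle"` or `"constant"`
#' @param peak_mult one-cycle peak as multiple of the base rate
#' @param warmup_frac one-cycle warm-up fraction
#' @param seed seed for shuffling, dropout and initialisation sub-seeds
#' @return a `train_config`
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 256,
                         max_epochs = 50, early_stop_patience = 15,
                         early_stop_min_delta = 0.01, weight_decay = 0.01,
                         lr_policy = c("one_cycle", "constant"),
                         peak_mult = 10, warmup_frac = 0.3, seed = 1) {
  lr_policy <- match.arg(lr_policy)
  stopifnot(learning_rate >= 0, batch_size >= 1, max_epochs >= 1,
            early_stop_patience >= 1, weight_decay >= 0,
            early_stop_patience < max_epochs || max_epochs == 1)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         early_stop_min_delta = early_stop_min_delta,
         weight_decay = weight_decay, lr_policy = lr_policy,
         peak_mult = peak_mult, warmup_frac = warmup_frac,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

check_no_leakage <- function(train_ws, val_ws) {
  overlap <- intersect(unique(train_ws$animal_id), unique(val_ws$animal_id))
  if (length(overlap) > 0) {
    stop("animal leakage between training and validation sets: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# one optimisation epoch; lr_for_step maps the global step counter to a rate
run_epoch <- function(model, ws, opt_state, config, lr_for_step) {
  n <- length(ws)
  y <- as.integer(ws$labels)
  perm <- sample.int(n)
  total_loss <- 0
  n_batches <- 0L
  last_lr <- NA_real_
  for (start in seq(1, n, by = config$batch_size)) {
    idx <- perm[start:min(n, start + config$batch_size - 1)]
    fw <- forward_cnn(model, ws$data[, , idx, drop = FALSE], train = TRUE,
                      cache = TRUE)
    model <- fw$model   # running batch-norm statistics
    gr <- backward_cnn(model, fw, y[idx])
    last_lr <- lr_for_step(opt_state$t + 1L)
    st <- adamw_step(model, gr, opt_state, last_lr, config$weight_decay)
    model <- st$model
    opt_state <- st$state
    total_loss <- total_loss + gr$loss
    n_batches <- n_batches + 1L
  }
  list(model = model, opt_state = opt_state,
       train_loss = total_loss / n_batches, lr = last_lr)
}

#' Train the classifier
#'
#' Optimises softmax cross-entropy with AdamW under the configured
#' learning-rate policy, monitors validation loss for early stopping, and
#' returns the weights of the best-validation-loss epoch. Training and
#' validation window sets must come from disjoint animals.
#'
#' @param model a `cnn_model` (see [build_model()])
#' @param train_windows training `window_set`
#' @param val_windows validation `window_set` (disjoint animals)
#' @param config a [train_config()]
#' @return list with `model` (best state), `history` (per-epoch data.frame
#'   of train loss, validation loss and learning rate) and `best_epoch`
#' @export
train_cnn <- function(model, train_windows, val_windows, config = train_config()) {
  stopifnot(inherits(model, "cnn_model"),
            inherits(train_windows, "window_set"),
            inherits(val_windows, "window_set"))
  if (length(train_windows) == 0 || length(val_windows) == 0) {
    stop("empty training or validation set", call. = FALSE)
  }
  check_no_leakage(train_windows, val_windows)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  steps_per_epoch <- ceiling(length(train_windows) / config$batch_size)
  total_steps <- steps_per_epoch * config$max_epochs
  lr_for_step <- switch(config$lr_policy,
    one_cycle = function(s) one_cycle_lr(min(s, total_steps), total_steps,
                                         config$learning_rate,
                                         config$peak_mult,
                                         config$warmup_frac),
    constant = function(s) config$learning_rate
  )
  opt_state <- adamw_init(model)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  best_loss <- Inf
  best_model <- model
  best_epoch <- 0L
  stale <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ep <- run_epoch(model, train_windows, opt_state, config, lr_for_step)
    model <- ep$model
    opt_state <- ep$opt_state
    vl <- eval_loss(model, val_windows, config$batch_size)$loss
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep$train_loss,
                                val_loss = vl, lr = ep$lr))
    if (vl < best_loss - config$early_stop_min_delta) {
      best_loss <- vl
      best_model <- model
      best_epoch <- epoch
      stale <- 0L
    } else {
      if (vl < best_loss) {  # improvement below min_delta: keep best state
        best_loss <- vl
        best_model <- model
        best_epoch <- epoch
      }
      stale <- stale + 1L
      if (stale >= config$early_stop_patience) break
    }
  }
  list(model = best_model, history = history, best_epoch = best_epoch)
}

#' Animal-grouped k-fold cross-validation
#'
#' For each fold of the plan, trains on the windows of all out-of-fold
#' animals (optionally re-balanced) and evaluates on the fold's animals.
#' No animal ever contributes windows to both sides of a split.
#'
#' @param windows pooled `window_set` covering all plan animals
#' @param plan a `fold_plan` from [make_folds()]
#' @param spec an [architecture_spec()]
#' @param config a [train_config()]
#' @param balance re-balance the training windows of each fold
#' @return list with `fold_reports` (per-fold `metrics_report`), `summary`
#'   (mean and sd of macro precision/recall/F1) and `models`
#' @export
cross_validate <- function(windows, plan, spec = default_architecture(),
                           config = train_config(), balance = TRUE) {
  stopifnot(inherits(windows, "window_set"), inherits(plan, "fold_plan"))
  animals <- unique(windows$animal_id)
  unknown <- setdiff(unlist(plan$folds), animals)
  if (length(unknown) > 0) {
    stop("fold plan references unknown animal(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  fold_reports <- vector("list", plan$k)
  models <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    val_animals <- plan$folds[[f]]
    tr_ws <- windows[!(windows$animal_id %in% val_animals)]
    va_ws <- windows[windows$animal_id %in% val_animals]
    if (length(tr_ws) == 0) {
      stop("fold ", f, " leaves no training animals", call. = FALSE)
    }
    if (balance) tr_ws <- balance_windows(tr_ws, seed = config$seed + f)
    model <- build_model(spec, seed = config$seed + 100 * f)
    fit <- train_cnn(model, tr_ws, va_ws, config)
    pred <- predict(fit$model, va_ws, config$batch_size)
    fold_reports[[f]] <- metrics_report(va_ws$labels, pred)
    models[[f]] <- fit$model
  }
  macro <- t(vapply(fold_reports, function(r) unlist(r$macro),
                    numeric(3)))
  list(
    fold_reports = fold_reports,
    summary = data.frame(
      metric = colnames(macro),
      mean = colMeans(macro),
      sd = apply(macro, 2, stats::sd),
      row.names = NULL
    ),
    models = models
  )
}

#' Grid search over architecture hyper-parameters
#'
#' Full grid over block counts, kernel sizes and dropout probabilities,
#' each evaluated by animal-grouped cross-validation and repeated
#' `repeats` times with derived sub-seeds; the configuration with the
#' highest mean macro F1 wins. For block counts below the default, the
#' kernel-1 expansion block is always retained as the last block (it fixes
#' the head width) and only the number of feature blocks varies.
#'
#' @param space list with elements `n_blocks`, `kernel_sizes`,
#'   `dropout_ps` (candidate vectors) and `repeats`
#' @param windows pooled `window_set`
#' @param plan a `fold_plan`
#' @param config a [train_config()]
#' @param filters filters per feature block during the search
#' @param expansion expansion width during the search
#' @param balance re-balance each fold's training windows (passed to
#'   [cross_validate()])
#' @return list with `best_spec`, `best_row` and the full `score_table`
#'   (one row per grid point, repeat and fold)
#' @export
hyperparameter_search <- function(space, windows, plan,
                                  config = train_config(),
                                  filters = 64, expansion = 8 * filters,
                                  balance = TRUE) {
  stopifnot(length(space$n_blocks) > 0, length(space$kernel_sizes) > 0,
            length(space$dropout_ps) > 0)
  repeats <- if (is.null(space$repeats)) 5L else as.integer(space$repeats)
  grid <- expand.grid(n_blocks = space$n_blocks,
                      kernel = space$kernel_sizes,
                      dropout_p = space$dropout_ps)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    spec <- default_architecture(filters = filters, expansion = expansion,
                                 kernel = grid$kernel[g],
                                 n_blocks = grid$n_blocks[g],
                                 dropout_p = grid$dropout_p[g])
    for (r in seq_len(repeats)) {
      cfg <- config
      cfg$seed <- config$seed + 1000L * r
      cv <- cross_validate(windows, plan, spec, cfg, balance = balance)
      f1 <- vapply(cv$fold_reports, function(x) x$macro$f1, 0)
      rows[[length(rows) + 1L]] <-
        data.frame(n_blocks = grid$n_blocks[g], kernel = grid$kernel[g],
                   dropout_p = grid$dropout_p[g], repeat_id = r,
                   fold = seq_along(f1), f1 = f1)
    }
  }
  score_table <- do.call(rbind, rows)
  agg <- stats::aggregate(f1 ~ n_blocks + kernel + dropout_p,
                          data = score_table, FUN = mean)
  best <- agg[which.max(agg$f1), ]
  list(
    best_spec = default_architecture(filters = filters,
                                     expansion = expansion,
                                     kernel = best$kernel,
                                     n_blocks = best$n_blocks,
                                     dropout_p = best$dropout_p),
    best_row = best,
    score_table = score_table
  )
}

#' Window-length sensitivity study
#'
#' Trains one model per training window length and evaluates it on every
#' evaluation window length -- possible in a single architecture because
#' adaptive average pooling gives a fixed-size feature vector for any
#' input length. Cell scores are the mean macro F1 over folds with a
#' bootstrap confidence interval.
#'
#' @param traces labelled traces (the study re-windows them per length)
#' @param plan a `fold_plan`
#' @param spec an [architecture_spec()]
#' @param config a [train_config()]
#' @param lengths window lengths in seconds
#' @param ci_level bootstrap confidence level
#' @param resamples bootstrap resamples
#' @param balance re-balance each fold's training windows
#' @return list with `f1` (train-length x eval-length matrix), `ci_low`,
#'   `ci_high`
#' @export
window_length_study <- function(traces, plan, spec = default_architecture(),
                                config = train_config(),
                                lengths = c(60, 90, 120),
                                ci_level = 0.95, resamples = 200,
                                balance = TRUE) {
  ws_by_len <- lapply(lengths, function(l) windows_from_traces(traces, l))
  names(ws_by_len) <- as.character(lengths)
  nm <- paste0(lengths, "s")
  f1 <- ci_lo <- ci_hi <- matrix(NA_real_, length(lengths), length(lengths),
                                 dimnames = list(train = nm, eval = nm))
  for (ti in seq_along(lengths)) {
    train_all <- ws_by_len[[ti]]
    for (f in seq_len(plan$k)) {
      val_animals <- plan$folds[[f]]
      tr_ws <- train_all[!(train_all$animal_id %in% val_animals)]
      if (balance) tr_ws <- balance_windows(tr_ws, seed = config$seed + f)
      va_ws <- train_all[train_all$animal_id %in% val_animals]
      model <- build_model(spec, seed = config$seed + 100 * f)
      fit <- train_cnn(model, tr_ws, va_ws, config)
      for (ei in seq_along(lengths)) {
        eval_all <- ws_by_len[[ei]]
        ev_ws <- eval_all[eval_all$animal_id %in% val_animals]
        pred <- predict(fit$model, ev_ws, config$batch_size)
        rep <- metrics_report(ev_ws$labels, pred)
        key <- paste(ti, ei)
        if (f == 1) attr(f1, key) <- numeric(0)
        attr(f1, key) <- c(attr(f1, key), rep$macro$f1)
      }
    }
    for (ei in seq_along(lengths)) {
      scores <- attr(f1, paste(ti, ei))
      f1[ti, ei] <- mean(scores)
      ci <- bootstrap_ci(scores, level = ci_level, resamples = resamples,
                         seed = config$seed)
      ci_lo[ti, ei] <- ci[1]
      ci_hi[ti, ei] <- ci[2]
      attr(f1, paste(ti, ei)) <- NULL
    }
  }
  list(f1 = f1, ci_low = ci_lo, ci_high = ci_hi)
}
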