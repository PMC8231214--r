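#' Pruning configuration
#'
#' One pruning stage removes a fraction `s_f` of each conv block's filters
#' (relative to the filter count at the start of that stage), spread over
#' `n` pruning iterations applied every `delta_t` epochs according to the
#' cubic sparsity schedule of [target_sparsity()]. Between iterations the
#' network trains at a constant learning rate (`prune_lr`, no annealing);
#' after each stage it is fine-tuned for `fine_tune_epochs` under the
#' one-cycle policy. Four 50% stages take the default 64-filter blocks
#' through 32, 16 and 8 down to 4 filters.
#'
#' @param s_f final per-stage sparsity (fraction of filters removed)
#' @param n pruning iterations per stage
#' @param delta_t pruning frequency in epochs
#' @param stages number of pruning stages
#' @param fine_tune_epochs fine-tuning epochs after each stage
#' @param prune_lr constant learning rate during pruning iterations
#' @return a `prune_config`
#' @export
prune_config <- function(s_f = 0.5, n = 35, delta_t = 1, stages = 4,
                         fine_tune_epochs = 15, prune_lr = 1e-4) {
  stopifnot(s_f > 0, s_f <= 1, n >= 1, delta_t >= 1, stages >= 1,
            fine_tune_epochs >= 0, prune_lr >= 0)
  structure(
    list(s_f = s_f, n = as.integer(n), delta_t = as.integer(delta_t),
         stages = as.integer(stages),
         fine_tune_epochs = as.integer(fine_tune_epochs),
         prune_lr = prune_lr),
    class = "prune_config"
  )
}

#' Cubic sparsity schedule
#'
#' Target cumulative sparsity at pruning iteration (epoch) `t`:
#' `s_t = s_f - s_f * (1 - t/(n * delta_t))^3`, defined on the grid
#' `t in {0, delta_t, ..., n * delta_t}`. The schedule starts at zero,
#' rises steeply while the network still has redundant filters, flattens
#' as it approaches the target, and reaches exactly `s_f` at the end of
#' the stage.
#'
#' @param t pruning iteration (epoch), a multiple of `delta_t` within
#'   `[0, n * delta_t]`
#' @param cfg a [prune_config()]
#' @return sparsity fraction in `[0, s_f]`
#' @export
target_sparsity <- function(t, cfg = prune_config()) {
  stopifnot(inherits(cfg, "prune_config"))
  horizon <- cfg$n * cfg$delta_t
  if (any(t < 0) || any(t > horizon)) {
    stop("t must lie in [0, ", horizon, "]", call. = FALSE)
  }
  if (any(t %% cfg$delta_t != 0)) {
    stop("t must be a multiple of delta_t = ", cfg$delta_t, call. = FALSE)
  }
  cfg$s_f - cfg$s_f * (1 - t / horizon)^3
}

#' Rank a conv block's filters by l1-norm importance
#'
#' Importance of a filter is the sum of absolute values of its weights
#' (bias excluded). Returns filter indices in ascending importance --
#' the front of the vector is pruned first. Ties break toward the lower
#' index (stable).
#'
#' @param W conv weight array `(out_channels, in_channels, kernel)`
#' @return integer vector of 1-based filter indices, least important first
#' @export
rank_filters_l1 <- function(W) {
  stopifnot(length(dim(W)) == 3)
  norms <- rowSums(abs(flat_w(W)))
  order(norms, seq_along(norms))
}

# round half away from zero (commercial rounding), used for filter targets
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Remove filters from a model (structured surgery)
#'
#' Deletes, for every listed block, the filters' outgoing conv weights,
#' biases and batch-norm parameters, together with the corresponding
#' incoming-channel slices of the following block (or of the fully
#' connected head after the expansion block). Surviving weights are
#' carried over bit-exactly -- nothing is re-initialised.
#'
#' @param model a `cnn_model`
#' @param remove list (one element per conv block) of integer vectors of
#'   filter indices to remove; empty vectors leave a block untouched
#' @return the reduced `cnn_model`
#' @export
remove_filters <- function(model, remove) {
  stopifnot(inherits(model, "cnn_model"),
            length(remove) == length(model$blocks))
  n_blocks <- length(model$blocks)
  for (i in seq_len(n_blocks)) {
    rm_idx <- unique(as.integer(remove[[i]]))
    if (length(rm_idx) == 0) next
    bl <- model$blocks[[i]]
    if (any(rm_idx < 1 | rm_idx > bl$out_ch)) {
      stop("invalid filter index for block ", i, call. = FALSE)
    }
    if (length(rm_idx) >= bl$out_ch) {
      stop("cannot prune all ", bl$out_ch, " filters of block ", i,
           call. = FALSE)
    }
    keep <- setdiff(seq_len(bl$out_ch), rm_idx)
    bl$W <- bl$W[keep, , , drop = FALSE]
    bl$b <- bl$b[keep]
    bl$gamma <- bl$gamma[keep]
    bl$beta <- bl$beta[keep]
    bl$run_mean <- bl$run_mean[keep]
    bl$run_var <- bl$run_var[keep]
    bl$out_ch <- length(keep)
    model$blocks[[i]] <- bl
    if (i < n_blocks) {  # incoming channels of the next conv block
      nx <- model$blocks[[i + 1]]
      nx$W <- nx$W[, keep, , drop = FALSE]
      nx$in_ch <- length(keep)
      model$blocks[[i + 1]] <- nx
    } else {             # head input channels
      model$head$W <- model$head$W[, keep, drop = FALSE]
    }
  }
  model
}

#' One pruning stage: schedule-driven filter removal plus fine-tuning
#'
#' Over `n` pruning iterations (one every `delta_t` epochs) the cumulative
#' number of removed filters per block tracks [target_sparsity()] applied
#' to the block's stage-initial filter count (rounded half away from
#' zero, so the stage ends at exactly `s_f`). At each iteration the
#' currently least important filters by l1-norm are removed -- the ranking
#' is recomputed every iteration because weights keep moving -- and the
#' network then trains for `delta_t` epochs at the constant pruning
#' learning rate. Afterwards the network is fine-tuned for
#' `fine_tune_epochs` under the one-cycle policy.
#'
#' @param model a trained `cnn_model`
#' @param cfg a [prune_config()]
#' @param train_windows,val_windows training and validation `window_set`s
#'   (disjoint animals)
#' @param config a [train_config()]; its learning-rate policy is
#'   overridden as described above
#' @return list with `model`, `schedule` (per-iteration data.frame of
#'   sparsity and filter counts) and `fine_tune_history`
#' @export
prune_stage <- function(model, cfg, train_windows, val_windows,
                        config = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "prune_config"))
  check_no_leakage(train_windows, val_windows)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  f0 <- vapply(model$blocks, `[[`, 0L, "out_ch")
  removed <- rep(0L, length(f0))
  prune_cfg <- config
  prune_cfg$learning_rate <- cfg$prune_lr
  prune_cfg$lr_policy <- "constant"
  opt_state <- adamw_init(model)
  lr_const <- function(s) cfg$prune_lr
  sched <- list()
  for (iter in seq_len(cfg$n)) {
    t_epoch <- iter * cfg$delta_t
    s_t <- target_sparsity(t_epoch, cfg)
    target_rm <- as.integer(round_half_up(s_t * f0))
    target_rm <- pmin(target_rm, f0 - 1L)  # a block always keeps >= 1 filter
    todo <- target_rm - removed
    if (any(todo > 0)) {
      rm_sets <- lapply(seq_along(f0), function(i) {
        if (todo[i] <= 0) return(integer(0))
        rank_filters_l1(model$blocks[[i]]$W)[seq_len(todo[i])]
      })
      model <- remove_filters(model, rm_sets)
      removed <- removed + pmax(todo, 0L)
      opt_state <- adamw_init(model)  # optimiser state shapes changed
    }
    ep <- run_epoch(model, train_windows, opt_state, prune_cfg, lr_const)
    model <- ep$model
    opt_state <- ep$opt_state
    sched[[iter]] <- data.frame(
      iteration = iter, t = t_epoch, sparsity = s_t,
      t(stats::setNames(f0 - removed, paste0("filters_b", seq_along(f0)))),
      train_loss = ep$train_loss
    )
  }
  ft_history <- NULL
  if (cfg$fine_tune_epochs > 0) {
    ft_cfg <- config
    ft_cfg$lr_policy <- "one_cycle"
    ft_cfg$max_epochs <- cfg$fine_tune_epochs
    ft_cfg$early_stop_patience <- max(1L, cfg$fine_tune_epochs - 1L)
    fit <- train_cnn(model, train_windows, val_windows, ft_cfg)
    model <- fit$model
    ft_history <- fit$history
  }
  list(model = model, schedule = do.call(rbind, sched),
       fine_tune_history = ft_history)
}

#' Multi-stage structured pruning
#'
#' Runs [prune_stage()] `cfg$stages` times; each stage removes `s_f` of
#' the then-current filters, so four 50% stages reduce 64-filter blocks to
#' 4 filters (and the 512-channel expansion to 32). Records a trajectory
#' of filter counts, parameter counts and validation macro F1 per stage.
#'
#' @param model a trained `cnn_model`
#' @param cfg a [prune_config()]
#' @param train_windows,val_windows training and validation `window_set`s
#' @param config a [train_config()]
#' @return list with `model` (final), `models` (after each stage) and
#'   `trajectory` (data.frame: stage, filters per block, params, val F1)
#' @export
prune_model <- function(model, cfg, train_windows, val_windows,
                        config = train_config()) {
  rows <- list()
  models <- vector("list", cfg$stages)
  f <- vapply(model$blocks, `[[`, 0L, "out_ch")
  rows[[1]] <- data.frame(
    stage = 0L, t(stats::setNames(f, paste0("filters_b", seq_along(f)))),
    params = count_model_params(model),
    val_f1 = metrics_report(val_windows$labels,
                            predict(model, val_windows))$macro$f1)
  for (s in seq_len(cfg$stages)) {
    st <- prune_stage(model, cfg, train_windows, val_windows, config)
    model <- st$model
    models[[s]] <- model
    f <- vapply(model$blocks, `[[`, 0L, "out_ch")
    rows[[s + 1]] <- data.frame(
      stage = s, t(stats::setNames(f, paste0("filters_b", seq_along(f)))),
      params = count_model_params(model),
      val_f1 = metrics_report(val_windows$labels,
                              predict(model, val_windows))$macro$f1)
  }
  list(model = model, models = models, trajectory = do.call(rbind, rows))
}

#' Cast a model to half precision
#'
#' Rounds every convolutional and head weight and bias to the nearest
#' IEEE 754 binary16 value (round-to-nearest-even). Batch-norm scale,
#' shift and running statistics stay at full precision for numerical
#' stability. Memory accounting of an FP16 model nevertheless uses a
#' uniform 2 bytes per parameter.
#'
#' @param model a `cnn_model`
#' @return the model with FP16-quantised weights and `precision = "FP16"`
#' @export
to_half_precision <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  for (i in seq_along(model$blocks)) {
    model$blocks[[i]]$W <- fp16_round_cpp(model$blocks[[i]]$W)
    model$blocks[[i]]$b <- as.numeric(fp16_round_cpp(model$blocks[[i]]$b))
  }
  model$head$W <- matrix(fp16_round_cpp(model$head$W),
                         nrow(model$head$W), ncol(model$head$W))
  model$head$b <- as.numeric(fp16_round_cpp(model$head$b))
  model$precision <- "FP16"
  model
}
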