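# Network engine.
#
# The model is a plain list mirroring architecture_spec: one entry per conv
# block (weights as an out x in x kernel array plus bias and batch-norm
# scale/shift/running stats) and a fully connected head. Forward/backward
# passes run the convolutions through the compiled im2col/GEMM kernels in
# single precision (the deployment precision); batch-norm, dropout, ReLU,
# pooling and the head are vectorised R. A double-precision path exists so
# gradients can be checked against finite differences.

#' Build a model from an architecture specification
#'
#' Instantiates the network with deterministic fan-in uniform weight
#' initialisation (bound `1/sqrt(fan_in)`), batch-norm scale 1 / shift 0.
#'
#' @param spec an [architecture_spec()]
#' @param seed initialisation seed
#' @return an object of class `cnn_model`
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "architecture_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  cb <- spec$conv_blocks
  blocks <- lapply(seq_len(nrow(cb)), function(i) {
    cin <- as.integer(cb$in_channels[i])
    cout <- as.integer(cb$out_channels[i])
    k <- as.integer(cb$kernel[i])
    bound <- 1 / sqrt(cin * k)
    list(
      W = array(stats::runif(cout * cin * k, -bound, bound),
                dim = c(cout, cin, k)),
      b = stats::runif(cout, -bound, bound),
      gamma = rep(1, cout), beta = rep(0, cout),
      run_mean = rep(0, cout), run_var = rep(1, cout),
      kernel = k, stride = as.integer(cb$stride[i]), in_ch = cin,
      out_ch = cout
    )
  })
  feat <- cb$out_channels[nrow(cb)]
  bound <- 1 / sqrt(feat)
  head <- list(
    W = matrix(stats::runif(spec$n_classes * feat, -bound, bound),
               spec$n_classes, feat),
    b = stats::runif(spec$n_classes, -bound, bound)
  )
  structure(
    list(blocks = blocks, head = head, dropout_p = spec$dropout_p,
         n_classes = spec$n_classes, in_channels = spec$in_channels,
         precision = "FP32"),
    class = "cnn_model"
  )
}

#' Architecture specification of a (possibly pruned) model
#'
#' @param model a `cnn_model`
#' @return the [architecture_spec()] describing the model's current shape
#' @export
model_spec <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  cb <- data.frame(
    out_channels = vapply(model$blocks, `[[`, 0, "out_ch"),
    kernel = vapply(model$blocks, `[[`, 0, "kernel"),
    stride = vapply(model$blocks, `[[`, 0, "stride")
  )
  architecture_spec(cb, dropout_p = model$dropout_p,
                    n_classes = model$n_classes,
                    in_channels = model$in_channels)
}

#' Brute-force trainable parameter count of a built model
#'
#' Enumerates every trainable tensor (conv weights and biases, batch-norm
#' scale and shift, head weights and bias) and sums their lengths --
#' the independent check on [count_params()].
#'
#' @param model a `cnn_model`
#' @return integer parameter count
#' @export
count_model_params <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  n <- 0L
  for (bl in model$blocks) {
    n <- n + length(bl$W) + length(bl$b) + length(bl$gamma) + length(bl$beta)
  }
  n + length(model$head$W) + length(model$head$b)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s, %s trainable parameters\n", x$precision,
              format(count_model_params(x), big.mark = ",")))
  print(model_spec(x))
  invisible(x)
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# flatten conv weight array (out, in, k) to the GEMM layout (out, in*k)
flat_w <- function(W) {
  d <- dim(W)
  dim(W) <- c(d[1], d[2] * d[3])
  W
}

# mean over time for every (channel, window): (C, L, N) -> (C, N)
pool_mean <- function(A) pool_mean_cpp(A)

#' Forward pass
#'
#' @param model a `cnn_model`
#' @param X input array `(in_channels, L, n_windows)`
#' @param train training mode: apply dropout and batch-statistics
#'   normalisation (and update running statistics by side value)
#' @param cache keep intermediate activations for a backward pass
#' @param double_prec run convolutions in double precision (used by the
#'   finite-difference gradient checks; default single precision)
#' @return list with `logits` (`n_classes x n`), `probs`, and when
#'   requested `cache`; in training mode also the updated model (running
#'   statistics)
#' @keywords internal
forward_cnn <- function(model, X, train = FALSE, cache = FALSE,
                        double_prec = FALSE) {
  single <- !double_prec
  p <- model$dropout_p
  caches <- if (cache) vector("list", length(model$blocks))
  A <- X
  for (i in seq_along(model$blocks)) {
    bl <- model$blocks[[i]]
    Z <- conv1d_fw_cpp(A, flat_w(bl$W), bl$b, bl$stride, single)
    mask <- NULL
    if (train && p > 0) {
      mask <- (stats::runif(length(Z)) >= p) / (1 - p)
    }
    bn <- bn_act_fw_cpp(Z, mask, bl$gamma, bl$beta, bl$run_mean, bl$run_var,
                        train, cache, bn_momentum, bn_eps)
    if (train) {
      model$blocks[[i]]$run_mean <- as.numeric(bn$run_mean)
      model$blocks[[i]]$run_var <- as.numeric(bn$run_var)
    }
    if (cache) {
      caches[[i]] <- list(X = A, mask = mask, xhat = bn$xhat,
                          sdinv = as.numeric(bn$sdinv))
    }
    A <- bn$A
  }
  pooled <- pool_mean(A)
  L_last <- dim(A)[2]
  if (cache) last_A <- A
  logits <- model$head$W %*% pooled + model$head$b
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  probs <- sweep(ex, 2, colSums(ex), "/")
  out <- list(logits = logits, probs = probs, model = model)
  if (cache) {
    out$cache <- list(blocks = caches, pooled = pooled, L_last = L_last,
                      last_A = last_A)
  }
  out
}

#' Backward pass: cross-entropy gradient of all trainable tensors
#'
#' @param model a `cnn_model`
#' @param fw result of [forward_cnn()] with `cache = TRUE`
#' @param y integer class labels (1-based, length n)
#' @param double_prec match the forward precision
#' @return list of per-tensor gradients and the mean cross-entropy `loss`
#' @keywords internal
backward_cnn <- function(model, fw, y, double_prec = FALSE) {
  single <- !double_prec
  n <- length(y)
  probs <- fw$probs
  loss <- -mean(log(pmax(probs[cbind(y, seq_len(n))], 1e-12)))
  dlogits <- probs
  dlogits[cbind(y, seq_len(n))] <- dlogits[cbind(y, seq_len(n))] - 1
  dlogits <- dlogits / n
  grads <- list(blocks = vector("list", length(model$blocks)))
  grads$head <- list(
    dW = dlogits %*% t(fw$cache$pooled),
    db = rowSums(dlogits)
  )
  dpooled <- t(model$head$W) %*% dlogits
  dA <- pool_expand_cpp(dpooled, fw$cache$L_last)
  n_blocks <- length(model$blocks)
  for (i in rev(seq_len(n_blocks))) {
    bl <- model$blocks[[i]]
    cc <- fw$cache$blocks[[i]]
    # the block's post-ReLU output is the next block's cached input
    A_i <- if (i < n_blocks) fw$cache$blocks[[i + 1]]$X else fw$cache$last_A
    bn <- bn_act_bw_cpp(dA, A_i, cc$xhat, cc$sdinv, bl$gamma, cc$mask)
    bw <- conv1d_bw_cpp(cc$X, flat_w(bl$W), bn$dZ, bl$stride, single)
    dW <- bw$dW
    dim(dW) <- dim(bl$W)
    grads$blocks[[i]] <- list(dW = dW, db = as.numeric(bw$db),
                              dgamma = as.numeric(bn$dgamma),
                              dbeta = as.numeric(bn$dbeta))
    dA <- bw$dX
  }
  grads$loss <- loss
  grads
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(model) {
  zero_like <- function(x) {
    z <- x; z[] <- 0; z
  }
  list(
    t = 0L,
    blocks = lapply(model$blocks, function(bl) {
      list(m = lapply(bl[c("W", "b", "gamma", "beta")], zero_like),
           v = lapply(bl[c("W", "b", "gamma", "beta")], zero_like))
    }),
    head = list(m = lapply(model$head[c("W", "b")], zero_like),
                v = lapply(model$head[c("W", "b")], zero_like))
  )
}

# one decoupled-weight-decay Adam update of every trainable tensor
adamw_step <- function(model, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v, decay) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + decay * p)
    list(p = p, m = m, v = v)
  }
  names_bl <- c("W", "b", "gamma", "beta")
  gnames <- c("dW", "db", "dgamma", "dbeta")
  for (i in seq_along(model$blocks)) {
    for (j in seq_along(names_bl)) {
      nm <- names_bl[j]
      decay <- if (nm == "W") weight_decay else 0
      r <- upd(model$blocks[[i]][[nm]], grads$blocks[[i]][[gnames[j]]],
               state$blocks[[i]]$m[[nm]], state$blocks[[i]]$v[[nm]], decay)
      model$blocks[[i]][[nm]] <- r$p
      state$blocks[[i]]$m[[nm]] <- r$m
      state$blocks[[i]]$v[[nm]] <- r$v
    }
  }
  for (nm in c("W", "b")) {
    decay <- if (nm == "W") weight_decay else 0
    r <- upd(model$head[[nm]], grads$head[[paste0("d", nm)]],
             state$head$m[[nm]], state$head$v[[nm]], decay)
    model$head[[nm]] <- r$p
    state$head$m[[nm]] <- r$m
    state$head$v[[nm]] <- r$v
  }
  list(model = model, state = state)
}

#' One-cycle learning-rate schedule
#'
#' Cosine warm-up from the base rate to `peak_mult` times the base over the
#' first `warmup_frac` of training, then cosine annealing down to
#' `base / final_div`. The schedule starts below its peak and ends below
#' its starting rate.
#'
#' @param step 1-based step index
#' @param total_steps total optimisation steps in the cycle
#' @param base_lr base learning rate
#' @param peak_mult peak as a multiple of `base_lr`
#' @param warmup_frac fraction of steps spent warming up
#' @param final_div divisor for the final rate
#' @return learning rate for `step`
#' @export
one_cycle_lr <- function(step, total_steps, base_lr, peak_mult = 10,
                         warmup_frac = 0.3, final_div = 100) {
  stopifnot(total_steps >= 1, step >= 1, step <= total_steps)
  peak <- base_lr * peak_mult
  final <- base_lr / final_div
  n_up <- max(1, round(warmup_frac * total_steps))
  if (step <= n_up) {
    frac <- if (n_up == 1) 1 else (step - 1) / (n_up - 1)
    base_lr + (peak - base_lr) * (1 - cos(pi * frac)) / 2
  } else {
    n_down <- total_steps - n_up
    frac <- (step - n_up) / n_down
    final + (peak - final) * (1 + cos(pi * frac)) / 2
  }
}

# average cross-entropy loss + predictions in eval mode, batched
eval_loss <- function(model, ws, batch_size = 256, double_prec = FALSE) {
  n <- length(ws)
  y <- as.integer(ws$labels)
  total <- 0
  pred <- integer(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    fw <- forward_cnn(model, ws$data[, , idx, drop = FALSE], train = FALSE,
                      double_prec = double_prec)
    total <- total + sum(-log(pmax(fw$probs[cbind(y[idx],
                                                  seq_along(idx))], 1e-12)))
    pred[idx] <- max.col(t(fw$probs), ties.method = "first")
  }
  list(loss = total / n,
       pred = factor(behaviour_levels()[pred], levels = behaviour_levels()))
}

#' Predict behaviour labels for a window set
#'
#' @param object a `cnn_model`
#' @param windows a `window_set`
#' @param batch_size forward-pass batch size
#' @param ... unused
#' @return factor of predicted labels, with per-class probabilities in
#'   attribute `"probs"`
#' @export
predict.cnn_model <- function(object, windows, batch_size = 256, ...) {
  stopifnot(inherits(windows, "window_set"))
  n <- length(windows)
  probs <- matrix(NA_real_, object$n_classes, n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    fw <- forward_cnn(object, windows$data[, , idx, drop = FALSE],
                      train = FALSE)
    probs[, idx] <- fw$probs
  }
  pred <- factor(behaviour_levels()[max.col(t(probs), ties.method = "first")],
                 levels = behaviour_levels())
  attr(pred, "probs") <- probs
  pred
}
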