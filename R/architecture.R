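#' Declarative CNN architecture specification
#'
#' Describes the behaviour classifier as data: an ordered list of
#' convolutional blocks (each convolution is followed by dropout,
#' batch-normalisation and ReLU), adaptive average pooling over the time
#' dimension, and a fully connected head. The final conv block must have
#' kernel size 1: it is the expansion layer that widens the feature map
#' (64 to 512 channels in the default network) and fixes the head's input
#' width. All parameter, operation and memory accounting as well as model
#' construction and pruning operate on this object.
#'
#' @param conv_blocks data.frame with columns `out_channels`, `kernel`,
#'   `stride`, one row per block in order
#' @param dropout_p dropout probability in `[0, 1)`
#' @param n_classes number of output classes
#' @param in_channels input channels (3 accelerometer axes)
#'
#' @return an object of class `architecture_spec`
#' @seealso [default_architecture()] for the standard network family
#' @export
architecture_spec <- function(conv_blocks, dropout_p = 0.25, n_classes = 3,
                              in_channels = 3) {
  cb <- as.data.frame(conv_blocks)
  need <- c("out_channels", "kernel", "stride")
  if (!all(need %in% names(cb))) {
    stop("conv_blocks needs columns out_channels, kernel, stride",
         call. = FALSE)
  }
  cb <- cb[, c(need, intersect("in_channels", names(cb)))]
  if (nrow(cb) < 1) stop("need at least one conv block", call. = FALSE)
  if (any(cb$out_channels < 1) || any(cb$kernel < 1) || any(cb$stride < 1)) {
    stop("block dimensions must be positive", call. = FALSE)
  }
  implied_in <- c(in_channels, cb$out_channels[-nrow(cb)])
  if ("in_channels" %in% names(cb)) {
    if (any(cb$in_channels != implied_in)) {
      bad <- which(cb$in_channels != implied_in)[1]
      stop("block ", bad, " declares ", cb$in_channels[bad],
           " input channels but the preceding layer provides ",
           implied_in[bad], call. = FALSE)
    }
  }
  cb$in_channels <- implied_in
  if (cb$kernel[nrow(cb)] != 1) {
    stop("the last conv block must have kernel size 1 (expansion layer)",
         call. = FALSE)
  }
  if (dropout_p < 0 || dropout_p >= 1) {
    stop("dropout_p must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(in_channels = in_channels, conv_blocks = cb,
         dropout_p = dropout_p, n_classes = as.integer(n_classes)),
    class = "architecture_spec"
  )
}

#' The standard classifier architecture family
#'
#' `n_blocks - 1` convolutional blocks of `filters` filters with kernel
#' size `kernel` and stride `stride`, followed by the kernel-1 expansion
#' block of `expansion` channels, adaptive average pooling and a
#' `expansion -> n_classes` head. With the defaults (64 filters, expansion
#' 512, kernel 16, dropout 0.25) this is the full unpruned network; the
#' pruned family keeps the 8:1 expansion ratio (e.g. 16 filters / 128
#' expansion, 4 filters / 32 expansion).
#'
#' @param filters filters per kernel-16 block
#' @param expansion channels of the kernel-1 expansion block (default
#'   `8 * filters`)
#' @param kernel kernel size of the feature-extractor blocks
#' @param stride stride of the feature-extractor blocks (expansion stride
#'   is always 1)
#' @param n_blocks total conv blocks including the expansion layer
#' @param dropout_p dropout probability
#' @param n_classes output classes
#' @return an [architecture_spec()]
#' @export
default_architecture <- function(filters = 64, expansion = 8 * filters,
                                 kernel = 16, stride = 2, n_blocks = 4,
                                 dropout_p = 0.25, n_classes = 3) {
  stopifnot(n_blocks >= 1)  # n_blocks = 1 is the expansion layer alone
  k16 <- n_blocks - 1L
  cb <- data.frame(
    out_channels = c(rep(filters, k16), expansion),
    kernel = c(rep(kernel, k16), 1L),
    stride = c(rep(stride, k16), 1L)
  )
  architecture_spec(cb, dropout_p = dropout_p, n_classes = n_classes)
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat("<architecture_spec>\n")
  cb <- x$conv_blocks
  for (i in seq_len(nrow(cb))) {
    cat(sprintf("  conv%d: %d -> %d, k=%d, s=%d  (+dropout %.2f, BN, ReLU)\n",
                i, cb$in_channels[i], cb$out_channels[i], cb$kernel[i],
                cb$stride[i], x$dropout_p))
  }
  cat(sprintf("  adaptive average pool -> head %d -> %d\n",
              cb$out_channels[nrow(cb)], x$n_classes))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters of an architecture
#'
#' Per conv block: `in * out * kernel` weights, `out` biases and `2 * out`
#' batch-norm parameters (scale and shift; running statistics are buffers,
#' not trainable, and are excluded). The head adds `in * n_classes`
#' weights and `n_classes` biases.
#'
#' @param spec an [architecture_spec()]
#' @return integer parameter count
#' @export
count_params <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  cb <- spec$conv_blocks
  conv <- sum(cb$in_channels * cb$out_channels * cb$kernel +  # weights
                cb$out_channels +                             # biases
                2 * cb$out_channels)                          # BN scale/shift
  feat <- cb$out_channels[nrow(cb)]
  head_p <- feat * spec$n_classes + spec$n_classes
  as.integer(conv + head_p)
}

conv_out_length <- function(L, kernel, stride) {
  if (L < kernel) return(NA_integer_)
  as.integer((L - kernel) %/% stride + 1L)
}

#' Receptive-field / minimum input length of an architecture
#'
#' @param spec an [architecture_spec()]
#' @return smallest input length for which every conv layer has at least
#'   one output position
#' @export
min_input_length <- function(spec) {
  cb <- spec$conv_blocks
  # invert the chain: last layer needs length >= kernel
  L <- cb$kernel[nrow(cb)]
  for (i in rev(seq_len(nrow(cb) - 1L))) {
    L <- (L - 1L) * cb$stride[i] + cb$kernel[i]
  }
  as.integer(L)
}

#' Count multiply-accumulate operations of one forward pass
#'
#' Convolutions contribute `out_length * in_channels * kernel *
#' out_channels` MACCs each ("valid" convolution, output length
#' `floor((L - kernel)/stride) + 1`); the head contributes `in * out`.
#' Batch-norm, ReLU, pooling and bias additions are excluded by default;
#' `include_elementwise` adds an estimate of them (4 ops per conv output
#' element plus the pooling sum). Operation counts depend on the stride
#' and padding convention, so results carry their settings as attributes.
#'
#' @param spec an [architecture_spec()]
#' @param input_length input samples per axis
#' @param include_elementwise include elementwise/pooling arithmetic
#' @return MACC count with attribute `input_length`
#' @export
count_macc <- function(spec, input_length, include_elementwise = FALSE) {
  stopifnot(inherits(spec, "architecture_spec"))
  cb <- spec$conv_blocks
  if (input_length < min_input_length(spec)) {
    stop("input_length ", input_length, " is below the minimum ",
         min_input_length(spec), " for this architecture", call. = FALSE)
  }
  L <- as.integer(input_length)
  macc <- 0
  extra <- 0
  for (i in seq_len(nrow(cb))) {
    L <- conv_out_length(L, cb$kernel[i], cb$stride[i])
    macc <- macc + L * cb$in_channels[i] * cb$kernel[i] * cb$out_channels[i]
    extra <- extra + 4 * L * cb$out_channels[i]  # bias+BN+ReLU per element
  }
  extra <- extra + L * cb$out_channels[nrow(cb)]  # pooling sum
  macc <- macc + cb$out_channels[nrow(cb)] * spec$n_classes
  out <- macc + if (include_elementwise) extra else 0
  attr(out, "input_length") <- as.integer(input_length)
  out
}

#' Model memory footprint in kB
#'
#' @param n_params parameter count
#' @param precision `"FP32"` (4 bytes/parameter) or `"FP16"` (2 bytes)
#' @param digits decimal places to round to (default 1); `NA` for
#'   unrounded
#' @return memory in kB (1024 bytes)
#' @export
memory_kb <- function(n_params, precision = c("FP32", "FP16"), digits = 1) {
  precision <- match.arg(precision)
  stopifnot(n_params >= 0)
  bytes <- c(FP32 = 4, FP16 = 2)[[precision]]
  kb <- n_params * bytes / 1024
  if (is.na(digits)) kb else round(kb, digits)
}

#' Compression ratio of a pruned model
#'
#' @param reference_params parameter count of the reference (unpruned) model
#' @param pruned_params parameter count of the reduced model
#' @param digits decimal places (default 2); `NA` for unrounded
#' @return `reference_params / pruned_params`
#' @export
compression <- function(reference_params, pruned_params, digits = 2) {
  if (pruned_params <= 0) stop("pruned_params must be positive",
                               call. = FALSE)
  r <- reference_params / pruned_params
  if (is.na(digits)) r else round(r, digits)
}

#' Complexity report for an architecture
#'
#' Parameter count, MACCs, per-precision memory, and (against an optional
#' reference architecture) compression and speed-up ratios -- one row of a
#' model-comparison table.
#'
#' @param spec an [architecture_spec()]
#' @param input_length input samples per axis for the MACC count
#' @param reference optional reference [architecture_spec()]
#' @return a `complexity_report` list
#' @export
complexity_report <- function(spec, input_length = 899, reference = NULL) {
  p <- count_params(spec)
  m <- as.numeric(count_macc(spec, input_length))
  rep <- list(
    n_params = p,
    n_macc = m,
    input_length = as.integer(input_length),
    memory_kb = c(FP32 = memory_kb(p, "FP32"), FP16 = memory_kb(p, "FP16")),
    compression = NA_real_,
    speedup = NA_real_
  )
  if (!is.null(reference)) {
    rep$compression <- compression(count_params(reference), p)
    rep$speedup <- round(as.numeric(count_macc(reference, input_length)) / m,
                         1)
  }
  structure(rep, class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf(
    "params %s | compression %s | ops %.3g | speed-up %s | %0.1f kB FP32 / %0.1f kB FP16 (input %d)\n",
    format(x$n_params, big.mark = ","),
    ifelse(is.na(x$compression), "-", sprintf("%.2f", x$compression)),
    x$n_macc,
    ifelse(is.na(x$speedup), "-", sprintf("%.1f", x$speedup)),
    x$memory_kb[["FP32"]], x$memory_kb[["FP16"]], x$input_length))
  invisible(x)
}

#' Write / read an architecture specification as YAML
#'
#' @param spec an [architecture_spec()]
#' @param path YAML file path
#' @return `write_architecture` returns `path` invisibly;
#'   `read_architecture` returns the [architecture_spec()]
#' @export
write_architecture <- function(spec, path) {
  stopifnot(inherits(spec, "architecture_spec"))
  yaml::write_yaml(list(
    in_channels = spec$in_channels,
    n_classes = spec$n_classes,
    dropout_p = spec$dropout_p,
    conv_blocks = lapply(seq_len(nrow(spec$conv_blocks)), function(i) {
      as.list(spec$conv_blocks[i, c("out_channels", "kernel", "stride")])
    })
  ), path)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  y <- yaml::read_yaml(path)
  cb <- do.call(rbind, lapply(y$conv_blocks, as.data.frame))
  architecture_spec(cb, dropout_p = y$dropout_p, n_classes = y$n_classes,
                    in_channels = y$in_channels)
}
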