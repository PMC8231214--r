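#' Behaviour state labels
#'
#' The three behaviour states recognised by the classifier, in their fixed
#' declaration order. The order matters: majority-vote ties in window
#' labelling are broken in favour of the earlier level, so the ordering is
#' part of the package contract rather than a cosmetic choice.
#'
#' @return Character vector `c("RUMINATION", "EATING", "OTHER")`.
#' @export
behaviour_levels <- function() {
  c("RUMINATION", "EATING", "OTHER")
}

#' Coerce labels to the behaviour factor
#'
#' @param x character or factor of behaviour labels
#' @return factor with levels [behaviour_levels()]
#' @export
as_behaviour <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), behaviour_levels())
  if (length(bad) > 0) {
    stop("unknown behaviour label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = behaviour_levels())
}

#' Labelled accelerometer trace
#'
#' Container for one animal's 10 Hz 3-axis collar acceleration stream with
#' optional per-sample behaviour labels (the content of a merged
#' collar/halter CSV). Timestamps are epoch seconds and must be strictly
#' increasing; the nominal sampling interval is 0.1 s.
#'
#' @param animal_id single string identifying the animal
#' @param timestamps numeric vector of epoch seconds, strictly increasing
#' @param accel numeric matrix with one row per sample and columns x, y, z
#' @param labels optional per-sample behaviour labels (character or factor
#'   with values in [behaviour_levels()])
#' @param sampling_rate sampling frequency in Hz (default 10)
#'
#' @return An object of class `labelled_trace`.
#' @export
labelled_trace <- function(animal_id, timestamps, accel, labels = NULL,
                           sampling_rate = 10) {
  stopifnot(is.character(animal_id), length(animal_id) == 1L)
  timestamps <- as.numeric(timestamps)
  accel <- as.matrix(accel)
  if (ncol(accel) != 3L) stop("accel must have 3 columns (x, y, z)",
                              call. = FALSE)
  storage.mode(accel) <- "double"
  colnames(accel) <- c("x", "y", "z")
  if (nrow(accel) != length(timestamps)) {
    stop("timestamps and accel lengths differ", call. = FALSE)
  }
  if (anyNA(timestamps)) stop("timestamps contain NA", call. = FALSE)
  if (length(timestamps) > 1L) {
    d <- diff(timestamps)
    if (any(d <= 0)) {
      stop("timestamps must be strictly increasing (duplicate or ",
           "out-of-order timestamp near row ", which(d <= 0)[1] + 1L, ")",
           call. = FALSE)
    }
  }
  if (!is.null(labels)) {
    labels <- as_behaviour(labels)
    if (length(labels) != length(timestamps)) {
      stop("labels and timestamps lengths differ", call. = FALSE)
    }
  }
  structure(
    list(animal_id = animal_id, sampling_rate = sampling_rate,
         timestamps = timestamps, accel = accel, labels = labels),
    class = "labelled_trace"
  )
}

#' @export
length.labelled_trace <- function(x) length(x$timestamps)

#' @export
print.labelled_trace <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<labelled_trace> animal %s: %d samples @ %g Hz (%.1f min)%s\n",
              x$animal_id, n, x$sampling_rate,
              n / x$sampling_rate / 60,
              if (is.null(x$labels)) ", unlabelled" else ", labelled"))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}
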