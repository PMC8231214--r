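#' First-order differencing of a collar trace
#'
#' Computes the discrete difference along each axis,
#' `ds[t] = s[t] - s[t-1]`, removing the slowly varying gravity offset that
#' a shifting, rotating collar superimposes on the motion signal. The output
#' is one sample shorter; labels and timestamps align to the later sample of
#' each pair.
#'
#' @param trace a [labelled_trace()] of length at least 2
#' @return a differenced [labelled_trace()]
#' @export
diff_trace <- function(trace) {
  stopifnot(inherits(trace, "labelled_trace"))
  n <- length(trace)
  if (n < 2) stop("trace must have at least 2 samples to difference",
                  call. = FALSE)
  labelled_trace(trace$animal_id,
                 trace$timestamps[-1],
                 apply(trace$accel, 2, diff),
                 labels = if (is.null(trace$labels)) NULL
                          else as.character(trace$labels[-1]),
                 sampling_rate = trace$sampling_rate)
}

#' Majority-vote label of a block of per-sample labels
#'
#' The most frequent behaviour in the block; ties are broken by the fixed
#' declaration order of [behaviour_levels()] (RUMINATION before EATING
#' before OTHER), which keeps window labelling deterministic.
#'
#' @param labels non-empty vector of behaviour labels
#' @return single behaviour label (character)
#' @export
majority_label <- function(labels) {
  if (length(labels) == 0) stop("empty label block", call. = FALSE)
  counts <- table(as_behaviour(labels))
  names(counts)[which.max(counts)]  # which.max: first maximum wins ties
}

#' Segment a differenced trace into fixed-length labelled windows
#'
#' Cuts contiguous, non-overlapping windows of exactly
#' `window_seconds * sampling_rate` samples; the trailing remainder is
#' dropped. Each window takes the majority-vote label of its samples.
#'
#' @param trace labelled, differenced [labelled_trace()]
#' @param window_seconds window length in seconds (typically 60, 90 or 120)
#' @return a `window_set`: 3 x L x n data array with per-window label,
#'   animal id and start time
#' @export
segment_windows <- function(trace, window_seconds = 90) {
  stopifnot(inherits(trace, "labelled_trace"))
  if (is.null(trace$labels)) {
    stop("trace must be labelled before segmentation", call. = FALSE)
  }
  L <- as.integer(round(window_seconds * trace$sampling_rate))
  stopifnot(L > 0)
  n <- length(trace)
  n_win <- n %/% L
  if (n_win == 0) {
    warning("trace ", trace$animal_id, " shorter than one window; ",
            "returning empty window set")
    return(window_set(array(0, dim = c(3, L, 0)), character(0),
                      character(0), numeric(0), window_seconds,
                      trace$sampling_rate))
  }
  used <- n_win * L
  dat <- array(t(trace$accel[seq_len(used), , drop = FALSE]),
               dim = c(3, L, n_win))
  labmat <- matrix(as.integer(trace$labels[seq_len(used)]), nrow = L)
  counts <- vapply(1:3, function(cl) colSums(labmat == cl),
                   numeric(n_win))
  counts <- matrix(counts, nrow = n_win)
  win_lab <- behaviour_levels()[max.col(counts, ties.method = "first")]
  starts <- trace$timestamps[(seq_len(n_win) - 1L) * L + 1L]
  window_set(dat, win_lab, rep(trace$animal_id, n_win), starts,
             window_seconds, trace$sampling_rate)
}

#' Construct a window set
#'
#' Usually produced by [segment_windows()]; exposed for programmatic
#' construction in tests and simulations.
#'
#' @param data 3 x L x n numeric array of differenced acceleration
#' @param labels per-window behaviour labels (length n)
#' @param animal_id per-window animal ids (length n)
#' @param start_time per-window start times (length n)
#' @param window_seconds window length in seconds
#' @param sampling_rate sampling frequency in Hz
#' @return an object of class `window_set`
#' @export
window_set <- function(data, labels, animal_id, start_time,
                       window_seconds, sampling_rate = 10) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == 3)
  n <- dim(data)[3]
  labels <- as_behaviour(labels)
  stopifnot(length(labels) == n, length(animal_id) == n,
            length(start_time) == n)
  structure(
    list(data = data, labels = labels, animal_id = as.character(animal_id),
         start_time = as.numeric(start_time),
         window_seconds = window_seconds, sampling_rate = sampling_rate),
    class = "window_set"
  )
}

#' @export
length.window_set <- function(x) dim(x$data)[3]

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %g s (%d samples), %d animal(s)\n",
              length(x), x$window_seconds, dim(x$data)[2],
              length(unique(x$animal_id))))
  print(window_counts(x))
  invisible(x)
}

#' Per-(animal, class) window counts
#'
#' @param ws a `window_set`
#' @return contingency table of animal by behaviour class
#' @export
window_counts <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  table(animal = ws$animal_id, class = ws$labels)
}

#' Subset a window set
#'
#' @param x a `window_set`
#' @param i integer or logical index over windows
#' @param ... unused
#' @export
`[.window_set` <- function(x, i, ...) {
  window_set(x$data[, , i, drop = FALSE], as.character(x$labels[i]),
             x$animal_id[i], x$start_time[i], x$window_seconds,
             x$sampling_rate)
}

#' Concatenate window sets
#'
#' @param ... `window_set` objects with identical window geometry
#' @return combined `window_set`
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  sets <- Filter(function(s) length(s) > 0, sets)
  if (length(sets) == 0) stop("nothing to bind", call. = FALSE)
  ws0 <- sets[[1]]
  for (s in sets) {
    stopifnot(inherits(s, "window_set"),
              identical(dim(s$data)[1:2], dim(ws0$data)[1:2]),
              s$window_seconds == ws0$window_seconds)
  }
  window_set(
    array(unlist(lapply(sets, function(s) s$data), use.names = FALSE),
          dim = c(3, dim(ws0$data)[2], sum(vapply(sets, length, 0L)))),
    unlist(lapply(sets, function(s) as.character(s$labels))),
    unlist(lapply(sets, function(s) s$animal_id)),
    unlist(lapply(sets, function(s) s$start_time)),
    ws0$window_seconds, ws0$sampling_rate)
}

#' Segment a list of traces and pool the windows
#'
#' Convenience wrapper: difference (optional), segment and bind all traces.
#'
#' @param traces list of labelled traces
#' @param window_seconds window length in seconds
#' @param difference apply [diff_trace()] first (default TRUE)
#' @return pooled `window_set`
#' @export
windows_from_traces <- function(traces, window_seconds = 90,
                                difference = TRUE) {
  sets <- lapply(traces, function(tr) {
    if (difference) tr <- diff_trace(tr)
    segment_windows(tr, window_seconds)
  })
  bind_window_sets(sets)
}

#' Balance a window set across animals and classes
#'
#' Random undersampling so that every animal contributes the same number of
#' windows for every behaviour class: the common count is the minimum over
#' all (animal, class) cells. Deterministic given `seed`.
#'
#' @param ws a `window_set`
#' @param seed RNG seed for the undersampling
#' @param classes classes that must be balanced (default all three)
#' @return balanced `window_set`
#' @export
balance_windows <- function(ws, seed = 1, classes = behaviour_levels()) {
  stopifnot(inherits(ws, "window_set"))
  animals <- unique(ws$animal_id)
  counts <- window_counts(ws)
  for (a in animals) {
    for (cl in classes) {
      if (counts[a, cl] == 0) {
        stop("animal ", a, " has no ", cl,
             " windows; cannot balance", call. = FALSE)
      }
    }
  }
  target <- min(counts[animals, classes])
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  keep <- integer(0)
  for (a in animals) {
    for (cl in classes) {
      cell <- which(ws$animal_id == a & ws$labels == cl)
      keep <- c(keep, if (length(cell) == target) cell
                      else sample(cell, target))
    }
  }
  ws[sort(keep)]
}

#' Animal-grouped cross-validation folds
#'
#' Shuffles the unique animal ids with `seed` and slices the shuffled
#' vector contiguously into `k` folds (sizes differing by at most one).
#' Grouping by animal, not by window, is what prevents leakage: windows of
#' one animal are never split across training and validation.
#'
#' @param animal_ids vector of unique animal ids
#' @param k number of folds (default 5)
#' @param seed shuffling seed
#' @return a `fold_plan`: list of k disjoint animal-id sets
#' @export
make_folds <- function(animal_ids, k = 5, seed = 1) {
  ids <- unique(as.character(animal_ids))
  if (length(ids) < k) {
    stop("need at least k = ", k, " animals, got ", length(ids),
         call. = FALSE)
  }
  if (k < 2) stop("k must be at least 2 (one fold leaves no training set)",
                  call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  shuffled <- sample(ids)
  sizes <- rep(length(ids) %/% k, k)
  extra <- length(ids) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  folds <- lapply(seq_len(k), function(i) shuffled[starts[i]:ends[i]])
  structure(list(k = k, folds = folds, seed = seed), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds (seed %d)\n", x$k, x$seed))
  for (i in seq_len(x$k)) {
    cat(sprintf("  fold %d: %s\n", i, paste(x$folds[[i]], collapse = ", ")))
  }
  invisible(x)
}
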