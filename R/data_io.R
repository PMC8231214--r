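#' Read a collar accelerometer CSV
#'
#' Reads one animal's collar stream. The file must be comma-separated with a
#' header row; column names are configurable through `column_map` because
#' deployed logger formats vary. Timestamps may be numeric epoch seconds or
#' ISO-8601 strings; they are normalised to epoch seconds internally. Rows
#' are sorted by timestamp before validation, so row order in the file does
#' not matter, but duplicated timestamps are rejected (averaging them would
#' make the signal differencing step ill-defined).
#'
#' @param path CSV file path
#' @param column_map named list/character mapping the roles `timestamp`,
#'   `x`, `y`, `z` and optionally `label` to column names in the file
#' @param animal_id animal identifier; defaults to the file name without
#'   extension
#' @param sampling_rate sampling frequency in Hz
#'
#' @return a [labelled_trace()] (labelled when a `label` column is mapped)
#' @export
read_collar_csv <- function(path,
                            column_map = list(timestamp = "timestamp",
                                              x = "x", y = "y", z = "z"),
                            animal_id = NULL,
                            sampling_rate = 10) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(animal_id)) {
    animal_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  column_map <- as.list(column_map)
  needed <- c("timestamp", "x", "y", "z")
  if (!all(needed %in% names(column_map))) {
    stop("column_map must map 'timestamp', 'x', 'y' and 'z'", call. = FALSE)
  }
  want <- unlist(column_map[c(needed, intersect("label", names(column_map)))])
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- parse_timestamps(df[[column_map$timestamp]], basename(path))
  acc <- lapply(c("x", "y", "z"), function(axis) {
    raw <- df[[column_map[[axis]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & nzchar(trimws(as.character(raw))))
    if (length(bad) > 0 || anyNA(val)) {
      row <- if (length(bad) > 0) bad[1] else which(is.na(val))[1]
      stop("non-numeric acceleration in column '", column_map[[axis]],
           "' at data row ", row, " of ", basename(path), call. = FALSE)
    }
    val
  })
  accel <- cbind(x = acc[[1]], y = acc[[2]], z = acc[[3]])
  labels <- if (!is.null(column_map$label)) df[[column_map$label]] else NULL
  ord <- order(ts)
  labelled_trace(animal_id, ts[ord], accel[ord, , drop = FALSE],
                 labels = if (is.null(labels)) NULL else labels[ord],
                 sampling_rate = sampling_rate)
}

parse_timestamps <- function(x, what = "input") {
  if (is.numeric(x)) return(as.numeric(x))
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  ts <- as.POSIXct(as.character(x), tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) {
    stop("unparseable timestamp at data row ", which(is.na(ts))[1], " of ",
         what, call. = FALSE)
  }
  as.numeric(ts)
}

#' Attach halter ground-truth labels to a collar trace
#'
#' Merges the halter's per-sample behaviour labels onto a collar trace by
#' timestamp. Collar and halter run independent real-time clocks, so exact
#' equality cannot be assumed: each collar sample takes the label of the
#' nearest halter sample within `tolerance` seconds (default half the 10 Hz
#' sampling interval). Collar samples with no halter sample inside the
#' tolerance are dropped and counted.
#'
#' @param collar unlabelled [labelled_trace()]
#' @param halter_timestamps numeric vector of halter epoch seconds (sorted)
#' @param halter_labels behaviour labels aligned with `halter_timestamps`
#' @param tolerance matching tolerance in seconds
#'
#' @return a labelled trace; attribute `"n_dropped"` records how many collar
#'   samples found no matching label
#' @export
merge_by_timestamp <- function(collar, halter_timestamps, halter_labels,
                               tolerance = 0.05) {
  stopifnot(inherits(collar, "labelled_trace"))
  ht <- as.numeric(halter_timestamps)
  hl <- as_behaviour(halter_labels)
  if (length(ht) != length(hl)) {
    stop("halter timestamps and labels lengths differ", call. = FALSE)
  }
  if (length(ht) == 0 ||
      min(ht) > max(collar$timestamps) + tolerance ||
      max(ht) < min(collar$timestamps) - tolerance) {
    stop("no temporal overlap between collar and halter streams",
         call. = FALSE)
  }
  ord <- order(ht)
  ht <- ht[ord]; hl <- hl[ord]
  # nearest halter neighbour for each collar sample
  idx <- findInterval(collar$timestamps, ht)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(ht))
  d_lo <- abs(collar$timestamps - ht[lo])
  d_hi <- abs(collar$timestamps - ht[hi])
  nearest <- ifelse(d_hi < d_lo, hi, lo)
  dist <- pmin(d_lo, d_hi)
  keep <- dist <= tolerance
  if (!any(keep)) {
    stop("no collar samples matched a halter label within tolerance",
         call. = FALSE)
  }
  out <- labelled_trace(collar$animal_id,
                        collar$timestamps[keep],
                        collar$accel[keep, , drop = FALSE],
                        labels = as.character(hl[nearest[keep]]),
                        sampling_rate = collar$sampling_rate)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write a multi-animal dataset to disk
#'
#' One CSV per animal plus a YAML manifest listing the files, so a herd can
#' be round-tripped exactly. Acceleration is written at full precision.
#'
#' @param traces list of [labelled_trace()] objects
#' @param dir output directory (created if needed)
#' @param trial_id optional free-text trial identifier stored in the manifest
#' @return the manifest path, invisibly
#' @export
write_dataset <- function(traces, dir, trial_id = NULL) {
  stopifnot(is.list(traces))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  files <- character(0)
  for (tr in traces) {
    stopifnot(inherits(tr, "labelled_trace"))
    fn <- paste0(tr$animal_id, ".csv")
    df <- data.frame(timestamp = sprintf("%.10g", tr$timestamps),
                     x = sprintf("%.17g", tr$accel[, 1]),
                     y = sprintf("%.17g", tr$accel[, 2]),
                     z = sprintf("%.17g", tr$accel[, 3]),
                     check.names = FALSE)
    if (!is.null(tr$labels)) df$label <- as.character(tr$labels)
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE, quote = FALSE)
    files <- c(files, fn)
  }
  manifest <- list(
    format = "collarcnn-dataset",
    trial_id = trial_id,
    sampling_rate = if (length(traces)) traces[[1]]$sampling_rate else 10,
    animals = lapply(traces, function(tr) {
      list(animal_id = tr$animal_id, file = paste0(tr$animal_id, ".csv"),
           n_samples = length(tr), labelled = !is.null(tr$labels))
    })
  )
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.yaml`
#' @return list of [labelled_trace()] objects
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.yaml")
  if (!file.exists(mpath)) stop("no manifest.yaml in ", dir, call. = FALSE)
  manifest <- yaml::read_yaml(mpath)
  if (!identical(manifest$format, "collarcnn-dataset")) {
    stop("not a collarcnn dataset manifest: ", mpath, call. = FALSE)
  }
  lapply(manifest$animals, function(a) {
    cmap <- list(timestamp = "timestamp", x = "x", y = "y", z = "z")
    if (isTRUE(a$labelled)) cmap$label <- "label"
    tr <- read_collar_csv(file.path(dir, a$file), column_map = cmap,
                          animal_id = a$animal_id,
                          sampling_rate = manifest$sampling_rate)
    if (length(tr) != a$n_samples) {
      stop("file ", a$file, " has ", length(tr),
           " rows but manifest records ", a$n_samples,
           " (truncated or corrupted file?)", call. = FALSE)
    }
    tr
  })
}
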