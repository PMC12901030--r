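#' Read and write event and saccade tables
#'
#' Event tables are exchanged as tab-separated text with columns `trial`,
#' `onset`, `locus`, `label`, `source`; saccade tables with `trial`, `onset`,
#' `displacement`, `is_micro`.
#'
#' @param events An [event_table()].
#' @param path File path.
#' @return `write_event_table` returns `path` invisibly; `read_event_table`
#'   an [event_table()].
#' @export
write_event_table <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  event_table(df$trial, df$onset, df$locus,
              label = df$label %||% NA_character_,
              source = df$source %||% "detected")
}

#' Read and write gaze records as delimited text
#'
#' Long format with columns `trial`, `t`, `x`, `y`, `pupil`.
#'
#' @param gaze A [gaze_record()].
#' @param path File path.
#' @return `write_gaze_record` returns `path` invisibly; `read_gaze_record` a
#'   [gaze_record()] (without planted ground truth).
#' @export
write_gaze_record <- function(gaze, path) {
  tt <- epoch_times(gaze)
  n_trials <- nrow(gaze$x)
  df <- data.frame(trial = rep(seq_len(n_trials), each = length(tt)),
                   t = rep(tt, n_trials),
                   x = as.vector(t(gaze$x)), y = as.vector(t(gaze$y)),
                   pupil = if (!is.null(gaze$pupil))
                     as.vector(t(gaze$pupil)) else NA_real_)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_record
#' @export
read_gaze_record <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  trials <- sort(unique(df$trial))
  tt <- sort(unique(df$t))
  fs <- 1 / stats::median(diff(tt))
  shape <- function(col) {
    m <- matrix(NA_real_, length(trials), length(tt))
    m[cbind(match(df$trial, trials), match(df$t, tt))] <- df[[col]]
    m
  }
  gaze_record(shape("x"), shape("y"),
              pupil = if (all(is.na(df$pupil))) NULL else shape("pupil"),
              fs = round(fs), t0 = tt[1])
}

#' Write and read an epoch set (binary array plus JSON sidecar)
#'
#' The data array is stored as little-endian doubles in trial-major order
#' next to a JSON sidecar holding the dimensions, sampling rate, epoch start,
#' channel names and trial metadata.
#'
#' @param epochs An [epoch_set()].
#' @param path Path of the binary array file; the sidecar is `path` +
#'   `".json"`.
#' @return `write_epoch_set` returns `path` invisibly; `read_epoch_set` an
#'   [epoch_set()].
#' @export
write_epoch_set <- function(epochs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  sidecar <- list(dim = dim(epochs$data), fs = epochs$fs, t0 = epochs$t0,
                  channel_names = dimnames(epochs$data)[[2]],
                  meta = epochs$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(sc$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  data <- array(readBin(con, "double", n = n, size = 8, endian = "little"),
                dim = sc$dim)
  if (!is.null(sc$channel_names))
    dimnames(data) <- list(NULL, sc$channel_names, NULL)
  epoch_set(data, fs = sc$fs, t0 = sc$t0,
            meta = as.data.frame(sc$meta, stringsAsFactors = FALSE))
}
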