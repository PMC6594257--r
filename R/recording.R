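#' Construct a multichannel recording
#'
#' The basic container consumed by every analysis stage: a continuous
#' multichannel voltage trace sampled at a fixed rate, with named channels.
#'
#' @param data numeric matrix, samples in rows, channels in columns
#'   (microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param channels character vector of unique channel labels; defaults to
#'   the column names of `data`.
#' @param meta named list of free-form metadata (animal id, group, week...).
#'
#' @return An object of class `multichannel_recording` with fields `data`,
#'   `fs`, `channels`, `meta`.
#' @export
multichannel_recording <- function(data, fs, channels = colnames(data),
                                   meta = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L)
    stop("'data' must be a numeric matrix with at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  if (is.null(channels))
    channels <- paste0("ch", seq_len(ncol(data)))
  channels <- as.character(channels)
  if (length(channels) != ncol(data))
    stop("number of channel labels does not match number of data columns")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  bad <- which(!is.finite(data))
  if (length(bad) > 0L) {
    idx <- bad[1L]
    stop(sprintf("non-finite sample at row %d, channel '%s'",
                 ((idx - 1L) %% nrow(data)) + 1L,
                 channels[((idx - 1L) %/% nrow(data)) + 1L]))
  }
  colnames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels, meta = meta),
            class = "multichannel_recording")
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("<multichannel_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples and duration of a recording
#'
#' @param rec a [multichannel_recording()].
#' @return `n_samples()` the number of rows; `duration()` seconds.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' @rdname n_samples
#' @export
duration <- function(rec) nrow(rec$data) / rec$fs

#' Construct an epoch set
#'
#' @param epochs list of equal-dimension numeric matrices
#'   (samples x channels).
#' @param fs sampling rate (Hz).
#' @param channels channel labels.
#' @param epoch_len_s epoch length in seconds.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, channels, epoch_len_s) {
  if (!is.list(epochs) || length(epochs) < 1L)
    stop("'epochs' must be a non-empty list of matrices")
  len <- nrow(epochs[[1L]])
  ok <- vapply(epochs, function(e) is.matrix(e) && nrow(e) == len &&
                 ncol(e) == length(channels), logical(1L))
  if (!all(ok)) stop("all epochs must be matrices of identical dimensions")
  if (abs(epoch_len_s * fs - len) > 1e-8)
    stop("epoch_len_s * fs must equal the epoch sample count")
  structure(list(epochs = epochs, fs = fs, channels = channels,
                 epoch_len_s = epoch_len_s),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %g s x %d channels @ %g Hz\n",
              length(x$epochs), x$epoch_len_s, length(x$channels), x$fs))
  invisible(x)
}

#' Slice a recording into fixed-length epochs
#'
#' Windows of `epoch_len_s` seconds are taken every `step_s` seconds from
#' the start of the recording; the number of epochs is
#' `floor((n_samples - epoch_len) / step) + 1`.
#'
#' @param rec a [multichannel_recording()].
#' @param epoch_len_s epoch length in seconds; `epoch_len_s * fs` must be
#'   an integer.
#' @param step_s step between epoch starts in seconds (default:
#'   non-overlapping).
#' @return An [epoch_set()].  The sample index of each epoch start is kept
#'   in attribute `starts` (1-based, into the original recording).
#' @export
slice_epochs <- function(rec, epoch_len_s = 8, step_s = epoch_len_s) {
  stopifnot(inherits(rec, "multichannel_recording"))
  len <- epoch_len_s * rec$fs
  if (abs(len - round(len)) > 1e-8)
    stop("epoch_len_s * fs must be an integer number of samples")
  len <- as.integer(round(len))
  step <- step_s * rec$fs
  if (step <= 0) stop("step_s must be positive")
  step <- as.integer(round(step))
  n <- nrow(rec$data)
  if (n < len)
    stop(sprintf("recording (%d samples) shorter than one epoch (%d samples)",
                 n, len))
  n_epochs <- (n - len) %/% step + 1L
  starts <- 1L + (seq_len(n_epochs) - 1L) * step
  epochs <- lapply(starts, function(s) rec$data[s:(s + len - 1L), , drop = FALSE])
  out <- epoch_set(epochs, rec$fs, rec$channels, epoch_len_s)
  attr(out, "starts") <- starts
  out
}
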