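#' Read a multichannel recording from disk
#'
#' Two on-disk representations are supported: European Data Format
#' (`format = "edf"`, 16-bit, the realistic acquisition format) and a
#' plain-text delimited format (`format = "csv"`) used for inspectable
#' fixtures.  The delimited dialect is comma-separated with one header row
#' of channel labels, preceded by a sidecar comment line `# fs=<Hz>`; if
#' the sidecar line is absent the sampling rate must be supplied via `fs`.
#'
#' @param path file to read.
#' @param format `"edf"`, `"csv"`, or `"auto"` (default; decided by file
#'   extension).
#' @param fs sampling rate override for delimited files without a sidecar
#'   line.
#' @return A [multichannel_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(read_edf(path))
  read_recording_csv(path, fs = fs)
}

#' Write a multichannel recording to disk
#'
#' The delimited format round-trips exactly; EDF stores 16-bit integers
#' scaled to the per-channel physical range, so the round-trip error is
#' bounded by `range / 2^15`.
#'
#' @param rec a [multichannel_recording()].
#' @param path destination file.
#' @param format `"edf"`, `"csv"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv")) {
  stopifnot(inherits(rec, "multichannel_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(invisible(write_edf(rec, path)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  writeLines(paste(rec$channels, collapse = ","), con)
  write.table(rec$data, con, sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_recording_csv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#", first)) {
    skip <- 1L
    m <- regmatches(first, regexec("fs\\s*=\\s*([0-9.eE+-]+)", first))[[1L]]
    if (length(m) == 2L) fs <- as.numeric(m[2L])
  }
  if (is.null(fs))
    stop("sampling rate not found: no '# fs=' sidecar line and no 'fs' argument")
  df <- read.csv(path, skip = skip, header = TRUE, check.names = FALSE)
  if (ncol(df) < 1L || nrow(df) < 1L) stop("delimited file has no data")
  labels <- names(df)
  if (any(labels == "" | is.na(labels))) stop("missing channel label in header")
  if (anyDuplicated(labels)) stop("duplicate channel labels in header")
  data <- as.matrix(df)
  if (!is.numeric(data)) stop("non-numeric values in delimited recording")
  multichannel_recording(data, fs = fs, channels = labels)
}
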