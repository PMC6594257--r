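# Minimal European Data Format (EDF) reader/writer.
#
# Implements the plain EDF profile this package needs: one continuous
# multichannel trace, identical sampling rate on every signal, 1-second
# data records, 16-bit little-endian samples scaled between the declared
# digital and physical ranges.  EDF+ annotation channels and
# discontinuous files are out of scope.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width = 8L) {
  s <- sprintf("%.6g", x)
  if (nchar(s) > width) s <- sprintf("%.3g", x)
  if (nchar(s) > width) s <- sprintf("%.2g", x)
  edf_pad(s, width)
}

write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- rec$data
  n <- nrow(x)
  ns <- ncol(x)
  n_rec <- ceiling(n / fs)
  # per-channel symmetric physical range; digital range -32767..32767
  pmax <- apply(abs(x), 2L, max)
  pmax[pmax == 0] <- 1
  dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad(if (!is.null(rec$meta$animal)) rec$meta$animal else "X", 80L),
    # stash the exact sample count so a padded final record round-trips
    edf_pad(sprintf("NSAMP=%d", n), 80L),
    edf_pad("01.01.00", 8L),
    edf_pad("00.00.00", 8L),
    edf_pad(sprintf("%d", 256L * (ns + 1L)), 8L),
    edf_pad("", 44L),
    edf_pad(sprintf("%d", n_rec), 8L),
    edf_pad("1", 8L),
    edf_pad(sprintf("%d", ns), 4L))
  field <- function(f, width) paste(vapply(seq_len(ns), f, character(1L),
                                           USE.NAMES = FALSE), collapse = "")
  hdr <- paste0(hdr,
    field(function(i) edf_pad(rec$channels[i], 16L), 16L),
    field(function(i) edf_pad("", 80L), 80L),
    field(function(i) edf_pad("uV", 8L), 8L),
    field(function(i) edf_num(-pmax[i]), 8L),
    field(function(i) edf_num(pmax[i]), 8L),
    field(function(i) edf_pad("-32767", 8L), 8L),
    field(function(i) edf_pad("32767", 8L), 8L),
    field(function(i) edf_pad("", 80L), 80L),
    field(function(i) edf_pad(sprintf("%d", fs), 8L), 8L),
    field(function(i) edf_pad("", 32L), 32L))
  writeChar(hdr, con, eos = NULL)
  # digital conversion, channel-major within each 1 s record
  pad <- n_rec * fs - n
  for (r in seq_len(n_rec)) {
    i0 <- (r - 1L) * fs + 1L
    i1 <- min(r * fs, n)
    for (j in seq_len(ns)) {
      seg <- x[i0:i1, j]
      if (i1 - i0 + 1L < fs) seg <- c(seg, rep(0, fs - (i1 - i0 + 1L)))
      dig <- as.integer(round(seg / pmax[j] * dmax))
      dig[dig > dmax] <- dmax
      dig[dig < -dmax] <- -dmax
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8L)
  patient <- rd(80L)
  recid <- rd(80L)
  rd(8L); rd(8L)                       # start date/time
  rd(8L)                               # header bytes
  rd(44L)                              # reserved
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1L))
  for (i in seq_len(ns)) rd(80L)       # transducer
  for (i in seq_len(ns)) rd(8L)        # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1L))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1L))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1L))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1L))
  for (i in seq_len(ns)) rd(80L)       # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8L)), integer(1L))
  for (i in seq_len(ns)) rd(32L)
  if (length(unique(spr / rec_dur)) != 1L)
    stop("EDF reader supports a single common sampling rate only")
  fs <- spr[1L] / rec_dur
  total <- n_rec * sum(spr)
  raw <- readBin(con, integer(), n = total, size = 2L, endian = "little",
                 signed = TRUE)
  if (length(raw) < total) stop("EDF file truncated")
  x <- matrix(0, nrow = n_rec * spr[1L], ncol = ns)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      seg <- raw[(pos + 1L):(pos + spr[j])]
      pos <- pos + spr[j]
      x[((r - 1L) * spr[j] + 1L):(r * spr[j]), j] <-
        (seg - dmin[j]) * (pmax[j] - pmin[j]) / (dmax[j] - dmin[j]) + pmin[j]
    }
  }
  m <- regmatches(recid, regexec("NSAMP=([0-9]+)", recid))[[1L]]
  if (length(m) == 2L) {
    nkeep <- as.integer(m[2L])
    if (nkeep <= nrow(x)) x <- x[seq_len(nkeep), , drop = FALSE]
  }
  multichannel_recording(x, fs = fs, channels = labels,
                         meta = list(patient = patient))
}
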