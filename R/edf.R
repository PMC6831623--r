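# Minimal EDF (European Data Format) reader/writer: 16-bit samples,
# 1-second data records, one physical range per channel. The true sample
# count is stored in the recording-id header field so a zero-padded final
# record can be trimmed on read.

pad <- function(x, n) {
  s <- substr(format(x), 1, n)
  paste0(s, strrep(" ", n - nchar(s)))
}

#' Write a channels x samples matrix as EDF
#'
#' @param data channels x samples matrix (uV)
#' @param fs integer sampling rate
#' @param labels channel labels
#' @param path output path
#' @export
write_edf <- function(data, fs, labels, path) {
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  nc <- nrow(data); n <- ncol(data)
  nrec <- ceiling(n / fs)
  # symmetric physical range per channel, parsed back from its own ASCII
  # representation so the stored scaling is self-consistent; the parsed
  # value is guaranteed to cover the data range
  pm_str <- vapply(seq_len(nc), function(i) {
    mx <- max(abs(range(data[i, ])), 1e-6)
    cand <- mx * 1.001
    repeat {
      s <- trimws(format(signif(cand, 6), scientific = FALSE))
      if (nchar(s) <= 8 && as.numeric(s) >= mx) break
      cand <- cand * 1.01
    }
    pad(s, 8)
  }, "")
  pm <- as.numeric(pm_str)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeChar(pad(x, n), con, n, eos = NULL)
  wr("0", 8)
  wr("synthetic", 80)
  wr(sprintf("EEGTRACK n=%d", n), 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(format(256 * (1 + nc)), 8)
  wr("", 44)
  wr(format(nrec), 8)
  wr("1", 8)
  wr(format(nc), 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(nc)) wr("synthetic EEG", 80)
  for (i in seq_len(nc)) wr("uV", 8)
  for (i in seq_len(nc)) wr(paste0("-", trimws(pm_str[i])), 8)
  for (i in seq_len(nc)) wr(trimws(pm_str[i]), 8)
  for (i in seq_len(nc)) wr("-32768", 8)
  for (i in seq_len(nc)) wr("32767", 8)
  for (i in seq_len(nc)) wr("BP:1-50Hz", 80)
  for (i in seq_len(nc)) wr(format(fs), 8)
  for (i in seq_len(nc)) wr("", 32)
  padded <- cbind(data, matrix(0, nc, nrec * fs - n))
  # the EDF linear map: phys = dig * scale + offset with
  # scale = (pmax - pmin)/(dmax - dmin), offset = pmin - dmin * scale
  scale <- 2 * pm / 65535
  dig <- round((padded + pm) / scale) - 32768
  dig <- pmin(pmax(dig, -32768), 32767)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any 16-bit EDF with a
#' common sampling rate across channels)
#'
#' @param path EDF path
#' @return list with `data`, `fs`, `labels`
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80)
  recid <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  for (i in seq_len(nc)) rd(80)
  for (i in seq_len(nc)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(80)
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1)
    stopf("mixed per-channel sampling rates are not supported")
  fs <- spr[1] / dur
  data <- matrix(0, nc, nrec * spr[1])
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", nc * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      matrix(raw, nc, spr[1], byrow = TRUE)
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- data * scale + (pmin_ - dmin * scale)
  ntrue <- suppressWarnings(
    as.integer(sub("^EEGTRACK n=", "", recid)))
  if (!is.na(ntrue) && ntrue <= ncol(data))
    data <- data[, seq_len(ntrue), drop = FALSE]
  list(data = data, fs = fs, labels = labels)
}
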