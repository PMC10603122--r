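# Minimal EDF (European Data Format) writer/reader: 16-bit integer samples,
# 1-second data records, one physical range per channel. Covers what the
# pipeline needs (multichannel uniform-rate biosignals with labels and
# units); no annotations / EDF+ features.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' @param rec a [recording]; the sampling rate must be a whole number so that
#'   1-second data records hold an integer number of samples.
#' @param path output file path.
#' @param patient,recording_id header strings.
#' @return the path, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "synthetic") {
  assert_that(inherits(rec, "recording"), "rec must be a recording")
  srate <- rec$srate
  assert_that(abs(srate - round(srate)) < 1e-9, "integer sampling rate required")
  srate <- round(srate)
  ns <- ncol(rec$data)
  n_rec <- floor(nrow(rec$data) / srate)
  assert_that(n_rec >= 1, "recording shorter than one 1-s data record")
  x <- rec$data[seq_len(n_rec * srate), , drop = FALSE]
  pmin <- apply(x, 2, min); pmax <- apply(x, 2, max)
  same <- pmax - pmin < 1e-12
  pmin[same] <- pmin[same] - 1; pmax[same] <- pmax[same] + 1
  dmin <- -32768; dmax <- 32767
  dig <- round(sweep(sweep(x, 2, pmin), 2, (pmax - pmin) / (dmax - dmin), "/")) + dmin
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad_field(s, w), con, eos = NULL)
  wr("0", 8); wr(patient, 80); wr(recording_id, 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (i in seq_len(ns)) wr(paste(rec$channels[i]), 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (i in seq_len(ns)) wr(rec$units, 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", pmin[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", pmax[i]), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(srate, 8)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * srate + 1):(r * srate)
    for (i in seq_len(ns))
      writeBin(as.integer(dig[rows, i]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return a [recording] (values reconstructed from the stored physical
#'   ranges; quantization error is bounded by range / 65535).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  assert_that(length(n_rec) == 1 && is.finite(n_rec) && n_rec > 0 &&
                length(ns) == 1 && is.finite(ns) && ns > 0 &&
                is.finite(rec_dur) && rec_dur > 0,
              "corrupt or unsupported EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  assert_that(length(unique(spr)) == 1, "per-channel rates must match")
  out <- matrix(0, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      out[rows, i] <- pmin[i] + (d - dmin[i]) *
        (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    }
  }
  recording(out, spr[1] / rec_dur, labels, units[1])
}

#' Write / read an event stream as a tab-separated table
#'
#' Columns `onset_s`, `duration_s`, `label`.
#'
#' @param events event data.frame.
#' @param path file path.
#' @return `read_events` returns the data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
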