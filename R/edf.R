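#' Minimal EDF (European Data Format) reader and writer
#'
#' Implements the EDF subset this package needs: one-second data records,
#' 16-bit little-endian samples, per-signal sampling rates (so the 10 Hz
#' stimulation/truth traces coexist with 2048 Hz signals in one file).
#' Physical scaling is symmetric about zero per channel; the quantization
#' step is `phys_max / 32767`. Sessions must span a whole number of
#' seconds (EDF records are fixed-duration).
#'
#' `channels` is a list of `list(label, samples, rate, unit)`.
#'
#' @param channels list of channel descriptors (see Details).
#' @param path output file.
#' @return `write_edf` returns `path` invisibly; `read_edf` returns a list
#'   of channel descriptors with an added `phys_max` field.
#' @keywords internal
#' @export
write_edf <- function(channels, path) {
  if (!length(channels)) tl_stop("invalid-session", "no channels")
  rates <- vapply(channels, `[[`, 0, "rate")
  durs <- vapply(channels, function(ch) length(ch$samples) / ch$rate, 0)
  if (max(durs) - min(durs) > 1e-9)
    tl_stop("invalid-session", "channels span different durations")
  dur <- durs[1]
  if (abs(dur - round(dur)) > 1e-9)
    tl_stop("invalid-session", "EDF sessions must span whole seconds")
  n_rec <- as.integer(round(dur))
  if (n_rec < 1) tl_stop("invalid-session", "zero-length session")
  spr <- as.integer(round(rates))        # samples per (1 s) record
  if (any(abs(rates - spr) > 1e-9))
    tl_stop("invalid-session", "EDF requires integer samples per second")
  ns <- length(channels)

  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    paste0(x, strrep(" ", w - nchar(x)))
  }
  # symmetric physical range; reparse the 8-char header string so that
  # writer and reader use the identical scale (quantization bound exact)
  pm_str <- character(ns); pm <- numeric(ns)
  for (i in seq_len(ns)) {
    m <- max(abs(channels[[i]]$samples), na.rm = TRUE)
    if (!is.finite(m) || m == 0) m <- 1
    s <- sprintf("%.6g", m)
    if (nchar(s) > 8) s <- sprintf("%.2e", m)
    pm_str[i] <- s
    pm[i] <- as.numeric(s)
    if (pm[i] < m) { # never clip: bump the parsed value up if rounding shrank it
      s <- sprintf("%.6g", m * 1.001)
      if (nchar(s) > 8) s <- sprintf("%.3e", m * 1.001)
      pm_str[i] <- s; pm[i] <- as.numeric(s)
    }
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(pad("0", 8))
  wr(pad("X X X X", 80))
  wr(pad("Startdate 01-JAN-2000 X X X", 80))
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 * (ns + 1), 8))
  wr(pad("", 44))
  wr(pad(n_rec, 8))
  wr(pad("1", 8))
  wr(pad(ns, 4))
  for (ch in channels) wr(pad(ch$label, 16))
  for (ch in channels) wr(pad("", 80))
  for (ch in channels) wr(pad(if (is.null(ch$unit)) "" else ch$unit, 8))
  for (i in seq_len(ns)) wr(pad(paste0("-", pm_str[i]), 8))
  for (i in seq_len(ns)) wr(pad(pm_str[i], 8))
  for (i in seq_len(ns)) wr(pad("-32767", 8))
  for (i in seq_len(ns)) wr(pad("32767", 8))
  for (ch in channels) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad(spr[i], 8))
  for (ch in channels) wr(pad("", 32))

  dig <- vector("list", ns)
  for (i in seq_len(ns))
    dig[[i]] <- as.integer(pmax(-32767, pmin(32767,
      round(channels[[i]]$samples / pm[i] * 32767))))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                              # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)      # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)      # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw[[i]][[r]] <- readBin(con, "integer", n = spr[i], size = 2,
                               signed = TRUE, endian = "little")
    }
  }
  lapply(seq_len(ns), function(i) {
    d <- unlist(raw[[i]])
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    list(label = labels[i],
         samples = phys_min[i] + (d - dig_min[i]) * scale,
         rate = spr[i] / rec_dur, unit = units[i],
         phys_max = phys_max[i])
  })
}
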