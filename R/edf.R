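# Minimal EDF (European Data Format) reader/writer for continuous 16-bit
# recordings with one sampling rate shared by all signals. Covers the subset
# this package writes; the reader also handles multi-record files produced by
# other tools as long as rates agree across signals.

edf_fmt <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = -width)
}

# Format a physical bound into <= 8 ASCII chars, rounding outward so the
# written bound still covers the data.
edf_fmt_bound <- function(x, lower) {
  f <- if (lower) floor else ceiling
  v <- f(x * 100) / 100
  s <- formatC(v, format = "f", digits = 2)
  if (nchar(s) > 8) {
    v <- f(x)
    s <- formatC(v, format = "d")
  }
  if (nchar(s) > 8) abort_format("physical range too wide for EDF header")
  s
}

write_edf <- function(rec, path) {
  x <- rec$data
  ns <- nrow(x)
  n_samples <- ncol(x)
  fs <- rec$fs
  if (fs == round(fs) && n_samples %% fs == 0) {
    n_rec <- n_samples / fs
    rec_dur <- 1
    spr <- fs
  } else {
    n_rec <- 1
    rec_dur <- n_samples / fs
    spr <- n_samples
  }
  dmin <- -32767L
  dmax <- 32767L
  pmin_s <- vapply(seq_len(ns), function(i) edf_fmt_bound(min(x[i, ]) - 1e-9, TRUE), "")
  pmax_s <- vapply(seq_len(ns), function(i) edf_fmt_bound(max(x[i, ]) + 1e-9, FALSE), "")
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_fmt(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr("fbcsp recording", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(format(rec_dur, digits = 7), 8)
  wr(ns, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (s in pmin_s) wr(s, 8)
  for (s in pmax_s) wr(s, 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      d <- as.integer(round((x[i, idx] - pmin[i]) * scale[i]) + dmin)
      writeBin(d, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8) # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) abort_format("unreadable EDF header")
  if (is.na(header_bytes) || header_bytes != 256 + ns * 256) {
    abort_format("EDF header size field inconsistent with signal count")
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  if (any(labels == "")) abort_format("EDF signal with empty label")
  if (anyDuplicated(labels)) {
    abort_format(sprintf(
      "duplicate channel labels in EDF: %s",
      paste(unique(labels[duplicated(labels)]), collapse = ", ")
    ))
  }
  fs <- spr / rec_dur
  if (length(unique(fs)) != 1L) {
    abort_format("EDF signals with differing sampling rates are not supported")
  }
  fs <- fs[1]

  x <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(d) < spr[i]) abort_format("truncated EDF data record")
      x[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (d - dmin[i]) * scale[i] + pmin[i]
    }
  }
  recording(x, fs = fs, channel_labels = labels,
            subject_id = if (subject_id == "") "unknown" else subject_id)
}
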