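edf_num <- function(x, width = 8) {
  s <- formatC(x, width = width, format = "g", digits = 6)
  s <- gsub(" ", "", s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

edf_str <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as EDF+ (European Data Format)
#'
#' Stores the 14 data channels (microvolts), the per-channel quality series
#' as auxiliary 1 Hz channels `CQ_<label>` / `EQ_<label>` (EDF has no native
#' quality field; this dialect is documented and understood by [read_edf()]),
#' and the four event markers as EDF+ annotations (`Event <k>`). Samples are
#' quantised to the 16-bit EDF integer range over each channel's physical
#' span, so a write/read round trip preserves values to within one
#' quantisation step.
#'
#' @param recording An `eeg_recording` whose length is a whole number of
#'   seconds.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  n_samp <- ncol(recording$data)
  if (n_samp %% fs != 0)
    abort("EDF export needs a whole number of 1 s records.",
          class = "neuroplay_format_error")
  n_rec <- n_samp / fs
  labels <- rownames(recording$data)
  n_ch <- nrow(recording$data)
  q_secs <- ncol(recording$quality$cq)
  if (q_secs < n_rec)
    abort("Quality series shorter than the recording.",
          class = "neuroplay_format_error")

  # annotation payload: one timestamp TAL per record, events in record 1
  ev <- recording$events
  ev_tals <- sprintf("+%g\x15%g\x14Event %d\x14",
                     (ev$onset - 1) / fs, ev$n_samples / fs, ev$event)
  rec_tals <- lapply(seq_len(n_rec) - 1, function(t) {
    s <- sprintf("+%d\x14\x14", t)
    if (t == 0) s <- paste0(s, paste(ev_tals, collapse = ""))
    s
  })
  ann_bytes <- max(vapply(rec_tals, nchar, integer(1))) + 2
  ann_bytes <- ann_bytes + (ann_bytes %% 2)
  ann_ns <- ann_bytes / 2

  sig_labels <- c(labels, paste0("CQ_", labels), paste0("EQ_", labels),
                  "EDF Annotations")
  n_sig <- length(sig_labels)
  pmin_ <- c(apply(recording$data, 1, min), rep(0, 2 * n_ch), -1)
  pmax_ <- c(apply(recording$data, 1, max), rep(100, 2 * n_ch), 1)
  flat <- pmax_ <= pmin_
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  spr <- c(rep(fs, n_ch), rep(1, 2 * n_ch), ann_ns)
  units <- c(rep("uV", n_ch), rep("%", 2 * n_ch), "")

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256 + 256 * n_sig
  writeChar(paste0(
    edf_str("0", 8), edf_str("X X X X", 80),
    edf_str("Startdate 01-JAN-2000 X X X", 80),
    "01.01.00", "00.00.00",
    edf_str(as.character(hdr_bytes), 8), edf_str("EDF+C", 44),
    edf_str(as.character(n_rec), 8), edf_str("1", 8),
    edf_str(as.character(n_sig), 4)), con, eos = NULL)
  field <- function(f, w) writeChar(paste(vapply(f, edf_str, "", width = w),
                                          collapse = ""), con, eos = NULL)
  field(sig_labels, 16)
  field(rep("", n_sig), 80)
  field(units, 8)
  writeChar(paste(vapply(pmin_, edf_num, ""), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(pmax_, edf_num, ""), collapse = ""), con, eos = NULL)
  field(rep("-32768", n_sig), 8)
  field(rep("32767", n_sig), 8)
  field(rep("", n_sig), 80)
  field(as.character(spr), 8)
  field(rep("", n_sig), 32)

  # re-read the physical extrema exactly as truncated into the header,
  # so quantisation uses the values a reader will see
  pmin_h <- as.numeric(vapply(pmin_, edf_num, ""))
  pmax_h <- as.numeric(vapply(pmax_, edf_num, ""))
  quant <- function(x, lo, hi) {
    d <- round((x - lo) / (hi - lo) * 65535 - 32768)
    as.integer(pmin(32767, pmax(-32768, d)))
  }
  for (r in seq_len(n_rec)) {
    t0 <- (r - 1) * fs
    for (ch in seq_len(n_ch))
      writeBin(quant(recording$data[ch, (t0 + 1):(t0 + fs)],
                     pmin_h[ch], pmax_h[ch]), con, size = 2, endian = "little")
    for (ch in seq_len(n_ch))
      writeBin(quant(recording$quality$cq[ch, r], 0, 100), con,
               size = 2, endian = "little")
    for (ch in seq_len(n_ch))
      writeBin(quant(recording$quality$eq[ch, r], 0, 100), con,
               size = 2, endian = "little")
    tal <- rec_tals[[r]]
    raw_tal <- c(charToRaw(tal), raw(ann_bytes - nchar(tal)))
    writeBin(raw_tal, con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ recording written in this package's dialect
#'
#' Expects the 14 montage data channels, optional `CQ_`/`EQ_` quality
#' channels and an EDF+ annotation channel carrying `Event <k>` markers.
#'
#' @param path EDF file path.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    trimws(s)
  }
  rd(8)               # version
  rd(80); rd(80); rd(8); rd(8); rd(8)
  rd(44)              # reserved (EDF+C)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_sig <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(n_sig) || n_sig < 1)
    abort("Malformed EDF header.", class = "neuroplay_format_error")
  sig_labels <- vapply(seq_len(n_sig), function(i) rd(16), "")
  for (i in seq_len(n_sig)) rd(80)
  for (i in seq_len(n_sig)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  for (i in seq_len(n_sig)) rd(80)
  spr <- as.integer(vapply(seq_len(n_sig), function(i) rd(8), ""))
  for (i in seq_len(n_sig)) rd(32)

  is_ann <- sig_labels == "EDF Annotations"
  is_cq <- startsWith(sig_labels, "CQ_")
  is_eq <- startsWith(sig_labels, "EQ_")
  data_idx <- which(!is_ann & !is_cq & !is_eq)
  montage <- emotiv_montage()
  if (!setequal(sig_labels[data_idx], montage$label))
    abort("EDF channels do not match the 14-electrode montage.",
          class = "neuroplay_format_error")

  vals <- lapply(seq_len(n_sig), function(i)
    matrix(0L, nrow = spr[i], ncol = n_rec))
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_sig)) {
      if (is_ann[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", spr[i] * 2))
      } else {
        vals[[i]][, r] <- readBin(con, "integer", spr[i], size = 2,
                                  signed = TRUE, endian = "little")
      }
    }
  }
  phys <- function(i) {
    v <- as.numeric(vals[[i]])
    (v - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) + pmin_[i]
  }
  fs <- spr[data_idx[1]] / rec_dur
  ord <- match(montage$label, sig_labels[data_idx])
  data <- do.call(rbind, lapply(data_idx[ord], phys))
  rownames(data) <- montage$label
  qmat <- function(prefix, idx) {
    if (!any(idx)) return(NULL)
    lab <- sub(paste0("^", prefix, "_"), "", sig_labels[idx])
    m <- do.call(rbind, lapply(which(idx)[match(montage$label, lab)], phys))
    rownames(m) <- montage$label
    m
  }
  cq <- qmat("CQ", is_cq); eq <- qmat("EQ", is_eq)

  txt <- rawToChar(ann_raw[ann_raw != as.raw(0)])
  tals <- strsplit(txt, "\x14\\+", fixed = FALSE)[[1]]
  ev_pat <- "\\+?([0-9.]+)\x15([0-9.]+)\x14Event ([0-9]+)"
  mm <- regmatches(txt, gregexpr(ev_pat, txt))[[1]]
  events <- purrr::map_dfr(mm, function(s) {
    g <- regmatches(s, regexec(ev_pat, s))[[1]]
    tibble(event = as.integer(g[4]),
           onset = as.integer(round(as.numeric(g[2]) * fs)) + 1L,
           n_samples = as.integer(round(as.numeric(g[3]) * fs)))
  })
  if (nrow(events) > 0) {
    events$label <- c("eyes_open", "eyes_closed", "lecture",
                      "play")[events$event]
    events <- arrange(events, .data$event) |>
      select("event", "label", "onset", "n_samples")
  }
  structure(list(data = data, sampling_rate = fs, montage = montage,
                 quality = list(cq = cq, eq = eq), events = events),
            class = "eeg_recording")
}

#' CSV interchange for recordings
#'
#' Writes (or reads) a recording as a directory of plain-text tables:
#' `data.csv` (samples x channels), `quality_cq.csv` / `quality_eq.csv`
#' (seconds x channels), `events.csv` and `meta.yaml` (sampling rate).
#' Doubles are written in shortest round-trip representation, so the CSV
#' round trip is bit-exact.
#'
#' @param recording An `eeg_recording`.
#' @param dir Directory to create/read.
#' @return `dir` (write) or an `eeg_recording` (read).
#' @export
write_recording_csv <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  full <- function(m) {
    # %.17g round-trips IEEE doubles exactly through text
    out <- as_tibble(matrix(sprintf("%.17g", t(m)), ncol = nrow(m),
                            dimnames = list(NULL, rownames(m))),
                     .name_repair = "minimal")
    out
  }
  readr::write_csv(full(recording$data), file.path(dir, "data.csv"))
  readr::write_csv(full(recording$quality$cq),
                   file.path(dir, "quality_cq.csv"))
  readr::write_csv(full(recording$quality$eq),
                   file.path(dir, "quality_eq.csv"))
  readr::write_csv(recording$events, file.path(dir, "events.csv"))
  yaml::write_yaml(list(sampling_rate = recording$sampling_rate),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  rdm <- function(f) {
    d <- readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
    m <- t(vapply(d, as.numeric, numeric(nrow(d))))
    m
  }
  data <- rdm("data.csv")
  montage <- emotiv_montage()
  if (!setequal(rownames(data), montage$label))
    abort("CSV channels do not match the 14-electrode montage.",
          class = "neuroplay_format_error")
  data <- data[montage$label, , drop = FALSE]
  structure(list(data = data, sampling_rate = meta$sampling_rate,
                 montage = montage,
                 quality = list(cq = rdm("quality_cq.csv")[montage$label, ,
                                                           drop = FALSE],
                                eq = rdm("quality_eq.csv")[montage$label, ,
                                                           drop = FALSE]),
                 events = readr::read_csv(file.path(dir, "events.csv"),
                                          show_col_types = FALSE)),
            class = "eeg_recording")
}
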