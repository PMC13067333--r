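# Recording writers/readers: BrainVision (.vhdr/.vmrk/.eeg, INT_16 with a
# per-channel microvolt resolution field) and plain EDF (16-bit, 1 s records;
# markers travel in the TSV events sidecar, which is written for both
# formats).

.events_sidecar <- function(path) paste0(tools::file_path_sans_ext(path),
                                         "_events.tsv")

#' Write the events sidecar (onset_sample, duration_sample, label)
#' @param markers marker `data.frame` (`sample`, `label`, optional
#'   `trial_id`).
#' @param path path of the recording file the sidecar belongs to.
#' @export
write_events_tsv <- function(markers, path) {
  d <- data.frame(onset_sample = markers$sample, duration_sample = 0L,
                  label = markers$label,
                  trial_id = markers$trial_id %||% NA_integer_)
  write.table(d, .events_sidecar(path), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

.read_events_tsv <- function(path) {
  f <- .events_sidecar(path)
  if (!file.exists(f)) return(NULL)
  d <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  data.frame(sample = d$onset_sample, label = d$label,
             trial_id = d$trial_id)
}

.write_brainvision <- function(rec, base) {
  vhdr <- paste0(base, ".vhdr"); vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  nch <- nrow(rec$signal)
  labels <- rownames(rec$signal) %||% paste0("Ch", seq_len(nch))
  res <- pmax(apply(abs(rec$signal), 1, max), 1e-6) / 32000
  hdr <- c("BrainVision Data Exchange Header File Version 1.0", "",
           "[Common Infos]", "Codepage=UTF-8",
           sprintf("DataFile=%s", basename(eeg)),
           sprintf("MarkerFile=%s", basename(vmrk)),
           "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
           sprintf("NumberOfChannels=%d", nch),
           sprintf("SamplingInterval=%.6f", 1e6 / rec$fs), "",
           "[Binary Infos]", "BinaryFormat=INT_16", "",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,%.10g,µV", seq_len(nch), labels, res))
  writeLines(hdr, vhdr, useBytes = TRUE)
  q <- round(rec$signal / res) # rows scaled by channel resolution
  q <- pmax(pmin(q, 32767), -32768)
  con <- file(eeg, "wb")
  writeBin(as.integer(q), con, size = 2, endian = "little")
  close(con)
  mk <- c("BrainVision Data Exchange Marker File, Version 1.0", "",
          "[Common Infos]", "Codepage=UTF-8",
          sprintf("DataFile=%s", basename(eeg)), "",
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0",
          sprintf("Mk%d=Stimulus,%s,%d,1,0",
                  seq_len(nrow(rec$markers)) + 1,
                  rec$markers$label, rec$markers$sample))
  writeLines(mk, vmrk, useBytes = TRUE)
  write_events_tsv(rec$markers, vhdr)
  vhdr
}

.ini_value <- function(lines, key) {
  m <- grep(paste0("^", key, "="), lines, value = TRUE)
  if (!length(m)) stopf("missing header field %s", key)
  sub(paste0("^", key, "="), "", m[1])
}

.read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, encoding = "UTF-8")
  nch <- as.integer(.ini_value(lines, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(.ini_value(lines, "SamplingInterval"))
  if (.ini_value(lines, "BinaryFormat") != "INT_16")
    stopf("only INT_16 BrainVision data supported")
  chl <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", chl), ",")
  labels <- vapply(parts, `[`, "", 1)
  res <- as.numeric(vapply(parts, `[`, "", 3))
  eeg <- file.path(dirname(vhdr), .ini_value(lines, "DataFile"))
  n <- file.info(eeg)$size / 2
  con <- file(eeg, "rb")
  q <- readBin(con, "integer", n = n, size = 2, endian = "little")
  close(con)
  sig <- matrix(q, nrow = nch) * res
  rownames(sig) <- labels
  vmrk <- file.path(dirname(vhdr), .ini_value(lines, "MarkerFile"))
  ml <- grep("^Mk[0-9]+=", readLines(vmrk, encoding = "UTF-8"), value = TRUE)
  mp <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
  keep <- vapply(mp, `[`, "", 1) == "Stimulus"
  markers <- data.frame(sample = as.integer(vapply(mp[keep], `[`, "", 3)),
                        label = vapply(mp[keep], `[`, "", 2))
  side <- .read_events_tsv(vhdr)
  if (!is.null(side) && nrow(side) == nrow(markers))
    markers$trial_id <- side$trial_id
  structure(list(signal = sig, fs = fs, markers = markers, layout = NULL,
                 truth = NULL, schedule = NULL),
            class = "tp_recording")
}

.pad_field <- function(x, width) {
  s <- substr(format(x, scientific = FALSE, trim = TRUE), 1, width)
  formatC(s, width = width, flag = "-")
}

.write_edf <- function(rec, path) {
  nch <- nrow(rec$signal)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stopf("EDF writer needs an integer Hz rate")
  labels <- rownames(rec$signal) %||% paste0("Ch", seq_len(nch))
  nrec <- ceiling(ncol(rec$signal) / fs)
  pm <- pmax(apply(abs(rec$signal), 1, max), 1e-6) * 1.0001
  con <- file(path, "wb")
  wr <- function(x, w) writeChar(paste0(.pad_field(x, w), collapse = ""), con,
                                 eos = NULL)
  wr("0", 8); wr("tpeeg synthetic subject", 80); wr("tpeeg recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(256 * (1 + nch)), 8); wr("", 44)
  wr(as.character(nrec), 8); wr("1", 8); wr(as.character(nch), 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(nch)) wr("simulated EEG", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(sprintf("%.6g", -pm[i]), 8)
  for (i in seq_len(nch)) wr(sprintf("%.6g", pm[i]), 8)
  for (i in seq_len(nch)) wr("-32768", 8)
  for (i in seq_len(nch)) wr("32767", 8)
  for (i in seq_len(nch)) wr("HP:0.0Hz", 80)
  for (i in seq_len(nch)) wr(as.character(fs), 8)
  for (i in seq_len(nch)) wr("", 32)
  padded <- cbind(rec$signal,
                  matrix(0, nch, nrec * fs - ncol(rec$signal)))
  for (r in seq_len(nrec)) {
    seg <- padded[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    for (i in seq_len(nch)) {
      # encode against the declared physical/digital ranges so the reader's
      # linear decode inverts exactly (within half a quantization step)
      dig <- as.integer(round((seg[i, ] + pm[i]) / (2 * pm[i]) * 65535)) -
        32768L
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  close(con)
  write_events_tsv(rec$markers, path)
  path
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8)); dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  sig <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (i in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      sig[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin_[i] + (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i])
    }
  }
  close(con)
  rownames(sig) <- labels
  structure(list(signal = sig, fs = spr[1] / dur,
                 markers = .read_events_tsv(path), layout = NULL,
                 truth = NULL, schedule = NULL),
            class = "tp_recording")
}

#' Write a recording to a standard EEG format
#'
#' BrainVision writes the `.vhdr/.vmrk/.eeg` triplet (INT_16, per-channel
#' microvolt resolution in the header, markers in the `.vmrk`); EDF writes a
#' plain 16-bit EDF with 1 s records (the trailing record is zero-padded).
#' Both also emit a tab-separated events sidecar
#' (`onset_sample`, `duration_sample`, `label`).
#'
#' @param rec a `tp_recording`.
#' @param path output path: base name (BrainVision, extensions added) or
#'   `.edf` file.
#' @param format `"brainvision"` or `"edf"`.
#' @return the path of the written header/file.
#' @export
write_recording <- function(rec, path, format = c("brainvision", "edf")) {
  format <- match.arg(format)
  if (format == "brainvision")
    .write_brainvision(rec, sub("\\.vhdr$", "", path))
  else
    .write_edf(rec, if (grepl("\\.edf$", path)) path else paste0(path, ".edf"))
}

#' Read a recording written by [write_recording()]
#'
#' The simulation ground truth is not part of either format, so the returned
#' recording carries signal, sampling rate and markers only.
#'
#' @param path a `.vhdr` or `.edf` file.
#' @return a `tp_recording` (truth absent).
#' @export
read_recording <- function(path) {
  if (grepl("\\.vhdr$", path)) .read_brainvision(path)
  else if (grepl("\\.edf$", path)) .read_edf(path)
  else stopf("unknown recording format: %s", path)
}
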