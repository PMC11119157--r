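# Minimal EDF (European Data Format) reader/writer.  EDF is a fixed-layout
# ASCII-header format with 16-bit little-endian samples, scaled per channel
# by a physical/digital calibration; this implements the vanilla continuous
# dialect (no EDF+ annotations).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)  # left-justified, space padded
}

#' Write one trial to an EDF file
#'
#' Samples are quantized to 16 bits over each channel's observed amplitude
#' range (the format's native resolution), so a round trip preserves data to
#' about 1/65000 of the per-channel range.
#'
#' @param trial an [eeg_trial()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(trial, path) {
  stopifnot(inherits(trial, "eeg_trial"))
  C <- n_channels(trial); T_len <- n_samples(trial)
  fs <- trial$fs
  # one-second records when fs divides T, else a single record
  if (abs(fs - round(fs)) < 1e-9 && T_len %% round(fs) == 0) {
    spr <- as.integer(round(fs)); n_rec <- T_len %/% spr; rec_dur <- 1
  } else {
    spr <- T_len; n_rec <- 1L; rec_dur <- T_len / fs
  }
  pmin <- apply(trial$data, 1L, min); pmax <- apply(trial$data, 1L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb"); on.exit(close(con))
  hdr_bytes <- 256L + 256L * C
  hdr <- paste0(
    edf_pad("0", 8L), edf_pad(trial$trial_id, 80L), edf_pad("emognn", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(hdr_bytes, 8L), edf_pad("", 44L),
    edf_pad(n_rec, 8L), edf_pad(format(rec_dur, digits = 7), 8L),
    edf_pad(C, 4L))
  field <- function(vals, width)
    paste(vapply(vals, edf_pad, "", width = width), collapse = "")
  hdr <- paste0(hdr,
    field(trial$channels, 16L), field(rep("", C), 80L),
    field(rep("uV", C), 8L),
    field(format(pmin, digits = 7), 8L), field(format(pmax, digits = 7), 8L),
    field(rep(dmin, C), 8L), field(rep(dmax, C), 8L),
    field(rep("", C), 80L), field(rep(spr, C), 8L), field(rep("", C), 32L))
  writeChar(hdr, con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round((trial$data - pmin) * scale + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file as a trial
#'
#' All channels must share one sampling rate.  The trial id defaults to the
#' file's base name; the class label is left unset (labels live in the
#' dataset manifest, see [load_eeg_dataset()]).
#'
#' @param path an EDF file.
#' @return An [eeg_trial()] with `label = NA`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8L)                       # version
  patient <- trimws(rd(80L)); rd(80L); rd(8L); rd(8L)
  rd(8L); rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  C <- as.integer(rd(4L))
  rdv <- function(width) {
    vapply(seq_len(C), function(i) trimws(rd(width)), "")
  }
  channels <- rdv(16L); rdv(80L); rdv(8L)
  pmin <- as.numeric(rdv(8L)); pmax <- as.numeric(rdv(8L))
  dmin <- as.numeric(rdv(8L)); dmax <- as.numeric(rdv(8L))
  rdv(80L)
  spr <- as.integer(rdv(8L)); rdv(32L)
  if (length(unique(spr)) != 1L)
    stop("EDF file mixes sampling rates across channels")
  spr1 <- spr[1L]
  fs <- spr1 / rec_dur
  dat <- matrix(0, nrow = C, ncol = n_rec * spr1)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = C * spr1, size = 2L, signed = TRUE,
                   endian = "little")
    dat[, ((r - 1L) * spr1 + 1L):(r * spr1)] <-
      matrix(raw, nrow = C, byrow = TRUE)
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  dat <- dat * gain + (pmin - dmin * gain)
  tid <- if (nzchar(patient)) patient else sub("\\.edf$", "", basename(path),
                                              ignore.case = TRUE)
  eeg_trial(dat, fs = fs, channels = channels, label = NA_character_,
            trial_id = tid)
}

#' Save a dataset as EDF files plus a label manifest
#'
#' Writes one `<trial_id>.edf` per trial into `dir` together with
#' `labels.csv` (columns `trial_id,label`).
#'
#' @param trials list of [eeg_trial()] objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_eeg_dataset <- function(trials, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- vapply(trials, function(tr) tr$trial_id, "")
  if (anyDuplicated(ids)) stop("trial ids must be unique")
  for (tr in trials) write_edf(tr, file.path(dir, paste0(tr$trial_id, ".edf")))
  manifest <- data.frame(trial_id = ids,
                         label = vapply(trials, function(tr) tr$label, ""))
  utils::write.csv(manifest, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a dataset from EDF files plus a label manifest
#'
#' @param dir directory of `.edf` files.
#' @param manifest path to the label manifest CSV (columns
#'   `trial_id,label`); defaults to `labels.csv` inside `dir`.
#' @return A list of labelled [eeg_trial()] objects, in manifest order.
#' @export
load_eeg_dataset <- function(dir, manifest = file.path(dir, "labels.csv")) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("trial_id", "label") %in% names(man)))
    stop("manifest must have columns trial_id,label")
  files <- file.path(dir, paste0(man$trial_id, ".edf"))
  missing <- man$trial_id[!file.exists(files)]
  if (length(missing))
    stop("manifest lists unknown trial id(s): ",
         paste(missing, collapse = ", "))
  on_disk <- sub("\\.edf$", "", list.files(dir, pattern = "\\.edf$",
                                           ignore.case = TRUE))
  unlabelled <- setdiff(on_disk, man$trial_id)
  if (length(unlabelled))
    stop("missing label for trial(s): ", paste(unlabelled, collapse = ", "))
  trials <- lapply(seq_len(nrow(man)), function(i) {
    tr <- read_edf(files[i])
    tr$trial_id <- man$trial_id[i]
    tr$label <- as.character(man$label[i])
    tr
  })
  fss <- vapply(trials, function(tr) tr$fs, 0)
  if (length(unique(fss)) != 1L)
    stop("sampling rate differs across trials: ",
         paste(unique(fss), collapse = ", "), " Hz")
  trials
}
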