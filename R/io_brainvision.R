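#' Read an EEG recording from disk
#'
#' Supports BrainVision (`.vhdr` + `.eeg`, binary `IEEE_FLOAT_32` or
#' `INT_16`, multiplexed or vectorized) and EDF. Samples are returned in
#' microvolts; channels keep header order. The reference annotation is taken
#' from the header when present (BrainVision `Reference` comment field) and
#' defaults to `"Cz"`.
#'
#' @param path path to the `.vhdr` (BrainVision) or `.edf` file.
#' @param format `"brainvision"` or `"edf"`; inferred from the file
#'   extension by default.
#' @param blocks optional block table to attach (see [eeg_recording()]).
#' @param subject_id optional subject identifier.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "brainvision", "edf"),
                           blocks = NULL, subject_id = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     vhdr = "brainvision", edf = "edf",
                     stop("cannot infer format from extension of ", path))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- switch(format,
                brainvision = read_brainvision(path),
                edf = read_edf(path))
  if (!is.null(blocks)) rec$blocks <- validate_blocks(blocks, recording_duration(rec))
  if (!is.na(subject_id)) rec$subject_id <- subject_id
  rec
}

# ---- BrainVision ----------------------------------------------------------

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("﻿", "", lines)
  section <- ""
  kv <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      kv[[section]] <- character()
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0 && nzchar(section)) {
      key <- trimws(substr(ln, 1, eq - 1))
      val <- trimws(substr(ln, eq + 1, nchar(ln)))
      kv[[section]][key] <- val
    }
  }
  kv
}

read_brainvision <- function(vhdr_path) {
  if (file.info(vhdr_path)$size == 0) stop("empty BrainVision header: ", vhdr_path)
  hdr <- parse_vhdr(vhdr_path)
  ci <- hdr[["Common Infos"]]
  if (is.null(ci) || is.na(ci["DataFile"]))
    stop("malformed BrainVision header (no [Common Infos]/DataFile): ", vhdr_path)
  nchan <- as.integer(ci["NumberOfChannels"])
  interval_us <- as.numeric(ci["SamplingInterval"])
  if (is.na(nchan) || nchan < 1L) stop("invalid NumberOfChannels in ", vhdr_path)
  if (is.na(interval_us) || interval_us <= 0)
    stop("invalid SamplingInterval in ", vhdr_path)
  rate <- 1e6 / interval_us
  orientation <- toupper(ci["DataOrientation"] %||% "MULTIPLEXED")
  bf <- hdr[["Binary Infos"]]
  binfmt <- toupper(bf["BinaryFormat"] %||% "IEEE_FLOAT_32")

  # Channel lines: Ch<i>=<label>,<ref>,<resolution>,<unit>
  chsec <- hdr[["Channel Infos"]]
  if (is.null(chsec) || length(chsec) < nchan)
    stop("BrainVision header lacks channel infos: ", vhdr_path)
  labels <- character(nchan); resol <- rep(1, nchan); unit <- rep("µV", nchan)
  for (i in seq_len(nchan)) {
    parts <- strsplit(chsec[[paste0("Ch", i)]], ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resol[i] <- as.numeric(parts[3])
    if (length(parts) >= 4 && nzchar(parts[4])) unit[i] <- parts[4]
  }

  datafile <- file.path(dirname(vhdr_path), ci["DataFile"])
  if (!file.exists(datafile)) stop("BrainVision data file not found: ", datafile)
  nbytes <- file.info(datafile)$size
  if (nbytes == 0) stop("empty BrainVision data file: ", datafile)
  con <- file(datafile, "rb"); on.exit(close(con))
  if (binfmt == "IEEE_FLOAT_32") {
    vals <- readBin(con, "numeric", n = nbytes / 4, size = 4, endian = "little")
  } else if (binfmt == "INT_16") {
    vals <- readBin(con, "integer", n = nbytes / 2, size = 2, signed = TRUE,
                    endian = "little")
  } else stop("unsupported BinaryFormat: ", binfmt)
  if (length(vals) %% nchan != 0)
    stop("data length not a multiple of channel count in ", datafile)
  npts <- length(vals) %/% nchan
  samples <- if (orientation == "MULTIPLEXED") {
    matrix(vals, nrow = nchan, ncol = npts)          # sample-major on disk
  } else {
    t(matrix(vals, nrow = npts, ncol = nchan))       # channel-major on disk
  }
  samples <- samples * resol
  # convert to microvolts where the header declares other units
  scale <- vapply(unit, unit_to_uv, numeric(1))
  samples <- samples * scale
  reference <- ci["Reference"]
  eeg_recording(samples, rate, labels,
                reference = if (is.na(reference)) "Cz" else reference)
}

unit_to_uv <- function(u) {
  switch(u, "µV" = 1, "uV" = 1, "mV" = 1e3, "V" = 1e6,
         stop("unknown amplitude unit: ", u))
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<basename>.vhdr`, `<basename>.vmrk` and `<basename>.eeg`
#' (multiplexed `IEEE_FLOAT_32`, resolution 1, microvolts). Block boundaries
#' are stored as `New Segment` markers in the `.vmrk` file.
#'
#' @param rec an [eeg_recording()].
#' @param basename output path without extension.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg  <- paste0(basename, ".eeg")
  nchan <- nrow(rec$samples)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nchan),
    paste0("SamplingInterval=", format(1e6 / rec$rate, scientific = FALSE)),
    paste0("Reference=", rec$reference),
    "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nchan), rec$channels))
  writeLines(hdr, vhdr, useBytes = TRUE)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]", "Codepage=UTF-8",
          paste0("DataFile=", basename(eeg)),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,0")
  if (nrow(rec$blocks)) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$blocks)) + 1L,
                        rec$blocks$task_id,
                        round(rec$blocks$start_s * rec$rate) + 1L))
  }
  writeLines(mk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  writeBin(as.numeric(rec$samples), con, size = 4, endian = "little")
  close(con)
  invisible(vhdr)
}

# ---- EDF ------------------------------------------------------------------

# Minimal EDF (not EDF+) support: 16-bit samples with per-channel
# physical/digital scaling, one data record per second.

read_edf <- function(path) {
  sz <- file.info(path)$size
  if (sz == 0) stop("empty EDF file: ", path)
  if (sz < 256) stop("malformed EDF header (too short): ", path)
  con <- file(path, "rb"); on.exit(close(con))
  rs <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- rs(8)
  rs(80); rs(80); rs(8); rs(8)                 # patient, recording, date, time
  header_bytes <- as.integer(rs(8))
  rs(44)
  n_records <- as.integer(rs(8))
  record_dur <- as.numeric(rs(8))
  ns <- as.integer(rs(4))
  if (is.na(ns) || ns < 1 || is.na(n_records) || is.na(record_dur) ||
      record_dur <= 0)
    stop("malformed EDF header: ", path)
  labels <- vapply(seq_len(ns), function(i) rs(16), "")
  for (i in seq_len(ns)) rs(80)                # transducer
  units <- vapply(seq_len(ns), function(i) rs(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rs(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rs(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rs(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rs(8), ""))
  for (i in seq_len(ns)) rs(80)                # prefiltering
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rs(8), ""))
  for (i in seq_len(ns)) rs(32)                # reserved
  if (length(unique(nsamp)) != 1L)
    stop("mixed per-channel sampling rates are not supported: ", path)
  rate <- nsamp[1] / record_dur
  gain <- (pmax - pmin) / (dmax - dmin)
  offset <- pmin - gain * dmin
  seek(con, header_bytes)
  raw16 <- readBin(con, "integer", n = n_records * sum(nsamp), size = 2,
                   signed = TRUE, endian = "little")
  if (length(raw16) < n_records * sum(nsamp))
    stop("EDF data truncated: ", path)
  samples <- matrix(0, nrow = ns, ncol = n_records * nsamp[1])
  for (r in seq_len(n_records)) {
    base <- (r - 1L) * sum(nsamp)
    for (ch in seq_len(ns)) {
      idx <- base + (ch - 1L) * nsamp[1] + seq_len(nsamp[1])
      samples[ch, (r - 1L) * nsamp[1] + seq_len(nsamp[1])] <-
        raw16[idx] * gain[ch] + offset[ch]
    }
  }
  scale <- vapply(units, function(u) if (u %in% c("uV", "µV", "")) 1
                  else unit_to_uv(u), numeric(1))
  eeg_recording(samples * scale, rate, labels, reference = "Cz")
}

#' Write a recording as EDF
#'
#' Minimal EDF writer: 16-bit samples, one data record per second, physical
#' range set per channel to cover the data. Quantization to 16 bits is lossy
#' (relative error about 3e-5 of the channel range); use
#' [write_brainvision()] for exact float storage.
#'
#' @param rec an [eeg_recording()]. Duration must be a whole number of
#'   seconds.
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$samples)
  npts <- ncol(rec$samples)
  if (npts %% rec$rate != 0)
    stop("EDF writer requires whole-second recordings")
  n_records <- npts / rec$rate
  nsamp <- as.integer(rec$rate)
  prng <- apply(abs(rec$samples), 1, max)
  prng <- ifelse(prng <= 0, 1, prng * 1.0001)
  dig <- 32767
  con <- file(path, "wb"); on.exit(close(con))
  ws <- function(x, n) {
    s <- sprintf(paste0("%-", n, "s"), substr(as.character(x), 1, n))
    writeBin(charToRaw(s), con)
  }
  header_bytes <- 256 + ns * 256
  ws("0", 8); ws("X", 80); ws("X", 80)
  ws("01.01.26", 8); ws("00.00.00", 8)
  ws(header_bytes, 8); ws("", 44); ws(n_records, 8); ws("1", 8); ws(ns, 4)
  for (l in rec$channels) ws(l, 16)
  for (i in seq_len(ns)) ws("AgAgCl", 80)
  for (i in seq_len(ns)) ws("uV", 8)
  for (p in prng) ws(formatC(-p, digits = 7, width = 8, format = "g"), 8)
  for (p in prng) ws(formatC(p, digits = 7, width = 8, format = "g"), 8)
  for (i in seq_len(ns)) ws(-dig, 8)
  for (i in seq_len(ns)) ws(dig, 8)
  for (i in seq_len(ns)) ws("BP:0.5-40Hz", 80)
  for (i in seq_len(ns)) ws(nsamp, 8)
  for (i in seq_len(ns)) ws("", 32)
  # re-read the ASCII physical ranges so scaling matches what a reader sees
  pneg <- as.numeric(formatC(-prng, digits = 7, width = 8, format = "g"))
  ppos <- as.numeric(formatC(prng, digits = 7, width = 8, format = "g"))
  gain <- (ppos - pneg) / (2 * dig)
  for (r in seq_len(n_records)) {
    cols <- (r - 1L) * nsamp + seq_len(nsamp)
    for (ch in seq_len(ns)) {
      d <- as.integer(round(rec$samples[ch, cols] / gain[ch]))
      d <- as.integer(pmin(pmax(d, -dig), dig))
      writeBin(d, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
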