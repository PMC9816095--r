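# Minimal EDF (European Data Format) I/O for single-channel ECoG.
#
# EDF stores 16-bit integers mapped linearly between a physical and a digital
# range declared in the ASCII header. The writer fixes the physical range at
# +/- 5000 uV, which covers the amplitudes produced by the simulator and makes
# the quantization step (10000/65535 ~ 0.153 uV) deterministic for round-trip
# tests. Experiment metadata that EDF headers cannot carry (condition,
# experiment-clock start, injection timeline) travels in a YAML sidecar
# written next to the file.

edf_phys_min <- -5000
edf_phys_max <- 5000
edf_dig_min <- -32768L
edf_dig_max <- 32767L

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a recording to an EDF file
#'
#' Writes the voltage trace as one EDF signal (physical dimension uV, fixed
#' physical range of +/-5000 uV, 1-s data records) plus a YAML sidecar
#' (`<path>.yaml`) holding subject id, condition, `t0` and the injection
#' timeline. The last data record is zero-padded; the true sample count is
#' recorded in the sidecar so [read_recording()] restores the exact length.
#'
#' @param rec an [recording()] object; `fs` must be a whole number.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ecosyn_recording"))
  if (rec$fs != round(rec$fs))
    abort_validation("EDF writer requires an integer sampling rate")
  if (any(rec$samples < edf_phys_min | rec$samples > edf_phys_max))
    abort_validation(sprintf("samples exceed the EDF physical range [%g, %g] uV",
                             edf_phys_min, edf_phys_max))
  spr <- as.integer(rec$fs)            # samples per 1-s record
  n <- length(rec$samples)
  nrec <- ceiling(n / spr)
  x <- c(rec$samples, numeric(nrec * spr - n))
  dig <- as.integer(round((x - edf_phys_min) / (edf_phys_max - edf_phys_min) *
                            (edf_dig_max - edf_dig_min) + edf_dig_min))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad(paste("condition", rec$condition), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * 2L, 8),
    edf_pad("", 44),
    edf_pad(nrec, 8),
    edf_pad("1", 8),
    edf_pad("1", 4),
    # signal header block (one signal)
    edf_pad("ECoG", 16), edf_pad("screw electrode", 80), edf_pad("uV", 8),
    edf_pad(edf_phys_min, 8), edf_pad(edf_phys_max, 8),
    edf_pad(edf_dig_min, 8), edf_pad(edf_dig_max, 8),
    edf_pad("HP:1Hz LP:500Hz", 80), edf_pad(spr, 8), edf_pad("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")

  yaml::write_yaml(list(
    subject_id = rec$subject_id, condition = rec$condition,
    t0 = rec$t0, n_samples = n,
    timeline = unclass(rec$timeline)), sidecar_path(path))
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Reads the first signal of an EDF/EDF+ file as the ECoG trace, at exactly
#' the stored sampling rate and scale (no resampling, no rescaling). If the
#' YAML sidecar written by [write_recording()] is present it supplies subject
#' id, condition, `t0`, true sample count and timeline; otherwise the default
#' [timeline()] is assumed with a warning.
#'
#' @param path EDF file path.
#' @return an [recording()] object.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort_format(paste("no such file:", path))
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) abort_format("file too short to be EDF")
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256L) abort_format("truncated EDF header")
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  nrec <- suppressWarnings(as.integer(fld(fixed, 237, 8)))
  recdur <- suppressWarnings(as.numeric(fld(fixed, 245, 8)))
  ns <- suppressWarnings(as.integer(fld(fixed, 253, 4)))
  if (is.na(ns)) abort_format("unparsable EDF header")
  if (ns < 1L) abort_validation("EDF file declares zero signals")
  if (is.na(nrec) || is.na(recdur) || recdur <= 0)
    abort_format("unparsable EDF record geometry")
  sig <- readChar(con, 256L * ns, useBytes = TRUE)
  if (nchar(sig, type = "bytes") < 256L * ns) abort_format("truncated EDF signal header")
  seg <- function(block_from, len, i) fld(sig, (block_from - 1L) * ns + (i - 1L) * len + 1L, len)
  # per-signal blocks: label 16, transducer 80, dim 8, pmin 8, pmax 8,
  # dmin 8, dmax 8, prefilter 80, spr 8, reserved 32
  off <- cumsum(c(0, 16, 80, 8, 8, 8, 8, 80, 8)) * ns
  field_at <- function(k, len, i) fld(sig, off[k] + (i - 1L) * len + 1L, len)
  pmin <- as.numeric(field_at(4, 8, 1)); pmax <- as.numeric(field_at(5, 8, 1))
  dmin <- as.numeric(field_at(6, 8, 1)); dmax <- as.numeric(field_at(7, 8, 1))
  spr <- as.integer(vapply(seq_len(ns), function(i) as.integer(field_at(9, 8, i)), 1L))
  if (anyNA(c(pmin, pmax, dmin, dmax)) || anyNA(spr) || dmax <= dmin)
    abort_format("unparsable EDF signal header fields")
  subject_id <- fld(fixed, 9, 80)

  rec_words <- sum(spr)
  want <- nrec * rec_words
  raw_all <- readBin(con, "integer", n = want, size = 2L, signed = TRUE,
                     endian = "little")
  if (length(raw_all) < want) abort_format("EDF data shorter than header declares")
  # interleaved records: take signal 1's chunk from each record
  idx <- outer(seq_len(spr[1L]), (seq_len(nrec) - 1L) * rec_words, `+`)
  dig <- raw_all[as.vector(idx)]
  x <- (dig - dmin) / (dmax - dmin) * (pmax - pmin) + pmin
  fs <- spr[1L] / recdur

  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    tl <- do.call(timeline, meta$timeline)
    if (!is.null(meta$n_samples)) x <- x[seq_len(min(length(x), meta$n_samples))]
    recording(x, fs, subject_id = meta$subject_id, condition = meta$condition,
              t0 = meta$t0, tl = tl)
  } else {
    warning("no timeline sidecar found for ", path,
            "; assuming the default injection timeline", call. = FALSE)
    recording(x, fs, subject_id = subject_id, condition = "sham", t0 = 0,
              tl = timeline())
  }
}
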