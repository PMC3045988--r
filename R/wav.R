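## Minimal RIFF/WAVE reader and writer (mono, PCM16 or IEEE float32).
## Heart-sound recordings are single channel, so only mono is supported.

#' Write a heart-sound record to a WAV file
#'
#' Writes mono PCM 16-bit (samples clipped to \[-1, 1\]) or IEEE float32.
#' When the record carries a label or truth annotation, a JSON sidecar
#' (`<path>.json`) holding `{label, cycle_length_samples, event_onsets}` is
#' written alongside.
#'
#' @param record a [heart_sound_record()].
#' @param path output file path.
#' @param format `"pcm16"` or `"float32"`.
#' @param sidecar write the JSON annotation sidecar (default: only when the
#'   record has a label or truth annotation).
#' @return `path`, invisibly.
#' @export
write_wav <- function(record, path, format = c("pcm16", "float32"),
                      sidecar = !is.na(record$label) || !is.null(record$truth)) {
  format <- match.arg(format)
  x <- record$samples
  fs <- as.integer(round(record$fs))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  bits <- if (format == "pcm16") 16L else 32L
  fmt_code <- if (format == "pcm16") 1L else 3L
  block <- bits %/% 8L
  data_bytes <- length(x) * block
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  if (sidecar) {
    ann <- list(label = if (is.na(record$label)) NULL else record$label,
                cycle_length_samples = record$truth$cycle_length,
                event_onsets = list(s1 = record$truth$s1_onsets,
                                    s2 = record$truth$s2_onsets))
    jsonlite::write_json(ann, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a WAV file as a heart-sound record
#'
#' Reads mono PCM16 or float32 WAV. If a `<path>.json` sidecar written by
#' [write_wav()] exists, its label and truth annotation are attached.
#'
#' @param path WAV file path.
#' @return a [heart_sound_record()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; samples <- NULL; fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      n_chan <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
      if (n_chan != 1L) stop("only mono WAV supported", call. = FALSE)
      fmt <- list(code = fmt_code, bits = bits)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$code == 1L && fmt$bits == 16L) {
        raw16 <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                         endian = "little", signed = TRUE)
        samples <- raw16 / 32767
      } else if (fmt$code == 3L && fmt$bits == 32L) {
        samples <- readBin(con, numeric(), n = sz %/% 4L, size = 4,
                           endian = "little")
      } else stop("unsupported WAV encoding (need PCM16 or float32)", call. = FALSE)
      break
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2L))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  label <- NA_integer_; truth <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    ann <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(ann$label)) label <- as.integer(ann$label)
    if (!is.null(ann$cycle_length_samples))
      truth <- list(cycle_length = as.integer(ann$cycle_length_samples),
                    s1_onsets = as.integer(ann$event_onsets$s1),
                    s2_onsets = as.integer(ann$event_onsets$s2))
  }
  heart_sound_record(samples, fs, label = label, truth = truth)
}
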