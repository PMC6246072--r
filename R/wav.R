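#' Read a WAV file
#'
#' Supports PCM 16/24-bit and IEEE float32, mono or stereo. Mono files
#' return a [mono_signal()], stereo files a [binaural_signal()] (channel 1 =
#' left). Sampling-rate metadata is preserved in the returned object.
#'
#' @param path file path
#' @return `mono_signal` or `binaural_signal`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(fmt_raw[1:2]) * c(1L, 256L)),
        n_channels   = sum(as.integer(fmt_raw[3:4]) * c(1L, 256L)),
        sample_rate  = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(fmt_raw[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1)   # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)

  nch <- fmt$n_channels
  if (!nch %in% 1:2) stop("only mono or stereo WAV supported")
  if (fmt$audio_format == 1 && fmt$bits == 16) {
    v <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1 && fmt$bits == 24) {
    n <- length(data_raw) / 3
    b <- matrix(as.integer(data_raw), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    v <- readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format,
         ", ", fmt$bits, " bit)")
  }
  if (nch == 1) return(mono_signal(v, fmt$sample_rate))
  binaural_signal(mono_signal(v[c(TRUE, FALSE)], fmt$sample_rate),
                  mono_signal(v[c(FALSE, TRUE)], fmt$sample_rate))
}

#' Write a WAV file
#'
#' @param x `mono_signal` or `binaural_signal`
#' @param path output path
#' @param bits 16 or 24 for integer PCM, 32 for IEEE float
#' @return `path`, invisibly
#' @export
write_wav <- function(x, path, bits = 32) {
  if (inherits(x, "binaural_signal")) {
    rate <- x$rate
    v <- as.vector(rbind(x$left$samples, x$right$samples))
    nch <- 2L
  } else if (inherits(x, "mono_signal")) {
    rate <- x$rate
    v <- x$samples
    nch <- 1L
  } else stop("x must be a mono_signal or binaural_signal")
  if (!bits %in% c(16, 24, 32)) stop("bits must be 16, 24 or 32")

  fmt_code <- if (bits == 32) 3L else 1L
  bytes_per <- bits / 8
  data_size <- length(v) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(nch, con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * nch * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(pmax(pmin(round(v * 32768), 32767), -32768)),
             con, 2, endian = "little")
  } else if (bits == 24) {
    iv <- pmax(pmin(round(v * 8388608), 8388607), -8388608)
    iv <- ifelse(iv < 0, iv + 16777216, iv)
    b <- rbind(iv %% 256, (iv %/% 256) %% 256, (iv %/% 65536) %% 256)
    writeBin(as.raw(as.vector(b)), con)
  } else {
    writeBin(v, con, 4, endian = "little")
  }
  invisible(path)
}
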