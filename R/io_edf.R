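#' Construct a PSG recording
#'
#' A recording is a set of physiological channels (EEG, EOG, EMG, ...) with
#' per-channel sampling rate and samples in microvolts. All channels must
#' span the same duration to within one sample period.
#'
#' @param channels List of channels, each a list with elements `label`
#'   (character), `role` (one of `"EEG"`, `"EOG"`, `"EMG"`, `"other"`),
#'   `samples` (numeric vector, microvolts) and `rate` (Hz).
#' @param start_time Optional `POSIXct` start time.
#' @return Object of class `"psg_recording"`.
#' @export
recording <- function(channels, start_time = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  durs <- vapply(channels, function(ch) {
    stopifnot(is.numeric(ch$samples), is.numeric(ch$rate), ch$rate > 0)
    length(ch$samples) / ch$rate
  }, numeric(1))
  max_period <- max(vapply(channels, function(ch) 1 / ch$rate, numeric(1)))
  if (diff(range(durs)) > max_period + 1e-9) {
    stop("channels span unequal durations: ", paste(round(durs, 3), collapse = ", "), " s")
  }
  roles <- vapply(channels, function(ch) ch$role %||% "other", character(1))
  for (r in c("EEG", "EOG", "EMG")) {
    if (sum(roles == r) > 1L) stop("role ", r, " assigned more than once")
  }
  structure(list(channels = channels, start_time = start_time,
                 duration_s = max(durs)),
            class = "psg_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %.1f s, %d channel(s)\n", x$duration_s,
              length(x$channels)))
  for (ch in x$channels) {
    cat(sprintf("  [%s] %-16s %g Hz, %d samples\n", ch$role, ch$label,
                ch$rate, length(ch$samples)))
  }
  invisible(x)
}

# internal: fetch the single channel with a given role
get_channel <- function(rec, role) {
  for (ch in rec$channels) if (identical(ch$role, role)) return(ch)
  NULL
}

# ---- EDF binary format ------------------------------------------------------
# EDF: 256-byte fixed header + 256 bytes per signal, then data records of
# little-endian int16 samples scaled linearly from digital to physical range.

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n)
}

read_edf_header <- function(con) {
  hdr <- readChar(con, 256, useBytes = TRUE)
  version <- trimws(substr(hdr, 1, 8))
  if (!identical(version, "0")) {
    stop("not an EDF file (version field is '", version, "', expected '0')")
  }
  n_records <- as.integer(trimws(substr(hdr, 237, 244)))
  record_dur <- as.numeric(trimws(substr(hdr, 245, 252)))
  ns <- as.integer(trimws(substr(hdr, 253, 256)))
  if (is.na(ns) || ns < 1) stop("not a valid EDF file: bad signal count")
  sig_raw <- readChar(con, 256 * ns, useBytes = TRUE)
  # sequential per-field blocks: labels(16) transducer(80) dim(8) pmin(8)
  # pmax(8) dmin(8) dmax(8) prefilter(80) nsamp(8) reserved(32)
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32)
  vals <- vector("list", length(widths))
  pos <- 1
  for (k in seq_along(widths)) {
    w <- widths[k]
    block <- substr(sig_raw, pos, pos + w * ns - 1)
    vals[[k]] <- vapply(seq_len(ns), function(i) {
      trimws(substr(block, (i - 1) * w + 1, i * w))
    }, character(1))
    pos <- pos + w * ns
  }
  list(n_records = n_records, record_dur = record_dur, ns = ns,
       labels = vals[[1]], phys_dim = vals[[3]],
       phys_min = as.numeric(vals[[4]]), phys_max = as.numeric(vals[[5]]),
       dig_min = as.numeric(vals[[6]]), dig_max = as.numeric(vals[[7]]),
       n_samp = as.integer(vals[[9]]))
}

# unit handling: trust the EDF physical-dimension field; accept uV (and the
# Unicode micro variants), convert mV to uV, refuse anything else so
# amplitude-dependent features never run on mis-scaled data
edf_unit_factor <- function(dim, label) {
  d <- tolower(dim)
  if (d %in% c("uv", "µv", "μv", "")) return(1)
  if (d == "mv") return(1000)
  stop("channel '", label, "' has physical dimension '", dim,
       "'; expected uV or mV (no silent unit guessing)")
}

#' Read selected channels from an EDF file
#'
#' Reads a European Data Format (EDF/EDF+) PSG file and returns the channels
#' requested by role, converted to microvolts. Each channel keeps its native
#' sampling rate. Physical units are taken from the EDF physical-dimension
#' field: `uV` is used as-is, `mV` is converted (x1000), anything else is an
#' error — amplitude-dependent features fail silently on mis-scaled input,
#' so no unit guessing is done.
#'
#' @param path EDF file path.
#' @param channel_spec Named character vector mapping roles to channel
#'   labels, e.g. `c(EEG = "C4-M1", EOG = "EOG-L", EMG = "EMG-Chin")`.
#'   Only requested roles are read.
#' @return A [recording()] with one channel per requested role.
#' @examples
#' \donttest{
#' night <- simulate_night(seed = 1, n_epochs = 20)
#' f <- tempfile(fileext = ".edf")
#' write_edf(night$recording, f)
#' rec <- read_recording(f, c(EEG = "C4-M1"))
#' }
#' @export
read_recording <- function(path, channel_spec) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(length(channel_spec) >= 1L, !is.null(names(channel_spec)))
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  missing_lab <- setdiff(unname(channel_spec), h$labels)
  if (length(missing_lab)) {
    stop("channel label(s) not in EDF file: ",
         paste(missing_lab, collapse = ", "),
         "; available: ", paste(h$labels, collapse = ", "))
  }
  rec_size <- sum(h$n_samp)
  data <- readBin(con, "integer", n = rec_size * h$n_records, size = 2,
                  signed = TRUE, endian = "little")
  offsets <- c(0, cumsum(h$n_samp))
  channels <- vector("list", length(channel_spec))
  for (k in seq_along(channel_spec)) {
    i <- match(channel_spec[[k]], h$labels)
    gain <- (h$phys_max[i] - h$phys_min[i]) / (h$dig_max[i] - h$dig_min[i])
    scale <- edf_unit_factor(h$phys_dim[i], h$labels[i])
    idx <- as.vector(outer(seq_len(h$n_samp[i]) + offsets[i],
                           (seq_len(h$n_records) - 1) * rec_size, `+`))
    dig <- data[idx]
    phys <- (h$phys_min[i] + (dig - h$dig_min[i]) * gain) * scale
    channels[[k]] <- list(label = h$labels[i], role = names(channel_spec)[k],
                          samples = phys, rate = h$n_samp[i] / h$record_dur)
  }
  recording(channels)
}

#' Write a recording to an EDF file
#'
#' Writes 16-bit EDF with one-second data records. Samples are linearly
#' quantized into the channel's physical range, so a write-then-read round
#' trip reproduces samples to within half a quantization step. The duration
#' is truncated to a whole number of one-second records.
#'
#' @param rec A [recording()]; every channel rate must be a whole number.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "psg_recording"))
  ns <- length(rec$channels)
  rates <- vapply(rec$channels, `[[`, numeric(1), "rate")
  if (any(abs(rates - round(rates)) > 1e-9)) {
    stop("EDF writing requires integer per-second sampling rates")
  }
  n_records <- floor(min(vapply(rec$channels, function(ch)
    length(ch$samples) / ch$rate, numeric(1))))
  if (n_records < 1) stop("recording shorter than one EDF data record (1 s)")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_records, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  pmin_ <- numeric(ns); pmax_ <- numeric(ns)
  for (i in seq_len(ns)) {
    rng <- range(rec$channels[[i]]$samples)
    half <- max(abs(rng), 1)
    pmin_[i] <- -half; pmax_[i] <- half
  }
  put <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_pad, character(1), n = width),
                    collapse = ""), con, eos = NULL, useBytes = TRUE)
  }
  put(vapply(rec$channels, `[[`, character(1), "label"), 16)
  put(rep("", ns), 80)
  put(rep("uV", ns), 8)
  put(formatC(pmin_, format = "g", digits = 6), 8)
  put(formatC(pmax_, format = "g", digits = 6), 8)
  put(rep("-32768", ns), 8)
  put(rep("32767", ns), 8)
  put(rep("", ns), 80)
  put(as.character(round(rates)), 8)
  put(rep("", ns), 32)
  # digital conversion per channel, then interleave by record
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- rec$channels[[i]]$samples[seq_len(n_records * rates[i])]
    d <- round((x - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(32767, pmax(-32768, d)))
  }
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      s <- rates[i]
      writeBin(dig[[i]][((r - 1) * s + 1):(r * s)], con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
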